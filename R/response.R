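PATTERNS <- c("UNI_ATTRACT", "UNI_REPEL", "BI_REPEL_TO_ATTRACT", "BAR")

# Sign of the response numerator N(f) = wA hA (aI f + cI) - wI hI (aA f + cA);
# denominators are positive, so sign(dE/E*) = sign(g_eff) * sign(N(f)).
# N is linear in f, hence at most one zero crossing: the two f-limits
# classify the whole curve.
numerator_sign <- function(f, hA, hI, wA, wI, pA, pI) {
  if (is.infinite(f)) return(sign(wA * hA * pI$alpha - wI * hI * pA$alpha))
  if (f == 0 && pA$c == 0 && pI$c == 0)   # limit f -> 0+ when both c vanish
    return(sign(wA * hA / pA$alpha - wI * hI / pI$alpha))
  sign(wA * hA * (pI$alpha * f + pI$c) - wI * hI * (pA$alpha * f + pA$c))
}

# Pattern from the signs of the response at the two G-limits. Zero signs
# (measure-zero boundaries) are tie-broken away from BAR.
pattern_from_signs <- function(s_low, s_high) {
  if (s_low > 0 && s_high < 0) return("BAR")
  if (s_low >= 0 && s_high >= 0) return("UNI_ATTRACT")
  if (s_low <= 0 && s_high <= 0) return("UNI_REPEL")
  "BI_REPEL_TO_ATTRACT"
}

# Classify the concentration-dependent response in G-space: evaluate the
# numerator sign at the f-values reached as G -> 0 and G -> Inf, flip by the
# (constant) sign of df/dG and of the cue gradient.
classify_response <- function(pA, pI, L, m = receptor_model("identity"),
                              dGdx = 1, mode = "reduced", n_terms = 500) {
  mode <- match_mode(mode)
  hA <- as.numeric(h_series(pA$D / pA$k, L, n_terms))
  hI <- as.numeric(h_series(pI$D / pI$k, L, n_terms))
  wA <- if (mode == "physical") pA$alpha else 1
  wI <- if (mode == "physical") pI$alpha else 1
  lim <- receptor_limits(m)
  sgn <- lim$sgn * sign(dGdx)
  s_low <- sgn * numerator_sign(lim$f0, hA, hI, wA, wI, pA, pI)
  s_high <- sgn * numerator_sign(lim$finf, hA, hI, wA, wI, pA, pI)
  pattern_from_signs(s_low, s_high)
}

#' Condition for the attraction-to-repulsion switch
#'
#' The bidirectional attraction-to-repulsion (BAR) pattern - attraction
#' below and repulsion above a preferred concentration - occurs exactly
#' when \deqn{c_A / c_I < \eta < \alpha_A / \alpha_I,}
#' with \eqn{\eta = h(D_A/k_A) / h(D_I/k_I)}. Since `h` is strictly
#' decreasing, the interval position is set by the relative spatial reach
#' (`sqrt(D/k)`) of the two species. Degenerate ratios (zero denominators)
#' are handled as infinities; both strict inequalities must hold.
#'
#' The inequality is the reduced-mode boundary; classification under the
#' physical convention is available through [response_curve()].
#'
#' @param pA,pI [species_params()] for activator and inhibitor.
#' @param L Growth-cone length (um).
#' @param n_terms Odd modes retained in the h-series.
#' @return An object of class `"bar_condition"`: list with `eta`, `lower`
#'   (`c_A/c_I`), `upper` (`alpha_A/alpha_I`) and logical `satisfied`.
#' @examples
#' pre <- table1_preset("fig3E")
#' bar_condition(pre$pA, pre$pI, L = pre$L)
#' @export
bar_condition <- function(pA, pI, L = 10, n_terms = 500) {
  assert_species(pA, "pA"); assert_species(pI, "pI")
  hA <- as.numeric(h_series(pA$D / pA$k, L, n_terms))
  hI <- as.numeric(h_series(pI$D / pI$k, L, n_terms))
  ratio <- function(num, den) {
    if (den > 0) num / den else if (num > 0) Inf else NaN
  }
  eta <- hA / hI
  lower <- ratio(pA$c, pI$c)
  upper <- ratio(pA$alpha, pI$alpha)
  satisfied <- isTRUE(lower < eta) && isTRUE(eta < upper)
  structure(list(eta = eta, lower = lower, upper = upper,
                 satisfied = satisfied, L = L),
            class = "bar_condition")
}

#' @export
print.bar_condition <- function(x, ...) {
  cat(sprintf("BAR condition: c_A/c_I = %.4g %s eta = %.4g %s alpha_A/alpha_I = %.4g\n",
              x$lower, if (isTRUE(x$lower < x$eta)) "<" else ">=", x$eta,
              if (isTRUE(x$eta < x$upper)) "<" else ">=", x$upper))
  cat(if (x$satisfied) "  satisfied: attraction-to-repulsion switch exists\n"
      else "  not satisfied\n")
  invisible(x)
}

#' Signal threshold of the preferred concentration
#'
#' At the preferred concentration the response vanishes; the transduced
#' signal there equals \deqn{\gamma = (\eta c_I - c_A) / (\alpha_A - \eta \alpha_I),}
#' so `f(R, G_pref) = gamma` for any transfer function. Under the physical
#' convention `eta` is replaced by `alpha_A h_A / (alpha_I h_I)`. `gamma`
#' is positive exactly when the BAR condition holds; outside that region it
#' may be negative or correspond to the unstable repulsion-to-attraction
#' crossing, and a warning is raised.
#'
#' @inheritParams bar_condition
#' @param mode `"reduced"` or `"physical"`.
#' @return The threshold signal level gamma (a.u., same scale as f).
#' @examples
#' pre <- table1_preset("fig3E")
#' gamma_threshold(pre$pA, pre$pI, L = pre$L)
#' @export
gamma_threshold <- function(pA, pI, L = 10, mode = "reduced", n_terms = 500) {
  assert_species(pA, "pA"); assert_species(pI, "pI")
  mode <- match_mode(mode)
  hA <- as.numeric(h_series(pA$D / pA$k, L, n_terms))
  hI <- as.numeric(h_series(pI$D / pI$k, L, n_terms))
  wA <- if (mode == "physical") pA$alpha else 1
  wI <- if (mode == "physical") pI$alpha else 1
  eta_w <- (wA * hA) / (wI * hI)
  den <- pA$alpha - eta_w * pI$alpha
  if (den == 0)
    stop("degenerate threshold: alpha_A - eta * alpha_I = 0", call. = FALSE)
  gamma <- (eta_w * pI$c - pA$c) / den
  if (!isTRUE(gamma > 0))
    warning("gamma <= 0: the BAR condition does not hold for these parameters",
            call. = FALSE)
  gamma
}

#' Preferred cue concentration for a transfer function
#'
#' Solves `f(R, G_pref) = gamma` for the cue concentration. Closed forms:
#' identity `G_pref = gamma`; bound-active `gamma K / (R - gamma)` and
#' unbound-active `(K / gamma) (R - gamma)`, both requiring `R > gamma`
#' (otherwise the saturating signal never reaches, or never falls to, the
#' threshold and no preference exists); competitive
#' `(gamma / R_c) (K + R_c + R)`. `method = "numeric"` instead brackets the
#' root of `f(R, G) = gamma` on a log-concentration grid and bisects; it
#' must agree with the closed forms to near machine precision.
#'
#' @param m A [receptor_model()].
#' @param gamma Threshold signal level, `> 0` (see [gamma_threshold()]).
#' @param method `"closed"` (default) or `"numeric"`.
#' @return `G_pref` (uM), or `NA` with attribute `"reason"` when no
#'   preferred concentration exists for this receptor level.
#' @examples
#' preferred_concentration(receptor_model("bound_active", R = 4, K = 1), 2)
#' @export
preferred_concentration <- function(m, gamma, method = c("closed", "numeric")) {
  assert_receptor(m)
  method <- match.arg(method)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("gamma must be a finite scalar > 0", call. = FALSE)
  absent <- function(reason) structure(NA_real_, reason = reason)
  if (m$variant %in% c("bound_active", "unbound_active") && m$R <= gamma)
    return(absent(sprintf(
      "receptor level R = %g does not exceed gamma = %g; the saturating signal never crosses the threshold",
      m$R, gamma)))
  if (method == "closed") {
    return(switch(m$variant,
      identity = gamma,
      bound_active = gamma * m$K / (m$R - gamma),
      unbound_active = (m$K / gamma) * (m$R - gamma),
      competitive = (gamma / m$Rc) * (m$K + m$Rc + m$R)))
  }
  g <- function(G) activation(m, G) - gamma
  bisect_log(g, 1e-12, 1e12)
}

# Bisection on log10(G) for a continuous monotone-crossing function.
bisect_log <- function(fun, lo, hi, iter = 100L) {
  flo <- fun(lo); fhi <- fun(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    return(structure(NA_real_,
                     reason = "no sign change on the bracketing interval"))
  llo <- log10(lo); lhi <- log10(hi)
  for (i in seq_len(iter)) {
    mid <- (llo + lhi) / 2
    fm <- fun(10^mid)
    if (fm == 0) return(10^mid)
    if (fm * flo < 0) lhi <- mid else { llo <- mid; flo <- fm }
  }
  10^((llo + lhi) / 2)
}

#' Receptor-level sensitivity of the preferred concentration
#'
#' Implicit differentiation of `f(R, G_pref) = gamma` gives
#' `dG_pref/dR = -(df/dR) / (df/dG)` at `(R, G_pref)`: negative for
#' bound-active receptors (more receptor, lower preferred concentration;
#' the type 1 law), positive for unbound-active and competitive receptors
#' (type 2), zero for the identity (no receptor stage).
#'
#' @param m A [receptor_model()].
#' @param G_pref Preferred concentration (uM) at which to evaluate.
#' @return `dG_pref/dR` (uM per a.u. receptor).
#' @export
gpref_sensitivity <- function(m, G_pref) {
  assert_receptor(m)
  if (!is.numeric(G_pref) || length(G_pref) != 1L || !is.finite(G_pref) ||
      G_pref < 0)
    stop("G_pref must be a finite scalar >= 0", call. = FALSE)
  G <- G_pref
  dfdR <- switch(m$variant,
    identity = 0,
    bound_active = G / (m$K + G),
    unbound_active = m$K / (m$K + G),
    competitive = -m$Rc * G / (m$K + m$Rc + m$R)^2)
  dfdG <- activation_slope(m, G, 1)
  if (dfdG == 0) stop("df/dG = 0: sensitivity undefined", call. = FALSE)
  -dfdR / dfdG
}

#' Concentration-dependent response curve and its pattern
#'
#' Evaluates the relative polarity dE/E* on a log-spaced grid of baseline
#' cue concentrations, classifies the curve into one of the four patterns
#' from the analytic concentration limits (not from the sampled
#' endpoints), and locates the preferred concentration by bracketed
#' bisection on log G when the pattern crosses zero.
#'
#' @param m A [receptor_model()].
#' @param pA,pI [species_params()].
#' @param L Growth-cone length (um).
#' @param dGdx Extracellular cue gradient (uM/um), fixed along the curve.
#' @param G_range Positive concentration range (uM), length 2.
#' @param n_points Grid size, `>= 3`.
#' @param mode `"reduced"` or `"physical"`.
#' @param n_terms Odd modes in the h-series.
#' @return An object of class `"response_curve"`: `G_star_values`,
#'   `response_values`, `pattern` (one of `"UNI_ATTRACT"`, `"UNI_REPEL"`,
#'   `"BI_REPEL_TO_ATTRACT"`, `"BAR"`), `G_pref` (`NA` when the response
#'   never crosses zero), plus the model ingredients.
#' @examples
#' pre <- table1_preset("fig3E")
#' rc <- response_curve(receptor_model("identity"), pre$pA, pre$pI, L = pre$L)
#' rc$pattern
#' @export
response_curve <- function(m, pA, pI, L = 10, dGdx = 0.75,
                           G_range = c(1e-2, 1e3), n_points = 201,
                           mode = "reduced", n_terms = 500) {
  assert_receptor(m); assert_species(pA, "pA"); assert_species(pI, "pI")
  mode <- match_mode(mode)
  if (length(G_range) != 2L || any(!is.finite(G_range)) || any(G_range < 0) ||
      G_range[1] >= G_range[2])
    stop("G_range must be an increasing positive pair", call. = FALSE)
  if (n_points < 3) stop("n_points must be >= 3", call. = FALSE)
  if (G_range[1] == 0) {
    if (pA$c == 0 && pI$c == 0) {
      warning("G* = 0 is degenerate when c_A = c_I = 0; excluded from the grid",
              call. = FALSE)
      G_range[1] <- G_range[2] * 1e-6
    } else stop("G_range must be strictly positive (log-spaced grid)",
                call. = FALSE)
  }
  G <- 10^seq(log10(G_range[1]), log10(G_range[2]), length.out = n_points)
  ev <- polarity_evaluator(pA, pI, L, mode, n_terms)
  f <- activation(m, G)
  g <- activation_slope(m, G, dGdx)
  resp <- ev(f, g)
  pattern <- classify_response(pA, pI, L, m, dGdx, mode, n_terms)
  G_pref <- NA_real_
  if (pattern %in% c("BAR", "BI_REPEL_TO_ATTRACT")) {
    cross <- which(resp[-1] * resp[-n_points] < 0)
    bracket <- if (length(cross)) c(G[cross[1]], G[cross[1] + 1]) else
      c(G_range[1] * 1e-6, G_range[2] * 1e6)
    G_pref <- as.numeric(bisect_log(function(gg)
      ev(activation(m, gg), activation_slope(m, gg, dGdx)), bracket[1],
      bracket[2]))
  }
  structure(list(G_star_values = G, response_values = resp, pattern = pattern,
                 G_pref = G_pref, receptor = m, mode = mode, L = L,
                 dGdx = dGdx),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("response_curve [%s receptor, %s mode]: pattern %s\n",
              x$receptor$variant, x$mode, x$pattern))
  cat(sprintf("  G* in [%.3g, %.3g] uM (%d points), dG/dx = %g\n",
              min(x$G_star_values), max(x$G_star_values),
              length(x$G_star_values), x$dGdx))
  if (is.finite(x$G_pref))
    cat(sprintf("  preferred concentration G_pref = %.6g uM\n", x$G_pref))
  invisible(x)
}

#' @export
plot.response_curve <- function(x, ...) {
  graphics::plot(x$G_star_values, x$response_values, type = "l", log = "x",
                 xlab = "baseline concentration G* (uM)",
                 ylab = "relative polarity dE/E*",
                 main = sprintf("pattern: %s", x$pattern), ...)
  graphics::abline(h = 0, lty = 3)
  if (is.finite(x$G_pref)) {
    graphics::abline(v = x$G_pref, lty = 2, col = "grey40")
    graphics::mtext(sprintf("G_pref = %.3g", x$G_pref), side = 3, line = -1.2,
                    adj = 0.98, cex = 0.8)
  }
  invisible(x)
}

#' Pattern phase diagram over input-ratio space
#'
#' Classifies the response pattern on a log-spaced grid of the two input
#' ratios `c_A/c_I` and `alpha_A/alpha_I`, holding the inhibitor
#' parameters and both (D, k) pairs fixed. The analytic critical lines are
#' `ratio = eta` in each axis: BAR in the quadrant
#' `c_A/c_I < eta < alpha_A/alpha_I`, its mirror pattern in the opposite
#' quadrant, unidirectional responses elsewhere.
#'
#' @param pA,pI [species_params()] supplying the fixed (D, k) pairs and the
#'   inhibitor's `c_I`, `alpha_I` (both must be positive).
#' @param L Growth-cone length (um).
#' @param c_ratio_range,alpha_ratio_range Positive ranges for the two axes.
#' @param n Grid resolution per axis.
#' @param mode,n_terms Passed through to the classifier.
#' @return An object of class `"phase_diagram"`: a data frame with columns
#'   `row`, `col`, `c_ratio`, `alpha_ratio`, `pattern`, and attributes
#'   `eta`, `c_grid`, `alpha_grid`.
#' @examples
#' pre <- table1_preset("fig3E")
#' pd <- phase_diagram(pre$pA, pre$pI, L = pre$L, n = 21)
#' table(pd$pattern)
#' @export
phase_diagram <- function(pA, pI, L = 10, c_ratio_range = c(1e-4, 1e2),
                          alpha_ratio_range = c(1e-4, 1e2), n = 101,
                          mode = "reduced", n_terms = 500) {
  assert_species(pA, "pA"); assert_species(pI, "pI")
  if (pI$c <= 0 || pI$alpha <= 0)
    stop("phase_diagram needs c_I > 0 and alpha_I > 0 as the ratio baseline",
         call. = FALSE)
  if (any(c(c_ratio_range, alpha_ratio_range) <= 0))
    stop("ratio ranges must be positive", call. = FALSE)
  cr <- 10^seq(log10(c_ratio_range[1]), log10(c_ratio_range[2]), length.out = n)
  ar <- 10^seq(log10(alpha_ratio_range[1]), log10(alpha_ratio_range[2]),
               length.out = n)
  hA <- as.numeric(h_series(pA$D / pA$k, L, n_terms))
  hI <- as.numeric(h_series(pI$D / pI$k, L, n_terms))
  eta <- hA / hI
  grid <- expand.grid(row = seq_len(n), col = seq_len(n))
  grid$c_ratio <- cr[grid$row]
  grid$alpha_ratio <- ar[grid$col]
  grid$pattern <- vapply(seq_len(nrow(grid)), function(i) {
    pA2 <- species_params(pA$D, pA$k, c = grid$c_ratio[i] * pI$c,
                          alpha = grid$alpha_ratio[i] * pI$alpha)
    classify_response(pA2, pI, L, mode = mode, n_terms = n_terms)
  }, character(1))
  structure(grid, eta = eta, c_grid = cr, alpha_grid = ar, L = L,
            class = c("phase_diagram", "data.frame"))
}

#' @export
plot.phase_diagram <- function(x, ...) {
  cr <- attr(x, "c_grid"); ar <- attr(x, "alpha_grid"); eta <- attr(x, "eta")
  z <- matrix(match(x$pattern, PATTERNS), nrow = length(cr))
  cols <- c("#d95f02", "#7570b3", "#1b9e77", "#e7298a")
  graphics::image(log10(cr), log10(ar), z, col = cols,
                  breaks = c(0.5, 1.5, 2.5, 3.5, 4.5),
                  xlab = "log10 c_A / c_I", ylab = "log10 alpha_A / alpha_I",
                  main = "response-pattern phase diagram", ...)
  graphics::abline(v = log10(eta), h = log10(eta), lty = 2)
  graphics::legend("topleft", legend = PATTERNS, fill = cols, cex = 0.7,
                   bg = "white")
  invisible(x)
}
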