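#' Terminal-zone position implied by the preferred concentration
#'
#' An axon expressing receptor level `R` settles where the tectal ligand
#' concentration equals its preferred concentration. This inverts the
#' target gradient analytically at `G_pref` from
#' [preferred_concentration()]; when the preference lies outside the
#' gradient's range the axon would run into a tectal border and no
#' interior terminal exists.
#'
#' @param R Receptor expression level of the axon (a.u.).
#' @param tgt A [target_gradient()].
#' @param gamma Threshold signal level (see [gamma_threshold()]).
#' @param m A [receptor_model()]; its graded level is replaced by `R`.
#' @return A list of class `"terminal"`: `x_tgt` (normalised position or
#'   `NA`), `G_pref`, `R`, and `status` (`"ok"`, `"pinned_low"`,
#'   `"pinned_high"`, or `"no_preference"`).
#' @export
terminal_from_preference <- function(R, tgt, gamma, m) {
  assert_receptor(m)
  if (!inherits(tgt, "target_gradient"))
    stop("tgt must be a target_gradient", call. = FALSE)
  m2 <- set_receptor_level(m, R)
  G_pref <- preferred_concentration(m2, gamma)
  if (is.na(G_pref))
    return(structure(list(x_tgt = NA_real_, G_pref = NA_real_, R = R,
                          status = "no_preference",
                          reason = attr(G_pref, "reason")),
                     class = "terminal"))
  x <- gradient_invert(tgt, G_pref)
  status <- "ok"
  if (is.na(x)) {
    lo <- gradient_level(tgt, 0); hi <- gradient_level(tgt, tgt$sigma)
    status <- if (G_pref < min(lo, hi)) "pinned_low" else "pinned_high"
  }
  structure(list(x_tgt = x, G_pref = G_pref, R = R, status = status),
            class = "terminal")
}

default_motility <- function(motility = list()) {
  def <- list(v0 = 0.01, s = 0.1, max_steps = 1e5, stop_tol = 1e-6)
  def[names(motility)] <- motility
  def
}

#' Chemotactic migration of a single growth cone across the tectal axis
#'
#' Deterministic gradient-following: at each step the cone senses the
#' local linearised stimulus (baseline `f(R, G(x))`, slope
#' `(df/dG) dG/dx` with `dG/dx` the target-gradient slope per normalised
#' axis unit), evaluates the relative polarity dE/E*, and advances by
#' `v0 * tanh((dE/E*) / s)` - a smooth, bounded speed whose sign follows
#' the response. Positions are clamped to the axis `[0, sigma]`. Migration
#' stops when `|dE/E*| < stop_tol` (converged at the terminal zone, where
#' the response changes sign from attraction to repulsion) or after
#' `max_steps`.
#'
#' The activator-inhibitor pair must produce the bidirectional
#' attraction-to-repulsion pattern along the gradient: unidirectional
#' patterns have no interior fixed point and never settle.
#'
#' @param x0 Start position in `[0, sigma]`.
#' @param R Receptor expression level of this axon.
#' @param tgt A [target_gradient()].
#' @param m A [receptor_model()] (graded level replaced by `R`).
#' @param pA,pI [species_params()].
#' @param L Growth-cone length (um).
#' @param motility List overriding `v0` (step length scale, axis units per
#'   step), `s` (response scale of the speed saturation), `max_steps`,
#'   `stop_tol`.
#' @param mode,n_terms Passed to the polarity evaluator.
#' @param record Keep the full trace (positions and responses per step)?
#' @return An object of class `"migration_trace"`: `terminal`, `converged`,
#'   `pinned`, `steps`, `response_at_stop`, and (when `record = TRUE`)
#'   `times`, `positions`, `responses`.
#' @export
simulate_migration <- function(x0, R, tgt, m, pA, pI, L = 10,
                               motility = list(), mode = "reduced",
                               n_terms = 500, record = TRUE) {
  assert_species(pA, "pA"); assert_species(pI, "pI"); assert_receptor(m)
  if (!inherits(tgt, "target_gradient"))
    stop("tgt must be a target_gradient", call. = FALSE)
  if (!is.numeric(x0) || length(x0) != 1L || x0 < 0 || x0 > tgt$sigma)
    stop("x0 must lie on the axis [0, sigma]", call. = FALSE)
  mot <- default_motility(motility)
  m2 <- set_receptor_level(m, R)
  pattern <- classify_response(pA, pI, L, m2, dGdx = 1, mode = mode,
                               n_terms = n_terms)
  if (pattern != "BAR")
    stop(sprintf(
      "migration requires the BAR pattern; these parameters give %s, which never settles at an interior terminal",
      pattern), call. = FALSE)
  ev <- polarity_evaluator(pA, pI, L, mode, n_terms)
  x <- x0
  n_max <- as.integer(mot$max_steps)
  pos <- if (record) numeric(n_max + 1L) else NULL
  rsp <- if (record) numeric(n_max + 1L) else NULL
  converged <- FALSE; resp <- NA_real_; step <- 0L
  for (step in 0:n_max) {
    G <- gradient_level(tgt, x)
    resp <- ev(activation(m2, G), activation_slope(m2, G, gradient_slope(tgt, x)))
    if (record) { pos[step + 1L] <- x; rsp[step + 1L] <- resp }
    if (abs(resp) < mot$stop_tol) { converged <- TRUE; break }
    if (step == n_max) break
    x <- min(max(x + mot$v0 * tanh(resp / mot$s), 0), tgt$sigma)
  }
  pinned <- (x <= 0 && resp < 0) || (x >= tgt$sigma && resp > 0)
  out <- list(terminal = x, converged = converged, pinned = pinned,
              steps = step, response_at_stop = resp, x0 = x0, R = R,
              motility = mot)
  if (record) {
    keep <- seq_len(step + 1L)
    out$times <- keep - 1L
    out$positions <- pos[keep]
    out$responses <- rsp[keep]
  }
  structure(out, class = "migration_trace")
}

#' @export
print.migration_trace <- function(x, ...) {
  cat(sprintf("migration_trace: x0 = %.4g -> terminal %.6g in %d steps (%s%s)\n",
              x$x0, x$terminal, x$steps,
              if (x$converged) "converged" else "not converged",
              if (x$pinned) ", pinned at border" else ""))
  invisible(x)
}

#' @export
plot.migration_trace <- function(x, ...) {
  if (is.null(x$positions))
    stop("trace was recorded with record = FALSE", call. = FALSE)
  graphics::plot(x$times, x$positions, type = "l",
                 xlab = "step", ylab = "tectal position (axis units)", ...)
  graphics::abline(h = x$terminal, lty = 3)
  invisible(x)
}

#' Matched retino-tectal gradient pair
#'
#' Convenience constructor for a source/target gradient pair whose scales
#' are matched so that the map spans the whole axis: for type 1
#' (bound-active receptors) `R0 * G0 = gamma * K`; for type 2
#' `G0 = (K / gamma) R0` (unbound-active) or `G0 = (gamma / Rc) R0`
#' (competitive). In the regime `R >> gamma` the resulting maps are the
#' closed-form lines `x_tgt = sigma - x_src` (type 1) and
#' `x_tgt = x_src` (type 2).
#'
#' @param map_type `"type1"` or `"type2"`.
#' @param gamma Threshold signal level of the activator-inhibitor pair.
#' @param variant Receptor variant; defaults to `"bound_active"` for type 1
#'   and `"unbound_active"` for type 2.
#' @param R0 Receptor level at the axis origin; the default `1000 * gamma`
#'   keeps every axon far above threshold.
#' @param q,sigma Gradient steepness and axis length.
#' @param K,Rc Receptor constants.
#' @return List with `src`, `tgt`, `m`.
#' @export
matched_gradients <- function(map_type = c("type1", "type2"), gamma,
                              variant = NULL, R0 = 1000 * gamma, q = 2,
                              sigma = 1, K = 1, Rc = 1) {
  map_type <- match.arg(map_type)
  if (is.null(variant))
    variant <- if (map_type == "type1") "bound_active" else "unbound_active"
  if (map_type == "type1" && variant != "bound_active")
    stop("type1 maps use the bound_active variant", call. = FALSE)
  if (map_type == "type2" && !variant %in% c("unbound_active", "competitive"))
    stop("type2 maps use unbound_active or competitive variants", call. = FALSE)
  G0 <- switch(variant,
    bound_active = gamma * K / R0,
    unbound_active = (K / gamma) * R0,
    competitive = (gamma / Rc) * R0)
  list(src = source_gradient(R0 = R0, q = q, sigma = sigma,
                             axis = if (map_type == "type1") "NT" else "DV"),
       tgt = target_gradient(G0 = G0, q = q, sigma = sigma,
                             form = if (map_type == "type1") "RC_type1"
                                    else "ML_type2"),
       m = receptor_model(variant, R = R0, K = K, Rc = Rc))
}

#' Build a full retina-to-tectum topographic map
#'
#' For `n_axons` evenly spaced retinal positions, reads the receptor level
#' off the source gradient, computes each axon's terminal both analytically
#' (gradient inversion at the preferred concentration) and by migration
#' simulation, and fits the terminal-versus-source line. Type 1 maps
#' (bound-active receptors on a rostral-caudal ligand gradient) run with
#' negative slope - nasal, low-receptor axons map caudally; type 2 maps
#' run with positive slope.
#'
#' @param map_type `"type1"` or `"type2"` (orientation bookkeeping).
#' @param n_axons Number of axons, `>= 2`.
#' @param src A [source_gradient()].
#' @param tgt A [target_gradient()].
#' @param m A [receptor_model()].
#' @param pA,pI [species_params()]; must satisfy the BAR condition.
#' @param L Growth-cone length (um).
#' @param motility See [simulate_migration()].
#' @param mode,n_terms Passed through.
#' @param x0 Common start position of all simulated axons (default: axis
#'   midpoint).
#' @param simulate Run the migration simulation per axon (set `FALSE` for
#'   the analytic map only).
#' @return An object of class `"topographic_map"`: a per-axon data frame
#'   `map` (columns `x_src`, `R`, `G_pref`, `x_tgt_analytic`, `x_tgt_sim`,
#'   `converged`, `pinned`) plus `slope`, `intercept`, `r_squared`,
#'   `gamma`, `map_type` and the ingredients.
#' @examples
#' pre <- table1_preset("fig3E")
#' gam <- gamma_threshold(pre$pA, pre$pI, L = pre$L)
#' mg <- matched_gradients("type1", gam)
#' tm <- build_map("type1", 11, mg$src, mg$tgt, mg$m, pre$pA, pre$pI,
#'                 L = pre$L, simulate = FALSE)
#' @export
build_map <- function(map_type = c("type1", "type2"), n_axons = 21, src, tgt,
                      m, pA, pI, L = 10, motility = list(), mode = "reduced",
                      n_terms = 500, x0 = NULL, simulate = TRUE) {
  map_type <- match.arg(map_type)
  if (!inherits(src, "source_gradient"))
    stop("src must be a source_gradient", call. = FALSE)
  if (!inherits(tgt, "target_gradient"))
    stop("tgt must be a target_gradient", call. = FALSE)
  if (n_axons < 2) stop("n_axons must be >= 2", call. = FALSE)
  gamma <- gamma_threshold(pA, pI, L, mode, n_terms)
  if (is.null(x0)) x0 <- tgt$sigma / 2
  x_src <- seq(0, src$sigma, length.out = as.integer(n_axons))
  R <- gradient_level(src, x_src)
  rows <- lapply(seq_along(x_src), function(i) {
    term <- terminal_from_preference(R[i], tgt, gamma, m)
    x_sim <- NA_real_; conv <- NA
    if (simulate) {
      tr <- simulate_migration(x0, R[i], tgt, m, pA, pI, L, motility, mode,
                               n_terms, record = FALSE)
      x_sim <- tr$terminal; conv <- tr$converged
      if (tr$pinned && term$status == "ok") term$status <- "pinned_sim"
    }
    data.frame(x_src = x_src[i], R = R[i], G_pref = term$G_pref,
               x_tgt_analytic = term$x_tgt, x_tgt_sim = x_sim,
               converged = conv, pinned = term$status != "ok")
  })
  map <- do.call(rbind, rows)
  if (mean(map$pinned) > 0.2)
    warning(sprintf(
      "%.0f%% of axons pinned at tectal borders or without preference: source and target gradient scales are mismatched",
      100 * mean(map$pinned)), call. = FALSE)
  fitted_on <- if (simulate) "x_tgt_sim" else "x_tgt_analytic"
  ok <- !map$pinned & is.finite(map[[fitted_on]])
  slope <- intercept <- r2 <- NA_real_
  if (sum(ok) >= 2) {
    fit <- stats::lm(map[[fitted_on]][ok] ~ map$x_src[ok])
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- summary(fit)$r.squared
  }
  structure(list(map = map, slope = slope, intercept = intercept,
                 r_squared = r2, gamma = gamma, map_type = map_type,
                 fitted_on = fitted_on, src = src, tgt = tgt, receptor = m,
                 mode = mode),
            class = "topographic_map")
}

#' @export
print.topographic_map <- function(x, ...) {
  cat(sprintf("topographic_map (%s, %s receptor): %d axons\n", x$map_type,
              x$receptor$variant, nrow(x$map)))
  cat(sprintf("  fit on %s: slope = %.4g, intercept = %.4g, r^2 = %.6g\n",
              x$fitted_on, x$slope, x$intercept, x$r_squared))
  np <- sum(x$map$pinned)
  if (np > 0) cat(sprintf("  %d axon(s) pinned at borders\n", np))
  invisible(x)
}

#' @export
summary.topographic_map <- function(object, ...) {
  print(object)
  cat(sprintf("  gamma = %.6g; receptor range [%.4g, %.4g]\n", object$gamma,
              min(object$map$R), max(object$map$R)))
  invisible(object)
}

#' @export
plot.topographic_map <- function(x, ...) {
  graphics::plot(x$map$x_src, x$map$x_tgt_analytic, type = "l", lty = 2,
                 xlab = "source position (retina)",
                 ylab = "terminal position (tectum)",
                 main = sprintf("%s map, slope %.3g", x$map_type, x$slope), ...)
  graphics::points(x$map$x_src, x$map$x_tgt_sim, pch = 1, col = "firebrick")
  graphics::legend("top", legend = c("analytic inversion", "migration"),
                   lty = c(2, NA), pch = c(NA, 1),
                   col = c("black", "firebrick"), cex = 0.8, bty = "n")
  invisible(x)
}

#' Local precision factors of a topographic map
#'
#' The local magnification `dx_tgt / dx_src` of the map factors into three
#' terms by the chain rule: the source-gradient steepness `dR/dx_src`, the
#' mapping-function steepness `dG_pref/dR`, and the inverse
#' target-gradient steepness `(dG/dx_tgt)^-1`. For type 1 maps the middle
#' factor, `-gamma K / (R - gamma)^2`, grows in magnitude as the receptor
#' level falls toward `gamma`; for type 2 receptors it is constant in `R`.
#'
#' @param map A [build_map()] result.
#' @param src,tgt,m,gamma Override the ingredients stored in `map`.
#' @return A data frame of class `"projection_precision"`, one row per
#'   interior non-pinned axon: the three factors, their product
#'   `magnification`, and the centred finite-difference slope
#'   `numeric_slope` of the analytic map for comparison.
#' @export
projection_precision <- function(map, src = map$src, tgt = map$tgt,
                                 m = map$receptor, gamma = map$gamma) {
  if (!inherits(map, "topographic_map"))
    stop("map must be a topographic_map", call. = FALSE)
  df <- map$map
  n <- nrow(df)
  num_slope <- rep(NA_real_, n)
  idx <- 2:(n - 1)
  num_slope[idx] <- (df$x_tgt_analytic[idx + 1] - df$x_tgt_analytic[idx - 1]) /
    (df$x_src[idx + 1] - df$x_src[idx - 1])
  keep <- seq_len(n) %in% idx & !df$pinned & is.finite(df$x_tgt_analytic)
  out <- do.call(rbind, lapply(which(keep), function(i) {
    F1 <- (src$q / src$sigma) * df$R[i]
    F2 <- gpref_sensitivity(set_receptor_level(m, df$R[i]), df$G_pref[i])
    F3 <- 1 / gradient_slope(tgt, df$x_tgt_analytic[i])
    data.frame(x_src = df$x_src[i], R = df$R[i],
               dR_dxsrc = F1, dGpref_dR = F2, inv_dG_dxtgt = F3,
               magnification = F1 * F2 * F3, numeric_slope = num_slope[i])
  }))
  class(out) <- c("projection_precision", "data.frame")
  out
}
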