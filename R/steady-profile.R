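# Baselines for an activator/inhibitor pair; errors name the offending species.
pair_baselines <- function(pA, pI, f_star) {
  A_star <- (pA$alpha * f_star + pA$c) / pA$k
  I_star <- (pI$alpha * f_star + pI$c) / pI$k
  if (A_star <= 0)
    stop("degenerate baseline: the activator has zero baseline activity ",
         "(alpha_A * f* + c_A = 0); supply f* > 0 or a positive c_A", call. = FALSE)
  if (I_star <= 0)
    stop("degenerate baseline: the inhibitor has zero baseline activity ",
         "(alpha_I * f* + c_I = 0); supply f* > 0 or a positive c_I", call. = FALSE)
  list(A = A_star, I = I_star)
}

# Cosine-series steady-state profile of one species on a grid x in [-L/2, L/2].
# Z(x) = Z* - (4 amp L^3 / (pi^4 k)) sum_{odd n} cos(n pi (x + L/2) / L) /
#                                                (n^2 (n^2 s + (L/pi)^2))
# where amp = g_eff (reduced) or alpha * g_eff (physical). The mode-1-and-up
# odd-cosine sum evaluates to a straight line g x / k when D = 0.
species_profile <- function(p, g_eff, L, x, mode, n_terms, z_star) {
  n <- 2 * (seq_len(n_terms) - 1) + 1
  csq <- (L / pi)^2
  s <- p$D / p$k
  amp <- if (mode == "physical") p$alpha * g_eff else g_eff
  wt <- 1 / (n^2 * (n^2 * s + csq))                  # length n_terms
  basis <- cos(outer(x + L / 2, n) * (pi / L))       # |x| x n_terms
  z_star - (4 * amp * L^3 / (pi^4 * p$k)) * as.numeric(basis %*% wt)
}

#' Analytic steady-state profile of activator, inhibitor and effector
#'
#' Evaluates the closed-form steady state of the activator-inhibitor
#' reaction-diffusion system under the linearised stimulus
#' `f* + g_eff x` on a grid spanning the growth cone, and forms the
#' effector ratio `E(x) = A(x) / I(x)`.
#'
#' @param pA,pI [species_params()] for the activator and the inhibitor.
#' @param ctx A [growth_cone_context()] carrying `L`, `f_star`, `g_eff`.
#' @param grid_n Number of grid points (both ends included), `>= 2`.
#' @param mode `"reduced"` or `"physical"`; only `"physical"` matches the
#'   reaction-diffusion oracle when `alpha_A != alpha_I` (see
#'   [relative_polarity()]).
#' @param n_terms Odd cosine modes retained.
#' @return An object of class `"steady_profile"`: list with `positions`
#'   (um, `x = 0` at the cone centre), `A_values`, `I_values`, `E_values`,
#'   the baselines `A_star`, `I_star`, and `mode`.
#' @examples
#' pre <- table1_preset("fig2C")
#' ctx <- growth_cone_context(L = pre$L, f_star = pre$G_star, g_eff = pre$g)
#' prof <- steady_profile(pre$pA, pre$pI, ctx)
#' @export
steady_profile <- function(pA, pI, ctx, grid_n = 201, mode = "reduced",
                           n_terms = 500) {
  assert_species(pA, "pA"); assert_species(pI, "pI"); assert_context(ctx)
  mode <- match_mode(mode)
  if (!is.numeric(grid_n) || length(grid_n) != 1L || grid_n < 2)
    stop("grid_n must be >= 2", call. = FALSE)
  n_terms <- as.integer(n_terms)
  base <- pair_baselines(pA, pI, ctx$f_star)
  x <- seq(-ctx$L / 2, ctx$L / 2, length.out = as.integer(grid_n))
  A <- species_profile(pA, ctx$g_eff, ctx$L, x, mode, n_terms, base$A)
  I <- species_profile(pI, ctx$g_eff, ctx$L, x, mode, n_terms, base$I)
  if (any(A <= 0) || any(I <= 0))
    warning("profile crosses zero: the stimulus is too steep for positive ",
            "activities across the whole cone", call. = FALSE)
  structure(list(positions = x, A_values = A, I_values = I, E_values = A / I,
                 A_star = base$A, I_star = base$I, mode = mode, L = ctx$L),
            class = "steady_profile")
}

#' @export
print.steady_profile <- function(x, ...) {
  cat(sprintf("steady_profile (%s mode): %d points on [%g, %g] um\n",
              x$mode, length(x$positions), min(x$positions), max(x$positions)))
  cat(sprintf("  A* = %.6g, I* = %.6g, E* = %.6g\n", x$A_star, x$I_star,
              x$A_star / x$I_star))
  cat(sprintf("  dE/E* (profile ends) = %.6g\n", polarity_from_profile(x)))
  invisible(x)
}

#' @export
plot.steady_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$positions, x$A_values, type = "l", col = "firebrick",
                 xlab = "", ylab = "A(x) (uM)", main = "activator")
  graphics::plot(x$positions, x$I_values, type = "l", col = "steelblue",
                 xlab = "", ylab = "I(x) (uM)", main = "inhibitor")
  graphics::plot(x$positions, x$E_values, type = "l", col = "black",
                 xlab = "x (um)", ylab = "E(x) = A/I", main = "effector")
  invisible(x)
}

#' Relative polarity extracted from an evaluated profile
#'
#' `(E(L/2) - E(-L/2)) / E(0)` from a profile's grid ends and centre. Works
#' for analytic [steady_profile()] objects and for [integrate_rd()]
#' solutions; used to compare the two routes.
#'
#' @param profile A `"steady_profile"` or `"rd_solution"` object.
#' @return The relative effector polarity (dimensionless).
#' @export
polarity_from_profile <- function(profile) {
  E <- profile$E_values
  n <- length(E)
  mid <- E[(n + 1L) %/% 2L]
  if (n %% 2L == 0L) mid <- mean(E[n / 2L + c(0L, 1L)])
  (E[n] - E[1L]) / mid
}

#' Relative effector polarity of the growth cone
#'
#' The chemotactic readout of the model: the linearised relative spatial
#' polarity of the effector,
#' \deqn{\Delta E / E^* = \Delta A / A^* - \Delta I / I^*
#'  = \frac{8 g_{eff} L^3}{\pi^4}\left[\frac{w_A h(D_A/k_A)}{\alpha_A f^* + c_A}
#'  - \frac{w_I h(D_I/k_I)}{\alpha_I f^* + c_I}\right],}
#' with weights `w = 1` in `"reduced"` mode and `w = alpha` in `"physical"`
#' mode. Positive values mean attraction (migration up the cue gradient),
#' negative repulsion.
#'
#' @inheritParams steady_profile
#' @return An object of class `"polarity_response"`: list with
#'   `delta_E_rel`, `delta_A_rel`, `delta_I_rel` and `mode`. The
#'   decomposition `delta_E_rel = delta_A_rel - delta_I_rel` holds exactly.
#' @examples
#' pre <- table1_preset("fig2C")
#' ctx <- growth_cone_context(L = pre$L, f_star = pre$G_star, g_eff = pre$g)
#' relative_polarity(pre$pA, pre$pI, ctx)$delta_E_rel  # > 0: attraction
#' @export
relative_polarity <- function(pA, pI, ctx, mode = "reduced", n_terms = 500) {
  assert_species(pA, "pA"); assert_species(pI, "pI"); assert_context(ctx)
  mode <- match_mode(mode)
  base <- pair_baselines(pA, pI, ctx$f_star)
  dA <- spatial_difference(pA, ctx$g_eff, ctx$L, mode, n_terms) / base$A
  dI <- spatial_difference(pI, ctx$g_eff, ctx$L, mode, n_terms) / base$I
  if (!is.finite(dA) && !is.finite(dI))
    stop("both response terms are non-finite; check parameters", call. = FALSE)
  structure(list(delta_E_rel = dA - dI, delta_A_rel = dA, delta_I_rel = dI,
                 mode = mode),
            class = "polarity_response")
}

#' @export
print.polarity_response <- function(x, ...) {
  dir <- if (x$delta_E_rel > 0) "attraction" else if (x$delta_E_rel < 0)
    "repulsion" else "neutral"
  cat(sprintf("dE/E* = %.6g (%s mode): %s\n", x$delta_E_rel, x$mode, dir))
  cat(sprintf("  dA/A* = %.6g, dI/I* = %.6g\n", x$delta_A_rel, x$delta_I_rel))
  invisible(x)
}

# Fast evaluator used in hot loops (response curves, migration): returns a
# function resp(f_star, g_eff) avoiding per-call validation and h recomputation.
polarity_evaluator <- function(pA, pI, L, mode, n_terms = 500) {
  mode <- match_mode(mode)
  hA <- as.numeric(h_series(pA$D / pA$k, L, n_terms))
  hI <- as.numeric(h_series(pI$D / pI$k, L, n_terms))
  wA <- if (mode == "physical") pA$alpha else 1
  wI <- if (mode == "physical") pI$alpha else 1
  pref <- 8 * L^3 / pi^4
  aA <- pA$alpha; cA <- pA$c; aI <- pI$alpha; cI <- pI$c
  function(f_star, g_eff) {
    pref * g_eff * (wA * hA / (aA * f_star + cA) - wI * hI / (aI * f_star + cI))
  }
}
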