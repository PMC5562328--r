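#' Kinetic parameters of one intracellular species
#'
#' Bundles the four kinetic constants of the activator or the inhibitor:
#' diffusion across the growth cone, first-order decay, a constant
#' (cue-independent) input, and the transmission efficacy that couples the
#' transduced guidance-cue signal into the species.
#'
#' @param D Diffusion constant (um^2/s), `>= 0`.
#' @param k Decay rate (1/s), `> 0`.
#' @param c Constant input (uM/s), `>= 0`.
#' @param alpha Transmission efficacy of the transduced cue signal (1/s),
#'   `>= 0`.
#'
#' @details At least one of `c` and `alpha` must be strictly positive,
#'   otherwise the species has zero baseline activity and the effector ratio
#'   E = A/I is undefined everywhere.
#'
#' @return An object of class `"species_params"`: a validated list with
#'   elements `D`, `k`, `c`, `alpha`.
#' @examples
#' species_params(D = 20, k = 1, c = 0.05, alpha = 5)
#' @export
species_params <- function(D, k, c = 0, alpha = 0) {
  for (v in list(D = D, k = k, c = c, alpha = alpha)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("species_params fields must be finite numeric scalars", call. = FALSE)
  }
  if (D < 0) stop("diffusion constant D must be >= 0", call. = FALSE)
  if (k <= 0) stop("decay rate k must be > 0", call. = FALSE)
  if (c < 0) stop("constant input c must be >= 0", call. = FALSE)
  if (alpha < 0) stop("efficacy alpha must be >= 0", call. = FALSE)
  if (c == 0 && alpha == 0)
    stop("at least one of c and alpha must be positive (baseline activity would be 0)",
         call. = FALSE)
  structure(list(D = D, k = k, c = c, alpha = alpha), class = "species_params")
}

is_species_params <- function(x) inherits(x, "species_params")

assert_species <- function(p, what = "species") {
  if (!is_species_params(p))
    stop(sprintf("`%s` must be a species_params object", what), call. = FALSE)
  p
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf("species_params: D = %g um^2/s, k = %g 1/s, c = %g uM/s, alpha = %g 1/s\n",
              x$D, x$k, x$c, x$alpha))
  invisible(x)
}

#' @export
format.species_params <- function(x, ...) {
  sprintf("(D=%g, k=%g, c=%g, alpha=%g)", x$D, x$k, x$c, x$alpha)
}

#' Local stimulus seen by a growth cone
#'
#' The growth cone of length `L` senses the transduced guidance-cue signal
#' f(R, G(x)) linearised across its span: a baseline `f_star = f(R, G*)` at
#' the cone centre plus an effective slope
#' `g_eff = (df/dG at G*) * (dG/dx at the centre)`.
#'
#' @param L Growth-cone length (um), `> 0`.
#' @param f_star Baseline transduced signal at the cone centre (uM-equivalent),
#'   `>= 0`.
#' @param g_eff Effective slope of the transduced signal across the cone
#'   (per um). May be negative (signal running against the cue gradient).
#' @param shallow_tol Relative threshold for the shallow-gradient warning:
#'   warn when `|g_eff| * L / 2 > shallow_tol * f_star`. The linearised
#'   steady-state theory assumes a shallow gradient; the condition is warned
#'   about, never enforced. Set to `Inf` to silence.
#'
#' @return An object of class `"growth_cone_context"`.
#' @examples
#' growth_cone_context(L = 10, f_star = 10, g_eff = 0.75)
#' @export
growth_cone_context <- function(L = 10, f_star, g_eff, shallow_tol = 0.5) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("growth-cone length L must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(f_star) || length(f_star) != 1L || !is.finite(f_star) || f_star < 0)
    stop("baseline signal f_star must be a finite scalar >= 0", call. = FALSE)
  if (!is.numeric(g_eff) || length(g_eff) != 1L || !is.finite(g_eff))
    stop("effective slope g_eff must be a finite scalar", call. = FALSE)
  if (is.finite(shallow_tol) && f_star > 0 && abs(g_eff) * L / 2 > shallow_tol * f_star)
    warning(sprintf(
      "stimulus is not shallow: |g_eff|*L/2 = %.3g exceeds %g * f_star = %.3g; %s",
      abs(g_eff) * L / 2, shallow_tol, shallow_tol * f_star,
      "the linearised response is a first-order approximation there"),
      call. = FALSE)
  structure(list(L = L, f_star = f_star, g_eff = g_eff),
            class = "growth_cone_context")
}

assert_context <- function(ctx) {
  if (!inherits(ctx, "growth_cone_context"))
    stop("`ctx` must be a growth_cone_context object", call. = FALSE)
  ctx
}

#' @export
print.growth_cone_context <- function(x, ...) {
  cat(sprintf("growth_cone_context: L = %g um, f* = %g, g_eff = %g per um\n",
              x$L, x$f_star, x$g_eff))
  invisible(x)
}

# "reduced": the conventional closed-form algebra of this model family, in
# which the efficacy alpha_Z is absorbed into the gradient amplitude (the
# response and all pattern boundaries depend on alpha only through the
# baseline). "physical": the gradient input term carries alpha_Z explicitly,
# which is what the reaction-diffusion equations integrate; both modes agree
# whenever alpha_A = alpha_I.
match_mode <- function(mode) {
  match.arg(mode, c("reduced", "physical"))
}
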