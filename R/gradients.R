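#' Exponential receptor and ligand gradients
#'
#' The retinotectal axes carry exponential expression gradients.
#' `source_gradient()` describes the graded receptor across a retinal axis,
#' `R(x) = R0 exp(q x / sigma)` for `x` in `[0, sigma]`.
#' `target_gradient()` describes the ligand across the matching tectal
#' axis: form `"RC_type1"` is `G(x) = G0 exp(-q (1 - x/sigma))` (rising
#' toward the caudal end, the ephrinA arrangement) and `"ML_type2"` is
#' `G(x) = G0 exp(q x / sigma)` (the ephrinB arrangement). Both have slope
#' `dG/dx = (q / sigma) G(x)`.
#'
#' Axis coordinates are normalised (`sigma = 1` spans the axis); receptor
#' densities are unitless, ligand concentrations in uM.
#'
#' @param R0 Receptor level at the axis origin (a.u.), `> 0`.
#' @param G0 Ligand concentration scale (uM), `> 0`.
#' @param q Exponential steepness (dimensionless), `> 0`.
#' @param sigma Axis length (normalised), `> 0`.
#' @param axis Retinal axis label, `"NT"` or `"DV"` (metadata only).
#' @param form `"RC_type1"` or `"ML_type2"`.
#' @return Objects of class `"source_gradient"` / `"target_gradient"`.
#' @examples
#' src <- source_gradient(R0 = 1, q = 2)
#' gradient_level(src, c(0, 0.5, 1))
#' @export
source_gradient <- function(R0 = 1, q = 2, sigma = 1, axis = c("NT", "DV")) {
  axis <- match.arg(axis)
  stopifnot(R0 > 0, q > 0, sigma > 0)
  structure(list(R0 = R0, q = q, sigma = sigma, axis = axis),
            class = "source_gradient")
}

#' @rdname source_gradient
#' @export
target_gradient <- function(G0 = 1, q = 2, sigma = 1,
                            form = c("RC_type1", "ML_type2")) {
  form <- match.arg(form)
  stopifnot(G0 > 0, q > 0, sigma > 0)
  structure(list(G0 = G0, q = q, sigma = sigma, form = form),
            class = "target_gradient")
}

#' Evaluate, differentiate and invert a gradient
#'
#' `gradient_level()` returns the receptor level or ligand concentration at
#' axis position `x`; `gradient_slope()` the spatial derivative (target
#' gradients only); `gradient_invert()` the axis position at which a target
#' gradient attains concentration `G` (`NA` outside the axis range).
#'
#' @param grad A `"source_gradient"` or `"target_gradient"`.
#' @param x Axis positions in `[0, sigma]`. Vectorised.
#' @param G Ligand concentrations (uM). Vectorised.
#' @return Numeric vector.
#' @export
gradient_level <- function(grad, x) {
  if (inherits(grad, "source_gradient"))
    return(grad$R0 * exp(grad$q * x / grad$sigma))
  if (inherits(grad, "target_gradient"))
    return(switch(grad$form,
      RC_type1 = grad$G0 * exp(-grad$q * (1 - x / grad$sigma)),
      ML_type2 = grad$G0 * exp(grad$q * x / grad$sigma)))
  stop("grad must be a source_gradient or target_gradient", call. = FALSE)
}

#' @rdname gradient_level
#' @export
gradient_slope <- function(grad, x) {
  if (!inherits(grad, "target_gradient"))
    stop("gradient_slope is defined for target gradients", call. = FALSE)
  (grad$q / grad$sigma) * gradient_level(grad, x)
}

#' @rdname gradient_level
#' @export
gradient_invert <- function(grad, G) {
  if (!inherits(grad, "target_gradient"))
    stop("gradient_invert is defined for target gradients", call. = FALSE)
  x <- switch(grad$form,
    RC_type1 = grad$sigma * (1 + log(G / grad$G0) / grad$q),
    ML_type2 = grad$sigma * log(G / grad$G0) / grad$q)
  ifelse(is.finite(x) & x >= 0 & x <= grad$sigma, x, NA_real_)
}
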