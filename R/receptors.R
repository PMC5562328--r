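RECEPTOR_VARIANTS <- c("identity", "bound_active", "unbound_active",
                       "competitive")

#' Receptor transfer functions f(R, G)
#'
#' How the extracellular guidance-cue concentration `G` is transduced into
#' the intracellular drive, given the graded receptor density `R`:
#'
#' * `"identity"` - `f = G`; the cue acts directly (no receptor stage).
#' * `"bound_active"` - `f = R G / (K + G)`; cue-bound receptors signal
#'   (the EphA/ephrinA-style scheme).
#' * `"unbound_active"` - `f = R K / (K + G)`; cue-free receptors signal,
#'   so signal falls as cue rises.
#' * `"competitive"` - `f = R_c G / (K + R_c + R)`; a uniformly expressed
#'   receptor `R_c` signals while the graded receptor `R` competes for a
#'   limited ligand (the strong-binding limit of
#'   [competitive_binding_steady()]). Linear, unbounded in `G`.
#'
#' Receptor densities are unitless abundances; only their ratios to `K`
#' and to each other matter. The source model prints no values for `K` or
#' `R_c`; the defaults `K = 1`, `R_c = 1` are conventional scales, not
#' measurements.
#'
#' @param variant One of `"identity"`, `"bound_active"`, `"unbound_active"`,
#'   `"competitive"`.
#' @param R Graded receptor density (a.u.), `>= 0`. Ignored by `"identity"`.
#' @param K Dissociation constant (uM), `> 0`. Ignored by `"identity"`.
#' @param Rc Uniformly expressed receptor density (a.u.), `> 0`;
#'   `"competitive"` only.
#' @return An object of class `"receptor_model"`.
#' @examples
#' m <- receptor_model("bound_active", R = 4, K = 1)
#' activation(m, G = 1)        # 2
#' activation_slope(m, G = 1, dGdx = 1)  # 1
#' @export
receptor_model <- function(variant = RECEPTOR_VARIANTS, R = 1, K = 1, Rc = 1) {
  variant <- match.arg(variant)
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R < 0)
    stop("receptor density R must be a finite scalar >= 0", call. = FALSE)
  if (variant != "identity" &&
      (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0))
    stop("dissociation constant K must be > 0", call. = FALSE)
  if (variant == "competitive" &&
      (!is.numeric(Rc) || length(Rc) != 1L || !is.finite(Rc) || Rc <= 0))
    stop("uniform receptor density Rc must be > 0 for the competitive variant",
         call. = FALSE)
  structure(list(variant = variant, R = R, K = K,
                 Rc = if (variant == "competitive") Rc else NULL),
            class = "receptor_model")
}

assert_receptor <- function(m) {
  if (!inherits(m, "receptor_model"))
    stop("`m` must be a receptor_model object", call. = FALSE)
  m
}

# Same transfer function with the graded receptor density replaced.
set_receptor_level <- function(m, R) {
  receptor_model(m$variant, R = R, K = m$K, Rc = if (is.null(m$Rc)) 1 else m$Rc)
}

#' @export
print.receptor_model <- function(x, ...) {
  extra <- switch(x$variant,
    identity = "f(G) = G",
    bound_active = sprintf("f = R G / (K + G), R = %g, K = %g", x$R, x$K),
    unbound_active = sprintf("f = R K / (K + G), R = %g, K = %g", x$R, x$K),
    competitive = sprintf("f = Rc G / (K + Rc + R), R = %g, K = %g, Rc = %g",
                          x$R, x$K, x$Rc))
  cat("receptor_model [", x$variant, "]: ", extra, "\n", sep = "")
  invisible(x)
}

#' Transduced signal and its concentration sensitivity
#'
#' `activation()` evaluates the transfer function f(R, G) at cue
#' concentration `G`; `activation_slope()` returns the effective stimulus
#' slope `g_eff = (df/dG) * dG/dx` with the partial derivative taken
#' analytically. `df/dG` is positive for `"identity"`, `"bound_active"`
#' and `"competitive"`, and negative for `"unbound_active"` (an up-gradient
#' of cue is then a down-gradient of signal).
#'
#' @param m A [receptor_model()].
#' @param G Guidance-cue concentration (uM), `>= 0`. Vectorised.
#' @param dGdx Extracellular cue gradient at the cone centre (uM/um).
#' @return Numeric vector: the transduced signal (a.u.), or the effective
#'   slope (per um).
#' @export
activation <- function(m, G) {
  assert_receptor(m)
  if (!is.numeric(G) || any(!is.finite(G)) || any(G < 0))
    stop("G must be finite numeric >= 0", call. = FALSE)
  switch(m$variant,
    identity = G,
    bound_active = m$R * G / (m$K + G),
    unbound_active = m$R * m$K / (m$K + G),
    competitive = m$Rc * G / (m$K + m$Rc + m$R))
}

#' @rdname activation
#' @export
activation_slope <- function(m, G, dGdx) {
  assert_receptor(m)
  if (!is.numeric(G) || any(!is.finite(G)) || any(G < 0))
    stop("G must be finite numeric >= 0", call. = FALSE)
  dfdG <- switch(m$variant,
    identity = rep(1, length(G)),
    bound_active = m$R * m$K / (m$K + G)^2,
    unbound_active = -m$R * m$K / (m$K + G)^2,
    competitive = rep(m$Rc / (m$K + m$Rc + m$R), length(G)))
  dfdG * dGdx
}

# f at the G -> 0 and G -> Inf limits, and the constant sign of df/dG.
# Used for pattern classification in f-space mapped back to G-space.
receptor_limits <- function(m) {
  switch(m$variant,
    identity = list(f0 = 0, finf = Inf, sgn = 1),
    bound_active = list(f0 = 0, finf = m$R, sgn = 1),
    unbound_active = list(f0 = m$R, finf = 0, sgn = -1),
    competitive = list(f0 = 0, finf = Inf, sgn = 1))
}

#' Exact steady state of competitive ligand binding
#'
#' Two receptor pools (uniform `R_c`, graded `R_g`) bind a limited ligand
#' with identical kinetics. At steady state the free ligand `G_f` solves
#' `G_f + (R_c + R_g) G_f / (K + G_f) = G_total` (mass conservation), a
#' quadratic with a unique non-negative root; bound pools are
#' `R_j G_f / (K + G_f)`. The weak-occupancy approximation valid for
#' `K >> G_f`, `Rc_bound ~ R_c G_total / (K + R_c + R_g)`, is returned
#' alongside with its relative error - it is the algebra behind the
#' `"competitive"` transfer function.
#'
#' @param R_c,R_g Total receptor densities (a.u.), `>= 0`.
#' @param G_total Total guidance-cue concentration (uM), `>= 0`.
#' @param K Dissociation constant (uM), `> 0`.
#' @return An object of class `"binding_state"`: list with `G_f`,
#'   `Rc_bound`, `Rg_bound`, `approx_Rc_bound`, `approx_rel_error`.
#' @examples
#' competitive_binding_steady(R_c = 1, R_g = 1, G_total = 4, K = 2)
#' @export
competitive_binding_steady <- function(R_c, R_g, G_total, K) {
  for (v in list(R_c = R_c, R_g = R_g, G_total = G_total, K = K))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("all arguments must be finite scalars >= 0", call. = FALSE)
  if (K <= 0) stop("K must be > 0", call. = FALSE)
  # G_f^2 + (K + R - G) G_f - K G = 0, R = R_c + R_g; stable positive root.
  b <- K + R_c + R_g - G_total
  disc <- sqrt(b^2 + 4 * K * G_total)
  G_f <- if (b >= 0) 2 * K * G_total / (b + disc) else (disc - b) / 2
  if (!is.finite(G_f) || G_f < 0)
    stop("internal error: no non-negative root for free ligand", call. = FALSE)
  occ <- G_f / (K + G_f)
  Rc_b <- R_c * occ
  Rg_b <- R_g * occ
  approx <- R_c * G_total / (K + R_c + R_g)
  rel_err <- if (Rc_b > 0) abs(approx - Rc_b) / Rc_b else 0
  structure(list(G_f = G_f, Rc_bound = Rc_b, Rg_bound = Rg_b,
                 approx_Rc_bound = approx, approx_rel_error = rel_err),
            class = "binding_state")
}

#' @export
print.binding_state <- function(x, ...) {
  cat(sprintf("binding_state: G_f = %.6g, Rc* = %.6g, Rg* = %.6g\n",
              x$G_f, x$Rc_bound, x$Rg_bound))
  cat(sprintf("  weak-occupancy approx Rc* = %.6g (rel. error %.3g)\n",
              x$approx_Rc_bound, x$approx_rel_error))
  invisible(x)
}
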