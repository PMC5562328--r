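#' Growth-cone chemotaxis model
#'
#' The package's central model object: an activator/inhibitor pair, a cone
#' length, a receptor transfer function and an algebra mode, bundled with
#' the derived quantities that characterise its chemotactic behaviour
#' (the mode-weight ratio eta, the BAR condition, the threshold gamma and
#' the preferred concentration where they exist, and the response-pattern
#' label).
#'
#' @param pA,pI [species_params()] for the activator and the inhibitor.
#' @param L Growth-cone length (um).
#' @param receptor A [receptor_model()].
#' @param mode `"reduced"` or `"physical"` (see [relative_polarity()]).
#' @param n_terms Odd modes retained in the series solution.
#' @return An object of class `"growth_cone"` with methods `print`,
#'   `summary`, `coef`, `predict`, `plot` and `simulate`.
#' @examples
#' pre <- table1_preset("fig3E")
#' gc <- growth_cone(pre$pA, pre$pI, L = pre$L)
#' summary(gc)
#' predict(gc, G_star = c(1, 10, 100), dGdx = 0.75)
#' @export
growth_cone <- function(pA, pI, L = 10, receptor = receptor_model("identity"),
                        mode = "reduced", n_terms = 500) {
  assert_species(pA, "pA"); assert_species(pI, "pI"); assert_receptor(receptor)
  mode <- match_mode(mode)
  bar <- bar_condition(pA, pI, L, n_terms)
  gamma <- tryCatch(suppressWarnings(
    gamma_threshold(pA, pI, L, mode, n_terms)), error = function(e) NA_real_)
  pattern <- classify_response(pA, pI, L, receptor, dGdx = 1, mode, n_terms)
  G_pref <- if (is.finite(gamma) && gamma > 0)
    suppressWarnings(as.numeric(preferred_concentration(receptor, gamma)))
  else NA_real_
  structure(list(pA = pA, pI = pI, L = L, receptor = receptor, mode = mode,
                 n_terms = n_terms, bar = bar, gamma = gamma,
                 pattern = pattern, G_pref = G_pref),
            class = "growth_cone")
}

#' @export
print.growth_cone <- function(x, ...) {
  cat("growth_cone model (", x$mode, " mode)\n", sep = "")
  cat("  activator ", format(x$pA), "\n  inhibitor ", format(x$pI), "\n",
      sep = "")
  cat(sprintf("  L = %g um; receptor: %s\n", x$L, x$receptor$variant))
  cat(sprintf("  response pattern (rising cue gradient): %s\n", x$pattern))
  invisible(x)
}

#' @export
summary.growth_cone <- function(object, ...) {
  print(object)
  b <- object$bar
  cat(sprintf("  eta = %.6g, interval (c_A/c_I, alpha_A/alpha_I) = (%.4g, %.4g) -> BAR %s\n",
              b$eta, b$lower, b$upper,
              if (b$satisfied) "satisfied" else "not satisfied"))
  if (is.finite(object$gamma))
    cat(sprintf("  threshold gamma = %.6g", object$gamma),
        if (is.finite(object$G_pref))
          sprintf("; preferred concentration G_pref = %.6g uM", object$G_pref)
        else "", "\n", sep = "")
  invisible(object)
}

#' @export
coef.growth_cone <- function(object, ...) {
  c(D_A = object$pA$D, k_A = object$pA$k, c_A = object$pA$c,
    alpha_A = object$pA$alpha,
    D_I = object$pI$D, k_I = object$pI$k, c_I = object$pI$c,
    alpha_I = object$pI$alpha, L = object$L)
}

#' Predict the chemotactic response at baseline concentrations
#'
#' Evaluates the relative polarity dE/E* of a [growth_cone()] model at
#' given baseline cue concentrations and extracellular gradient, routing
#' the cue through the model's receptor transfer function.
#'
#' @param object A `"growth_cone"` model.
#' @param G_star Baseline cue concentrations (uM). Vectorised.
#' @param dGdx Extracellular cue gradient (uM/um).
#' @param ... Unused.
#' @return Numeric vector of dE/E* values.
#' @export
predict.growth_cone <- function(object, G_star, dGdx = 0.75, ...) {
  ev <- polarity_evaluator(object$pA, object$pI, object$L, object$mode,
                           object$n_terms)
  f <- activation(object$receptor, G_star)
  g <- activation_slope(object$receptor, G_star, dGdx)
  ev(f, g)
}

#' @export
plot.growth_cone <- function(x, G_range = c(1e-2, 1e3), dGdx = 0.75, ...) {
  rc <- response_curve(x$receptor, x$pA, x$pI, x$L, dGdx, G_range,
                       mode = x$mode, n_terms = x$n_terms)
  plot(rc, ...)
}

#' Simulate the reaction-diffusion profile of a growth-cone model
#'
#' Runs the brute-force integrator ([integrate_rd()]) for the model at a
#' given stimulus - the numerical counterpart of [steady_profile()].
#'
#' @param object A `"growth_cone"` model.
#' @param nsim Unused (the dynamics are deterministic); kept for the
#'   generic's signature.
#' @param seed Unused.
#' @param G_star Baseline cue concentration (uM).
#' @param dGdx Extracellular cue gradient (uM/um).
#' @param ... Passed to [integrate_rd()] (e.g. `grid`, `scheme`).
#' @return An `"rd_solution"`.
#' @export
simulate.growth_cone <- function(object, nsim = 1, seed = NULL, G_star,
                                 dGdx = 0.75, ...) {
  f_star <- activation(object$receptor, G_star)
  g_eff <- activation_slope(object$receptor, G_star, dGdx)
  ctx <- growth_cone_context(L = object$L, f_star = f_star, g_eff = g_eff,
                             shallow_tol = Inf)
  integrate_rd(object$pA, object$pI, ctx, ...)
}
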