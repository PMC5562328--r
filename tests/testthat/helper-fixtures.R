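# Shared fixtures: everything is generated in code; no data files.

preset_keys <- c("fig2C", "fig2D", "fig3B", "fig3C", "fig3D", "fig3E")

# Reproducible random species pair away from degenerate corners.
random_species_pair <- function() {
  draw <- function() species_params(D = 10^runif(1, -1, 2),
                                    k = 10^runif(1, -0.3, 1.5),
                                    c = 10^runif(1, -2, 2),
                                    alpha = 10^runif(1, -1, 1.3))
  list(pA = draw(), pI = draw())
}

# Stimulus used for the profile presets.
profile_ctx <- function(pre, shallow_tol = Inf) {
  growth_cone_context(L = pre$L, f_star = pre$G_star, g_eff = pre$g,
                      shallow_tol = shallow_tol)
}
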