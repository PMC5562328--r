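test_that("transfer functions evaluate their closed forms and limits", {
  expect_equal(activation(receptor_model("identity"), 7), 7)
  expect_equal(activation(receptor_model("bound_active", R = 4, K = 1), 1), 2)
  m_un <- receptor_model("unbound_active", R = 4, K = 1)
  expect_equal(activation(m_un, 0), 4)
  expect_lt(activation(m_un, 1e9), 1e-8)
  expect_equal(activation(receptor_model("competitive", R = 1, K = 1, Rc = 2),
                          2), 1)
  expect_error(activation(receptor_model("identity"), -1), ">= 0")
  # saturating variants are bounded by R; competitive is linear in G
  mb <- receptor_model("bound_active", R = 3, K = 2)
  expect_true(all(activation(mb, 10^(0:6)) < 3))
  mc <- receptor_model("competitive", R = 2, K = 1, Rc = 1)
  expect_equal(activation(mc, 8), 2 * activation(mc, 4))
})

test_that("analytic slopes match central finite differences", {
  expect_equal(activation_slope(receptor_model("identity"), 5, 0.75), 0.75)
  expect_equal(activation_slope(receptor_model("bound_active", R = 4, K = 1),
                                1, 1), 1)
  expect_equal(activation_slope(receptor_model("unbound_active", R = 4, K = 1),
                                1, 1), -1)
  set.seed(31)
  for (variant in c("bound_active", "unbound_active", "competitive")) {
    for (i in 1:10) {
      m <- receptor_model(variant, R = 10^runif(1, -1, 2),
                          K = 10^runif(1, -1, 1), Rc = 10^runif(1, -1, 1))
      G <- 10^runif(1, -2, 2)
      hstep <- G * 1e-6
      fd <- (activation(m, G + hstep) - activation(m, G - hstep)) / (2 * hstep)
      expect_equal(activation_slope(m, G, 1), fd, tolerance = 1e-6)
    }
  }
})

test_that("competitive binding solves the conservation quadratic exactly", {
  bs <- competitive_binding_steady(R_c = 1, R_g = 1, G_total = 4, K = 2)
  expect_equal(bs$G_f, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(bs$Rc_bound, 2 * sqrt(2) / (2 + 2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(bs$G_f + bs$Rc_bound + bs$Rg_bound, 4, tolerance = 1e-12)
  # no ligand: everything zero
  bs0 <- competitive_binding_steady(1, 1, 0, 2)
  expect_identical(c(bs0$G_f, bs0$Rc_bound, bs0$Rg_bound), c(0, 0, 0))
  # strong-binding regime approaches the weak-occupancy closed form
  bsK <- competitive_binding_steady(1, 1, 1, 1e3)
  expect_equal(bsK$Rc_bound, 1 / (1e3 + 2), tolerance = 5e-3)
})

test_that("ligand is conserved to 1e-9 and the approximation error decays in K", {
  set.seed(32)
  for (i in 1:20) {
    Rc <- 10^runif(1, -1, 2); Rg <- 10^runif(1, -1, 2)
    G <- 10^runif(1, -2, 2); K <- 10^runif(1, -1, 3)
    bs <- competitive_binding_steady(Rc, Rg, G, K)
    expect_lt(abs(bs$G_f + bs$Rc_bound + bs$Rg_bound - G) / G, 1e-9)
  }
  errs <- vapply(10^(1:5), function(K)
    competitive_binding_steady(2, 3, 1, K)$approx_rel_error, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[5], 1e-5)
})

test_that("time integration of the binding kinetics reaches the algebraic fixed point", {
  # two-ODE system in the bound pools with G_f eliminated by conservation
  set.seed(33)
  deriv <- function(t, y, parms) {
    with(as.list(c(y, parms)), {
      Gf <- G - Rcb - Rgb
      list(c(kf * (Rc - Rcb) * Gf - kb * Rcb,
             kf * (Rg - Rgb) * Gf - kb * Rgb))
    })
  }
  for (i in 1:20) {
    parms <- c(Rc = 10^runif(1, -1, 1), Rg = 10^runif(1, -1, 1),
               G = 10^runif(1, -1, 1), kf = 1, kb = 10^runif(1, -0.5, 1.5))
    K <- parms[["kb"]] / parms[["kf"]]
    out <- deSolve::ode(c(Rcb = 0, Rgb = 0), seq(0, 400, by = 50), deriv,
                        parms, rtol = 1e-10, atol = 1e-12)
    fin <- out[nrow(out), c("Rcb", "Rgb")]
    bs <- competitive_binding_steady(parms[["Rc"]], parms[["Rg"]],
                                     parms[["G"]], K)
    expect_equal(unname(fin[["Rcb"]]), bs$Rc_bound, tolerance = 1e-6)
    expect_equal(unname(fin[["Rgb"]]), bs$Rg_bound, tolerance = 1e-6)
  }
})
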