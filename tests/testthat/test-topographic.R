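test_that("matched gradient pairs invert to straight maps", {
  pre <- table1_preset("fig3E")
  gam <- gamma_threshold(pre$pA, pre$pI, pre$L)
  # type 1: R >> gamma, R0 G0 = gamma K -> x_tgt ~ sigma - x_src
  mg <- matched_gradients("type1", gam)
  for (xs in c(0.2, 0.5, 0.8)) {
    term <- terminal_from_preference(gradient_level(mg$src, xs), mg$tgt, gam,
                                     mg$m)
    expect_identical(term$status, "ok")
    expect_equal(term$x_tgt, 1 - xs, tolerance = 5e-3)
  }
  # type 2: (K/gamma) R0 = G0 -> x_tgt ~ x_src
  mg2 <- matched_gradients("type2", gam)
  for (xs in c(0.2, 0.5, 0.8)) {
    term <- terminal_from_preference(gradient_level(mg2$src, xs), mg2$tgt, gam,
                                     mg2$m)
    expect_equal(term$x_tgt, xs, tolerance = 5e-3)
  }
  # a preference beyond the tectal range reports border pinning
  term_hi <- terminal_from_preference(2 * gam, mg$tgt, gam, mg$m)
  expect_identical(term_hi$status, "pinned_high")
  expect_true(is.na(term_hi$x_tgt))
  # receptor level at or below gamma: no preference at all
  term_no <- terminal_from_preference(gam / 2, mg$tgt, gam, mg$m)
  expect_identical(term_no$status, "no_preference")
})

test_that("migration settles at the response zero from both sides", {
  pre <- table1_preset("fig3E")
  gam <- gamma_threshold(pre$pA, pre$pI, pre$L)
  mg <- matched_gradients("type1", gam)
  R <- gradient_level(mg$src, 0.5)
  xa <- terminal_from_preference(R, mg$tgt, gam, mg$m)$x_tgt
  lo <- simulate_migration(0.1, R, mg$tgt, mg$m, pre$pA, pre$pI, L = pre$L)
  hi <- simulate_migration(0.9, R, mg$tgt, mg$m, pre$pA, pre$pI, L = pre$L)
  expect_true(lo$converged && hi$converged)
  expect_lt(abs(lo$terminal - xa), 1e-3)
  expect_lt(abs(hi$terminal - xa), 1e-3)
  expect_lt(abs(lo$terminal - hi$terminal), 1e-4)
  # monotone approach from either side
  expect_true(all(diff(lo$positions) >= 0))
  expect_true(all(diff(hi$positions) <= 0))
  # starting at the terminal: immediate convergence, no displacement
  still <- simulate_migration(xa, R, mg$tgt, mg$m, pre$pA, pre$pI, L = pre$L)
  expect_true(still$converged)
  expect_lt(still$steps, 3)
  expect_lt(abs(still$terminal - xa), 1e-6)
})

test_that("migration refuses parameter sets without an interior fixed point", {
  pre <- table1_preset("fig3B")   # repulsion-to-attraction: unstable crossing
  tgt <- target_gradient(G0 = 1, q = 2, form = "ML_type2")
  expect_error(simulate_migration(0.5, 1, tgt, receptor_model("identity"),
                                  pre$pA, pre$pI, L = pre$L),
               "never settles")
})

test_that("simulated terminals track analytic ones over random BAR draws", {
  draws <- Filter(function(d) d$pattern == "BAR",
                  sample_parameters(n = 120, seed = 8))
  expect_gt(length(draws), 10)
  set.seed(9)
  n_checked <- 0
  for (d in draws[seq_len(min(25, length(draws)))]) {
    gam <- gamma_threshold(d$pA, d$pI, 10)
    tgt <- target_gradient(G0 = gam * exp(-1), q = 2, form = "ML_type2")
    tr <- simulate_migration(runif(1, 0.05, 0.95), 1, tgt,
                             receptor_model("identity"), d$pA, d$pI, L = 10,
                             record = FALSE)
    if (tr$converged) {
      expect_lt(abs(tr$terminal - gradient_invert(tgt, gam)), 1e-3)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)
})

test_that("type 1 and type 2 maps are straight, oriented and order-preserving", {
  pre <- table1_preset("fig3E")
  gam <- gamma_threshold(pre$pA, pre$pI, pre$L)
  mg1 <- matched_gradients("type1", gam)
  tm1 <- build_map("type1", 15, mg1$src, mg1$tgt, mg1$m, pre$pA, pre$pI,
                   L = pre$L)
  expect_lt(abs(tm1$slope + 1), 0.02)
  expect_gt(tm1$r_squared, 0.999)
  ok1 <- !tm1$map$pinned
  expect_lt(max(abs(tm1$map$x_tgt_sim[ok1] - tm1$map$x_tgt_analytic[ok1])),
            1e-3)
  expect_true(all(diff(tm1$map$x_tgt_analytic[ok1]) < 0))   # monotone
  mg2 <- matched_gradients("type2", gam)
  tm2 <- build_map("type2", 15, mg2$src, mg2$tgt, mg2$m, pre$pA, pre$pI,
                   L = pre$L)
  expect_lt(abs(tm2$slope - 1), 0.02)
  expect_gt(tm2$r_squared, 0.999)
  ok2 <- !tm2$map$pinned
  expect_true(all(diff(tm2$map$x_tgt_analytic[ok2]) > 0))
  # orientation is set by the map type, not by the steepness
  mg1b <- matched_gradients("type1", gam, q = 4)
  tm1b <- build_map("type1", 9, mg1b$src, mg1b$tgt, mg1b$m, pre$pA, pre$pI,
                    L = pre$L, simulate = FALSE)
  expect_lt(tm1b$slope, 0)
})

test_that("badly mismatched gradient scales trigger the pinning warning", {
  pre <- table1_preset("fig3E")
  gam <- gamma_threshold(pre$pA, pre$pI, pre$L)
  mg <- matched_gradients("type1", gam)
  # ligand scale far above every axon's preference: all pinned
  tgt_bad <- target_gradient(G0 = mg$tgt$G0 * 1e4, q = 2, form = "RC_type1")
  expect_warning(build_map("type1", 9, mg$src, tgt_bad, mg$m, pre$pA, pre$pI,
                           L = pre$L, simulate = FALSE), "mismatch")
})

test_that("precision factors multiply to the local map magnification", {
  pre <- table1_preset("fig3E")
  gam <- gamma_threshold(pre$pA, pre$pI, pre$L)
  mg1 <- matched_gradients("type1", gam)
  tm1 <- build_map("type1", 21, mg1$src, mg1$tgt, mg1$m, pre$pA, pre$pI,
                   L = pre$L, simulate = FALSE)
  pp1 <- projection_precision(tm1)
  cmp <- stats::complete.cases(pp1)
  expect_gt(sum(cmp), 10)
  expect_lt(max(abs(pp1$magnification[cmp] - pp1$numeric_slope[cmp]) /
                  abs(pp1$numeric_slope[cmp])), 0.01)
  # type 1: the mapping-function steepness grows as R falls toward gamma
  expect_true(all(diff(abs(pp1$dGpref_dR)) < 0))   # R increases along x_src
  mg2 <- matched_gradients("type2", gam, variant = "competitive")
  tm2 <- build_map("type2", 21, mg2$src, mg2$tgt, mg2$m, pre$pA, pre$pI,
                   L = pre$L, simulate = FALSE)
  pp2 <- projection_precision(tm2)
  # type 2 competitive: constant mapping steepness gamma / Rc
  expect_equal(pp2$dGpref_dR, rep(gam / mg2$m$Rc, nrow(pp2)),
               tolerance = 1e-9)
})
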