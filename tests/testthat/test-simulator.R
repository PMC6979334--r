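test_that("the coupled solver honours the demand equation at infinite conductance", {
  p <- sim_leaf_params(vcmax = 108, j = 1e6, gm = Inf, gsw = Inf, rd = 1)
  st <- solve_coupled(p, ca = 400)
  expect_equal(st$A, 108 * 360 / 1110.3203 - 1, tolerance = 1e-4)
  expect_equal(st$ci, 400)
  expect_equal(st$cc, 400)
  expect_equal(st$limitation, "rubisco")
})

test_that("a leaf with no photosynthetic capacity relaxes to the dark state", {
  p <- sim_leaf_params(vcmax = 0, j = 0, gm = 0.2, gsw = 0.6, rd = 1.2,
                       constants = kinetic_constants(Rd = 1.2))
  st <- solve_coupled(p, ca = 400)
  expect_equal(st$A, -1.2)
  expect_equal(st$ci, 400 + 1.2 / (0.6 / 1.6))
  expect_equal(st$flag, "no_solution")
})

test_that("bisection and fixed-point solvers agree to 1e-8", {
  draws <- draw_rubp_limited(20, seed = 13)
  draws$vcmax <- runif(20, 60, 200)  # cover both limitation regimes
  for (i in seq_len(nrow(draws))) {
    p <- with(draws[i, ], sim_leaf_params(vcmax = vcmax, j = j, gm = gm,
                                          gsw = gsw, rd = rd))
    b <- solve_coupled(p, ca = 400, method = "bisection")
    f <- solve_coupled(p, ca = 400, method = "fixed_point")
    expect_lt(abs(b$cc - f$cc), 1e-8)
    expect_lt(abs(b$A - f$A), 1e-8)
  }
})

test_that("noise-free records satisfy both diffusion supply equations", {
  recs <- make_records(20, seed = 31)
  gsc <- recs$gsw / 1.6
  # A = gsc (Ca - Ci) exactly, by construction of the solver
  expect_equal(recs$A, gsc * (recs$ca - recs$ci), tolerance = 1e-9)
  # full flux closure A = gsc (Ca - Ci) = gm (Ci - Cc) on solver states
  draws <- draw_rubp_limited(10, seed = 19)
  for (i in seq_len(nrow(draws))) {
    p <- with(draws[i, ], sim_leaf_params(vcmax = vcmax, j = j, gm = gm,
                                          gsw = gsw, rd = rd))
    st <- solve_coupled(p, ca = 400)
    expect_equal(st$A, draws$gm[i] * (st$ci - st$cc), tolerance = 1e-9)
    expect_equal(st$A, (draws$gsw[i] / 1.6) * (400 - st$ci), tolerance = 1e-9)
  }
})

test_that("record simulation is deterministic and inverts compute_j", {
  p <- sim_leaf_params()
  r1 <- simulate_record(p)
  r2 <- simulate_record(p)
  expect_identical(r1, r2)
  expect_equal(r1$phi_psii, 198 / (1500 * 0.44))
  expect_equal(compute_j(r1$phi_psii, r1$ppfd), 198)
  # default cuvette setpoints
  expect_equal(c(r1$ca, r1$ppfd, r1$rh, r1$tleaf), c(400, 1500, 65, 28))
})

test_that("seeded measurement noise has the configured magnitude", {
  p <- sim_leaf_params(noise_sd_a = 0.5)
  expect_error(simulate_record(p), "seed")
  a <- vapply(1:100, function(s) simulate_record(p, seed = s)$A, numeric(1))
  # chi-square bounds on a sample SD at n = 100, sigma = 0.5
  expect_gt(sd(a), 0.35)
  expect_lt(sd(a), 0.65)
})

test_that("simulated light curves are monotone and fit back to their plateau", {
  p <- sim_leaf_params()
  curve <- simulate_light_curve(p)
  expect_equal(curve$A[curve$ppfd == 0], -1)  # dark point = -rd
  expect_true(all(diff(curve$A) >= -1e-9))
  fit <- nrh_fit(curve[, c("ppfd", "A")])
  plateau <- max(curve$A)
  expect_lt(abs(fit$asat - plateau) / plateau, 0.02)
})

test_that("population generation is anchored, reproducible and truthful", {
  spec <- population_spec(n_lines = 568)
  pop <- generate_population(spec, seed = 1)
  expect_equal(nrow(pop$records), 568)
  expect_equal(nrow(pop$truth), 568)
  expect_identical(pop$records$line_id, pop$truth$line_id)
  # byte-identical rerun under the same seed
  pop2 <- generate_population(spec, seed = 1)
  expect_identical(pop, pop2)
  # single line
  one <- generate_population(population_spec(n_lines = 1), seed = 4)
  expect_equal(nrow(one$records), 1)
  # documented skew direction of the conductances
  expect_gt(e1071::skewness(pop$truth$gsw_true), 0)
  expect_gt(e1071::skewness(pop$truth$gm_true), 0)
  # infeasible correlation matrices are rejected outright
  bad <- diag(5); bad[1, 2] <- bad[2, 1] <- 0.9; bad[1, 3] <- bad[3, 1] <- 0.9
  bad[2, 3] <- bad[3, 2] <- -0.9
  expect_error(population_spec(correlation = bad), "positive semi-definite")
})

test_that("the full pipeline recovers truth from a noise-free population", {
  spec <- population_spec(n_lines = 50, j_mean = 120, j_sd = 10,
                          vcmax_mean = 180, vcmax_sd = 15,
                          noise_sd_a = 0, noise_sd_gsw = 0, noise_sd_phi = 0)
  pop <- generate_population(spec, seed = 8)
  expect_true(all(pop$truth$limitation == "RuBP"))
  d <- derive_traits(pop$records)
  rel <- abs(d$gm - pop$truth$gm_true) / pop$truth$gm_true
  expect_lt(max(rel), 1e-6)
})

test_that("one-point Vcmax is exact when Rubisco-limited and biased low otherwise", {
  km <- compute_km(default_kc)
  withr::local_seed(17)
  for (i in 1:20) {
    vc <- runif(1, 60, 180)
    kc <- kinetic_constants(Rd = 0.015 * vc)
    # Rubisco-limited leaf evaluated at Cc (no diffusion resistance)
    p <- sim_leaf_params(vcmax = vc, j = 1e6, gm = Inf, gsw = Inf,
                         rd = 0.015 * vc, constants = kc)
    st <- solve_coupled(p, ca = runif(1, 250, 400))
    est <- compute_vcmax_one_point(st$A, st$ci, kc, form = "inverted")$vcmax
    expect_equal(est, vc, tolerance = 1e-9)
  }
  # RuBP-limited conditions: the estimator reports less than the truth
  p <- sim_leaf_params(vcmax = 150, j = 120, gm = 0.25, gsw = 0.7, rd = 1)
  st <- solve_coupled(p, ca = 400)
  expect_equal(st$limitation, "RuBP")
  est <- compute_vcmax_one_point(st$A, st$ci, form = "inverted")$vcmax
  expect_lt(est, 150)
})

test_that("the steady-state approach crosses the detector threshold analytically", {
  p <- sim_leaf_params()
  ser <- simulate_steady_approach(p, duration = 400, step = 5, tau = 30, a0 = 0)
  idx <- detect_steady_state(ser, window = 60, rel_tol = 0.005)
  expect_false(is.na(idx))
  # analytic crossing: worst deviation in the trailing window is against
  # the oldest sample; find the first sampled time where it dips below tol
  a_ss <- ser$A[length(ser$A)]
  crossing <- NA_real_
  for (t in ser$t[ser$t >= 60]) {
    dev <- abs((a_ss * (1 - exp(-t / 30))) - (a_ss * (1 - exp(-(t - 60) / 30))))
    if (dev / abs(a_ss * (1 - exp(-t / 30))) < 0.005) { crossing <- t; break }
  }
  expect_equal(ser$t[idx], crossing)
  # near-instant relaxation: fires at the first full window
  fast <- simulate_steady_approach(p, duration = 200, step = 5, tau = 1e-6,
                                   a0 = solve_coupled(p)$A)
  expect_equal(fast$t[detect_steady_state(fast)], 60)
})
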