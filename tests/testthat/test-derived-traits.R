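test_that("electron transport is the product of efficiency, light and absorptance", {
  expect_equal(compute_j(0.3, 1500), 198)
  expect_equal(compute_j(0, 1234), 0)
  expect_equal(compute_j(0.5, 1000), 220)
  # linear in each argument
  expect_equal(compute_j(0.2, 800), 2 * compute_j(0.1, 800))
  expect_equal(compute_j(0.2, 800), 2 * compute_j(0.2, 400))
  expect_error(compute_j(1.2, 100), "phi_psii")
  expect_error(compute_j(0.3, -5), "ppfd")
})

test_that("variable-J mesophyll conductance matches independent evaluation", {
  # independent arithmetic route for the worked example
  x <- 20 + 1
  cc_expected <- 40 * (198 + 8 * x) / (198 - 4 * x)
  gm_expected <- 20 / (280 - cc_expected)
  res <- compute_gm(20, 280, 198)
  expect_equal(res$gm, gm_expected, tolerance = 1e-12)
  expect_equal(res$cc, cc_expected, tolerance = 1e-12)
  expect_equal(res$gm, 0.13194, tolerance = 1e-4)
  expect_equal(res$cc, 128.42, tolerance = 1e-4)
  # Cc consistency: cc == ci - A/gm whenever gm finite positive
  expect_equal(res$cc, 280 - 20 / res$gm, tolerance = 1e-9)
})

test_that("singular and degenerate gm cases yield QC codes, not errors", {
  sing <- compute_gm(20, 280, 84)  # J = 4 (A + Rd) exactly
  expect_true(is.na(sing$gm))
  expect_equal(sing$qc_reason, "J_limit_singular")
  zero <- compute_gm(0, 280, 198)
  expect_equal(zero$gm, 0)
  expect_equal(zero$qc_reason, "nonpositive_gm")
  lowci <- compute_gm(20, 100, 198)  # implied Cc above Ci
  expect_true(is.na(lowci$gm))
  expect_equal(lowci$qc_reason, "nonpositive_denominator")
})

test_that("closed-form dCc/dA equals the finite-difference derivative", {
  res <- compute_dccda(20, 198)
  expect_equal(res$dccda, 95040 / 12996, tolerance = 1e-12)
  # brute-force oracle: central difference of Cc(A) from compute_gm
  withr::local_seed(7)
  for (i in 1:100) {
    A <- runif(1, 1, 30)
    J <- 4 * (A + 1) + runif(1, 20, 200)
    h <- 1e-4
    fd <- (compute_gm(A + h, 5000, J)$cc - compute_gm(A - h, 5000, J)$cc) / (2 * h)
    expect_equal(compute_dccda(A, J)$dccda, fd, tolerance = 1e-6)
  }
  # large-J asymptote: dCc/dA -> 12 gamma_star / J
  expect_equal(compute_dccda(20, 1e7)$dccda, 12 * 40 / 1e7, tolerance = 1e-4)
  expect_equal(compute_dccda(20, 84)$qc_reason, "J_limit_singular")
})

test_that("the dCc/dA quality window and gm positivity gate records", {
  kc <- default_kc
  expect_true(apply_qc(25, 0.2, kc)$qc_pass)
  out <- apply_qc(7.31, 0.13, kc)
  expect_false(out$qc_pass)
  expect_match(out$qc_reasons, "dCcdA_out_of_range")
  und <- apply_qc(25, NA_real_, kc)
  expect_false(und$qc_pass)
  expect_match(und$qc_reasons, "nonpositive_gm")
  # pass <=> no reasons
  batch <- apply_qc(c(25, 7, 60, 25), c(0.2, 0.2, 0.2, -1), kc)
  expect_equal(batch$qc_pass, batch$qc_reasons == "")
})

test_that("apparent Michaelis constant reflects O2 competition", {
  expect_equal(compute_km(default_kc), 404.9 * (1 + 210 / 278.4),
               tolerance = 1e-12)
  expect_equal(compute_km(default_kc), 710.3, tolerance = 1e-3)
  expect_equal(compute_km(kinetic_constants(Oi = 1e-12)), 404.9,
               tolerance = 1e-9)
  expect_equal(compute_km(kinetic_constants(Ko = 1e12)), 404.9,
               tolerance = 1e-9)
})

test_that("one-point Vcmax matches hand evaluation and scales linearly in A", {
  res <- compute_vcmax_one_point(20, 280)
  expect_equal(res$vcmax, 20 * ((280 + compute_km(default_kc)) / 240 - 0.015),
               tolerance = 1e-12)
  expect_equal(res$vcmax, 82.22, tolerance = 1e-4)
  expect_equal(compute_vcmax_one_point(0, 280)$vcmax, 0)
  expect_equal(compute_vcmax_one_point(40, 280)$vcmax, 2 * res$vcmax)
  sing <- compute_vcmax_one_point(20, 40)
  expect_true(is.na(sing$vcmax))
  expect_equal(sing$qc_reason, "Ci_below_gamma_star")
})

test_that("the inverted Vcmax form exactly inverts the Rubisco-limited demand", {
  # forward: A = Vc*(ci-g)/(ci+Km) - 0.015*Vc; inverted form must return Vc
  km <- compute_km(default_kc)
  withr::local_seed(3)
  for (i in 1:20) {
    vc <- runif(1, 40, 200); ci <- runif(1, 150, 380)
    A <- vc * (ci - 40) / (ci + km) - 0.015 * vc
    est <- compute_vcmax_one_point(A, ci, form = "inverted")$vcmax
    expect_equal(est, vc, tolerance = 1e-12)
  }
})

test_that("intrinsic water-use efficiency is a guarded ratio", {
  expect_equal(compute_iwue(21.03, 0.69), 21.03 / 0.69)
  expect_equal(compute_iwue(0, 0.5), 0)
  expect_error(compute_iwue(10, 0), "gsw must be positive")
})

test_that("gm from the variable-J equation is strictly decreasing in J", {
  # at fixed A, Ci, Rd: larger J implies lower chloroplast CO2, hence
  # a larger drawdown already explained and a smaller gm
  J <- seq(160, 400, by = 10)
  gm <- compute_gm(20, 300, J)$gm
  expect_true(all(diff(gm) < 0))
})

test_that("derive_traits processes batches without aborting and reconciles QC", {
  recs <- make_records(10)
  recs$A[3] <- 60  # force J_limit_singular for one record
  d <- derive_traits(recs)
  expect_equal(nrow(d), 10)
  expect_equal(sum(d$qc_pass) + sum(!d$qc_pass), 10)
  expect_true(all(d$qc_pass == (d$qc_reasons == "")))
  expect_match(d$qc_reasons[3], "nonpositive_gm|J_limit_singular|dCcdA")
  # empty input -> empty output with the derived columns present
  e <- derive_traits(recs[0, ])
  expect_equal(nrow(e), 0)
  expect_true(all(c("J", "gm", "vcmax", "qc_pass") %in% names(e)))
})

test_that("noise-free simulated records invert to the true gm", {
  draws <- draw_rubp_limited(30, seed = 5)
  for (i in seq_len(nrow(draws))) {
    p <- with(draws[i, ], sim_leaf_params(vcmax = vcmax, j = j, gm = gm,
                                          gsw = gsw, rd = rd,
                                          constants = kinetic_constants(Rd = draws$rd[i])))
    rec <- simulate_record(p, record_id = "x")
    d <- derive_traits(rec, constants = kinetic_constants(Rd = draws$rd[i]))
    expect_equal(d$gm, draws$gm[i], tolerance = 1e-6)
  }
})

test_that("steady-state detection fires per the trailing-window rule", {
  const <- tibble::tibble(t = seq(0, 120, by = 5), A = 20)
  i <- detect_steady_state(const)
  expect_equal(const$t[i], 60)  # first point with a full window behind it

  # 2%/min ramp never settles at the 0.5%/min tolerance
  ramp <- tibble::tibble(t = seq(0, 600, by = 5))
  ramp$A <- 10 * (1 + 0.02 * ramp$t / 60)
  expect_true(is.na(detect_steady_state(ramp)))

  # exponential approach: compare against an exhaustive scan oracle
  appr <- tibble::tibble(t = seq(0, 400, by = 5))
  appr$A <- 20 * (1 - exp(-appr$t / 30))
  got <- detect_steady_state(appr, window = 60, rel_tol = 0.005)
  oracle <- NA_integer_
  for (i in seq_along(appr$t)) {
    if (appr$t[i] - appr$t[1] < 60) next
    win <- which(appr$t >= appr$t[i] - 60 & appr$t <= appr$t[i])
    if (all(abs(appr$A[i] - appr$A[win]) / abs(appr$A[i]) < 0.005)) {
      oracle <- i
      break
    }
  }
  expect_equal(got, oracle)
  expect_false(is.na(got))
  expect_error(detect_steady_state(tibble::tibble(t = c(0, 0, 5), A = 1:3)),
               "strictly increasing")
})
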