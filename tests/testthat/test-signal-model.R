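test_that("closed-form steady-state models agree with the Bloch recursion", {
  set.seed(42)
  for (i in 1:60) {
    prm <- random_valid_protocol()
    t1 <- runif(1, 80, 1500)
    with_inv <- ref_bloch(prm$tr_ms, prm$flip_deg, prm$ti_ms, prm$rr_ms,
                          prm$n_views, t1, beta = prm$inversion_factor)
    no_inv <- ref_bloch(prm$tr_ms, prm$flip_deg, prm$ti_ms, prm$rr_ms,
                        prm$n_views, t1, invert = FALSE)
    expect_lt(abs(mzss_ir(prm, t1) - with_inv), 1e-9)
    expect_lt(abs(mzss_noinv(prm, t1) - no_inv), 1e-9)
    expect_lt(abs(bloch_steady_state(prm, t1) - with_inv), 1e-9)
    expect_lt(abs(bloch_steady_state(prm, t1, invert = FALSE) - no_inv),
              1e-9)
  }
})

test_that("the 90-degree single-pulse limit reduces to the simple IR model", {
  prm <- seq_params(tr_ms = 5, flip_deg = 90, ti_ms = 300, rr_ms = 900,
                    n_views = 1)
  t1 <- c(150, 280, 300, 500, 777)
  expect_equal(mzss_ir(prm, t1, m0 = 1.3),
               mzss_simple(t1, 1.3, 300, 900), tolerance = 1e-12)
  expect_equal(perturbation_coefficient(prm, t1), rep(1, 5),
               tolerance = 1e-12)
})

test_that("perturbation coefficient is >= 1 and -> 1 for vanishing flip", {
  set.seed(7)
  for (i in 1:40) {
    prm <- random_valid_protocol()
    expect_gte(perturbation_coefficient(prm, runif(1, 80, 1500)),
               1 - 1e-9)
  }
  tiny <- seq_params(tr_ms = 5, flip_deg = 1e-4, ti_ms = 300,
                     rr_ms = 900, n_views = 33)
  expect_equal(perturbation_coefficient(tiny, 280), 1, tolerance = 1e-6)
})

test_that("oracle-validated spot values reproduce", {
  # frozen from the independent recursion run to steady state
  expect_equal(perturbation_coefficient(precision_protocol(), 280),
               1.289352, tolerance = 1e-6)
  expect_equal(mzss_ir(precision_protocol(), 280), 0.3545052,
               tolerance = 1e-6)
  expect_equal(f_weight(precision_protocol(), 500), 0.07052688,
               tolerance = 1e-6)
  expect_equal(f_weight(precision_protocol(750), 280), 0.3948551,
               tolerance = 1e-6)
  expect_equal(mzss_noinv(swine_protocol(), 400), 0.9245113,
               tolerance = 1e-6)
  expect_equal(mzss_simple(280, 1, 300, 900), 0.3551463,
               tolerance = 1e-6)
})

test_that("simple IR model obeys its limits and domain checks", {
  expect_equal(mzss_simple(1e9, 2, 300, 900), 0, tolerance = 1e-6)
  expect_equal(mzss_simple(280, 1.7, 1e5, 2e5), 1.7, tolerance = 1e-3)
  expect_error(mzss_simple(-5, 1, 300, 900), "t1_ms")
  expect_error(mzss_simple(280, 1, -1, 900), "> 0")
  expect_error(f_weight(accuracy_protocol(), c(300, NA)), "finite")
})

test_that("signal is linear in M0 and the no-inversion limits hold", {
  prm <- accuracy_protocol()
  expect_equal(mzss_ir(prm, 400, m0 = 0), 0)
  expect_equal(mzss_ir(prm, 400, m0 = 2), 2 * mzss_ir(prm, 400))
  # T1 -> 0: full recovery each RR regardless of the pulse train
  expect_equal(mzss_noinv(prm, 1e-3), 1, tolerance = 1e-9)
  tiny_flip <- seq_params(tr_ms = 5, flip_deg = 1e-5, ti_ms = 300,
                          rr_ms = 900, n_views = 33)
  expect_equal(mzss_noinv(tiny_flip, 400), 1, tolerance = 1e-6)
})

test_that("T1-weighting is monotone on the grid, positive over the
          post-contrast range", {
  grid <- t1_grid(grid_spec())
  protos <- c(list(accuracy_protocol(), precision_protocol(),
                   precision_protocol(750), swine_protocol()),
              lapply(protocol_suite(), `[[`, "params"))
  for (prm in protos) {
    # strict monotonicity is the one-to-one signal-T1 guarantee
    expect_true(all(diff(f_weight(prm, grid)) < 0))
  }
  # positivity (no de-rectification needed) over the post-contrast range:
  # holds for the simulation / tube-phantom protocols (RR <= 950 ms); the
  # null point moves down into the range as RR grows (e.g. RR = 1000 ms)
  for (prm in c(list(accuracy_protocol(), precision_protocol(),
                     precision_protocol(750)),
                lapply(protocol_suite(), `[[`, "params"))) {
    fv <- f_weight(prm, grid)
    expect_true(all(fv[grid <= 620] > 0))
  }
})

test_that("imperfect inversion reduces correctly and matches its oracle", {
  prm <- accuracy_protocol()
  grid <- seq(200, 600, by = 50)
  expect_equal(f_imperfect(prm, grid, beta = 1), f_weight(prm, grid),
               tolerance = 1e-12)
  for (t1 in grid) {
    expect_lt(abs(f_imperfect(prm, t1, beta = 0.92) -
                    ref_bloch(5, 15, 300, 900, 33, t1, beta = 0.92)),
              1e-9)
  }
  # a weaker inversion leaves Mz closer to equilibrium: larger signal
  expect_gt(f_imperfect(prm, 600, beta = 0.92), f_weight(prm, 600))
  expect_error(f_imperfect(prm, 300, beta = 1.2), "beta")
})

test_that("f_prime is negative with decreasing magnitude, flags boundaries", {
  prm <- precision_protocol()
  t1 <- seq(150, 750, by = 25)
  fp <- f_prime(prm, t1)
  expect_true(all(fp < 0))
  expect_false(any(attr(fp, "one_sided")))
  mag <- abs(as.numeric(f_prime(prm, seq(200, 600, by = 25))))
  expect_true(all(diff(mag) < 0))
  # agrees with a finite difference of the independent recursion
  fd <- (ref_bloch(5, 15, 300, 950, 33, 501) -
           ref_bloch(5, 15, 300, 950, 33, 499)) / 2
  expect_equal(as.numeric(f_prime(prm, 500)), fd, tolerance = 1e-7)
  at_edge <- f_prime(prm, c(100, 400, 800))
  expect_identical(as.logical(attr(at_edge, "one_sided")),
                   c(TRUE, FALSE, TRUE))
})

test_that("sequence parameter invariants are enforced", {
  expect_error(seq_params(5, 15, 300, 400, 33), "timing")
  expect_error(seq_params(5, 95, 300, 900, 33), "flip_deg")
  expect_error(seq_params(5, 15, 300, 900, 33, inversion_factor = 0),
               "inversion_factor")
  expect_error(seq_params(5, 15, 300, 900, 33.5), "n_views")
  expect_error(seq_params(-1, 15, 300, 900, 33), "tr_ms")
  prm <- update_params(accuracy_protocol(), rr_ms = 950)
  expect_equal(prm$rr_ms, 950)
  expect_error(update_params(accuracy_protocol(), rr_ms = 100), "timing")
})
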