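test_that("single-point calibration is self-consistent and linear", {
  prm <- precision_protocol()
  expect_equal(estimate_m0(f_weight(prm, 280), 280, prm), 1,
               tolerance = 1e-12)
  expect_equal(estimate_m0(2 * f_weight(prm, 280), 280, prm), 2,
               tolerance = 1e-12)
  # frozen oracle value of f(280) for the RR = 950 ms protocol
  expect_equal(estimate_m0(0.3545052, 280, prm), 1, tolerance = 1e-5)
  expect_error(estimate_m0(-1, 280, prm), "ref_signal")
  # reference sitting on the null point of the signal-T1 curve
  null_t1 <- uniroot(function(t) f_weight(prm, t), c(500, 800))$root
  expect_error(estimate_m0(0.5, null_t1, prm), "degenerate")
})

test_that("grid-search inversion round-trips, quantizes, clamps and flags", {
  prm <- accuracy_protocol()
  grid <- grid_spec()
  gt1 <- t1_grid(grid)
  on_grid <- gt1[c(1, 41, 105, 201, 281)]
  est <- invert_signal(2 * f_weight(prm, on_grid), 2, prm, grid)
  expect_equal(as.numeric(est), on_grid)

  off <- c(201.3, 333.7, 514.9)
  est2 <- invert_signal(f_weight(prm, off), 1, prm, grid)
  expect_true(all(abs(as.numeric(est2) - off) <= grid$step_ms))

  # brighter than the shortest-T1 model signal clamps low, flagged
  hot <- invert_signal(f_weight(prm, 100) * 1.5, 1, prm, grid)
  expect_equal(as.numeric(hot), 100)
  expect_true(attr(hot, "boundary"))

  mixed <- invert_signal(c(NA, f_weight(prm, 400), Inf), 1, prm, grid)
  expect_identical(as.logical(attr(mixed, "invalid")),
                   c(TRUE, FALSE, TRUE))
  expect_true(is.na(mixed[1]) && is.na(mixed[3]))
  expect_equal(mixed[2], 400)

  # monotone contract: brighter voxels never map to longer T1
  s <- sort(runif(50, f_weight(prm, 650), f_weight(prm, 150)))
  t1s <- as.numeric(invert_signal(s, 1, prm, grid))
  expect_true(all(diff(t1s) <= 0))
})

test_that("noiseless phantom maps recover compartment T1s to grid accuracy", {
  prm <- accuracy_protocol()
  uniform <- m0_composition(
    pd = c(background = 0.8, blood = 0.8, myocardium = 0.8, scar = 0.8),
    t2star_ms = c(background = 100, blood = 100, myocardium = 100,
                  scar = 100))
  spec <- phantom_spec(geometry = "cardiac", dim = c(24, 24, 6),
                       noise = "none", composition = uniform,
                       protocol = prm, seed = 3)
  ph <- generate_phantom(spec)
  fit <- refblochi(ph$image, prm, ref_t1_ms = 280, ref_roi = ph$ref_mask,
                   mask = ph$truth$labels > 0)
  for (lab in 1:3) {
    sel <- ph$truth$labels == lab
    true_t1 <- unique(ph$truth$t1[sel])
    expect_lt(abs(mean(fit$t1[sel]) - true_t1), 2.6)
  }
  expect_true(all(is.na(fit$t1[ph$truth$labels == 0])))
})

test_that("a global M0 scale cancels through the calibration", {
  prm <- accuracy_protocol()
  spec <- phantom_spec(geometry = "cardiac", dim = c(20, 20, 4),
                       noise = "none", protocol = prm, seed = 5)
  ph <- generate_phantom(spec)
  msk <- ph$truth$labels > 0
  f1 <- refblochi(ph$image, prm, 280, ref_roi = ph$ref_mask, mask = msk)
  f2 <- refblochi(ph$image * 1.1, prm, 280, ref_roi = ph$ref_mask,
                  mask = msk)
  expect_identical(f1$t1, f2$t1)
})

test_that("10% M0 heterogeneity biases compartments by under 20 ms", {
  prm <- accuracy_protocol()
  t1s <- seq(200, 600, by = 50)
  for (fac in c(0.9, 1.1)) {
    s <- fac * f_weight(prm, t1s)              # tissue M0 off by 10%
    est <- invert_signal(s, 1, prm, grid_spec())  # reference M0 = 1
    expect_lt(max(abs(as.numeric(est) - t1s)), 20.1)
  }
})

test_that("a biased reference T1 biases longer T1s by less than itself", {
  prm <- accuracy_protocol()
  t1s <- seq(282.5, 600, by = 2.5)
  for (shift in c(-30, 30)) {
    m0_hat <- f_weight(prm, 280) / f_weight(prm, 280 + shift)
    est <- invert_signal(f_weight(prm, t1s), m0_hat, prm, grid_spec())
    expect_lte(max(abs(as.numeric(est) - t1s)), 30)
  }
})

test_that("reference round-trip lands within one grid step", {
  prm <- precision_protocol()
  cal_sig <- 0.42
  m0 <- estimate_m0(cal_sig, 280, prm)
  back <- invert_signal(cal_sig, m0, prm, grid_spec())
  expect_lte(abs(as.numeric(back) - 280), 2.5)
})

test_that("refblochi object methods report the fit", {
  prm <- accuracy_protocol()
  spec <- phantom_spec(geometry = "cardiac", dim = c(16, 16, 4),
                       noise = "gaussian", snr = 30, protocol = prm,
                       seed = 11)
  ph <- generate_phantom(spec)
  fit <- refblochi(ph$image, prm, 280, ref_roi = ph$ref_mask,
                   mask = ph$truth$labels > 0)
  expect_s3_class(fit, "refblochi")
  expect_output(print(fit), "refblochi")
  expect_output(print(summary(fit)), "quantiles")
  expect_named(coef(fit), "m0")
  # predictions at the fitted T1s reproduce the model signal
  pred <- predict(fit)
  sel <- fit$mask & !fit$invalid
  expect_equal(pred[sel], fit$m0 * f_weight(prm, fit$t1[sel]))
  r <- residuals(fit)
  expect_equal(r[sel], ph$image[sel] - pred[sel])
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  expect_error(refblochi(ph$image, prm, 280), "ref_signal")
  expect_error(refblochi(ph$image, prm, 280, ref_signal = 0.3,
                         mask = array(1, c(2, 2, 2))), "mask")
})

test_that("ECVa follows the relaxation-rate ratio formula", {
  expect_equal(ecva(1150, 350), 0)
  expect_equal(ecva(350, 350, t1_m0_ms = 1500), 1 - 0.45)
  # blood-equivalent voxel at any hematocrit
  expect_equal(ecva(420, 420, t1_m0_ms = 1500, hct = 0.38), 1 - 0.38)
  # native-T1 assumption sensitivity is independent of myocardial T1:
  # (1/1150 - 1/1250) * 0.55 / (1/350 - 1/1500) = 0.01746692
  for (t1m in c(250, 300, 480)) {
    d <- ecva(t1m, 350, t1_m0_ms = 1250) - ecva(t1m, 350, t1_m0_ms = 1150)
    expect_equal(d, 0.01746692, tolerance = 1e-6)
    expect_equal(round(d, 2), 0.02)
  }
  expect_error(ecva(300, 1500), "degenerate")
  expect_error(ecva(-300, 350), "> 0")
  expect_error(ecva(300, 350, hct = 1.2), "hct")
})
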