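test_that("cross-correlation recovers exact shifts on uniform grids", {
  sched <- uniform_schedule(120)
  set.seed(2)
  base <- stats::dgamma(seq(0.5, 119.5), shape = 4, scale = 4) * 1e4
  x <- tac(sched, base)
  shifted <- tac(sched, c(rep(0, 5), base[1:115]))  # +5 s integer shift
  expect_equal(xcorr_delay(shifted, x), 5)
  expect_equal(xcorr_delay(x, shifted), -5)
  # antisymmetry on randomized shifts
  for (k in c(2, 9, 17)) {
    sh <- tac(sched, c(rep(0, k), base[1:(120 - k)]))
    expect_identical(xcorr_delay(sh, x), -xcorr_delay(x, sh))
  }
})

test_that("degenerate inputs for cross-correlation are handled", {
  sched <- uniform_schedule(60)
  flat <- tac(sched, rep(5, 60))
  bumpy <- tac(sched, stats::dnorm(1:60, 30, 5))
  expect_true(is.na(xcorr_delay(flat, bumpy)))
  expect_true(is.na(xcorr_delay(bumpy, flat)))
})

test_that("an accumulating TAC drives cross-correlation to large lags", {
  # small k2: the tissue peak moves to the scan end, cross-correlation
  # co-aligns peaks and so vastly overestimates the delay
  x <- clean_tissue(K1 = 200, k2 = 0.05)
  d <- xcorr_delay(x, h2o_idif)
  expect_gt(d, 30)
})

test_that("the one-tissue solver matches closed forms", {
  time <- seq(0, 100, by = 0.1)
  inp <- stats::dgamma(time, shape = 3, scale = 3) * 1e4

  # no influx: identically zero
  expect_equal(predict_one_tissue(time, inp, K1 = 0, k2 = 1),
               rep(0, length(time)))

  # no efflux: K1 * running integral of the input
  ct <- predict_one_tissue(time, inp, K1 = 60, k2 = 0)
  n <- length(time)
  trapz <- c(0, cumsum((inp[-1] + inp[-n]) / 2 * 0.1))
  expect_equal(ct, (60 / 6000) * trapz, tolerance = 1e-10)

  # impulse input: exponential washout with rate k2/60 per second
  imp <- c(1, rep(0, length(time) - 1))
  ct2 <- predict_one_tissue(time, imp, K1 = 100, k2 = 2)
  washout <- ct2[100:1000]
  ratios <- washout[-1] / washout[-length(washout)]
  expect_equal(ratios, rep(exp(-2 / 60 * 0.1), length(ratios)),
               tolerance = 1e-8)
  # half-life ln 2 / k2
  hl <- 0.1 * (which.min(abs(washout - washout[1] / 2)) - 1)
  expect_equal(hl, 60 * log(2) / 2, tolerance = 0.1)
})

test_that("frame averages of smooth model curves track mid-time values", {
  time <- seq(0, 180, by = 0.1)
  inp <- gamma_variate_input(h2o_idif_model, time)
  ct <- predict_one_tissue(time, inp, K1 = 80, k2 = 0.5)
  avg <- tacdelay:::frame_average(time, ct, h2o)
  mid <- stats::approx(time, ct, xout = h2o$mid_time)$y
  # discretization error O(duration^2): compare on the late 20 s frames
  # where the curve is smooth, scaled to the curve magnitude
  late <- 52:54
  expect_lt(max(abs(avg[late] - mid[late])) / max(ct), 0.01)
  # and exactly on the 1 s frames of the upslope within a loose band
  early <- 1:40
  expect_lt(max(abs(avg[early] - mid[early])) / max(ct), 0.02)
})

test_that("the one-tissue fit recovers noise-free parameters", {
  x <- clean_tissue(K1 = 50, k2 = 1, delay = 3)
  fit <- one_tissue_fit(x, h2o_idif)
  expect_true(fit$converged)
  expect_lt(abs(fit$delay - 3), 0.5)
  expect_lt(abs(fit$K1 - 50) / 50, 0.02)
  expect_lt(abs(fit$k2 - 1), 0.02)

  # the fitted optimum is at least as good as the generating parameters
  time <- tacdelay:::dense_grid(h2o, 0.1)
  a0 <- tacdelay:::densify_tac(h2o_idif, time)
  m_true <- tacdelay:::frame_average(
    time, predict_one_tissue(time, a0, 50, 1, 3), h2o)
  rss_true <- sum((x$activity - m_true)^2)
  expect_lte(fit$rss, rss_true + 1e-8)
})

test_that("a scaled input fits with near-zero delay", {
  # tissue = scaled input is the fast-exchange limit (k2 -> Inf with
  # K1/k2 fixed), so the k2 search range must extend far beyond the
  # tissue-like values for the delay to vanish
  scaled <- tac(h2o, h2o_idif$activity * 0.3)
  fit <- one_tissue_fit(scaled, h2o_idif, k2_range = c(0.01, 600))
  expect_lt(abs(fit$delay), 0.75)
  expect_equal(fit$K1 / (100 * fit$k2), 0.3, tolerance = 0.05)
})

test_that("high-noise fits still return an estimate with a flag", {
  x <- clean_tissue(K1 = 40, k2 = 0.4, delay = 5, sigma = 0.4, seed = 21L)
  fit <- one_tissue_fit(x, h2o_idif)
  expect_true(is.finite(fit$delay))
  expect_true(is.logical(fit$converged))
  expect_true(fit$delay >= -20 && fit$delay <= 60)
})

test_that("one_tissue_fit behaves like a model object", {
  x <- clean_tissue(K1 = 50, k2 = 1, delay = 3, sigma = 0.1, seed = 2L)
  fit <- one_tissue_fit(x, h2o_idif)
  expect_named(coef(fit), c("K1", "k2", "delay"))
  expect_equal(length(residuals(fit)), length(fit$observed))
  expect_equal(fitted(fit) + residuals(fit), fit$observed)
  expect_equal(predict(fit), fitted(fit))
  expect_output(print(fit), "K1")
  sims <- simulate(fit, nsim = 2, seed = 5, sigma = 0.2)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "tac")
  # reproducible given the seed
  sims2 <- simulate(fit, nsim = 2, seed = 5, sigma = 0.2)
  expect_identical(sims[[1]]$activity, sims2[[1]]$activity)
})

test_that("fitting is restricted to frames before the endtime", {
  x <- clean_tissue(K1 = 50, k2 = 1, delay = 3)
  fit <- one_tissue_fit(x, h2o_idif, endtime = 120)
  expect_true(all(fit$fit_schedule$mid_time <= 120))
  expect_lt(length(fit$observed), n_frames(h2o))
})
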