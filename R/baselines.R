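#' Cross-correlation delay estimate
#'
#' Both curves are linearly resampled onto a common uniform grid over
#' their shared mid-time support and the full (zero-padded)
#' cross-correlation of the raw curves is computed over all integer lags
#' within `max_lag` seconds; the lag of highest correlation is the delay,
#' with the sign convention `dT = T_tissue - T_input` (a tissue curve
#' arriving later than the input gives a positive delay). The raw (not
#' mean-subtracted) product is used: activity curves are non-negative
#' and the estimator's characteristic behaviour is to co-align their
#' peaks, which mean subtraction of strongly trending curves destroys.
#'
#' @param tissue,input_fn [tac()] objects.
#' @param resample_dt resampling step in seconds (default 1).
#' @param max_lag largest lag searched, seconds (default 120).
#' @param ... unused.
#' @return Delay in seconds; `NA` when either curve has zero variance.
#' @export
xcorr_delay <- function(tissue, input_fn, resample_dt = 1, max_lag = 120,
                        ...) {
  stopifnot(inherits(tissue, "tac"), inherits(input_fn, "tac"))
  t0 <- max(min(tissue$schedule$mid_time), min(input_fn$schedule$mid_time))
  t1 <- min(max(tissue$schedule$mid_time), max(input_fn$schedule$mid_time))
  if (t1 - t0 < 2 * resample_dt)
    stop("curves share too little temporal support", call. = FALSE)
  grid <- seq(t0, t1, by = resample_dt)
  x <- stats::approx(tissue$schedule$mid_time, tissue$activity, grid)$y
  y <- stats::approx(input_fn$schedule$mid_time, input_fn$activity, grid)$y
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  n <- length(grid)
  kmax <- min(n - 2L, floor(max_lag / resample_dt))
  lags <- (-kmax):kmax
  # normalized by the global signal norms (constant in the lag, so the
  # argmax equals that of the raw product sum)
  nrm <- sqrt(sum(x^2) * sum(y^2))
  r <- vapply(lags, function(k) {
    if (k >= 0) sum(x[(1L + k):n] * y[1:(n - k)])
    else sum(x[1:(n + k)] * y[(1L - k):n])
  }, numeric(1)) / nrm
  lags[which.max(r)] * resample_dt
}

#' Predict a tissue curve from the one-tissue compartment model
#'
#' Solves `dC_T/dt = K1 * C_A(t - delay) - k2 * C_T`, `C_T(0) = 0`, on a
#' uniform dense grid via the exact exponential-kernel convolution
#' `C_T = K1 * C_A(t - delay) (x) exp(-k2 t)` (piecewise-linear input,
#' recursive evaluation). `K1` in ml/(100 g min) is converted to 1/s
#' assuming a tissue density of 1 g/ml (divide by 6000); `k2` in 1/min is
#' converted to 1/s.
#'
#' @param time uniform dense time grid, seconds (step <= 0.1 s advised).
#' @param input input-function values (Bq/ml) on `time`.
#' @param K1 influx rate, ml/(100 g min); >= 0.
#' @param k2 efflux rate, 1/min; >= 0.
#' @param delay arrival delay of the input at the tissue, seconds.
#' @return Tissue curve (Bq/ml) on `time`.
#' @export
predict_one_tissue <- function(time, input, K1, k2, delay = 0) {
  stopifnot(K1 >= 0, k2 >= 0)
  a <- if (delay != 0) shift_dense(time, input, delay) else input
  (K1 / 6000) * exp_conv(time, a, k2 / 60)
}

#' Fit a one-tissue compartment model with incorporated delay
#'
#' The comparator kinetic estimator: a one-tissue model whose input is
#' shifted by a jointly estimated delay, least-squares fitted to the
#' tissue frames with mid-time up to `endtime` (180 s by default). The
#' model prediction is averaged over each frame before comparison. The
#' delay is first searched on a coarse grid (`delay_grid`, default -20 to
#' +60 s in 0.5 s steps) with `K1` profiled analytically (the model is
#' linear in `K1`) and `k2` profiled by 1-D optimization at each grid
#' point, then all three parameters are refined jointly. No blood-volume
#' fraction term is included.
#'
#' @param tissue,input_fn [tac()] objects on compatible schedules.
#' @param endtime last tissue mid-time used in the fit, seconds
#'   (default 180). If the curves cover less, the available span is used.
#' @param delay_grid coarse delay search grid, seconds.
#' @param dense_dt dense model grid step, seconds (default 0.1).
#' @param k2_range `k2` search interval for the profile, 1/min.
#' @param k2_grid_n number of log-spaced `k2` values in the grid stage.
#' @param ... unused.
#' @return An object of class `one_tissue_fit`: `K1` (ml/100g/min), `k2`
#'   (1/min), `delay` (s), `rss`, `converged`, plus the fitted frames.
#' @export
one_tissue_fit <- function(tissue, input_fn, endtime = 180,
                           delay_grid = seq(-20, 60, by = 0.5),
                           dense_dt = 0.1, k2_range = c(1e-2, 12),
                           k2_grid_n = 24L, ...) {
  stopifnot(inherits(tissue, "tac"), inherits(input_fn, "tac"))
  sched <- tissue$schedule
  if (schedule_end(sched) < endtime) {
    message(sprintf(
      "curves cover %g s < endtime %g s; using the available span",
      schedule_end(sched), endtime))
    endtime <- schedule_end(sched)
  }
  sel <- which(sched$mid_time <= endtime)
  fit_sched <- frame_schedule(sched$frame_start[sel],
                              sched$frame_duration[sel])
  y <- tissue$activity[sel]
  time <- dense_grid(sched, dense_dt)
  n <- length(time)
  a0 <- densify_tac(input_fn, time)
  W <- frame_weight_matrix(time, fit_sched)
  # The model is linear in K1 and, being time-invariant, delaying the
  # input equals delaying the convolution output; so convolve once per
  # k2 and realise every candidate delay as a (usually integer) shift of
  # that output, profiling K1 analytically for all delays at once.
  sh <- delay_grid / dense_dt
  integer_shifts <- all(abs(sh - round(sh)) < 1e-9)
  if (integer_shifts) {
    sh <- round(sh)
    idx <- outer(seq_len(n), sh, `-`)
    zero_mask <- idx >= 1L
    idx_cl <- pmin(pmax(idx, 1L), n)
  }
  shift_cols <- function(conv) {
    if (integer_shifts)
      matrix(conv[idx_cl], nrow = n) * zero_mask
    else
      vapply(delay_grid, function(d) shift_dense(time, conv, d),
             numeric(n))
  }
  k2g <- exp(seq(log(k2_range[1L]), log(k2_range[2L]),
                 length.out = k2_grid_n))
  yty <- sum(y^2)
  best <- NULL
  for (k2 in k2g) {
    conv <- exp_conv(time, a0, k2 / 60) / 6000  # K1 = 1 response
    M <- W %*% shift_cols(conv)                 # frames x delays
    num <- as.vector(crossprod(M, y))
    den <- colSums(M^2)
    K1s <- ifelse(den > 0, pmax(0, num / den), 0)
    rss <- yty - 2 * K1s * num + K1s^2 * den
    j <- which.min(rss)
    if (is.null(best) || rss[j] < best$rss)
      best <- list(K1 = K1s[j], k2 = k2, delay = delay_grid[j],
                   rss = rss[j])
  }
  # joint refinement around the grid optimum
  obj <- function(p) {
    m <- frame_average(time, predict_one_tissue(time, a0, p[1], p[2], p[3]),
                       fit_sched)
    sum((y - m)^2)
  }
  ref <- tryCatch(
    stats::nlminb(c(best$K1, best$k2, best$delay), obj,
                  lower = c(0, 0, min(delay_grid)),
                  upper = c(Inf, k2_range[2], max(delay_grid))),
    error = function(e) NULL)
  if (!is.null(ref) && is.finite(ref$objective) &&
      ref$objective <= best$rss) {
    out <- list(K1 = ref$par[1], k2 = ref$par[2], delay = ref$par[3],
                rss = ref$objective, converged = TRUE)
  } else {
    out <- list(K1 = best$K1, k2 = best$k2, delay = best$delay,
                rss = best$rss, converged = !is.null(best))
  }
  m <- frame_average(time,
                     predict_one_tissue(time, a0, out$K1, out$k2, out$delay),
                     fit_sched)
  structure(c(out,
              list(fitted_values = m, observed = y,
                   fit_schedule = fit_sched, endtime = endtime,
                   tissue = tissue, input_fn = input_fn,
                   dense_dt = dense_dt, call = match.call())),
            class = "one_tissue_fit")
}

#' @export
print.one_tissue_fit <- function(x, ...) {
  cat("One-tissue compartment fit with incorporated delay\n")
  cat(sprintf("  K1 = %.4g ml/(100 g min), k2 = %.4g 1/min, delay = %.2f s\n",
              x$K1, x$k2, x$delay))
  cat(sprintf("  rss = %.6g over %d frames (endtime %g s)%s\n",
              x$rss, length(x$observed), x$endtime,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' @export
coef.one_tissue_fit <- function(object, ...) {
  c(K1 = object$K1, k2 = object$k2, delay = object$delay)
}

#' Predict frame activity from a fitted one-tissue model
#'
#' @param object a [one_tissue_fit()].
#' @param newdata optional [frame_schedule()] to average the model onto;
#'   defaults to the fitted frames.
#' @param ... unused.
#' @return numeric vector of frame-averaged activities (Bq/ml).
#' @export
predict.one_tissue_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  stopifnot(inherits(newdata, "frame_schedule"))
  time <- seq(0, schedule_end(newdata), by = object$dense_dt)
  a0 <- densify_tac(object$input_fn, time)
  frame_average(time,
                predict_one_tissue(time, a0, object$K1, object$k2,
                                   object$delay),
                newdata)
}

#' @export
fitted.one_tissue_fit <- function(object, ...) object$fitted_values

#' @export
residuals.one_tissue_fit <- function(object, ...) {
  object$observed - object$fitted_values
}

#' @export
plot.one_tissue_fit <- function(x, ..., xlab = "Frame mid-time [s]",
                                ylab = "Activity [Bq/ml]") {
  tt <- x$fit_schedule$mid_time
  graphics::plot(tt, x$observed, xlab = xlab, ylab = ylab, pch = 1, ...)
  graphics::lines(tt, x$fitted_values, col = "red3", lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = c("measured", "model"),
                   col = c("black", "red3"), pch = c(1, NA),
                   lty = c(NA, 1))
  invisible(x)
}

#' Simulate noisy TACs from a fitted one-tissue model
#'
#' Draws `nsim` replicate tissue curves from the fitted model with
#' multiplicative Gaussian frame noise (see [apply_noise()]).
#'
#' @param object a [one_tissue_fit()].
#' @param nsim number of replicates.
#' @param seed integer seed for reproducibility.
#' @param sigma noise standard deviation (unitless, default 0.1).
#' @param ... unused.
#' @return A list of [tac()] objects of length `nsim`.
#' @export
simulate.one_tissue_fit <- function(object, nsim = 1, seed = NULL,
                                    sigma = 0.1, ...) {
  sched <- object$tissue$schedule
  time <- dense_grid(sched, object$dense_dt)
  a0 <- densify_tac(object$input_fn, time)
  clean <- tac(sched,
               frame_average(time,
                             predict_one_tissue(time, a0, object$K1,
                                                object$k2, object$delay),
                             sched))
  base <- if (is.null(seed)) 0L else as.integer(seed)
  lapply(seq_len(nsim), function(i)
    apply_noise(clean, sigma, seed = base + i))
}
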