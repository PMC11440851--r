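#' Control parameters for the onset estimator
#'
#' Collects every tunable of the cumulative-sum onset algorithm with its
#' default. Defaults follow the published configuration of the method;
#' `band_fraction` and `min_points` may be fine-tuned for more or less
#' sensitive plateau detection, and `shape_factor` is exposed only as an
#' expert setting (the onset formula `T = c - shape_factor * b` uses the
#' empirically chosen constant 3.5).
#'
#' @param min_points minimum number of consecutive points that make a
#'   plateau (default 3).
#' @param band_fraction plateau tolerance band as a fraction of the maximum
#'   of the summed curve over the detection window (default 0.001, i.e.
#'   0.1 %).
#' @param window_s plateau detection window in seconds from scan start
#'   (default 120); the tail of the curve is never scanned.
#' @param max_ranges maximum number of candidate fitting ranges
#'   (default 10).
#' @param r2_min minimum goodness of fit R^2 for a fit to be accepted
#'   (default 0.8).
#' @param bounds named list of `c(lower, upper)` box bounds for the fit
#'   parameters: `a` (amplitude scale, default `c(0.1, 2e7)`), `b`
#'   (transition tightness in s, default `c(0.01, 10)`) and `c`
#'   (transition centre in s, default `c(0, 60)`).
#' @param shape_factor the onset-formula constant (default 3.5).
#' @return A list of class `onset_control`.
#' @export
onset_control <- function(min_points = 3L,
                          band_fraction = 0.001,
                          window_s = 120,
                          max_ranges = 10L,
                          r2_min = 0.8,
                          bounds = list(a = c(0.1, 2e7),
                                        b = c(0.01, 10),
                                        c = c(0, 60)),
                          shape_factor = 3.5) {
  stopifnot(min_points >= 2, band_fraction >= 0, window_s > 0,
            max_ranges >= 1, is.list(bounds),
            all(c("a", "b", "c") %in% names(bounds)))
  structure(list(min_points = as.integer(min_points),
                 band_fraction = band_fraction,
                 window_s = window_s,
                 max_ranges = as.integer(max_ranges),
                 r2_min = r2_min,
                 bounds = bounds,
                 shape_factor = shape_factor),
            class = "onset_control")
}

#' Read onset-estimator settings from a JSON config file
#'
#' Accepts flat dotted keys (`plateau.min_points`, `plateau.band_fraction`,
#' `plateau.window_s`, `fit.max_ranges`, `fit.r2_min`, `fit.bounds`,
#' `onset.shape_factor`); unknown keys raise an error.
#'
#' @param path JSON file path.
#' @return An [onset_control()].
#' @export
read_onset_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctrl <- onset_control()
  map <- c("plateau.min_points" = "min_points",
           "plateau.band_fraction" = "band_fraction",
           "plateau.window_s" = "window_s",
           "fit.max_ranges" = "max_ranges",
           "fit.r2_min" = "r2_min",
           "onset.shape_factor" = "shape_factor")
  for (key in names(cfg)) {
    if (key == "fit.bounds") {
      b <- lapply(cfg[[key]], as.numeric)
      ctrl$bounds[names(b)] <- b
    } else if (key %in% names(map)) {
      ctrl[[map[[key]]]] <- as.numeric(cfg[[key]])
    } else {
      stop("unknown config key: ", key, call. = FALSE)
    }
  }
  ctrl$min_points <- as.integer(ctrl$min_points)
  ctrl$max_ranges <- as.integer(ctrl$max_ranges)
  ctrl
}

#' Logistic onset model and its integral
#'
#' `sigmoid_model()` evaluates the three-parameter logistic
#' `a / (1 + exp((c - t)/b))`: `a` is the saturation level reached for
#' `t >> c`, `b` (seconds) sets how rapidly the curve transitions from 0
#' to `a` (`b -> 0` means an instantaneous switch), and `c` (seconds) is
#' the centre of the transition. `summed_model()` evaluates its
#' antiderivative `a*b*log(exp((c - t)/b) + 1) + a*(t - c)`, the function
#' actually fitted to cumulatively summed TACs. Both are overflow-safe for
#' large `(c - t)/b`.
#'
#' @param t time(s), seconds.
#' @param a,b,c model parameters; `b > 0`.
#' @return numeric vector of model values.
#' @export
sigmoid_model <- function(t, a, b, c) {
  if (!is.finite(b) || b <= 0) stop("b must be > 0", call. = FALSE)
  a * stats::plogis((t - c) / b)
}

#' @rdname sigmoid_model
#' @export
summed_model <- function(t, a, b, c) {
  if (!is.finite(b) || b <= 0) stop("b must be > 0", call. = FALSE)
  z <- (c - t) / b
  # softplus(z) = log(1 + exp(z)), evaluated stably in both tails
  sp <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  a * b * sp + a * (t - c)
}

#' Onset time from fitted parameters
#'
#' The transition centre `c` lies after the true departure from baseline;
#' the onset is taken `shape_factor` transition widths earlier:
#' `T = c - shape_factor * b`, with the constant 3.5 chosen empirically.
#'
#' @param b,c fitted parameters (seconds).
#' @param shape_factor shape constant, default 3.5.
#' @return onset time in seconds.
#' @export
onset_time <- function(b, c, shape_factor = 3.5) c - shape_factor * b

#' Detect a plateau in a cumulatively summed TAC
#'
#' Early spurious activity (e.g. the venous bolus passing the arm of
#' injection) adds a step to the summed curve followed by a flat plateau
#' before the arterial rise; a fit would lock onto the first step. This
#' detector scans frames with mid-time within `window` seconds of scan
#' start for runs of at least `min_points` consecutive values that lie
#' within a band of `band_fraction` times the window maximum of each
#' other. Among the detected runs, the one immediately preceding the
#' largest subsequent level rise is reported (so the main, arterial rise
#' is preserved by the correction). A curve whose largest rise does not
#' exceed the band reports no plateau.
#'
#' @param curve a `cumulative_curve`.
#' @param min_points,band_fraction,window see [onset_control()].
#' @return A list of class `plateau_correction` with `detected`,
#'   `plateau_end_index`, `plateau_level`, `n_runs`.
#' @export
detect_plateau <- function(curve, min_points = 3L, band_fraction = 0.001,
                           window = 120) {
  stopifnot(inherits(curve, "cumulative_curve"))
  v <- curve$values
  mid <- curve$schedule$mid_time
  win <- which(mid <= window)
  none <- structure(list(detected = FALSE, plateau_end_index = NA_integer_,
                         plateau_level = NA_real_, n_runs = 0L),
                    class = "plateau_correction")
  if (length(win) < min_points) return(none)
  band <- band_fraction * max(v[win])
  # maximal runs by greedy left-to-right extension: extend while the run's
  # max - min stays within the band
  runs <- list()
  i <- 1L
  nw <- length(win)
  while (i <= nw) {
    lo <- hi <- v[win[i]]
    j <- i
    while (j < nw) {
      nlo <- min(lo, v[win[j + 1L]])
      nhi <- max(hi, v[win[j + 1L]])
      if (nhi - nlo <= band) {
        j <- j + 1L; lo <- nlo; hi <- nhi
      } else break
    }
    if (j - i + 1L >= min_points)
      runs[[length(runs) + 1L]] <-
        list(start = win[i], end = win[j], level = mean(v[win[i]:win[j]]))
    i <- j + 1L
  }
  if (length(runs) == 0L) return(none)
  # level rise following each run: to the next run's level, or (for the
  # last run) to the maximum of the remaining full curve
  levels <- vapply(runs, `[[`, numeric(1), "level")
  m <- length(runs)
  rises <- numeric(m)
  if (m > 1L) rises[seq_len(m - 1L)] <- diff(levels)
  last_end <- runs[[m]]$end
  rises[m] <- if (last_end < length(v)) max(v[(last_end + 1L):length(v)]) - levels[m]
              else 0
  if (max(rises) <= band) return(none)  # essentially flat: nothing to correct
  pick <- max(which(rises == max(rises)))  # ties: the later run
  structure(list(detected = TRUE,
                 plateau_end_index = runs[[pick]]$end,
                 plateau_level = levels[pick],
                 n_runs = m),
            class = "plateau_correction")
}

#' Apply a plateau correction to a summed curve
#'
#' Every value up to and including the plateau end is set to zero and
#' every following value is lowered by the plateau level (floored at 0),
#' so the fit locks onto the rise that follows the plateau.
#'
#' @param curve a `cumulative_curve`.
#' @param corr a `plateau_correction` from [detect_plateau()].
#' @return A corrected `cumulative_curve` (`plateau_corrected = TRUE`);
#'   if `corr$detected` is `FALSE` the curve is returned unchanged with a
#'   warning.
#' @export
apply_plateau_correction <- function(curve, corr) {
  stopifnot(inherits(curve, "cumulative_curve"),
            inherits(corr, "plateau_correction"))
  if (!isTRUE(corr$detected)) {
    warning("no plateau detected; curve returned unchanged", call. = FALSE)
    return(curve)
  }
  v <- curve$values
  e <- corr$plateau_end_index
  v[seq_len(e)] <- 0
  if (e < length(v)) {
    idx <- (e + 1L):length(v)
    v[idx] <- pmax(0, v[idx] - corr$plateau_level)
  }
  cumulative_curve(curve$schedule, v, plateau_corrected = TRUE)
}

# |second derivative| of values on the (non-uniform) mid-time grid, by
# three-point central differences; NA at both endpoints.
second_derivative <- function(tt, v) {
  n <- length(v)
  d2 <- rep(NA_real_, n)
  if (n < 3L) return(d2)
  i <- 2:(n - 1L)
  h1 <- tt[i] - tt[i - 1L]
  h2 <- tt[i + 1L] - tt[i]
  d2[i] <- 2 * (v[i - 1L] / (h1 * (h1 + h2)) -
                v[i] / (h1 * h2) +
                v[i + 1L] / (h2 * (h1 + h2)))
  d2
}

#' Select candidate fitting-range endpoints
#'
#' The summed model tends to the straight asymptote `a*(t - c)` for
#' `t >> c`, while measured summed TACs bend away from it (falling off, or
#' rising above it for accumulating tracers). Candidate range endpoints
#' are placed where the curve bends most: local maxima of the absolute
#' second derivative on the mid-time grid (adjacent-point comparison, ties
#' to the earlier index), ranked by peak height; the `max_ranges` largest
#' are returned. When no interior peak exists (e.g. a perfect ramp) the
#' last frame is the fallback endpoint, so fitting can always proceed.
#'
#' @param curve a `cumulative_curve` with at least 5 frames.
#' @param max_ranges maximum number of endpoints (default 10).
#' @param min_index smallest usable endpoint index (default 5; a 3-parameter
#'   fit needs at least 5 points).
#' @return Integer vector of frame indices, ordered by descending peak
#'   magnitude.
#' @export
select_fit_endpoints <- function(curve, max_ranges = 10L, min_index = 5L) {
  stopifnot(inherits(curve, "cumulative_curve"))
  v <- curve$values
  tt <- curve$schedule$mid_time
  n <- length(v)
  if (n < 5L) stop("too few frames to select fitting ranges", call. = FALSE)
  ad2 <- abs(second_derivative(tt, v))
  # local maxima by adjacent comparison over interior points; a run of
  # equal values yields its first index
  idx <- 3:(n - 2L)
  is_peak <- ad2[idx] > ad2[idx - 1L] & ad2[idx] >= ad2[idx + 1L] &
    ad2[idx] > 0
  peaks <- idx[which(is_peak)]
  peaks <- peaks[peaks >= min_index]
  if (length(peaks) == 0L) return(n)
  ord <- order(-ad2[peaks], peaks)
  utils::head(peaks[ord], max_ranges)
}

#' Fit the summed onset model over one range
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box bounds)
#' of [summed_model()] against `curve$values[1:end_index]` at frame
#' mid-times. The range always starts at the first frame: after plateau
#' correction the curve is zero before onset, so the start adds no bias.
#' Two starting points are tried and the lower-residual solution kept:
#' one from the late-slope asymptote (`a` = end slope, `c` = its zero
#' intercept `t_end - y_end/slope`), one from coarse curve statistics
#' (`a` = final value / elapsed time, `c` = time of half-maximum); `b`
#' starts at 1 s, and all starts are clipped into bounds. Optimizer
#' failure and degenerate ranges (zero total sum of squares) are encoded
#' as `r_squared = -Inf`, never thrown.
#'
#' @param curve a `cumulative_curve`.
#' @param end_index last frame index of the range (>= 5).
#' @param control an [onset_control()].
#' @return A list of class `onset_range_fit`: `params` (named a, b, c),
#'   `r_squared`, `range_end_index`, `range_end_time`, `onset_time`,
#'   `at_bound`, `ok`.
#' @export
fit_summed_range <- function(curve, end_index, control = onset_control()) {
  stopifnot(inherits(curve, "cumulative_curve"))
  end_index <- as.integer(end_index)
  if (end_index < 5L || end_index > n_frames(curve$schedule))
    stop("end_index must be in [5, n_frames]", call. = FALSE)
  tt <- curve$schedule$mid_time[seq_len(end_index)]
  y <- curve$values[seq_len(end_index)]
  bl <- control$bounds
  lower <- c(bl$a[1], bl$b[1], bl$c[1])
  upper <- c(bl$a[2], bl$b[2], bl$c[2])
  failed <- structure(
    list(params = c(a = NA_real_, b = NA_real_, c = NA_real_),
         r_squared = -Inf, range_end_index = end_index,
         range_end_time = tt[end_index], onset_time = NA_real_,
         at_bound = FALSE, ok = FALSE),
    class = "onset_range_fit")
  ss_tot <- sum((y - mean(y))^2)
  if (!is.finite(ss_tot) || ss_tot <= 0) return(failed)
  clip <- function(x, b) min(max(x, b[1]), b[2])
  half <- which(y >= y[end_index] / 2)
  start_half <- c(clip(y[end_index] / max(tt[end_index], 1e-6), bl$a),
                  clip(1, bl$b),
                  clip(if (length(half)) tt[half[1L]] else
                         tt[end_index] / 2, bl$c))
  k <- max(1L, end_index - 3L)
  slope <- (y[end_index] - y[k]) / (tt[end_index] - tt[k])
  start_asym <- if (is.finite(slope) && slope > 0)
    c(clip(slope, bl$a), clip(1, bl$b),
      clip(tt[end_index] - y[end_index] / slope, bl$c))
  else NULL
  resid_fn <- function(p) summed_model(tt, p[1], p[2], p[3]) - y
  best <- NULL
  for (start in Filter(Negate(is.null), list(start_asym, start_half))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$par))) next
    rss <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) return(failed)
  p <- best$par
  r2 <- 1 - sum((summed_model(tt, p[1], p[2], p[3]) - y)^2) / ss_tot
  structure(
    list(params = c(a = p[1], b = p[2], c = p[3]),
         r_squared = r2, range_end_index = end_index,
         range_end_time = tt[end_index],
         onset_time = onset_time(p[2], p[3], control$shape_factor),
         at_bound = any(abs(p - lower) < 1e-8) || any(abs(p - upper) < 1e-8),
         ok = TRUE),
    class = "onset_range_fit")
}

#' Filter and aggregate per-range fits into one onset estimate
#'
#' A fit is accepted when it converged, `r_squared >= r2_min`, its onset
#' time is positive, and its onset time lies before the endpoint of its
#' fitting range. The top half (ceiling of n/2) of the accepted fits by
#' R^2 is kept and the component-wise median of their parameters taken;
#' the estimate's onset time is `median(c) - shape_factor * median(b)`.
#'
#' @param fits list of `onset_range_fit` objects.
#' @param control an [onset_control()].
#' @return A list of class `onset_estimate` with `onset_time` (NA when no
#'   fit was accepted), `n_fits_attempted`, `n_fits_accepted`,
#'   `used_fallback`, `median_params`, `accepted` (the kept fits).
#' @export
aggregate_fits <- function(fits, control = onset_control()) {
  ok <- vapply(fits, function(f)
    isTRUE(f$ok) &&
      is.finite(f$r_squared) && f$r_squared >= control$r2_min &&
      is.finite(f$onset_time) && f$onset_time > 0 &&
      f$onset_time < f$range_end_time,
    logical(1))
  acc <- fits[ok]
  if (length(acc) == 0L)
    return(structure(list(onset_time = NA_real_,
                          n_fits_attempted = length(fits),
                          n_fits_accepted = 0L,
                          used_fallback = FALSE,
                          median_params = c(a = NA_real_, b = NA_real_,
                                            c = NA_real_),
                          accepted = list()),
                     class = "onset_estimate"))
  r2 <- vapply(acc, `[[`, numeric(1), "r_squared")
  keep <- acc[order(-r2)][seq_len(ceiling(length(acc) / 2))]
  pm <- sapply(keep, `[[`, "params")  # 3 x k matrix
  med <- apply(pm, 1L, stats::median)
  structure(list(onset_time = onset_time(med[["b"]], med[["c"]],
                                         control$shape_factor),
                 n_fits_attempted = length(fits),
                 n_fits_accepted = length(acc),
                 used_fallback = FALSE,
                 median_params = med,
                 accepted = keep),
            class = "onset_estimate")
}

#' Fit the onset time of a time-activity curve
#'
#' The full single-curve pipeline of the proposed delay algorithm:
#' cumulative summation with frame weighting, plateau detection and
#' correction, candidate-range selection at the largest bends of the
#' summed curve, bounded fitting of the summed onset model over each
#' range, filtering, and median aggregation of the best half of the
#' accepted fits. Both tissue curves and the input function go through
#' this identical processing.
#'
#' @param x a [tac()].
#' @param control an [onset_control()].
#' @return An object of class `onset_fit`; its `estimate$onset_time` is
#'   `NA` when no fit was accepted (degenerate or pure-noise curves fail
#'   softly, they do not throw).
#' @examples
#' sched <- h2o_schedule()
#' idif <- input_tac(input_preset("h2o_idif"), sched)
#' fit <- onset_fit(idif)
#' coef(fit)
#' @export
onset_fit <- function(x, control = onset_control()) {
  stopifnot(inherits(x, "tac"), inherits(control, "onset_control"))
  curve <- cumulative_sum(x)
  plateau <- detect_plateau(curve, control$min_points,
                            control$band_fraction, control$window_s)
  corrected <- if (plateau$detected)
    apply_plateau_correction(curve, plateau) else curve
  n <- n_frames(x$schedule)
  est <- if (n < 5L || all(corrected$values == 0)) {
    structure(list(onset_time = NA_real_, n_fits_attempted = 0L,
                   n_fits_accepted = 0L, used_fallback = FALSE,
                   median_params = c(a = NA_real_, b = NA_real_,
                                     c = NA_real_),
                   accepted = list()),
              class = "onset_estimate")
  } else {
    ends <- select_fit_endpoints(corrected, control$max_ranges)
    fits <- lapply(ends, fit_summed_range, curve = corrected,
                   control = control)
    aggregate_fits(fits, control)
  }
  structure(list(estimate = est,
                 curve = corrected,
                 plateau = plateau,
                 tac = x,
                 control = control,
                 call = match.call()),
            class = "onset_fit")
}

#' Estimate the tissue-to-input arrival delay
#'
#' Estimates the onset time of the tissue curve and of the input function
#' independently (identical processing for both) and returns their
#' difference `dT = T_tissue - T_input`. `method = "xcorr"` and
#' `method = "onetc"` dispatch to the comparator estimators
#' ([xcorr_delay()] and [one_tissue_fit()]).
#'
#' @param tissue a [tac()].
#' @param input_fn a [tac()] (the input function).
#' @param method one of `"onset"` (the proposed algorithm, default),
#'   `"xcorr"`, `"onetc"`.
#' @param control an [onset_control()] (onset method only).
#' @param input_onset optional precomputed [onset_fit()] of `input_fn`,
#'   reused when many tissue curves share one input function.
#' @param ... passed to the comparator estimators (e.g. `endtime`).
#' @return Delay in seconds; `NA` when the estimate is undefined (onset
#'   failure on either curve, or comparator failure).
#' @export
estimate_delay <- function(tissue, input_fn,
                           method = c("onset", "xcorr", "onetc"),
                           control = onset_control(),
                           input_onset = NULL, ...) {
  method <- match.arg(method)
  if (method == "xcorr")
    return(xcorr_delay(tissue, input_fn, ...))
  if (method == "onetc") {
    fit <- one_tissue_fit(tissue, input_fn, ...)
    return(if (isTRUE(fit$converged)) fit$delay else NA_real_)
  }
  tfit <- onset_fit(tissue, control)
  ifit <- if (is.null(input_onset)) onset_fit(input_fn, control)
          else input_onset
  t_t <- tfit$estimate$onset_time
  t_i <- ifit$estimate$onset_time
  if (!is.finite(t_t) || !is.finite(t_i)) return(NA_real_)
  t_t - t_i
}
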