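# Dense-grid utilities shared by the one-tissue model and the synthetic
# generator. A "dense curve" is a pair (time, values) on a uniform grid
# (default step 0.1 s).

check_uniform <- function(time, tol = 1e-9) {
  if (length(time) < 2L) stop("dense grid needs >= 2 points", call. = FALSE)
  dt <- diff(time)
  if (max(dt) - min(dt) > tol * max(abs(time)) + tol)
    stop("dense grid must be uniform", call. = FALSE)
  dt[1L]
}

# exact exponential-kernel convolution integral(0,t) v(s) exp(-k(t-s)) ds
# assuming v piecewise linear between grid points; evaluated by a
# recursive filter, O(n). k = 0 reduces to the trapezoidal running
# integral.
exp_conv <- function(time, v, k) {
  dt <- check_uniform(time)
  n <- length(v)
  if (k * dt < 1e-12) {
    return(c(0, cumsum((v[-1L] + v[-n]) / 2 * dt)))
  }
  ek <- exp(-k * dt)
  i0 <- (1 - ek) / k
  i1 <- i0 - (1 - ek * (1 + k * dt)) / (k^2 * dt)
  u <- v[-n] * (i0 - i1) + v[-1L] * i1
  c(0, as.numeric(stats::filter(u, ek, method = "recursive")))
}

# shift a dense curve by +d seconds (later arrival for d > 0), linear
# interpolation back onto the original grid; zero before the shifted
# start, last value held beyond the end.
shift_dense <- function(time, v, d) {
  if (d == 0) return(v)
  span <- time[length(time)] - time[1L]
  if (abs(d) > span)
    stop("shift exceeds the grid span", call. = FALSE)
  stats::approx(time, v, xout = time - d, yleft = 0,
                yright = v[length(v)])$y
}

# average a dense curve over the frames of a schedule (integral over each
# frame divided by its duration) -- PET frames measure the mean activity
# over the frame, not the mid-time sample.
frame_average <- function(time, v, schedule) {
  dt <- check_uniform(time)
  n <- length(v)
  ctrap <- c(0, cumsum((v[-1L] + v[-n]) / 2 * dt))
  s <- schedule$frame_start
  e <- s + schedule$frame_duration
  if (min(s) < time[1L] - 1e-9 || max(e) > time[n] + 1e-9)
    stop("dense grid does not cover the schedule", call. = FALSE)
  ci <- stats::approx(time, ctrap, xout = c(s, e), rule = 2)$y
  m <- length(s)
  (ci[(m + 1L):(2L * m)] - ci[seq_len(m)]) / schedule$frame_duration
}

# frame averaging as a linear operator: a frames x n matrix W such that
# frame_average(time, v, schedule) == W %*% v; built once and reused when
# many curves are averaged onto the same schedule.
frame_weight_matrix <- function(time, schedule) {
  dt <- check_uniform(time)
  n <- length(time)
  # coefficients of the running trapezoidal integral I(tq) in terms of v
  coef_I <- function(tq) {
    pos <- (tq - time[1L]) / dt + 1
    k <- floor(pos + 1e-9)
    f <- pos - k
    w <- numeric(n)
    if (k >= 2L) {
      w[1:k] <- dt
      w[1L] <- dt / 2
      w[k] <- dt / 2
    }
    if (f > 1e-12) {
      w[k] <- w[k] + f * dt / 2
      w[k + 1L] <- w[k + 1L] + f * dt / 2
    }
    w
  }
  s <- schedule$frame_start
  e <- s + schedule$frame_duration
  if (min(s) < time[1L] - 1e-9 || max(e) > time[n] + 1e-9)
    stop("dense grid does not cover the schedule", call. = FALSE)
  m <- length(s)
  W <- matrix(0, nrow = m, ncol = n)
  for (j in seq_len(m))
    W[j, ] <- (coef_I(e[j]) - coef_I(s[j])) / schedule$frame_duration[j]
  W
}

# linear interpolation of a frame-sampled TAC onto a dense grid; activity
# before the first mid-time ramps from the first value (held), after the
# last mid-time the last value is held.
densify_tac <- function(x, time) {
  stats::approx(x$schedule$mid_time, x$activity, xout = time, rule = 2)$y
}

dense_grid <- function(schedule, dt = 0.1) {
  seq(0, schedule_end(schedule), by = dt)
}
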