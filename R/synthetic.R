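#' Parametric bolus input-function model
#'
#' A gamma-variate bolus with an optional recirculation tail, standing in
#' for a measured image-derived input function. The first pass is
#' `peak_amplitude * ((t - t0)/(alpha*beta))^alpha * exp(alpha - (t - t0)/beta)`
#' for `t >= t0` (zero before arrival; peak-normalized, mode at
#' `t0 + alpha*beta`); recirculation adds
#' `recirculation_fraction * peak_amplitude` times the first-pass shape
#' convolved with an exponential density of rate `recirculation_decay`.
#'
#' @param arrival_time bolus arrival `t0`, seconds.
#' @param peak_amplitude first-pass peak, Bq/ml.
#' @param alpha gamma-variate shape (unitless, > 0).
#' @param beta gamma-variate scale, seconds (> 0).
#' @param recirculation_fraction tail amplitude relative to the peak, in
#'   `[0, 1)`.
#' @param recirculation_decay tail rate constant, 1/s.
#' @return A list of class `input_function_model`.
#' @export
input_function_model <- function(arrival_time, peak_amplitude, alpha, beta,
                                 recirculation_fraction = 0,
                                 recirculation_decay = 0.01) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  stopifnot(peak_amplitude > 0, recirculation_fraction >= 0,
            recirculation_fraction < 1, recirculation_decay > 0)
  structure(list(arrival_time = arrival_time,
                 peak_amplitude = peak_amplitude,
                 alpha = alpha, beta = beta,
                 recirculation_fraction = recirculation_fraction,
                 recirculation_decay = recirculation_decay),
            class = "input_function_model")
}

#' Input-function presets
#'
#' `"h2o_idif"`: arrival 12 s, shape 2.5, scale 4 s, peak 30 kBq/ml,
#' recirculation fraction 0.08 — a fast sharp bolus as seen in the
#' descending aorta on the 180 s water protocol. `"fdg_idif"`: the same
#' bolus shape on the 600 s protocol with a slower recirculation decay.
#'
#' @param name preset name.
#' @return An [input_function_model()].
#' @export
input_preset <- function(name = c("h2o_idif", "fdg_idif")) {
  name <- match.arg(name)
  switch(name,
    h2o_idif = input_function_model(arrival_time = 12,
                                    peak_amplitude = 30000,
                                    alpha = 2.5, beta = 4,
                                    recirculation_fraction = 0.08,
                                    recirculation_decay = 0.01),
    fdg_idif = input_function_model(arrival_time = 12,
                                    peak_amplitude = 30000,
                                    alpha = 2.5, beta = 4,
                                    recirculation_fraction = 0.08,
                                    recirculation_decay = 0.005))
}

#' Evaluate a bolus input-function model on a dense grid
#'
#' @param model an [input_function_model()].
#' @param time numeric vector of times, seconds (uniform grid required
#'   when the model has a recirculation tail).
#' @return Input activity (Bq/ml) at `time`.
#' @export
gamma_variate_input <- function(model, time) {
  stopifnot(inherits(model, "input_function_model"))
  tau <- time - model$arrival_time
  fp <- numeric(length(time))
  pos <- tau > 0
  x <- tau[pos] / (model$alpha * model$beta)
  fp[pos] <- model$peak_amplitude *
    exp(model$alpha * (log(x) + 1) - tau[pos] / model$beta)
  if (model$recirculation_fraction > 0) {
    lam <- model$recirculation_decay
    fp <- fp + model$recirculation_fraction * lam *
      exp_conv(time, fp, lam)
  }
  fp
}

#' Frame-sampled input function
#'
#' Averages a bolus model over the frames of a schedule, producing the
#' input-function TAC an estimator would see.
#'
#' @param model an [input_function_model()].
#' @param schedule a [frame_schedule()].
#' @param dense_dt dense evaluation step, seconds.
#' @return A [tac()].
#' @export
input_tac <- function(model, schedule, dense_dt = 0.1) {
  time <- dense_grid(schedule, dense_dt)
  tac(schedule, frame_average(time, gamma_variate_input(model, time),
                              schedule))
}

#' Shift a dense curve by a delay
#'
#' Moves a dense curve `d` seconds later (`d > 0`; earlier for `d < 0`)
#' and linearly interpolates back onto the original grid; values before
#' the shifted start are zero.
#'
#' @param time uniform dense grid, seconds.
#' @param values curve values on `time`.
#' @param d shift, seconds; `|d|` must not exceed the grid span.
#' @return Shifted values on `time`.
#' @export
apply_delay <- function(time, values, d) {
  check_uniform(time)
  shift_dense(time, values, d)
}

#' Multiplicative Gaussian frame noise
#'
#' Multiplies each frame value by an independent draw from `N(1, sigma^2)`
#' and clips negative products to 0. Deterministic given `seed`; the
#' global RNG state is saved and restored.
#'
#' @param x a [tac()].
#' @param sigma noise standard deviation (unitless, >= 0).
#' @param seed integer seed.
#' @return A noisy [tac()]; `sigma = 0` returns `x` unchanged.
#' @export
apply_noise <- function(x, sigma, seed) {
  stopifnot(inherits(x, "tac"))
  if (!is.finite(sigma) || sigma < 0)
    stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(x)
  n <- length(x$activity)
  noisy <- with_preserved_seed(seed, x$activity * stats::rnorm(n, 1, sigma))
  tac(x$schedule, pmax(0, noisy))
}

with_preserved_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' One synthetic-TAC configuration
#'
#' @param K1 influx rate, ml/(100 g min).
#' @param k2 efflux rate, 1/min.
#' @param delay tissue arrival delay relative to the input, seconds.
#' @param sigma multiplicative noise SD (unitless).
#' @param seed integer RNG seed for the noise draws.
#' @param schedule a [frame_schedule()].
#' @param input_model an [input_function_model()].
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(K1, k2, delay, sigma, seed,
                            schedule = h2o_schedule(),
                            input_model = input_preset("h2o_idif")) {
  stopifnot(K1 >= 0, k2 >= 0, sigma >= 0,
            inherits(schedule, "frame_schedule"),
            inherits(input_model, "input_function_model"))
  structure(list(K1 = K1, k2 = k2, delay = delay, sigma = sigma,
                 seed = as.integer(seed), schedule = schedule,
                 input_model = input_model),
            class = "simulation_spec")
}

#' Simulate a one-tissue tissue TAC
#'
#' Generates a synthetic tissue curve: the one-tissue compartment model
#' is solved on a dense grid (step `dense_dt`) against the bolus input
#' with zero delay, the dense tissue curve is shifted by the spec's delay
#' and re-interpolated, averaged onto the frame schedule, and
#' multiplicative Gaussian noise applied frame-wise.
#'
#' @param spec a [simulation_spec()].
#' @param dense_dt dense grid step, seconds (default 0.1).
#' @return A [tac()].
#' @export
simulate_tissue <- function(spec, dense_dt = 0.1) {
  stopifnot(inherits(spec, "simulation_spec"))
  time <- dense_grid(spec$schedule, dense_dt)
  a <- gamma_variate_input(spec$input_model, time)
  ct <- predict_one_tissue(time, a, spec$K1, spec$k2, delay = 0)
  ct <- apply_delay(time, ct, spec$delay)
  clean <- tac(spec$schedule, frame_average(time, ct, spec$schedule))
  apply_noise(clean, spec$sigma, spec$seed)
}

#' Inclusive-by-step parameter grids
#'
#' `grid_values()` expands a `(start, step, stop)` triple into
#' `start, start + step, ...` up to `stop` inclusive (within floating
#' point). `grid_spec()` bundles the four triples of a simulation grid,
#' and `table1_grid()` is the published benchmark grid:
#' K1 (1, 3.5, 350) — 100 values; k2 (0.05, 0.03, 3) — 99 values;
#' delay (-10, 1, 10) — 21 values; sigma (0, 0.1, 0.5) — 6 values.
#'
#' @param start,step,stop triple defining the value list; `step > 0`.
#' @return `grid_values()`: numeric vector.
#' @export
grid_values <- function(start, step, stop) {
  if (!is.finite(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  if (stop < start) stop("stop must be >= start", call. = FALSE)
  start + step * (0:floor((stop - start) / step + 1e-9))
}

#' @rdname grid_values
#' @param K1,k2,delay,sigma numeric `(start, step, stop)` triples.
#' @export
grid_spec <- function(K1, k2, delay, sigma) {
  spec <- list(K1 = K1, k2 = k2, delay = delay, sigma = sigma)
  lapply(spec, function(x) stopifnot(length(x) == 3))
  structure(spec, class = "grid_spec")
}

#' @rdname grid_values
#' @export
table1_grid <- function() {
  grid_spec(K1 = c(1, 3.5, 350),
            k2 = c(0.05, 0.03, 3),
            delay = c(-10, 1, 10),
            sigma = c(0, 0.1, 0.5))
}

# deterministic per-cell seed derived from a base seed and the linear
# grid index; kept strictly below 2^31
cell_seed <- function(base_seed, index) {
  v <- ((as.numeric(base_seed) %% 2147483647) * 48271 + index) %%
    2147483647
  as.integer(v)
}

#' Expand a grid specification into simulation specs
#'
#' Takes the Cartesian product of the per-parameter value lists (K1
#' varying fastest, then k2, delay, sigma) and assigns each cell a
#' deterministic seed derived from `base_seed` and the cell's linear
#' index.
#'
#' @param grid a [grid_spec()], or a named list of explicit value vectors
#'   (`K1`, `k2`, `delay`, `sigma`).
#' @param schedule a [frame_schedule()].
#' @param input_model an [input_function_model()].
#' @param base_seed integer base seed.
#' @return A list of [simulation_spec()] objects, with attributes `K1`,
#'   `k2`, `delay`, `sigma` holding the axis value lists.
#' @export
build_grid <- function(grid, schedule = h2o_schedule(),
                       input_model = input_preset("h2o_idif"),
                       base_seed = 1L) {
  vals <- if (inherits(grid, "grid_spec"))
    lapply(grid, function(tr) grid_values(tr[1], tr[2], tr[3]))
  else {
    stopifnot(all(c("K1", "k2", "delay", "sigma") %in% names(grid)))
    lapply(grid[c("K1", "k2", "delay", "sigma")], as.numeric)
  }
  cells <- expand.grid(K1 = vals$K1, k2 = vals$k2, delay = vals$delay,
                       sigma = vals$sigma, KEEP.OUT.ATTRS = FALSE)
  specs <- lapply(seq_len(nrow(cells)), function(i)
    simulation_spec(cells$K1[i], cells$k2[i], cells$delay[i],
                    cells$sigma[i], seed = cell_seed(base_seed, i),
                    schedule = schedule, input_model = input_model))
  attributes(specs) <- c(attributes(specs), vals)
  specs
}
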