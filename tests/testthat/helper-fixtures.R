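# Shared fixtures: everything is generated in code at test time.

h2o <- h2o_schedule()
h2o_idif_model <- input_preset("h2o_idif")
h2o_idif <- input_tac(h2o_idif_model, h2o)

# a clean mid-map tissue curve (moderate uptake and clearance)
clean_tissue <- function(K1 = 100, k2 = 1, delay = 0, sigma = 0, seed = 1L,
                         schedule = h2o) {
  simulate_tissue(simulation_spec(K1, k2, delay, sigma, seed,
                                  schedule = schedule,
                                  input_model = h2o_idif_model))
}

# uniform 1 s schedule of n frames, for hand-built curves
uniform_schedule <- function(n, dt = 1) build_schedule(list(c(n, dt)))

# a TAC from explicit activity values on a uniform schedule
uniform_tac <- function(activity, dt = 1)
  tac(uniform_schedule(length(activity), dt), activity)

# dense shift of a frame-sampled TAC: resample on a fine grid, shift,
# frame-average back; the reference transformation for shift-equivariance
# checks
shift_tac <- function(x, d, dense_dt = 0.05) {
  time <- seq(0, schedule_end(x$schedule), by = dense_dt)
  v <- stats::approx(x$schedule$mid_time, x$activity, xout = time,
                     rule = 2)$y
  tac(x$schedule, tacdelay:::frame_average(time, apply_delay(time, v, d),
                                           x$schedule))
}
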