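# a small phantom: every voxel carries the same clean one-tissue TAC
# (delay 4 s) unless overridden
make_phantom <- function(nx = 6, ny = 6, nz = 6, delay = 4) {
  base <- clean_tissue(K1 = 100, k2 = 1, delay = delay)
  vol <- array(rep(base$activity, each = nx * ny * nz),
               dim = c(nx, ny, nz, n_frames(h2o)))
  list(volume = vol, base = base)
}

test_that("mask curves are per-frame means over the mask", {
  ph <- make_phantom(3, 3, 3)
  vol <- ph$volume
  # single-voxel mask returns that voxel's TAC
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  expect_equal(extract_mask_curve(vol, m1, h2o)$activity,
               vol[2, 2, 2, ])
  # uniform volume: any mask gives the same curve
  m2 <- array(FALSE, c(3, 3, 3)); m2[, 1, ] <- TRUE
  expect_equal(extract_mask_curve(vol, m2, h2o)$activity,
               ph$base$activity)
  # two-voxel mask averages
  vol[1, 1, 1, ] <- 2 * vol[1, 1, 1, ]
  m3 <- array(FALSE, c(3, 3, 3)); m3[1, 1, 1] <- TRUE; m3[3, 3, 3] <- TRUE
  expect_equal(extract_mask_curve(vol, m3, h2o)$activity,
               (vol[1, 1, 1, ] + vol[3, 3, 3, ]) / 2)
  expect_error(extract_mask_curve(vol, array(FALSE, c(3, 3, 3)), h2o),
               "no voxels")
})

test_that("a uniform phantom yields a uniform delay map", {
  ph <- make_phantom(4, 4, 3)
  dm <- suppressMessages(
    voxelwise_delay_map(ph$volume, h2o, h2o_idif, method = "onset"))
  expect_equal(dm$n_failed, 0L)
  expect_equal(dm$n_fallback, 0L)
  vals <- dm$delay[is.finite(dm$delay)]
  expect_length(vals, 48)
  expect_equal(stats::sd(vals), 0)          # identical voxels, one value
  expect_lt(abs(vals[1] - 4), 2)            # near the true 4 s delay
})

test_that("failed voxels recover through the 5x5x5 fallback", {
  ph <- make_phantom(6, 6, 6)
  vol <- ph$volume
  # 5 voxels of pure zero signal: direct estimation must fail there
  bad <- rbind(c(1, 1, 1), c(3, 4, 2), c(6, 6, 6), c(2, 5, 3), c(4, 4, 4))
  for (r in seq_len(nrow(bad))) vol[bad[r, 1], bad[r, 2], bad[r, 3], ] <- 0
  dm <- suppressMessages(
    voxelwise_delay_map(vol, h2o, h2o_idif, method = "onset"))
  expect_equal(dm$n_fallback, 5L)
  expect_equal(dm$n_failed, 0L)
  for (r in seq_len(nrow(bad)))
    expect_true(dm$fallback[bad[r, 1], bad[r, 2], bad[r, 3]])
  # fallback conservation: direct + fallback + failed = mask size
  expect_equal(dm$n_direct + dm$n_fallback + dm$n_failed, dm$n_voxels)
})

test_that("an all-dead neighbourhood leaves the centre failed", {
  ph <- make_phantom(7, 7, 7)
  vol <- ph$volume
  vol[2:6, 2:6, 2:6, ] <- 0  # a 5x5x5 dead block
  dm <- suppressMessages(
    voxelwise_delay_map(vol, h2o, h2o_idif, method = "onset"))
  expect_true(dm$failed[4, 4, 4])
  expect_true(is.nan(dm$delay[4, 4, 4]))
  expect_equal(dm$n_direct + dm$n_fallback + dm$n_failed, dm$n_voxels)
  expect_gt(dm$n_failed, 0L)
})

test_that("delay maps are chunk-invariant and respect the body mask", {
  ph <- make_phantom(4, 4, 2)
  vol <- ph$volume
  vol[1, 1, 1, ] <- 0
  mask <- array(TRUE, c(4, 4, 2)); mask[, 4, ] <- FALSE
  maps <- lapply(c(1, 2, 8), function(ch) suppressMessages(
    voxelwise_delay_map(vol, h2o, h2o_idif, body_mask = mask,
                        method = "onset", chunks = ch)))
  expect_identical(maps[[1]]$delay, maps[[2]]$delay)
  expect_identical(maps[[1]]$delay, maps[[3]]$delay)
  expect_true(all(is.na(maps[[1]]$delay[, 4, ])))
  expect_equal(maps[[1]]$n_voxels, sum(mask))
})

test_that("an unestimable input function aborts map generation", {
  ph <- make_phantom(3, 3, 2)
  zero_input <- tac(h2o, rep(0, 54))
  expect_error(suppressMessages(
    voxelwise_delay_map(ph$volume, h2o, zero_input, method = "onset")),
    "input-function onset")
})

test_that("delay maps round-trip through NIfTI with NaN for failures", {
  ph <- make_phantom(3, 3, 2)
  vol <- ph$volume
  vol[1, 1, 1, ] <- 0
  mask <- array(TRUE, c(3, 3, 2))
  dm <- suppressMessages(
    voxelwise_delay_map(vol, h2o, h2o_idif, body_mask = mask))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_delay_map(dm, path)
  back <- as.array(RNifti::readNifti(path))
  expect_equal(dim(back), c(3, 3, 2))
  finite_in <- is.finite(dm$delay)
  expect_equal(back[finite_in], dm$delay[finite_in], tolerance = 1e-6)

  # 4D volume + sidecar round trip
  vol_path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(ph$volume), vol_path)
  json_path <- withr::local_tempfile(fileext = ".json")
  write_frame_timing(h2o, json_path)
  pet <- read_dynamic_pet(vol_path, json_path)
  expect_equal(dim(pet$volume), dim(ph$volume))
  expect_equal(n_frames(pet$schedule), 54L)
})

test_that("residual grids have the right orientation and an exact oracle", {
  specs <- build_grid(list(K1 = c(50, 150, 250), k2 = c(0.5, 1),
                           delay = c(0, 5), sigma = 0), base_seed = 2)
  grids <- residual_parameter_map(specs, method = "oracle")
  expect_length(grids, 2)              # one per (sigma, delay)
  for (g in grids) {
    expect_equal(dim(g$residual), c(2, 3))   # rows k2, cols K1
    expect_equal(unname(g$residual), matrix(0, 2, 3))  # perfect estimator
    expect_equal(g$n_failed, 0L)
  }
  expect_equal(vapply(grids, `[[`, numeric(1), "delay"), c(0, 5))
})

test_that("an estimator with constant over-delay has residual -eps", {
  # over-delaying by eps must show as a residual of -eps everywhere:
  # simulate delay 2, compare against onset estimates of delay 2 + eps
  specs <- build_grid(list(K1 = 100, k2 = 1, delay = 2, sigma = 0),
                      base_seed = 1)
  tt <- simulate_tissue(specs[[1]])
  est <- estimate_delay(tt, h2o_idif)
  res <- specs[[1]]$delay - (est + 1.5)  # estimator shifted by +1.5 s
  res0 <- specs[[1]]$delay - est
  expect_equal(res, res0 - 1.5)
})

test_that("residual summaries pool correctly and audit histogram mass", {
  mk_grid <- function(vals, sigma, delay, method = "m") {
    structure(list(residual = matrix(vals, 2), K1 = c(1, 2), k2 = c(1, 2),
                   sigma = sigma, delay = delay, method = method,
                   n_failed = sum(is.na(vals))),
              class = "residual_grid")
  }
  g1 <- mk_grid(c(0, 0, 0, 0), 0.1, 0)
  s1 <- summarize_residuals(list(g1))
  expect_equal(s1$summary$mean, 0)
  expect_equal(s1$summary$sd, 0)

  # pooling two disjoint halves equals the weighted mean
  g2 <- mk_grid(c(1, 1, 3, 3), 0.1, -5)
  s2 <- summarize_residuals(list(g1, g2))
  expect_equal(s2$summary$mean, mean(c(0, 0, 0, 0, 1, 1, 3, 3)))
  expect_equal(s2$summary$n_cells, 8)

  # histogram mass equals n_cells minus failures
  g3 <- mk_grid(c(0.1, -20, NA, 2), 0.4, 0)
  s3 <- summarize_residuals(list(g3))
  h <- s3$histograms[[which(s3$summary$sigma == 0.4)]]
  expect_equal(sum(h$counts) + h$n_below + h$n_above, 3)
  expect_equal(h$n_below, 1)  # the -20 s cell lies below the -8 s bound
  # bin width 0.25 s over [-8, 8]
  expect_equal(unique(round(diff(h$breaks), 10)), 0.25)
  expect_equal(range(h$breaks), c(-8, 8))
})

test_that("the benchmark orchestrator is reproducible and writes a report", {
  cfg <- list(K1_every = 50, k2_every = 50, delays = 0, sigmas = c(0, 0.1),
              methods = c("oracle", "xcorr"), base_seed = 4)
  out1 <- withr::local_tempdir()
  s1 <- run_benchmark(cfg, out_dir = out1)
  expect_true(file.exists(file.path(out1, "residual_summary.csv")))
  expect_true(file.exists(file.path(out1, "metrics.json")))
  expect_true(any(grepl("^map_", list.files(out1))))
  # oracle rows are exactly zero
  oracle_rows <- s1$summary[s1$summary$method == "oracle", ]
  expect_equal(oracle_rows$mean, rep(0, 2))
  # rerun: identical metrics
  s2 <- run_benchmark(cfg)
  expect_equal(s1$summary, s2$summary)
  expect_error(run_benchmark(list(methods = "bogus")), "unknown method")
})
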