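test_that("resampling is an identity on already-uniform input and exact on ramps", {
  # uniform 100 Hz input: output equals input on the shared grid
  t <- seq(0, 5, by = 0.01)
  rec <- list(time = t, acc = cbind(sin(t), cos(t), t))
  out <- resample_uniform(rec, 100)
  expect_equal(nrow(out$samples), length(t))
  expect_equal(out$samples[, 1L], sin(t), tolerance = 1e-12)

  # 30 s span at 100 Hz has 3001 inclusive grid points
  rec30 <- list(time = seq(0, 30, by = 0.025), acc = matrix(1, 1201, 1))
  expect_equal(nrow(resample_uniform(rec30, 100)$samples), 3001L)

  # linear interpolation is exact on linear signals, irregular stamps or not
  set.seed(3)
  ti <- sort(runif(200, 0, 10))
  rec_ramp <- list(time = ti, acc = matrix(2 * ti, ncol = 1L))
  out <- resample_uniform(rec_ramp, 100)
  grid <- ti[1L] + seq(0, floor((max(ti) - ti[1L]) * 100)) / 100
  expect_equal(as.numeric(out$samples), 2 * grid, tolerance = 1e-10)

  expect_error(resample_uniform(list(time = 1, acc = matrix(1)), 100), "2 samples")
  expect_error(resample_uniform(list(time = c(1, 1, 2), acc = matrix(0, 3, 1)), 100),
               "strictly increasing")
})

test_that("vertical channel selection follows gravity and removes the mean", {
  t <- seq(0, 10, by = 0.01)
  sig <- structure(list(rate = 100, origin = 0,
                        samples = cbind(9.81 + sin(t), rnorm(length(t), 0, 0.01),
                                        rnorm(length(t), 0, 0.01))),
                   class = "uniform_signal")
  v <- vertical_component(sig)
  expect_identical(attr(v, "axis"), 1L)
  expect_equal(mean(v$samples), 0, tolerance = 1e-12)

  const <- structure(list(rate = 100, origin = 0,
                          samples = matrix(9.81, 1000, 3)),
                     class = "uniform_signal")
  expect_equal(as.numeric(vertical_component(const)$samples), rep(0, 1000))

  zero <- structure(list(rate = 100, origin = 0, samples = matrix(0, 100, 3)),
                    class = "uniform_signal")
  expect_error(vertical_component(zero), "all channels are zero")
})

test_that("the generator's vertical axis is always the one selected", {
  hits <- vapply(1:25, function(s) {
    rec <- simulate_accelerometer(gait_sim_params(seed = s))
    v <- vertical_component(resample_uniform(rec))
    attr(v, "axis") == rec$truth$vertical_axis
  }, logical(1))
  expect_true(all(hits))
})

test_that("RMS has its closed form on sines and its symmetries", {
  t <- seq(0, 10, by = 0.01)
  A <- 2.7
  x <- A * sin(2 * pi * 2 * t)
  sig <- structure(list(rate = 100, origin = 0, samples = matrix(x, ncol = 1L)),
                   class = "uniform_signal")
  expect_equal(acceleration_rms(sig), A / sqrt(2), tolerance = 0.01)

  zero <- structure(list(rate = 100, origin = 0, samples = matrix(0, 100, 1)),
                    class = "uniform_signal")
  expect_identical(acceleration_rms(zero), 0)

  set.seed(4)
  y <- rnorm(500)
  s1 <- structure(list(rate = 100, origin = 0, samples = matrix(y, ncol = 1L)),
                  class = "uniform_signal")
  s2 <- structure(list(rate = 100, origin = 0, samples = matrix(rev(y), ncol = 1L)),
                  class = "uniform_signal")
  s3 <- structure(list(rate = 100, origin = 0, samples = matrix(-y, ncol = 1L)),
                  class = "uniform_signal")
  expect_identical(acceleration_rms(s1), acceleration_rms(s2))
  expect_identical(acceleration_rms(s1), acceleration_rms(s3))
})

test_that("step detection finds one event per cycle on a clean sine", {
  t <- seq(0, 10, by = 0.01)
  x <- sin(2 * pi * 2 * t)               # 2 Hz: 20 full cycles
  sig <- structure(list(rate = 100, origin = 0, samples = matrix(x, ncol = 1L)),
                   class = "uniform_signal")
  ev <- detect_steps(sig)
  expect_equal(length(ev), 20L)
  # intervals equal the 0.5 s period up to one grid sample
  expect_true(all(abs(diff(ev) - 0.50) <= 0.01 + 1e-12))
})

test_that("detected events match generator ground truth within 50 ms", {
  frac <- vapply(1:10, function(s) {
    p <- gait_sim_params(noise_sd = 0.2 * 3.0, step_amplitude = 3.0, seed = s)
    rec <- simulate_accelerometer(p)
    ev <- detect_steps(vertical_component(resample_uniform(rec)))
    mean(vapply(ev, function(e) min(abs(rec$truth$step_times - e)) <= 0.05,
                logical(1)))
  }, numeric(1))
  expect_gte(mean(frac), 0.95)
})

test_that("pure noise does not pass the downstream periodicity check", {
  # noise peaks may mimic a cadence, but the autocorrelation stage must then
  # report the absence of a periodic gait (error or low regularity)
  results <- vapply(1:10, function(s) {
    set.seed(s)
    rec <- list(time = seq(0, 30, by = 0.025),
                acc = cbind(rnorm(1201, 0, 0.3), 9.81 + rnorm(1201, 0, 0.3),
                            rnorm(1201, 0, 0.3)))
    f <- tryCatch(extract_sensor_features(rec), error = function(e) e)
    if (inherits(f, "error")) 0 else f$step_regularity
  }, numeric(1))
  expect_true(all(results < 0.4))
})

test_that("temporal features recover frequency and variability", {
  ev <- seq(0, 10, by = 0.5)
  tf <- temporal_features(ev)
  expect_equal(tf$step_frequency, 2.0)
  expect_equal(tf$step_variability, 0)
  expect_error(temporal_features(c(0, 1)), "insufficient")
  expect_error(temporal_features(c(0, 1, 1)), "non-positive")
})

test_that("perfect periodic symmetric recordings give regularity and symmetry near 1", {
  p <- gait_sim_params(timing_jitter_cv = 0, amplitude_jitter_cv = 0,
                       asymmetry = 0, noise_sd = 0, rate_jitter_cv = 0,
                       seed = 5)
  f <- extract_sensor_features(simulate_accelerometer(p))
  expect_gt(f$step_regularity, 0.97)
  expect_gt(f$step_symmetry, 0.97)
  expect_lt(f$step_variability, 0.02)
  expect_equal(f$step_frequency, 1.75, tolerance = 0.01)
})

test_that("injected parameters are recovered across seeds", {
  res <- vapply(1:20, function(s) {
    p <- gait_sim_params(step_frequency = 1.8, timing_jitter_cv = 0.12,
                         seed = 100 + s)
    f <- extract_sensor_features(simulate_accelerometer(p))
    c(f$step_frequency, f$step_variability)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) / 1.8 - 1), 0.03)
  expect_lt(abs(mean(res[2, ]) - 0.12), 0.03)
})

test_that("regularity falls with timing jitter and symmetry with asymmetry", {
  reg_at <- function(tj) mean(vapply(1:20, function(s) {
    p <- gait_sim_params(timing_jitter_cv = tj, seed = 200 + s)
    extract_sensor_features(simulate_accelerometer(p))$step_regularity
  }, numeric(1)))
  expect_gt(reg_at(0.03), reg_at(0.10))
  expect_gt(reg_at(0.10), reg_at(0.20))

  sym_at <- function(a) mean(vapply(1:20, function(s) {
    p <- gait_sim_params(asymmetry = a, timing_jitter_cv = 0.05, seed = 300 + s)
    extract_sensor_features(simulate_accelerometer(p))$step_symmetry
  }, numeric(1)))
  expect_gt(sym_at(0), sym_at(0.4))
})

test_that("regularity and symmetry respect their ranges", {
  for (s in 1:10) {
    p <- gait_sim_params(timing_jitter_cv = runif(1, 0, 0.2),
                         asymmetry = runif(1, 0, 0.6),
                         noise_sd = runif(1, 0.05, 0.8), seed = 400 + s)
    f <- extract_sensor_features(simulate_accelerometer(p))
    expect_lte(f$step_regularity, 1 + 1e-9)
    expect_gte(f$step_symmetry, 0)
    expect_lte(f$step_symmetry, 1)
  }
})

test_that("stage failures carry stage identity", {
  rec <- list(time = seq(0, 5, by = 0.025),
              acc = matrix(rnorm(201 * 3), ncol = 3))
  expect_error(extract_sensor_features(rec), "shorter than 10 s")
})
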