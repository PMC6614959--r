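single_layer_cfg <- function(noise = 0, seed = NULL, ...) {
  generator_config(list(tissue_layer("gel", thickness = 3, k1 = 0.3,
                                     k2 = 0.03, puncture_drop_frac = 0.5,
                                     friction_level = 0.25, osc_amp = 0.1,
                                     osc_freq = 2)),
                   noise_sigma = noise, seed = seed, ...)
}

test_that("force ramps monotonically until the first rupture", {
  tr <- generate_trace(single_layer_cfg(), duration = 2)
  # rupture when depth = 3 mm at 3 mm/s -> t = 1 s -> sample 1001
  pre <- tr$force[1:1000]
  expect_true(all(diff(pre) >= 0))
})

test_that("sample count is floor(duration * fs)", {
  tr <- generate_trace(single_layer_cfg(), duration = 1.2345)
  expect_length(tr$t, 1234L)
  tr12 <- generate_trace(preset("kidney_left", noise_sigma = 0, seed = 1),
                         duration = 2)
  expect_length(tr12$t, 2000L)
})

test_that("generation is deterministic for a fixed config and seed", {
  cfg <- single_layer_cfg(noise = 0.02, seed = 99)
  a <- generate_trace(cfg, 1.5)
  b <- generate_trace(cfg, 1.5)
  expect_identical(a$force, b$force)
  # noiseless output is seed-independent
  n1 <- generate_trace(single_layer_cfg(seed = 1), 1.5)
  n2 <- generate_trace(single_layer_cfg(seed = 2), 1.5)
  expect_identical(n1$force, n2$force)
})

test_that("the rupture drop equals puncture_drop_frac of the peak force", {
  tr <- generate_trace(single_layer_cfg(), duration = 2)
  r <- which(diff(tr$force) < -0.1)[1L] + 1L
  f_pre <- tr$force[r - 1L]
  f_post <- tr$force[r]
  expect_equal((f_pre - f_post) / f_pre, 0.5, tolerance = 1e-9)
})

test_that("generator honours the RNG isolation contract", {
  set.seed(123)
  before <- stats::rnorm(1)
  set.seed(123)
  invisible(generate_trace(single_layer_cfg(noise = 0.01, seed = 7), 0.5))
  after <- stats::rnorm(1)
  expect_identical(before, after)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(list()), "non-empty")
  expect_error(generator_config(list(tissue_layer("x", 1, 0.1)),
                                noise_sigma = 0.01), "seed is mandatory")
  expect_error(generate_trace(single_layer_cfg(), 0), "duration")
  expect_error(tissue_layer("x", 1, 0.1, puncture_drop_frac = 1.2),
               "puncture_drop_frac")
})

test_that("organ presets carry the published respiration defaults", {
  expect_equal(preset("kidney_left")$respiration$amplitude_pp, 7.1)
  expect_equal(preset("lung")$respiration$period, 5)
  for (org in c("kidney_left", "liver", "lung", "heart", "dorsal_muscles")) {
    cfg <- preset(org)
    expect_gte(length(cfg$layers), 3L)
    expect_equal(cfg$fs, 1000)
    expect_equal(cfg$velocity, 3)
  }
})

test_that("a held needle under breathing oscillates at the breath rate", {
  cfg <- single_layer_cfg()
  cfg$velocity <- 0
  cfg$depth0 <- 1.5                      # mid-layer, pre-rupture
  cfg$respiration <- respiratory_params("kidney_left", amplitude_pp = 4.5)
  cfg$coupling <- 0.2                    # keep the tip inside the layer
  tr <- generate_trace(cfg, duration = 20)
  y <- tr$force - mean(tr$force)
  p <- Mod(stats::fft(y))^2
  nf <- floor(length(y) / 2)
  peak_hz <- which.max(p[2:(nf + 1L)]) * tr$fs / length(y)
  expect_equal(peak_hz, 1 / cfg$respiration$period, tolerance = 0.05)
})

test_that("plateau phases stay well fit at low sensor noise", {
  # post-rupture plateau: friction + oscillation, noise at 5% of osc_amp
  degrees <- vapply(1:20, function(seed) {
    cfg <- single_layer_cfg(noise = 0.005, seed = seed)
    tr <- generate_trace(cfg, 4)
    plateau <- slice_trace(tr, 3000L, 4000L)
    N <- suppressWarnings(select_order(plateau))
    fit_fourier(plateau, N, omega_mode = "free")$fitting_degree
  }, numeric(1))
  expect_true(all(degrees >= 0.99))
})
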