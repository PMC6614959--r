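test_that("phases tile the trace exactly", {
  tr <- drops_trace(c(2, 4, 6, 8))
  seg <- segment_phases(tr, n_phases = 5, method = "equal")
  b <- seg$boundaries
  covered <- unlist(lapply(seq_len(seg$n_phases), function(k)
    seq.int(b[k], b[k + 1L] - 1L)))
  expect_identical(covered, 0:(length(tr$t) - 1L))
})

test_that("a smooth ramp has no events and falls back to equal phases", {
  tr <- fn_trace(function(t) 0.1 + 0.2 * t, duration = 10, fs = 500)
  expect_warning(seg <- segment_phases(tr, n_phases = 5), "equal-length")
  expect_equal(seg$boundaries, c(0, 1000, 2000, 3000, 4000, 5000))
})

test_that("single-phase segmentation is the identity partition", {
  tr <- drops_trace(c(2, 4))
  seg <- segment_phases(tr, n_phases = 1)
  expect_equal(seg$boundaries, c(0L, length(tr$t)))
})

test_that("puncture events are located within 50 ms of the true drops", {
  # duration chosen so an equal split cannot coincide with the drop times
  tr <- drops_trace(c(2, 4, 6, 8), drop_size = 0.8, drop_width_ms = 10,
                    duration = 11, noise = 0.01, seed = 6)
  expect_no_warning(seg <- segment_phases(tr, n_phases = 5,
                                          method = "events"))
  found <- tr$t[seg$boundaries[2:5] + 1L]
  expect_true(all(abs(found - c(2, 4, 6, 8)) <= 0.05))
})

test_that("traces too short for the requested phases are rejected", {
  tr <- fn_trace(function(t) sin(t), duration = 0.05, fs = 1000)
  expect_error(segment_phases(tr, n_phases = 5), "too short")
})

test_that("segmentation objects validate their boundary structure", {
  expect_error(phase_segmentation(c(5, 100), 100), "start at 0")
  expect_error(phase_segmentation(c(0, 50, 50, 100), 100),
               "strictly increasing")
  expect_error(phase_segmentation(c(0, 3, 100), 100), ">= ")
})

test_that("piecewise fitting recovers per-phase generating models", {
  span <- 2
  fs <- 500
  # a 1000-sample slice spans 1.998 s; the fixed-omega fit periodizes on
  # that sampled span, so generate from the matching fundamental
  w_slice <- 2 * pi / (span - 1 / fs)
  models <- lapply(1:3, function(k)
    random_model(order = 2, omega = w_slice, seed = 100 + k,
                 domain = c((k - 1) * span, k * span)))
  t <- time_grid(3 * span * fs, fs)
  y <- numeric(length(t))
  for (k in 1:3) {
    ix <- which(t >= (k - 1) * span & t < k * span)
    y[ix] <- brute_force_eval(models[[k]], t[ix])
  }
  tr <- force_trace(t, 3 * t, y, fs = fs)
  seg <- phase_segmentation(c(0L, 1000L, 2000L, 3000L), 3000L)
  rep <- fit_piecewise(tr, seg, "fourier", order = 2, omega_mode = "fixed")
  expect_true(rep$ok)
  for (k in 1:3) {
    expect_gte(rep$per_phase$degree[k], 1 - 1e-10)
    expect_equal(rep$models[[k]]$alphas, models[[k]]$alphas,
                 tolerance = 1e-6)
    expect_equal(rep$models[[k]]$betas, models[[k]]$betas,
                 tolerance = 1e-6)
  }
  expect_equal(rep$average, mean(rep$per_phase$degree), tolerance = 1e-12)
})

test_that("a five-phase report has five rows plus one average", {
  tr <- oscillatory_trace(n_phases = 5, phase_s = 1, fs = 300, seed = 2)
  seg <- segment_phases(tr, n_phases = 5, method = "equal")
  rep <- fit_piecewise(tr, seg, "fourier", omega_mode = "fixed")
  expect_equal(nrow(rep$per_phase), 5L)
  expect_length(rep$average, 1L)
})

test_that("per-phase degrees from a recorded table average to 0.9855", {
  expect_equal(round(aggregate_report(
    c(0.9975, 0.9446, 0.9939, 0.9936, 0.9980)), 4), 0.9855)
})

test_that("refining a segmentation improves shared-omega fixed-order fits", {
  # nested-LSQ property: with a common fundamental and order, fitting the
  # halves separately can only reduce the residual, and on segments with
  # healthy variance the average fitting degree rises with it
  tr <- oscillatory_trace(n_phases = 2, phase_s = 2, fs = 500, seed = 15,
                          noise = 0.05)
  L <- length(tr$t)
  w <- 2 * pi / (tr$t[L] - tr$t[1L])
  fit_at <- function(a, b) {
    sub <- slice_trace(tr, a, b)
    f <- fit_fourier(sub, order = 3, omega_mode = "fixed", omega = w)
    list(sse = sum((sub$force - evaluate(f$model, sub$t))^2),
         fd = f$fitting_degree)
  }
  coarse <- list(fit_at(0L, L %/% 2L), fit_at(L %/% 2L, L))
  fine <- list(fit_at(0L, L %/% 4L), fit_at(L %/% 4L, L %/% 2L),
               fit_at(L %/% 2L, 3L * (L %/% 4L)),
               fit_at(3L * (L %/% 4L), L))
  sse <- function(fits) sum(vapply(fits, `[[`, numeric(1), "sse"))
  fd <- function(fits) mean(vapply(fits, `[[`, numeric(1), "fd"))
  expect_lte(sse(fine), sse(coarse) + 1e-10)
  expect_gte(fd(fine), fd(coarse) - 1e-10)
})
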