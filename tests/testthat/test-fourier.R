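test_that("evaluate handles constant and single-harmonic models exactly", {
  m0 <- fourier_series_model(a0 = 2, omega = 1)
  expect_equal(evaluate(m0, c(-3, 0, 17.5)), rep(2, 3))
  m1 <- fourier_series_model(a0 = 0, alphas = 1, betas = 0, omega = 2 * pi)
  expect_equal(evaluate(m1, 0), 1)
  expect_equal(evaluate(m1, 0.25), 0, tolerance = 1e-14)
})

test_that("evaluate matches a term-by-term brute-force sum", {
  m <- random_model(order = 5, omega = 3.7, seed = 42)
  x <- seq(-1, 4, length.out = 100)
  expect_equal(evaluate(m, x), brute_force_eval(m, x), tolerance = 1e-12)
})

test_that("evaluate is exactly periodic with period 2*pi/omega", {
  m <- random_model(order = 4, omega = 2.2, seed = 7)
  x <- seq(0, 10, length.out = 57)
  expect_lt(max(abs(evaluate(m, x) - evaluate(m, x + 2 * pi / m$omega))),
            1e-9)
})

test_that("model construction rejects invalid parameter sets", {
  expect_error(fourier_series_model(0, 1:3, 1:2, omega = 1),
               "equal length")
  expect_error(fourier_series_model(0, 1:9, 1:9, omega = 1), "max_order")
  expect_error(fourier_series_model(0, omega = -1), "omega")
  expect_error(fourier_series_model(0, omega = 1, domain_start = 1,
                                    domain_end = 1), "domain_end")
})

test_that("quadrature coefficients recover known harmonic content", {
  span <- 2
  w <- 2 * pi / span
  tr <- fn_trace(function(t) cos(w * t), duration = span, fs = 5000)
  ab <- analytic_coefficients(tr, 1)
  expect_equal(ab[["alpha"]], 1, tolerance = 1e-3)
  expect_equal(ab[["beta"]], 0, tolerance = 1e-3)

  const <- fn_trace(function(t) rep(3, length(t)), duration = 1)
  expect_equal(analytic_coefficients(const, 0),
               c(alpha = 3, beta = 0))

  # odd square wave of amplitude 1: beta_1 = 4/pi
  sq <- fn_trace(function(t) ifelse(t %% 1 < 0.5, 1, -1),
                 duration = 1, fs = 1e4)
  expect_equal(analytic_coefficients(sq, 1)[["beta"]], 4 / pi,
               tolerance = 1e-2)
  expect_error(analytic_coefficients(sq, -1), "n must be >= 0")
})

test_that("complex coefficients satisfy the Euler decomposition", {
  span <- 1
  w <- 2 * pi / span
  tr <- fn_trace(function(t) cos(w * t), duration = span, fs = 5000)
  m1 <- complex_coefficients(tr, 1)
  expect_equal(Re(m1), 0.5, tolerance = 1e-3)
  expect_equal(Im(m1), 0, tolerance = 1e-3)

  const <- fn_trace(function(t) rep(2.5, length(t)), duration = 1)
  expect_equal(Re(complex_coefficients(const, 0)), 2.5)
})

test_that("complex and real coefficients agree: m_n = (alpha - i beta)/2", {
  m <- random_model(order = 4, omega = 2 * pi / 1.5, seed = 3)
  tr <- model_trace(m, n = 4001)
  for (n in 1:4) {
    ab <- analytic_coefficients(tr, n)
    mn <- complex_coefficients(tr, n)
    expect_equal(mn, complex(real = ab[["alpha"]] / 2,
                             imaginary = -ab[["beta"]] / 2),
                 tolerance = 1e-10)
  }
})

test_that("fixed-omega fitting recovers a generating model's coefficients", {
  span <- 2
  m <- random_model(order = 3, omega = 2 * pi / span, seed = 5,
                    domain = c(0, span))
  tr <- model_trace(m, n = 2000)
  fit <- fit_fourier(tr, order = 3, omega_mode = "fixed")
  expect_equal(fit$model$a0, m$a0, tolerance = 1e-6)
  expect_equal(fit$model$alphas, m$alphas, tolerance = 1e-6)
  expect_equal(fit$model$betas, m$betas, tolerance = 1e-6)
  expect_gte(fit$fitting_degree, 1 - 1e-10)
})

test_that("free-omega fitting recovers an off-fundamental frequency", {
  # true fundamental 1.3x the span-periodic default
  span <- 3
  w_true <- 1.3 * 2 * pi / span
  tr <- fn_trace(function(t) 0.5 + sin(w_true * t) + 0.3 * cos(2 * w_true * t),
                 duration = span, fs = 500)
  fit <- fit_fourier(tr, order = 2, omega_mode = "free")
  expect_equal(fit$model$omega, w_true, tolerance = 1e-4)
  expect_gte(fit$fitting_degree, 1 - 1e-6)
})

test_that("degenerate traces are rejected by fitting", {
  const <- fn_trace(function(t) rep(1, length(t)), duration = 1)
  expect_error(fit_fourier(const, 2), "degenerate")
  expect_error(select_order(const), "degenerate")
})

test_that("fixed-omega LSQ agrees with the quadrature coefficients on a
           densely sampled periodic signal", {
  span <- 2
  m <- random_model(order = 3, omega = 2 * pi / span, seed = 9,
                    domain = c(0, span))
  tr <- model_trace(m, n = 4001)
  fit <- fit_fourier(tr, order = 3, omega_mode = "fixed")
  for (n in 1:3) {
    ab <- analytic_coefficients(tr, n)
    expect_equal(fit$model$alphas[n], ab[["alpha"]], tolerance = 1e-2)
    expect_equal(fit$model$betas[n], ab[["beta"]], tolerance = 1e-2)
  }
})

test_that("fitting degree is non-decreasing in the order (nested LSQ)", {
  set.seed(21)
  tr <- fn_trace(function(t) 1 + sin(2 * pi * t) + 0.4 * cos(6 * pi * t) +
                   stats::rnorm(length(t), 0, 0.2),
                 duration = 1, fs = 1000)
  fds <- vapply(0:6, function(N)
    fit_fourier(tr, N, omega_mode = "fixed")$fitting_degree, numeric(1))
  expect_true(all(diff(fds) >= -1e-12))
})

test_that("residual collapses once the order covers the harmonic content", {
  span <- 1
  m <- random_model(order = 3, omega = 2 * pi / span, seed = 13,
                    domain = c(0, span))
  tr <- model_trace(m, n = 1000)
  sse <- function(N) {
    f <- fit_fourier(tr, N, omega_mode = "fixed")
    sum((tr$force - evaluate(f$model, tr$t))^2)
  }
  expect_lt(sse(3), 1e-8 * sse(0))
})

test_that("spectral order selection finds the harmonic content", {
  span <- 5
  w <- 2 * pi / span
  one <- fn_trace(function(t) sin(w * t), duration = span, fs = 200)
  expect_identical(select_order(one), 1L)

  three <- fn_trace(function(t) sin(w * t) + 0.5 * sin(2 * w * t) +
                      0.25 * sin(3 * w * t), duration = span, fs = 200)
  expect_identical(select_order(three), 3L)

  set.seed(2)
  wn <- fn_trace(function(t) stats::rnorm(length(t)), duration = 1,
                 fs = 1000)
  expect_warning(N <- select_order(wn, max_order = 8), "returning max_order")
  expect_identical(N, 8L)
})

test_that("model serialization round-trips through the key-value format", {
  m <- random_model(order = 4, omega = 3.3, seed = 17, domain = c(1.2, 4.5))
  p <- withr::local_tempfile(fileext = ".model")
  write_model(m, p)
  back <- read_model(p)
  expect_equal(back$a0, m$a0)
  expect_equal(back$alphas, m$alphas)
  expect_equal(back$betas, m$betas)
  expect_equal(back$omega, m$omega)
  expect_equal(back$domain_start, m$domain_start)

  m0 <- fourier_series_model(a0 = 1.5, omega = 2, domain_start = 0,
                             domain_end = 3)
  write_model(m0, p)
  expect_equal(read_model(p)$order, 0L)
})
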