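#' Finite Fourier-series force model
#'
#' The insertion-force model used throughout the package:
#' \deqn{y(x) = a_0 + \sum_{n=1}^{N} [\alpha_n \cos(n \omega x) +
#'       \beta_n \sin(n \omega x)]}
#' where `x` is time in seconds, `a0` the constant offset (N), `alphas` and
#' `betas` the harmonic coefficient pairs (N), `omega` the fundamental
#' angular frequency (rad/s), and `order` the number of harmonics N. A
#' non-periodic force segment is treated as one period of a periodic
#' function (periodic extension), so the model is defined on the whole real
#' line; `domain_start`/`domain_end` record the fitted interval.
#'
#' @param a0 constant offset (N).
#' @param alphas,betas cosine/sine coefficients, each of length `order`.
#' @param omega fundamental angular frequency (rad/s), > 0.
#' @param domain_start,domain_end fitted interval (s), `domain_end >
#'   domain_start`.
#' @param max_order upper bound on the order accepted without complaint;
#'   the default policy caps the series at 8 harmonics.
#' @return object of class `fourier_series_model`.
#' @export
fourier_series_model <- function(a0, alphas = numeric(0), betas = numeric(0),
                                 omega, domain_start = 0,
                                 domain_end = 2 * pi / omega,
                                 max_order = 8L) {
  alphas <- as.numeric(alphas); betas <- as.numeric(betas)
  if (length(alphas) != length(betas))
    stop("fourier_series_model: alphas and betas must have equal length")
  order <- length(alphas)
  if (order > max_order)
    stop("fourier_series_model: order ", order, " exceeds max_order ",
         max_order)
  if (!is.finite(omega) || omega <= 0)
    stop("fourier_series_model: omega must be finite and > 0")
  if (!all(is.finite(c(a0, alphas, betas))))
    stop("fourier_series_model: coefficients must be finite")
  if (!(domain_end > domain_start))
    stop("fourier_series_model: domain_end must exceed domain_start")
  structure(list(a0 = a0, alphas = alphas, betas = betas, omega = omega,
                 order = order, domain_start = domain_start,
                 domain_end = domain_end),
            class = "fourier_series_model")
}

#' @export
print.fourier_series_model <- function(x, ...) {
  cat(sprintf(
    "<fourier_series_model> order %d, omega = %.6g rad/s (period %.6g s)\n",
    x$order, x$omega, 2 * pi / x$omega))
  cat(sprintf("  a0 = %.6g N, domain [%.6g, %.6g] s\n",
              x$a0, x$domain_start, x$domain_end))
  invisible(x)
}

#' Evaluate a Fourier-series model
#'
#' Returns `a0 + sum_n alphas[n] cos(n omega x) + betas[n] sin(n omega x)`.
#' Evaluation outside the fitted domain is permitted: under periodic
#' extension the model repeats with period `2*pi/omega`.
#'
#' @param model a [fourier_series_model].
#' @param x time(s) in seconds, scalar or vector.
#' @return force in N, same length as `x`.
#' @export
evaluate <- function(model, x) {
  stopifnot(inherits(model, "fourier_series_model"))
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("evaluate: x must be finite")
  y <- rep(model$a0, length(x))
  if (model$order > 0L) {
    n <- seq_len(model$order)
    # outer(x, n*omega) is an |x| x N matrix of phases
    ph <- outer(x, n * model$omega)
    y <- y + drop(cos(ph) %*% model$alphas + sin(ph) %*% model$betas)
  }
  y
}

#' @rdname evaluate
#' @param object,... S3 method arguments; `newdata` is passed as `x`.
#' @param newdata evaluation times (s); defaults to the fitted domain grid.
#' @export
predict.fourier_series_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    stop("predict.fourier_series_model: supply newdata (times in s)")
  evaluate(object, newdata)
}

#' Harmonic coefficients by quadrature
#'
#' Treats the trace as one period of a periodic function (T = trace span,
#' omega = 2*pi/T) and computes the classical coefficient integrals by
#' trapezoidal quadrature:
#' alpha_n = (2/T) Int y cos(n omega x) dx, beta_n = (2/T) Int y sin(n
#' omega x) dx. For n = 0 the adopted convention is (mean(y), 0), so a
#' constant signal is represented exactly by the offset term.
#'
#' @param trace a [force_trace], treated as one period.
#' @param n harmonic index, >= 0.
#' @return numeric `c(alpha_n, beta_n)`.
#' @seealso [complex_coefficients()]
#' @export
analytic_coefficients <- function(trace, n) {
  stopifnot(inherits(trace, "force_trace"))
  if (n < 0) stop("analytic_coefficients: n must be >= 0")
  x <- trace$t - trace$t[1L]
  span <- x[length(x)]
  if (span <= 0) stop("analytic_coefficients: trace span must be > 0")
  if (n == 0) return(c(alpha = trapz_mean(x, trace$force), beta = 0))
  w <- 2 * pi / span
  c(alpha = 2 * trapz_mean(x, trace$force * cos(n * w * x)),
    beta  = 2 * trapz_mean(x, trace$force * sin(n * w * x)))
}

#' Complex Fourier coefficients by quadrature
#'
#' m_n = (1/T) Int y exp(-i n omega x) dx over one period. Satisfies
#' m_0 = mean(y) and, for n >= 1, m_n = (alpha_n - i beta_n)/2 up to
#' quadrature error.
#'
#' @inheritParams analytic_coefficients
#' @param n harmonic index; may be negative.
#' @return a complex scalar.
#' @export
complex_coefficients <- function(trace, n) {
  stopifnot(inherits(trace, "force_trace"))
  x <- trace$t - trace$t[1L]
  span <- x[length(x)]
  if (span <= 0) stop("complex_coefficients: trace span must be > 0")
  w <- 2 * pi / span
  f <- trace$force * exp(-1i * n * w * x)
  complex(real = trapz_mean(x, Re(f)), imaginary = trapz_mean(x, Im(f)))
}

# (1/T) Int f dx by the trapezoid rule on possibly irregular x
trapz_mean <- function(x, f) {
  n <- length(x)
  sum(diff(x) * (f[-1L] + f[-n])) / 2 / (x[n] - x[1L])
}

#' Fit a Fourier-series force model by least squares
#'
#' Minimizes the sum of squared residuals between the trace's force and the
#' model. With `omega_mode = "fixed"` the fundamental is pinned (by default
#' to 2*pi/span, the periodic extension of the segment) and the problem is
#' linear least squares on the trigonometric design matrix. With
#' `omega_mode = "free"` (the default) omega is an additional nonlinear
#' parameter: a Levenberg-Marquardt search over omega with the coefficients
#' profiled out by the linear solver (variable projection), started from 5
#' spread initial values in `[0.2, 5] * 2*pi/span`.
#'
#' @param trace a [force_trace] with positive force variance.
#' @param order number of harmonics N (0..`max_order`).
#' @param omega_mode `"free"` or `"fixed"`.
#' @param omega optional fixed fundamental (rad/s); only honoured in
#'   `"fixed"` mode, default `2*pi/span`.
#' @param max_order order cap (default 8).
#' @param omega_bounds multiplicative search bounds on omega around
#'   `2*pi/span` in `"free"` mode.
#' @return a list with elements `model` (the fitted
#'   [fourier_series_model]) and `fitting_degree` (R-squared, see
#'   [fitting_degree()]).
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' tr <- force_trace(t, 3 * t, 1 + cos(2 * pi * t) + 0.3 * sin(4 * pi * t))
#' fit <- fit_fourier(tr, order = 2, omega_mode = "fixed")
#' fit$fitting_degree
#' @export
fit_fourier <- function(trace, order, omega_mode = c("free", "fixed"),
                        omega = NULL, max_order = 8L,
                        omega_bounds = c(0.2, 5)) {
  stopifnot(inherits(trace, "force_trace"))
  omega_mode <- match.arg(omega_mode)
  if (order < 0 || order > max_order)
    stop("fit_fourier: order must be in [0, ", max_order, "]")
  x <- trace$t - trace$t[1L]
  y <- trace$force
  span <- x[length(x)]
  if (span <= 0) stop("fit_fourier: trace span must be > 0")
  if (stats::var(y) == 0)
    stop("fit_fourier: degenerate input (zero force variance); ",
         "fitting degree undefined")
  w0 <- 2 * pi / span

  if (omega_mode == "fixed") {
    w <- if (is.null(omega)) w0 else omega
    if (!is.finite(w) || w <= 0) stop("fit_fourier: omega must be > 0")
    sol <- fourier_linear_lsq(x, y, w, order)
    w_hat <- w
  } else {
    # variable projection: LM over omega, coefficients solved linearly
    lo <- omega_bounds[1L] * w0; hi <- omega_bounds[2L] * w0
    starts <- exp(seq(log(lo), log(hi), length.out = 5L))
    best <- NULL
    for (ws in starts) {
      res_fn <- function(p) {
        wv <- min(max(p[1L], lo), hi)
        y - fourier_linear_lsq(x, y, wv, order)$fitted
      }
      fit <- tryCatch(
        minpack.lm::nls.lm(par = ws, fn = res_fn,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-10, ptol = 1e-10, maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      wv <- min(max(fit$par[1L], lo), hi)
      cost <- sum((y - fourier_linear_lsq(x, y, wv, order)$fitted)^2)
      if (is.null(best) || cost < best$cost) best <- list(w = wv, cost = cost)
    }
    if (is.null(best)) {
      # all LM starts failed: fall back to the linear solution at 2*pi/span
      sol <- fourier_linear_lsq(x, y, w0, order)
      cond <- structure(
        class = c("needleforce_convergence_error", "error", "condition"),
        list(message = "fit_fourier: nonlinear solver failed on all starts",
             call = sys.call(), best = sol))
      stop(cond)
    }
    w_hat <- best$w
    sol <- fourier_linear_lsq(x, y, w_hat, order)
  }

  model <- fourier_series_model(
    a0 = sol$coef[1L],
    alphas = if (order > 0) sol$coef[1L + seq_len(order)] else numeric(0),
    betas  = if (order > 0) sol$coef[1L + order + seq_len(order)]
             else numeric(0),
    omega = w_hat, domain_start = trace$t[1L],
    domain_end = trace$t[length(trace$t)], max_order = max(max_order, order))
  # model was fit on re-zeroed time; shift the phase back to absolute time
  model <- shift_model_origin(model, trace$t[1L])
  list(model = model,
       fitting_degree = fitting_degree(y, evaluate(model, trace$t)))
}

# linear LSQ of y on [1, cos(n w x), sin(n w x)]; returns coef and fitted
fourier_linear_lsq <- function(x, y, w, order) {
  X <- matrix(1, nrow = length(x), ncol = 1L + 2L * order)
  if (order > 0L) {
    ph <- outer(x, seq_len(order) * w)
    X[, 1L + seq_len(order)] <- cos(ph)
    X[, 1L + order + seq_len(order)] <- sin(ph)
  }
  cf <- qr.coef(qr(X), y)
  cf[is.na(cf)] <- 0          # rank deficiency (e.g. w at Nyquist): drop term
  list(coef = cf, fitted = drop(X %*% cf))
}

# re-express the model with time origin moved by dt (y'(x) = y(x - dt))
shift_model_origin <- function(model, dt) {
  if (model$order == 0L || dt == 0) return(model)
  n <- seq_len(model$order)
  phi <- n * model$omega * dt
  a <- model$alphas * cos(phi) - model$betas * sin(phi)
  b <- model$alphas * sin(phi) + model$betas * cos(phi)
  model$alphas <- a
  model$betas <- b
  model
}

#' Choose the harmonic order from the spectrum
#'
#' Computes the periodogram of the mean-removed trace (no taper) and returns
#' the smallest N <= `max_order` such that the spectral energy in the first
#' N harmonic bins of the fundamental 2*pi/span captures at least
#' `energy_threshold` of the total non-DC energy. If no order qualifies
#' (broadband input), returns `max_order` with a warning.
#'
#' @param trace a [force_trace] with positive force variance.
#' @param max_order largest admissible order (default 8).
#' @param energy_threshold required cumulative energy fraction (default
#'   0.99).
#' @return integer order N in `1..max_order`.
#' @export
select_order <- function(trace, max_order = 8L, energy_threshold = 0.99) {
  stopifnot(inherits(trace, "force_trace"))
  if (max_order < 1L) stop("select_order: max_order must be >= 1")
  y <- trace$force - mean(trace$force)
  if (stats::var(trace$force) == 0)
    stop("select_order: degenerate input (zero force variance)")
  L <- length(y)
  p <- Mod(stats::fft(y))^2
  nfreq <- floor(L / 2)                 # one-sided, excluding DC
  p <- p[1L + seq_len(nfreq)]
  total <- sum(p)
  # fundamental of the periodized segment: 1/span Hz; bin spacing fs/L.
  span <- trace$t[L] - trace$t[1L]
  df <- trace$fs / L
  f0 <- 1 / span
  harm_bin <- pmin(pmax(round(seq_len(max_order) * f0 / df), 1L), nfreq)
  cum <- cumsum(p[harm_bin]) / total
  ok <- which(cum >= energy_threshold)
  if (length(ok) == 0L) {
    warning("select_order: no order <= ", max_order, " reaches ",
            energy_threshold, " of non-DC energy; returning max_order")
    return(as.integer(max_order))
  }
  as.integer(min(ok))
}

#' Serialize / deserialize a Fourier model as plain text
#'
#' Key-value block with one `key: value` pair per line (`a0`, `omega`,
#' `order`, `alphas`, `betas`, `domain`), the interchange format consumed by
#' the stream renderer and the command-line tools.
#'
#' @param model a [fourier_series_model].
#' @param path destination (write) / source (read) file.
#' @return `write_model`: `path` invisibly; `read_model`: the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "fourier_series_model"))
  num <- function(v) paste(format(v, digits = 17, trim = TRUE),
                           collapse = " ")
  lines <- c(paste0("a0: ", num(model$a0)),
             paste0("omega: ", num(model$omega)),
             paste0("order: ", model$order),
             paste0("alphas: ", num(model$alphas)),
             paste0("betas: ", num(model$betas)),
             paste0("domain: ", num(c(model$domain_start,
                                      model$domain_end))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([a-z0-9_]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) {
      v <- trimws(m[3L])
      kv[[m[2L]]] <- if (nzchar(v)) as.numeric(strsplit(v, "\\s+")[[1L]])
                     else numeric(0)
    }
  }
  dom <- kv$domain
  fourier_series_model(a0 = kv$a0, alphas = kv$alphas %||% numeric(0),
                       betas = kv$betas %||% numeric(0), omega = kv$omega,
                       domain_start = dom[1L], domain_end = dom[2L],
                       max_order = max(8L, length(kv$alphas)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
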