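#' Baseline model specification
#'
#' Classical force-model families fitted under the same least-squares /
#' fitting-degree protocol as the Fourier model, for comparison tables:
#' * `polynomial`: y = sum_k c_k x^k, linear least squares, default
#'   degree 2 (the classical prepuncture stiffness fit);
#' * `exponential`: y = a * exp(b x) + c, nonlinear least squares (force
#'   as an exponential of the abscissa);
#' * `nonlinear_power`: y = a * x^b + c with x shifted to be >= 0, the
#'   package's concrete form of a generic nonlinear spring-type law.
#'
#' @param family one of `"polynomial"`, `"exponential"`,
#'   `"nonlinear_power"`.
#' @param degree polynomial degree (polynomial only), >= 0.
#' @param params_init optional named initial values for the nonlinear
#'   families (`a`, `b`, `c`).
#' @return object of class `baseline_spec`.
#' @export
baseline_spec <- function(family = c("polynomial", "exponential",
                                     "nonlinear_power"),
                          degree = 2L, params_init = NULL) {
  family <- match.arg(family)
  if (family == "polynomial" && degree < 0)
    stop("baseline_spec: polynomial degree must be >= 0")
  structure(list(family = family, degree = as.integer(degree),
                 params_init = params_init),
            class = "baseline_spec")
}

#' Fit a baseline force model
#'
#' Least-squares fit of the family in `spec` on the trace's time axis (the
#' same abscissa as the Fourier model, for comparability). Nonlinear
#' families use Levenberg-Marquardt with data-driven starts and a few
#' fallback restarts; on total non-convergence the best solution so far is
#' attached to the error condition.
#'
#' @param trace a [force_trace] with positive force variance.
#' @param spec a [baseline_spec].
#' @return list with `model` (class `baseline_model`: family, parameters,
#'   prediction function domain) and `fitting_degree`.
#' @export
fit_baseline <- function(trace, spec) {
  stopifnot(inherits(trace, "force_trace"), inherits(spec, "baseline_spec"))
  x <- trace$t - trace$t[1L]
  y <- trace$force
  if (stats::var(y) == 0)
    stop("fit_baseline: degenerate input (zero force variance)")
  fitted <- NULL
  if (spec$family == "polynomial") {
    X <- outer(x, 0:spec$degree, `^`)
    cf <- qr.coef(qr(X), y)
    cf[is.na(cf)] <- 0
    pars <- stats::setNames(cf, paste0("c", 0:spec$degree))
    fitted <- drop(X %*% cf)
  } else if (spec$family == "exponential") {
    pars <- fit_nls_family(x, y, spec$params_init,
      f = function(p, x) p[1L] * exp(p[2L] * x) + p[3L],
      starts = exp_starts(x, y), names = c("a", "b", "c"))
    fitted <- pars$fitted; pars <- pars$par
  } else {                              # nonlinear_power
    pars <- fit_nls_family(x, y, spec$params_init,
      f = function(p, x) p[1L] * pmax(x, 1e-12)^p[2L] + p[3L],
      starts = power_starts(x, y), names = c("a", "b", "c"))
    fitted <- pars$fitted; pars <- pars$par
  }
  model <- structure(list(family = spec$family, parameters = pars,
                          t0 = trace$t[1L]),
                     class = "baseline_model")
  list(model = model, fitting_degree = fitting_degree(y, fitted))
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model> %s: %s\n", x$family,
              paste(names(x$parameters),
                    format(x$parameters, digits = 4),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @rdname fit_baseline
#' @param object,newdata,... predict method: evaluation times in seconds.
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  x <- as.numeric(newdata) - object$t0
  p <- object$parameters
  switch(object$family,
    polynomial = drop(outer(x, seq_along(p) - 1L, `^`) %*% p),
    exponential = p[["a"]] * exp(p[["b"]] * x) + p[["c"]],
    nonlinear_power = p[["a"]] * pmax(x, 1e-12)^p[["b"]] + p[["c"]])
}

# LM fit over a small start set; returns best parameters and fitted values
fit_nls_family <- function(x, y, params_init, f, starts, names) {
  if (!is.null(params_init))
    starts <- c(list(as.numeric(params_init[names])), starts)
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = function(p) y - f(p, x),
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-12, ptol = 1e-12, maxiter = 300)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    cost <- sum((y - f(fit$par, x))^2)
    if (is.finite(cost) && (is.null(best) || cost < best$cost))
      best <- list(par = fit$par, cost = cost)
  }
  if (is.null(best)) {
    cond <- structure(
      class = c("needleforce_convergence_error", "error", "condition"),
      list(message = "fit_baseline: nonlinear solver failed on all starts",
           call = sys.call()))
    stop(cond)
  }
  list(par = stats::setNames(best$par, names),
       fitted = f(best$par, x))
}

# starting values for y = a e^{bx} + c: log-linear fit above a floor
exp_starts <- function(x, y) {
  c0 <- min(y) - 0.05 * (max(y) - min(y)) - 1e-9
  z <- log(pmax(y - c0, 1e-12))
  cf <- stats::coef(stats::lm(z ~ x))
  list(c(exp(cf[[1L]]), cf[[2L]], c0),
       c(1, 0.1, 0), c(-1, -0.1, mean(y)), c(0.1, 1, min(y)))
}

# starting values for y = a x^b + c: log-log slope on the upper range
power_starts <- function(x, y) {
  pos <- x > 0
  b0 <- 1
  if (sum(pos) > 2L) {
    cf <- tryCatch(stats::coef(stats::lm(
      log(pmax(y[pos] - min(y) + 1e-9, 1e-12)) ~ log(x[pos]))),
      error = function(e) c(0, 1))
    b0 <- max(min(cf[[2L]], 6), 0.1)
  }
  a0 <- (max(y) - min(y)) / max(max(x)^b0, 1e-12)
  list(c(a0, b0, min(y)), c(1, 1, 0), c(1, 2, 0), c(0.5, 1.5, mean(y)))
}

#' Compare model families phase-by-phase
#'
#' Fits every family in `specs` (plus the Fourier model, always included)
#' over the phases of `segmentation` and lays the per-phase fitting degrees
#' out as a comparison table: one row per family, one column per phase,
#' plus the unweighted row average. Failed fits render as `NA` and make
#' that row's average undefined.
#'
#' @param trace a [force_trace].
#' @param segmentation a [phase_segmentation].
#' @param specs list of [baseline_spec] objects; default polynomial
#'   (degree 2), exponential, and power-law.
#' @param fourier_order fixed Fourier order, or `NULL` for per-phase
#'   spectral selection.
#' @param omega_mode passed to [fit_fourier()].
#' @return object of class `comparison_table`: a data.frame (rows =
#'   families) with phase columns and `average`, plus the per-family
#'   [fit_report]s in attribute `reports`.
#' @export
compare_models <- function(trace, segmentation,
                           specs = list(baseline_spec("polynomial"),
                                        baseline_spec("exponential"),
                                        baseline_spec("nonlinear_power")),
                           fourier_order = NULL, omega_mode = "free") {
  stopifnot(inherits(trace, "force_trace"),
            inherits(segmentation, "phase_segmentation"))
  fams <- c(vapply(specs, function(s) s$family, character(1)), "fourier")
  reports <- c(lapply(specs, function(s)
                 fit_piecewise(trace, segmentation, s)),
               list(fit_piecewise(trace, segmentation, "fourier",
                                  order = fourier_order,
                                  omega_mode = omega_mode)))
  K <- segmentation$n_phases
  tab <- as.data.frame(t(vapply(reports, function(r)
    c(r$per_phase$degree, r$average), numeric(K + 1L))))
  names(tab) <- c(paste0("phase", seq_len(K)), "average")
  tab <- cbind(family = fams, tab)
  structure(tab, reports = stats::setNames(reports, fams),
            class = c("comparison_table", "data.frame"))
}

#' @export
print.comparison_table <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "failed", sprintf("%.4f", v)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a comparison table as delimited text
#'
#' Rows = model families, columns = per-phase fitting degrees plus the row
#' average, rendered at 4 decimal places.
#'
#' @param table a [compare_models()] result.
#' @param path destination file.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "comparison_table"))
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "failed", sprintf("%.4f", v)))
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
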