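#' Fitting degree (coefficient of determination)
#'
#' The package's goodness-of-fit statistic for a fitted force model:
#' `1 - SSE/SST` with `SSE = sum((obs - pred)^2)` and
#' `SST = sum((obs - mean(obs))^2)`. Equals 1 for a perfect fit, 0 for a
#' fit no better than the observed mean, and may be negative for worse
#' fits. This is the default goodness-of-fit statistic of standard
#' curve-fitting workflows (R-squared).
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return a scalar <= 1.
#' @examples
#' fitting_degree(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))  # 0.98
#' @export
fitting_degree <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("fitting_degree: length mismatch (", length(observed), " vs ",
         length(predicted), ")")
  if (length(observed) < 2L)
    stop("fitting_degree: need at least 2 observations")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    stop("fitting_degree: degenerate input (zero observed variance)")
  1 - sum((observed - predicted)^2) / sst
}

#' Average per-phase fitting degrees
#'
#' The unweighted arithmetic mean used for the "average" column of piecewise
#' fit reports. Full precision is retained; rendering rounds to 4 decimal
#' places (round-half-even, R's default).
#'
#' @param per_phase_degrees non-empty numeric vector of finite values.
#' @return the mean.
#' @export
aggregate_report <- function(per_phase_degrees) {
  if (length(per_phase_degrees) == 0L)
    stop("aggregate_report: empty list of fitting degrees")
  if (!all(is.finite(per_phase_degrees)))
    stop("aggregate_report: fitting degrees must be finite")
  mean(per_phase_degrees)
}

#' Piecewise fit report
#'
#' Container for the result of fitting one model family phase-by-phase:
#' one row per phase (index, model descriptor, fitting degree) plus the
#' unweighted average. Failed phases carry `NA` and make the average
#' undefined (`NA`, with `ok = FALSE`).
#'
#' @param phase integer phase indices (1-based for reporting).
#' @param model list of per-phase fitted model objects (or `NULL` for
#'   failed phases).
#' @param degree per-phase fitting degrees (`NA` where failed).
#' @param label trace/family tag.
#' @return object of class `fit_report` with fields `per_phase`
#'   (data.frame), `models`, `average`, `ok`, `label`.
#' @export
fit_report <- function(phase, model, degree, label = "") {
  stopifnot(length(phase) == length(degree))
  ok <- all(is.finite(degree))
  avg <- if (ok) aggregate_report(degree) else NA_real_
  structure(list(per_phase = data.frame(phase = phase, degree = degree),
                 models = model, average = avg, ok = ok,
                 label = as.character(label)[1L]),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report>%s %d phases\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              nrow(x$per_phase)))
  df <- x$per_phase
  df$degree <- ifelse(is.na(df$degree), "failed",
                      sprintf("%.4f", df$degree))
  print(df, row.names = FALSE)
  cat(if (x$ok) sprintf("  average: %.4f\n", x$average)
      else "  average: undefined (failed phases)\n")
  invisible(x)
}

#' Write a fit report as delimited text
#'
#' One row per phase plus a final `average` row; columns `phase`,
#' `fitting_degree` (4 decimal places, matching report rendering).
#'
#' @param report a [fit_report].
#' @param path destination file.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, delimiter = ",") {
  stopifnot(inherits(report, "fit_report"))
  fmt <- function(v) ifelse(is.na(v), "failed", sprintf("%.4f", v))
  df <- data.frame(phase = c(as.character(report$per_phase$phase),
                             "average"),
                   fitting_degree = c(fmt(report$per_phase$degree),
                                      fmt(report$average)))
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
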