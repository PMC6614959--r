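#' Force trace objects
#'
#' A `force_trace` is the package's record of one needle insertion: a
#' uniformly sampled time axis (s), the needle tip depth (mm) and the axial
#' force (N), together with the sampling rate (Hz) and a free-text label.
#'
#' @param t numeric vector of sample times in seconds; strictly increasing
#'   with a uniform step.
#' @param depth numeric vector of needle tip depths in mm. May be
#'   respiration-modulated, hence not necessarily monotone, but finite.
#' @param force numeric vector of axial forces in N.
#' @param fs sampling rate in Hz. If `NULL`, inferred as `1/median(diff(t))`.
#' @param label free-text tissue/source tag.
#'
#' @return An object of class `force_trace`: a list with elements `t`,
#'   `depth`, `force`, `fs`, `label`.
#' @examples
#' tr <- force_trace(t = seq(0, 0.999, by = 1e-3),
#'                   depth = 3 * seq(0, 0.999, by = 1e-3),
#'                   force = sin(seq(0, 0.999, by = 1e-3) * 2 * pi))
#' tr$fs
#' @export
force_trace <- function(t, depth, force, fs = NULL, label = "") {
  t <- as.numeric(t); depth <- as.numeric(depth); force <- as.numeric(force)
  if (length(t) < 2L)
    stop("force_trace: need at least 2 samples, got ", length(t))
  if (length(depth) != length(t) || length(force) != length(t))
    stop("force_trace: t, depth, force must have equal length (",
         length(t), ", ", length(depth), ", ", length(force), ")")
  if (!all(is.finite(t)) || !all(is.finite(depth)) || !all(is.finite(force)))
    stop("force_trace: all values must be finite")
  dt <- diff(t)
  if (any(dt <= 0))
    stop("force_trace: time must be strictly increasing")
  if (is.null(fs)) fs <- 1 / stats::median(dt)
  # uniformity: successive steps may deviate from 1/fs by < 1e-6 s
  if (max(abs(dt - 1 / fs)) >= 1e-6)
    stop("force_trace: non-uniform sampling (max step deviation ",
         format(max(abs(dt - 1 / fs))), " s >= 1e-6 s)")
  structure(list(t = t, depth = depth, force = force, fs = fs,
                 label = as.character(label)[1L]),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %d samples @ %.6g Hz, t in [%.6g, %.6g] s%s\n",
              length(x$t), x$fs, x$t[1L], x$t[length(x$t)],
              if (nzchar(x$label)) paste0(", label: ", x$label) else ""))
  cat(sprintf("  force [%.4g, %.4g] N, depth [%.4g, %.4g] mm\n",
              min(x$force), max(x$force), min(x$depth), max(x$depth)))
  invisible(x)
}

#' @export
length.force_trace <- function(x) length(x$t)

#' Read a force trace from delimited text
#'
#' Expects a header naming the columns `time_s`, `depth_mm`, `force_N` in any
#' order. Lines starting with `#` are ignored. A missing `depth_mm` column is
#' tolerated: depth is synthesized as `v_default * time` with a warning, for
#' recordings without depth telemetry.
#'
#' @param path file to read.
#' @param delimiter field separator; `","` (default) or `"\t"`.
#' @param v_default insertion velocity (mm/s) used to synthesize depth when
#'   the column is absent. Default 3 mm/s, the bench protocol's constant
#'   insertion speed.
#' @return a [force_trace].
#' @seealso [write_trace()]
#' @export
read_trace <- function(path, delimiter = ",", v_default = 3) {
  if (!file.exists(path)) stop("read_trace: no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          comment.char = "#", check.names = TRUE,
                          stringsAsFactors = FALSE)
  for (col in c("time_s", "force_N"))
    if (!col %in% names(df))
      stop("read_trace: missing required column '", col, "' in ", path)
  if (nrow(df) < 2L)
    stop("read_trace: fewer than 2 data rows in ", path)
  if (!"depth_mm" %in% names(df)) {
    warning("read_trace: no depth_mm column; synthesizing depth = ",
            v_default, " mm/s * time_s")
    df$depth_mm <- v_default * df$time_s
  }
  label <- sub("\\.[^.]*$", "", basename(path))
  force_trace(t = df$time_s, depth = df$depth_mm, force = df$force_N,
              label = label)
}

#' Write a force trace as delimited text
#'
#' Writes a header `time_s,depth_mm,force_N` and one row per sample at full
#' precision (15 significant digits), so that [read_trace()] recovers the
#' trace to well within 1e-9 per element.
#'
#' @param trace a [force_trace].
#' @param path destination file.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, delimiter = ",") {
  stopifnot(inherits(trace, "force_trace"))
  df <- data.frame(time_s = format(trace$t, digits = 15, scientific = FALSE,
                                   trim = TRUE),
                   depth_mm = format(trace$depth, digits = 15, trim = TRUE),
                   force_N = format(trace$force, digits = 15, trim = TRUE))
  ok <- tryCatch({
    utils::write.table(df, path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("write_trace: cannot write ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Extract a contiguous sub-trace
#'
#' Half-open, 0-based index range `[start_index, end_index)`, the indexing
#' convention used by all modules. The time axis is not re-zeroed and the
#' sampling rate is preserved.
#'
#' @param trace a [force_trace].
#' @param start_index first sample (0-based, inclusive).
#' @param end_index one past the last sample (exclusive).
#' @return a [force_trace] with `end_index - start_index` samples.
#' @export
slice_trace <- function(trace, start_index, end_index) {
  stopifnot(inherits(trace, "force_trace"))
  n <- length(trace$t)
  if (start_index < 0 || end_index > n || start_index >= end_index)
    stop("slice_trace: invalid range [", start_index, ", ", end_index,
         ") for trace of length ", n)
  idx <- seq.int(start_index + 1L, end_index)
  if (length(idx) < 2L)
    stop("slice_trace: slice must keep at least 2 samples")
  force_trace(t = trace$t[idx], depth = trace$depth[idx],
              force = trace$force[idx], fs = trace$fs, label = trace$label)
}
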