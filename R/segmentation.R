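#' Phase segmentation of an insertion trace
#'
#' A needle insertion is modeled piecewise over (by default) five phases:
#' contiguous half-open index ranges `[b[k], b[k+1])` covering the whole
#' trace. `boundaries` are 0-based sample indices with `b[1] = 0` and
#' `b[K+1] = length(trace)`.
#'
#' @param boundaries strictly increasing integer vector starting at 0 and
#'   ending at `trace_length`.
#' @param trace_length number of samples the segmentation partitions.
#' @param min_phase minimum samples per phase (fit feasibility), default
#'   `max(10, 2*(max_order+1))` with the package's order cap of 8.
#' @return object of class `phase_segmentation`.
#' @export
phase_segmentation <- function(boundaries, trace_length,
                               min_phase = max(10L, 2L * (8L + 1L))) {
  boundaries <- as.integer(boundaries)
  if (boundaries[1L] != 0L ||
      boundaries[length(boundaries)] != trace_length)
    stop("phase_segmentation: boundaries must start at 0 and end at the ",
         "trace length")
  if (any(diff(boundaries) <= 0))
    stop("phase_segmentation: boundaries must be strictly increasing")
  if (any(diff(boundaries) < min_phase))
    stop("phase_segmentation: each phase needs >= ", min_phase, " samples")
  structure(list(boundaries = boundaries,
                 n_phases = length(boundaries) - 1L),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("<phase_segmentation> %d phases, boundaries: %s\n",
              x$n_phases, paste(x$boundaries, collapse = ", ")))
  invisible(x)
}

#' Segment an insertion trace into puncture phases
#'
#' With `method = "events"` (default), puncture events are detected as
#' abrupt drops in the median-smoothed force: a drop of at least
#' `drop_threshold` N within `window_ms`. Events are ranked by drop
#' magnitude and the largest `n_phases - 1` become phase boundaries, placed
#' at the steepest force decrease within each event. If fewer admissible
#' events exist, the method falls back to equal-length phases with a
#' warning. `method = "equal"` always splits into equal-length phases.
#'
#' @param trace a [force_trace].
#' @param n_phases number of phases (default 5).
#' @param method `"events"` or `"equal"`.
#' @param drop_threshold minimum force drop (N) that counts as a puncture
#'   event; default 0.3 N.
#' @param window_ms time window (ms) within which the drop must occur;
#'   default 50 ms.
#' @param smooth_samples running-median width for pre-smoothing (odd;
#'   default 21).
#' @param min_phase minimum samples per phase.
#' @return a [phase_segmentation].
#' @export
segment_phases <- function(trace, n_phases = 5L,
                           method = c("events", "equal"),
                           drop_threshold = 0.3, window_ms = 50,
                           smooth_samples = 21L,
                           min_phase = max(10L, 2L * (8L + 1L))) {
  stopifnot(inherits(trace, "force_trace"))
  method <- match.arg(method)
  L <- length(trace$t)
  if (L < n_phases * min_phase)
    stop("segment_phases: trace too short (", L, " samples) for ",
         n_phases, " phases of >= ", min_phase, " samples")
  equal_bounds <- function() {
    b <- round(seq(0L, L, length.out = n_phases + 1L))
    phase_segmentation(b, L, min_phase)
  }
  if (method == "equal" || n_phases == 1L) return(equal_bounds())

  k <- min(smooth_samples, if (L %% 2L == 0L) L - 1L else L)
  if (k %% 2L == 0L) k <- k - 1L
  s <- stats::runmed(trace$force, k)
  w <- max(1L, round(window_ms / 1000 * trace$fs))
  # largest drop from sample i to any of the next w samples
  drop <- s - runmin_window(s, w)
  cand <- which(drop >= drop_threshold)
  if (length(cand) == 0L) {
    warning("segment_phases: no puncture events found; ",
            "falling back to equal-length phases")
    return(equal_bounds())
  }
  # cluster contiguous candidates (gap > w starts a new event)
  grp <- cumsum(c(1L, diff(cand) > w))
  events <- do.call(rbind, lapply(split(cand, grp), function(ix) {
    # boundary at the steepest decrease inside the event window
    hi <- min(max(ix) + w, L - 1L)
    seg <- seq.int(min(ix), hi)
    d1 <- diff(s)[seg]
    c(pos = seg[which.min(d1)] + 1L, mag = max(drop[ix]))
  }))
  events <- events[order(-events[, "mag"]), , drop = FALSE]
  picked <- integer(0)
  for (p in events[, "pos"]) {
    ok <- all(abs(c(picked, 0L, L) - p) >= min_phase)
    if (ok) picked <- c(picked, p)
    if (length(picked) == n_phases - 1L) break
  }
  if (length(picked) < n_phases - 1L) {
    warning("segment_phases: only ", length(picked), " admissible events ",
            "for ", n_phases, " phases; falling back to equal-length phases")
    return(equal_bounds())
  }
  phase_segmentation(c(0L, sort(picked), L), L, min_phase)
}

# rolling minimum of the next `w` values (inclusive of self)
runmin_window <- function(x, w) {
  L <- length(x)
  out <- x
  if (w <= 0L) return(out)
  for (off in seq_len(w)) {
    shifted <- c(x[-seq_len(off)], rep(x[L], off))
    out <- pmin(out, shifted)
  }
  out
}

#' Fit a model family phase-by-phase
#'
#' For every phase of `segmentation`, slices the trace and fits either the
#' Fourier model (order chosen per phase by [select_order()] unless
#' `order` is given) or a baseline family, then collects per-phase fitting
#' degrees and their unweighted mean into a [fit_report].
#'
#' @param trace a [force_trace].
#' @param segmentation a [phase_segmentation] of `trace`.
#' @param model_spec either the string `"fourier"` or a [baseline_spec].
#' @param order fixed Fourier order; `NULL` (default) selects per phase.
#' @param omega_mode passed to [fit_fourier()].
#' @param max_order order cap for selection and fitting.
#' @param energy_threshold passed to [select_order()].
#' @return a [fit_report].
#' @export
fit_piecewise <- function(trace, segmentation, model_spec = "fourier",
                          order = NULL, omega_mode = "free",
                          max_order = 8L, energy_threshold = 0.99) {
  stopifnot(inherits(trace, "force_trace"),
            inherits(segmentation, "phase_segmentation"))
  b <- segmentation$boundaries
  K <- segmentation$n_phases
  degrees <- rep(NA_real_, K)
  models <- vector("list", K)
  for (k in seq_len(K)) {
    sub <- slice_trace(trace, b[k], b[k + 1L])
    res <- tryCatch({
      if (identical(model_spec, "fourier")) {
        N <- if (is.null(order))
          suppressWarnings(select_order(sub, max_order, energy_threshold))
        else order
        fit_fourier(sub, N, omega_mode = omega_mode, max_order = max_order)
      } else {
        fit_baseline(sub, model_spec)
      }
    }, error = function(e) e)
    if (!inherits(res, "error")) {
      models[[k]] <- res$model
      degrees[k] <- res$fitting_degree
    }
  }
  lab <- if (identical(model_spec, "fourier")) "fourier"
         else model_spec$family
  fit_report(seq_len(K), models, degrees,
             label = paste0(trace$label,
                            if (nzchar(trace$label)) "/" else "", lab))
}
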