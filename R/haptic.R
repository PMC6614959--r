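#' Render bundle: a piecewise model ready for haptic playback
#'
#' Packages a phase segmentation (as boundary times), the per-phase
#' Fourier models, and optional respiration settings into a renderable
#' object. Piecewise models are discontinuous at phase boundaries; the
#' renderer removes the node discontinuity by linearly cross-fading the
#' two adjacent phase models inside a window of `blend_ms` centred on each
#' interior boundary.
#'
#' @param boundaries_s strictly increasing phase boundary times in s
#'   (length = number of phases + 1).
#' @param models list of [fourier_series_model]s, one per phase.
#' @param respiration optional [respiratory_params].
#' @param coupling respiration-to-depth coupling in `[0, 1]`.
#' @param resp_force_gain additive force modulation gain (N per mm of
#'   respiratory displacement), default 0. Models fitted on traces that
#'   already contain respiratory modulation should leave this at 0; it
#'   exists to animate bench-static models.
#' @param blend_ms cross-fade window at interior boundaries (ms), >= 0;
#'   default 20.
#' @param rate playback sample rate in Hz (default 1000, the conventional
#'   haptic update rate).
#' @param velocity insertion velocity (mm/s) used for the rendered depth
#'   channel (default 3).
#' @return object of class `render_bundle`.
#' @export
render_bundle <- function(boundaries_s, models, respiration = NULL,
                          coupling = 1, resp_force_gain = 0,
                          blend_ms = 20, rate = 1000, velocity = 3) {
  if (length(models) != length(boundaries_s) - 1L)
    stop("render_bundle: need one model per phase (",
         length(boundaries_s) - 1L, " phases, ", length(models),
         " models)")
  if (any(diff(boundaries_s) <= 0))
    stop("render_bundle: boundaries must be strictly increasing")
  for (m in models) stopifnot(inherits(m, "fourier_series_model"))
  if (blend_ms < 0) stop("render_bundle: blend_ms must be >= 0")
  if (rate <= 0) stop("render_bundle: rate must be > 0")
  structure(list(boundaries_s = as.numeric(boundaries_s), models = models,
                 respiration = respiration, coupling = coupling,
                 resp_force_gain = resp_force_gain, blend_ms = blend_ms,
                 rate = rate, velocity = velocity),
            class = "render_bundle")
}

#' Build a render bundle from a piecewise fit
#'
#' Convenience constructor: takes the trace, its segmentation and the
#' [fit_piecewise()] report and assembles the [render_bundle] with
#' boundary times taken from the trace's time axis.
#'
#' @param trace the fitted [force_trace].
#' @param segmentation the [phase_segmentation] used for the fit.
#' @param report the [fit_report] from [fit_piecewise()] (Fourier models).
#' @param ... further arguments to [render_bundle()].
#' @return a [render_bundle].
#' @export
bundle_from_fit <- function(trace, segmentation, report, ...) {
  stopifnot(inherits(report, "fit_report"))
  if (!report$ok) stop("bundle_from_fit: report contains failed phases")
  b <- segmentation$boundaries
  L <- length(trace$t)
  # boundary b[k] (0-based, half-open) lies between samples b[k]-1 and b[k]
  # interior boundary k sits halfway between the last sample of phase k
  # and the first sample of phase k+1, so grid samples never sit on a node
  times <- c(trace$t[1L],
             trace$t[b[-c(1L, length(b))]] + 1 / trace$fs / 2,
             trace$t[L] + 1 / trace$fs / 2)
  render_bundle(times, report$models, ...)
}

#' Evaluate the rendered force at a time point
#'
#' Evaluates the phase model owning `t`; inside the `blend_ms` window
#' centred on an interior boundary the two adjacent models are linearly
#' cross-faded, which makes the rendered force continuous at the node.
#' Respiration, when configured with a non-zero `resp_force_gain`, adds
#' `-resp_force_gain * coupling * d(t)` (motion away from the needle
#' unloads it).
#'
#' @param bundle a [render_bundle].
#' @param t time in s, scalar or vector, within
#'   `[boundaries_s[1], boundaries_s[end]]`.
#' @return force in N.
#' @export
force_at <- function(bundle, t) {
  stopifnot(inherits(bundle, "render_bundle"))
  t <- as.numeric(t)
  b <- bundle$boundaries_s
  if (any(t < b[1L]) || any(t > b[length(b)]))
    stop("force_at: t outside the rendered range [", b[1L], ", ",
         b[length(b)], "] s")
  K <- length(bundle$models)
  phase <- pmin(pmax(findInterval(t, b, rightmost.closed = TRUE), 1L), K)
  y <- numeric(length(t))
  for (k in unique(phase)) {
    ix <- which(phase == k)
    y[ix] <- evaluate(bundle$models[[k]], t[ix])
  }
  half <- bundle$blend_ms / 1000 / 2
  if (half > 0 && K > 1L) {
    for (k in seq_len(K - 1L)) {          # interior boundary b[k + 1]
      bb <- b[k + 1L]
      ix <- which(t > bb - half & t < bb + half)
      if (length(ix)) {
        w <- (t[ix] - (bb - half)) / (2 * half)
        y[ix] <- (1 - w) * evaluate(bundle$models[[k]], t[ix]) +
          w * evaluate(bundle$models[[k + 1L]], t[ix])
      }
    }
  }
  if (!is.null(bundle$respiration) && bundle$resp_force_gain != 0)
    y <- y - bundle$resp_force_gain * bundle$coupling *
      displacement(bundle$respiration, t)
  y
}

#' Render the bundle as a fixed-rate force stream
#'
#' Samples [force_at()] on the uniform grid at `bundle$rate` over
#' `[t_start, t_end)` — the batch realization of a fixed-rate haptic
#' playback loop — and returns the result as a [force_trace]. The depth
#' channel is reconstructed from the bundle's velocity and respiration
#' settings.
#'
#' @param bundle a [render_bundle].
#' @param t_start,t_end window in s, `t_start < t_end`, within the
#'   rendered range.
#' @return a [force_trace] with `floor((t_end - t_start) * rate)` samples.
#' @export
stream <- function(bundle, t_start, t_end) {
  stopifnot(inherits(bundle, "render_bundle"))
  if (!(t_start < t_end)) stop("stream: need t_start < t_end")
  n <- floor((t_end - t_start) * bundle$rate)
  if (n < 2L) stop("stream: window shorter than 2 samples at rate ",
                   bundle$rate)
  t <- t_start + (seq_len(n) - 1L) / bundle$rate
  f <- force_at(bundle, t)
  d <- if (!is.null(bundle$respiration))
    effective_depth(bundle$velocity, t, bundle$respiration,
                    bundle$coupling)
  else pmax(bundle$velocity * t, 0)
  force_trace(t = t, depth = d, force = f, fs = bundle$rate,
              label = "rendered")
}
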