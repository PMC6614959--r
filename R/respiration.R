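#' Respiratory organ-motion parameters
#'
#' Head-foot (cranio-caudal) organ displacement under quiet breathing,
#' parameterised by the organ's peak-to-peak motion amplitude and the
#' breath cycle. Defaults are the published mid-range cranio-caudal motion
#' amplitudes per organ (mm) with a 5 s breath cycle:
#' kidney_left 7.1 (range 4.5-9.8), heart 5.2 (2.4-7.9), lung 8.6
#' (5.2-12.0), liver 4.5 (3.0-6.0), dorsal_muscles 2.9 (0.3-5.5).
#'
#' @param organ one of `"kidney_left"`, `"heart"`, `"lung"`, `"liver"`,
#'   `"dorsal_muscles"`.
#' @param amplitude_pp peak-to-peak displacement in mm; defaults to the
#'   organ's published mid value.
#' @param period breath cycle in s (default 5; typical range 4-6).
#' @param phase0 initial phase in radians (default 0: displacement starts
#'   at 0, i.e. end-expiration).
#' @return object of class `respiratory_params`.
#' @examples
#' rp <- respiratory_params("kidney_left")
#' rp$amplitude_pp  # 7.1 mm
#' @export
respiratory_params <- function(organ = c("kidney_left", "heart", "lung",
                                         "liver", "dorsal_muscles"),
                               amplitude_pp = NULL, period = 5,
                               phase0 = 0) {
  organ <- match.arg(organ)
  defaults <- c(kidney_left = 7.1, heart = 5.2, lung = 8.6, liver = 4.5,
                dorsal_muscles = 2.9)
  ranges <- list(kidney_left = c(4.5, 9.8), heart = c(2.4, 7.9),
                 lung = c(5.2, 12.0), liver = c(3.0, 6.0),
                 dorsal_muscles = c(0.3, 5.5))
  if (is.null(amplitude_pp)) amplitude_pp <- defaults[[organ]]
  r <- ranges[[organ]]
  if (amplitude_pp < r[1L] || amplitude_pp > r[2L])
    warning("respiratory_params: amplitude ", amplitude_pp,
            " mm outside the published ", organ, " range [",
            r[1L], ", ", r[2L], "] mm")
  if (!is.finite(period) || period <= 0)
    stop("respiratory_params: period must be > 0")
  structure(list(organ = organ, amplitude_pp = amplitude_pp,
                 period = period, phase0 = phase0),
            class = "respiratory_params")
}

#' Respiratory displacement waveform
#'
#' Raised-cosine head-foot displacement:
#' `d(t) = (amplitude_pp / 2) * (1 - cos(2*pi*t/period + phase0))`.
#' Non-negative, smooth, periodic with the breath cycle, and spanning
#' exactly the peak-to-peak amplitude over one cycle.
#'
#' @param params a [respiratory_params].
#' @param t time(s) in seconds, scalar or vector.
#' @return displacement in mm, same length as `t`.
#' @export
displacement <- function(params, t) {
  stopifnot(inherits(params, "respiratory_params"))
  t <- as.numeric(t)
  if (!all(is.finite(t))) stop("displacement: t must be finite")
  params$amplitude_pp / 2 *
    (1 - cos(2 * pi * t / params$period + params$phase0))
}

#' Effective needle-tissue depth under respiration
#'
#' Couples organ motion into the insertion axis: with the needle advancing
#' at constant `velocity`, the tissue moves toward/away from the tip, so
#' the effective penetration is
#' `x_eff(t) = velocity * t - coupling * d(t)`, clamped at >= 0.
#' `coupling = 0` reproduces the static-bench constant-velocity depth;
#' `coupling = 1` is full head-foot projection onto the needle axis.
#'
#' @param velocity insertion speed in mm/s, >= 0.
#' @param t time(s) in seconds.
#' @param params a [respiratory_params].
#' @param coupling dimensionless projection factor in `[0, 1]`.
#' @return effective depth in mm.
#' @export
effective_depth <- function(velocity, t, params, coupling = 1) {
  if (velocity < 0) stop("effective_depth: velocity must be >= 0")
  if (coupling < 0 || coupling > 1)
    stop("effective_depth: coupling must be in [0, 1]")
  d <- if (coupling > 0) displacement(params, t) else 0
  pmax(velocity * as.numeric(t) - coupling * d, 0)
}
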