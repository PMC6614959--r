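#' Tissue layer parameters for the synthetic generator
#'
#' One mechanical layer of the multilayer insertion model. Before rupture
#' the needle loads the layer as a quadratic stiffness ramp
#' `k1 * delta + k2 * delta^2` (delta = penetration into the layer, mm);
#' when the tip has traversed the layer (`delta = thickness`) the layer
#' ruptures: the force drops by `puncture_drop_frac` of its momentary value
#' within one sample, and from then on the layer contributes a friction
#' plateau plus a sinusoidal cutting/friction oscillation.
#'
#' @param name layer tag.
#' @param thickness layer thickness in mm, > 0.
#' @param k1,k2 stiffness coefficients (N/mm, N/mm^2), >= 0.
#' @param puncture_drop_frac fraction of the momentary force lost at
#'   rupture, in `[0, 1]`.
#' @param friction_level post-rupture friction plateau (N), >= 0.
#' @param osc_amp amplitude of the post-rupture oscillation (N), >= 0.
#' @param osc_freq oscillation frequency (Hz), >= 0.
#' @return object of class `tissue_layer`.
#' @export
tissue_layer <- function(name, thickness, k1, k2 = 0,
                         puncture_drop_frac = 0.4, friction_level = 0.2,
                         osc_amp = 0.05, osc_freq = 2) {
  if (thickness <= 0) stop("tissue_layer: thickness must be > 0")
  if (any(c(k1, k2, friction_level, osc_amp, osc_freq) < 0))
    stop("tissue_layer: force parameters must be >= 0")
  if (puncture_drop_frac < 0 || puncture_drop_frac > 1)
    stop("tissue_layer: puncture_drop_frac must be in [0, 1]")
  structure(list(name = name, thickness = thickness, k1 = k1, k2 = k2,
                 puncture_drop_frac = puncture_drop_frac,
                 friction_level = friction_level, osc_amp = osc_amp,
                 osc_freq = osc_freq),
            class = "tissue_layer")
}

#' Synthetic-trace generator configuration
#'
#' Bench-protocol defaults: 1000 Hz force sampling and a constant 3 mm/s
#' insertion velocity (clinically reported insertion speeds span roughly
#' 0.1-10 mm/s). `noise_sigma` defaults to 0.01 N, the precision of the
#' force sensor the bench protocol is modeled on.
#'
#' @param layers ordered list of [tissue_layer]s, proximal to distal.
#' @param fs sampling rate in Hz (default 1000).
#' @param velocity insertion velocity in mm/s (default 3).
#' @param noise_sigma additive Gaussian sensor-noise SD in N (default
#'   0.01).
#' @param seed RNG seed; mandatory when `noise_sigma > 0`.
#' @param respiration optional [respiratory_params].
#' @param coupling respiration-to-depth coupling in `[0, 1]` (default 1
#'   when respiration is given).
#' @param depth0 initial needle depth in mm (default 0), for scenarios
#'   where the needle is already inserted (e.g. breath-hold studies with
#'   `velocity = 0`).
#' @param relax_tau time constant (s) of the post-rupture elastic
#'   relaxation term (default 0.5).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(layers, fs = 1000, velocity = 3,
                             noise_sigma = 0.01, seed = NULL,
                             respiration = NULL, coupling = 1,
                             depth0 = 0, relax_tau = 0.5) {
  if (length(layers) == 0L) stop("generator_config: layers must be non-empty")
  for (ly in layers) stopifnot(inherits(ly, "tissue_layer"))
  if (fs <= 0) stop("generator_config: fs must be > 0")
  if (velocity < 0) stop("generator_config: velocity must be >= 0")
  if (noise_sigma > 0 && is.null(seed))
    stop("generator_config: seed is mandatory when noise_sigma > 0")
  if (!is.null(respiration)) stopifnot(inherits(respiration,
                                                "respiratory_params"))
  structure(list(layers = layers, fs = fs, velocity = velocity,
                 noise_sigma = noise_sigma, seed = seed,
                 respiration = respiration, coupling = coupling,
                 depth0 = depth0, relax_tau = relax_tau),
            class = "generator_config")
}

#' Generate a synthetic multilayer insertion-force trace
#'
#' Realizes the classical stiffness / friction / cutting decomposition of
#' needle-insertion force over an ordered stack of tissue layers, with
#' optional respiratory depth modulation and Gaussian sensor noise:
#' * depth: `depth0 + velocity*t - coupling*d(t)`, clamped at >= 0;
#' * within the first unruptured layer, a quadratic stiffness ramp;
#' * at rupture (tracked on the running maximum depth, so breathing cannot
#'   "un-rupture" a layer), the force drops by exactly
#'   `puncture_drop_frac` of its momentary value within one sample; the
#'   released elastic force relaxes exponentially (`relax_tau`);
#' * every ruptured layer contributes its friction plateau plus a
#'   sinusoidal oscillation phase-referenced to its rupture time;
#' * i.i.d. Gaussian noise (SD `noise_sigma`) is added with the config
#'   seed; identical config and seed give a bit-identical trace.
#'
#' @param config a [generator_config].
#' @param duration trace length in s; `floor(duration * fs)` samples.
#' @return a [force_trace].
#' @examples
#' cfg <- preset("kidney_left")
#' cfg$noise_sigma <- 0
#' tr <- generate_trace(cfg, duration = 2)
#' @export
generate_trace <- function(config, duration) {
  stopifnot(inherits(config, "generator_config"))
  if (duration <= 0) stop("generate_trace: duration must be > 0")
  n <- floor(duration * config$fs)
  if (n < 2L) stop("generate_trace: duration * fs must be >= 2")
  t <- (seq_len(n) - 1L) / config$fs

  resp_d <- if (!is.null(config$respiration) && config$coupling > 0)
    config$coupling * displacement(config$respiration, t) else 0
  depth <- pmax(config$depth0 + config$velocity * t - resp_d, 0)
  dmax <- cummax(depth)

  layers <- config$layers
  L <- length(layers)
  bnd <- cumsum(vapply(layers, function(l) l$thickness, numeric(1)))
  prox <- c(0, bnd[-L])
  # rupture sample of each layer: first crossing of its distal boundary
  rupt <- vapply(seq_len(L), function(l) {
    i <- which(dmax >= bnd[l])
    if (length(i)) i[1L] else NA_integer_
  }, integer(1))

  force <- numeric(n)
  base_at <- function(i, state) {
    # friction + oscillation + relaxation of all ruptured layers at sample i
    tot <- 0
    for (s in state) {
      dt_r <- t[i] - s$t_r
      tot <- tot + s$friction + s$osc_amp * sin(2 * pi * s$osc_freq * dt_r) +
        s$c * exp(-dt_r / config$relax_tau)
    }
    tot
  }
  stiffness_at <- function(i, active) {
    if (active > L) return(0)
    ly <- layers[[active]]
    delta <- min(max(depth[i] - prox[active], 0), ly$thickness)
    ly$k1 * delta + ly$k2 * delta^2
  }

  state <- list()
  events <- sort(rupt[!is.na(rupt)])
  epochs <- cbind(start = c(1L, events),
                  end = c(events - 1L, n))
  active <- 1L
  for (e in seq_len(nrow(epochs))) {
    i0 <- epochs[e, "start"]; i1 <- epochs[e, "end"]
    if (i0 <= i1) {
      idx <- seq.int(i0, i1)
      base <- if (length(state)) vapply(idx, base_at, numeric(1),
                                        state = state) else 0
      stiff <- vapply(idx, stiffness_at, numeric(1), active = active)
      force[idx] <- base + stiff
    }
    if (e < nrow(epochs)) {              # rupture at sample i1 + 1
      r <- i1 + 1L
      ly <- layers[[active]]
      f_pre <- if (r > 1L) force[r - 1L] else stiffness_at(r, active)
      target <- (1 - ly$puncture_drop_frac) * f_pre
      new_s <- list(friction = ly$friction_level, osc_amp = ly$osc_amp,
                    osc_freq = ly$osc_freq, t_r = t[r], c = 0)
      state_try <- c(state, list(new_s))
      active <- active + 1L
      rest <- base_at(r, state_try) + stiffness_at(r, active)
      new_s$c <- target - rest
      state <- c(state, list(new_s))
      force[r] <- base_at(r, state) + stiffness_at(r, active)
    }
  }

  if (config$noise_sigma > 0) {
    force <- force + with_local_seed(config$seed,
                                     stats::rnorm(n, 0, config$noise_sigma))
  }
  force_trace(t = t, depth = depth, force = force, fs = config$fs,
              label = "synthetic")
}

# run expr under a temporary RNG seed, restoring global RNG state after
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Organ presets for the synthetic generator
#'
#' A 4-5 layer skin/fat/muscle/capsule/parenchyma-style stack with the
#' organ's published respiratory-motion defaults attached (full coupling).
#' Layer mechanics are plausibility-tuned so that generated traces show
#' the qualitative anatomy of recorded insertions: quadratic stiffness
#' ramps, abrupt puncture drops of 0.3 N or more (detectable at the
#' segmentation defaults), and oscillatory friction/cutting plateaus.
#'
#' @param name `"kidney_left"`, `"liver"`, `"lung"`, `"heart"` or
#'   `"dorsal_muscles"`.
#' @param noise_sigma,seed forwarded to [generator_config()].
#' @return a [generator_config].
#' @export
preset <- function(name = c("kidney_left", "liver", "lung", "heart",
                            "dorsal_muscles"),
                   noise_sigma = 0.01, seed = 1L) {
  name <- match.arg(name)
  common <- list(
    tissue_layer("skin", thickness = 2, k1 = 0.45, k2 = 0.05,
                 puncture_drop_frac = 0.45, friction_level = 0.30,
                 osc_amp = 0.05, osc_freq = 1.8),
    tissue_layer("fat", thickness = 6, k1 = 0.08, k2 = 0.010,
                 puncture_drop_frac = 0.35, friction_level = 0.18,
                 osc_amp = 0.04, osc_freq = 1.2),
    tissue_layer("muscle", thickness = 8, k1 = 0.12, k2 = 0.012,
                 puncture_drop_frac = 0.40, friction_level = 0.35,
                 osc_amp = 0.08, osc_freq = 2.2))
  organ_layers <- switch(name,
    kidney_left = list(
      tissue_layer("renal_capsule", thickness = 2.5, k1 = 0.35, k2 = 0.05,
                   puncture_drop_frac = 0.55, friction_level = 0.22,
                   osc_amp = 0.06, osc_freq = 2.8),
      tissue_layer("renal_parenchyma", thickness = 40, k1 = 0.08,
                   k2 = 0.004, puncture_drop_frac = 0.30,
                   friction_level = 0.25, osc_amp = 0.07, osc_freq = 1.5)),
    liver = list(
      tissue_layer("liver_capsule", thickness = 1.5, k1 = 0.45, k2 = 0.06,
                   puncture_drop_frac = 0.50, friction_level = 0.20,
                   osc_amp = 0.05, osc_freq = 2.5),
      tissue_layer("liver_parenchyma", thickness = 40, k1 = 0.05,
                   k2 = 0.003, puncture_drop_frac = 0.30,
                   friction_level = 0.22, osc_amp = 0.06, osc_freq = 1.3)),
    lung = list(
      tissue_layer("pleura", thickness = 1.5, k1 = 0.40, k2 = 0.05,
                   puncture_drop_frac = 0.60, friction_level = 0.15,
                   osc_amp = 0.05, osc_freq = 2.6),
      tissue_layer("lung_parenchyma", thickness = 40, k1 = 0.03,
                   k2 = 0.002, puncture_drop_frac = 0.30,
                   friction_level = 0.12, osc_amp = 0.05, osc_freq = 1.0)),
    heart = list(
      tissue_layer("pericardium", thickness = 2, k1 = 0.50, k2 = 0.06,
                   puncture_drop_frac = 0.55, friction_level = 0.25,
                   osc_amp = 0.08, osc_freq = 3.0),
      tissue_layer("myocardium", thickness = 40, k1 = 0.15, k2 = 0.008,
                   puncture_drop_frac = 0.30, friction_level = 0.30,
                   osc_amp = 0.10, osc_freq = 1.8)),
    dorsal_muscles = list(
      tissue_layer("fascia", thickness = 1.5, k1 = 0.40, k2 = 0.05,
                   puncture_drop_frac = 0.50, friction_level = 0.25,
                   osc_amp = 0.06, osc_freq = 2.4),
      tissue_layer("deep_muscle", thickness = 40, k1 = 0.14, k2 = 0.010,
                   puncture_drop_frac = 0.30, friction_level = 0.35,
                   osc_amp = 0.09, osc_freq = 2.0)))
  generator_config(layers = c(common, organ_layers),
                   fs = 1000, velocity = 3,
                   noise_sigma = noise_sigma, seed = seed,
                   respiration = respiratory_params(name), coupling = 1)
}
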