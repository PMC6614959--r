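# Shared fixture builders. Everything is generated in code; no stored data.

# uniform time grid of n samples at rate fs
time_grid <- function(n, fs = 1000) (seq_len(n) - 1L) / fs

# trace sampled from an explicit function of time
fn_trace <- function(f, duration = 1, fs = 1000, velocity = 3,
                     label = "fn") {
  t <- time_grid(floor(duration * fs), fs)
  force_trace(t, velocity * t, f(t), fs = fs, label = label)
}

# random Fourier-series model with seeded coefficients
random_model <- function(order, omega, seed, a0 = NULL, scale = 1,
                         domain = c(0, 2 * pi / omega)) {
  set.seed(seed)
  fourier_series_model(
    a0 = if (is.null(a0)) stats::rnorm(1) else a0,
    alphas = stats::rnorm(order, sd = scale),
    betas = stats::rnorm(order, sd = scale),
    omega = omega, domain_start = domain[1L], domain_end = domain[2L])
}

# term-by-term brute-force evaluation, independent of evaluate()
brute_force_eval <- function(model, x) {
  vapply(x, function(xi) {
    y <- model$a0
    for (n in seq_len(model$order))
      y <- y + model$alphas[n] * cos(n * model$omega * xi) +
        model$betas[n] * sin(n * model$omega * xi)
    y
  }, numeric(1))
}

# trace drawn from a model over its domain (noiseless unless sigma > 0)
model_trace <- function(model, n = 1000, sigma = 0, seed = 1) {
  span <- model$domain_end - model$domain_start
  fs <- (n - 1) / span
  t <- model$domain_start + (seq_len(n) - 1L) * span / (n - 1)
  y <- brute_force_eval(model, t)
  if (sigma > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(n, 0, sigma)
  }
  force_trace(t, 3 * t, y, fs = fs, label = "model")
}

# ramp-plus-drops trace: linear load with step drops at given times
drops_trace <- function(drop_times, drop_size = 0.8, drop_width_ms = 10,
                        duration = 10, fs = 1000, slope = 0.25,
                        noise = 0, seed = 1) {
  t <- time_grid(floor(duration * fs), fs)
  y <- 1 + slope * t
  for (td in drop_times) {
    w <- drop_width_ms / 1000
    frac <- pmin(pmax((t - td) / w, 0), 1)   # ramp down across the width
    y <- y - drop_size * frac
  }
  if (noise > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(t), 0, noise)
  }
  force_trace(t, 3 * t, y, fs = fs, label = "drops")
}

# oscillatory multi-phase trace: per-phase Fourier content + puncture drops,
# the comparison fixture on which a trigonometric model should dominate
oscillatory_trace <- function(n_phases = 5, phase_s = 2, fs = 500,
                              seed = 11, noise = 0) {
  set.seed(seed)
  n <- floor(n_phases * phase_s * fs)
  t <- time_grid(n, fs)
  y <- numeric(n)
  level <- 1
  for (k in seq_len(n_phases)) {
    ix <- which(t >= (k - 1) * phase_s & t < k * phase_s)
    w <- 2 * pi / phase_s
    amp <- stats::runif(3, 0.1, 0.5)
    y[ix] <- level + 0.15 * (t[ix] - (k - 1) * phase_s) +
      amp[1] * sin(w * t[ix]) + amp[2] * cos(2 * w * t[ix]) +
      amp[3] * sin(3 * w * t[ix])
    level <- level + stats::runif(1, 0.2, 0.5) *
      (if (k %% 2 == 0) 1 else -1)
  }
  if (noise > 0) y <- y + stats::rnorm(n, 0, noise)
  force_trace(t, 3 * t, y, fs = fs, label = "oscillatory")
}
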