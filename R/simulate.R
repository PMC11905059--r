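#' Coupling specification for the synthetic generator
#'
#' Describes one injected cross-frequency dependence between two canonical
#' bands. For `kind = "PAC"` the high-band carrier's envelope follows the
#' low-band phase, envelope(t) = A (1 + m cos(phi_low(t) - preferred_phase))
#' / (1 + m), with modulation depth m = `base_strength` x circular
#' orientation tuning x stimulus gain. For `kind = "AAC"` the two carriers
#' ride on log-normal slow envelopes sharing a common component mixed as
#' rho * shared + sqrt(1 - rho^2) * private in the log domain, with
#' rho = `base_strength` x tuning x gain.
#'
#' @param kind "PAC" or "AAC".
#' @param low_band,high_band canonical band labels; the low band's frequency
#'   range must lie below the high band's.
#' @param base_strength coupling strength in \[0, 1\] at the preferred
#'   orientation (modulation depth for PAC, target envelope correlation for
#'   AAC).
#' @param preferred_orientation degrees, or `NULL` for flat (untuned)
#'   coupling.
#' @param tuning_width circular-Gaussian tuning width in degrees (`Inf` =
#'   flat tuning).
#' @param stimulus_gain named numeric vector of multiplicative gains per
#'   stimulus type (e.g. `c(LG = 1, CG = 0.5)`).
#' @param preferred_phase PAC only: low-band phase (radians) at which the
#'   high-band envelope peaks.
#' @param low_amp,high_amp amplitudes of the injected band components, in
#'   units of the background 1/f source SD.
#' @param env_sigma AAC only: log-SD of the slow log-normal envelopes.
#' @param env_bandwidth AAC only: bandwidth (Hz) of the slow envelopes.
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(kind, low_band, high_band, base_strength,
                          preferred_orientation = NULL, tuning_width = Inf,
                          stimulus_gain = c(LG = 1, CG = 1),
                          preferred_phase = 0,
                          low_amp = 1.5, high_amp = 1,
                          env_sigma = 0.25, env_bandwidth = 4) {
  kind <- match.arg(kind, c("PAC", "AAC"))
  bands <- canonical_bands()
  lo <- band_row(low_band, bands)
  hi <- band_row(high_band, bands)
  if (lo$center >= hi$center)
    stop("low_band center frequency must be below high_band center", call. = FALSE)
  if (base_strength < 0 || base_strength * max(stimulus_gain) > 1)
    stop("coupling strength times maximum stimulus gain must lie in [0, 1]",
         call. = FALSE)
  structure(list(kind = kind, low_band = low_band, high_band = high_band,
                 base_strength = base_strength,
                 preferred_orientation = preferred_orientation,
                 tuning_width = tuning_width, stimulus_gain = stimulus_gain,
                 preferred_phase = preferred_phase,
                 low_amp = low_amp, high_amp = high_amp,
                 env_sigma = env_sigma, env_bandwidth = env_bandwidth),
            class = "coupling_spec")
}

#' Simulation configuration for a synthetic LFP session
#'
#' Defaults emulate the recording geometry and task structure the pipeline
#' expects: 32 channels on 4 shanks at 1.25 kHz, 3-s trials (0.5 s
#' prestimulus gray, 2 s drifting grating, 0.5 s poststimulus gray), 8
#' orientations at 45 degree steps times 2 stimulus types (LG, CG) times 30
#' trials per condition in pseudorandom order, with a 1-s gray screen between
#' stimuli. Background is 1/f-shaped noise per shank plus independent white
#' noise per channel.
#'
#' @param sampling_rate Hz.
#' @param n_channels,n_shanks probe geometry; `n_channels` must be divisible
#'   by `n_shanks`.
#' @param n_trials_per_condition trials per orientation x stimulus cell.
#' @param orientations distinct degrees in \[0, 360).
#' @param stimulus_types character labels.
#' @param pre_s,stim_s,post_s trial layout in seconds (all > 0).
#' @param gap_s gray-screen gap between stimulus offset and next onset, s.
#' @param background_exponent 1/f spectral slope of the shank background.
#' @param noise_sd per-channel white-noise SD, in units of the unit-SD shank
#'   background.
#' @param coupling_specs list of [coupling_spec()] objects.
#' @param seed integer RNG seed; the same seed and config reproduce the
#'   session exactly.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate = 1250, n_channels = 32,
                              n_shanks = 4, n_trials_per_condition = 30,
                              orientations = seq(0, 315, by = 45),
                              stimulus_types = c("LG", "CG"),
                              pre_s = 0.5, stim_s = 2, post_s = 0.5,
                              gap_s = 1,
                              background_exponent = 1, noise_sd = 0.5,
                              coupling_specs = list(), seed = 1L) {
  if (n_channels %% n_shanks != 0)
    stop("n_channels must be divisible by n_shanks", call. = FALSE)
  if (any(c(pre_s, stim_s, post_s) <= 0))
    stop("trial durations must be strictly positive", call. = FALSE)
  if (anyDuplicated(orientations) || any(orientations < 0 | orientations >= 360))
    stop("orientations must be distinct and in [0, 360)", call. = FALSE)
  for (sp in coupling_specs) {
    if (!inherits(sp, "coupling_spec"))
      stop("coupling_specs must be a list of coupling_spec objects", call. = FALSE)
    if (length(sp$stimulus_gain) &&
        !any(names(sp$stimulus_gain) %in% stimulus_types))
      stop("stimulus_gain names match none of the stimulus_types", call. = FALSE)
  }
  structure(list(sampling_rate = sampling_rate, n_channels = n_channels,
                 n_shanks = n_shanks,
                 n_trials_per_condition = n_trials_per_condition,
                 orientations = orientations, stimulus_types = stimulus_types,
                 pre_s = pre_s, stim_s = stim_s, post_s = post_s, gap_s = gap_s,
                 background_exponent = background_exponent, noise_sd = noise_sd,
                 coupling_specs = coupling_specs, seed = as.integer(seed)),
            class = "simulation_config")
}

# circular-Gaussian orientation tuning, 1 at the preferred orientation
orientation_tuning <- function(theta, preferred, width) {
  if (is.null(preferred) || !is.finite(width)) return(rep(1, length(theta)))
  d <- (theta - preferred) %% 360
  d <- pmin(d, 360 - d)
  exp(-d^2 / (2 * width^2))
}

# 1/f^alpha noise by direct spectral synthesis (random-phase Gaussian
# coefficients with amplitude f^(-alpha/2), one inverse FFT), unit SD
noise_1f <- function(n, exponent, sampling_rate) {
  if (exponent == 0) return(stats::rnorm(n))
  m <- stats::nextn(n, 2)
  half <- m %/% 2
  f <- seq_len(half - 1) / m * sampling_rate
  amp <- f^(-exponent / 2)
  pos <- complex(real = amp * stats::rnorm(half - 1),
                 imaginary = amp * stats::rnorm(half - 1))
  nyq <- complex(real = (sampling_rate / 2)^(-exponent / 2) * stats::rnorm(1))
  X <- c(0 + 0i, pos, nyq, Conj(rev(pos)))   # Hermitian: real inverse
  x <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

# unit-variance slow random process: random-phase Fourier synthesis on [0, T)
slow_process <- function(n, sampling_rate, bandwidth) {
  T <- n / sampling_rate
  K <- max(2L, round(bandwidth * T))
  t <- seq_len(n) / sampling_rate
  z <- numeric(n)
  for (k in seq_len(K))
    z <- z + cos(2 * pi * k * t / T + stats::runif(1, 0, 2 * pi))
  z * sqrt(2 / K)
}

# narrowband random oscillation: a handful of random in-band tones with
# random phases; its instantaneous phase wanders within a trial, so trials
# decohere from one another (as real band-limited rhythms do)
narrowband_process <- function(n, sampling_rate, f_min, f_max) {
  T <- n / sampling_rate
  K <- max(3L, round((f_max - f_min) * T))
  f <- stats::runif(K, f_min, f_max)
  th <- stats::runif(K, 0, 2 * pi)
  t <- seq_len(n) / sampling_rate
  z <- numeric(n)
  for (k in seq_len(K)) z <- z + cos(2 * pi * f[k] * t + th[k])
  z / stats::sd(z)
}

#' Generate a synthetic LFP session
#'
#' Builds a continuous multi-channel signal covering all trials in
#' pseudorandom condition order with gray-screen gaps, plus a stimulus event
#' table, per the configured [simulation_config()]. Injected couplings (see
#' [coupling_spec()]) are added to every shank source during each stimulus
#' window with orientation- and stimulus-dependent strength; channels within
#' a shank share the source and receive independent white noise.
#'
#' @param config a [simulation_config()].
#' @param keep_truth if `TRUE`, attach per-trial ground-truth injection
#'   parameters (and, for AAC, the generated envelopes) as attribute
#'   `"truth"`.
#' @return a `session_bundle` (see [read_bundle()] for the structure).
#' @export
generate_session <- function(config, keep_truth = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  stim_n <- round(config$stim_s * fs)
  step_n <- round((config$stim_s + config$gap_s) * fs)
  lead_n <- round(max(1, config$pre_s + 0.5) * fs)
  grid <- expand.grid(orientation_deg = config$orientations,
                      stimulus_type = config$stimulus_types,
                      stringsAsFactors = FALSE)
  cond <- rep(seq_len(nrow(grid)), each = config$n_trials_per_condition)
  cond <- sample(cond)                      # pseudorandom condition order
  n_trials <- length(cond)
  onsets <- lead_n + (seq_len(n_trials) - 1L) * step_n   # 0-based samples
  total_n <- lead_n + n_trials * step_n +
    round(max(1, config$post_s + 0.5) * fs)

  events <- data.frame(onset_sample = as.integer(onsets),
                       orientation_deg = as.integer(grid$orientation_deg[cond]),
                       stimulus_type = grid$stimulus_type[cond],
                       stringsAsFactors = FALSE)

  bands <- canonical_bands()
  tt <- seq_len(stim_n) / fs
  inject <- numeric(total_n)               # shared across shanks
  truth <- if (keep_truth) vector("list", length(config$coupling_specs)) else NULL

  for (si in seq_along(config$coupling_specs)) {
    sp <- config$coupling_specs[[si]]
    lo_band <- band_row(sp$low_band, bands)
    hi_band <- band_row(sp$high_band, bands)
    bw_lo <- lo_band$high - lo_band$low
    bw_hi <- hi_band$high - hi_band$low
    tune <- orientation_tuning(events$orientation_deg,
                               sp$preferred_orientation, sp$tuning_width)
    gain <- sp$stimulus_gain[events$stimulus_type]
    gain[is.na(gain)] <- 1
    strength <- sp$base_strength * tune * as.numeric(gain)
    tr_truth <- if (keep_truth) vector("list", n_trials) else NULL
    for (tr in seq_len(n_trials)) {
      idx <- (onsets[tr] + 1L):(onsets[tr] + stim_n)
      # the high carrier's frequency drifts across trials; the low-band
      # component is a narrowband random process whose phase wanders within
      # the trial, so trial-shuffle surrogates form a valid coupling null
      f_lo <- stats::runif(1, lo_band$low + 0.1 * bw_lo,
                           lo_band$high - 0.1 * bw_lo)
      f_hi <- stats::runif(1, hi_band$center - 0.15 * bw_hi,
                           hi_band$center + 0.15 * bw_hi)
      if (sp$kind == "PAC") {
        z_lo <- narrowband_process(stim_n, fs, lo_band$low + 0.1 * bw_lo,
                                   lo_band$high - 0.1 * bw_lo)
        phi <- Arg(analytic_core(z_lo))
        psi0 <- stats::runif(1, 0, 2 * pi)
        m <- strength[tr]
        env <- (1 + m * cos(phi - sp$preferred_phase)) / (1 + m)
        comp <- sp$low_amp * z_lo +
          sp$high_amp * env * cos(2 * pi * f_hi * tt + psi0)
        if (keep_truth) tr_truth[[tr]] <- list(m = m, phase = phi)
      } else {
        z_sh <- slow_process(stim_n, fs, sp$env_bandwidth)
        z_lo <- slow_process(stim_n, fs, sp$env_bandwidth)
        z_hi <- slow_process(stim_n, fs, sp$env_bandwidth)
        rho <- strength[tr]
        # each log-envelope takes a shared-variance fraction rho, so the
        # two envelopes correlate at rho (the target coupling strength)
        a <- sqrt(rho)
        b <- sqrt(1 - rho)
        e_lo <- exp(sp$env_sigma * (a * z_sh + b * z_lo))
        e_hi <- exp(sp$env_sigma * (a * z_sh + b * z_hi))
        phi0 <- stats::runif(1, 0, 2 * pi)
        psi0 <- stats::runif(1, 0, 2 * pi)
        comp <- sp$low_amp * e_lo * cos(2 * pi * f_lo * tt + phi0) +
          sp$high_amp * e_hi * cos(2 * pi * f_hi * tt + psi0)
        if (keep_truth) tr_truth[[tr]] <- list(rho = rho, env_low = e_lo,
                                               env_high = e_hi)
      }
      inject[idx] <- inject[idx] + comp
    }
    if (keep_truth) truth[[si]] <- tr_truth
  }

  per_shank <- config$n_channels / config$n_shanks
  signal <- matrix(0, config$n_channels, total_n)
  shank_map <- rep(seq_len(config$n_shanks), each = per_shank)
  for (s in seq_len(config$n_shanks)) {
    src <- noise_1f(total_n, config$background_exponent, fs) + inject
    for (ch in which(shank_map == s))
      signal[ch, ] <- src + stats::rnorm(total_n, sd = config$noise_sd)
  }

  bundle <- structure(list(signal = signal, sampling_rate = fs,
                           shank_map = shank_map, area = "synthetic",
                           subject = sprintf("sim%03d", config$seed),
                           events = events),
                      class = "session_bundle")
  if (keep_truth) attr(bundle, "truth") <- truth
  bundle
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf(paste0("<session_bundle: %d channels x %d samples @ %g Hz, ",
                     "%d shanks, %d events, subject %s, area %s>\n"),
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              length(unique(x$shank_map)), nrow(x$events), x$subject, x$area))
  invisible(x)
}
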