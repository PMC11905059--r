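#' Phase--amplitude coupling (PAC)
#'
#' PAC between a low-band phase series and a high-band amplitude series:
#' the modulus of the power-weighted mean phasor,
#' PAC = |sum_n p_y(n) e^{i phi_x(n)}| / sum_n p_y(n), with p_y the squared
#' high-band amplitude. Bounded in \[0, 1\]: 0 when high-band power is
#' distributed uniformly over low-band phase, 1 when all power falls at a
#' single phase.
#'
#' @param phase_sig low-band [analytic_signal()], or a numeric vector of
#'   instantaneous phases in radians.
#' @param amp_sig high-band [analytic_signal()], or a numeric vector of
#'   instantaneous amplitudes (>= 0).
#' @return PAC value in \[0, 1\]; `NA_real_` when total high-band power is
#'   zero (undefined).
#' @export
compute_pac <- function(phase_sig, amp_sig) {
  phi <- as_phase(phase_sig)
  amp <- as_amplitude(amp_sig)
  if (length(phi) != length(amp))
    stop("phase and amplitude series must have equal length", call. = FALSE)
  p <- amp^2
  tot <- sum(p)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  Mod(sum(p * exp(1i * phi))) / tot
}

#' Amplitude--amplitude coupling (AAC)
#'
#' Pearson correlation between two amplitude envelopes:
#' AAC = cov(A_x, A_y) / (sd(A_x) sd(A_y)), in \[-1, 1\]. Positive values
#' indicate the envelopes co-vary linearly, negative values an inverse linear
#' relation, zero no linear coupling.
#'
#' @param amp_x,amp_y [analytic_signal()] objects or numeric amplitude
#'   vectors of equal length (>= 3).
#' @return correlation in \[-1, 1\]; `NA_real_` when either envelope has zero
#'   variance (undefined).
#' @export
compute_aac <- function(amp_x, amp_y) {
  ax <- as_amplitude(amp_x)
  ay <- as_amplitude(amp_y)
  if (length(ax) != length(ay))
    stop("amplitude series must have equal length", call. = FALSE)
  if (length(ax) < 3)
    stop("need at least 3 samples for a correlation", call. = FALSE)
  if (stats::sd(ax) == 0 || stats::sd(ay) == 0) return(NA_real_)
  stats::cor(ax, ay)
}

#' Per-trial coupling table over all band pairs
#'
#' For every trial and octrode in a [preprocess_session()] trial tensor,
#' computes PAC (lower band's phase against higher band's squared amplitude)
#' and AAC (amplitude correlation) for each of the 21 band pairs over the
#' stimulus window. Amplitude and phase come from the per-trial analytic
#' signal of the already filtered, z-scored stimulus segment.
#'
#' Degenerate trials (e.g. an all-zero band) yield `NA` coupling values;
#' such rows are retained with explicit missingness and excluded pairwise
#' downstream.
#'
#' @param trials a `trial_tensor` from [preprocess_session()].
#' @return a data frame of class `coupling_table` with columns `trial_id`,
#'   `orientation_deg`, `stimulus_type`, `octrode`, `low_band`, `high_band`,
#'   `kind` (PAC/AAC) and `value`; 42 rows per (trial, octrode) with the
#'   canonical seven bands.
#' @export
coupling_table <- function(trials) {
  stopifnot(inherits(trials, "trial_tensor"))
  v <- trials$values                      # trial x band x octrode x time
  dm <- dim(v)
  n_trial <- dm[1]; n_band <- dm[2]; n_oct <- dm[3]; n_time <- dm[4]
  labels <- trials$bands$label
  pairs <- band_pairs(trials$bands)
  n_pair <- nrow(pairs)
  li <- match(pairs$low_band, labels)
  hi <- match(pairs$high_band, labels)

  n_block <- 2L * n_pair                  # 42 rows per (trial, octrode)
  values <- numeric(n_trial * n_oct * n_block)
  vt <- aperm(v, c(4, 2, 1, 3))           # time-contiguous slices
  k <- 0L
  for (tr in seq_len(n_trial)) {
    for (oc in seq_len(n_oct)) {
      A <- matrix(0, n_time, n_band)      # amplitude
      C <- matrix(0, n_time, n_band)      # cos(phase)
      S <- matrix(0, n_time, n_band)      # sin(phase)
      for (b in seq_len(n_band)) {
        xb <- vt[, b, tr, oc]
        if (all(xb == 0)) next            # leaves A = 0 -> NA couplings
        z <- analytic_core(xb)
        a <- Mod(z)
        A[, b] <- a
        nz <- a > 0
        C[nz, b] <- Re(z)[nz] / a[nz]
        S[nz, b] <- Im(z)[nz] / a[nz]
      }
      P <- A^2
      tot <- colSums(P)
      num <- sqrt(crossprod(C, P)^2 + crossprod(S, P)^2)  # [phase band, power band]
      pac <- num[cbind(li, hi)] / tot[hi]
      pac[tot[hi] <= 0 | tot[li] <= 0] <- NA_real_
      sds <- apply(A, 2, stats::sd)
      CC <- suppressWarnings(stats::cor(A))
      aac <- CC[cbind(li, hi)]
      aac[sds[li] == 0 | sds[hi] == 0] <- NA_real_
      values[k + seq_len(n_block)] <- c(pac, aac)
      k <- k + n_block
    }
  }
  to <- rep(seq_len(n_trial), each = n_oct * n_block)   # trial per row
  oo <- rep(rep(seq_len(n_oct), each = n_block), n_trial)
  out <- data.frame(
    trial_id = trials$trial_id[to],
    orientation_deg = trials$orientation[to],
    stimulus_type = trials$stimulus[to],
    octrode = oo,
    low_band = rep(rep(pairs$low_band, 2L), n_trial * n_oct),
    high_band = rep(rep(pairs$high_band, 2L), n_trial * n_oct),
    kind = rep(rep(c("PAC", "AAC"), each = n_pair), n_trial * n_oct),
    value = values,
    stringsAsFactors = FALSE
  )
  class(out) <- c("coupling_table", "data.frame")
  attr(out, "bands") <- trials$bands
  attr(out, "n_missing") <- sum(is.na(out$value))
  out
}
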