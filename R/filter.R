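#' Butterworth band-pass design in second-order sections
#'
#' Designs a digital Butterworth band-pass filter by the standard route:
#' analog low-pass prototype poles, low-pass-to-band-pass transform with
#' pre-warped edge frequencies, bilinear transform, and pairing of conjugate
#' poles into second-order sections (biquads). The -3 dB points fall at the
#' requested edges. SOS form keeps the 0.1--4 Hz band numerically stable at
#' kHz sampling rates, where the expanded transfer-function polynomial is not.
#'
#' @param order prototype filter order per direction (the pipeline uses 3).
#' @param low,high band edges in Hz.
#' @param sampling_rate sampling rate in Hz.
#' @return numeric matrix with one row per section, columns
#'   `b0, b1, b2, a0, a1, a2` (`a0` normalized to 1).
#' @export
butter_bandpass_sos <- function(order, low, high, sampling_rate) {
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low)
    stop("invalid band edges", call. = FALSE)
  if (high >= sampling_rate / 2)
    stop("band high edge at or above Nyquist frequency", call. = FALSE)
  # Butterworth prototype: poles on the unit circle in the left half plane
  p <- -exp(1i * pi * seq(-order + 1, order - 1, by = 2) / (2 * order))
  fs2 <- 2 * sampling_rate
  w1 <- fs2 * tan(pi * low / sampling_rate)
  w2 <- fs2 * tan(pi * high / sampling_rate)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # low-pass -> band-pass: each prototype pole maps to the two roots of
  # s^2 - p*bw*s + w0^2
  pb <- complex(0)
  for (pp in p) {
    half <- pp * bw / 2
    disc <- sqrt(half^2 - w0^2)
    pb <- c(pb, half + disc, half - disc)
  }
  # bilinear transform; band-pass gain k = bw^order, zeros: `order` at s=0
  # (-> z=1) and `order` at infinity (-> z=-1)
  kd <- Re(bw^order * fs2^order / prod(fs2 - pb))
  zd <- (fs2 + pb) / (fs2 - pb)
  tol <- 1e-8
  is_real <- abs(Im(zd)) < tol * pmax(abs(zd), 1)
  p_real <- sort(Re(zd[is_real]))
  p_cplx <- zd[!is_real & Im(zd) > 0]
  p_cplx <- p_cplx[order(Mod(p_cplx))]
  secs <- lapply(p_cplx, function(pc) c(pc, Conj(pc)))
  if (length(p_real) %% 2L != 0L)
    stop("internal error: unpaired real pole in SOS pairing")
  if (length(p_real))
    for (i in seq(1L, length(p_real), by = 2L))
      secs <- c(secs, list(complex(real = p_real[i:(i + 1L)])))
  # each section carries one zero at z=1 and one at z=-1: numerator z^2 - 1
  sos <- t(vapply(seq_along(secs), function(i) {
    pr <- secs[[i]]
    g <- if (i == length(secs)) kd else 1
    c(g, 0, -g, 1, -Re(pr[1] + pr[2]), Re(pr[1] * pr[2]))
  }, numeric(6)))
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

#' Frequency response of a second-order-section filter
#'
#' Evaluates H(e^{i 2 pi f / fs}) exactly from the section coefficients.
#'
#' @param sos SOS matrix from [butter_bandpass_sos()].
#' @param f frequencies in Hz at which to evaluate.
#' @param sampling_rate sampling rate in Hz.
#' @return complex vector of responses; `Mod()` gives the magnitude.
#' @export
sos_response <- function(sos, f, sampling_rate) {
  zi <- exp(-1i * 2 * pi * f / sampling_rate)
  H <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos)))
    H <- H * (sos[i, 1] + sos[i, 2] * zi + sos[i, 3] * zi^2) /
             (sos[i, 4] + sos[i, 5] * zi + sos[i, 6] * zi^2)
  H
}

# reflection-padding length: at least 3x the slowest pole's time constant,
# never more than the signal allows
filtfilt_padlen <- function(sos, n) {
  rmax <- sqrt(max(sos[, 6]))
  tc <- if (rmax < 1) ceiling(-3 / log(rmax)) else n
  min(n - 1L, max(9L * nrow(sos), tc))
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies the 3rd-order Butterworth band-pass of [butter_bandpass_sos()]
#' forward and backward (filtfilt), giving zero net phase shift and squaring
#' the magnitude response. Edges are handled by odd reflection padding of at
#' least three times the filter's impulse-response time constant.
#'
#' @param x numeric vector, or a channels x samples matrix (each row filtered
#'   independently).
#' @param band single-row band definition (columns `low`, `high`), a band
#'   label from [canonical_bands()], or a numeric length-2 vector of edges Hz.
#' @param sampling_rate sampling rate in Hz.
#' @param order Butterworth order per direction (default 3).
#' @return filtered signal, same shape as `x`.
#' @export
bandpass_filter <- function(x, band, sampling_rate, order = 3) {
  if (is.character(band)) band <- band_row(band)
  if (is.numeric(band) && length(band) == 2) band <- list(low = band[1], high = band[2])
  if (!all(is.finite(if (is.matrix(x)) x else as.numeric(x))))
    stop("non-finite samples in input signal", call. = FALSE)
  sos <- butter_bandpass_sos(order, band$low, band$high, sampling_rate)
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (n <= 6 * order)
    stop("signal too short to filter at this order", call. = FALSE)
  padlen <- filtfilt_padlen(sos, n)
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- sosfiltfilt_cpp(x[i, ], sos, padlen)
    out
  } else {
    sosfiltfilt_cpp(as.numeric(x), sos, padlen)
  }
}
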