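#' Analytic signal via the discrete Hilbert transform
#'
#' Computes the analytic signal z(n) = x(n) + i*xh(n), where xh is the
#' discrete Hilbert transform of x under periodic boundary treatment,
#' obtained by zeroing the negative-frequency half of the spectrum (the
#' frequency-domain equivalent of the odd/even parity convolution sums with
#' the 2/(pi*(k-n)) kernel wrapped onto the circle). The instantaneous
#' amplitude is Mod(z) = sqrt(x^2 + xh^2) and the instantaneous phase is the
#' four-quadrant angle Arg(z) in (-pi, pi].
#'
#' @param x finite numeric vector, length >= 4.
#' @return an object of class `analytic_signal`: a list with elements `x`,
#'   `x_hilbert`, `amplitude`, `phase`.
#' @examples
#' n <- 0:255
#' a <- analytic_signal(cos(2 * pi * 8 * n / 256))
#' range(a$amplitude)  # ~1
#' @export
analytic_signal <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("signal too short (need length >= 4)", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite samples in input signal", call. = FALSE)
  z <- analytic_core(x)
  structure(list(x = x,
                 x_hilbert = Im(z),
                 amplitude = Mod(z),
                 phase = Arg(z)),
            class = "analytic_signal")
}

#' @export
print.analytic_signal <- function(x, ...) {
  cat(sprintf("<analytic_signal: %d samples, amplitude range [%.3g, %.3g]>\n",
              length(x$x), min(x$amplitude), max(x$amplitude)))
  invisible(x)
}

# accept an analytic_signal or a bare numeric vector
as_phase <- function(x) if (inherits(x, "analytic_signal")) x$phase else as.numeric(x)
as_amplitude <- function(x) if (inherits(x, "analytic_signal")) x$amplitude else as.numeric(x)

# complex analytic signal only (no amplitude/phase derivation); core of
# analytic_signal, shared by the per-trial coupling loop
analytic_core <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- 1
  if (n %% 2 == 0) {
    w[n / 2 + 1] <- 1
    if (n > 2) w[2:(n / 2)] <- 2
  } else {
    w[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * w, inverse = TRUE) / n
}
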