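# Independent brute-force oracles, kept deliberately separate from the
# package implementations they check.

# O(N^2) discrete Hilbert transform for even N: parity-structured circular
# kernel. The infinite odd-lag kernel 2/(pi*m) summed over the periodic
# extension equals (2/N) cot(pi*m/N) at odd lags (and 0 at even lags), so
# this is the periodic-boundary evaluation of the parity convolution sums.
hilbert_oracle <- function(x) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  m <- seq_len(n - 1)
  h <- numeric(n)
  h[m + 1] <- ifelse(m %% 2 == 1, (2 / n) / tan(pi * m / n), 0)
  K <- matrix(0, n, n)
  for (k in seq_len(n))
    K[k, ] <- h[((k - seq_len(n)) %% n) + 1]
  as.numeric(K %*% x)
}

# direct summation of the PAC statistic, scalar accumulation
pac_oracle <- function(phase, amp) {
  num <- 0 + 0i
  den <- 0
  for (i in seq_along(phase)) {
    p <- amp[i]^2
    num <- num + p * exp(1i * phase[i])
    den <- den + p
  }
  Mod(num) / den
}

# Pearson correlation from first principles
aac_oracle <- function(a, b) {
  n <- length(a)
  ca <- a - mean(a); cb <- b - mean(b)
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}

# all-pairs PAC matrix for one band pair across trials: entry [i, j] pairs
# the phase series of trial i with the amplitude series of trial j, so the
# diagonal holds the observed per-trial PAC and off-diagonal entries are
# trial-shuffle surrogates
pac_cross_trials <- function(phase_mat, amp_mat) {
  P <- amp_mat^2                       # time x trial
  C <- cos(phase_mat)
  S <- sin(phase_mat)
  num <- sqrt(crossprod(C, P)^2 + crossprod(S, P)^2)
  sweep(num, 2, colSums(P), "/")
}

# small-session factory: defaults keep unit tests fast
quick_config <- function(..., n_channels = 4, n_shanks = 1,
                         n_trials_per_condition = 3, seed = 1) {
  simulation_config(n_channels = n_channels, n_shanks = n_shanks,
                    n_trials_per_condition = n_trials_per_condition,
                    seed = seed, ...)
}

# shared mid-sized fixture with an injected theta->H PAC, built lazily once
theta_h_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        n_channels = 4, n_shanks = 1, n_trials_per_condition = 6,
        coupling_specs = list(coupling_spec(
          "PAC", "theta", "H", 0.6, preferred_orientation = 90,
          tuning_width = 45, stimulus_gain = c(LG = 1, CG = 0.5))),
        seed = 404)
      b <- generate_session(cfg)
      tt <- preprocess_session(b)
      cache <<- list(config = cfg, bundle = b, trials = tt,
                     table = coupling_table(tt))
    }
    cache
  }
})
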