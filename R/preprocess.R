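#' Trial window layout
#'
#' @param pre_s,stim_s,post_s window durations in seconds (prestimulus,
#'   stimulus, poststimulus); all strictly positive.
#' @return an object of class `trial_layout`.
#' @export
trial_layout <- function(pre_s = 0.5, stim_s = 2, post_s = 0.5) {
  if (any(c(pre_s, stim_s, post_s) <= 0))
    stop("trial durations must be strictly positive", call. = FALSE)
  structure(list(pre_s = pre_s, stim_s = stim_s, post_s = post_s),
            class = "trial_layout")
}

layout_samples <- function(layout, sampling_rate) {
  list(pre = round(layout$pre_s * sampling_rate),
       stim = round(layout$stim_s * sampling_rate),
       post = round(layout$post_s * sampling_rate))
}

#' Average channels within each shank (octrode averaging)
#'
#' @param signal channels x samples matrix.
#' @param shank_map integer vector assigning each channel (row) to a shank.
#' @return shanks x samples matrix; row s is the per-sample arithmetic mean
#'   over the channels of shank s, ordered by shank id.
#' @export
octrode_average <- function(signal, shank_map) {
  stopifnot(is.matrix(signal), length(shank_map) == nrow(signal))
  shanks <- seq_len(max(shank_map))
  counts <- table(factor(shank_map, levels = shanks))
  if (any(counts == 0)) stop("empty shank in shank_map", call. = FALSE)
  out <- rowsum(signal, group = shank_map, reorder = TRUE) / as.numeric(counts)
  rownames(out) <- NULL
  out
}

#' Slice filtered session signal into trial windows
#'
#' Windows are half-open sample intervals `[onset - pre, onset + stim + post)`
#' on 0-based onsets; events whose window falls outside the recording are
#' skipped with a warning and reported.
#'
#' @param filtered a 3-d array (band x shank x sample) of whole-session
#'   band-filtered signals, or a shank x sample matrix for a single band.
#' @param events data frame with columns `onset_sample` (0-based),
#'   `orientation_deg`, `stimulus_type`.
#' @param layout a [trial_layout()].
#' @param sampling_rate Hz.
#' @return list with `windows` (trial x band x shank x time array over the
#'   full pre+stim+post window), `events` (the retained rows, with
#'   `trial_id`), and `skipped` (data frame of dropped events with reasons).
#' @export
segment_trials <- function(filtered, events, layout, sampling_rate) {
  if (is.matrix(filtered))
    filtered <- array(filtered, c(1, nrow(filtered), ncol(filtered)))
  stopifnot(length(dim(filtered)) == 3)
  ls <- layout_samples(layout, sampling_rate)
  width <- ls$pre + ls$stim + ls$post
  n_samp <- dim(filtered)[3]
  start <- events$onset_sample - ls$pre          # 0-based window start
  ok <- start >= 0 & (start + width) <= n_samp
  skipped <- data.frame(row = which(!ok),
                        onset_sample = events$onset_sample[!ok],
                        reason = rep("window out of bounds", sum(!ok)))
  if (any(!ok))
    warning(sprintf("%d event(s) skipped: trial window out of bounds", sum(!ok)),
            call. = FALSE)
  kept <- events[ok, , drop = FALSE]
  kept$trial_id <- which(ok)
  n_tr <- nrow(kept)
  windows <- array(0, c(n_tr, dim(filtered)[1], dim(filtered)[2], width))
  for (i in seq_len(n_tr)) {
    idx <- (start[ok][i] + 1L):(start[ok][i] + width)    # to 1-based
    windows[i, , , ] <- filtered[, , idx, drop = FALSE]
  }
  list(windows = windows, events = kept, skipped = skipped)
}

#' Z-score a trial window against its prestimulus segment
#'
#' Normalizes the stimulus segment by the prestimulus mean and SD:
#' z = (stim - mean(pre)) / sd(pre). Only the stimulus segment is returned;
#' the statistics used are attached so the transform can be verified or
#' re-applied.
#'
#' @param window numeric vector covering a full pre+stim+post trial window.
#' @param layout a [trial_layout()].
#' @param sampling_rate Hz.
#' @return numeric vector of length `stim_s * sampling_rate` with attributes
#'   `prestim_mean` and `prestim_sd`; an error if the prestimulus SD is zero.
#' @export
zscore_to_prestim <- function(window, layout, sampling_rate) {
  ls <- layout_samples(layout, sampling_rate)
  stopifnot(length(window) >= ls$pre + ls$stim)
  pre <- window[seq_len(ls$pre)]
  stim <- window[(ls$pre + 1L):(ls$pre + ls$stim)]
  mu <- mean(pre)
  sdv <- stats::sd(pre)
  if (!is.finite(sdv) || sdv == 0)
    stop("zero prestimulus SD: trial cannot be z-scored", call. = FALSE)
  structure((stim - mu) / sdv, prestim_mean = mu, prestim_sd = sdv)
}

#' Preprocess a session bundle into a trial tensor
#'
#' Runs the fixed order filter -> octrode average -> segment -> z-score:
#' each channel of the whole continuous session is band-passed with the
#' zero-phase 3rd-order Butterworth for each band (so trial edges carry no
#' filter transients), channels are averaged within shanks, trials are
#' sliced around the stimulus onsets, and each trial's stimulus segment is
#' z-scored against its own prestimulus segment. Trials with an
#' out-of-bounds window or a zero prestimulus SD in any band/octrode are
#' dropped and counted.
#'
#' @param bundle a `session_bundle` (from [generate_session()] or
#'   [read_bundle()]).
#' @param bands band table; the canonical seven bands by default.
#' @param layout a [trial_layout()].
#' @param allow_custom_bands permit a non-canonical band set.
#' @return an object of class `trial_tensor`: list with `values` (trial x
#'   band x octrode x stimulus-window time array, z-units), `trial_id`,
#'   `orientation`, `stimulus` (per-trial labels), `bands`, `sampling_rate`,
#'   `window_samples`, `prestim_mean` / `prestim_sd` (trial x band x octrode
#'   arrays) and `skipped`.
#' @export
preprocess_session <- function(bundle, bands = canonical_bands(),
                               layout = trial_layout(),
                               allow_custom_bands = FALSE) {
  stopifnot(inherits(bundle, "session_bundle"))
  fs <- bundle$sampling_rate
  bands <- validate_bands(bands, fs, require_canonical = !allow_custom_bands)
  n_band <- nrow(bands)
  n_shank <- max(bundle$shank_map)
  n_samp <- ncol(bundle$signal)

  ls <- layout_samples(layout, fs)
  width <- ls$pre + ls$stim + ls$post
  start <- bundle$events$onset_sample - ls$pre    # 0-based window starts
  ok <- start >= 0 & (start + width) <= n_samp
  skipped <- data.frame(row = which(!ok),
                        onset_sample = bundle$events$onset_sample[!ok],
                        reason = rep("window out of bounds", sum(!ok)))
  if (any(!ok))
    warning(sprintf("%d event(s) skipped: trial window out of bounds", sum(!ok)),
            call. = FALSE)
  events <- bundle$events[ok, , drop = FALSE]
  events$trial_id <- which(ok)
  n_tr <- nrow(events)
  gather <- outer(as.integer(start[ok]), seq_len(width), `+`)  # 1-based
  pre_cols <- seq_len(ls$pre)
  stim_cols <- ls$pre + seq_len(ls$stim)

  values <- array(0, c(n_tr, n_band, n_shank, ls$stim))
  pm <- array(0, c(n_tr, n_band, n_shank))
  psd <- array(0, c(n_tr, n_band, n_shank))
  bad <- logical(n_tr)
  for (b in seq_len(n_band)) {
    # filter whole-session channels, averaging into shanks on the fly
    sos <- butter_bandpass_sos(3, bands$low[b], bands$high[b], fs)
    padlen <- filtfilt_padlen(sos, n_samp)
    filt <- sosfiltfilt_multi_cpp(bundle$signal, sos, padlen)
    acc <- octrode_average(filt, bundle$shank_map)
    for (s in seq_len(n_shank)) {
      W <- matrix(acc[s, ][gather], n_tr, width)
      mu <- rowMeans(W[, pre_cols, drop = FALSE])
      sdv <- sqrt(rowSums((W[, pre_cols, drop = FALSE] - mu)^2) / (ls$pre - 1))
      zero <- !is.finite(sdv) | sdv == 0
      bad <- bad | zero
      sdv[zero] <- NA_real_
      pm[, b, s] <- mu
      psd[, b, s] <- sdv
      values[, b, s, ] <- (W[, stim_cols, drop = FALSE] - mu) / sdv
    }
  }
  if (any(bad)) {
    warning(sprintf("%d trial(s) dropped: zero prestimulus SD", sum(bad)),
            call. = FALSE)
    skipped <- rbind(skipped,
                     data.frame(row = events$trial_id[bad],
                                onset_sample = events$onset_sample[bad],
                                reason = rep("zero prestimulus SD", sum(bad))))
    keep <- !bad
    values <- values[keep, , , , drop = FALSE]
    pm <- pm[keep, , , drop = FALSE]
    psd <- psd[keep, , , drop = FALSE]
    events <- events[keep, , drop = FALSE]
  }

  structure(list(values = values,
                 trial_id = events$trial_id,
                 orientation = events$orientation_deg,
                 stimulus = events$stimulus_type,
                 bands = bands, sampling_rate = fs,
                 window_samples = c(pre = ls$pre, stim = ls$stim,
                                    post = ls$post),
                 prestim_mean = pm, prestim_sd = psd,
                 skipped = skipped),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf(paste0("<trial_tensor: %d trials x %d bands x %d octrodes x ",
                     "%d samples @ %g Hz (%d skipped)>\n"),
              dm[1], dm[2], dm[3], dm[4], x$sampling_rate, nrow(x$skipped)))
  invisible(x)
}
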