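#' Write a session bundle to a directory
#'
#' On-disk layout: `signal.f32` (little-endian 32-bit float, channel-major:
#' all samples of channel 1, then channel 2, ...), `metadata.json`
#' (sampling rate, channel count, shank map, area, subject, sample count)
#' and `events.csv` with header `onset_sample,orientation_deg,stimulus_type`
#' (0-based onsets). Writing the same bundle twice produces byte-identical
#' files. Note the signal is quantized to float32 on disk; a bundle that has
#' itself been read back round-trips exactly.
#'
#' @param bundle a `session_bundle`.
#' @param path directory to create/populate.
#' @return invisibly, the paths of the written files.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sig_path <- file.path(path, "signal.f32")
  con <- file(sig_path, "wb")
  writeBin(as.numeric(t(bundle$signal)), con, size = 4L, endian = "little")
  close(con)
  meta <- list(sampling_rate = bundle$sampling_rate,
               n_channels = nrow(bundle$signal),
               n_samples = ncol(bundle$signal),
               shank_map = as.integer(bundle$shank_map),
               area = bundle$area, subject = bundle$subject,
               stimulus_types = sort(unique(bundle$events$stimulus_type)))
  meta_path <- file.path(path, "metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  ev_path <- file.path(path, "events.csv")
  utils::write.csv(bundle$events[, c("onset_sample", "orientation_deg",
                                     "stimulus_type")],
                   ev_path, row.names = FALSE, quote = FALSE)
  invisible(c(signal = sig_path, metadata = meta_path, events = ev_path))
}

#' Read a session bundle from a directory
#'
#' Loads and validates the three-file bundle written by [write_bundle()]:
#' channel count must match the signal size, onsets must be strictly
#' increasing and in bounds, and stimulus labels must come from the declared
#' set. Violations raise an error naming the offending field or row.
#'
#' @param path bundle directory.
#' @return a `session_bundle`: list with `signal` (channels x samples
#'   matrix), `sampling_rate`, `shank_map`, `area`, `subject`, `events`.
#' @export
read_bundle <- function(path) {
  need <- file.path(path, c("signal.f32", "metadata.json", "events.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("bundle incomplete, missing: ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  meta <- jsonlite::read_json(need[2], simplifyVector = TRUE)
  for (f in c("sampling_rate", "n_channels", "n_samples", "shank_map"))
    if (is.null(meta[[f]]))
      stop(sprintf("metadata.json: missing field '%s'", f), call. = FALSE)
  n_val <- file.size(need[1]) / 4
  if (n_val != meta$n_channels * meta$n_samples)
    stop(sprintf(paste0("signal.f32: %d values on disk but metadata declares ",
                        "%d channels x %d samples"),
                 n_val, meta$n_channels, meta$n_samples), call. = FALSE)
  if (length(meta$shank_map) != meta$n_channels)
    stop("metadata.json: shank_map length does not match n_channels",
         call. = FALSE)
  con <- file(need[1], "rb")
  raw <- readBin(con, numeric(), n = n_val, size = 4L, endian = "little")
  close(con)
  signal <- matrix(raw, nrow = meta$n_channels, byrow = TRUE)
  events <- utils::read.csv(need[3], stringsAsFactors = FALSE)
  req <- c("onset_sample", "orientation_deg", "stimulus_type")
  if (!all(req %in% names(events)))
    stop("events.csv: expected columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(events)) {
    if (any(diff(events$onset_sample) <= 0))
      stop(sprintf("events.csv: onsets not strictly increasing at row %d",
                   which(diff(events$onset_sample) <= 0)[1] + 1L), call. = FALSE)
    oob <- which(events$onset_sample < 0 |
                   events$onset_sample >= meta$n_samples)
    if (length(oob))
      stop(sprintf("events.csv: onset beyond signal length at row %d", oob[1]),
           call. = FALSE)
    if (!is.null(meta$stimulus_types)) {
      bad <- which(!events$stimulus_type %in% meta$stimulus_types)
      if (length(bad))
        stop(sprintf("events.csv: unknown stimulus label '%s' at row %d",
                     events$stimulus_type[bad[1]], bad[1]), call. = FALSE)
    }
  }
  structure(list(signal = signal, sampling_rate = meta$sampling_rate,
                 shank_map = as.integer(meta$shank_map),
                 area = meta$area %||% "unknown",
                 subject = meta$subject %||% "unknown",
                 events = events),
            class = "session_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trial tensor to a directory
#'
#' `values.f32` holds the z-scored stimulus windows as little-endian float32
#' in array order (trial, band, octrode, time); `index.json` carries the
#' dimensions, per-trial labels, band set and normalization statistics.
#'
#' @param trials a `trial_tensor`.
#' @param path directory.
#' @return invisibly, the written file paths.
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "trial_tensor"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  vp <- file.path(path, "values.f32")
  con <- file(vp, "wb")
  writeBin(as.numeric(trials$values), con, size = 4L, endian = "little")
  close(con)
  idx <- list(dim = dim(trials$values),
              trial_id = trials$trial_id,
              orientation_deg = trials$orientation,
              stimulus_type = trials$stimulus,
              bands = trials$bands,
              sampling_rate = trials$sampling_rate,
              window_samples = as.list(trials$window_samples),
              prestim_mean = as.numeric(trials$prestim_mean),
              prestim_sd = as.numeric(trials$prestim_sd),
              skipped = trials$skipped)
  ip <- file.path(path, "index.json")
  jsonlite::write_json(idx, ip, auto_unbox = TRUE, digits = NA)
  invisible(c(values = vp, index = ip))
}

#' Read a trial tensor written by [write_trials()]
#' @param path directory.
#' @return a `trial_tensor`.
#' @export
read_trials <- function(path) {
  ip <- file.path(path, "index.json")
  vp <- file.path(path, "values.f32")
  if (!file.exists(ip) || !file.exists(vp))
    stop("trial tensor incomplete (need values.f32 and index.json)",
         call. = FALSE)
  idx <- jsonlite::read_json(ip, simplifyVector = TRUE)
  con <- file(vp, "rb")
  vals <- readBin(con, numeric(), n = prod(idx$dim), size = 4L,
                  endian = "little")
  close(con)
  dm <- as.integer(idx$dim)
  structure(list(values = array(vals, dm),
                 trial_id = idx$trial_id,
                 orientation = idx$orientation_deg,
                 stimulus = idx$stimulus_type,
                 bands = as.data.frame(idx$bands),
                 sampling_rate = idx$sampling_rate,
                 window_samples = unlist(idx$window_samples),
                 prestim_mean = array(idx$prestim_mean, dm[1:3]),
                 prestim_sd = array(idx$prestim_sd, dm[1:3]),
                 skipped = as.data.frame(idx$skipped)),
            class = "trial_tensor")
}
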