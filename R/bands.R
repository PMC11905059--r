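#' Canonical LFP frequency bands
#'
#' The seven-band partition used throughout the pipeline: delta (0.1--4 Hz),
#' theta (4--8), alpha (8--12), beta (12--30), gamma1 (30--70), gamma2
#' (70--100) and H (100--200 Hz). Bands are non-overlapping and ordered by
#' frequency.
#'
#' @return A data frame with columns `label`, `low`, `high` (Hz) and the
#'   derived `center` (arithmetic midpoint, Hz), one row per band, ordered by
#'   increasing frequency.
#' @examples
#' canonical_bands()
#' @export
canonical_bands <- function() {
  data.frame(
    label  = c("delta", "theta", "alpha", "beta", "gamma1", "gamma2", "H"),
    low    = c(0.1, 4, 8, 12, 30, 70, 100),
    high   = c(4, 8, 12, 30, 70, 100, 200),
    center = c(2.05, 6, 10, 21, 50, 85, 150),
    stringsAsFactors = FALSE
  )
}

#' Validate a band-definition table
#'
#' @param bands data frame with columns `label`, `low`, `high`.
#' @param sampling_rate sampling rate in Hz (edges must stay below Nyquist).
#' @param require_canonical refuse any band set other than [canonical_bands()].
#' @return the validated band table, invisibly augmented with `center`.
#' @keywords internal
validate_bands <- function(bands, sampling_rate, require_canonical = TRUE) {
  stopifnot(is.data.frame(bands), all(c("label", "low", "high") %in% names(bands)))
  if (anyDuplicated(bands$label))
    stop("duplicate band labels", call. = FALSE)
  if (any(bands$low >= bands$high))
    stop("band low edge must be below high edge", call. = FALSE)
  if (any(bands$high >= sampling_rate / 2))
    stop("band high edge at or above Nyquist frequency", call. = FALSE)
  if (require_canonical) {
    canon <- canonical_bands()
    same <- nrow(bands) == nrow(canon) &&
      identical(bands$label, canon$label) &&
      isTRUE(all.equal(bands$low, canon$low)) &&
      isTRUE(all.equal(bands$high, canon$high))
    if (!same)
      stop("non-canonical band set; pass allow_custom_bands = TRUE to override",
           call. = FALSE)
  }
  if (is.null(bands$center)) bands$center <- (bands$low + bands$high) / 2
  bands
}

#' All low/high band pairs
#'
#' Unordered pairs of distinct bands, the lower-frequency band listed first.
#' With the canonical seven bands this yields choose(7, 2) = 21 pairs.
#'
#' @param bands band table as returned by [canonical_bands()].
#' @return data frame with columns `low_band`, `high_band`.
#' @export
band_pairs <- function(bands = canonical_bands()) {
  idx <- utils::combn(nrow(bands), 2)
  data.frame(low_band = bands$label[idx[1, ]],
             high_band = bands$label[idx[2, ]],
             stringsAsFactors = FALSE)
}

band_row <- function(label, bands = canonical_bands()) {
  i <- match(label, bands$label)
  if (is.na(i))
    stop(sprintf("unknown band label '%s' (expected one of: %s)",
                 label, paste(bands$label, collapse = ", ")), call. = FALSE)
  bands[i, ]
}
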