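# per-trial values for one band pair and kind, octrodes averaged (default)
# or kept as replicates
pair_values <- function(table, low, high, kind, octrodes = "average",
                        missing_ok = FALSE) {
  rows <- table[table$low_band == low & table$high_band == high &
                  table$kind == kind, , drop = FALSE]
  if (!nrow(rows)) {
    if (missing_ok) return(NULL)
    stop(sprintf("band pair %s-%s (%s) not present in table",
                 low, high, kind), call. = FALSE)
  }
  if (octrodes == "average") {
    agg <- stats::aggregate(value ~ trial_id + orientation_deg + stimulus_type,
                            data = rows, FUN = mean, na.rm = TRUE,
                            na.action = stats::na.pass)
    agg$value[is.nan(agg$value)] <- NA_real_
    agg
  } else {
    rows[, c("trial_id", "orientation_deg", "stimulus_type", "octrode",
             "value")]
  }
}

#' Screen band pairs for orientation and stimulus selectivity
#'
#' For each of the 21 band pairs, fits a two-factor fixed-effects ANOVA on
#' per-trial coupling values with orientation and stimulus type as crossed
#' factors and trials as within-cell replicates, and flags pairs whose
#' main-effect p-values fall below `alpha`. Coupling values are averaged
#' over octrodes per trial by default. Missing values are excluded listwise
#' per band pair; a pair with an empty orientation x stimulus cell is
#' flagged untestable rather than dropped.
#'
#' @param table a `coupling_table` from [coupling_table()].
#' @param kind "PAC" or "AAC".
#' @param alpha selectivity threshold on the (possibly corrected) p-values.
#' @param correction multiplicity correction across the 21 pairs: "none"
#'   (default), "bonferroni" or "BH".
#' @param octrodes "average" (one value per trial) or "replicates" (octrodes
#'   enter as additional replicates).
#' @return data frame of class `selectivity_report`, one row per band pair:
#'   `low_band`, `high_band`, `kind`, `p_orientation`, `p_stimulus`,
#'   `p_interaction`, `selective_orientation`, `selective_stimulus`,
#'   `testable`.
#' @export
anova_screen <- function(table, kind = c("PAC", "AAC"), alpha = 0.05,
                         correction = c("none", "bonferroni", "BH"),
                         octrodes = c("average", "replicates")) {
  kind <- match.arg(kind)
  correction <- match.arg(correction)
  octrodes <- match.arg(octrodes)
  bands <- attr(table, "bands")
  if (is.null(bands)) bands <- canonical_bands()
  pairs <- band_pairs(bands)
  out <- pairs
  out$kind <- kind
  out$p_orientation <- NA_real_
  out$p_stimulus <- NA_real_
  out$p_interaction <- NA_real_
  out$testable <- FALSE
  for (i in seq_len(nrow(pairs))) {
    d <- pair_values(table, pairs$low_band[i], pairs$high_band[i], kind,
                     octrodes, missing_ok = TRUE)
    if (is.null(d)) next
    d <- d[is.finite(d$value), , drop = FALSE]
    cells <- table(d$orientation_deg, d$stimulus_type)
    if (length(unique(d$orientation_deg)) < 2 ||
        length(unique(d$stimulus_type)) < 2 || any(cells < 2))
      next
    d$orientation_deg <- factor(d$orientation_deg)
    d$stimulus_type <- factor(d$stimulus_type)
    fit <- stats::aov(value ~ orientation_deg * stimulus_type, data = d)
    p <- summary(fit)[[1]][["Pr(>F)"]]
    out$p_orientation[i] <- p[1]
    out$p_stimulus[i] <- p[2]
    out$p_interaction[i] <- p[3]
    out$testable[i] <- TRUE
  }
  p_orient <- stats::p.adjust(out$p_orientation, method = correction)
  p_stim <- stats::p.adjust(out$p_stimulus, method = correction)
  out$selective_orientation <- !is.na(p_orient) & p_orient < alpha
  out$selective_stimulus <- !is.na(p_stim) & p_stim < alpha
  class(out) <- c("selectivity_report", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  out
}

#' Normalized tuning curves for one band pair
#'
#' Trial-mean coupling per orientation and stimulus type, jointly normalized
#' by the maximum across both stimulus types (so the largest point of the
#' curve set is 1 whenever any cell is positive).
#'
#' @param table a `coupling_table`.
#' @param pair list or data-frame row with `low_band` and `high_band`, or a
#'   character vector `c(low, high)`.
#' @param kind "PAC" or "AAC".
#' @return data frame of class `tuning_curve` with columns
#'   `orientation_deg` (ascending), `stimulus_type`, `mean`, `sd`, `n`,
#'   `norm`; the joint normalization factor is attached as attribute
#'   `"norm_factor"`.
#' @export
tuning_curves <- function(table, pair, kind = c("PAC", "AAC")) {
  kind <- match.arg(kind)
  pair <- as_pair(pair)
  d <- pair_values(table, pair$low_band, pair$high_band, kind)
  grid <- expand.grid(orientation_deg = sort(unique(d$orientation_deg)),
                      stimulus_type = sort(unique(d$stimulus_type)),
                      stringsAsFactors = FALSE)
  stat <- function(o, s) {
    v <- d$value[d$orientation_deg == o & d$stimulus_type == s]
    v <- v[is.finite(v)]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) stats::sd(v) else NA_real_,
      n = length(v))
  }
  st <- mapply(stat, grid$orientation_deg, grid$stimulus_type)
  out <- cbind(grid, t(st))
  mx <- suppressWarnings(max(out$mean, na.rm = TRUE))
  norm_factor <- if (is.finite(mx) && mx > 0) mx else NA_real_
  out$norm <- if (is.na(norm_factor)) NA_real_ else out$mean / norm_factor
  out <- out[order(out$stimulus_type, out$orientation_deg), ]
  rownames(out) <- NULL
  class(out) <- c("tuning_curve", "data.frame")
  attr(out, "norm_factor") <- norm_factor
  attr(out, "pair") <- c(pair$low_band, pair$high_band)
  attr(out, "kind") <- kind
  out
}

as_pair <- function(pair) {
  if (is.character(pair) && length(pair) == 2)
    return(list(low_band = pair[1], high_band = pair[2]))
  stopifnot(!is.null(pair$low_band), !is.null(pair$high_band))
  list(low_band = as.character(pair$low_band[1]),
       high_band = as.character(pair$high_band[1]))
}

#' Mean per-orientation Euclidean distance between LG and CG couplings
#'
#' For each orientation, pairs the LG and CG trials by within-orientation
#' trial index (ascending trial id, trimmed to the common count), computes
#' the Euclidean distance between the two per-trial coupling vectors divided
#' by the number of trials, and averages over orientations. Values are
#' max-normalized (by the tuning-curve normalization factor) so the distance
#' lives on the plotted tuning-curve scale. This pairing/normalization
#' convention is recorded in the result.
#'
#' @param table a `coupling_table`.
#' @param pair band pair (see [tuning_curves()]).
#' @param kind "PAC" or "AAC".
#' @param stimulus_types the two labels to compare (first vs second).
#' @return list of class `lg_cg_distance` with `d` (mean over orientations),
#'   `per_orientation`, `n_trials`, and `convention`.
#' @export
lg_cg_distance <- function(table, pair, kind = c("PAC", "AAC"),
                           stimulus_types = c("LG", "CG")) {
  kind <- match.arg(kind)
  pair <- as_pair(pair)
  d <- pair_values(table, pair$low_band, pair$high_band, kind)
  tc <- tuning_curves(table, pair, kind)
  nf <- attr(tc, "norm_factor")
  if (!is.finite(nf) || nf <= 0)
    return(structure(list(d = NA_real_, per_orientation = NULL,
                          n_trials = 0L,
                          convention = "undefined: non-positive normalization"),
                     class = "lg_cg_distance"))
  d$value <- d$value / nf
  orients <- sort(unique(d$orientation_deg))
  per_o <- rep(NA_real_, length(orients))
  n_used <- rep(0L, length(orients))
  for (i in seq_along(orients)) {
    a <- d[d$orientation_deg == orients[i] &
             d$stimulus_type == stimulus_types[1], ]
    b <- d[d$orientation_deg == orients[i] &
             d$stimulus_type == stimulus_types[2], ]
    a <- a$value[order(a$trial_id)]
    b <- b$value[order(b$trial_id)]
    n <- min(length(a), length(b))
    if (n == 0) next
    if (length(a) != length(b))
      warning("unequal LG/CG trial counts; trimmed to the minimum",
              call. = FALSE)
    va <- a[seq_len(n)]; vb <- b[seq_len(n)]
    ok <- is.finite(va) & is.finite(vb)
    if (!any(ok)) next
    per_o[i] <- sqrt(sum((va[ok] - vb[ok])^2)) / sum(ok)
    n_used[i] <- sum(ok)
  }
  structure(list(d = mean(per_o, na.rm = TRUE),
                 per_orientation = stats::setNames(per_o, orients),
                 n_trials = n_used,
                 convention = paste("trials paired by within-orientation index;",
                                    "distance / n_trials; couplings",
                                    "max-normalized to the tuning-curve scale")),
            class = "lg_cg_distance")
}

#' Tuning-range standard-deviation ratio (SDR)
#'
#' SDR = SD_LG / SD_CG, where each SD is taken over orientations of the
#' per-orientation trial-mean tuning values of that stimulus type. SDR > 1
#' indicates a reduced tuning range for the second-order (CG) stimulus.
#'
#' @inheritParams lg_cg_distance
#' @return the SDR (positive scalar), or `NA_real_` (flagged undefined) when
#'   the CG tuning SD is zero.
#' @export
sdr <- function(table, pair, kind = c("PAC", "AAC"),
                stimulus_types = c("LG", "CG")) {
  kind <- match.arg(kind)
  pair <- as_pair(pair)
  tc <- tuning_curves(table, pair, kind)
  sd_of <- function(s) {
    v <- tc$mean[tc$stimulus_type == s]
    stats::sd(v[is.finite(v)])
  }
  sd1 <- sd_of(stimulus_types[1])
  sd2 <- sd_of(stimulus_types[2])
  if (!is.finite(sd2) || sd2 == 0) return(NA_real_)
  sd1 / sd2
}

#' Consensus selective band pairs across subjects
#'
#' Intersects per-subject selectivity flags: a pair is in the consensus set
#' for a factor when it is selective in every subject's report. Also
#' summarizes each pair's p-values across subjects as mean and SD.
#'
#' @param reports list of `selectivity_report` objects (one per subject),
#'   all for the same coupling kind.
#' @return list with `orientation` and `stimulus` (character vectors of
#'   consensus pair ids `"low-high"`) and `p_summary` (per pair: mean/sd of
#'   each p-value across subjects).
#' @export
consensus_pairs <- function(reports) {
  stopifnot(length(reports) >= 1)
  ids <- paste(reports[[1]]$low_band, reports[[1]]$high_band, sep = "-")
  ori <- Reduce(`&`, lapply(reports, function(r) r$selective_orientation))
  sti <- Reduce(`&`, lapply(reports, function(r) r$selective_stimulus))
  p_o <- sapply(reports, function(r) r$p_orientation)
  p_s <- sapply(reports, function(r) r$p_stimulus)
  p_summary <- data.frame(
    pair = ids,
    p_orientation_mean = rowMeans(p_o, na.rm = TRUE),
    p_orientation_sd = apply(p_o, 1, stats::sd, na.rm = TRUE),
    p_stimulus_mean = rowMeans(p_s, na.rm = TRUE),
    p_stimulus_sd = apply(p_s, 1, stats::sd, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  list(orientation = ids[ori], stimulus = ids[sti], p_summary = p_summary)
}
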