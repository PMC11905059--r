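config_from_list <- function(cfg) {
  sim <- cfg$simulate %||% list()
  specs <- lapply(sim$coupling, function(sp) {
    sp$stimulus_gain <- unlist(sp$stimulus_gain %||% c(LG = 1, CG = 1))
    do.call(coupling_spec, sp)
  })
  sim$coupling <- NULL
  sim$coupling_specs <- specs
  do.call(simulation_config, sim)
}

#' Run the full coupling pipeline
#'
#' Executes simulate (unless an existing bundle is given) -> preprocess ->
#' coupling -> selectivity statistics -> optional report figures, writing
#' every intermediate artifact plus a run manifest with content checksums.
#' With a fixed seed and config the output files are identical across runs.
#'
#' @param config a configuration list or the path of a YAML file with the
#'   documented schema: top-level `seed`, `alpha`, `correction`, `figures`,
#'   `bundle` (path to an existing session bundle, or omitted to simulate)
#'   and `simulate` (fields of [simulation_config()], with `coupling` a list
#'   of [coupling_spec()] fields).
#' @param out output directory.
#' @param seed optional override of the config seed.
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.null(seed)) cfg$seed <- seed
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  alpha <- cfg$alpha %||% 0.05
  correction <- cfg$correction %||% "none"
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  manifest <- list(tool = "crossfreq",
                   version = as.character(utils::packageVersion("crossfreq")),
                   seed = cfg$seed, alpha = alpha, correction = correction,
                   started = format(Sys.time(), tz = "UTC"))
  res <- tryCatch({
    if (!is.null(cfg$bundle)) {
      bundle <- read_bundle(cfg$bundle)
    } else {
      sim <- cfg$simulate %||% list()
      # stage seed = global seed + fixed per-stage offset (simulate: +1)
      sim$seed <- cfg$seed + 1L
      cfg$simulate <- sim
      bundle <- generate_session(config_from_list(cfg))
      write_bundle(bundle, file.path(out, "bundle"))
    }
    manifest$n_events <- nrow(bundle$events)

    stage <- "preprocess"
    trials <- preprocess_session(bundle)
    write_trials(trials, file.path(out, "trials"))
    manifest$n_trials <- dim(trials$values)[1]
    manifest$n_skipped <- nrow(trials$skipped)
    manifest$skipped_reasons <- as.list(table(trials$skipped$reason))

    stage <- "coupling"
    ct <- coupling_table(trials)
    utils::write.csv(ct, file.path(out, "coupling.csv"), row.names = FALSE,
                     quote = FALSE)
    manifest$n_coupling_rows <- nrow(ct)
    manifest$n_coupling_missing <- attr(ct, "n_missing")

    stage <- "stats"
    pairs <- band_pairs(attr(ct, "bands"))
    sim_rows <- list()
    for (kind in c("PAC", "AAC")) {
      rep <- anova_screen(ct, kind, alpha = alpha, correction = correction)
      utils::write.csv(as.data.frame(rep),
                       file.path(out, sprintf("selectivity_%s.csv", kind)),
                       row.names = FALSE, quote = FALSE)
      tcs <- lapply(seq_len(nrow(pairs)), function(i) {
        tc <- tuning_curves(ct, pairs[i, ], kind)
        cbind(low_band = pairs$low_band[i], high_band = pairs$high_band[i],
              kind = kind, as.data.frame(tc))
      })
      utils::write.csv(do.call(rbind, tcs),
                       file.path(out, sprintf("tuning_%s.csv", kind)),
                       row.names = FALSE, quote = FALSE)
      both <- all(c("LG", "CG") %in% ct$stimulus_type)
      sim_rows[[kind]] <- data.frame(
        low_band = pairs$low_band, high_band = pairs$high_band, kind = kind,
        distance = if (both) vapply(seq_len(nrow(pairs)), function(i)
          suppressWarnings(lg_cg_distance(ct, pairs[i, ], kind)$d),
          numeric(1)) else NA_real_,
        sdr = if (both) vapply(seq_len(nrow(pairs)), function(i)
          suppressWarnings(sdr(ct, pairs[i, ], kind)), numeric(1))
          else NA_real_)
    }
    utils::write.csv(do.call(rbind, sim_rows),
                     file.path(out, "similarity.csv"), row.names = FALSE,
                     quote = FALSE)

    if (isTRUE(cfg$figures)) {
      stage <- "report"
      fig_dir <- file.path(out, "figures")
      dir.create(fig_dir, showWarnings = FALSE)
      for (kind in c("PAC", "AAC")) {
        rep <- anova_screen(ct, kind, alpha = alpha, correction = correction)
        ggplot2::ggsave(file.path(fig_dir, sprintf("selectivity_%s.png", kind)),
                        plot_selectivity_heatmap(rep), width = 6, height = 5,
                        dpi = 120)
        best <- rep[order(rep$p_orientation), ][1, ]
        tc <- tuning_curves(ct, best, kind)
        ggplot2::ggsave(file.path(fig_dir,
                                  sprintf("tuning_%s_%s-%s.png", kind,
                                          best$low_band, best$high_band)),
                        plot_tuning_curve(tc), width = 6, height = 4,
                        dpi = 120)
      }
    }
    TRUE
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$files <- lapply(stats::setNames(files, substring(files, nchar(out) + 2)),
                           function(f) unname(tools::md5sum(f)))
  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
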