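# hand-built coupling table: one band pair (theta-H), given cell values
make_table <- function(values_fun, kinds = "PAC", n_trials = 10,
                       orientations = seq(0, 315, by = 45),
                       stimulus_types = c("LG", "CG")) {
  grid <- expand.grid(trial = seq_len(n_trials),
                      orientation_deg = orientations,
                      stimulus_type = stimulus_types,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(kinds, function(k) {
    data.frame(trial_id = seq_len(nrow(grid)),
               orientation_deg = grid$orientation_deg,
               stimulus_type = grid$stimulus_type,
               octrode = 1L,
               low_band = "theta", high_band = "H", kind = k,
               value = values_fun(grid), stringsAsFactors = FALSE)
  }))
  class(out) <- c("coupling_table", "data.frame")
  out
}
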