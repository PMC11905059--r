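test_that("a pure stimulus effect yields a floor p_stimulus and p_orientation 1", {
  set.seed(1)
  # noise identical across orientations within stimulus: orientation SS = 0
  noise <- matrix(rnorm(10 * 2, sd = 0.1), 10)
  tab <- make_table(function(g)
    10 * (g$stimulus_type == "LG") +
      noise[cbind(g$trial, 1 + (g$stimulus_type == "CG"))])
  rep <- anova_screen(tab, "PAC")
  row <- rep[rep$low_band == "theta" & rep$high_band == "H", ]
  expect_lt(row$p_stimulus, 1e-12)
  expect_equal(row$p_orientation, 1)
  expect_true(row$selective_stimulus)
  expect_false(row$selective_orientation)
  # untested pairs are flagged untestable, not invented
  expect_equal(sum(rep$testable), 1)
  expect_equal(nrow(rep), 21)
})

test_that("orientation type-I error is calibrated at the nominal level", {
  set.seed(2024)
  n_rep <- 300
  hits <- 0
  for (r in seq_len(n_rep)) {
    tab <- make_table(function(g) rnorm(nrow(g)), n_trials = 5)
    p <- anova_screen(tab, "PAC")$p_orientation
    if (p[!is.na(p)][1] < 0.05) hits <- hits + 1
  }
  expect_lt(abs(hits / n_rep - 0.05), 0.03)
})

test_that("tuning curves normalize jointly to the curve-set maximum", {
  tab <- make_table(function(g) rep(3, nrow(g)))
  tc <- tuning_curves(tab, c("theta", "H"), "PAC")
  expect_true(all(tc$norm == 1))
  expect_equal(attr(tc, "norm_factor"), 3)
  # single nonzero cell
  tab2 <- make_table(function(g)
    ifelse(g$orientation_deg == 90 & g$stimulus_type == "LG", 2, 0.5))
  tc2 <- tuning_curves(tab2, c("theta", "H"), "PAC")
  expect_equal(tc2$norm[tc2$orientation_deg == 90 &
                          tc2$stimulus_type == "LG"], 1)
  expect_true(all(tc2$norm[tc2$orientation_deg != 90 |
                             tc2$stimulus_type != "LG"] == 0.25))
  expect_equal(tc2$n, rep(10, 16))
  # invariant to positive rescaling of all couplings
  tab3 <- tab2
  tab3$value <- tab3$value * 7
  tc3 <- tuning_curves(tab3, c("theta", "H"), "PAC")
  expect_equal(tc3$norm, tc2$norm)
})

test_that("tuning-curve argmax recovers the injected orientation", {
  fx <- theta_h_fixture()
  tc <- tuning_curves(fx$table, c("theta", "H"), "PAC")
  lg <- tc[tc$stimulus_type == "LG", ]
  expect_equal(lg$orientation_deg[which.max(lg$mean)], 90)
  expect_equal(max(tc$norm, na.rm = TRUE), 1)
})

test_that("LG/CG distance follows its closed form for constant offsets", {
  tab <- make_table(function(g) ifelse(g$stimulus_type == "LG", 1, 1 - 0.2),
                    n_trials = 30)
  d <- lg_cg_distance(tab, c("theta", "H"), "PAC")
  # max-normalization factor is 1 here, so d_o = sqrt(30 * 0.2^2) / 30
  expect_equal(d$d, 0.2 / sqrt(30), tolerance = 1e-12)
  expect_equal(unname(d$per_orientation), rep(0.2 / sqrt(30), 8))
  # identical LG and CG responses give zero distance
  tab0 <- make_table(function(g) g$trial / 30, n_trials = 30)
  expect_equal(lg_cg_distance(tab0, c("theta", "H"), "PAC")$d, 0)
})

test_that("a stronger LG/CG asymmetry increases the distance", {
  fx <- theta_h_fixture()            # stimulus_gain CG = 0.5
  cfg_eq <- simulation_config(
    n_channels = 4, n_shanks = 1, n_trials_per_condition = 6,
    coupling_specs = list(coupling_spec(
      "PAC", "theta", "H", 0.6, preferred_orientation = 90,
      tuning_width = 45, stimulus_gain = c(LG = 1, CG = 1))),
    seed = 404)                      # matched seed, no asymmetry
  ct_eq <- coupling_table(preprocess_session(generate_session(cfg_eq)))
  d_asym <- lg_cg_distance(fx$table, c("theta", "H"), "PAC")$d
  d_eq <- lg_cg_distance(ct_eq, c("theta", "H"), "PAC")$d
  expect_gt(d_asym, d_eq)
})

test_that("SDR is the ratio of tuning-range standard deviations", {
  base <- c(1, 2, 4, 8, 4, 2, 1, 1)
  curve <- function(g) {
    o <- match(g$orientation_deg, seq(0, 315, by = 45))
    lg <- base[o]
    cg <- mean(base) + (base[o] - mean(base)) / 2   # half the deviation
    ifelse(g$stimulus_type == "LG", lg, cg)
  }
  tab <- make_table(curve)
  expect_equal(sdr(tab, c("theta", "H"), "PAC"), 2, tolerance = 1e-12)
  tab_eq <- make_table(function(g) base[match(g$orientation_deg,
                                              seq(0, 315, by = 45))])
  expect_equal(sdr(tab_eq, c("theta", "H"), "PAC"), 1)
  flat <- make_table(function(g) ifelse(g$stimulus_type == "LG",
                                        base[match(g$orientation_deg,
                                                   seq(0, 315, by = 45))], 1))
  expect_true(is.na(sdr(flat, c("theta", "H"), "PAC")))
})

test_that("tuned LG with attenuated CG drives SDR above one", {
  fx <- theta_h_fixture()
  expect_gt(sdr(fx$table, c("theta", "H"), "PAC"), 1)
})

test_that("consensus is the intersection of per-subject selectivity", {
  template <- anova_screen(make_table(function(g) rnorm(nrow(g)),
                                      n_trials = 3), "PAC")
  mk <- function(sel) {
    r <- template
    r$selective_orientation <- FALSE
    r$selective_orientation[match(sel, paste(r$low_band, r$high_band,
                                             sep = "-"))] <- TRUE
    r$p_orientation <- ifelse(r$selective_orientation, 0.01, 0.5)
    r
  }
  reps <- list(mk("theta-H"), mk(c("theta-H", "alpha-H")), mk("theta-H"))
  cons <- consensus_pairs(reps)
  expect_equal(cons$orientation, "theta-H")
  expect_equal(
    cons$p_summary$p_orientation_mean[cons$p_summary$pair == "theta-H"], 0.01)
  reps2 <- c(reps, list(mk(character(0))))
  expect_equal(consensus_pairs(reps2)$orientation, character(0))
})

test_that("multiple synthetic subjects agree on the injected pair", {
  reports <- lapply(1:3, function(s) {
    cfg <- simulation_config(
      n_channels = 4, n_shanks = 1, n_trials_per_condition = 6,
      coupling_specs = list(coupling_spec(
        "PAC", "theta", "H", 0.6, preferred_orientation = 90,
        tuning_width = 45)),
      seed = 500 + s)
    ct <- coupling_table(preprocess_session(generate_session(cfg)))
    anova_screen(ct, "PAC")
  })
  cons <- consensus_pairs(reports)
  expect_true("theta-H" %in% cons$orientation)
})

test_that("screening does not mutate the coupling table", {
  fx <- theta_h_fixture()
  before <- fx$table
  invisible(anova_screen(fx$table, "PAC"))
  invisible(tuning_curves(fx$table, c("theta", "H"), "PAC"))
  invisible(lg_cg_distance(fx$table, c("theta", "H"), "PAC"))
  invisible(sdr(fx$table, c("theta", "H"), "PAC"))
  expect_identical(as.data.frame(fx$table), as.data.frame(before))
})

test_that("distances are non-negative and triangle-consistent", {
  set.seed(77)
  a <- rnorm(30); b <- rnorm(30); c <- rnorm(30)
  d <- function(x, y) sqrt(sum((x - y)^2)) / length(x)
  expect_gte(d(a, b), 0)
  expect_lte(d(a, c), d(a, b) + d(b, c))
})
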