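# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# a small trained pipeline: 10 assays, 2 training chips, corrected mode
trained_fixture <- function() {
  if (is.null(.fixture_env$trained)) {
    panel <- synthetic_panel(10)
    cfg <- generator_config(n_assays = 10, n_chips = 2, seed = 404)
    run <- simulate_training_run(cfg, panel, n_pools = 60, n_chips = 2)
    rec <- apply_correction(run$records)
    tr <- train_assay_classifiers(rec, run$truth, mode = "corrected",
                                  seed = 5, ntree = 300)
    .fixture_env$trained <- list(panel = panel, cfg = cfg, run = run,
                                 records = rec, trained = tr)
  }
  .fixture_env$trained
}

# brute-force two-pass sums-of-squares eta^2, independent of the anova path
brute_force_eta2 <- function(values, groups) {
  grand <- mean(values)
  ss_total <- sum((values - grand)^2)
  ss_between <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_between <- ss_between + length(v) * (mean(v) - grand)^2
  }
  ss_between / ss_total
}

# independent Beta quantile: bisection on pbeta, no qbeta call
beta_quantile_bisect <- function(p, a, b, tol = 1e-12) {
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stats::pbeta(mid, a, b) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# control-record data frame builder for variance-decomposition tests
control_records <- function(y_values, chip_ids, assay_ids,
                            type = "CTS_CONTROL") {
  n <- length(y_values)
  data.frame(chip_id = rep_len(chip_ids, n),
             sample_well = 91L, assay_well = seq_len(n),
             assay_id = rep_len(assay_ids, n), replicate = 1L,
             sample_id = type, sample_type = type,
             x_raw = y_values, y_raw = y_values,
             stringsAsFactors = FALSE)
}

# one-row call table builder for triage tests
call_row <- function(pool, assay, c1, c2) {
  data.frame(pool_id = pool, assay_id = assay,
             replicate1_call = c1, replicate2_call = c2,
             call_probability_1 = ifelse(c1 == "missing", NA_real_, 0.9),
             call_probability_2 = ifelse(c2 == "missing", NA_real_, 0.9),
             status = ifelse(c1 == "missing" | c2 == "missing", "filtered", "called"),
             stringsAsFactors = FALSE)
}
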