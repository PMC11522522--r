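test_that("panel files round-trip and preserve order", {
  panel <- synthetic_panel(48)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  back <- read_panel(path, version = "synthetic")
  expect_equal(nrow(back), 48)
  expect_identical(back$assay_id, panel$assay_id)
  expect_identical(attr(back, "version"), "synthetic")
})

test_that("panel validation rejects duplicates and identical alleles", {
  df <- as.data.frame(synthetic_panel(5))
  df$assay_id[4] <- "S07"
  df$assay_id[5] <- "S07"
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_panel(path), "S07")

  df2 <- as.data.frame(synthetic_panel(2))
  df2$y_allele[1] <- df2$x_allele[1]
  expect_error(new_assay_panel(df2), "identical X and Y")
})

test_that("an assay-less panel file yields an empty panel with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("assay_id\tlocus_name\tx_allele\ty_allele\tflank_5\tflank_3", path)
  expect_warning(p <- read_panel(path), "no assays")
  expect_equal(nrow(p), 0)
})

test_that("a full chip yields 9216 reactions with 48 duplicated assays", {
  layout <- build_chip_layout(sprintf("p%02d", 1:90), synthetic_panel(48), "chipA")
  expect_equal(layout$n_reactions, 9216)
  expect_equal(sum(layout$sample_wells != "EMPTY"), 96)
  aw <- layout$assay_wells[!is.na(layout$assay_wells$assay_id), ]
  expect_equal(length(unique(aw$assay_id)), 48)
  reps <- tapply(aw$replicate, aw$assay_id, function(r) sort(r))
  expect_true(all(vapply(reps, identical, logical(1), c(1L, 2L))))
  # replicate 1 sits in the lower-numbered well
  w <- tapply(aw$well, paste(aw$assay_id, aw$replicate), identity)
  expect_true(all(aw$well[aw$replicate == 1] < aw$well[aw$replicate == 2][
    match(aw$assay_id[aw$replicate == 1], aw$assay_id[aw$replicate == 2])]))
})

test_that("a sparse chip pads with EMPTY and counts reactions accordingly", {
  layout <- build_chip_layout("p01", synthetic_panel(48), "chipB")
  expect_equal(sum(layout$sample_wells != "EMPTY"), 7)  # 1 pool + 6 controls
  expect_equal(sum(layout$sample_wells == "EMPTY"), 89)
  expect_equal(layout$sample_wells[91:96],
               c("CTS_CONTROL", "CTS_CONTROL", "BTS_CONTROL", "BTS_CONTROL",
                 "NTC", "NTC"))
  for (k in c(0, 1, 45, 90)) {
    l <- build_chip_layout(if (k > 0) sprintf("q%02d", seq_len(k)) else character(0),
                           synthetic_panel(10), "chipC")
    expect_equal(l$n_reactions, (k + 6) * 96)
  }
})

test_that("chip capacity limits are enforced", {
  expect_error(build_chip_layout(sprintf("p%02d", 1:91), synthetic_panel(10), "c"),
               "at most 90")
  expect_error(build_chip_layout("p1", synthetic_panel(49), "c"), "at most 48")
})

test_that("plan_pools chunks 5805 tissues into 387 pools of 15", {
  plan <- plan_pools(c(big_pond = 5805))
  expect_equal(length(plan$pools), 387)
  expect_true(all(vapply(plan$pools, function(p) length(p$individual_ids), integer(1)) == 15))
  expect_length(plan$unpooled, 0)
})

test_that("small ponds merge into one mixed-pond pool", {
  plan <- plan_pools(c(pondA = 7, pondB = 6))
  expect_equal(length(plan$pools), 1)
  p <- plan$pools[[1]]
  expect_equal(length(p$individual_ids), 13)
  expect_true(p$mixed_pond)
  expect_setequal(p$pond_ids, c("pondA", "pondB"))
})

test_that("plan_pools handles empty input and conserves individuals", {
  empty <- plan_pools(integer(0))
  expect_length(empty$pools, 0)
  set.seed(31)
  for (i in 1:10) {
    counts <- stats::setNames(sample(0:40, 6, replace = TRUE),
                              paste0("pond", 1:6))
    plan <- plan_pools(counts)
    sizes <- vapply(plan$pools, function(p) length(p$individual_ids), integer(1))
    expect_equal(sum(sizes), sum(counts))
    expect_true(all(sizes <= 15))
    ids <- unlist(lapply(plan$pools, `[[`, "individual_ids"))
    expect_false(anyDuplicated(ids) > 0)
  }
})

test_that("fluorescence exports round-trip field-for-field", {
  cfg <- generator_config(n_assays = 5, n_chips = 2, seed = 9)
  rec <- simulate_background(cfg, synthetic_panel(5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fluorescence(rec, path)
  back <- read_fluorescence(path)
  expect_equal(back, rec, tolerance = 1e-12)
  # corrected columns survive the round trip too
  cor_rec <- apply_correction(rec)
  write_fluorescence(cor_rec, path)
  expect_equal(read_fluorescence(path), cor_rec, tolerance = 1e-12)
})

test_that("fluorescence validation flags bad rows by number", {
  cfg <- generator_config(n_assays = 3, n_chips = 1, seed = 9)
  rec <- simulate_background(cfg, synthetic_panel(3))
  rec$y_raw[4] <- -0.1
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rec, path, row.names = FALSE)
  expect_error(read_fluorescence(path), "row\\(s\\): 4")

  rec2 <- simulate_background(cfg, synthetic_panel(3))
  rec2$sample_type[2] <- "WEIRD"
  utils::write.csv(rec2, path, row.names = FALSE)
  expect_error(read_fluorescence(path), "unknown sample_type")

  utils::write.csv(rec2[-3], path, row.names = FALSE)
  expect_error(read_fluorescence(path), "missing columns")
})

test_that("call reports and pool manifests round-trip", {
  calls <- rbind(call_row("poolX", "S01", "Het", "CTS"),
                 call_row("poolX", "S02", "missing", "missing"),
                 call_row("poolY", "S01", "CTS", "CTS"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_calls(calls, path)
  expect_equal(read_calls(path), calls, tolerance = 1e-12)

  plan <- plan_pools(c(pondA = 20, pondB = 7, pondC = 6))
  mpath <- withr::local_tempfile(fileext = ".csv")
  write_pool_manifest(plan, mpath)
  back <- read_pool_manifest(mpath)
  expect_equal(back, plan$pools)
})
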