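test_that("rare-allele ratios reproduce the pooled-design worked examples", {
  expect_equal(rare_allele_ratio(15, het_count = 1), 1 / 30)
  expect_equal(rare_allele_ratio(15), 0)
  expect_equal(rare_allele_ratio(15, hom_bts_count = 1), 1 / 15)
  # scaling all counts leaves the ratio unchanged
  for (k in c(2, 5, 10)) {
    expect_equal(rare_allele_ratio(15 * k, het_count = k), 1 / 30)
  }
  expect_error(rare_allele_ratio(0), "at least one")
  expect_error(rare_allele_ratio(3, het_count = 2, hom_bts_count = 2), "exceed")
})

test_that("expected validation reads scale with depth and ratio", {
  e <- expected_bts_reads(579, 1 / 30)
  expect_equal(e$expected, 19.3)
  expect_identical(e$expected_integer, 19L)
  expect_equal(expected_bts_reads(579, 0)$expected, 0)
  expect_identical(expected_bts_reads(30, 1 / 30)$expected_integer, 1L)
})

test_that("amplicon assessment detects presence and flags contamination", {
  all_bts <- data.frame(assay_id = sprintf("S%02d", 1:48),
                        cts_reads = 560, bts_reads = 19)
  a <- assess_amplicon_pool(all_bts)
  expect_true(a$contamination)  # non-native reads at every locus
  expect_equal(a$fraction_bts_loci, 1)

  clean <- data.frame(assay_id = sprintf("S%02d", 1:48),
                      cts_reads = 579, bts_reads = 0)
  expect_false(assess_amplicon_pool(clean)$contamination)
  expect_equal(assess_amplicon_pool(clean)$fraction_bts_loci, 0)

  # zero-depth loci are excluded and block the contamination flag
  holey <- all_bts
  holey$cts_reads[5] <- holey$bts_reads[5] <- 0
  h <- assess_amplicon_pool(holey)
  expect_true(is.na(h$presence[5]))
  expect_true(h$contamination)  # all *assayed* loci positive
  below <- all_bts
  below$bts_reads[7] <- 2  # under the read threshold
  expect_false(assess_amplicon_pool(below)$contamination)
})

test_that("a genuine F1-like pool shows partial presence without the flag", {
  panel <- synthetic_panel(48)
  hyb <- simulate_hybrid_genotype(0.5, panel, seed = 3)
  fr <- pool_fractions(c(list(hyb), lapply(1:14, function(i)
    simulate_hybrid_genotype(0, panel, seed = 50 + i))))
  set.seed(8)
  counts <- data.frame(assay_id = names(fr),
                       bts_reads = stats::rbinom(48, 579, fr))
  counts$cts_reads <- 579 - counts$bts_reads
  a <- assess_amplicon_pool(counts)
  expect_false(a$contamination)
  expect_gt(a$fraction_bts_loci, 0.3)
  expect_lt(a$fraction_bts_loci, 0.95)
})

test_that("backcross dilution halves ancestry each generation", {
  expect_equal(backcross_fraction(1, 5), 0.03125)
  expect_equal(round(backcross_fraction(1, 5), 2), 0.03)
  expect_equal(backcross_fraction(0.7, 0), 0.7)
  # semigroup property: g = a + b composes exactly
  for (a in 0:3) for (b in 0:3) {
    expect_identical(backcross_fraction(1, a + b),
                     backcross_fraction(backcross_fraction(1, a), b))
  }
  # smallest g with 2^-g below one locus of 31: enumeration oracle
  g_oracle <- min(which(sapply(0:20, function(g) 0.5^g <= 1 / 31)) - 1)
  expect_identical(generations_to_fraction(1, 1 / 31), as.integer(g_oracle))
  expect_identical(generations_to_fraction(1, 1 / 31), 5L)
  expect_error(generations_to_fraction(1, 0), "positive")
})

test_that("detection probability follows the closed form and its limits", {
  expect_equal(detection_probability(0, 0.9), 0)
  expect_equal(detection_probability(1, 0.969), 0.969)
  expect_equal(detection_probability(10, 0.9), 1 - 0.1^10)
  # nondecreasing in both arguments
  s_grid <- seq(0, 1, 0.1)
  expect_true(all(diff(sapply(s_grid, detection_probability, loci = 5)) >= 0))
  expect_true(all(diff(sapply(0:10, detection_probability, sensitivity = 0.5)) >= 0))
})

test_that("Monte-Carlo detection agrees with the closed form within 3 SE", {
  for (case in list(c(10, 0.9), c(3, 0.5), c(1, 0.969))) {
    p <- detection_probability(case[1], case[2])
    reps <- 1e5
    mc <- detection_probability_mc(case[1], case[2], reps = reps, seed = 17)
    se <- sqrt(p * (1 - p) / reps)
    expect_lt(abs(mc - p), max(3 * se, 1e-12))
  }
})

test_that("the accuracy regression flags degenerate fits", {
  set.seed(2)
  rows <- data.frame(correct = 1, raratio = stats::runif(50),
                     dilution = sample(1:2, 50, TRUE),
                     zygosity = sample(1:2, 50, TRUE),
                     pool_type = sample(c("extract", "tissue"), 50, TRUE))
  expect_warning(fit <- evaluate_accuracy_model(rows), "separation")
  expect_true(fit$separation)
})

test_that("the accuracy regression is null-calibrated when predictors are inert", {
  set.seed(12)
  n <- 2000
  rows <- data.frame(correct = stats::rbinom(n, 1, 0.8),
                     raratio = stats::runif(n),
                     dilution = sample(1:2, n, TRUE),
                     zygosity = sample(0:2, n, TRUE),
                     pool_type = sample(c("extract", "tissue"), n, TRUE))
  fit <- evaluate_accuracy_model(rows)
  co <- fit$coefficients
  design <- co[co$term %in% c("raratio", "dilution", "zygosity", "pool_typetissue"), ]
  expect_true(all(abs(design$z) < 3))
  expect_false(fit$separation)
  # refit reproducibility
  fit2 <- evaluate_accuracy_model(rows)
  expect_equal(fit$coefficients$estimate, fit2$coefficients$estimate, tolerance = 1e-12)
})

test_that("the accuracy regression recovers strong planted effects", {
  set.seed(5)
  n <- 3000
  raratio <- sample(c(1, 1/8, 1/15, 1/20, 1/30), n, TRUE)
  zyg <- sample(1:2, n, TRUE)
  pool_type <- sample(c("extract", "tissue"), n, TRUE)
  dil <- sample(1:2, n, TRUE)
  eta <- 1 + 1.5 * scale(raratio)[, 1] + 0.7 * scale(zyg)[, 1] +
    2.0 * (pool_type == "tissue")
  rows <- data.frame(correct = stats::rbinom(n, 1, stats::plogis(eta)),
                     raratio = raratio, dilution = dil, zygosity = zyg,
                     pool_type = pool_type)
  fit <- evaluate_accuracy_model(rows)
  co <- fit$coefficients
  get <- function(term) co[co$term == term, ]
  expect_gt(get("raratio")$estimate, 0)
  expect_lt(get("raratio")$p, 0.01)
  expect_gt(get("zygosity")$estimate, 0)
  expect_gt(get("pool_typetissue")$estimate, 0)
  expect_gt(get("dilution")$p, 0.01)  # planted null
})
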