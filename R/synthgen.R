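# Synthetic fluorescence data generator. Emulates the variance structure of
# endpoint-fluorescence SNP chips: assay-specific and chip-specific background
# offsets plus within-reaction noise, with channel signal proportional to the
# allele fraction carried by the pool.

#' Generator configuration
#'
#' Parameters of the synthetic fluorescence model. The intensity of a channel
#' for a pool carrying allele fraction f at an assay is
#' \deqn{background\_mean + assay\_effect + chip\_effect +
#'       (signal\_full - background\_mean) \, f^{signal\_exponent} + noise}
#' truncated at zero (raw fluorescence is nonnegative). Assay effects are
#' drawn once per assay per channel (SD \code{assay_baseline_sd}), chip
#' effects once per chip per channel (SD \code{chip_offset_sd}) and noise
#' independently per reaction (SD \code{noise_sd}).
#'
#' The default values are the calibrated preset used throughout: they place
#' almost all background variance at the assay level with a small chip-level
#' component, the ordering observed on real chips, and make a 1:30
#' rare-allele ratio separable from an all-native pool.
#'
#' @param n_assays Number of assays the config describes (informational).
#' @param n_chips Number of chips for [simulate_background()].
#' @param assay_baseline_sd Between-assay SD of background intensity.
#' @param chip_offset_sd Between-chip SD of background intensity.
#' @param noise_sd Within-reaction SD.
#' @param signal_full Mean channel intensity at allele fraction 1.
#' @param background_mean Mean channel intensity at allele fraction 0.
#' @param signal_exponent Shape of the intensity response in allele fraction
#'   (1 = linear; endpoint PCR chemistry may saturate, but no response curve
#'   beyond linearity is assumed by default).
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(n_assays = 48L, n_chips = 4L,
                             assay_baseline_sd = 0.060,
                             chip_offset_sd = 0.018,
                             noise_sd = 0.012,
                             signal_full = 1.00,
                             background_mean = 0.10,
                             signal_exponent = 1,
                             seed = 1L) {
  stopifnot(assay_baseline_sd >= 0, chip_offset_sd >= 0, noise_sd >= 0,
            signal_full > background_mean, signal_exponent > 0)
  structure(list(n_assays = as.integer(n_assays), n_chips = as.integer(n_chips),
                 assay_baseline_sd = assay_baseline_sd,
                 chip_offset_sd = chip_offset_sd, noise_sd = noise_sd,
                 signal_full = signal_full, background_mean = background_mean,
                 signal_exponent = signal_exponent, seed = as.integer(seed)),
            class = "generator_config")
}

#' A small synthetic assay panel
#'
#' Convenience constructor for simulated panels: assays \code{S01..Snn} with
#' arbitrary (valid) flanking sequence.
#'
#' @param n_assays Number of assays.
#' @return An \code{assay_panel}.
#' @export
synthetic_panel <- function(n_assays = 48L) {
  ids <- sprintf("S%02d", seq_len(n_assays))
  new_assay_panel(data.frame(
    assay_id = ids,
    locus_name = paste0("locus_", ids),
    x_allele = rep(c("A", "C", "G", "T"), length.out = n_assays),
    y_allele = rep(c("G", "T", "A", "C"), length.out = n_assays),
    flank_5 = strrep("ACGT", 15),
    flank_3 = strrep("TGCA", 15),
    stringsAsFactors = FALSE
  ), version = "synthetic")
}

# evaluate code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

# per-channel assay and chip effects, deterministic in (config$seed, ids)
draw_effects <- function(config, assay_ids, chip_ids) {
  n_a <- length(assay_ids)
  n_c <- length(chip_ids)
  with_seed(config$seed, {
    list(
      assay_y = stats::setNames(stats::rnorm(n_a, 0, config$assay_baseline_sd), assay_ids),
      assay_x = stats::setNames(stats::rnorm(n_a, 0, config$assay_baseline_sd), assay_ids),
      chip_y = stats::setNames(stats::rnorm(n_c, 0, config$chip_offset_sd), chip_ids),
      chip_x = stats::setNames(stats::rnorm(n_c, 0, config$chip_offset_sd), chip_ids)
    )
  })
}

# channel mean for allele fraction f at one assay/chip (before noise)
channel_mean <- function(config, frac, assay_eff, chip_eff) {
  config$background_mean + assay_eff + chip_eff +
    (config$signal_full - config$background_mean) * frac^config$signal_exponent
}

#' Simulate background intensities of homozygous controls across chips
#'
#' Generates the absent-allele channel structure used to quantify background:
#' CTS homozygote controls carry no Y allele (their y_raw is pure background)
#' and BTS homozygote controls no X allele. Two control samples of each type
#' are placed per chip; each is read once per assay, so a panel larger than
#' 48 assays (which could not be duplicated on a real chip) is supported.
#'
#' @param config A [generator_config()]; \code{config$n_chips} chips are drawn.
#' @param panel An \code{assay_panel}.
#' @return Fluorescence record data frame (both control types, all chips).
#' @export
simulate_background <- function(config, panel) {
  chips <- sprintf("chip%02d", seq_len(config$n_chips))
  eff <- draw_effects(config, panel$assay_id, chips)
  grid <- expand.grid(control = 1:2,
                      sample_type = c("CTS_CONTROL", "BTS_CONTROL"),
                      assay_id = panel$assay_id, chip_id = chips,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  frac_y <- ifelse(grid$sample_type == "BTS_CONTROL", 1, 0)
  mu_y <- channel_mean(config, frac_y, eff$assay_y[grid$assay_id], eff$chip_y[grid$chip_id])
  mu_x <- channel_mean(config, 1 - frac_y, eff$assay_x[grid$assay_id], eff$chip_x[grid$chip_id])
  noise <- with_seed(config$seed + 1L, matrix(stats::rnorm(2 * n, 0, config$noise_sd), ncol = 2))
  data.frame(
    chip_id = grid$chip_id,
    sample_well = 90L + 2L * (grid$sample_type == "BTS_CONTROL") + grid$control,
    assay_well = match(grid$assay_id, panel$assay_id),
    assay_id = grid$assay_id,
    replicate = 1L,
    sample_id = paste0(grid$sample_type, "_", grid$control),
    sample_type = grid$sample_type,
    x_raw = pmax(0, mu_x + noise[, 1]),
    y_raw = pmax(0, mu_y + noise[, 2]),
    stringsAsFactors = FALSE
  )
}

#' Simulate one reaction's intensity pair for a pool
#'
#' @param y_fraction Non-native allele fraction of the pool at this assay
#'   (the rare-allele ratio); the X channel mirrors with fraction
#'   \code{1 - y_fraction}.
#' @param config A [generator_config()].
#' @param assay_eff,chip_eff Optional named lists with elements \code{x},
#'   \code{y} giving the assay/chip offsets for each channel (default 0).
#' @param n Number of independent draws.
#' @return Data frame with columns \code{x_raw}, \code{y_raw}.
#' @export
simulate_pool_intensities <- function(y_fraction, config,
                                      assay_eff = list(x = 0, y = 0),
                                      chip_eff = list(x = 0, y = 0),
                                      n = 1L) {
  stopifnot(y_fraction >= 0, y_fraction <= 1)
  mu_y <- channel_mean(config, y_fraction, assay_eff$y, chip_eff$y)
  mu_x <- channel_mean(config, 1 - y_fraction, assay_eff$x, chip_eff$x)
  data.frame(
    x_raw = pmax(0, stats::rnorm(n, mu_x, config$noise_sd)),
    y_raw = pmax(0, stats::rnorm(n, mu_y, config$noise_sd))
  )
}

# Pool-to-ratio assignment for training chips. When the ratio set mixes the
# all-native ratio 0 with positive ratios, pools alternate between ratio 0
# and the cycled positive ratios so the two presence classes stay balanced
# (training pools are constructed, so balance is a design choice); a ratio
# set without 0 (or only 0) is cycled directly.
training_ratio_sequence <- function(ratios, n_pools) {
  pos <- ratios[ratios > 0]
  if (!any(ratios == 0) || length(pos) == 0) {
    return(ratios[((seq_len(n_pools) - 1L) %% length(ratios)) + 1L])
  }
  out <- numeric(n_pools)
  odd <- seq(1L, n_pools, by = 2L)
  even <- setdiff(seq_len(n_pools), odd)
  out[odd] <- 0
  out[even] <- pos[((seq_along(even) - 1L) %% length(pos)) + 1L]
  out
}

# build the record rows for one chip given per-pool per-assay Y fractions.
# fractions: matrix pools x assays (rownames pool ids, colnames assay ids)
simulate_chip_records <- function(config, panel, fractions, chip_id,
                                  chip_eff, assay_eff, noise_seed) {
  layout <- build_chip_layout(rownames(fractions), panel, chip_id)
  occupied <- which(layout$sample_wells != "EMPTY")
  assay_rows <- layout$assay_wells[!is.na(layout$assay_wells$assay_id), ]
  grid <- expand.grid(si = occupied, ai = seq_len(nrow(assay_rows)))
  sample_id <- layout$sample_wells[grid$si]
  sample_type <- ifelse(sample_id %in% CONTROL_TYPES, sample_id, "POOL")
  # distinguish the two controls of each type by well
  sample_id <- ifelse(sample_type == "POOL", sample_id,
                      paste0(sample_id, "_", grid$si - 90L))
  assay_id <- assay_rows$assay_id[grid$ai]
  frac_y <- numeric(nrow(grid))
  is_pool <- sample_type == "POOL"
  frac_y[is_pool] <- fractions[cbind(sample_id[is_pool], assay_id[is_pool])]
  frac_y[sample_type == "BTS_CONTROL"] <- 1
  frac_x <- 1 - frac_y
  frac_x[sample_type == "NTC"] <- 0  # no template: both channels at background
  mu_y <- channel_mean(config, frac_y, assay_eff$assay_y[assay_id], chip_eff$y)
  mu_x <- channel_mean(config, frac_x, assay_eff$assay_x[assay_id], chip_eff$x)
  n <- nrow(grid)
  noise <- with_seed(noise_seed, matrix(stats::rnorm(2 * n, 0, config$noise_sd), ncol = 2))
  data.frame(
    chip_id = chip_id,
    sample_well = grid$si,
    assay_well = assay_rows$well[grid$ai],
    assay_id = assay_id,
    replicate = assay_rows$replicate[grid$ai],
    sample_id = sample_id,
    sample_type = sample_type,
    x_raw = pmax(0, mu_x + noise[, 1]),
    y_raw = pmax(0, mu_y + noise[, 2]),
    stringsAsFactors = FALSE
  )
}

#' Simulate one training chip of known-composition pools
#'
#' Emits a full chip-consistent record set (pools plus the six controls)
#' with constructed pools at the given rare-allele ratios, mirroring
#' training runs built by mixing precise amounts of pure native and
#' non-native DNA. Pools cycle through \code{ratios}; the truth table maps
#' every (pool, assay) to contains-BTS / no-BTS.
#'
#' Reaction noise is seeded independently of \code{chip}, so two chips
#' simulated from the same config differ only through their chip effects;
#' pass distinct \code{reaction_seed}s (as [simulate_training_run()] does)
#' to emulate fully independent runs.
#'
#' @param config A [generator_config()].
#' @param panel An \code{assay_panel} (at most 48 assays).
#' @param ratios Rare-allele ratios to cycle pools through.
#' @param n_pools Number of pools on the chip (at most 90).
#' @param chip Chip index: selects which chip effect from the config's chip
#'   stream applies.
#' @param reaction_seed Seed for reaction noise (default \code{config$seed + 1}).
#' @return List with \code{records} (fluorescence data frame) and
#'   \code{truth} (data frame pool_id, ratio, contains_bts).
#' @export
simulate_training_chip <- function(config, panel, ratios = c(0, 1/30, 1/15),
                                   n_pools = 90L, chip = 1L,
                                   reaction_seed = config$seed + 1L) {
  stopifnot(all(ratios >= 0), all(ratios <= 1), n_pools <= 90)
  chip_id <- sprintf("train%02d", chip)
  chips_all <- sprintf("train%02d", seq_len(max(chip, config$n_chips)))
  eff <- draw_effects(config, panel$assay_id, chips_all)
  pool_ids <- sprintf("%s_p%02d", chip_id, seq_len(n_pools))
  pool_ratio <- training_ratio_sequence(ratios, n_pools)
  fractions <- matrix(pool_ratio, nrow = n_pools, ncol = nrow(panel),
                      dimnames = list(pool_ids, panel$assay_id))
  chip_eff <- list(x = eff$chip_x[[chip_id]], y = eff$chip_y[[chip_id]])
  records <- simulate_chip_records(config, panel, fractions, chip_id,
                                   chip_eff, eff, reaction_seed)
  truth <- data.frame(pool_id = pool_ids, ratio = pool_ratio,
                      contains_bts = pool_ratio > 0, stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Simulate several independent training chips
#'
#' Like [simulate_training_chip()] run once per chip, but with chip-specific
#' reaction noise so chips are independent replicate runs.
#'
#' @inheritParams simulate_training_chip
#' @param n_chips Number of chips.
#' @return List with combined \code{records} and \code{truth}.
#' @export
simulate_training_run <- function(config, panel, ratios = c(0, 1/30, 1/15),
                                  n_pools = 90L, n_chips = config$n_chips) {
  out <- lapply(seq_len(n_chips), function(i) {
    simulate_training_chip(config, panel, ratios, n_pools, chip = i,
                           reaction_seed = config$seed + i)
  })
  list(records = do.call(rbind, lapply(out, `[[`, "records")),
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}

#' Simulate a field screen of pools with known composition
#'
#' Distributes pools across as many chips as needed (90 per chip), each chip
#' with its own controls, chip effect and reaction noise. Compositions give
#' each pool's per-assay non-native allele fraction; all-native pools have
#' fraction 0 everywhere.
#'
#' @param config A [generator_config()].
#' @param panel An \code{assay_panel}.
#' @param fractions Matrix (pools x assays) of non-native allele fractions,
#'   rownames pool ids, colnames assay ids. Use [pool_fractions()] to build
#'   one from individual genotypes.
#' @return List with \code{records} and \code{truth} (pool_id, contains_bts:
#'   any positive fraction at any assay).
#' @export
simulate_screen <- function(config, panel, fractions) {
  n_pools <- nrow(fractions)
  n_chips <- ceiling(n_pools / 90)
  chips <- sprintf("field%02d", seq_len(n_chips))
  eff <- draw_effects(config, panel$assay_id, chips)
  recs <- vector("list", n_chips)
  for (i in seq_len(n_chips)) {
    idx <- ((i - 1L) * 90L + 1L):min(i * 90L, n_pools)
    chip_eff <- list(x = eff$chip_x[[chips[i]]], y = eff$chip_y[[chips[i]]])
    recs[[i]] <- simulate_chip_records(config, panel,
                                       fractions[idx, , drop = FALSE],
                                       chips[i], chip_eff, eff,
                                       noise_seed = config$seed + 1000L + i)
  }
  truth <- data.frame(pool_id = rownames(fractions),
                      contains_bts = apply(fractions > 0, 1, any),
                      stringsAsFactors = FALSE)
  list(records = do.call(rbind, recs), truth = truth)
}

#' Simulate a hybrid individual's per-locus genotype
#'
#' Each locus receives two independent allele draws, non-native with
#' probability \code{bts_fraction}, giving 0, 1 or 2 non-native copies.
#'
#' @param bts_fraction Genome-wide non-native ancestry fraction in [0, 1].
#' @param panel An \code{assay_panel} defining the loci.
#' @param seed Integer seed.
#' @param individual_id Identifier for the individual.
#' @return A \code{hybrid_genotype} list: \code{individual_id},
#'   \code{bts_fraction}, \code{copies} (named integer vector per assay).
#' @export
simulate_hybrid_genotype <- function(bts_fraction, panel, seed,
                                     individual_id = "hybrid_1") {
  stopifnot(bts_fraction >= 0, bts_fraction <= 1)
  copies <- with_seed(seed, stats::rbinom(nrow(panel), 2, bts_fraction))
  structure(list(individual_id = individual_id, bts_fraction = bts_fraction,
                 copies = stats::setNames(as.integer(copies), panel$assay_id)),
            class = "hybrid_genotype")
}

#' Per-assay allele fractions of a pool of individuals
#'
#' Sums non-native copy counts over the pooled individuals; the pool's
#' fraction at each locus is total copies / (2 x pool size), i.e. its
#' rare-allele ratio at that locus.
#'
#' @param genotypes List of \code{hybrid_genotype} objects (use
#'   \code{simulate_hybrid_genotype(0, ...)} for pure natives).
#' @return Named numeric vector of fractions per assay.
#' @export
pool_fractions <- function(genotypes) {
  copies <- Reduce(`+`, lapply(genotypes, `[[`, "copies"))
  copies / (2 * length(genotypes))
}

#' All-native pool fraction matrix
#'
#' @param n_pools Number of pools.
#' @param panel An \code{assay_panel}.
#' @param prefix Pool id prefix.
#' @return Zero matrix (pools x assays) suitable for [simulate_screen()].
#' @export
all_native_fractions <- function(n_pools, panel, prefix = "pool") {
  matrix(0, nrow = n_pools, ncol = nrow(panel),
         dimnames = list(sprintf("%s_%04d", prefix, seq_len(n_pools)),
                         panel$assay_id))
}

#' Degraded-panel preset
#'
#' Marks a subset of assays as degraded: their reaction noise is inflated
#' tenfold, which reliably pushes them past the out-of-bag-error and
#' sensitivity filters. Used to test planted-truth recovery of assay
#' filtering.
#'
#' @param panel An \code{assay_panel}.
#' @param degraded_assays Character vector of assay ids to degrade.
#' @param factor Noise inflation factor (default 10).
#' @return Named numeric vector of per-assay noise multipliers.
#' @export
degraded_noise_factors <- function(panel, degraded_assays, factor = 10) {
  out <- stats::setNames(rep(1, nrow(panel)), panel$assay_id)
  out[degraded_assays] <- factor
  out
}

#' Simulate training chips with a degraded assay subset
#'
#' As [simulate_training_run()], but reaction noise for degraded assays is
#' inflated by \code{factor}.
#'
#' @inheritParams simulate_training_run
#' @param degraded_assays Assay ids whose noise is inflated.
#' @param factor Noise inflation factor.
#' @return List with \code{records}, \code{truth} and \code{degraded_assays}.
#' @export
simulate_degraded_run <- function(config, panel, degraded_assays,
                                  ratios = c(0, 1/30, 1/15), n_pools = 90L,
                                  n_chips = config$n_chips, factor = 10) {
  run <- simulate_training_run(config, panel, ratios, n_pools, n_chips)
  rec <- run$records
  bad <- rec$assay_id %in% degraded_assays
  if (any(bad)) {
    extra_sd <- config$noise_sd * sqrt(factor^2 - 1)
    extra <- with_seed(config$seed + 9999L,
                       matrix(stats::rnorm(2 * sum(bad), 0, extra_sd), ncol = 2))
    rec$x_raw[bad] <- pmax(0, rec$x_raw[bad] + extra[, 1])
    rec$y_raw[bad] <- pmax(0, rec$y_raw[bad] + extra[, 2])
  }
  list(records = rec, truth = run$truth, degraded_assays = degraded_assays)
}
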