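# Amplicon read-count validation and the design mathematics of pooled
# screening: rare-allele ratios, expected validation read counts, backcross
# dilution, detection probability and the call-accuracy regression.

#' Rare-allele ratio of a pool
#'
#' The fraction of allele copies in a DNA pool that are non-native:
#' \eqn{(het + 2 \cdot homBTS) / (2n)} for a pool of \code{n} individuals of
#' which \code{het} are heterozygous and \code{hom_bts} homozygous
#' non-native at the locus. One heterozygote among 15 individuals gives
#' 1/30.
#'
#' @param n_individuals Pool size (>= 1).
#' @param het_count Heterozygous individuals at the locus.
#' @param hom_bts_count Homozygous non-native individuals at the locus.
#' @return The ratio as a numeric value.
#' @export
rare_allele_ratio <- function(n_individuals, het_count = 0L, hom_bts_count = 0L) {
  if (n_individuals < 1) stop("pool must contain at least one individual")
  if (het_count < 0 || hom_bts_count < 0) stop("counts must be nonnegative")
  if (het_count + hom_bts_count > n_individuals) {
    stop("carrier counts exceed pool size")
  }
  (het_count + 2 * hom_bts_count) / (2 * n_individuals)
}

#' Expected non-native reads in amplicon validation
#'
#' At sequencing depth \code{depth} over a locus, a pool at rare-allele
#' ratio \code{raratio} is expected to yield \code{depth * raratio}
#' non-native reads; the integer form is the floor.
#'
#' @param depth Mean per-locus read depth (>= 0).
#' @param raratio Rare-allele ratio in [0, 1].
#' @return List \code{expected} (real) and \code{expected_integer} (floor).
#' @export
expected_bts_reads <- function(depth, raratio) {
  stopifnot(depth >= 0, raratio >= 0, raratio <= 1)
  e <- depth * raratio
  list(expected = e, expected_integer = as.integer(floor(e)))
}

#' Assess amplicon read counts of a pool
#'
#' Declares the non-native allele present at a locus when its read count
#' reaches \code{min_bts_reads}. Zero-depth loci are marked no-data and
#' excluded from the presence fraction. A contamination flag is raised when
#' the non-native allele is present at 100\% of assayed loci: real
#' introgressed pools carry non-native alleles at only a subset of
#' diagnostic loci, so an every-locus signal indicates contamination with
#' non-native control DNA.
#'
#' @param counts Data frame with columns \code{assay_id}, \code{cts_reads},
#'   \code{bts_reads} for one pool.
#' @param min_bts_reads Minimum reads to declare presence (default 3).
#' @return List: \code{presence} (named logical, NA for no-data loci),
#'   \code{fraction_bts_loci}, \code{contamination}, \code{mean_depth}.
#' @export
assess_amplicon_pool <- function(counts, min_bts_reads = 3L) {
  stopifnot(all(counts$cts_reads >= 0), all(counts$bts_reads >= 0))
  depth <- counts$cts_reads + counts$bts_reads
  presence <- ifelse(depth == 0, NA, counts$bts_reads >= min_bts_reads)
  names(presence) <- counts$assay_id
  assayed <- !is.na(presence)
  frac <- if (any(assayed)) mean(presence[assayed]) else NA_real_
  list(presence = presence,
       fraction_bts_loci = frac,
       contamination = isTRUE(frac == 1) && any(assayed),
       mean_depth = mean(depth))
}

#' Backcross dilution of non-native ancestry
#'
#' Each generation of backcrossing to pure natives halves the expected
#' non-native genome fraction: \eqn{f(g) = f_0 \cdot 0.5^g}.
#'
#' @param f0 Initial non-native fraction in (0, 1].
#' @param g Number of backcross generations (>= 0).
#' @return The expected fraction after \code{g} generations.
#' @export
backcross_fraction <- function(f0, g) {
  stopifnot(f0 > 0, f0 <= 1, g >= 0)
  f0 * 0.5^g
}

#' Generations of backcrossing to reach a target fraction
#'
#' Smallest integer \code{g} with \eqn{f_0 \cdot 0.5^g \le target}.
#'
#' @param f0 Initial non-native fraction in (0, 1].
#' @param target Target fraction (> 0).
#' @return Integer number of generations.
#' @export
generations_to_fraction <- function(f0, target) {
  if (target <= 0) stop("target must be positive")
  stopifnot(f0 > 0, f0 <= 1)
  g <- 0L
  while (backcross_fraction(f0, g) > target) g <- g + 1L
  g
}

#' Screen-level detection probability
#'
#' Probability of detecting a single hybrid individual screened in one pool
#' at \code{loci} informative loci, each detected independently with
#' per-locus sensitivity \code{sensitivity}: \eqn{1 - (1 - s)^L}. The
#' hybrid sits in exactly one pool (pooling is by pond of origin), so the
#' number of pools cancels.
#'
#' @param loci Number of informative loci L (loci at which the hypothesized
#'   hybrid carries the non-native allele and that survived assay
#'   filtering).
#' @param sensitivity Per-locus (both-replicate) detection sensitivity s.
#' @return Detection probability.
#' @export
detection_probability <- function(loci, sensitivity) {
  stopifnot(loci >= 0, sensitivity >= 0, sensitivity <= 1)
  1 - (1 - sensitivity)^loci
}

#' Monte-Carlo detection probability
#'
#' Simulates Bernoulli detection at each locus; agrees with the closed form
#' within Monte-Carlo error.
#'
#' @inheritParams detection_probability
#' @param reps Number of simulated screens.
#' @param seed Integer seed.
#' @return Estimated detection probability.
#' @export
detection_probability_mc <- function(loci, sensitivity, reps = 1e5, seed = 1L) {
  stopifnot(loci >= 0, sensitivity >= 0, sensitivity <= 1)
  if (loci == 0) return(0)
  detected <- with_seed(seed, stats::rbinom(reps, loci, sensitivity) > 0)
  mean(detected)
}

#' Regression of call correctness on screening design factors
#'
#' Binomial (logit-link) regression of per-(pool x assay) call correctness
#' on rare-allele ratio, dilution and locus zygosity as scaled continuous
#' predictors and pool type as a discrete predictor. The grouping structure
#' (hybrid individual and assay) is absorbed by entering both identifiers
#' as categorical covariates, a fixed-effects approximation whose targets
#' are the fixed-effect signs and significance. Positive coefficients mean
#' higher odds of a correct call.
#'
#' @param rows Data frame with \code{correct} (0/1), \code{raratio},
#'   \code{dilution}, \code{zygosity} (numeric), \code{pool_type} (two
#'   levels), and optional \code{assay_id}, \code{hybrid_id}.
#' @return An \code{accuracy_model_fit} list: \code{coefficients} (data
#'   frame estimate/se/z/p for intercept and the four design predictors),
#'   \code{scaling} (means/SDs used), \code{separation} (logical flag),
#'   \code{fit} (the glm object).
#' @export
evaluate_accuracy_model <- function(rows) {
  needed <- c("correct", "raratio", "dilution", "zygosity", "pool_type")
  missing <- setdiff(needed, names(rows))
  if (length(missing) > 0) stop("missing columns: ", paste(missing, collapse = ", "))
  if (length(unique(rows$pool_type)) < 2) stop("pool_type needs 2 levels")
  scale_rec <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("cannot scale a constant predictor")
    list(mean = mean(v), sd = s, z = (v - mean(v)) / s)
  }
  sc <- lapply(rows[c("raratio", "dilution", "zygosity")], scale_rec)
  d <- data.frame(correct = rows$correct,
                  raratio = sc$raratio$z, dilution = sc$dilution$z,
                  zygosity = sc$zygosity$z,
                  pool_type = factor(rows$pool_type))
  form <- correct ~ raratio + dilution + zygosity + pool_type
  if (!is.null(rows$assay_id) && length(unique(rows$assay_id)) > 1) {
    d$assay_id <- factor(rows$assay_id)
    form <- stats::update(form, . ~ . + assay_id)
  }
  if (!is.null(rows$hybrid_id) && length(unique(rows$hybrid_id)) > 1) {
    d$hybrid_id <- factor(rows$hybrid_id)
    form <- stats::update(form, . ~ . + hybrid_id)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (all(rows$correct == 1) || all(rows$correct == 0)) separation <- TRUE
  if (separation) warning("possible complete separation; coefficients unreliable")
  sm <- summary(fit)$coefficients
  keep <- c("(Intercept)", "raratio", "dilution", "zygosity",
            grep("^pool_type", rownames(sm), value = TRUE))
  co <- data.frame(term = keep,
                   estimate = sm[keep, 1], se = sm[keep, 2],
                   z = sm[keep, 3], p = sm[keep, 4],
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = co,
                 scaling = lapply(sc, function(s) s[c("mean", "sd")]),
                 separation = separation, fit = fit),
            class = "accuracy_model_fit")
}

#' @export
print.accuracy_model_fit <- function(x, ...) {
  cat("binomial call-accuracy model (logit link)",
      if (x$separation) "[separation flagged]" else "", "\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}
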