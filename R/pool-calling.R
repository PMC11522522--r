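# Field-pool genotype calling: technical-replicate concordance filtering,
# per-pool calls from the trained per-assay classifiers, and the suspect-pool
# triage state machine.

#' Pair the technical replicates of each (pool x assay)
#'
#' Each pool is assayed twice on the same chip (the duplicated assay wells).
#' Pairs carry the absolute between-replicate difference in each channel,
#' computed on corrected intensities when present.
#'
#' @param records Fluorescence records (pool reactions; controls ignored).
#' @return Data frame, one row per (chip x pool x assay) with both
#'   replicates' intensities and \code{dx}, \code{dy}.
#' @export
make_replicate_pairs <- function(records) {
  pools <- records[records$sample_type == "POOL", ]
  xcol <- if ("x_corr" %in% names(pools)) "x_corr" else "x_raw"
  ycol <- if ("y_corr" %in% names(pools)) "y_corr" else "y_raw"
  r1 <- pools[pools$replicate == 1L, ]
  r2 <- pools[pools$replicate == 2L, ]
  key1 <- paste(r1$chip_id, r1$sample_id, r1$assay_id)
  key2 <- paste(r2$chip_id, r2$sample_id, r2$assay_id)
  idx <- match(key1, key2)
  if (anyNA(idx)) stop("unpaired replicate for: ", utils::head(key1[is.na(idx)], 1))
  r2 <- r2[idx, ]
  data.frame(
    chip_id = r1$chip_id, pool_id = r1$sample_id, assay_id = r1$assay_id,
    x1 = r1[[xcol]], y1 = r1[[ycol]], x2 = r2[[xcol]], y2 = r2[[ycol]],
    dx = abs(r1[[xcol]] - r2[[xcol]]), dy = abs(r1[[ycol]] - r2[[ycol]]),
    stringsAsFactors = FALSE
  )
}

#' Concordance-filter replicate pairs
#'
#' Flags discordant technical replicates: the distribution of
#' between-replicate absolute differences is computed per channel over the
#' whole run batch, and a pair is removed when its difference exceeds the
#' channel threshold in either channel. The default threshold is
#' mean + 1 SD of the difference distribution (scale-free); \code{"sd_only"}
#' uses 1 SD above zero.
#'
#' @param pairs Data frame from [make_replicate_pairs()].
#' @param method \code{"mean_plus_sd"} (default) or \code{"sd_only"}.
#' @return \code{pairs} with a logical \code{kept} column.
#' @export
filter_replicate_pairs <- function(pairs, method = c("mean_plus_sd", "sd_only")) {
  method <- match.arg(method)
  if (nrow(pairs) < 2) stop("need at least 2 pairs to estimate the difference SD")
  thr <- function(d) if (method == "mean_plus_sd") mean(d) + stats::sd(d) else stats::sd(d)
  pairs$kept <- !(pairs$dx > thr(pairs$dx) | pairs$dy > thr(pairs$dy))
  pairs
}

#' Call pools at every retained assay
#'
#' Applies each retained assay's classifier to both replicates of every kept
#' pair. Pairs removed by concordance filtering yield \code{missing} calls;
#' dropped assays are never called.
#'
#' @param models Named list of \code{assay_classifier} objects.
#' @param records Corrected fluorescence records of the screen.
#' @param retained Character vector of retained assay ids.
#' @param pairs Optional pre-filtered pairs (defaults to
#'   \code{filter_replicate_pairs(make_replicate_pairs(records))}).
#' @return Pool-call data frame: \code{pool_id}, \code{assay_id},
#'   \code{replicate1_call}, \code{replicate2_call} (\code{Het}/\code{CTS}/
#'   \code{missing}), \code{call_probability_1/2} (NA when missing),
#'   \code{status} (\code{called}/\code{filtered}).
#' @export
call_pools <- function(models, records, retained,
                       pairs = filter_replicate_pairs(make_replicate_pairs(records))) {
  unknown <- setdiff(retained, names(models))
  if (length(unknown) > 0) {
    stop("no trained model for retained assay(s): ", paste(unknown, collapse = ", "))
  }
  pairs <- pairs[pairs$assay_id %in% retained, ]
  out <- vector("list", length(retained))
  for (i in seq_along(retained)) {
    a <- retained[i]
    pa <- pairs[pairs$assay_id == a, ]
    if (nrow(pa) == 0) next
    res <- data.frame(pool_id = pa$pool_id, assay_id = a,
                      replicate1_call = "missing", replicate2_call = "missing",
                      call_probability_1 = NA_real_, call_probability_2 = NA_real_,
                      status = ifelse(pa$kept, "called", "filtered"),
                      stringsAsFactors = FALSE)
    kept <- which(pa$kept)
    if (length(kept) > 0) {
      clf <- models[[a]]
      feats1 <- data.frame(x = pa$x1[kept], y = pa$y1[kept])
      feats2 <- data.frame(x = pa$x2[kept], y = pa$y2[kept])
      p1 <- predict_frame(clf, feats1)
      p2 <- predict_frame(clf, feats2)
      res$replicate1_call[kept] <- p1$call
      res$replicate2_call[kept] <- p2$call
      res$call_probability_1[kept] <- p1$call_probability
      res$call_probability_2[kept] <- p2$call_probability
    }
    out[[i]] <- res
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  calls
}

# predict from an already-built feature frame (pairs store the mode's columns)
predict_frame <- function(classifier, feats) {
  votes <- stats::predict(classifier$forest, feats, type = "prob")
  win <- max.col(votes, ties.method = "first")
  data.frame(call = ifelse(colnames(votes)[win] == "BTS", "Het", "CTS"),
             call_probability = votes[cbind(seq_len(nrow(votes)), win)],
             stringsAsFactors = FALSE)
}

#' Triage pools from their replicate calls
#'
#' A pool is \code{CLEAR} when no assay shows a Het call in either replicate;
#' \code{SINGLE_REP_DISMISSED} when every Het appears in only one replicate
#' of its pair (the expected false-positive signature, since a true
#' heterozygous pool should be Het in both technical replicates); and
#' \code{SUSPECT} when at least one assay is Het in both replicates.
#'
#' @param calls Pool-call data frame from [call_pools()].
#' @return \code{pool_status} data frame: \code{pool_id}, \code{status},
#'   \code{evidence_assays} (semicolon-joined both-replicate-Het assays;
#'   for dismissed pools, the single-replicate-Het assays).
#' @export
triage_pools <- function(calls) {
  by_pool <- split(calls, calls$pool_id)
  out <- lapply(by_pool, function(cp) {
    het1 <- cp$replicate1_call == "Het"
    het2 <- cp$replicate2_call == "Het"
    both <- het1 & het2
    any_het <- het1 | het2
    if (any(both)) {
      status <- "SUSPECT"
      evidence <- cp$assay_id[both]
    } else if (any(any_het)) {
      status <- "SINGLE_REP_DISMISSED"
      evidence <- cp$assay_id[any_het]
    } else {
      status <- "CLEAR"
      evidence <- character(0)
    }
    data.frame(pool_id = cp$pool_id[1], status = status,
               evidence_assays = paste(evidence, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resolve a suspect pool with re-assay calls
#'
#' A suspect pool is re-assayed on an independent chip run. If the re-assay
#' shows no both-replicate Het at any assay the original detection is
#' \code{REFUTED}; a both-replicate Het on re-assay makes the pool
#' \code{CONFIRMED}, with the confirming assays listed and a directive to
#' genotype the constituent individuals. If the suspect assay's re-assay
#' pair was concordance-filtered (missing), the pool stays \code{SUSPECT}
#' with a needs-rerun flag.
#'
#' @param status One row of the pool-status frame (must be \code{SUSPECT}).
#' @param reassay_calls Pool-call data frame of the re-assay run for this
#'   pool.
#' @return Updated one-row status data frame with columns \code{pool_id},
#'   \code{status}, \code{evidence_assays}, \code{needs_rerun},
#'   \code{directive}.
#' @export
resolve_suspect <- function(status, reassay_calls) {
  if (nrow(status) != 1 || status$status != "SUSPECT") {
    stop("resolve_suspect expects a single SUSPECT pool")
  }
  rc <- reassay_calls[reassay_calls$pool_id == status$pool_id, ]
  if (nrow(rc) == 0) stop("no re-assay calls for pool ", status$pool_id)
  both <- rc$replicate1_call == "Het" & rc$replicate2_call == "Het"
  suspect_assays <- strsplit(status$evidence_assays, ";", fixed = TRUE)[[1]]
  on_suspect <- rc$assay_id %in% suspect_assays
  missing <- rc$replicate1_call == "missing" | rc$replicate2_call == "missing"
  # refutation needs an informative (unfiltered) re-assay pair at some
  # originally suspect assay; all-missing there is inconclusive
  if (any(both)) {
    data.frame(pool_id = status$pool_id, status = "CONFIRMED",
               evidence_assays = paste(rc$assay_id[both], collapse = ";"),
               needs_rerun = FALSE,
               directive = "genotype constituent individuals",
               stringsAsFactors = FALSE)
  } else if (any(on_suspect) && all(missing[on_suspect])) {
    data.frame(pool_id = status$pool_id, status = "SUSPECT",
               evidence_assays = status$evidence_assays,
               needs_rerun = TRUE, directive = "re-run re-assay chip",
               stringsAsFactors = FALSE)
  } else {
    data.frame(pool_id = status$pool_id, status = "REFUTED",
               evidence_assays = "", needs_rerun = FALSE,
               directive = "", stringsAsFactors = FALSE)
  }
}

#' Screen-level call summary
#'
#' Reconciles call counts: total (pool x retained assay) slots, filtered
#' pairs, replicate-level calls, Het calls and their fraction.
#'
#' @param calls Pool-call data frame.
#' @return Named list of counts and fractions.
#' @export
summarize_calls <- function(calls) {
  called <- calls$status == "called"
  reps <- c(calls$replicate1_call[called], calls$replicate2_call[called])
  list(
    n_pool_assay = nrow(calls),
    n_filtered_pairs = sum(!called),
    n_calls = length(reps),
    n_het_calls = sum(reps == "Het"),
    het_fraction = if (length(reps) > 0) mean(reps == "Het") else NA_real_
  )
}
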