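# Per-assay presence/absence classifiers for the non-native allele.
#
# One random forest per SNP assay, trained on the two-channel intensity pair
# of known-composition pools, with out-of-bag error, hold-out metrics,
# quality filtering, and closed-form Beta posteriors for predictive values.

CLASS_LEVELS <- c("CTS", "BTS")  # no-BTS vs contains-BTS

#' Assemble per-assay training rows from records and pool truth
#'
#' @param records Fluorescence records of training chips (corrected via
#'   [apply_correction()] when \code{mode = "corrected"} is to be used).
#' @param truth Data frame with \code{pool_id} and logical
#'   \code{contains_bts}.
#' @return Data frame of pool reactions joined to labels: one row per
#'   (pool x assay x replicate) with \code{x_raw, y_raw} (and corrected
#'   columns if present) and \code{label} in \code{CTS}/\code{BTS}.
#' @export
assemble_training <- function(records, truth) {
  pools <- records[records$sample_type == "POOL", ]
  idx <- match(pools$sample_id, truth$pool_id)
  if (anyNA(idx)) {
    stop("pools without truth labels: ",
         paste(utils::head(unique(pools$sample_id[is.na(idx)])), collapse = ", "))
  }
  pools$label <- factor(ifelse(truth$contains_bts[idx], "BTS", "CTS"),
                        levels = CLASS_LEVELS)
  pools$pool_id <- pools$sample_id
  pools
}

#' Split known pools into training and hold-out halves
#'
#' Pool-level random split, stratified by class so both halves contain both
#' classes; both technical replicates of a pool stay on the same side. With
#' an odd class count the training side takes the floor.
#'
#' @param truth Data frame with \code{pool_id} and \code{contains_bts}.
#' @param fraction Training fraction (default 0.5).
#' @param seed Integer seed.
#' @return \code{truth} with a \code{split} column (\code{train}/\code{holdout}).
#' @export
split_training <- function(truth, fraction = 0.5, seed = 1L) {
  cls <- split(truth$pool_id, truth$contains_bts)
  if (length(cls) < 2 || any(lengths(cls) < 2)) {
    stop("need at least 2 pools of each class to split")
  }
  train_ids <- with_seed(seed, unlist(lapply(cls, function(ids) {
    sample(ids, floor(length(ids) * fraction))
  }), use.names = FALSE))
  truth$split <- ifelse(truth$pool_id %in% train_ids, "train", "holdout")
  truth
}

#' Train the random-forest classifier of one assay
#'
#' Fits a bagged ensemble (500 trees, one candidate feature per split) on
#' the two intensity channels of one assay's training reactions. The
#' out-of-bag error is the ensemble's internal error estimate from the
#' bootstrap-excluded rows.
#'
#' @param rows Training rows of a single assay (from [assemble_training()]),
#'   with a \code{label} factor.
#' @param mode \code{"corrected"} (use \code{x_corr}/\code{y_corr}) or
#'   \code{"raw"}.
#' @param seed Integer seed (predictions are deterministic given it).
#' @param ntree Number of trees.
#' @return An \code{assay_classifier} list: \code{assay_id}, \code{mode},
#'   \code{forest}, \code{oob_error}, \code{seed}.
#' @export
train_assay_classifier <- function(rows, mode = c("corrected", "raw"),
                                   seed = 1L, ntree = 500L) {
  mode <- match.arg(mode)
  assay <- unique(rows$assay_id)
  if (length(assay) != 1) stop("training rows must belong to a single assay")
  if (nlevels(droplevels(rows$label)) < 2) {
    stop("assay ", assay, ": both classes must be present to train")
  }
  feats <- classifier_features(rows, mode)
  forest <- with_seed(seed, randomForest::randomForest(
    x = feats, y = rows$label, ntree = ntree, mtry = 1L))
  oob <- unname(forest$err.rate[ntree, "OOB"])
  structure(list(assay_id = assay, mode = mode, forest = forest,
                 oob_error = oob, seed = seed),
            class = "assay_classifier")
}

classifier_features <- function(rows, mode) {
  if (mode == "corrected") {
    if (is.null(rows$x_corr)) stop("corrected mode requires x_corr/y_corr columns (run apply_correction)")
    data.frame(x = rows$x_corr, y = rows$y_corr)
  } else {
    data.frame(x = rows$x_raw, y = rows$y_raw)
  }
}

#' Predict presence calls with an assay classifier
#'
#' @param classifier An \code{assay_classifier}.
#' @param rows Reaction rows of the classifier's assay.
#' @return Data frame \code{call} (\code{Het} for contains-BTS, \code{CTS})
#'   and \code{call_probability} (winning-class vote fraction in [0.5, 1]).
#' @export
predict_calls <- function(classifier, rows) {
  feats <- classifier_features(rows, classifier$mode)
  votes <- stats::predict(classifier$forest, feats, type = "prob")
  win <- max.col(votes, ties.method = "first")
  data.frame(
    call = ifelse(colnames(votes)[win] == "BTS", "Het", "CTS"),
    call_probability = votes[cbind(seq_len(nrow(votes)), win)],
    stringsAsFactors = FALSE
  )
}

#' Classification metrics from true and predicted labels
#'
#' Sensitivity is detected contains-BTS reactions over true contains-BTS
#' reactions (true positive rate), specificity the equivalent for all-native
#' reactions, accuracy the overall fraction correct. A metric whose class is
#' absent from \code{truth} is \code{NA}.
#'
#' @param truth Factor/character of true labels (\code{BTS}/\code{CTS}).
#' @param predicted Predicted labels.
#' @return Named list \code{sensitivity}, \code{specificity}, \code{accuracy}.
#' @export
classification_metrics <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  pos <- truth == "BTS"
  list(
    sensitivity = if (any(pos)) mean(predicted[pos] == "BTS") else NA_real_,
    specificity = if (any(!pos)) mean(predicted[!pos] == "CTS") else NA_real_,
    accuracy = mean(predicted == truth)
  )
}

#' Evaluate an assay classifier on hold-out rows
#'
#' @param classifier An \code{assay_classifier}.
#' @param rows Hold-out rows of the same assay, with \code{label}.
#' @return One-row \code{assay_performance} data frame: \code{assay_id},
#'   \code{oob_error}, \code{sensitivity}, \code{specificity},
#'   \code{accuracy}.
#' @export
evaluate_classifier <- function(classifier, rows) {
  if (nrow(rows) == 0) stop("empty holdout for assay ", classifier$assay_id)
  pred <- predict_calls(classifier, rows)
  m <- classification_metrics(rows$label, ifelse(pred$call == "Het", "BTS", "CTS"))
  data.frame(assay_id = classifier$assay_id, oob_error = classifier$oob_error,
             sensitivity = m$sensitivity, specificity = m$specificity,
             accuracy = m$accuracy, stringsAsFactors = FALSE)
}

#' Filter assays on out-of-bag error and sensitivity
#'
#' An assay is dropped iff its OOB error exceeds \code{oob_max} or its
#' hold-out sensitivity falls below \code{sens_min}; boundary values
#' (exactly at either threshold) are retained, matching the strict
#' inequalities of the filtering rule.
#'
#' @param performances \code{assay_performance} data frame.
#' @param oob_max Maximum tolerated OOB error (default 0.05).
#' @param sens_min Minimum tolerated sensitivity (default 0.90).
#' @return \code{performances} with a logical \code{retained} column.
#' @export
filter_assays <- function(performances, oob_max = 0.05, sens_min = 0.90) {
  performances$retained <- !(performances$oob_error > oob_max |
                               performances$sensitivity < sens_min)
  performances
}

#' Beta posterior for a call-correctness proportion
#'
#' Conjugate update of a uniform prior with \code{true_count} correct and
#' \code{false_count} incorrect calls: the proportion's posterior is
#' Beta(true + 1, false + 1). Used for positive and negative predictive
#' values of the trained classifiers.
#'
#' @param true_count,false_count Nonnegative integer counts.
#' @return A \code{call_confidence} list: \code{shape1}, \code{shape2},
#'   \code{median}, \code{ci95} (central 95\% interval).
#' @export
posterior_call_probability <- function(true_count, false_count) {
  stopifnot(true_count >= 0, false_count >= 0)
  a <- true_count + 1
  b <- false_count + 1
  q <- stats::qbeta(c(0.025, 0.5, 0.975), a, b)
  structure(list(shape1 = a, shape2 = b, median = q[2],
                 ci95 = c(low = q[1], high = q[3])),
            class = "call_confidence")
}

#' @export
print.call_confidence <- function(x, ...) {
  cat(sprintf("Beta(%g, %g): median %.4f, 95%% CI (%.4f, %.4f)\n",
              x$shape1, x$shape2, x$median, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Train and evaluate classifiers for every assay
#'
#' Convenience pipeline: splits pools 50/50 (stratified by class), trains a
#' per-assay forest on the training half and evaluates it on the hold-out
#' half.
#'
#' @param records Training-chip fluorescence records (corrected when
#'   \code{mode = "corrected"}).
#' @param truth Pool truth table (\code{pool_id}, \code{contains_bts}).
#' @param mode \code{"corrected"} or \code{"raw"}.
#' @param seed Integer seed for the split and the forests.
#' @param ntree Trees per forest.
#' @return List: \code{models} (named list of \code{assay_classifier}),
#'   \code{performance} (data frame, one row per assay, with
#'   \code{retained} flag from [filter_assays()] defaults), \code{split}.
#' @export
train_assay_classifiers <- function(records, truth, mode = c("corrected", "raw"),
                                    seed = 1L, ntree = 500L) {
  mode <- match.arg(mode)
  split <- split_training(truth, 0.5, seed)
  rows <- assemble_training(records, truth)
  rows$split <- split$split[match(rows$pool_id, split$pool_id)]
  by_assay <- split(rows, rows$assay_id)
  models <- list()
  perf <- vector("list", length(by_assay))
  for (i in seq_along(by_assay)) {
    a <- by_assay[[i]]
    clf <- train_assay_classifier(a[a$split == "train", ], mode, seed = seed + i, ntree = ntree)
    models[[clf$assay_id]] <- clf
    perf[[i]] <- evaluate_classifier(clf, a[a$split == "holdout", ])
  }
  performance <- filter_assays(do.call(rbind, perf))
  list(models = models, performance = performance, split = split)
}
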