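# Chip-specific control correction and background variance decomposition.
#
# Each chip carries homozygous controls of both parental types. A control
# that is homozygous for one allele should show no fluorescence in the other
# channel, so its absent-channel intensity measures that chip's background.
# The correction assumes this false-positive fluorescence is uniform across
# assays on a chip: one scalar per channel per chip is subtracted everywhere.

#' Estimate per-chip background from homozygous controls
#'
#' \code{b_y} is the mean raw Y (non-native) intensity over all CTS-control
#' reactions on the chip, pooling assays and replicates; \code{b_x} likewise
#' from BTS controls. No-template controls are excluded: backgrounds come
#' from homozygous DNA, and NTCs are reserved for sanity checks.
#'
#' @param records Fluorescence records of a single chip.
#' @return One-row data frame: \code{chip_id}, \code{b_x}, \code{b_y},
#'   \code{n_controls_x}, \code{n_controls_y}.
#' @export
estimate_background <- function(records) {
  chip <- unique(records$chip_id)
  if (length(chip) != 1) stop("estimate_background expects records of one chip")
  cts <- records[records$sample_type == "CTS_CONTROL", ]
  bts <- records[records$sample_type == "BTS_CONTROL", ]
  if (nrow(cts) == 0) stop("chip ", chip, " has no CTS controls; cannot estimate Y background")
  if (nrow(bts) == 0) stop("chip ", chip, " has no BTS controls; cannot estimate X background")
  data.frame(chip_id = chip,
             b_x = mean(bts$x_raw), b_y = mean(cts$y_raw),
             n_controls_x = nrow(bts), n_controls_y = nrow(cts),
             stringsAsFactors = FALSE)
}

#' Estimate backgrounds for every chip in a record set
#'
#' @param records Fluorescence records (any number of chips).
#' @return Data frame with one row per chip (see [estimate_background()]).
#' @export
estimate_backgrounds <- function(records) {
  out <- lapply(split(records, records$chip_id), estimate_background)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply chip-specific control correction
#'
#' Subtracts each chip's background from every reaction on that chip:
#' \code{y_corr = y_raw - b_y(chip)}, \code{x_corr = x_raw - b_x(chip)}.
#' Corrected values may be negative; clipping would distort the
#' class-conditional intensity distributions the classifiers learn. By
#' construction the corrected Y channel averages exactly zero over each
#' chip's CTS controls, and the corrected X channel over its BTS controls.
#'
#' @param records Fluorescence records.
#' @param backgrounds Data frame from [estimate_backgrounds()] (computed
#'   from \code{records} when omitted).
#' @return \code{records} with \code{x_corr} and \code{y_corr} columns.
#' @export
apply_correction <- function(records, backgrounds = estimate_backgrounds(records)) {
  idx <- match(records$chip_id, backgrounds$chip_id)
  if (anyNA(idx)) {
    stop("no background estimate for chip(s): ",
         paste(unique(records$chip_id[is.na(idx)]), collapse = ", "))
  }
  records$x_corr <- records$x_raw - backgrounds$b_x[idx]
  records$y_corr <- records$y_raw - backgrounds$b_y[idx]
  records
}

#' One-way variance decomposition of background intensity
#'
#' Fixed-effects one-way ANOVA of raw absent-allele background intensity
#' grouped by chip or by assay. The Y channel uses CTS controls (which carry
#' no Y allele) and the X channel uses BTS controls. Effect size is
#' \eqn{\eta^2 = SS_{between} / SS_{total}}; with a single factor this equals
#' partial \eqn{\eta^2}.
#'
#' @param records Control fluorescence records spanning several chips.
#' @param factor_name Grouping factor, \code{"chip"} or \code{"assay"}.
#' @param channel \code{"y"} (non-native background in CTS controls) or
#'   \code{"x"} (native background in BTS controls).
#' @return A \code{variance_decomposition} list: \code{factor},
#'   \code{channel}, \code{f_stat}, \code{df_between}, \code{df_within},
#'   \code{eta_squared}, \code{p_value}.
#' @export
variance_decomposition <- function(records, factor_name = c("assay", "chip"),
                                   channel = c("y", "x")) {
  factor_name <- match.arg(factor_name)
  channel <- match.arg(channel)
  ctrl_type <- if (channel == "y") "CTS_CONTROL" else "BTS_CONTROL"
  df <- records[records$sample_type == ctrl_type, ]
  if (nrow(df) == 0) stop("no ", ctrl_type, " records to decompose")
  value <- if (channel == "y") df$y_raw else df$x_raw
  group <- factor(if (factor_name == "chip") df$chip_id else df$assay_id)
  if (nlevels(group) < 2) stop("need at least 2 levels of ", factor_name)
  if (any(table(group) < 2)) stop("need at least 2 observations per ", factor_name, " level")
  if (stats::var(value) == 0) {
    warning("zero total variance; eta squared defined as 0")
    return(structure(list(factor = factor_name, channel = channel,
                          f_stat = NA_real_, df_between = nlevels(group) - 1L,
                          df_within = length(value) - nlevels(group),
                          eta_squared = 0, p_value = NA_real_),
                     class = "variance_decomposition"))
  }
  tab <- stats::anova(stats::lm(value ~ group))
  ss_b <- tab$`Sum Sq`[1]
  ss_w <- tab$`Sum Sq`[2]
  structure(list(factor = factor_name, channel = channel,
                 f_stat = tab$`F value`[1],
                 df_between = tab$Df[1], df_within = tab$Df[2],
                 eta_squared = ss_b / (ss_b + ss_w),
                 p_value = tab$`Pr(>F)`[1]),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("one-way ANOVA by %s (%s channel): F = %.3f, df = (%d, %d), eta^2 = %.3f, p = %.3g\n",
              x$factor, x$channel, x$f_stat, x$df_between, x$df_within,
              x$eta_squared, x$p_value))
  invisible(x)
}
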