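# Data model and file I/O for SNP panels, chip layouts, fluorescence exports,
# pool manifests and call reports, plus the pooling planner.

CONTROL_TYPES <- c("CTS_CONTROL", "BTS_CONTROL", "NTC")
SAMPLE_TYPES <- c("POOL", CONTROL_TYPES)

#' Read a diagnostic SNP assay panel
#'
#' A panel is a tab-delimited file with one row per assay and columns
#' \code{assay_id}, \code{locus_name}, \code{x_allele}, \code{y_allele},
#' \code{flank_5}, \code{flank_3}. The X allele is the native (CTS) allele
#' and the Y allele the non-native (BTS) allele of each diagnostic SNP.
#'
#' @param path Path to the panel TSV.
#' @param version Panel version string recorded on the returned object so
#'   downstream call reports can state which panel produced them.
#' @return An \code{assay_panel}: a data frame of assays (input order
#'   preserved) with attribute \code{version}.
#' @export
read_panel <- function(path, version = "1") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("assay_id", "locus_name", "x_allele", "y_allele", "flank_5", "flank_3")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("panel file is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("panel file '", path, "' contains no assays")
    return(new_assay_panel(df[required], version))
  }
  new_assay_panel(df[required], version)
}

#' Construct a validated assay panel from a data frame
#'
#' @param assays Data frame with columns \code{assay_id}, \code{locus_name},
#'   \code{x_allele}, \code{y_allele}, \code{flank_5}, \code{flank_3}.
#' @param version Panel version string.
#' @return An \code{assay_panel} data frame.
#' @export
new_assay_panel <- function(assays, version = "1") {
  assays <- as.data.frame(assays, stringsAsFactors = FALSE)
  if (nrow(assays) > 0) {
    dup <- assays$assay_id[duplicated(assays$assay_id)]
    if (length(dup) > 0) {
      stop("duplicate assay_id in panel: ", paste(unique(dup), collapse = ", "))
    }
    bad_base <- !(assays$x_allele %in% c("A", "C", "G", "T")) |
      !(assays$y_allele %in% c("A", "C", "G", "T"))
    if (any(bad_base)) {
      stop("non-ACGT allele base for assay(s): ",
           paste(assays$assay_id[bad_base], collapse = ", "))
    }
    same <- assays$x_allele == assays$y_allele
    if (any(same)) {
      stop("identical X and Y allele bases for assay(s): ",
           paste(assays$assay_id[same], collapse = ", "))
    }
  }
  rownames(assays) <- NULL
  structure(assays, version = as.character(version), class = c("assay_panel", "data.frame"))
}

#' Write an assay panel to a TSV file
#'
#' @param panel An \code{assay_panel}.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Lay out pools and controls on a 96 x 96 chip
#'
#' Builds the sample-side and assay-side well assignments of one integrated
#' fluidic circuit run. The 96 sample wells take up to 90 pools (wells 1
#' upward, row-major) followed by fixed control positions: native homozygote
#' (CTS) controls in wells 91-92, non-native homozygote (BTS) controls in
#' 93-94 and no-template controls in 95-96; unassigned wells are EMPTY.
#' Each panel assay occupies two assay wells as technical replicates,
#' replicate 1 in the lower-numbered well.
#'
#' @param pool_ids Character vector of up to 90 pool identifiers.
#' @param panel An \code{assay_panel} of at most 48 assays.
#' @param chip_id Chip identifier string.
#' @return A \code{chip_layout} list with elements \code{chip_id},
#'   \code{sample_wells} (96-long character vector of pool ids or control
#'   types), \code{assay_wells} (data frame well/assay_id/replicate) and
#'   \code{n_reactions} (occupied sample wells x 96).
#' @export
build_chip_layout <- function(pool_ids, panel, chip_id) {
  pool_ids <- as.character(pool_ids)
  if (length(pool_ids) > 90) {
    stop("a chip holds at most 90 pools alongside its 6 controls; got ",
         length(pool_ids))
  }
  if (nrow(panel) > 48) {
    stop("a duplicated panel holds at most 48 assays; got ", nrow(panel))
  }
  if (anyDuplicated(pool_ids)) stop("duplicate pool ids on one chip")
  sample_wells <- rep("EMPTY", 96)
  if (length(pool_ids) > 0) sample_wells[seq_along(pool_ids)] <- pool_ids
  sample_wells[91:92] <- "CTS_CONTROL"
  sample_wells[93:94] <- "BTS_CONTROL"
  sample_wells[95:96] <- "NTC"
  n_assays <- nrow(panel)
  assay_wells <- data.frame(
    well = seq_len(96),
    assay_id = NA_character_,
    replicate = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (n_assays > 0) {
    idx <- seq_len(2 * n_assays)
    assay_wells$assay_id[idx] <- rep(panel$assay_id, each = 2)
    assay_wells$replicate[idx] <- rep(c(1L, 2L), times = n_assays)
  }
  occupied <- sum(sample_wells != "EMPTY")
  structure(
    list(chip_id = as.character(chip_id), sample_wells = sample_wells,
         assay_wells = assay_wells, n_reactions = occupied * 96L),
    class = "chip_layout"
  )
}

#' @export
print.chip_layout <- function(x, ...) {
  n_pools <- sum(!x$sample_wells %in% c("EMPTY", CONTROL_TYPES))
  n_assays <- length(unique(stats::na.omit(x$assay_wells$assay_id)))
  cat("chip_layout", x$chip_id, ":", n_pools, "pools + 6 controls,",
      n_assays, "assays in duplicate,", x$n_reactions, "reactions\n")
  invisible(x)
}

#' Plan DNA pools from per-pond tissue counts
#'
#' Within each pond, tissues are chunked into pools of \code{pool_max}
#' individuals with one remainder pool. Remainder (or whole-pond) pools
#' smaller than \code{merge_below} are merged pairwise across ponds into
#' mixed-pond pools where the combined size stays within \code{pool_max}:
#' the smallest eligible remainder is merged with the smallest partner that
#' fits, ties broken by pond id.
#'
#' @param pond_counts Named integer vector or list, tissue count per pond.
#' @param pool_max Maximum individuals per pool (default 15).
#' @param merge_below Remainders below this size are candidates for
#'   cross-pond merging (default 10).
#' @return A \code{pool_plan} list with \code{pools} (list of pool manifests:
#'   pool_id, pond_ids, individual_ids, mixed_pond) and \code{unpooled}
#'   (character vector, empty by construction).
#' @export
plan_pools <- function(pond_counts, pool_max = 15L, merge_below = 10L) {
  pond_counts <- unlist(pond_counts)
  if (length(pond_counts) == 0) {
    return(structure(list(pools = list(), unpooled = character(0)),
                     class = "pool_plan"))
  }
  if (is.null(names(pond_counts)) || any(names(pond_counts) == "")) {
    stop("pond_counts must be named by pond id")
  }
  if (any(pond_counts < 0)) stop("tissue counts must be nonnegative")
  pond_counts <- pond_counts[pond_counts > 0]
  ponds <- sort(names(pond_counts))

  full <- list()      # completed single-pond pools
  remnants <- list()  # pond remainders eligible for merging or self-pooling
  for (pond in ponds) {
    n <- pond_counts[[pond]]
    ids <- sprintf("%s_%03d", pond, seq_len(n))
    n_full <- n %/% pool_max
    for (k in seq_len(n_full)) {
      full[[length(full) + 1L]] <- list(
        pond_ids = pond,
        individual_ids = ids[((k - 1L) * pool_max + 1L):(k * pool_max)]
      )
    }
    rem <- n %% pool_max
    if (rem > 0) {
      remnants[[length(remnants) + 1L]] <- list(
        pond_ids = pond,
        individual_ids = ids[(n_full * pool_max + 1L):n]
      )
    }
  }

  # merge small remainders pairwise: smallest first, with the smallest
  # partner that keeps the merged pool within pool_max
  sizes <- vapply(remnants, function(r) length(r$individual_ids), integer(1))
  ord <- order(sizes, vapply(remnants, function(r) r$pond_ids[1], character(1)))
  remnants <- remnants[ord]
  merged <- list()
  while (length(remnants) > 0) {
    cur <- remnants[[1]]
    remnants <- remnants[-1]
    cur_n <- length(cur$individual_ids)
    if (cur_n < merge_below && length(remnants) > 0) {
      partner_sizes <- vapply(remnants, function(r) length(r$individual_ids), integer(1))
      fits <- which(partner_sizes < merge_below & cur_n + partner_sizes <= pool_max)
      if (length(fits) > 0) {
        j <- fits[1]  # remnants are size-then-pond ordered, so first fit is smallest
        partner <- remnants[[j]]
        remnants <- remnants[-j]
        cur <- list(
          pond_ids = sort(c(cur$pond_ids, partner$pond_ids)),
          individual_ids = c(cur$individual_ids, partner$individual_ids)
        )
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }

  pools <- c(full, merged)
  pools <- lapply(seq_along(pools), function(i) {
    p <- pools[[i]]
    list(pool_id = sprintf("pool_%04d", i),
         pond_ids = p$pond_ids,
         individual_ids = p$individual_ids,
         mixed_pond = length(p$pond_ids) > 1)
  })
  structure(list(pools = pools, unpooled = character(0)), class = "pool_plan")
}

#' @export
print.pool_plan <- function(x, ...) {
  sizes <- vapply(x$pools, function(p) length(p$individual_ids), integer(1))
  cat("pool_plan:", length(x$pools), "pools,",
      sum(sizes), "individuals,", sum(vapply(x$pools, `[[`, logical(1), "mixed_pond")),
      "mixed-pond\n")
  invisible(x)
}

fluor_columns <- c("chip_id", "sample_well", "assay_well", "assay_id",
                   "replicate", "sample_id", "sample_type", "x_raw", "y_raw")

#' Read a fluorescence export
#'
#' One row per sealed reaction: a (sample well x assay well) intersection on
#' one chip with its raw X-allele (native) and Y-allele (non-native)
#' endpoint intensities. Columns: \code{chip_id, sample_well, assay_well,
#' assay_id, replicate, sample_id, sample_type, x_raw, y_raw}; corrected
#' columns \code{x_corr}/\code{y_corr} are read back when present.
#'
#' @param path Path to the CSV export.
#' @return Data frame of fluorescence records.
#' @export
read_fluorescence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(fluor_columns, names(df))
  if (length(missing) > 0) {
    stop("fluorescence export is missing columns: ", paste(missing, collapse = ", "))
  }
  validate_fluorescence(df)
  df
}

validate_fluorescence <- function(df) {
  bad <- which(df$x_raw < 0 | df$y_raw < 0)
  if (length(bad) > 0) {
    stop("negative raw intensity at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  unknown <- which(!df$sample_type %in% SAMPLE_TYPES)
  if (length(unknown) > 0) {
    stop("unknown sample_type '", df$sample_type[unknown[1]],
         "' at row ", unknown[1])
  }
  key <- paste(df$chip_id, df$sample_well, df$assay_well)
  if (anyDuplicated(key)) {
    stop("duplicate (chip_id, sample_well, assay_well) at row ",
         which(duplicated(key))[1])
  }
  invisible(df)
}

#' Write fluorescence records to CSV
#'
#' @param records Fluorescence record data frame.
#' @param path Output path.
#' @export
write_fluorescence <- function(records, path) {
  cols <- c(fluor_columns, intersect(c("x_corr", "y_corr"), names(records)))
  utils::write.csv(records[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read pool-level call reports
#'
#' The report has one row per (pool x assay): both technical-replicate calls
#' (\code{Het}, \code{CTS} or \code{missing}), their call probabilities, and
#' the row status.
#'
#' @param calls Pool call data frame (see [call_pools()]).
#' @param path CSV path.
#' @return \code{read_calls} returns the call data frame.
#' @export
write_calls <- function(calls, path) {
  cols <- c("pool_id", "assay_id", "replicate1_call", "replicate2_call",
            "call_probability_1", "call_probability_2", "status")
  missing <- setdiff(cols, names(calls))
  if (length(missing) > 0) stop("call table missing columns: ", paste(missing, collapse = ", "))
  utils::write.csv(calls[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(call_probability_1 = "numeric",
                                 call_probability_2 = "numeric"))
}

#' Write and read pool manifests
#'
#' Columns: \code{pool_id}, \code{pond_ids} (semicolon-joined),
#' \code{individual_ids} (semicolon-joined).
#'
#' @param plan A \code{pool_plan} or list of pool manifests.
#' @param path CSV path.
#' @export
write_pool_manifest <- function(plan, path) {
  pools <- if (inherits(plan, "pool_plan")) plan$pools else plan
  df <- data.frame(
    pool_id = vapply(pools, `[[`, character(1), "pool_id"),
    pond_ids = vapply(pools, function(p) paste(p$pond_ids, collapse = ";"), character(1)),
    individual_ids = vapply(pools, function(p) paste(p$individual_ids, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pool_manifest
#' @export
read_pool_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    ponds <- strsplit(df$pond_ids[i], ";", fixed = TRUE)[[1]]
    inds <- strsplit(df$individual_ids[i], ";", fixed = TRUE)[[1]]
    if (length(inds) < 1 || length(inds) > 15) {
      stop("pool ", df$pool_id[i], " has ", length(inds),
           " individuals; expected 1-15")
    }
    list(pool_id = df$pool_id[i], pond_ids = ponds, individual_ids = inds,
         mixed_pond = length(ponds) > 1)
  })
}
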