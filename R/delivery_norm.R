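#' Normalized delivery
#'
#' The screen's core score. Each sorted sample's barcode proportions are
#' divided by the injected input pool's proportions (so a score above 1
#' means the LNP reached that population more than expected from its pool
#' abundance) and rescaled so retained LNP scores sum to 100 per sample. The
#' naked (unencapsulated) control barcode is excluded from the rescaling
#' denominator and reported separately, so its inefficiency does not inflate
#' LNP scores; it serves as a delivery floor.
#'
#' @name delivery_norm
NULL

#' QC thresholds for normalized delivery
#'
#' @param min_input_prop Minimum input-pool proportion for a barcode to be
#'   retained; `NULL` defaults to half the uniform expectation
#'   (`0.5 / n_barcodes`). Inclusive bound.
#' @param min_sample_reads Minimum assigned reads for a sample to be
#'   retained (inclusive).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_input_prop = NULL, min_sample_reads = 1e4) {
  structure(list(min_input_prop = min_input_prop,
                 min_sample_reads = min_sample_reads),
            class = "qc_thresholds")
}

#' Convert a counts column to proportions
#'
#' @param counts_column Nonnegative numeric vector.
#' @return The vector divided by its total (sums to 1). An all-zero column is
#'   a degenerate sample the caller must exclude; this function errors on it.
#' @export
proportions_column <- function(counts_column) {
  if (any(counts_column < 0)) stop("counts must be nonnegative")
  tot <- sum(counts_column)
  if (tot <= 0) stop("all-zero counts column: sample must be flagged and excluded")
  counts_column / tot
}

#' QC flags for a barcode count table
#'
#' @param counts A [barcode_counts()] table (the input-pool column is
#'   identified from `sample_meta$is_input`).
#' @param thresholds A [qc_thresholds()].
#' @return A list: `sample_pass` (named logical; input excluded), `barcode_pass`
#'   (named logical, from input-pool representation), `input_proportions`,
#'   and a `log` character vector of exclusions with reasons.
#' @export
apply_qc <- function(counts, thresholds = qc_thresholds()) {
  stopifnot(inherits(counts, "barcode_counts"))
  meta <- counts$sample_meta
  input_cols <- meta$sample_id[which(meta$is_input)]
  if (!length(input_cols)) stop("no input-pool sample in the table")
  input_counts <- rowSums(counts$counts[, input_cols, drop = FALSE])
  if (sum(input_counts) <= 0) stop("input pool has zero reads")
  input_props <- input_counts / sum(input_counts)

  min_prop <- thresholds$min_input_prop %||% (0.5 / nrow(counts$counts))
  barcode_pass <- input_props >= min_prop

  sample_cols <- setdiff(colnames(counts$counts), input_cols)
  totals <- colSums(counts$counts[, sample_cols, drop = FALSE])
  sample_pass <- totals >= thresholds$min_sample_reads & totals > 0

  log <- c(
    if (any(!barcode_pass)) sprintf(
      "barcode %s excluded: input-pool proportion %.2e < %.2e",
      names(which(!barcode_pass)), input_props[!barcode_pass], min_prop),
    if (any(!sample_pass)) sprintf(
      "sample %s excluded: %d assigned reads < %g",
      names(which(!sample_pass)), as.integer(totals[!sample_pass]),
      thresholds$min_sample_reads)
  )
  list(sample_pass = sample_pass, barcode_pass = barcode_pass,
       input_proportions = input_props, log = log %||% character(0))
}

#' Normalized delivery for one sample
#'
#' @param sample_props Barcode proportions in the sorted sample.
#' @param input_pool_props Barcode proportions in the injected input pool
#'   (same barcode index; must be > 0 for retained barcodes).
#' @return Per-barcode scores on the percent scale, summing to 100.
#' @examples
#' normalized_delivery(c(0.5, 0.3, 0.2), c(0.25, 0.25, 0.5))
#' # 55.56 33.33 11.11
#' @export
normalized_delivery <- function(sample_props, input_pool_props) {
  if (length(sample_props) != length(input_pool_props)) {
    stop("sample and input-pool vectors must share the barcode index")
  }
  if (any(input_pool_props <= 0)) {
    stop("input-pool proportion is zero for a retained barcode; ",
         "apply QC before normalizing")
  }
  ratio <- sample_props / input_pool_props
  tot <- sum(ratio)
  if (tot <= 0) return(ratio * 0)
  100 * ratio / tot
}

#' Normalized delivery table from a barcode count table
#'
#' Applies QC, computes per-sample normalized delivery over retained LNP
#' barcodes (the naked control is scored against the same input pool but
#' excluded from the 100-sum rescaling and reported separately), and maps
#' barcodes to design IDs.
#'
#' @param counts A [barcode_counts()] table including an input-pool sample.
#' @param library The `lnp_library` (supplies the barcode-to-design map and
#'   the naked control barcode ID).
#' @param thresholds A [qc_thresholds()].
#' @return An `nd_table`: `nd` (matrix, retained LNP barcodes x retained
#'   samples, columns sum to 100), `naked_control_nd` (per-sample unscaled
#'   ratio of the control, plus `naked_control_pct` on the LNP percent scale
#'   for comparison), `sample_meta`, `design_map`, `qc` (flags + log).
#' @export
normalized_delivery_table <- function(counts, library,
                                      thresholds = qc_thresholds()) {
  stopifnot(inherits(counts, "barcode_counts"), inherits(library, "lnp_library"))
  qc <- apply_qc(counts, thresholds)
  meta <- counts$sample_meta
  naked <- library$naked_control_barcode

  lnp_bc <- intersect(rownames(counts$counts),
                      library$designs$barcode_id[library$designs$pooled])
  retained_bc <- lnp_bc[qc$barcode_pass[lnp_bc]]
  if (!length(retained_bc)) stop("no LNP barcodes pass input-pool QC")
  samples <- names(which(qc$sample_pass))

  input_props <- qc$input_proportions
  nd <- matrix(NA_real_, length(retained_bc), length(samples),
               dimnames = list(retained_bc, samples))
  naked_ratio <- stats::setNames(rep(NA_real_, length(samples)), samples)
  naked_pct <- naked_ratio
  has_naked <- naked %in% rownames(counts$counts) && isTRUE(qc$barcode_pass[naked])

  for (s in samples) {
    col <- counts$counts[, s]
    props <- proportions_column(col)
    nd[, s] <- normalized_delivery(props[retained_bc], input_props[retained_bc])
    if (has_naked) {
      naked_ratio[s] <- props[naked] / input_props[naked]
      lnp_ratio_sum <- sum(props[retained_bc] / input_props[retained_bc])
      naked_pct[s] <- if (lnp_ratio_sum > 0) 100 * naked_ratio[s] / lnp_ratio_sum else NA_real_
    }
  }
  design_map <- library$designs[match(retained_bc, library$designs$barcode_id),
                                c("design_id", "barcode_id")]
  structure(list(
    nd = nd,
    naked_control_nd = naked_ratio,
    naked_control_pct = naked_pct,
    sample_meta = meta[match(samples, meta$sample_id), , drop = FALSE],
    design_map = design_map,
    qc = qc
  ), class = "nd_table")
}

#' @export
print.nd_table <- function(x, ...) {
  cat(sprintf("nd_table: %d LNPs x %d samples (columns sum to 100)\n",
              nrow(x$nd), ncol(x$nd)))
  if (length(x$qc$log)) cat(sprintf("  %d QC exclusions\n", length(x$qc$log)))
  invisible(x)
}

#' Aggregate normalized delivery across replicate mice
#'
#' Mean and SEM (sd / sqrt(n)) per LNP per cell type over mice with retained
#' samples. SEM is `NA` when only one mouse contributes.
#'
#' @param nd_table An `nd_table` from [normalized_delivery_table()].
#' @return A list of matrices `mean`, `sem`, `n` (LNP barcodes x cell types)
#'   plus `cell_types` (data.frame with tissue lookup) and `design_map`.
#' @export
aggregate_mice <- function(nd_table) {
  stopifnot(inherits(nd_table, "nd_table"))
  meta <- nd_table$sample_meta
  cts <- unique(meta[!meta$is_input, c("tissue", "cell_type")])
  cts <- cts[!is.na(cts$cell_type), , drop = FALSE]
  if (!nrow(cts)) stop("no cell-type samples retained")
  mean_m <- sem_m <- n_m <- matrix(
    NA_real_, nrow(nd_table$nd), nrow(cts),
    dimnames = list(rownames(nd_table$nd), cts$cell_type))
  for (j in seq_len(nrow(cts))) {
    cols <- meta$sample_id[!is.na(meta$cell_type) & meta$cell_type == cts$cell_type[j]]
    vals <- nd_table$nd[, cols, drop = FALSE]
    n <- rowSums(!is.na(vals))
    mu <- rowMeans(vals, na.rm = TRUE)
    sdv <- apply(vals, 1, stats::sd, na.rm = TRUE)
    mean_m[, j] <- mu
    sem_m[, j] <- ifelse(n > 1, sdv / sqrt(n), NA_real_)
    n_m[, j] <- n
  }
  list(mean = mean_m, sem = sem_m, n = n_m, cell_types = cts,
       design_map = nd_table$design_map)
}

#' Write normalized delivery tables to CSV
#' @param nd_table An `nd_table`.
#' @param nd_path Per-sample ND CSV path.
#' @param aggregated_path Optional aggregated (mean/SEM/n per cell type) CSV.
#' @export
write_nd_table <- function(nd_table, nd_path, aggregated_path = NULL) {
  stopifnot(inherits(nd_table, "nd_table"))
  utils::write.csv(data.frame(barcode_id = rownames(nd_table$nd), nd_table$nd,
                              check.names = FALSE),
                   nd_path, row.names = FALSE)
  if (!is.null(aggregated_path)) {
    agg <- aggregate_mice(nd_table)
    long <- do.call(rbind, lapply(colnames(agg$mean), function(ct) {
      data.frame(barcode_id = rownames(agg$mean), cell_type = ct,
                 mean = agg$mean[, ct], sem = agg$sem[, ct], n = agg$n[, ct],
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(long, aggregated_path, row.names = FALSE)
  }
  invisible(nd_table)
}
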