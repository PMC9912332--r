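#' Barcode extraction and counting
#'
#' Turns barcode-tagged amplicon reads into a barcodes x samples count
#' table. A read is assigned to the unique library barcode within
#' `max_mismatch` Hamming distance of its barcode window (exact matches
#' first); ambiguous or anchor-failing reads are counted as unassigned, so
#' `assigned + unassigned = reads in` always holds per sample.
#'
#' @name barcode_quant
NULL

#' Barcode read-layout specification
#'
#' @param offset 0-based position of the barcode start within the read.
#' @param length Barcode length (nt).
#' @param upstream_anchor,downstream_anchor Optional flanking sequences that
#'   must match (within `anchor_max_mismatch`) for a read to be assigned.
#' @param max_mismatch Maximum Hamming distance for barcode rescue. For
#'   unambiguous assignment keep `max_mismatch < min_pairwise_hamming / 2`
#'   of the library.
#' @param anchor_max_mismatch Per-anchor mismatch budget.
#' @return A `barcode_spec` list.
#' @export
barcode_spec <- function(offset = 8L, length = 8L,
                         upstream_anchor = "TCAGACGT",
                         downstream_anchor = "AGTCGTAC",
                         max_mismatch = 1L,
                         anchor_max_mismatch = 1L) {
  if (length < 1L) stop("barcode length must be >= 1")
  if (offset < 0L) stop("offset must be >= 0")
  if (max_mismatch < 0L || anchor_max_mismatch < 0L) stop("mismatch budgets must be >= 0")
  structure(list(offset = as.integer(offset), length = as.integer(length),
                 upstream_anchor = upstream_anchor,
                 downstream_anchor = downstream_anchor,
                 max_mismatch = as.integer(max_mismatch),
                 anchor_max_mismatch = as.integer(anchor_max_mismatch)),
            class = "barcode_spec")
}

#' Barcode count table
#'
#' @param counts Nonnegative integer matrix, barcodes x samples.
#' @param sample_meta Data.frame with one row per sample: `sample_id`,
#'   `mouse`, `tissue`, `cell_type`, `is_input`.
#' @param unassigned Named integer vector of unassigned reads per sample
#'   (defaults to zeros).
#' @return A `barcode_counts` object.
#' @export
barcode_counts <- function(counts, sample_meta,
                           unassigned = stats::setNames(
                             integer(ncol(counts)), colnames(counts))) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts needs barcode rownames and sample colnames")
  }
  if (!identical(sort(colnames(counts)), sort(sample_meta$sample_id))) {
    stop("sample_meta does not match count columns")
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(counts = counts, sample_meta = sample_meta,
                 unassigned = unassigned[colnames(counts)]),
            class = "barcode_counts")
}

#' @export
print.barcode_counts <- function(x, ...) {
  cat(sprintf("barcode_counts: %d barcodes x %d samples (%s unassigned reads)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$unassigned))))
  invisible(x)
}

# Anchor check for a batch of reads: TRUE where the window at [start, end]
# matches `anchor` within `budget` mismatches. Reads shorter than the window
# fail.
anchor_ok <- function(reads, anchor, start, budget) {
  if (is.null(anchor) || !nchar(anchor)) return(rep(TRUE, length(reads)))
  w <- nchar(anchor)
  window <- substr(reads, start, start + w - 1L)
  ok <- nchar(window) == w
  if (!any(ok)) return(ok)
  achars <- strsplit(anchor, "")[[1]]
  mm <- integer(length(reads))
  wm <- seq_char_matrix(window[ok], width = w)
  mm[ok] <- rowSums(wm != matrix(achars, nrow(wm), w, byrow = TRUE))
  ok & (mm <= budget)
}

# Vectorised assignment of reads to barcode IDs; returns a character vector
# with NA for unassigned reads.
assign_reads <- function(reads, spec, barcode_seqs) {
  n <- length(reads)
  out <- rep(NA_character_, n)
  if (!n) return(out)
  ids <- names(barcode_seqs)
  start <- spec$offset + 1L

  long_enough <- nchar(reads) >= spec$offset + spec$length
  ok <- long_enough &
    anchor_ok(reads, spec$upstream_anchor,
              start - nchar(spec$upstream_anchor %||% ""), spec$anchor_max_mismatch) &
    anchor_ok(reads, spec$downstream_anchor,
              start + spec$length, spec$anchor_max_mismatch)
  if (!any(ok)) return(out)

  window <- substr(reads[ok], start, start + spec$length - 1L)
  hit <- match(window, unname(barcode_seqs))
  res <- ifelse(is.na(hit), NA_character_, ids[hit])

  if (spec$max_mismatch > 0L && anyNA(hit)) {
    miss <- which(is.na(hit))
    uniq <- unique(window[miss])
    umat <- seq_char_matrix(unname(barcode_seqs), width = spec$length)
    qmat <- seq_char_matrix(uniq, width = spec$length)
    d <- hamming_to_universe(qmat, umat)
    best <- apply(d, 1, min)
    # unique nearest barcode within budget; ties are left unassigned
    n_best <- rowSums(d == best)
    assignable <- best <= spec$max_mismatch & n_best == 1L
    lut <- rep(NA_character_, length(uniq))
    lut[assignable] <- ids[apply(d[assignable, , drop = FALSE], 1, which.min)]
    res[miss] <- lut[match(window[miss], uniq)]
  }
  out[ok] <- res
  out
}

#' Extract the barcode ID from a single read
#'
#' Exact matches win; otherwise the unique barcode within `max_mismatch`
#' Hamming distance of the barcode window is returned. Reads that are too
#' short, fail an anchor, exceed the mismatch budget, or sit at equal
#' minimal distance from two barcodes return `NA` (unassigned).
#'
#' @param read_sequence Read sequence(s) as character.
#' @param spec A [barcode_spec()].
#' @param barcode_universe Named character vector of barcode sequences
#'   (names are barcode IDs).
#' @return Barcode ID per read, `NA` when unassigned.
#' @export
extract_barcode <- function(read_sequence, spec, barcode_universe) {
  stopifnot(inherits(spec, "barcode_spec"))
  if (!length(barcode_universe) || is.null(names(barcode_universe))) {
    stop("barcode_universe must be a named character vector")
  }
  assign_reads(as.character(read_sequence), spec, barcode_universe)
}

#' Count barcodes across FASTQ samples
#'
#' @param sample_sheet Data.frame mapping each FASTQ to its sample: columns
#'   `fastq`, `sample_id`, and the metadata columns `mouse`, `tissue`,
#'   `cell_type`, `is_input` (missing metadata columns are filled with NA).
#' @param spec A [barcode_spec()].
#' @param library The `lnp_library` whose barcodes define the universe
#'   (pooled designs plus the naked control; zero rows are kept).
#' @return A [barcode_counts()] table with per-sample unassigned-read counts.
#' @export
count_barcodes <- function(sample_sheet, spec, library) {
  stopifnot(inherits(spec, "barcode_spec"), inherits(library, "lnp_library"))
  if (is.null(library$barcodes)) stop("library must have barcodes assigned")
  if (!all(c("fastq", "sample_id") %in% names(sample_sheet))) {
    stop("sample sheet needs fastq and sample_id columns")
  }
  if (!is.na(library$min_pairwise_hamming) &&
      spec$max_mismatch >= library$min_pairwise_hamming / 2) {
    warning("max_mismatch >= min_pairwise_hamming/2: nearest-barcode ",
            "assignment may be ambiguous")
  }
  universe <- library$barcodes
  counts <- matrix(0L, nrow = length(universe), ncol = nrow(sample_sheet),
                   dimnames = list(names(universe), sample_sheet$sample_id))
  unassigned <- stats::setNames(integer(nrow(sample_sheet)), sample_sheet$sample_id)

  for (i in seq_len(nrow(sample_sheet))) {
    fp <- sample_sheet$fastq[i]
    reads <- tryCatch(
      as.character(Biostrings::readDNAStringSet(fp, format = "fastq")),
      error = function(e) stop(sprintf("FASTQ parse failure in '%s': %s",
                                       fp, conditionMessage(e)), call. = FALSE)
    )
    ids <- assign_reads(reads, spec, universe)
    tab <- table(factor(ids, levels = names(universe)))
    counts[, i] <- as.integer(tab)
    unassigned[i] <- sum(is.na(ids))
  }
  for (col in c("mouse", "tissue", "cell_type", "is_input")) {
    if (is.null(sample_sheet[[col]])) sample_sheet[[col]] <- NA
  }
  meta <- sample_sheet[, c("sample_id", "mouse", "tissue", "cell_type", "is_input")]
  barcode_counts(counts, meta, unassigned)
}

#' Write a barcode count table (counts + sample metadata) to CSV
#' @param x A [barcode_counts()] object.
#' @param counts_path,meta_path Output CSV paths.
#' @export
write_barcode_counts <- function(x, counts_path, meta_path = NULL) {
  stopifnot(inherits(x, "barcode_counts"))
  utils::write.csv(data.frame(barcode_id = rownames(x$counts), x$counts,
                              check.names = FALSE),
                   counts_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- x$sample_meta
    meta$unassigned <- x$unassigned[meta$sample_id]
    utils::write.csv(meta, meta_path, row.names = FALSE)
  }
  invisible(x)
}

#' Read a barcode count table written by [write_barcode_counts()]
#' @param counts_path,meta_path CSV paths.
#' @export
read_barcode_counts <- function(counts_path, meta_path) {
  df <- utils::read.csv(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$barcode_id
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  unas <- stats::setNames(meta$unassigned %||% integer(nrow(meta)), meta$sample_id)
  barcode_counts(m, meta[, c("sample_id", "mouse", "tissue", "cell_type", "is_input")],
                 unas)
}
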