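# Small in-code fixtures shared across test files.

# A tiny lipid panel: n lipids cycling through the three charge classes.
tiny_lipid_table <- function(n = 3) {
  data.frame(
    name = sprintf("lip%02d", seq_len(n)),
    charge_class = rep(c("cationic", "neutral", "anionic"), length.out = n),
    headgroup_mw = 50 + 10 * seq_len(n),
    tail = "18:1",
    headgroup_name = sprintf("hg%02d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

tiny_ratio_arms <- function(n = 2) {
  helper <- seq(0.1, 0.4, length.out = n)
  data.frame(
    molar_ratio_id = sprintf("R%d", seq_len(n)),
    ionizable_frac = 0.35,
    helper_frac = helper,
    chol_frac = 1 - 0.35 - helper - 0.025,
    peg_frac = 0.025,
    stringsAsFactors = FALSE
  )
}

tiny_peg_arms <- function(n = 1) {
  data.frame(peg_lipid = sprintf("PEG%d", seq_len(n)), stringsAsFactors = FALSE)
}

# A small barcoded library for pipeline tests.
tiny_library <- function(n_lipids = 3, n_ratios = 2, n_pegs = 1,
                         barcode_length = 8, min_hamming = 3, seed = 7) {
  lib <- enumerate_library(tiny_lipid_table(n_lipids),
                           tiny_ratio_arms(n_ratios), tiny_peg_arms(n_pegs))
  assign_barcodes(lib, length = barcode_length, min_hamming = min_hamming,
                  seed = seed)
}

# Brute-force pairwise Hamming distance between two sequences.
bf_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# A hand-built barcode_counts table with one input-pool column.
tiny_counts <- function(counts, barcode_ids = rownames(counts)) {
  stopifnot(!is.null(colnames(counts)))
  meta <- data.frame(
    sample_id = colnames(counts),
    mouse = seq_len(ncol(counts)),
    tissue = "lung", cell_type = "lung_EC",
    is_input = colnames(counts) == "input_pool",
    stringsAsFactors = FALSE
  )
  meta$mouse[meta$is_input] <- NA_integer_
  meta$tissue[meta$is_input] <- NA_character_
  meta$cell_type[meta$is_input] <- NA_character_
  rownames(counts) <- barcode_ids
  barcode_counts(counts, meta)
}
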