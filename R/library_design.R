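#' Full-factorial LNP library design
#'
#' A pooled barcode screen formulates every helper lipid under every
#' formulation arm (molar-ratio set x PEG-lipid choice), so the library is the
#' cartesian product of three small tables. An `lnp_library` object holds the
#' enumerated designs with their chemical annotation, the DNA barcode
#' assignment, and the naked (unencapsulated) control barcode that serves as a
#' delivery floor.
#'
#' @name library_design
NULL

CHARGE_CLASSES <- c("cationic", "neutral", "anionic")

validate_lipid_table <- function(lipid_table) {
  required <- c("name", "charge_class", "headgroup_mw", "tail", "headgroup_name")
  missing <- setdiff(required, names(lipid_table))
  if (length(missing)) {
    stop("lipid table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(lipid_table) == 0L) stop("lipid table is empty")
  if (anyDuplicated(lipid_table$name)) {
    stop("duplicate lipid names: ",
         paste(unique(lipid_table$name[duplicated(lipid_table$name)]), collapse = ", "))
  }
  bad <- setdiff(unique(lipid_table$charge_class), CHARGE_CLASSES)
  if (length(bad)) {
    stop("invalid charge_class values: ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(lipid_table$headgroup_mw)) || any(lipid_table$headgroup_mw <= 0)) {
    stop("headgroup_mw must be positive")
  }
  invisible(lipid_table)
}

validate_ratio_arms <- function(ratio_arms, tol = 1e-9) {
  required <- c("molar_ratio_id", "ionizable_frac", "helper_frac", "chol_frac", "peg_frac")
  missing <- setdiff(required, names(ratio_arms))
  if (length(missing)) {
    stop("ratio arm table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(ratio_arms) == 0L) stop("ratio arm table is empty")
  if (anyDuplicated(ratio_arms$molar_ratio_id)) stop("duplicate molar_ratio_id")
  tot <- ratio_arms$ionizable_frac + ratio_arms$helper_frac +
    ratio_arms$chol_frac + ratio_arms$peg_frac
  if (any(abs(tot - 1) > tol)) {
    stop("mole fractions must sum to 1 (max deviation ",
         format(max(abs(tot - 1))), ")")
  }
  fracs <- as.matrix(ratio_arms[, c("ionizable_frac", "helper_frac", "chol_frac", "peg_frac")])
  if (any(fracs < 0)) stop("mole fractions must be nonnegative")
  invisible(ratio_arms)
}

#' Default helper-lipid panel
#'
#' Eighteen helper lipids spanning three charge classes (3 cationic, 8
#' neutral, 7 anionic). The panel includes the field-standard lipids named in
#' structure-tropism screens (18:0 DDAB, DSPC, 18:1 PA, and a same-tail
#' neutral headgroup-size series: ammonium, methylamine, dimethylamine,
#' trimethylamine); the remaining entries are plausible catalogue lipids that
#' fill the charge split, with approximate headgroup molecular weights in
#' daltons. Any table with the same columns can replace it.
#'
#' @return A data.frame with columns `name`, `charge_class`, `headgroup_mw`
#'   (daltons), `tail`, `headgroup_name`.
#' @export
default_lipid_table <- function() {
  tbl <- rbind(
    data.frame(name = "18:0 DDAB",  charge_class = "cationic", headgroup_mw = 46,  tail = "18:0", headgroup_name = "dimethylammonium"),
    data.frame(name = "DOTAP",      charge_class = "cationic", headgroup_mw = 102, tail = "18:1", headgroup_name = "trimethylammonium-propane"),
    data.frame(name = "18:1 EPC",   charge_class = "cationic", headgroup_mw = 212, tail = "18:1", headgroup_name = "ethylphosphocholine"),
    data.frame(name = "DSPC",       charge_class = "neutral",  headgroup_mw = 184, tail = "18:0", headgroup_name = "phosphocholine"),
    data.frame(name = "DOPC",       charge_class = "neutral",  headgroup_mw = 184, tail = "18:1", headgroup_name = "phosphocholine"),
    data.frame(name = "DOPE",       charge_class = "neutral",  headgroup_mw = 141, tail = "18:1", headgroup_name = "phosphoethanolamine"),
    data.frame(name = "DSPE",       charge_class = "neutral",  headgroup_mw = 141, tail = "18:0", headgroup_name = "phosphoethanolamine"),
    data.frame(name = "18:1 P-NH4", charge_class = "neutral",  headgroup_mw = 18,  tail = "18:1", headgroup_name = "ammonium"),
    data.frame(name = "18:1 P-MA",  charge_class = "neutral",  headgroup_mw = 31,  tail = "18:1", headgroup_name = "methylamine"),
    data.frame(name = "18:1 P-DMA", charge_class = "neutral",  headgroup_mw = 45,  tail = "18:1", headgroup_name = "dimethylamine"),
    data.frame(name = "18:1 P-TMA", charge_class = "neutral",  headgroup_mw = 60,  tail = "18:1", headgroup_name = "trimethylamine"),
    data.frame(name = "18:1 PA",    charge_class = "anionic",  headgroup_mw = 98,  tail = "18:1", headgroup_name = "phosphate"),
    data.frame(name = "DSPA",       charge_class = "anionic",  headgroup_mw = 98,  tail = "18:0", headgroup_name = "phosphate"),
    data.frame(name = "DOPG",       charge_class = "anionic",  headgroup_mw = 172, tail = "18:1", headgroup_name = "phosphoglycerol"),
    data.frame(name = "DSPG",       charge_class = "anionic",  headgroup_mw = 172, tail = "18:0", headgroup_name = "phosphoglycerol"),
    data.frame(name = "DOPS",       charge_class = "anionic",  headgroup_mw = 185, tail = "18:1", headgroup_name = "phosphoserine"),
    data.frame(name = "DSPS",       charge_class = "anionic",  headgroup_mw = 185, tail = "18:0", headgroup_name = "phosphoserine"),
    data.frame(name = "18:1 PI",    charge_class = "anionic",  headgroup_mw = 260, tail = "18:1", headgroup_name = "phosphoinositol")
  )
  validate_lipid_table(tbl)
}

#' Default molar-ratio arms
#'
#' Four molar-ratio arms for the four-component LNP (ionizable lipid, helper
#' lipid, cholesterol, PEG-lipid). Helper-lipid fractions 12%, 27.5% and
#' 44.5% are the field-standard set for helper-lipid titration; the fourth
#' arm (20%) is a placeholder intermediate and, like the whole table, is
#' user-configurable. Ionizable (35%) and PEG (2.5%) fractions are held
#' constant; cholesterol absorbs the remainder.
#'
#' @return A data.frame with one row per arm; mole fractions sum to 1.
#' @export
default_ratio_arms <- function() {
  helper <- c(R1 = 0.12, R2 = 0.20, R3 = 0.275, R4 = 0.445)
  arms <- data.frame(
    molar_ratio_id = names(helper),
    ionizable_frac = 0.35,
    helper_frac    = unname(helper),
    peg_frac       = 0.025
  )
  arms$chol_frac <- 1 - arms$ionizable_frac - arms$helper_frac - arms$peg_frac
  validate_ratio_arms(arms[, c("molar_ratio_id", "ionizable_frac", "helper_frac",
                               "chol_frac", "peg_frac")])
}

#' Default PEG-lipid arms
#' @return A data.frame with column `peg_lipid`.
#' @export
default_peg_arms <- function() {
  data.frame(peg_lipid = c("C14PEG2000", "C18PEG2000"))
}

#' Enumerate the full-factorial LNP library
#'
#' Crosses every helper lipid with every molar-ratio arm and every PEG-lipid
#' arm, so the library size factorises exactly as
#' `nrow(lipid_table) * nrow(ratio_arms) * nrow(peg_arms)`.
#'
#' @param lipid_table Helper-lipid table (see [default_lipid_table()]).
#' @param ratio_arms Molar-ratio arm table (see [default_ratio_arms()]).
#' @param peg_arms PEG-lipid arm table (see [default_peg_arms()]).
#' @return An `lnp_library` object. `$designs` has one row per LNP design with
#'   full chemical annotation, a `pooled` flag (all `TRUE`; pooling failures
#'   are an experimental input, see [set_pooled()]) and an unassigned
#'   `barcode_id`.
#' @examples
#' lib <- enumerate_library(default_lipid_table(),
#'                          default_ratio_arms(), default_peg_arms())
#' nrow(lib$designs)  # 144
#' @export
enumerate_library <- function(lipid_table = default_lipid_table(),
                              ratio_arms = default_ratio_arms(),
                              peg_arms = default_peg_arms()) {
  validate_lipid_table(lipid_table)
  validate_ratio_arms(ratio_arms)
  if (nrow(peg_arms) == 0L || is.null(peg_arms$peg_lipid)) {
    stop("PEG arm table must be non-empty with a peg_lipid column")
  }
  if (anyDuplicated(peg_arms$peg_lipid)) stop("duplicate peg_lipid labels")

  grid <- expand.grid(
    lipid_idx = seq_len(nrow(lipid_table)),
    ratio_idx = seq_len(nrow(ratio_arms)),
    peg_idx   = seq_len(nrow(peg_arms)),
    KEEP.OUT.ATTRS = FALSE
  )
  designs <- cbind(
    lipid_table[grid$lipid_idx, , drop = FALSE],
    ratio_arms[grid$ratio_idx, , drop = FALSE],
    peg_arms[grid$peg_idx, , drop = FALSE]
  )
  names(designs)[names(designs) == "name"] <- "helper_lipid"
  rownames(designs) <- NULL
  designs$design_id <- sprintf(
    "LNP_%03d", seq_len(nrow(designs))
  )
  designs$barcode_id <- NA_character_
  designs$pooled <- TRUE
  designs <- designs[, c("design_id", "helper_lipid", "charge_class",
                         "headgroup_mw", "tail", "headgroup_name",
                         "molar_ratio_id", "ionizable_frac", "helper_frac",
                         "chol_frac", "peg_frac", "peg_lipid",
                         "barcode_id", "pooled")]
  structure(
    list(designs = designs,
         barcodes = NULL,
         naked_control_barcode = "NAKED",
         barcode_length = NA_integer_,
         min_pairwise_hamming = NA_integer_),
    class = "lnp_library"
  )
}

#' @export
print.lnp_library <- function(x, ...) {
  n <- nrow(x$designs)
  by_charge <- table(factor(x$designs$charge_class, levels = CHARGE_CLASSES))
  cat(sprintf("lnp_library: %d designs (%s), %d pooled\n", n,
              paste(sprintf("%d %s", as.integer(by_charge), names(by_charge)),
                    collapse = ", "),
              sum(x$designs$pooled)))
  if (!is.null(x$barcodes)) {
    cat(sprintf("  barcodes: %d x %d nt, min pairwise Hamming >= %d (control: %s)\n",
                length(x$barcodes), x$barcode_length,
                x$min_pairwise_hamming, x$naked_control_barcode))
  } else {
    cat("  barcodes: unassigned\n")
  }
  invisible(x)
}

#' Mark designs that failed pooling criteria
#'
#' Whether a formulated design enters the injected pool is an experimental
#' measurement (hydrodynamic diameter / monodispersity), supplied as input.
#'
#' @param library An `lnp_library`.
#' @param design_ids Designs to flag.
#' @param pooled Logical flag to set.
#' @return The modified library.
#' @export
set_pooled <- function(library, design_ids, pooled = FALSE) {
  stopifnot(inherits(library, "lnp_library"))
  unknown <- setdiff(design_ids, library$designs$design_id)
  if (length(unknown)) stop("unknown design_ids: ", paste(unknown, collapse = ", "))
  library$designs$pooled[library$designs$design_id %in% design_ids] <- pooled
  library
}

#' Assign Hamming-separated DNA barcodes to a library
#'
#' Draws random DNA barcodes by rejection sampling so that every pair of
#' accepted sequences differs at `min_hamming` or more positions; single-base
#' sequencing errors are then correctable whenever
#' `max_mismatch < min_hamming / 2`. One extra barcode is reserved for the
#' naked (unencapsulated) control. Deterministic under `seed`.
#'
#' @param library An `lnp_library`.
#' @param length Barcode length in nucleotides.
#' @param min_hamming Minimum pairwise Hamming distance (>= 1).
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling budget per barcode before the
#'   assignment is declared infeasible.
#' @return The library with `$barcodes` (named sequences; names are barcode
#'   IDs), per-design `barcode_id`, and the control barcode ID
#'   `$naked_control_barcode`.
#' @export
assign_barcodes <- function(library, length = 8L, min_hamming = 3L, seed = 1L,
                            max_attempts = 10000L) {
  stopifnot(inherits(library, "lnp_library"))
  n_needed <- nrow(library$designs) + 1L  # + naked control
  if (min_hamming < 1L) stop("min_hamming must be >= 1")
  if (min_hamming > length) stop("min_hamming cannot exceed barcode length")
  if (4^length < 2 * n_needed) {
    stop(sprintf("infeasible: %d barcodes requested but 4^%d = %s sequences exist",
                 n_needed, length, format(4^length)))
  }
  seqs <- character(0)
  with_seed(seed, {
    while (base::length(seqs) < n_needed) {
      accepted <- FALSE
      for (attempt in seq_len(max_attempts)) {
        cand <- random_dna(1L, length)
        if (base::length(seqs) == 0L ||
            all(hamming_pair(rep(cand, base::length(seqs)), seqs) >= min_hamming)) {
          seqs <- c(seqs, cand)
          accepted <- TRUE
          break
        }
      }
      if (!accepted) {
        stop(sprintf(paste0("infeasible barcode design: could not place barcode %d of %d ",
                            "at length %d with min Hamming distance %d"),
                     base::length(seqs) + 1L, n_needed, length, min_hamming))
      }
    }
  })
  ids <- c(sprintf("BC_%03d", seq_len(n_needed - 1L)), library$naked_control_barcode)
  names(seqs) <- ids
  library$designs$barcode_id <- ids[seq_len(n_needed - 1L)]
  library$barcodes <- seqs
  library$barcode_length <- as.integer(length)
  library$min_pairwise_hamming <- as.integer(min_hamming)
  library
}

#' Subset a library by helper-lipid charge class
#'
#' The screen is run as one library per charge class; this returns the
#' designs sharing `charge_class`, retaining the barcode table and the naked
#' control.
#'
#' @param library An `lnp_library`.
#' @param charge_class One of `"cationic"`, `"neutral"`, `"anionic"`.
#' @return An `lnp_library` restricted to the charge class.
#' @export
subset_by_charge <- function(library, charge_class) {
  stopifnot(inherits(library, "lnp_library"))
  charge_class <- match.arg(charge_class, CHARGE_CLASSES)
  keep <- library$designs$charge_class == charge_class
  out <- library
  out$designs <- library$designs[keep, , drop = FALSE]
  rownames(out$designs) <- NULL
  if (!is.null(library$barcodes)) {
    keep_bc <- c(out$designs$barcode_id, library$naked_control_barcode)
    out$barcodes <- library$barcodes[names(library$barcodes) %in% keep_bc]
  }
  out
}

#' Average dose per pooled LNP
#'
#' @param total_dose_mg_per_kg Total nucleic-acid dose (mg/kg) for the pool.
#' @param n_pooled Number of LNPs in the pool (>= 1).
#' @return Dose per LNP in mg/kg, reported to 2 significant figures.
#' @examples
#' dose_per_lnp(1.0, 23)  # 0.043
#' @export
dose_per_lnp <- function(total_dose_mg_per_kg, n_pooled) {
  if (!is.finite(total_dose_mg_per_kg) || total_dose_mg_per_kg <= 0) {
    stop("total dose must be positive")
  }
  if (!is.finite(n_pooled) || n_pooled < 1) {
    stop("n_pooled must be >= 1")
  }
  signif(total_dose_mg_per_kg / n_pooled, 2)
}

#' Default full screen library
#'
#' The enumerated 144-design library with barcodes assigned and seven designs
#' flagged as having failed pooling criteria (1 cationic, 5 neutral, 1
#' anionic -- the last-enumerated designs of each class, a synthetic stand-in
#' for per-design size measurements), giving 23/59/55 = 137 pooled designs.
#'
#' @param seed Seed for barcode assignment.
#' @param barcode_length,min_hamming Barcode design parameters.
#' @return An `lnp_library`.
#' @export
default_screen_library <- function(seed = 1L, barcode_length = 8L, min_hamming = 3L) {
  lib <- enumerate_library()
  lib <- assign_barcodes(lib, length = barcode_length, min_hamming = min_hamming,
                         seed = seed)
  d <- lib$designs
  fail <- c(
    utils::tail(d$design_id[d$charge_class == "cationic"], 1),
    utils::tail(d$design_id[d$charge_class == "neutral"], 5),
    utils::tail(d$design_id[d$charge_class == "anionic"], 1)
  )
  set_pooled(lib, fail, pooled = FALSE)
}

#' Chemical property assignments for enrichment analysis
#'
#' One categorical label per design per property. Headgroup size class splits
#' headgroup molecular weight at the library median (`small` <= median).
#'
#' @param library An `lnp_library`.
#' @return A data.frame keyed by `design_id` with property columns
#'   `helper_lipid`, `charge_class`, `headgroup_name`, `headgroup_size`,
#'   `molar_ratio_id`, `peg_lipid`, `tail`.
#' @export
lnp_properties <- function(library) {
  stopifnot(inherits(library, "lnp_library"))
  d <- library$designs
  med <- stats::median(d$headgroup_mw)
  data.frame(
    design_id = d$design_id,
    helper_lipid = d$helper_lipid,
    charge_class = d$charge_class,
    headgroup_name = d$headgroup_name,
    headgroup_size = ifelse(d$headgroup_mw <= med, "small", "large"),
    molar_ratio_id = d$molar_ratio_id,
    peg_lipid = d$peg_lipid,
    tail = d$tail,
    stringsAsFactors = FALSE
  )
}

#' Write a library to CSV (one design per row) and barcodes to FASTA
#'
#' @param library An `lnp_library` with barcodes assigned.
#' @param csv_path Output CSV path.
#' @param fasta_path Optional output FASTA path for barcode sequences
#'   (record ID = barcode ID).
#' @return Invisibly, the library.
#' @export
write_library <- function(library, csv_path, fasta_path = NULL) {
  stopifnot(inherits(library, "lnp_library"))
  utils::write.csv(library$designs, csv_path, row.names = FALSE)
  if (!is.null(fasta_path)) {
    if (is.null(library$barcodes)) stop("library has no barcodes assigned")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(library$barcodes), fasta_path
    )
  }
  invisible(library)
}

#' Read a helper-lipid table from CSV
#' @param path CSV with header row and the columns of [default_lipid_table()].
#' @return Validated lipid table.
#' @export
read_lipid_table <- function(path) {
  validate_lipid_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
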