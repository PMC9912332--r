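#' Decile enrichment for structure-activity analysis
#'
#' Relates lipid chemical properties to delivery: among the top (and bottom)
#' 10% of LNPs by normalized delivery, how often does a property value
#' appear relative to its library-wide frequency? Enrichment e = 1 is chance
#' level; fold enrichment is the top-decile enrichment minus the
#' bottom-decile enrichment, so positive fold associates the property with
#' efficient delivery. A label-permutation test supplies significance.
#'
#' @name enrichment
NULL

#' Top/bottom decile membership
#'
#' Both sets have size `ceiling(fraction * N)`. Scores are put through one
#' stable descending sort (ties broken by input order, i.e. design order);
#' the top set is the head and the bottom set the tail of that sort, which
#' keeps the sets disjoint even under complete ties.
#'
#' @param scores Numeric scores, one per LNP.
#' @param fraction Decile fraction in (0, 0.5].
#' @param ids Optional labels for the returned sets (defaults to indices).
#' @return A list with `top`, `bottom` (ids) and `k` (set size).
#' @export
decile_sets <- function(scores, fraction = 0.1, ids = NULL) {
  n <- length(scores)
  if (n < 2L) stop("need at least 2 scored LNPs")
  if (fraction <= 0 || fraction > 0.5) stop("fraction must lie in (0, 0.5]")
  if (any(!is.finite(scores))) stop("scores must be finite")
  k <- as.integer(ceiling(fraction * n))
  if (2L * k > n) {
    stop(sprintf("decile sets of size %d cannot be disjoint with %d LNPs", k, n))
  }
  ids <- ids %||% seq_len(n)
  ord <- order(-scores, seq_len(n))  # stable: ties keep design order
  list(top = ids[ord[seq_len(k)]],
       bottom = ids[ord[seq.int(n - k + 1L, n)]],
       k = k)
}

#' Enrichment of a property value within a subset
#'
#' `e = freq(value in subset) / freq(value in library)`; `e = 1` is chance
#' level, and e is bounded above by `1 / f` where `f` is the library
#' frequency of the value.
#'
#' @param subset_labels Property labels of the subset members.
#' @param library_labels Property labels of every scored LNP.
#' @param value The property value scored.
#' @return The enrichment score (nonnegative).
#' @export
enrichment_score <- function(subset_labels, library_labels, value) {
  f <- mean(library_labels == value)
  if (f == 0) stop(sprintf("value '%s' absent from the library", value))
  mean(subset_labels == value) / f
}

#' Fold enrichment
#'
#' Top-decile enrichment minus bottom-decile enrichment.
#' @param e_top,e_bottom Enrichment scores on the same property value.
#' @return `e_top - e_bottom`.
#' @export
fold_enrichment <- function(e_top, e_bottom) e_top - e_bottom

# Observed fold for one property value given fixed decile index sets.
fold_for_labels <- function(labels, top_idx, bottom_idx, value, f) {
  (mean(labels[top_idx] == value) - mean(labels[bottom_idx] == value)) / f
}

#' Permutation p-value for a fold enrichment
#'
#' Permutes the property labels against the scores (decile membership is
#' fixed by the scores) and reports a two-sided p-value on `|fold|`.
#'
#' The fold statistic is discrete (it counts label occurrences in two small
#' decile sets), so ties between permuted and observed statistics are
#' common. With `ties = "conservative"` (default) ties count as exceedances:
#' `p = (1 + #{|fold_perm| >= |fold_obs|}) / (1 + n_perm)`, which is valid
#' but super-uniform under the null (its null distribution has large atoms,
#' e.g. at p = 1 whenever the observed fold is 0). With `ties = "random"`
#' the observed statistic's rank among all `n_perm + 1` exchangeable
#' statistics is resolved uniformly at random within its tie group, which
#' makes p exactly discrete-uniform under the null -- use this when
#' calibration itself matters (e.g. comparing p-values across properties or
#' feeding them into further inference).
#'
#' @param scores Per-LNP scores.
#' @param labels Per-LNP property labels.
#' @param value Property value tested.
#' @param fraction Decile fraction.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param ties Tie handling: `"conservative"` or `"random"` (see Details).
#' @return A list with `fold` (observed) and `p`.
#' @export
permutation_pvalue <- function(scores, labels, value, fraction = 0.1,
                               n_perm = 999L, seed = 1L,
                               ties = c("conservative", "random")) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  ties <- match.arg(ties)
  n <- length(scores)
  stopifnot(length(labels) == n)
  ds <- decile_sets(scores, fraction)
  top_idx <- ds$top
  bottom_idx <- ds$bottom
  f <- mean(labels == value)
  if (f == 0) stop(sprintf("value '%s' absent from the library", value))
  obs <- fold_for_labels(labels, top_idx, bottom_idx, value, f)
  with_seed(seed, {
    exceed <- 0L
    tied <- 0L
    tol <- 1e-12
    for (b in seq_len(n_perm)) {
      stat <- abs(fold_for_labels(labels[sample.int(n)], top_idx, bottom_idx,
                                  value, f))
      if (stat > abs(obs) + tol) exceed <- exceed + 1L
      else if (abs(stat - abs(obs)) <= tol) tied <- tied + 1L
    }
    p <- if (ties == "conservative") {
      (1 + exceed + tied) / (1 + n_perm)
    } else {
      (1 + exceed + sample.int(tied + 1L, 1L) - 1L) / (1 + n_perm)
    }
    list(fold = obs, p = p)
  })
}

#' Enrichment across all property values and cell types
#'
#' @param nd_aggregated Output of [aggregate_mice()] (mouse-averaged
#'   normalized delivery), or any matrix of scores with LNP rows and
#'   cell-type columns.
#' @param properties Data.frame keyed by `design_id` with one or more
#'   property columns (see [lnp_properties()]); rows are matched to the
#'   aggregated table through its `design_map`.
#' @param property_names Which property columns to analyse (default: all
#'   non-key columns).
#' @param fraction Decile fraction.
#' @param n_perm Permutations per test; `0` skips the permutation test.
#' @param seed Integer seed.
#' @param ties Tie handling passed to [permutation_pvalue()].
#' @return A data.frame with one row per (property, value, cell type):
#'   `e_top`, `e_bottom`, `fold`, `n_top`, `n_bottom`, `lib_freq`, `perm_p`.
#' @export
enrich_all <- function(nd_aggregated, properties,
                       property_names = NULL,
                       fraction = 0.1, n_perm = 999L, seed = 1L,
                       ties = c("conservative", "random")) {
  ties <- match.arg(ties)
  if (is.list(nd_aggregated) && !is.null(nd_aggregated$mean)) {
    scores_m <- nd_aggregated$mean
    map <- nd_aggregated$design_map
    key <- map$design_id[match(rownames(scores_m), map$barcode_id)]
  } else {
    scores_m <- as.matrix(nd_aggregated)
    key <- rownames(scores_m)
  }
  prop_rows <- match(key, properties$design_id)
  if (anyNA(prop_rows)) stop("properties table lacks some scored designs")
  property_names <- property_names %||% setdiff(names(properties), "design_id")

  out <- list()
  seed_i <- seed
  for (ct in colnames(scores_m)) {
    scores <- scores_m[, ct]
    keep <- !is.na(scores)
    ds <- decile_sets(scores[keep], fraction, ids = which(keep))
    for (pn in property_names) {
      labels <- properties[[pn]][prop_rows]
      for (v in unique(labels[keep])) {
        f <- mean(labels[keep] == v)
        e_top <- mean(labels[ds$top] == v) / f
        e_bot <- mean(labels[ds$bottom] == v) / f
        perm_p <- NA_real_
        if (n_perm > 0L) {
          seed_i <- seed_i + 1L
          perm_p <- permutation_pvalue(scores[keep], labels[keep], v,
                                       fraction = fraction, n_perm = n_perm,
                                       seed = seed_i, ties = ties)$p
        }
        out[[length(out) + 1L]] <- data.frame(
          property = pn, value = v, cell_type = ct,
          e_top = e_top, e_bottom = e_bot,
          fold = fold_enrichment(e_top, e_bot),
          n_top = ds$k, n_bottom = ds$k, lib_freq = f, perm_p = perm_p,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Per-tissue fold enrichment
#'
#' The mean of per-cell-type folds within each tissue, each cell type
#' weighted equally.
#'
#' @param enrichment_table Output of [enrich_all()].
#' @param cell_types Data.frame mapping `cell_type` to `tissue`.
#' @return A data.frame (property, value, tissue, fold, n_cell_types).
#' @export
tissue_fold <- function(enrichment_table, cell_types) {
  m <- merge(enrichment_table, cell_types[, c("cell_type", "tissue")],
             by = "cell_type")
  agg <- stats::aggregate(fold ~ property + value + tissue, data = m, FUN = mean)
  n <- stats::aggregate(cell_type ~ property + value + tissue, data = m, FUN = length)
  names(n)[names(n) == "cell_type"] <- "n_cell_types"
  merge(agg, n, by = c("property", "value", "tissue"))
}
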