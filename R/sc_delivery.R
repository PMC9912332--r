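#' Single-cell delivery readout
#'
#' Quantifies reporter-mRNA delivery at single-cell resolution: the percent
#' of reporter-positive cells per cluster and treatment group, rank-sum
#' differential expression between treatment groups on library-size
#' normalized log counts, and hypergeometric gene-set overrepresentation of
#' the resulting gene lists.
#'
#' @name sc_delivery
NULL

#' Cell-by-gene count matrix with cluster and treatment labels
#'
#' @param counts Sparse nonnegative-integer matrix, genes x cells, with
#'   gene rownames and cell colnames.
#' @param cell_meta Data.frame with one row per cell: `cell_id`, `cluster`,
#'   `group`, and optionally `compartment`.
#' @param avhh_gene Name of the reporter pseudogene row (may be `NA` when no
#'   delivery analysis is requested).
#' @return A `cell_gene_matrix` object.
#' @export
cell_gene_matrix <- function(counts, cell_meta, avhh_gene = NA_character_) {
  if (!inherits(counts, "sparseMatrix")) {
    counts <- methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                          "CsparseMatrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts needs gene rownames and cell colnames")
  }
  if (!all(c("cell_id", "cluster", "group") %in% names(cell_meta))) {
    stop("cell_meta needs cell_id, cluster and group columns")
  }
  if (!identical(sort(colnames(counts)), sort(cell_meta$cell_id))) {
    stop("cell_meta does not match matrix columns")
  }
  if (anyNA(cell_meta$cluster) || anyNA(cell_meta$group)) {
    stop("every cell needs a cluster and a group label")
  }
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL
  if (!is.na(avhh_gene) && !avhh_gene %in% rownames(counts)) {
    stop(sprintf("reporter gene '%s' not present in the matrix", avhh_gene))
  }
  structure(list(counts = counts, cell_meta = cell_meta, avhh_gene = avhh_gene),
            class = "cell_gene_matrix")
}

#' @export
print.cell_gene_matrix <- function(x, ...) {
  cat(sprintf("cell_gene_matrix: %d genes x %d cells, %d clusters, groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$cluster)),
              paste(unique(x$cell_meta$group), collapse = ", ")))
  invisible(x)
}

#' Write a cell-by-gene matrix as Matrix Market + label files
#'
#' Writes `matrix.mtx` (genes x cells), `genes.tsv`, `cells.tsv` and
#' `cell_meta.csv` into `dir`.
#' @param x A [cell_gene_matrix()].
#' @param dir Output directory.
#' @export
write_cell_gene_matrix <- function(x, dir) {
  stopifnot(inherits(x, "cell_gene_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "cells.tsv"))
  meta <- x$cell_meta
  meta$avhh_gene <- x$avhh_gene
  utils::write.csv(meta, file.path(dir, "cell_meta.csv"), row.names = FALSE)
  invisible(x)
}

#' Read a cell-by-gene matrix written by [write_cell_gene_matrix()]
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`,
#'   `cell_meta.csv`.
#' @export
read_cell_gene_matrix <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "cells.tsv"))
  meta <- utils::read.csv(file.path(dir, "cell_meta.csv"), stringsAsFactors = FALSE)
  avhh <- if (!is.null(meta$avhh_gene)) meta$avhh_gene[1] else NA_character_
  cell_gene_matrix(m, meta[, setdiff(names(meta), "avhh_gene"), drop = FALSE],
                   avhh_gene = avhh)
}

#' Percent of positive cells per cluster and treatment group
#'
#' A cell is positive when its count for `gene` is at least `min_count`.
#' Strata with zero cells are absent from the output rather than reported
#' as 0.
#'
#' @param matrix A [cell_gene_matrix()].
#' @param gene Gene to score (defaults to the reporter pseudogene).
#' @param by_cluster,by_group Stratify by cluster / treatment group.
#' @param min_count Positivity threshold (>= 1).
#' @return A data.frame with `cluster` and/or `group`, `n_cells`,
#'   `n_positive`, `pct_positive` (0-100 scale).
#' @export
percent_positive <- function(matrix, gene = matrix$avhh_gene,
                             by_cluster = TRUE, by_group = TRUE,
                             min_count = 1L) {
  stopifnot(inherits(matrix, "cell_gene_matrix"))
  if (min_count < 1L) stop("min_count must be >= 1")
  if (is.na(gene) || !gene %in% rownames(matrix$counts)) {
    stop(sprintf("gene '%s' not present in the matrix", gene))
  }
  pos <- as.vector(matrix$counts[gene, ] >= min_count)
  meta <- matrix$cell_meta
  strata <- character(nrow(meta))
  keys <- list()
  if (by_cluster) keys$cluster <- meta$cluster
  if (by_group) keys$group <- meta$group
  if (!length(keys)) keys$all <- rep("all", nrow(meta))
  split_key <- interaction(keys, drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(levels(split_key), function(lv) {
    idx <- split_key == lv
    parts <- strsplit(lv, "\r", fixed = TRUE)[[1]]
    row <- as.data.frame(as.list(stats::setNames(parts, names(keys))),
                         stringsAsFactors = FALSE)
    row$n_cells <- sum(idx)
    row$n_positive <- sum(pos[idx])
    row$pct_positive <- 100 * mean(pos[idx])
    row
  }))
  rownames(out) <- NULL
  out
}

#' Rank-sum differential expression between treatment groups
#'
#' Counts are library-size normalized (scaled to `scale_factor` per cell) and
#' log1p-transformed; each gene gets a two-sided Wilcoxon rank-sum p-value,
#' a BH q-value over the tested genes, and a log2 fold change of group means
#' (pseudocount 1). Genes expressed in fewer than `min_frac_expressed` of
#' the filtered cells are excluded and reported.
#'
#' @param matrix A [cell_gene_matrix()].
#' @param group_a Treatment group of interest.
#' @param group_b Reference group(s); one or more labels pooled together.
#' @param cluster_filter Optional clusters to restrict to (e.g. endothelial
#'   clusters).
#' @param min_frac_expressed Expression filter threshold in [0, 1].
#' @param scale_factor Per-cell library-size target.
#' @return A `de_result` data.frame: `gene`, `log2fc` (a vs b), `p`, `q`,
#'   `direction` (`"up"`/`"down"`), `frac_expressed`; excluded genes are in
#'   `attr(, "excluded")`.
#' @export
differential_expression <- function(matrix, group_a, group_b,
                                    cluster_filter = NULL,
                                    min_frac_expressed = 0.05,
                                    scale_factor = 1e4) {
  stopifnot(inherits(matrix, "cell_gene_matrix"))
  meta <- matrix$cell_meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(cluster_filter)) keep <- meta$cluster %in% cluster_filter
  in_a <- keep & meta$group %in% group_a
  in_b <- keep & meta$group %in% group_b
  if (!sum(in_a) || !sum(in_b)) stop("empty treatment group after filtering")
  if (sum(in_a) < 3L || sum(in_b) < 3L) stop("need >= 3 cells per group")

  sub <- matrix$counts[, in_a | in_b, drop = FALSE]
  grp_a <- meta$group[in_a | in_b] %in% group_a
  libsize <- Matrix::colSums(sub)
  if (any(libsize == 0)) {
    keep_cells <- libsize > 0
    sub <- sub[, keep_cells, drop = FALSE]
    grp_a <- grp_a[keep_cells]
    libsize <- libsize[keep_cells]
  }
  norm <- log1p(t(t(as.matrix(sub)) / libsize * scale_factor))

  frac_expr <- Matrix::rowMeans(sub > 0)
  tested <- frac_expr >= min_frac_expressed
  excluded <- rownames(sub)[!tested]
  norm <- norm[tested, , drop = FALSE]

  a_cols <- which(grp_a)
  b_cols <- which(!grp_a)
  p <- apply(norm, 1, function(v) {
    if (all(v[a_cols] == v[a_cols][1]) && all(v == v[1])) return(1)
    stats::wilcox.test(v[a_cols], v[b_cols], exact = FALSE)$p.value
  })
  mu_a <- rowMeans(norm[, a_cols, drop = FALSE])
  mu_b <- rowMeans(norm[, b_cols, drop = FALSE])
  log2fc <- log2((mu_a + 1) / (mu_b + 1))
  res <- data.frame(
    gene = rownames(norm),
    log2fc = log2fc,
    p = p,
    q = stats::p.adjust(p, method = "BH"),
    direction = ifelse(log2fc >= 0, "up", "down"),
    frac_expressed = frac_expr[tested],
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  attr(res, "n_cells") <- c(a = length(a_cols), b = length(b_cols))
  class(res) <- c("de_result", class(res))
  res
}

#' Top upregulated genes from a DE result
#'
#' Among genes with positive log2 fold change and raw `p < p_cutoff`, ranks
#' by ascending p (ties by descending |log2fc|) and returns the first `k`.
#' When fewer than `k` genes qualify, all are returned with a message.
#'
#' @param de_result A [differential_expression()] result.
#' @param k Number of genes requested (>= 1).
#' @param p_cutoff Raw p-value filter.
#' @return Character vector of gene names.
#' @export
top_upregulated <- function(de_result, k = 10L, p_cutoff = 0.05) {
  if (k < 1L) stop("k must be >= 1")
  cand <- de_result[de_result$log2fc > 0 & de_result$p < p_cutoff, , drop = FALSE]
  if (!nrow(cand)) return(character(0))
  cand <- cand[order(cand$p, -abs(cand$log2fc)), , drop = FALSE]
  if (nrow(cand) < k) {
    message(sprintf("only %d of %d requested genes qualify", nrow(cand), k))
  }
  utils::head(cand$gene, k)
}

#' Hypergeometric overrepresentation of gene sets
#'
#' Upper-tail hypergeometric test of a query gene list against each set:
#' with background size N, set size m (after intersecting the set with the
#' background), query size n and overlap k, `p = P[X >= k]` for
#' `X ~ Hypergeometric(N, m, n)`.
#'
#' @param query_genes Character vector of genes of interest (must be a
#'   subset of `background`).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background Character vector: the gene universe.
#' @param alpha Significance threshold for the `enriched` flag.
#' @return An `ora_result` data.frame: `set`, `set_size` (in background),
#'   `overlap`, `query_size`, `background_size`, `p`, `enriched`.
#' @export
ora_hypergeometric <- function(query_genes, gene_sets, background,
                               alpha = 0.001) {
  if (!length(background)) stop("background is empty")
  background <- unique(background)
  query_genes <- unique(query_genes)
  stray <- setdiff(query_genes, background)
  if (length(stray)) {
    stop("query genes absent from background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  N <- length(background)
  n <- length(query_genes)
  out <- do.call(rbind, lapply(names(gene_sets), function(s) {
    set <- intersect(unique(gene_sets[[s]]), background)
    m <- length(set)
    k <- length(intersect(set, query_genes))
    p <- if (m == 0) 1 else stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(set = s, set_size = m, overlap = k, query_size = n,
               background_size = N, p = p, enriched = p < alpha,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("ora_result", class(out))
  out
}

#' Read gene sets from a GMT file
#' @param path GMT file (set name, description, member genes per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(s) {
    paste(c(s, s, gene_sets[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
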