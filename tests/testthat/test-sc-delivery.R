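# Small deterministic matrix: 2 clusters x 2 groups, 4 cells each stratum.
toy_matrix <- function() {
  genes <- c("g1", "g2", "aVHH")
  cells <- sprintf("c%02d", 1:16)
  meta <- data.frame(
    cell_id = cells,
    cluster = rep(c("EC", "imm"), each = 8),
    group = rep(rep(c("T", "C"), each = 4), 2),
    stringsAsFactors = FALSE
  )
  counts <- matrix(0L, 3, 16, dimnames = list(genes, cells))
  counts["g1", ] <- 1:16
  # aVHH: 3 of 4 positive in EC/T; none elsewhere
  counts["aVHH", meta$cluster == "EC" & meta$group == "T"] <- c(1L, 2L, 1L, 0L)
  cell_gene_matrix(counts, meta, avhh_gene = "aVHH")
}

test_that("percent positive counts cells at or above the threshold per stratum", {
  m <- toy_matrix()
  pp <- percent_positive(m)
  ec_t <- pp[pp$cluster == "EC" & pp$group == "T", ]
  expect_equal(ec_t$pct_positive, 75)  # 3 of 4
  expect_equal(ec_t$n_cells, 4)
  others <- pp[!(pp$cluster == "EC" & pp$group == "T"), ]
  expect_true(all(others$pct_positive == 0))
  # threshold is >= min_count
  pp2 <- percent_positive(m, min_count = 2)
  expect_equal(pp2[pp2$cluster == "EC" & pp2$group == "T", "pct_positive"], 25)
  expect_error(percent_positive(m, gene = "nope"), "nope")
})

test_that("percent positive is invariant to gene and cell order and drops empty strata", {
  m <- toy_matrix()
  perm_cells <- sample(colnames(m$counts))
  perm_genes <- sample(rownames(m$counts))
  m2 <- cell_gene_matrix(m$counts[perm_genes, perm_cells],
                         m$cell_meta[match(perm_cells, m$cell_meta$cell_id), ],
                         avhh_gene = "aVHH")
  a <- percent_positive(m)
  b <- percent_positive(m2)
  key <- function(d) d[order(d$cluster, d$group), ]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
  # zero-cell strata are absent, not zero
  expect_equal(nrow(a), 4)  # 2 clusters x 2 groups actually populated
})

test_that("differential expression recovers a planted fold change and filters unexpressed genes", {
  cl <- data.frame(cluster = "c1", compartment = "endothelial")
  cap <- matrix(0, 1, 2, dimnames = list("c1", c("T", "C")))
  de_block <- data.frame(gene = sprintf("gene_%04d", 1:5), group = "T", log2fc = 2)
  cfg <- sc_sim_config(clusters = cl, n_cells_per_cluster = 150,
                       treatment_groups = c("T", "C"), avhh_capture_prob = cap,
                       n_genes = 200, de_block = de_block, seed = 17)
  sim <- simulate_sc_matrix(cfg)
  # plant an all-zero gene by zeroing a row
  m <- sim$matrix
  m$counts["gene_0200", ] <- 0
  de <- differential_expression(m, "T", "C")
  expect_true(all(de$q >= de$p))
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_true("gene_0200" %in% attr(de, "excluded"))
  planted <- de[de$gene %in% de_block$gene, ]
  expect_true(all(planted$q < 0.05))
  expect_true(all(planted$log2fc > 0))
})

test_that("BH q-values are monotone non-decreasing in p-rank", {
  cl <- data.frame(cluster = "c1", compartment = "x")
  cap <- matrix(0, 1, 2, dimnames = list("c1", c("T", "C")))
  cfg <- sc_sim_config(clusters = cl, n_cells_per_cluster = 40,
                       treatment_groups = c("T", "C"), avhh_capture_prob = cap,
                       n_genes = 100, de_block = NULL, seed = 23)
  de <- differential_expression(simulate_sc_matrix(cfg)$matrix, "T", "C")
  ord <- order(de$p)
  expect_true(all(diff(de$q[ord]) >= -1e-12))
})

test_that("differential expression validates its groups", {
  m <- toy_matrix()
  expect_error(differential_expression(m, "T", "missing"), "empty")
  expect_error(differential_expression(m, "T", "C", cluster_filter = "EC",
                                       min_frac_expressed = 0),
               NA)  # 4 cells per group is enough
  tiny <- cell_gene_matrix(m$counts[, 1:5], m$cell_meta[1:5, ], avhh_gene = "aVHH")
  expect_error(differential_expression(tiny, "T", "C"), ">= 3 cells")
})

test_that("top upregulated genes are ranked by p then effect size", {
  de <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    log2fc = c(2, 1, -2, 3, 0.5),
    p = c(0.001, 0.001, 0.0001, 0.01, 0.2),
    q = c(0.01, 0.01, 0.001, 0.05, 0.4),
    direction = c("up", "up", "down", "up", "up"),
    stringsAsFactors = FALSE
  )
  class(de) <- c("de_result", class(de))
  expect_equal(top_upregulated(de, 2), c("a", "b"))  # tie broken by |log2fc|
  expect_equal(top_upregulated(de, 1), "a")
  expect_message(got <- top_upregulated(de, 10), "3 of 10")
  expect_equal(got, c("a", "b", "d"))
  none <- de[de$p > 0.5, , drop = FALSE]
  expect_equal(top_upregulated(none, 3), character(0))
})

test_that("hypergeometric ORA matches exhaustive enumeration on a small background", {
  set.seed(7)
  background <- sprintf("g%02d", 1:20)
  gs <- list(setA = sample(background, 8), setB = sample(background, 5),
             setC = c("g01", "g02"))
  query <- sample(background, 6)
  res <- ora_hypergeometric(query, gs, background, alpha = 0.05)
  # oracle: enumerate every 6-gene query; p = fraction of queries with
  # overlap >= observed, over all C(20,6) subsets
  combs <- combn(20, 6)
  for (s in names(gs)) {
    k_obs <- length(intersect(gs[[s]], query))
    in_set <- background %in% gs[[s]]
    overlaps <- colSums(matrix(in_set[combs], nrow = 6))
    p_oracle <- mean(overlaps >= k_obs)
    expect_equal(res$p[res$set == s], p_oracle, tolerance = 1e-12)
  }
})

test_that("ORA boundary cases: disjoint sets, saturation, invalid queries", {
  background <- letters[1:10]
  gs <- list(hit = c("a", "b", "c"), miss = c("x", "y"))
  res <- ora_hypergeometric(c("a", "b"), gs, background, alpha = 0.05)
  expect_equal(res$p[res$set == "miss"], 1)        # zero background overlap
  expect_equal(res$set_size[res$set == "miss"], 0)
  sat <- ora_hypergeometric(background, list(s = c("a", "b")), background)
  expect_equal(sat$p, 1)                            # P[X >= m] with n = N
  expect_equal(sat$overlap, 2)
  expect_error(ora_hypergeometric(c("zz"), gs, background), "absent")
  expect_error(ora_hypergeometric("a", gs, character(0)), "empty")
  # the documented small-instance value: all 10 query genes inside a 20-gene set
  bg100 <- sprintf("h%03d", 1:100)
  inset <- bg100[1:20]
  r <- ora_hypergeometric(bg100[1:10], list(s = inset), bg100)
  expect_equal(r$p, choose(20, 10) / choose(100, 10))
})

test_that("GMT files round-trip and feed ORA", {
  gs <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(gs, path)
  back <- read_gmt(path)
  expect_equal(back[names(gs)], gs)
})

test_that("cell-by-gene matrices round-trip through Matrix Market + labels", {
  cfg <- sc_sim_config(n_cells_per_cluster = 5, n_genes = 30, seed = 2)
  sim <- simulate_sc_matrix(cfg)
  dir <- withr::local_tempdir()
  write_cell_gene_matrix(sim$matrix, dir)
  back <- read_cell_gene_matrix(dir)
  expect_equal(as.matrix(back$counts), as.matrix(sim$matrix$counts))
  expect_equal(back$cell_meta$cluster, sim$matrix$cell_meta$cluster)
  expect_equal(back$avhh_gene, sim$matrix$avhh_gene)
})
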