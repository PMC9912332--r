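test_that("screen count simulation is a pure function of (config, seed)", {
  lib <- tiny_library(3, 2, 1)
  cfg <- screen_sim_config(lib, cell_types = default_cell_types()[1:3, ],
                           n_mice = 2, depth_input = 1e4, depth_sample = 5e3,
                           seed = 42)
  a <- simulate_screen_counts(cfg)
  b <- simulate_screen_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$potency, b$truth$potency)
  cfg2 <- screen_sim_config(lib, cell_types = default_cell_types()[1:3, ],
                            n_mice = 2, depth_input = 1e4, depth_sample = 5e3,
                            seed = 43)
  expect_false(identical(simulate_screen_counts(cfg2)$counts$counts,
                         a$counts$counts))
})

test_that("per-sample column sums equal the configured depth exactly", {
  lib <- tiny_library(3, 2, 1)
  cfg <- screen_sim_config(lib, cell_types = default_cell_types()[1:4, ],
                           n_mice = 3, depth_input = 2e4, depth_sample = 7e3)
  sim <- simulate_screen_counts(cfg)
  cs <- colSums(sim$counts$counts)
  expect_equal(unname(cs["input_pool"]), 2e4)
  expect_true(all(cs[setdiff(names(cs), "input_pool")] == 7e3))

  zero <- screen_sim_config(lib, cell_types = default_cell_types()[1:2, ],
                            n_mice = 1, depth_input = 1e3, depth_sample = 0)
  simz <- simulate_screen_counts(zero)
  expect_true(all(simz$counts$counts[, -1] == 0))
})

test_that("expected proportions are simplexes and counts converge to them", {
  lib <- tiny_library(4, 2, 1)
  cfg <- screen_sim_config(lib, cell_types = default_cell_types()[c(1, 6), ],
                           n_mice = 1, depth_input = 1e6, depth_sample = 1e6,
                           overdispersion = Inf, seed = 9)
  sim <- simulate_screen_counts(cfg)
  expect_true(all(abs(colSums(sim$truth$expected_proportions) - 1) < 1e-9))
  for (ct in colnames(sim$truth$expected_proportions)) {
    col <- sim$counts$counts[, paste0("m1_", ct)]
    emp <- col / sum(col)
    expect_lt(max(abs(emp - sim$truth$expected_proportions[, ct])), 0.01)
  }
})

test_that("screen truth encodes tropism and control structure", {
  lib <- default_screen_library(seed = 1)
  cfg <- screen_sim_config(lib, n_mice = 1, depth_input = 1e4, depth_sample = 1e4)
  sim <- simulate_screen_counts(cfg)
  pot <- sim$truth$potency
  naked <- lib$naked_control_barcode
  # the naked control has the lowest potency everywhere
  expect_true(all(pot[naked, ] == min(pot)))
  # cationic lipids dominate lung potency
  cat_bc <- lib$designs$barcode_id[lib$designs$pooled &
                                     lib$designs$charge_class == "cationic"]
  neu_bc <- lib$designs$barcode_id[lib$designs$pooled &
                                     lib$designs$charge_class == "neutral"]
  expect_gt(min(pot[cat_bc, "lung_EC"]), max(pot[neu_bc, "lung_EC"]))
})

test_that("config validation rejects degenerate screens", {
  lib <- tiny_library(2, 1, 1)
  expect_error(screen_sim_config(lib, cell_types = default_cell_types()[0, ]),
               "cell type")
  expect_error(screen_sim_config(lib, n_mice = 0), "n_mice")
  expect_error(screen_sim_config(lib, naked_control_multiplier = 1.5),
               "naked_control_multiplier")
  unassigned <- enumerate_library(tiny_lipid_table(2), tiny_ratio_arms(1),
                                  tiny_peg_arms(1))
  expect_error(screen_sim_config(unassigned), "barcodes")
})

test_that("FASTQ simulation round-trips losslessly at zero error rate", {
  lib <- tiny_library(4, 2, 1)
  cfg <- screen_sim_config(lib, cell_types = default_cell_types()[1:2, ],
                           n_mice = 1, depth_input = 3e3, depth_sample = 2e3)
  sim <- simulate_screen_counts(cfg)
  dir <- withr::local_tempdir()
  spec <- barcode_spec()
  fq <- simulate_screen_fastq(sim$counts, lib, dir, spec = spec,
                              read_error_rate = 0, seed = 5)
  bc <- count_barcodes(fq$sample_sheet, spec, lib)
  expect_identical(bc$counts[rownames(fq$truth), colnames(fq$truth)],
                   fq$truth)
  expect_true(all(bc$unassigned == 0))
})

test_that("empty count tables give empty FASTQ files", {
  lib <- tiny_library(2, 1, 1)
  cnt <- matrix(0L, nrow = 3, ncol = 1,
                dimnames = list(c(lib$designs$barcode_id, "NAKED"), "s1"))
  dir <- withr::local_tempdir()
  fq <- simulate_screen_fastq(cnt, lib, dir, read_error_rate = 0, seed = 1)
  expect_true(file.exists(fq$fastq_paths[["s1"]]))
  expect_equal(length(readLines(fq$fastq_paths[["s1"]])), 0)
})

test_that("single-cell simulation respects capture probabilities and seed", {
  cl <- default_sc_clusters()
  groups <- c("Cat-LNP", "PBS")
  zero <- matrix(0, nrow(cl), 2, dimnames = list(cl$cluster, groups))
  cfg <- sc_sim_config(clusters = cl, n_cells_per_cluster = 20,
                       treatment_groups = groups, avhh_capture_prob = zero,
                       n_genes = 50, de_block = NULL, seed = 2)
  sim <- simulate_sc_matrix(cfg)
  pp <- percent_positive(sim$matrix)
  expect_true(all(pp$pct_positive == 0))

  sim2 <- simulate_sc_matrix(cfg)
  expect_identical(as.matrix(sim$matrix$counts), as.matrix(sim2$matrix$counts))
})

test_that("planted fold changes shift group means as configured", {
  de_block <- data.frame(gene = "gene_0001", group = "A", log2fc = 2)
  cl <- data.frame(cluster = "c1", compartment = "endothelial")
  cap <- matrix(0, 1, 2, dimnames = list("c1", c("A", "B")))
  cfg <- sc_sim_config(clusters = cl, n_cells_per_cluster = 2000,
                       treatment_groups = c("A", "B"), avhh_capture_prob = cap,
                       n_genes = 5, de_block = de_block,
                       baseline_expression = rep(4, 5), seed = 3)
  sim <- simulate_sc_matrix(cfg)
  m <- sim$matrix
  g1 <- as.vector(m$counts["gene_0001", ])
  grp <- m$cell_meta$group
  ratio <- mean(g1[grp == "A"]) / mean(g1[grp == "B"])
  expect_gt(ratio, 3.3)
  expect_lt(ratio, 4.8)
  # untouched gene stays flat
  g2 <- as.vector(m$counts["gene_0002", ])
  expect_lt(abs(mean(g2[grp == "A"]) / mean(g2[grp == "B"]) - 1), 0.15)
})
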