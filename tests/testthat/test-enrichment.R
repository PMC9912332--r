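# Brute-force enrichment oracle: explicit counting, no shared code with the
# implementation.
bf_enrichment <- function(subset_ids, all_ids, labels, value) {
  names(labels) <- all_ids
  f_lib <- sum(labels == value) / length(all_ids)
  f_sub <- sum(labels[subset_ids] == value) / length(subset_ids)
  f_sub / f_lib
}

test_that("decile set sizes use the ceiling and match a brute-force sort", {
  set.seed(21)
  scores <- rnorm(55)
  ds <- decile_sets(scores, 0.10)
  expect_equal(ds$k, 6)  # ceil(5.5)
  ord <- order(scores, decreasing = TRUE)
  expect_setequal(ds$top, ord[1:6])
  expect_setequal(ds$bottom, ord[50:55])

  ds10 <- decile_sets(rnorm(10), 0.10)
  expect_equal(ds10$k, 1)

  # degenerate ties: sets come purely from stable design order, disjoint
  dst <- decile_sets(rep(1, 20), 0.10, ids = sprintf("d%02d", 1:20))
  expect_equal(dst$top, c("d01", "d02"))
  expect_equal(dst$bottom, c("d19", "d20"))
  expect_length(intersect(dst$top, dst$bottom), 0)

  expect_error(decile_sets(rnorm(3), 0.5), "disjoint")
  expect_error(decile_sets(1, 0.1), "at least 2")
  expect_error(decile_sets(rnorm(10), 0.6), "fraction")
})

test_that("enrichment is subset frequency over library frequency", {
  labels <- c(rep("a", 5), rep("b", 15))  # f(a) = 0.25
  expect_equal(enrichment_score(c("a", "a", "b", "b"), labels, "a"), 2.0)
  expect_equal(enrichment_score(labels, labels, "a"), 1.0)  # chance level
  expect_equal(enrichment_score(rep("b", 4), labels, "a"), 0)
  expect_error(enrichment_score("a", labels, "zz"), "absent")
})

test_that("fold enrichment is the top-bottom difference with its boundary cases", {
  expect_equal(fold_enrichment(2.0, 0.5), 1.5)
  expect_equal(fold_enrichment(1.3, 1.3), 0)
  # value fills the bottom set: minimum possible fold is -1/f
  f <- 0.2
  expect_equal(fold_enrichment(0, 1 / f), -1 / f)
})

test_that("weighted conservation holds on random subsets: sum f_v * e_v = 1", {
  set.seed(77)
  n <- 40
  labels <- sample(letters[1:5], n, replace = TRUE)
  ids <- seq_len(n)
  for (rep in 1:200) {
    subset <- sample(ids, sample(2:20, 1))
    vals <- unique(labels)
    s <- sum(vapply(vals, function(v) {
      f <- mean(labels == v)
      f * enrichment_score(labels[subset], labels, v)
    }, numeric(1)))
    expect_equal(s, 1, tolerance = 1e-12)
  }
})

test_that("fold stays within [-1/f, 1/f] over random scores", {
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(20:60, 1)
    labels <- sample(c("x", "y", "z"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    scores <- rnorm(n)
    ds <- decile_sets(scores, 0.1)
    for (v in unique(labels)) {
      f <- mean(labels == v)
      e_top <- enrichment_score(labels[ds$top], labels, v)
      e_bot <- enrichment_score(labels[ds$bottom], labels, v)
      fold <- fold_enrichment(e_top, e_bot)
      expect_lte(fold, 1 / f + 1e-12)
      expect_gte(fold, -1 / f - 1e-12)
    }
  }
})

test_that("enrichment matches the explicit-counting oracle on small libraries", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    ids <- sprintf("d%02d", seq_len(n))
    labels <- sample(c("p", "q"), n, replace = TRUE)
    scores <- rnorm(n)
    ds <- decile_sets(scores, 0.2, ids = ids)
    for (v in c("p", "q")) {
      if (!v %in% labels) next
      e_imp <- enrichment_score(labels[match(ds$top, ids)], labels, v)
      expect_equal(e_imp, bf_enrichment(ds$top, ids, labels, v))
    }
  }
})

test_that("permutation p-values are seed-deterministic and detect a perfect split", {
  set.seed(42)
  n <- 40
  labels <- c(rep("hit", 4), rep("other", n - 4))
  scores <- c(rep(10, 4), rnorm(n - 4))  # 'hit' fills the top decile
  a <- permutation_pvalue(scores, labels, "hit", n_perm = 999, seed = 1)
  b <- permutation_pvalue(scores, labels, "hit", n_perm = 999, seed = 1)
  expect_identical(a, b)
  # exhaustive floor: observed |fold| is maximal, so p is near 1/(1+n_perm);
  # the number of permutations that tie the maximum is hypergeometric
  expect_lt(a$p, 0.01)
  expect_gte(a$p, 1 / 1000)
  expect_error(permutation_pvalue(scores, labels, "hit", n_perm = 50), "n_perm")
})

test_that("tie-randomized permutation p is deterministic and never above the conservative p", {
  set.seed(55)
  for (rep in 1:10) {
    scores <- rnorm(30)
    labels <- sample(rep(c("u", "v"), 15))
    r1 <- permutation_pvalue(scores, labels, "u", n_perm = 199, seed = rep,
                             ties = "random")
    r2 <- permutation_pvalue(scores, labels, "u", n_perm = 199, seed = rep,
                             ties = "random")
    cons <- permutation_pvalue(scores, labels, "u", n_perm = 199, seed = rep)
    expect_identical(r1, r2)
    expect_lte(r1$p, cons$p)
  }
})

test_that("enrich_all produces one row per value x cell type and finds a planted effect", {
  lib <- default_screen_library(seed = 1)
  clib <- subset_by_charge(lib, "cationic")
  cfg <- screen_sim_config(clib, n_mice = 2, depth_input = 5e4,
                           depth_sample = 2e4, seed = 8)
  sim <- simulate_screen_counts(cfg)
  ndt <- normalized_delivery_table(sim$counts, clib, qc_thresholds(min_sample_reads = 1e3))
  agg <- aggregate_mice(ndt)
  lung <- agg
  lung$mean <- agg$mean[, agg$cell_types$cell_type[agg$cell_types$tissue == "lung"]]
  en <- enrich_all(lung, lnp_properties(clib), property_names = "helper_lipid",
                   n_perm = 0)
  expect_equal(nrow(en), 3 * 5)  # 3 cationic lipids x 5 lung cell types
  ddab <- en[en$value == "18:0 DDAB", ]
  expect_true(all(ddab$fold > 0))
  # per-tissue summary averages cell types within the tissue
  tf <- tissue_fold(en, default_cell_types())
  expect_equal(tf$fold[tf$value == "18:0 DDAB"],
               mean(ddab$fold))
})

test_that("shuffled labels give near-zero mean fold (null behaviour)", {
  set.seed(3)
  n <- 50
  scores <- rnorm(n)
  folds <- replicate(300, {
    labels <- sample(rep(c("u", "v"), n / 2))
    ds <- decile_sets(scores, 0.1)
    fold_enrichment(enrichment_score(labels[ds$top], labels, "u"),
                    enrichment_score(labels[ds$bottom], labels, "u"))
  })
  expect_lt(abs(mean(folds)), 3 * sd(folds) / sqrt(length(folds)))
})
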