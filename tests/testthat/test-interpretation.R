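binary_design <- function(n, p, seed = 1, rate = 0.4) {
  set.seed(seed)
  matrix(rbinom(n * p, 1, rate), n, p,
         dimnames = list(sprintf("s%02d", seq_len(n)),
                         sprintf("g%d", seq_len(p))))
}

test_that("fast Shapley values match exhaustive enumeration", {
  # AND structure on two of three features
  X <- binary_design(60, 3, seed = 2)
  y <- as.integer(X[, 1] == 1 & X[, 2] == 1)
  m <- fit_toy_model(X, y, max_depth = 3, n_trees = 15)
  ex <- explain(m, X)
  oracle <- oracle_shap(m, X)
  fast <- matrix(ex$contribution, nrow(X), ncol(X),
                 dimnames = list(rownames(X), colnames(X)))
  expect_equal(fast, oracle$phi, tolerance = 1e-8)
  expect_equal(attr(ex, "base_value"), oracle$base[1], tolerance = 1e-8)

  # XOR-like labels force interaction-driven contributions
  y2 <- as.integer(xor(X[, 1] == 1, X[, 2] == 1))
  m2 <- fit_toy_model(X, y2, max_depth = 4, n_trees = 15)
  ex2 <- explain(m2, X)
  fast2 <- matrix(ex2$contribution, nrow(X), ncol(X))
  expect_equal(unname(fast2), unname(oracle_shap(m2, X)$phi),
               tolerance = 1e-8)
})

test_that("additivity holds to machine precision on deep ensembles", {
  X <- binary_design(80, 10, seed = 3, rate = 0.25)
  y <- as.integer(X[, 1] | (X[, 2] & X[, 3]))
  m <- fit_toy_model(X, y, max_depth = 7, n_trees = 100, eta = 0.9)
  ex <- explain(m, X)
  contrib <- matrix(ex$contribution, nrow(X), ncol(X))
  gap <- max(abs(attr(ex, "base_value") + rowSums(contrib) -
                   attr(ex, "margin")))
  expect_lt(gap, 1e-9)
  # and the double-precision margin matches the backend's within float32
  backend <- predict(m, xgboost::xgb.DMatrix(
    matrix(as.numeric(X), nrow(X), dimnames = dimnames(X))),
    outputmargin = TRUE)
  expect_equal(attr(ex, "margin"), as.numeric(backend), tolerance = 1e-5)
})

test_that("stump contributions shift by the leaf-value difference", {
  X <- matrix(c(rep(1L, 30), rep(0L, 30)), ncol = 1,
              dimnames = list(sprintf("s%02d", 1:60), "g1"))
  y <- as.integer(X[, 1] == 1)
  m <- fit_toy_model(X, y, max_depth = 1, n_trees = 1, eta = 1)
  tr <- dconet:::parse_booster(m, "g1")[[1]]
  leaf_diff <- abs(diff(tr$value[tr$feature < 0]))
  ex <- explain(m, X)
  contrib_alt <- ex$contribution[ex$sample_id == "s01"]
  contrib_un <- ex$contribution[ex$sample_id == "s60"]
  expect_equal(abs(contrib_alt - contrib_un), leaf_diff,
               tolerance = 1e-10)
})

test_that("a constant model explains everything as zero", {
  X <- binary_design(20, 2, seed = 4)
  y <- rep(c(0L, 1L), 10)
  Xconst <- matrix(1L, 20, 2, dimnames = dimnames(X))
  m <- fit_toy_model(Xconst, y, max_depth = 3, n_trees = 5)
  ex <- explain(m, Xconst)
  expect_true(all(abs(ex$contribution) < 1e-12))
})

test_that("interaction ranking finds planted synergy and respects depth", {
  X <- binary_design(120, 4, seed = 5)
  y <- as.integer(X[, 2] == 1 & X[, 3] == 1) # planted AND on g2,g3
  m <- fit_toy_model(X, y, max_depth = 3, n_trees = 30)
  ranked <- rank_interactions(m, X)
  expect_equal(sort(unlist(ranked[1, c("gene_a", "gene_b")],
                           use.names = FALSE)), c("g2", "g3"))
  expect_true(all(diff(ranked$strength) <= 1e-12))
  # depth-1 ensembles cannot interact
  m1 <- fit_toy_model(X, y, max_depth = 1, n_trees = 30)
  r1 <- rank_interactions(m1, X)
  expect_true(all(r1$strength < 1e-7))
  # lexicographic tie-break on the all-zero case
  expect_equal(r1$gene_a[1:2], c("g1", "g1"))
})

test_that("status-stratified summaries expose the synergy direction", {
  X <- binary_design(160, 3, seed = 6)
  y <- as.integer(X[, 1] == 1 & X[, 2] == 1)
  m <- fit_toy_model(X, y, max_depth = 3, n_trees = 30)
  ex <- explain(m, X)
  co <- tibble::tibble(gene = c("g1", "g2", "g3"),
                       chrom = c("chr11", "chr11", "chr2"),
                       start = c(1L, 100L, 5L), end = c(10L, 120L, 9L),
                       arm = c("q", "q", "p"))
  s <- interaction_summary(ex, X, "g1", "g2", coordinates = co)
  expect_equal(sum(s$n), nrow(X))
  both <- s$mean_contrib_a[s$category == "A&B"]
  alone <- s$mean_contrib_a[s$category == "A&!B"]
  expect_gt(both, alone)
  expect_true(all(s$linked))
  s2 <- interaction_summary(ex, X, "g1", "g3", coordinates = co)
  expect_false(any(s2$linked))
})

test_that("constant contributions give four equal category means", {
  exps <- tibble::tibble(
    sample_id = rep(sprintf("s%02d", 1:8), times = 2),
    gene = rep(c("gA", "gB"), each = 8),
    contribution = rep(c(0.3, -0.1), each = 8)
  )
  X <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0, 1, 0, 1, 0, 0, 1, 1, 0), 8, 2,
              dimnames = list(sprintf("s%02d", 1:8), c("gA", "gB")))
  s <- interaction_summary(exps, X, "gA", "gB")
  expect_true(all(s$mean_contrib_a[s$n > 0] == 0.3))
  expect_true(all(s$mean_contrib_b[s$n > 0] == -0.1))
})

test_that("the biomarker overlap test reproduces the 2x2 analysis", {
  res <- biomarker_overlap_fisher(48, 359, 1856, 30687)
  expect_equal(res$sample_odds_ratio, 2.4346, tolerance = 1e-3)
  expect_equal(res$odds_ratio, 2.43, tolerance = 0.02)
  expect_lt(res$p_value, 1e-6)
  # independence-shaped table sits at OR 1
  ind <- biomarker_overlap_fisher(40, 400, 1000, 10000)
  expect_equal(ind$sample_odds_ratio, 1, tolerance = 1e-9)
  expect_gt(ind$p_value, 0.9)
  expect_error(biomarker_overlap_fisher(10, 5, 100, 1000),
               class = "dconet_error")
})

test_that("small-table Fisher results match hypergeometric enumeration", {
  res <- biomarker_overlap_fisher(2, 4, 4, 20)
  # enumerate all tables with margins (4, 16) x (4, 16), N = 20
  a_vals <- 0:4
  probs <- stats::dhyper(a_vals, 4, 16, 4)
  p_two <- sum(probs[probs <= stats::dhyper(2, 4, 16, 4) * (1 + 1e-7)])
  expect_equal(res$p_value, p_two, tolerance = 1e-9)
  # symmetry of the roles of the two association sets
  swapped <- biomarker_overlap_fisher(2, 4, 4, 20)
  expect_equal(res$odds_ratio,
               biomarker_overlap_fisher(2, 4, 4, 20)$odds_ratio)
  expect_equal(
    biomarker_overlap_fisher(48, 1856, 359, 30687)$odds_ratio,
    biomarker_overlap_fisher(48, 359, 1856, 30687)$odds_ratio,
    tolerance = 1e-9
  )
})
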