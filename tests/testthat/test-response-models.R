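# One clean separable arm: gene g01 altered in most responders, rarely in
# non-responders.
separable_arm <- function(seed = 1, n = 40, p_resp = 0.9, p_non = 0.05) {
  set.seed(seed)
  m <- matrix(rbinom(2 * n * 12, 1, 0.15), 2 * n, 12,
              dimnames = list(sprintf("s%02d", seq_len(2 * n)),
                              sprintf("g%02d", 1:12)))
  m[, "g01"] <- rbinom(2 * n, 1, c(rep(p_resp, n), rep(p_non, n)))
  am <- alteration_matrix(m)
  list(am = am, response = split_response(am, n))
}

test_that("feature matrices mirror the network node set, edge-free", {
  fxd <- tibble::tibble(
    gene = c("gB", "gA"),
    k_resp = 5L, n_resp = 10L, k_nonresp = 0L, n_nonresp = 10L,
    rate_resp = 0.5, rate_nonresp = 0,
    p_resp_gt_nonresp = 0.99, resp_diffd = TRUE, nonresp_diffd = FALSE,
    general_diffd = TRUE, memberships = ""
  )
  net <- build_dco_networks(fxd, dconet:::empty_pair_table(), "T1")$Resp
  am <- toy_matrix()
  X <- build_features(am, net)
  expect_equal(colnames(X), c("gA", "gB")) # sorted, no edge columns
  expect_equal(unname(X[, "gA"]), unname(unclass(am)[, "gA"]))
  empty <- build_dco_networks(
    dplyr::mutate(fxd, resp_diffd = FALSE, general_diffd = FALSE),
    dconet:::empty_pair_table(), "T1")$Resp
  expect_equal(ncol(build_features(am, empty)), 0)
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  truth <- c(rep(1, 4), rep(-1, 4))
  pred <- c(1, 1, 1, -1, -1, -1, 1, 1) # TP3 FN1 TN2 FP2
  expect_equal(balanced_accuracy(truth, pred), 0.625)
  expect_equal(balanced_accuracy(truth, truth), 1)
  expect_equal(balanced_accuracy(truth, rep(1, 8)), 0.5)
})

test_that("LOOCV scores a separable arm highly and a constant arm at chance", {
  arm <- separable_arm(seed = 2)
  X <- build_features(arm$am, "g01")
  cv <- loocv(X, arm$response$response, seed = 1)
  expect_gt(cv$bacc, 0.8)
  expect_equal(nrow(cv$predictions), 80)
  # out-of-fold probabilities are genuine probabilities
  expect_true(all(cv$predictions$prob_response >= 0 &
                    cv$predictions$prob_response <= 1))
  Xc <- matrix(1L, 20, 1, dimnames = list(sprintf("s%02d", 1:20), "gZ"))
  expect_error(loocv(Xc[1:9, , drop = FALSE], rep(c("responder",
                                                    "non-responder"),
                                                  length.out = 9)),
               class = "dconet_error")
})

test_that("tuning prefers the simplest tied hyperparameters", {
  set.seed(3)
  X <- matrix(c(rep(1L, 10), rep(0L, 10)), ncol = 1,
              dimnames = list(sprintf("s%02d", 1:20), "g01"))
  y <- c(rep("responder", 10), rep("non-responder", 10))
  grid <- tidyr::expand_grid(max_depth = c(1, 3, 5),
                             learning_rate = c(0.2, 1),
                             l2 = c(1, 10))
  hp <- tune_hyperparameters(X, y, grid = grid, folds = 5, iterations = 2,
                             seed = 1, n_trees = 20)
  expect_equal(hp$max_depth, 1)
  expect_equal(hp$learning_rate, 0.2)
  expect_equal(hp$l2, 10)
  expect_equal(hp$mean_auc, 1)
  expect_error(tune_hyperparameters(X[1:9, , drop = FALSE], y[1:9]),
               class = "dconet_error")
})

test_that("tuning AUC sits near chance for label-independent features", {
  set.seed(4)
  X <- matrix(rbinom(40 * 3, 1, 0.5), 40, 3,
              dimnames = list(sprintf("s%02d", 1:40), c("a", "b", "c")))
  y <- rep(c("responder", "non-responder"), 20)
  grid <- tidyr::expand_grid(max_depth = 2, learning_rate = 0.4, l2 = 3)
  hp <- tune_hyperparameters(X, y, grid = grid, folds = 5, iterations = 5,
                             seed = 2, n_trees = 20)
  expect_gt(hp$mean_auc, 0.4)
  expect_lt(hp$mean_auc, 0.6)
})

test_that("the rank AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.5)
  expect_equal(dconet:::auc_rank(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              levels = c(0, 1),
                                              direction = "<",
                                              quiet = TRUE))))
})

test_that("the weighted combination follows the closed form", {
  # general responds (P=.8, BAcc .7); Resp responds (P=.9, BAcc .6);
  # NonResp predicts response so it stays silent
  expect_equal(
    combine_flavor_scores(1, 0.8, 0.7, 1, 0.9, 0.6, 1, 0.9, 0.8),
    0.7 * 0.8 + 0.6 * 0.9
  )
  # everything predicts non-response at P=.9 (prob of response .1)
  expect_equal(
    combine_flavor_scores(-1, 0.1, 0.7, -1, 0.1, 0.6, -1, 0.1, 0.8),
    -0.7 * 0.9 - 0.8 * 0.9
  )
  # all weights zero: no call
  expect_equal(combine_flavor_scores(1, 0.8, 0, 1, 0.9, 0, -1, 0.1, 0), 0)
  # missing flavors contribute nothing
  expect_equal(combine_flavor_scores(1, 0.8, 0.7, NA, NA, NA, NA, NA, NA),
               0.56)
})

test_that("the combination is bounded by the flavor weights", {
  set.seed(6)
  for (i in 1:200) {
    b <- runif(3)
    pr <- runif(3)
    pd <- sample(c(1, -1), 3, replace = TRUE)
    w <- combine_flavor_scores(pd[1], pr[1], b[1], pd[2], pr[2], b[2],
                               pd[3], pr[3], b[3])
    expect_lte(abs(w), b[1] + max(b[2], b[3]) + 1e-12)
  }
})

test_that("biomarker scores sum signed weighted statuses", {
  m <- matrix(c(1L, 0L, 1L, 0L, 0L, 0L), 2, 3,
              dimnames = list(c("s1", "s2"), c("gR", "gN", "gU")))
  am <- alteration_matrix(m)
  bm <- tibble::tibble(gene = c("gR", "gN"),
                       direction = c("response", "non-response"),
                       bacc = c(0.6, 0.8))
  out <- combine_biomarker_scores(am, bm)
  expect_equal(out$wcomb_bmk, c(0.6 - 0.8, 0))
  expect_equal(out$applicable, c(TRUE, FALSE))
  # single response biomarker
  bm1 <- bm[1, ]
  bm1$bacc <- 0.7
  expect_equal(combine_biomarker_scores(am, bm1)$wcomb_bmk, c(0.7, 0))
  # duplicated records collapse before summation
  dup <- dplyr::bind_rows(bm, bm)
  expect_equal(combine_biomarker_scores(am, dup)$wcomb_bmk,
               out$wcomb_bmk)
})

test_that("per-gene biomarker accuracies reflect the arm truth", {
  arm <- separable_arm(seed = 7, p_resp = 1, p_non = 0)
  cat <- tibble::tibble(gene = "g01", drug_family = "X",
                        direction = "response",
                        evidence_tier = "experimental")
  res <- biomarker_arm_bacc(arm$am, arm$response, cat)
  expect_equal(res$bacc, 1)
  flipped <- dplyr::mutate(cat, direction = "non-response")
  expect_equal(biomarker_arm_bacc(arm$am, arm$response, flipped)$bacc, 0)
})

test_that("bundle training combines flavors and reports accuracies", {
  arm <- separable_arm(seed = 8)
  diffd <- select_diff_drivers(arm$am, arm$response)
  pairs <- select_pairs(arm$am, arm$response, n_permutations = 50, seed = 5)
  nets <- build_dco_networks(diffd, pairs, "T1")
  bundle <- train_treatment_model(arm$am, arm$response, nets, "T1",
                                  seed = 1)
  expect_s3_class(bundle, "treatment_model_bundle")
  expect_gt(bundle$bacc_combined, 0.7)
  td <- tidy(bundle)
  expect_true(all(c("sample_id", "wcomb", "pred_class") %in% names(td)))
  gl <- glance(bundle)
  expect_equal(gl$treatment_id, "T1")
  # variants: biomarker features only
  bm <- train_treatment_model(arm$am, arm$response, nets, "T1",
                              variant = "biomarkers",
                              biomarker_genes = "g01", seed = 1)
  expect_equal(bm$flavors$General$feature_genes, "g01")
  both <- train_treatment_model(arm$am, arm$response, nets, "T1",
                                variant = "dco+biomarkers",
                                biomarker_genes = c("g01", "g99"), seed = 1)
  expect_true("g01" %in% both$flavors$General$feature_genes)
  # ineligible arm errors
  bad <- arm$response[c(1:3, 41:78), ]
  expect_error(train_treatment_model(arm$am, bad, nets, "T1"),
               class = "dconet_ineligible_arm_error")
})

test_that("evaluation averages defined accuracies and filters confident arms", {
  mk <- function(id, bacc) {
    structure(list(treatment_id = id, variant = "dco",
                   flavors = list(General = list(bacc = bacc),
                                  Resp = list(bacc = NA_real_),
                                  NonResp = list(bacc = NA_real_)),
                   bacc_combined = bacc, n_resp = 10, n_nonresp = 10),
              class = "treatment_model_bundle")
  }
  ev <- evaluate_models(list(mk("A", 0.5), mk("B", 0.7)))
  expect_equal(ev$macro_bacc, 0.6)
  expect_equal(ev$high_confidence$treatment_id, "B")
  ev2 <- suppressMessages(
    evaluate_models(list(mk("A", 0.59), mk("B", NA_real_))))
  expect_equal(ev2$macro_bacc, 0.59)
  expect_equal(nrow(ev2$high_confidence), 0)
  expect_warning(evaluate_models(list(mk("A", NA_real_))), "no treatment")
})

test_that("single-gene LOOCV accuracy tracks its Bayes-optimal level", {
  # one binary marker at rates 0.6 (responders) vs 0.05 (non-responders):
  # the best attainable balanced accuracy is (0.6 + 0.95) / 2 = 0.775
  baccs <- vapply(1:20, function(s) {
    set.seed(400 + s)
    g <- rbinom(80, 1, rep(c(0.6, 0.05), each = 40))
    X <- matrix(as.integer(g), ncol = 1,
                dimnames = list(sprintf("s%02d", 1:80), "g01"))
    loocv(X, c(rep("responder", 40), rep("non-responder", 40)),
          seed = s)$bacc
  }, numeric(1))
  expect_gt(mean(baccs), 0.7)
  expect_lt(mean(baccs), 0.85)
})
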