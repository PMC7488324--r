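# Shared fixtures and independent oracles, all built in code.

# Small deterministic alteration matrix.
toy_matrix <- function() {
  m <- matrix(
    c(1, 0, 1, 0,
      1, 1, 0, 0,
      0, 1, 1, 0,
      0, 0, 1, 1,
      1, 0, 0, 1),
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("s", 1:5), c("gA", "gB", "gC", "gD"))
  )
  alteration_matrix(m)
}

# Random binary matrix with named dims.
random_matrix <- function(n, p, rate = 0.2, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n * p, 1, rate), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("g%03d", seq_len(p))))
  alteration_matrix(m)
}

# Balanced responder/non-responder labels for a matrix.
split_response <- function(am, n_resp = floor(nrow(am) / 2)) {
  ids <- rownames(am)
  tibble::tibble(
    sample_id = ids,
    response = c(rep("responder", n_resp),
                 rep("non-responder", length(ids) - n_resp))
  )
}

# Monte-Carlo oracle for the beta inequality probability.
mc_beta_prob <- function(k1, n1, k2, n2, prior = c(1, 1), draws = 1e6,
                         seed = 42) {
  set.seed(seed)
  x <- rbeta(draws, k1 + prior[1], n1 - k1 + prior[2])
  y <- rbeta(draws, k2 + prior[1], n2 - k2 + prior[2])
  p <- mean(x > y)
  # variance floor: the plug-in estimate degenerates when all draws agree
  list(p = p, se = sqrt(max(p * (1 - p), 1 / draws) / draws))
}

# --- Independent Shapley oracle -------------------------------------------
# Exhaustive subset enumeration over the parsed trees: E[f(x) | x_S] is
# computed by cover-weighted traversal (follow x on features in S, average
# children otherwise), and Shapley values by the factorial-weighted sum
# over all subsets. Only feasible for few features; used to validate the
# fast path algorithm.

oracle_tree_expect <- function(tree, x, in_s, node = 1) {
  f <- tree$feature[node]
  if (f < 0) return(tree$value[node])
  left <- tree$left[node] + 1
  right <- tree$right[node] + 1
  if (in_s[f + 1]) {
    nxt <- if (x[f + 1] < tree$threshold[node]) left else right
    return(oracle_tree_expect(tree, x, in_s, nxt))
  }
  wl <- tree$cover[left]
  wr <- tree$cover[right]
  (wl * oracle_tree_expect(tree, x, in_s, left) +
     wr * oracle_tree_expect(tree, x, in_s, right)) / (wl + wr)
}

oracle_ensemble_expect <- function(trees, x, in_s) {
  sum(vapply(trees, oracle_tree_expect, numeric(1), x = x, in_s = in_s))
}

oracle_shap <- function(model, X) {
  trees <- dconet:::parse_booster(model, colnames(X))
  p <- ncol(X)
  stopifnot(p <= 6)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  phi <- matrix(0, nrow(X), p, dimnames = list(rownames(X), colnames(X)))
  base <- numeric(nrow(X))
  for (s in seq_len(nrow(X))) {
    x <- as.numeric(X[s, ])
    ev <- apply(subsets, 1, function(in_s) {
      oracle_ensemble_expect(trees, x, as.logical(in_s))
    })
    base[s] <- ev[which(rowSums(subsets) == 0)]
    for (j in seq_len(p)) {
      without <- which(!subsets[[j]])
      for (w in without) {
        in_s <- as.logical(subsets[w, ])
        with_j <- in_s
        with_j[j] <- TRUE
        widx <- which(apply(subsets, 1, function(r) {
          all(as.logical(r) == with_j)
        }))
        k <- sum(in_s)
        weight <- factorial(k) * factorial(p - k - 1) / factorial(p)
        phi[s, j] <- phi[s, j] + weight * (ev[widx] - ev[w])
      }
    }
  }
  list(phi = phi, base = base)
}

# --- Log-rank oracle ------------------------------------------------------
# Exhaustive risk-set tabulation of the two-group log-rank statistic.
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chisq <- (o - e)^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Train a tiny boosted model on explicit labels.
fit_toy_model <- function(X, y01, max_depth = 3, n_trees = 20, eta = 0.5) {
  dconet:::fit_gbm(X, y01,
                   list(max_depth = max_depth, learning_rate = eta,
                        l2 = 1, n_trees = n_trees),
                   seed = 1)
}
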