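fixture_selections <- function() {
  diffd <- tibble::tibble(
    gene = c("gA", "gB", "gC", "gD", "gE"),
    k_resp = c(8L, 6L, 2L, 1L, 0L), n_resp = 20L,
    k_nonresp = c(0L, 0L, 2L, 6L, 5L), n_nonresp = 20L,
    rate_resp = k_resp / 20, rate_nonresp = k_nonresp / 20,
    p_resp_gt_nonresp = c(0.999, 0.99, 0.5, 0.01, 0.005),
    resp_diffd = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    nonresp_diffd = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    general_diffd = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    memberships = ""
  )
  pairs <- tibble::tibble(
    gene_a = c("gB", "gX"), gene_b = c("gC", "gY"),
    count_all = c(4L, 3L), rate_all = c(0.1, 0.075),
    count_resp = c(4L, 3L), rate_resp = c(0.2, 0.15),
    count_nonresp = c(0L, 0L), rate_nonresp = c(0, 0),
    tendency_all = c(0.97, 0.99), tendency_resp = c(0.99, 0.99),
    tendency_nonresp = c(0.4, 0.5),
    p_diff_cooccurrence = c(0.99, 0.98),
    null_q95_resp = c(0.9, 0.9), null_q95_nonresp = c(0.9, 0.9),
    general_ps = c(TRUE, FALSE), resp_ps = c(TRUE, TRUE),
    nonresp_ps = c(FALSE, FALSE), memberships = ""
  )
  list(diffd = diffd, pairs = pairs)
}

test_that("networks union drivers and pair genes with deduplication", {
  fx <- fixture_selections()
  nets <- build_dco_networks(fx$diffd, fx$pairs, "T1")
  resp <- nets$Resp
  expect_equal(sort(resp$nodes$gene), c("gA", "gB", "gC", "gX", "gY"))
  expect_equal(resp$nodes$source[resp$nodes$gene == "gB"], "both")
  expect_equal(resp$nodes$source[resp$nodes$gene == "gA"], "DiffD")
  expect_equal(resp$nodes$source[resp$nodes$gene == "gX"], "DiP")
  expect_equal(nrow(resp$edges), 2)
  # general flavor: only the general pair
  expect_equal(nrow(nets$General$edges), 1)
  expect_true(all(c(nets$General$edges$gene_a, nets$General$edges$gene_b)
                  %in% nets$General$nodes$gene))
})

test_that("empty selections give valid empty networks", {
  fx <- fixture_selections()
  none <- dplyr::mutate(fx$diffd, resp_diffd = FALSE, nonresp_diffd = FALSE,
                        general_diffd = FALSE)
  no_pairs <- fx$pairs[0, ]
  nets <- build_dco_networks(none, no_pairs, "T1")
  expect_equal(nrow(nets$Resp$nodes), 0)
  expect_equal(network_genes(nets$Resp), character(0))
  s <- network_summary(nets$Resp)
  expect_equal(s$networks$n_nodes, 0L)
  expect_equal(s$networks$n_edges, 0L)
})

test_that("importance pruning removes silent nodes and their edges", {
  fx <- fixture_selections()
  net <- build_dco_networks(fx$diffd, fx$pairs, "T1")$Resp
  imp <- tibble::tibble(gene = c("gA", "gB", "gC", "gX"),
                        importance = c(0.5, 0.3, 0, 0.2))
  pruned <- suppressMessages(prune_by_importance(net, imp))
  expect_false("gC" %in% pruned$nodes$gene) # zero importance
  expect_false("gY" %in% pruned$nodes$gene) # missing treated as zero
  expect_equal(nrow(pruned$edges), 0)       # both edges lost an endpoint
  again <- suppressMessages(prune_by_importance(pruned, imp))
  expect_identical(again$nodes$gene, pruned$nodes$gene)
  all_pos <- tibble::tibble(gene = net$nodes$gene, importance = 1)
  expect_identical(prune_by_importance(net, all_pos)$nodes$gene,
                   net$nodes$gene)
})

test_that("network summaries count nodes, edges and per-sample hits", {
  fx <- fixture_selections()
  net <- build_dco_networks(fx$diffd, fx$pairs, "T1")$General
  m <- matrix(0L, 2, 3, dimnames = list(c("s1", "s2"),
                                        c("gA", "gB", "gC")))
  m["s1", c("gB", "gC")] <- 1L
  am <- alteration_matrix(m)
  s <- network_summary(net, am)
  # general nodes: gA,gB,gD,gE from DiffD plus gC via the general pair
  expect_equal(s$networks$n_nodes, 5L)
  expect_equal(s$samples$n_altered_drivers[s$samples$sample_id == "s1"], 2L)
  expect_equal(s$samples$n_altered_pairs[s$samples$sample_id == "s1"], 1L)
  expect_equal(s$samples$n_altered_pairs[s$samples$sample_id == "s2"], 0L)
})

test_that("GraphML round-trips nodes, edges and attributes", {
  fx <- fixture_selections()
  net <- build_dco_networks(fx$diffd, fx$pairs, "T1")$Resp
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, "graphml")
  back <- read_network(path)
  expect_equal(back$treatment_id, net$treatment_id)
  expect_equal(back$flavor, net$flavor)
  expect_equal(sort(back$nodes$gene), sort(net$nodes$gene))
  ord_a <- order(net$nodes$gene)
  expect_equal(back$nodes$p_resp_gt_nonresp,
               net$nodes$p_resp_gt_nonresp[ord_a], tolerance = 1e-12)
  key <- function(e) paste(pmin(e$gene_a, e$gene_b),
                           pmax(e$gene_a, e$gene_b))
  expect_setequal(key(back$edges), key(net$edges))
  m <- match(key(net$edges), key(back$edges))
  expect_equal(back$edges$p_diff_cooccurrence[m],
               net$edges$p_diff_cooccurrence, tolerance = 1e-12)
})

test_that("SIF export writes co edges plus isolated nodes", {
  fx <- fixture_selections()
  net <- build_dco_networks(fx$diffd, fx$pairs, "T1")$Resp
  path <- withr::local_tempfile(fileext = ".sif")
  write_network(net, path, "sif")
  lines <- readLines(path)
  expect_true("gB\tco\tgC" %in% lines)
  expect_true("gA" %in% lines) # isolated DiffD node
  # empty network still writes a valid zero-edge file
  none <- dplyr::mutate(fx$diffd, resp_diffd = FALSE, nonresp_diffd = FALSE,
                        general_diffd = FALSE)
  empty <- build_dco_networks(none, fx$pairs[0, ], "T1")$Resp
  p2 <- withr::local_tempfile(fileext = ".sif")
  write_network(empty, p2, "sif")
  expect_length(readLines(p2), 0)
  expect_error(write_network(net, path, "dot"),
               class = "dconet_usage_error")
})

test_that("pairs on the same chromosome arm are flagged linked", {
  fx <- fixture_selections()
  coords <- tibble::tibble(
    gene = c("gB", "gC", "gX", "gY"),
    chrom = c("chr11", "chr11", "chr1", "chr2"),
    start = c(100L, 5000L, 1L, 1L), end = c(200L, 5100L, 10L, 10L),
    arm = c("q", "q", "p", "p")
  )
  nets <- build_dco_networks(fx$diffd, fx$pairs, "T1", coordinates = coords)
  e <- nets$Resp$edges
  expect_true(e$linked[e$gene_a == "gB"])
  expect_false(e$linked[e$gene_a == "gX"])
  expect_equal(e$distance_bp[e$gene_a == "gB"], 4800)
})
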