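# Assembly of driver co-occurrence (DCO) networks: differentially altered
# drivers (DiffD) are nodes; selected co-occurring pairs (Ps) contribute
# their genes as nodes (DiP) and an edge between them.

new_dco_network <- function(treatment_id, flavor, nodes, edges) {
  stopifnot(flavor %in% c("General", "Resp", "NonResp"))
  if (nrow(edges) > 0) {
    if (any(edges$gene_a == edges$gene_b)) {
      stop_dconet("self-loops are not allowed in a DCO network",
                  "dconet_network_error")
    }
    if (!all(c(edges$gene_a, edges$gene_b) %in% nodes$gene)) {
      stop_dconet("every edge endpoint must be a node",
                  "dconet_network_error")
    }
  }
  structure(
    list(treatment_id = treatment_id, flavor = flavor,
         nodes = nodes, edges = edges),
    class = "dco_network"
  )
}

#' @export
print.dco_network <- function(x, ...) {
  cat(sprintf("<dco_network> treatment %s, %s flavor: %d nodes, %d edges\n",
              x$treatment_id, x$flavor, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Build the three DCO networks of a treatment arm
#'
#' Combines the differential-driver table ([select_diff_drivers()]) and
#' the selected-pair table ([select_pairs()]) into General, Resp and
#' NonResp networks. For each flavor, nodes are the union of the
#' flavor's differential drivers and the genes of its selected pairs;
#' edges are the selected pairs. Node attributes carry the group
#' alteration rates, the enrichment probability, and whether the gene
#' entered as a differential driver (`DiffD`), a pair gene (`DiP`), or
#' both. When `coordinates` are supplied, each edge gets a `linked` flag
#' (both genes on the same chromosome arm) and a basepair distance.
#'
#' @param diffd Tibble from [select_diff_drivers()].
#' @param pairs Tibble from [select_pairs()] (may be empty).
#' @param treatment_id Treatment identifier attached to the networks.
#' @param coordinates Optional tibble from [read_gene_coordinates()].
#' @return A named list of three `dco_network` objects:
#'   `General`, `Resp`, `NonResp`.
#' @export
build_dco_networks <- function(diffd, pairs, treatment_id,
                               coordinates = NULL) {
  flavors <- c(General = "general", Resp = "resp", NonResp = "nonresp")
  out <- lapply(names(flavors), function(fl) {
    key <- flavors[[fl]]
    dg <- diffd$gene[diffd[[paste0(key, "_diffd")]]]
    pe <- pairs[pairs[[paste0(key, "_ps")]], , drop = FALSE]
    pg <- unique(c(pe$gene_a, pe$gene_b))
    genes <- sort(union(dg, pg))
    nodes <- tibble::tibble(
      gene = genes,
      source = dplyr::case_when(
        genes %in% dg & genes %in% pg ~ "both",
        genes %in% dg ~ "DiffD",
        .default = "DiP"
      )
    )
    nodes <- dplyr::left_join(
      nodes,
      diffd[, c("gene", "rate_resp", "rate_nonresp", "p_resp_gt_nonresp")],
      by = "gene"
    )
    edges <- tibble::as_tibble(pe)
    if (!is.null(coordinates) && nrow(edges) > 0) {
      edges <- annotate_linkage(edges, coordinates)
    }
    new_dco_network(treatment_id, fl, nodes, edges)
  })
  names(out) <- names(flavors)
  out
}

# Same-chromosome-arm flag plus basepair distance for each edge.
annotate_linkage <- function(edges, coordinates) {
  ca <- coordinates[match(edges$gene_a, coordinates$gene), ]
  cb <- coordinates[match(edges$gene_b, coordinates$gene), ]
  edges$linked <- !is.na(ca$chrom) & !is.na(cb$chrom) &
    ca$chrom == cb$chrom & ca$arm == cb$arm &
    ca$arm != "unknown"
  edges$distance_bp <- ifelse(
    !is.na(ca$chrom) & !is.na(cb$chrom) & ca$chrom == cb$chrom,
    pmax(ca$start, cb$start) - pmin(ca$end, cb$end),
    NA_real_
  )
  edges$distance_bp <- pmax(edges$distance_bp, 0)
  edges
}

#' Feature gene list of a DCO network
#'
#' The sorted node set; exactly the columns of the downstream feature
#' matrix.
#'
#' @param network A `dco_network`.
#' @return Character vector of gene ids.
#' @export
network_genes <- function(network) {
  stopifnot(inherits(network, "dco_network"))
  sort(network$nodes$gene)
}

#' Prune a DCO network by model feature importance
#'
#' Removes nodes whose mean feature importance across the
#' leave-one-out folds is at or below `threshold`, together with their
#' incident edges. Idempotent.
#'
#' @param network A `dco_network`.
#' @param importances Data frame with columns `gene` and `importance`.
#'   Genes missing from the table are treated as importance 0 (logged).
#' @param threshold Importance cutoff (default 0: drop non-contributing
#'   genes).
#' @return The pruned `dco_network`.
#' @export
prune_by_importance <- function(network, importances, threshold = 0) {
  stopifnot(inherits(network, "dco_network"))
  imp <- importances$importance[match(network$nodes$gene, importances$gene)]
  n_missing <- sum(is.na(imp))
  if (n_missing > 0) {
    inform(sprintf("prune_by_importance: %d nodes without importance treated as 0",
                   n_missing))
    imp[is.na(imp)] <- 0
  }
  keep <- network$nodes$gene[imp > threshold]
  nodes <- network$nodes[network$nodes$gene %in% keep, , drop = FALSE]
  edges <- network$edges
  if (nrow(edges) > 0) {
    edges <- edges[edges$gene_a %in% keep & edges$gene_b %in% keep, ,
                   drop = FALSE]
  }
  new_dco_network(network$treatment_id, network$flavor, nodes, edges)
}

#' Summarise DCO networks
#'
#' Node and edge counts per network, plus (when an alteration matrix is
#' supplied) the per-sample number of altered network genes and of fully
#' co-altered selected pairs.
#'
#' @param networks A `dco_network` or list of them.
#' @param am Optional [alteration_matrix()] for the per-sample counts.
#' @return A list with tibbles `networks` and (optionally) `samples`.
#' @export
network_summary <- function(networks, am = NULL) {
  if (inherits(networks, "dco_network")) networks <- list(networks)
  nets <- tibble::tibble(
    treatment_id = vapply(networks, function(n) n$treatment_id, character(1)),
    flavor = vapply(networks, function(n) n$flavor, character(1)),
    n_nodes = vapply(networks, function(n) nrow(n$nodes), integer(1)),
    n_edges = vapply(networks, function(n) nrow(n$edges), integer(1))
  )
  out <- list(networks = nets)
  if (!is.null(am)) {
    mat <- unclass(am)
    out$samples <- purrr::map_dfr(networks, function(n) {
      genes <- intersect(n$nodes$gene, colnames(mat))
      altered <- if (length(genes) > 0) {
        rowSums(mat[, genes, drop = FALSE])
      } else {
        rep(0L, nrow(mat))
      }
      pair_hits <- rep(0L, nrow(mat))
      if (nrow(n$edges) > 0) {
        for (i in seq_len(nrow(n$edges))) {
          ga <- n$edges$gene_a[i]; gb <- n$edges$gene_b[i]
          if (all(c(ga, gb) %in% colnames(mat))) {
            pair_hits <- pair_hits + (mat[, ga] * mat[, gb])
          }
        }
      }
      tibble::tibble(treatment_id = n$treatment_id, flavor = n$flavor,
                     sample_id = rownames(mat),
                     n_altered_drivers = as.integer(altered),
                     n_altered_pairs = as.integer(pair_hits))
    })
  }
  out
}

#' Convert a DCO network to an igraph object
#'
#' @param network A `dco_network`.
#' @return An undirected [igraph::graph] with node and edge attributes.
#' @export
dco_as_igraph <- function(network) {
  stopifnot(inherits(network, "dco_network"))
  vertices <- as.data.frame(network$nodes)
  names(vertices)[1] <- "name"
  edges <- as.data.frame(network$edges)
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, nrow(vertices))
    if (nrow(vertices) > 0) {
      for (cl in names(vertices)) {
        g <- igraph::set_vertex_attr(g, cl, value = vertices[[cl]])
      }
    }
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = vertices)
  }
  igraph::graph_attr(g, "treatment_id") <- network$treatment_id
  igraph::graph_attr(g, "flavor") <- network$flavor
  g
}

#' Write a DCO network to GraphML or SIF
#'
#' GraphML round-trips all node and edge attributes and is the format to
#' load into Cytoscape; SIF is the minimal interaction format with the
#' interaction label `"co"` (isolated nodes are written as single-column
#' lines).
#'
#' @param network A `dco_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "sif")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) {
                       stop_dconet(sprintf("unknown network format: %s",
                                           format[1]),
                                   "dconet_usage_error")
                     })
  if (format == "graphml") {
    g <- dco_as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- character(0)
    if (nrow(network$edges) > 0) {
      lines <- sprintf("%s\tco\t%s", network$edges$gene_a,
                       network$edges$gene_b)
      connected <- unique(c(network$edges$gene_a, network$edges$gene_b))
    } else {
      connected <- character(0)
    }
    isolated <- setdiff(network$nodes$gene, connected)
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}

#' Read a DCO network written by [write_network()]
#'
#' @param path GraphML file path.
#' @return A `dco_network` with the node and edge attributes restored.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  nodes <- tibble::as_tibble(va[setdiff(names(va), "id")])
  names(nodes)[names(nodes) == "name"] <- "gene"
  nodes <- nodes[order(nodes$gene), , drop = FALSE]
  el <- igraph::as_edgelist(g)
  ea <- igraph::edge_attr(g)
  if (nrow(el) > 0) {
    edges <- tibble::tibble(gene_a = pmin(el[, 1], el[, 2]),
                            gene_b = pmax(el[, 1], el[, 2]))
    for (nm in setdiff(names(ea), c("gene_a", "gene_b"))) {
      edges[[nm]] <- ea[[nm]]
    }
    if (all(c("gene_a", "gene_b") %in% names(ea))) {
      edges$gene_a <- ea$gene_a
      edges$gene_b <- ea$gene_b
    }
  } else {
    edges <- tibble::tibble(gene_a = character(), gene_b = character())
  }
  new_dco_network(igraph::graph_attr(g, "treatment_id"),
                  igraph::graph_attr(g, "flavor"), nodes, edges)
}
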