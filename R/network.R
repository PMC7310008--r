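#' Build a microbe co-abundance network
#'
#' Computes pairwise Pearson correlations between microbe profiles and keeps
#' an undirected edge wherever the correlation reaches `cutoff` (positive
#' co-abundance; set `signed = TRUE` to threshold on `|r|` instead). Profiles can come from the
#' raw abundance table (columns over patients; conventional cutoff 0.3) or
#' from the topic-space representation, each microbe's column of the
#' microbe model's phi (conventional cutoff 0.8). Isolated nodes are
#' retained.
#'
#' @param X Microbe abundance tibble (patients x microbes), or an
#'   `lda_model` / phi matrix whose columns are microbes.
#' @param cutoff Correlation threshold in (0, 1].
#' @param signed Threshold on `|r|` rather than `r`.
#' @return List of class `microbe_network`: igraph `graph`, `edges` tibble
#'   `(from, to, r)`, `nodes`, `cutoff`, `source` (`"raw"` or `"topic"`).
#' @export
build_network <- function(X, cutoff, signed = FALSE) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff > 1) {
    abort("cutoff must lie in (0, 1]")
  }
  if (inherits(X, "lda_model")) {
    m <- X$phi
    src <- "topic"
  } else if (is.matrix(X)) {
    m <- X
    src <- "topic"
  } else {
    m <- abund_matrix(X)
    src <- "raw"
  }
  if (ncol(m) < 3) abort("need at least 3 microbes")
  r <- suppressWarnings(cor(m))
  keep <- if (signed) abs(r) >= cutoff else r >= cutoff
  keep[is.na(keep)] <- FALSE
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble::tibble(from = colnames(m)[idx[, 1]],
                          to = colnames(m)[idx[, 2]],
                          r = r[idx])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = colnames(m))
  structure(list(graph = g, edges = edges, nodes = colnames(m),
                 cutoff = cutoff, source = src, signed = signed,
                 modules = NULL, topic_labels = NULL),
            class = "microbe_network")
}

#' @export
print.microbe_network <- function(x, ...) {
  cat(sprintf("Microbe co-abundance network (%s, cutoff %.2f): %d nodes, %d edges\n",
              x$source, x$cutoff, length(x$nodes), nrow(x$edges)))
  if (!is.null(x$modules)) {
    cat(sprintf("  %d modules detected (%s)\n",
                length(unique(x$modules$module)), attr(x$modules, "method")))
  }
  invisible(x)
}

#' Detect network modules
#'
#' Partitions the network into densely connected modules. Methods:
#' `"edge_betweenness"` (divisive removal of the highest-betweenness edges,
#' cut at maximum modularity), `"label_propagation"` (seeded), and
#' `"fast_greedy"` (agglomerative modularity optimization; runs on the
#' network with multi-edges/loops already absent).
#'
#' @param net A `microbe_network`.
#' @param method Community-detection algorithm.
#' @param seed Seed (label propagation is stochastic).
#' @return `net` with `modules`: tibble `(microbe, module)`, every node in
#'   exactly one module.
#' @export
detect_modules <- function(net, method = c("edge_betweenness",
                                           "label_propagation", "fast_greedy"),
                           seed = 1L) {
  method <- match.arg(method)
  if (length(net$nodes) == 0) abort("empty graph")
  comm <- withr::with_seed(seed, switch(
    method,
    edge_betweenness = igraph::cluster_edge_betweenness(net$graph,
                                                        weights = NULL),
    label_propagation = igraph::cluster_label_prop(net$graph),
    fast_greedy = igraph::cluster_fast_greedy(net$graph)
  ))
  mem <- igraph::membership(comm)
  modules <- tibble::tibble(microbe = names(mem), module = as.integer(mem))
  attr(modules, "method") <- method
  net$modules <- modules
  net
}

#' Label network nodes with their top topics
#'
#' A microbe is labeled with topic `k` whenever it ranks among the `top_n`
#' highest-weighted microbes of that topic's phi row; ties at the boundary
#' are all included, and a microbe may carry several labels.
#'
#' @param net A `microbe_network`.
#' @param phiM Microbe `lda_model` (or phi matrix, topics x microbes).
#' @param top_n Rank cut per topic (default 10).
#' @return `net` with `topic_labels`: tibble `(microbe, topics)` where
#'   `topics` is a list-column of integer topic ids.
#' @export
label_modules_with_topics <- function(net, phiM, top_n = 10L) {
  phi <- if (inherits(phiM, "lda_model")) phiM$phi else phiM
  miss <- setdiff(net$nodes, colnames(phi))
  if (length(miss)) {
    abort(paste0("node(s) missing from the topic vocabulary: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  labels <- setNames(vector("list", length(net$nodes)), net$nodes)
  for (k in seq_len(nrow(phi))) {
    row <- phi[k, ]
    nth <- sort(row, decreasing = TRUE)[min(top_n, length(row))]
    top <- names(row)[row >= nth]
    for (mic in intersect(top, net$nodes)) {
      labels[[mic]] <- c(labels[[mic]], k)
    }
  }
  net$topic_labels <- tibble::tibble(microbe = net$nodes,
                                     topics = unname(labels[net$nodes]))
  net
}

#' Tidy a microbe network into node and edge tables
#'
#' @param x A `microbe_network`.
#' @param what `"nodes"` (default; module and topic labels if present) or
#'   `"edges"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.microbe_network <- function(x, what = c("nodes", "edges"), ...) {
  what <- match.arg(what)
  if (what == "edges") return(x$edges)
  out <- tibble::tibble(microbe = x$nodes)
  if (!is.null(x$modules)) out <- dplyr::left_join(out, x$modules, by = "microbe")
  if (!is.null(x$topic_labels)) {
    out <- dplyr::left_join(out, x$topic_labels, by = "microbe")
  }
  out
}

#' Modularity of the detected partition
#'
#' @param net A `microbe_network` with modules detected.
#' @return Newman modularity of the module partition on the graph.
#' @export
network_modularity <- function(net) {
  if (is.null(net$modules)) abort("run detect_modules() first")
  igraph::modularity(net$graph, net$modules$module)
}

#' Write a network as edge-list and module TSVs (plus optional GraphML)
#'
#' @param net A `microbe_network`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @param graphml Also write GraphML.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, dir, prefix = "network", graphml = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_edges <- file.path(dir, paste0(prefix, "_edges.tsv"))
  write_table(net$edges, p_edges)
  paths <- p_edges
  nodes <- tidy(net, "nodes")
  if ("topics" %in% names(nodes)) {
    nodes$topics <- vapply(nodes$topics, function(t) paste(t, collapse = ","),
                           character(1))
  }
  p_nodes <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  write_table(nodes, p_nodes)
  paths <- c(paths, p_nodes)
  if (graphml) {
    p_gml <- file.path(dir, paste0(prefix, ".graphml"))
    igraph::write_graph(net$graph, p_gml, format = "graphml")
    paths <- c(paths, p_gml)
  }
  invisible(paths)
}
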