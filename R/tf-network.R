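# Transcription-factor association by hypergeometric overlap of lncRNA
# co-expressed gene lists with TF target sets, and construction of the
# bipartite lncRNA-TF and tripartite lncRNA-TF-target networks for export.

#' Construct a validated network graph
#'
#' @param nodes data.frame with columns `id`, `node_type` in
#'   {lncRNA, TF, gene}.
#' @param edges data.frame with columns `source`, `target`, `relation`,
#'   `score`.
#' @return A `NetworkGraph`.
#' @export
network_graph <- function(nodes, edges) {
  assert_that(all(c("id", "node_type") %in% names(nodes)),
              "nodes need columns id, node_type")
  assert_that(all(c("source", "target", "relation", "score") %in% names(edges)),
              "edges need columns source, target, relation, score")
  assert_that(!anyDuplicated(nodes$id), "duplicate node ids")
  assert_that(all(nodes$node_type %in% c("lncRNA", "TF", "gene")),
              "node_type must be lncRNA, TF or gene")
  assert_that(all(edges$source %in% nodes$id) && all(edges$target %in% nodes$id),
              "edge endpoint missing from node table")
  assert_that(!any(edges$source == edges$target), "self-edges not allowed")
  key <- paste(edges$source, edges$target, edges$relation, sep = "\r")
  assert_that(!anyDuplicated(key), "duplicate (source, target, relation) edge")
  structure(list(nodes = nodes[, c("id", "node_type")],
                 edges = edges[, c("source", "target", "relation", "score")]),
            class = "NetworkGraph")
}

#' @export
print.NetworkGraph <- function(x, ...) {
  cat(sprintf("NetworkGraph: %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(sprintf("%s=%d", names(table(x$nodes$node_type)),
                            as.integer(table(x$nodes$node_type))),
                    collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Associate transcription factors with differential lncRNAs
#'
#' For every (lncRNA, TF) combination, tests the overlap between the
#' lncRNA's co-expressed gene list and the TF's target set within the
#' universe with [hypergeom_upper_tail()]; BH correction is applied across
#' all tested combinations and associations retained at `q <= q_max`.
#'
#' @param coexpr_lists Named list: lncRNA probe id -> character vector of
#'   co-expressed gene symbols (from [coexpressed_genes()]).
#' @param tf_sets A tf_targets-kind [gene_set_collection()].
#' @param universe Background gene symbols.
#' @param q_max Association significance threshold (default 0.05).
#' @return data.frame with columns `lncrna`, `tf`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, `overlap_members`, retained rows only.
#' @export
associate_tfs <- function(coexpr_lists, tf_sets, universe, q_max = 0.05) {
  assert_that(tf_sets$kind_tag == "tf_targets",
              "tf_sets must have kind_tag 'tf_targets'")
  universe <- unique(as.character(universe))
  empty <- data.frame(lncrna = character(0), tf = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), overlap_members = character(0),
                      stringsAsFactors = FALSE)
  if (length(coexpr_lists) == 0 || length(tf_sets$sets) == 0 ||
      length(universe) == 0) {
    return(empty)
  }
  N <- length(universe)
  rows <- list()
  for (lnc in names(coexpr_lists)) {
    genes <- intersect(unique(coexpr_lists[[lnc]]), universe)
    n <- length(genes)
    for (tf in names(tf_sets$sets)) {
      targets <- intersect(tf_sets$sets[[tf]], universe)
      K <- length(targets)
      if (K == 0) next
      overlap <- intersect(genes, targets)
      k <- length(overlap)
      rows[[length(rows) + 1L]] <-
        data.frame(lncrna = lnc, tf = tf, k = k, K = K, n = n, N = N,
                   p_value = hypergeom_upper_tail(k, K, n, N),
                   overlap_members = paste(sort(overlap), collapse = ","),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  res <- do.call(rbind, rows)
  res$q_value <- bh_fdr(res$p_value)
  res <- res[res$q_value <= q_max, , drop = FALSE]
  res <- res[order(res$p_value, res$lncrna, res$tf), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("lncrna", "tf", "k", "K", "n", "N", "p_value", "q_value",
          "overlap_members")]
}

# -log10 P edge score, capped so exports stay finite and sortable
edge_score <- function(p) pmin(300, -log10(pmax(p, 1e-300)))

#' Build the bipartite lncRNA-TF co-expression network
#'
#' @param associations Table from [associate_tfs()].
#' @return A `NetworkGraph` whose lncRNA-TF edges carry `-log10 P` scores.
#' @export
build_lncrna_tf_network <- function(associations) {
  if (nrow(associations) == 0) {
    return(network_graph(
      data.frame(id = character(0), node_type = character(0)),
      data.frame(source = character(0), target = character(0),
                 relation = character(0), score = numeric(0))))
  }
  nodes <- rbind(
    data.frame(id = unique(associations$lncrna), node_type = "lncRNA",
               stringsAsFactors = FALSE),
    data.frame(id = unique(associations$tf), node_type = "TF",
               stringsAsFactors = FALSE))
  edges <- data.frame(source = associations$lncrna,
                      target = associations$tf,
                      relation = "tf_association",
                      score = edge_score(associations$p_value),
                      stringsAsFactors = FALSE)
  network_graph(nodes, edges)
}

#' Build the tripartite lncRNA-TF-target network
#'
#' lncRNA-TF edges come from the association table; a TF-gene edge is added
#' for each target gene that is also in the associated lncRNA's co-expressed
#' list (genes regulated by the lncRNA and the TF simultaneously).
#'
#' @param associations Table from [associate_tfs()].
#' @param tf_sets The tf_targets collection.
#' @param coexpr_lists Named list of co-expressed gene symbols per lncRNA.
#' @return A `NetworkGraph`.
#' @export
build_lncrna_tf_gene_network <- function(associations, tf_sets, coexpr_lists) {
  base <- build_lncrna_tf_network(associations)
  if (nrow(associations) == 0) return(base)
  gene_edges <- list()
  for (i in seq_len(nrow(associations))) {
    lnc <- associations$lncrna[i]
    tf <- associations$tf[i]
    shared <- intersect(tf_sets$sets[[tf]], coexpr_lists[[lnc]])
    if (length(shared) > 0) {
      gene_edges[[length(gene_edges) + 1L]] <-
        data.frame(source = tf, target = shared, relation = "tf_target",
                   score = 1, stringsAsFactors = FALSE)
    }
  }
  edges <- base$edges
  if (length(gene_edges) > 0) {
    ge <- unique(do.call(rbind, gene_edges))
    genes <- setdiff(unique(ge$target), base$nodes$id)
    nodes <- rbind(base$nodes,
                   data.frame(id = genes, node_type = "gene",
                              stringsAsFactors = FALSE))
    edges <- rbind(edges, ge)
  } else {
    nodes <- base$nodes
  }
  network_graph(nodes, edges)
}

#' Summary statistics of a network
#'
#' @param graph A `NetworkGraph`.
#' @return List with `n_nodes`, `nodes_by_type`, `n_edges`,
#'   `n_components` (connected components, isolated nodes counted), and
#'   `degree` (named per-node degree).
#' @export
network_summary <- function(graph) {
  ids <- graph$nodes$id
  deg <- stats::setNames(rep(0L, length(ids)), ids)
  if (nrow(graph$edges) > 0) {
    t1 <- table(graph$edges$source)
    t2 <- table(graph$edges$target)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  # connected components by label propagation over an adjacency list
  comp <- seq_along(ids)
  names(comp) <- ids
  if (nrow(graph$edges) > 0) {
    adj <- split(c(graph$edges$target, graph$edges$source),
                 c(graph$edges$source, graph$edges$target))
    visited <- stats::setNames(rep(FALSE, length(ids)), ids)
    label <- 0L
    for (start in ids) {
      if (visited[start]) next
      label <- label + 1L
      queue <- start
      visited[start] <- TRUE
      while (length(queue) > 0) {
        v <- queue[1]
        queue <- queue[-1]
        comp[v] <- label
        nb <- adj[[v]]
        nb <- nb[!visited[nb]]
        if (length(nb) > 0) {
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    n_comp <- label
  } else {
    n_comp <- length(ids)
  }
  list(n_nodes = length(ids),
       nodes_by_type = table(graph$nodes$node_type),
       n_edges = nrow(graph$edges),
       n_components = n_comp,
       degree = deg)
}
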