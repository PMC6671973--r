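# tf_network: TF association and network construction

test_that("associate_tfs recovers list-level planted modules cleanly", {
  set.seed(50)
  universe <- paste0("g", 1:1000)
  tf_sets <- gene_set_collection(
    lapply(stats::setNames(1:5, paste0("TF", 1:5)), function(i) {
      universe[(i - 1) * 40 + 1:40]
    }), kind_tag = "tf_targets")
  # each lncRNA co-expresses 30 of its TF's 40 targets plus 10 random genes
  lists <- lapply(stats::setNames(1:5, paste0("lnc", 1:5)), function(i) {
    c(sample(tf_sets$sets[[i]], 30), sample(universe[801:1000], 10))
  })
  assoc <- associate_tfs(lists, tf_sets, universe)
  planted <- paste0("lnc", 1:5, ":TF", 1:5)
  got <- paste0(assoc$lncrna, ":", assoc$tf)
  expect_gte(sum(planted %in% got), 4)
  expect_lte(sum(!(got %in% planted)), 1)      # at most one false edge

  # maximal overlap: co-expressed list equal to a target set
  one <- associate_tfs(list(L = tf_sets$sets$TF1), tf_sets, universe)
  expect_identical(one$tf[1], "TF1")
  expect_equal(one$k[1], 40)

  # disjoint list -> no associations
  none <- associate_tfs(list(L = universe[901:920]),
                        gene_set_collection(list(TFX = universe[1:40]),
                                            "tf_targets"),
                        universe)
  expect_equal(nrow(none), 0L)

  # single source of truth: P equals hypergeom_upper_tail on (k, K, n, N)
  i <- 1
  expect_equal(assoc$p_value[i],
               hypergeom_upper_tail(assoc$k[i], assoc$K[i], assoc$n[i],
                                    assoc$N[i]))
})

test_that("simulated lncRNA-TF module couplings are recovered", {
  sim <- simulate_dataset(module_only_config(seed = 51))
  m <- preprocess_default(sim)
  de <- differential_expression(m, sim$design, sim$annotation)
  sel <- select_differential(de)
  all_sel <- rbind(sel$up, sel$down)
  de_l <- all_sel$probe_id[all_sel$transcript_type == "lncRNA"]
  lists <- lapply(stats::setNames(de_l, de_l), coexpressed_genes,
                  mat = m, anno = sim$annotation)
  universe <- unique(sim$annotation$gene_symbol[
    sim$annotation$transcript_type == "mRNA"])
  assoc <- associate_tfs(lists, sim$tf_sets, universe)
  planted <- vapply(sim$truth$tf_modules, function(x) {
    paste0(x$driver_lncrna, ":", x$tf)
  }, "")
  got <- paste0(assoc$lncrna, ":", assoc$tf)
  expect_gte(sum(planted %in% got), 4)
})

test_that("network construction follows the bipartite/tripartite rules", {
  assoc <- data.frame(
    lncrna = c("L1", "L2"), tf = "TF1", k = 2, K = 4, n = 10, N = 100,
    p_value = c(1e-4, 1e-3), q_value = c(2e-4, 1e-3),
    overlap_members = c("G1,G2", "G1,G3"), stringsAsFactors = FALSE)
  g <- build_lncrna_tf_network(assoc)
  s <- network_summary(g)
  expect_equal(s$n_nodes, 3L)
  expect_equal(s$n_components, 1L)   # 2 lncRNAs sharing 1 TF connect
  expect_equal(g$edges$score, -log10(assoc$p_value))

  tf_sets <- gene_set_collection(list(TF1 = c("G1", "G2", "G3", "G4")),
                                 "tf_targets")
  lists <- list(L1 = c("G1", "G2", "Gx"), L2 = c("G1", "G3"))
  g3 <- build_lncrna_tf_gene_network(assoc, tf_sets, lists)
  # targets co-expressed with an associated lncRNA enter; G4 and Gx excluded
  expect_setequal(g3$nodes$id, c("L1", "L2", "TF1", "G1", "G2", "G3"))
  expect_equal(sum(g3$edges$relation == "tf_target"), 3L)
  expect_false("G4" %in% g3$nodes$id)

  # hand-enumerated fixture: nodes 6, edges 2 assoc + 3 target
  expect_equal(nrow(g3$edges), 5L)

  # empty associations -> empty graphs
  e <- build_lncrna_tf_network(assoc[0, ])
  expect_equal(nrow(e$nodes), 0L)
})

test_that("NetworkGraph invariants are enforced", {
  nodes <- data.frame(id = c("a", "b"), node_type = c("TF", "gene"))
  ok <- data.frame(source = "a", target = "b", relation = "r", score = 1)
  expect_s3_class(network_graph(nodes, ok), "NetworkGraph")
  expect_error(network_graph(nodes, transform(ok, target = "a")), "self-edge")
  expect_error(network_graph(nodes, rbind(ok, ok)), "duplicate")
  expect_error(network_graph(nodes, transform(ok, target = "zz")),
               "endpoint")
  expect_error(network_graph(transform(nodes, node_type = "x"), ok),
               "node_type")
})

test_that("network_summary matches the igraph oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(52)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    ids <- sprintf("n%02d", 1:n)
    ne <- sample(0:(2 * n), 1)
    edges <- unique(data.frame(
      source = sample(ids, ne, replace = TRUE),
      target = sample(ids, ne, replace = TRUE),
      relation = rep("r", ne), score = rep(1, ne),
      stringsAsFactors = FALSE))
    edges <- edges[edges$source != edges$target, , drop = FALSE]
    g <- network_graph(data.frame(id = ids, node_type = "gene"), edges)
    s <- network_summary(g)
    ig <- igraph::graph_from_data_frame(
      edges[, c("source", "target")], directed = FALSE,
      vertices = data.frame(name = ids))
    expect_equal(s$n_components, igraph::count_components(ig))
    expect_equal(unname(s$degree[ids]),
                 unname(igraph::degree(ig)[ids]))
  }
})

test_that("path and disjoint-edge summaries are exact", {
  nodes <- data.frame(id = c("a", "b", "c", "d"),
                      node_type = "gene")
  path3 <- network_graph(nodes[1:3, ],
                         data.frame(source = c("a", "b"), target = c("b", "c"),
                                    relation = "r", score = 1))
  s <- network_summary(path3)
  expect_equal(s$n_components, 1L)
  expect_equal(unname(s$degree), c(1L, 2L, 1L))
  two <- network_graph(nodes,
                       data.frame(source = c("a", "c"), target = c("b", "d"),
                                  relation = "r", score = 1))
  expect_equal(network_summary(two)$n_components, 2L)
})
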