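# Readers and writers for every external representation the pipeline
# touches: tab-separated expression/flag/annotation/design tables, GMT gene
# sets, SIF and GraphML networks, and the JSON run manifest. All validation
# errors name the offending location (row/column/line).

#' Read an expression matrix (and optional flag matrix) from TSV
#'
#' The matrix file is tab-separated with probe identifiers in the first
#' column and sample identifiers in the header. The optional flag file has
#' the identical layout with cells in `P`/`A`/`M`; when absent, all cells
#' are taken as present.
#'
#' @param path Path to the value matrix.
#' @param flag_path Optional path to the parallel flag matrix.
#' @param scale_tag Scale of the stored values (default `"raw"`).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, flag_path = NULL, scale_tag = "raw") {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  assert_that(ncol(raw) >= 2, "expression file '", path,
              "' needs a probe column plus at least one sample column")
  probes <- raw[[1]]
  assert_that(!anyDuplicated(probes), "duplicate probe identifiers in ", path)
  samples <- colnames(raw)[-1]
  assert_that(!anyDuplicated(samples), "duplicate sample identifiers in ", path)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    lrn_abort("non-numeric cell '", vals[bad[1, 1], bad[1, 2]],
              "' at probe '", probes[bad[1, 1]], "', sample '",
              samples[bad[1, 2]], "' in ", path)
  }
  assert_that(!anyNA(num), "missing values are not supported (", path, ")")
  dimnames(num) <- list(probes, samples)
  flags <- NULL
  if (!is.null(flag_path)) {
    fraw <- utils::read.delim(flag_path, check.names = FALSE,
                              colClasses = "character")
    fm <- as.matrix(fraw[, -1, drop = FALSE])
    assert_that(all(dim(fm) == dim(num)),
                "flag matrix dimensions (", paste(dim(fm), collapse = "x"),
                ") differ from values (", paste(dim(num), collapse = "x"),
                ") in ", flag_path)
    dimnames(fm) <- list(fraw[[1]], colnames(fraw)[-1])
    assert_that(identical(rownames(fm), probes) && identical(colnames(fm), samples),
                "flag matrix probe/sample identifiers differ from value matrix")
    flags <- fm
  }
  expression_matrix(num, flags = flags, scale_tag = scale_tag)
}

#' Write an expression matrix (and optionally its flags) to TSV
#'
#' Values are written at full precision (`%.17g`) so that a read/write
#' round trip is lossless.
#'
#' @param mat An [expression_matrix()].
#' @param path Output path for the values.
#' @param flag_path Optional output path for the flag matrix.
#' @export
write_expression_matrix <- function(mat, path, flag_path = NULL) {
  .write_matrix_tsv(matrix(sprintf("%.17g", mat$values), nrow(mat$values),
                           dimnames = dimnames(mat$values)),
                    path, id_col = "probe_id")
  if (!is.null(flag_path)) {
    .write_matrix_tsv(mat$flags, flag_path, id_col = "probe_id")
  }
  invisible(NULL)
}

.write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample design table from TSV
#'
#' Columns: `sample_id`, `patient_id`, `condition` (control/treated).
#'
#' @param path Path to the design file.
#' @return A [sample_design()].
#' @export
read_sample_design <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  req <- c("sample_id", "patient_id", "condition")
  assert_that(all(req %in% names(df)), "design file '", path,
              "' missing columns: ", paste(setdiff(req, names(df)), collapse = ", "))
  sample_design(df$sample_id, df$patient_id, df$condition)
}

#' @rdname read_sample_design
#' @param design A [sample_design()] to write.
#' @export
write_sample_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read a probe annotation table from TSV
#'
#' Columns: `probe_id`, `transcript_type` (mRNA/lncRNA), `gene_symbol`,
#' `chromosome`, `start`, `end` (1-based inclusive), `strand`.
#'
#' @param path Path to the annotation file.
#' @return A [probe_annotation()].
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  st <- suppressWarnings(as.integer(df$start))
  en <- suppressWarnings(as.integer(df$end))
  bad <- which(is.na(st) | is.na(en))
  assert_that(length(bad) == 0, "non-integer coordinates at line ",
              if (length(bad)) bad[1] + 1L else "", " of ", path)
  df$start <- st
  df$end <- en
  probe_annotation(df)
}

#' @rdname read_probe_annotation
#' @param anno A [probe_annotation()] to write.
#' @export
write_probe_annotation <- function(anno, path) {
  utils::write.table(as.data.frame(anno), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB
#' member1 TAB member2 ...`. Members are deduplicated, set order preserved.
#'
#' @param path Path to the GMT file.
#' @param kind_tag `"function"` or `"tf_targets"`.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, kind_tag = c("function", "tf_targets")) {
  kind_tag <- match.arg(kind_tag)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    lrn_note("GMT file '", path, "' is empty")
    return(gene_set_collection(list(), kind_tag = kind_tag))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  assert_that(length(short) == 0, "GMT line ", if (length(short)) short[1] else "",
              " of '", path, "' has fewer than 3 fields")
  nm <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, kind_tag = kind_tag, descriptions = desc)
}

#' @rdname read_gmt
#' @param collection A [gene_set_collection()] to write.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i],
            collection$descriptions[[i]],
            collection$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(NULL)
}

#' Export a network to SIF or GraphML
#'
#' SIF lines are `source TAB relation TAB target` (edge list only; isolated
#' nodes are dropped, as the format has no node records). GraphML carries
#' node `type` and edge `relation`/`score` attributes and is loadable by
#' Cytoscape.
#'
#' @param graph A `NetworkGraph` from [build_lncrna_tf_network()] or
#'   [build_lncrna_tf_gene_network()].
#' @param path Output path.
#' @param format `"SIF"` or `"GraphML"`.
#' @export
write_network <- function(graph, path, format = c("SIF", "GraphML")) {
  assert_that(inherits(graph, "NetworkGraph"), "graph must be a NetworkGraph")
  format <- match.arg(format)
  if (format == "SIF") {
    if (nrow(graph$edges) == 0) {
      writeLines(character(0), path)
    } else {
      writeLines(paste(graph$edges$source, graph$edges$relation,
                       graph$edges$target, sep = "\t"), path)
    }
  } else {
    .write_graphml(graph, path)
  }
  invisible(NULL)
}

.write_graphml <- function(graph, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  key_t <- xml2::xml_add_child(doc, "key", id = "d0", `for` = "node",
                               attr.name = "type", attr.type = "string")
  key_r <- xml2::xml_add_child(doc, "key", id = "d1", `for` = "edge",
                               attr.name = "relation", attr.type = "string")
  key_s <- xml2::xml_add_child(doc, "key", id = "d2", `for` = "edge",
                               attr.name = "score", attr.type = "double")
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (i in seq_len(nrow(graph$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = graph$nodes$id[i])
    dt <- xml2::xml_add_child(nd, "data", key = "d0")
    xml2::xml_text(dt) <- graph$nodes$node_type[i]
  }
  for (i in seq_len(nrow(graph$edges))) {
    ed <- xml2::xml_add_child(g, "edge",
                              source = graph$edges$source[i],
                              target = graph$edges$target[i])
    dr <- xml2::xml_add_child(ed, "data", key = "d1")
    xml2::xml_text(dr) <- graph$edges$relation[i]
    ds <- xml2::xml_add_child(ed, "data", key = "d2")
    xml2::xml_text(ds) <- sprintf("%.17g", graph$edges$score[i])
  }
  xml2::write_xml(doc, path)
}

#' Re-import a GraphML network written by [write_network()]
#'
#' @param path Path to a GraphML file.
#' @return A `NetworkGraph`.
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes <- xml2::xml_find_all(doc, ".//g:node", ns)
  node_df <- data.frame(
    id = xml2::xml_attr(nodes, "id"),
    node_type = vapply(nodes, function(n) {
      xml2::xml_text(xml2::xml_find_first(n, ".//g:data[@key='d0']", ns))
    }, ""),
    stringsAsFactors = FALSE)
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edge_df <- data.frame(
    source = xml2::xml_attr(edges, "source"),
    target = xml2::xml_attr(edges, "target"),
    relation = vapply(edges, function(e) {
      xml2::xml_text(xml2::xml_find_first(e, ".//g:data[@key='d1']", ns))
    }, ""),
    score = vapply(edges, function(e) {
      as.numeric(xml2::xml_text(xml2::xml_find_first(e, ".//g:data[@key='d2']", ns)))
    }, 0),
    stringsAsFactors = FALSE)
  network_graph(node_df, edge_df)
}

#' Write a tab-separated result table with a stable column order
#'
#' @param df A data.frame (e.g. differential or pair table).
#' @param path Output path.
#' @export
write_result_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
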