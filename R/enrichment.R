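# Hypergeometric over-representation analysis (ORA) and lncRNA functional
# prediction via co-expressed mRNAs. The universe is the post-filter array
# content, not the genome; sets with no members in the universe are dropped
# before BH so untestable hypotheses do not inflate the correction.

#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` successes when drawing `n` items
#' without replacement from a universe of `N` containing `K` successes:
#' `P = sum_{j=k}^{min(K,n)} C(K,j) C(N-K,n-j) / C(N,n)`.
#'
#' @param k Observed overlap (query AND set).
#' @param K Set size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  assert_that(all(c(k, K, n, N) >= 0) && all(c(k, K, n, N) == round(c(k, K, n, N))),
              "arguments must be non-negative integers")
  assert_that(all(K <= N) && all(n <= N), "K and n must not exceed N")
  assert_that(all(k <= pmin(K, n)), "k must not exceed min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' One hypergeometric upper-tail test per set, after intersecting query and
#' sets with the universe. Results are BH-corrected across the tested sets
#' and sorted by P.
#'
#' @param query Character vector of gene symbols (duplicates ignored).
#' @param collection A [gene_set_collection()].
#' @param universe Character vector of gene symbols defining the background.
#' @return A data.frame with columns `set_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, `overlap_members`.
#' @export
enrich <- function(query, collection, universe) {
  universe <- unique(as.character(universe))
  assert_that(length(universe) > 0, "empty universe")
  query <- intersect(unique(as.character(query)), universe)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    K <- length(members)
    if (K == 0) return(NULL)   # untestable: set absent from universe
    overlap <- intersect(query, members)
    k <- length(overlap)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N,
               p_value = hypergeom_upper_tail(k, K, n, N),
               overlap_members = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(set_name = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), overlap_members = character(0),
                      stringsAsFactors = FALSE)
    return(res)
  }
  res$q_value <- bh_fdr(res$p_value)
  res <- res[order(res$p_value, res$set_name), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[, c("set_name", "k", "K", "n", "N", "p_value", "q_value",
          "overlap_members")]
}

#' Co-expressed mRNA gene list for one lncRNA
#'
#' Correlates the lncRNA's expression with every mRNA probe across all
#' samples and keeps genes whose correlation (any sign) is significant at
#' `p_max`. This is the any-sign rule used for functional prediction, as
#' opposed to the strong-negative rule of the pair screen.
#'
#' @param lncrna_probe Probe id of the lncRNA.
#' @param mat A normalized [expression_matrix()] containing the lncRNA and
#'   the mRNA probes.
#' @param anno A [probe_annotation()]; mRNA probes are taken from it.
#' @param p_max Correlation-P threshold (default 0.05).
#' @return Character vector of co-expressed mRNA gene symbols (unique).
#' @export
coexpressed_genes <- function(lncrna_probe, mat, anno, p_max = 0.05) {
  assert_that(lncrna_probe %in% probe_ids(mat),
              "lncRNA probe '", lncrna_probe, "' absent from matrix")
  mrna <- anno$probe_id[anno$transcript_type == "mRNA"]
  mrna <- intersect(mrna, probe_ids(mat))
  if (length(mrna) == 0) return(character(0))
  x <- mat$values[lncrna_probe, ]
  mv <- mat$values[mrna, , drop = FALSE]
  n <- length(x)
  xc <- x - mean(x)
  sx <- sqrt(sum(xc^2))
  if (sx == 0) {
    lrn_note("constant lncRNA profile; no co-expressed genes")
    return(character(0))
  }
  mc <- mv - rowMeans(mv)
  sm <- sqrt(rowSums(mc^2))
  ok <- sm > 0
  r <- as.vector(mc[ok, , drop = FALSE] %*% xc) / (sm[ok] * sx)
  r[r > 1] <- 1
  r[r < -1] <- -1
  p <- correlation_p(r, n)
  hits <- mrna[ok][p < p_max]
  unique(anno$gene_symbol[match(hits, anno$probe_id)])
}

#' Predict the function of a differential lncRNA
#'
#' Builds the lncRNA's co-expressed mRNA gene list
#' ([coexpressed_genes()], correlation P < `p_max`, any sign) and runs
#' [enrich()] against the functional collection with universe = all mRNA
#' symbols present on the (post-filter) array.
#'
#' @inheritParams coexpressed_genes
#' @param collection A function-kind [gene_set_collection()].
#' @return The [enrich()] table for this lncRNA (empty, with a note, when no
#'   mRNA is co-expressed).
#' @export
predict_lncrna_function <- function(lncrna_probe, mat, anno, collection,
                                    p_max = 0.05) {
  genes <- coexpressed_genes(lncrna_probe, mat, anno, p_max = p_max)
  universe <- unique(anno$gene_symbol[anno$transcript_type == "mRNA" &
                                        anno$probe_id %in% probe_ids(mat)])
  if (length(genes) == 0) {
    lrn_note("no co-expressed mRNAs for ", lncrna_probe)
  }
  enrich(genes, collection, universe)
}
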