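# Bootstrap power analysis for the paired design: resample patients (the
# pair is the resampling unit) with replacement, rerun the paired t-test and
# BH correction over the full probe set, and record the fraction of
# replicates in which each target gene clears the detection rule.

#' Power-analysis configuration
#'
#' The default detection rule mirrors a q-value screen at q < 0.5 with the
#' usual two-fold change requirement; both are configurable.
#'
#' @param sample_sizes Integer vector of patient counts to evaluate
#'   (each >= 2).
#' @param n_bootstrap Replicates per sample size (default 1000).
#' @param detection ThresholdConfig used as the per-replicate detection rule
#'   (default `threshold_config(use_q = TRUE, q_max = 0.5)`).
#' @param target_genes Gene symbols whose power is tracked.
#' @param power_threshold Power considered sufficient (default 0.8).
#' @param seed Integer seed.
#' @return A `PowerConfig`.
#' @export
power_config <- function(sample_sizes, n_bootstrap = 1000,
                         detection = threshold_config(use_q = TRUE,
                                                      q_max = 0.5),
                         target_genes, power_threshold = 0.8, seed = 1L) {
  assert_that(all(sample_sizes >= 2), "sample sizes must be >= 2")
  assert_that(n_bootstrap >= 1, "n_bootstrap must be >= 1")
  assert_that(length(target_genes) > 0, "no target genes")
  structure(list(sample_sizes = as.integer(sample_sizes),
                 n_bootstrap = as.integer(n_bootstrap),
                 detection = detection,
                 target_genes = as.character(target_genes),
                 power_threshold = power_threshold,
                 seed = as.integer(seed)),
            class = "PowerConfig")
}

#' Bootstrap detection power per gene and sample size
#'
#' For each sample size m and replicate, draws m patients with replacement
#' (duplicates retained as distinct observations), reruns the paired t-test
#' and BH correction over all probes, and marks each target gene detected
#' when any of its probes passes the detection rule. Zero-variance
#' degenerate resamples count as non-detections.
#'
#' @param mat A normalized log2-scale [expression_matrix()].
#' @param design A [sample_design()].
#' @param anno A [probe_annotation()] (maps probes to gene symbols).
#' @param config A [power_config()].
#' @return A data.frame of class `PowerCurve` with columns `gene`,
#'   `sample_size`, `power`, `se` (binomial standard error),
#'   `n_bootstrap`.
#' @export
bootstrap_power <- function(mat, design, anno, config) {
  set.seed(config$seed)
  genes <- config$target_genes
  missing <- setdiff(genes, anno$gene_symbol[anno$probe_id %in% probe_ids(mat)])
  assert_that(length(missing) == 0, "target genes absent from matrix: ",
              paste(missing, collapse = ", "))
  ctrl <- design[design$condition == "control", ]
  trt <- design[design$condition == "treated", ]
  trt <- trt[match(ctrl$patient_id, trt$patient_id), ]
  d <- mat$values[, trt$sample_id, drop = FALSE] -
    mat$values[, ctrl$sample_id, drop = FALSE]
  gene_rows <- lapply(genes, function(g) {
    which(probe_ids(mat) %in% anno$probe_id[anno$gene_symbol == g])
  })
  names(gene_rows) <- genes
  th <- config$detection
  out <- list()
  for (m in config$sample_sizes) {
    hits <- matrix(FALSE, config$n_bootstrap, length(genes))
    for (b in seq_len(config$n_bootstrap)) {
      idx <- sample.int(ncol(d), m, replace = TRUE)
      db <- d[, idx, drop = FALSE]
      mu <- rowMeans(db)
      s <- sqrt(rowSums((db - mu)^2) / (m - 1))
      degen <- s == 0
      tstat <- mu / (s / sqrt(m))
      p <- 2 * stats::pt(abs(tstat), df = m - 1, lower.tail = FALSE)
      p[degen] <- NA
      q <- bh_fdr(p)
      fc_ok <- 2^abs(mu) >= th$fc_min
      pass <- if (th$use_q) q <= th$q_max else p <= th$p_max
      detected <- !degen & fc_ok & !is.na(pass) & pass
      hits[b, ] <- vapply(gene_rows, function(rows) any(detected[rows]),
                          FALSE)
    }
    phat <- colMeans(hits)
    out[[length(out) + 1L]] <- data.frame(
      gene = genes, sample_size = m, power = phat,
      se = sqrt(phat * (1 - phat) / config$n_bootstrap),
      n_bootstrap = config$n_bootstrap,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("PowerCurve", "data.frame")
  res
}

#' Minimum sample size reaching a power threshold
#'
#' @param curve A `PowerCurve` from [bootstrap_power()] covering at least
#'   two sample sizes.
#' @param power_threshold Required power (default 0.8).
#' @return data.frame with columns `gene` and `min_sample_size` (`NA` when
#'   the threshold is never met).
#' @export
minimum_sample_size <- function(curve, power_threshold = 0.8) {
  assert_that(length(unique(curve$sample_size)) >= 2,
              "curve must cover at least 2 sample sizes")
  res <- lapply(split(curve, curve$gene), function(g) {
    ok <- g$sample_size[g$power >= power_threshold]
    data.frame(gene = g$gene[1],
               min_sample_size = if (length(ok)) min(ok) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
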