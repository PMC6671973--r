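# Paired differential expression on per-patient log2 differences: the
# one-sample t-test on d_i = treated_i - control_i, Benjamini-Hochberg FDR,
# fold-change computation and threshold selection. Probes with zero variance
# of differences are degenerate and excluded (NA statistics), never handed a
# P of zero.

#' Paired t-test per probe
#'
#' For each probe, computes the per-patient log2 difference
#' `d_i = treated_i - control_i`, then `t = mean(d) / (sd(d) / sqrt(n))`
#' with the sample standard deviation (n-1 denominator) and a two-sided
#' P-value from the t distribution with n-1 degrees of freedom.
#'
#' @param mat A normalized log2-scale [expression_matrix()].
#' @param design A [sample_design()]; at least 2 complete patient pairs.
#' @return A data.frame with columns `probe_id`, `mean_log2_diff`,
#'   `t_statistic`, `p_value`, `degenerate`. Degenerate probes (zero
#'   variance of differences) carry `NA` statistics.
#' @export
paired_t_test <- function(mat, design) {
  assert_design_matches(mat, design)
  ctrl <- design[design$condition == "control", ]
  trt <- design[design$condition == "treated", ]
  trt <- trt[match(ctrl$patient_id, trt$patient_id), ]
  n <- nrow(ctrl)
  assert_that(n >= 2, "need at least 2 patient pairs")
  d <- mat$values[, trt$sample_id, drop = FALSE] -
    mat$values[, ctrl$sample_id, drop = FALSE]
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  degenerate <- s == 0
  tstat <- ifelse(degenerate, NA_real_, m / (s / sqrt(n)))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  if (any(degenerate)) {
    lrn_note(sum(degenerate), " probe(s) had zero variance of paired ",
             "differences; excluded from testing")
  }
  data.frame(probe_id = probe_ids(mat),
             mean_log2_diff = m,
             t_statistic = tstat,
             p_value = p,
             degenerate = degenerate,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard step-up: on sorted P-values, `q_(i) = min over j >= i of
#' min(1, p_(j) * m / j)`, mapped back to input order. `NA` entries
#' propagate as `NA` and do not count towards `m`.
#'
#' @param p Numeric vector of P-values in (0, 1].
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  assert_that(length(p) > 0, "empty P-value vector")
  ok <- !is.na(p)
  assert_that(all(p[ok] > 0 & p[ok] <= 1), "P-values must lie in (0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m > 0) {
    o <- order(pv)
    adj <- pmin(1, pv[o] * m / seq_len(m))
    adj <- rev(cummin(rev(adj)))
    qv <- numeric(m)
    qv[o] <- adj
    q[ok] <- qv
  }
  q
}

#' Assemble the full differential-expression result table
#'
#' Runs [paired_t_test()], attaches fold changes (`2^|mean_log2_diff|`, with
#' direction reported separately), BH q-values and probe annotation.
#'
#' @param mat A normalized log2-scale [expression_matrix()].
#' @param design A [sample_design()].
#' @param anno A [probe_annotation()] covering the matrix probes.
#' @return A `data.frame` with columns `probe_id`, `gene_symbol`,
#'   `transcript_type`, `mean_log2_diff`, `fold_change`, `direction`,
#'   `t_statistic`, `p_value`, `q_value`, `degenerate`.
#' @export
differential_expression <- function(mat, design, anno) {
  tt <- paired_t_test(mat, design)
  idx <- match(tt$probe_id, anno$probe_id)
  assert_that(!anyNA(idx), "matrix probes missing from annotation: ",
              paste(utils::head(tt$probe_id[is.na(idx)], 3), collapse = ", "))
  tt$gene_symbol <- anno$gene_symbol[idx]
  tt$transcript_type <- anno$transcript_type[idx]
  tt$fold_change <- 2^abs(tt$mean_log2_diff)
  tt$direction <- ifelse(tt$mean_log2_diff > 0, "up", "down")
  tt$q_value <- bh_fdr(tt$p_value)
  tt[, c("probe_id", "gene_symbol", "transcript_type", "mean_log2_diff",
         "fold_change", "direction", "t_statistic", "p_value", "q_value",
         "degenerate")]
}

#' Differential-expression selection thresholds
#'
#' Defaults follow the boundary-inclusive reading: fold change >= 2.0 and
#' P <= 0.05. Selection on BH q-values is available via `use_q`.
#'
#' @param fc_min Minimum linear fold change (>= 1, default 2).
#' @param p_max Maximum raw P (default 0.05).
#' @param use_q Select on q-values instead of raw P (default FALSE).
#' @param q_max Maximum q when `use_q` (default 0.05).
#' @return A `ThresholdConfig`.
#' @export
threshold_config <- function(fc_min = 2, p_max = 0.05, use_q = FALSE,
                             q_max = 0.05) {
  assert_that(fc_min >= 1, "fc_min must be >= 1")
  assert_that(p_max > 0 && p_max < 1, "p_max must lie in (0, 1)")
  assert_that(q_max > 0 && q_max < 1, "q_max must lie in (0, 1)")
  structure(list(fc_min = fc_min, p_max = p_max, use_q = use_q,
                 q_max = q_max),
            class = "ThresholdConfig")
}

#' Select differential probes
#'
#' @param results Table from [differential_expression()].
#' @param thresholds A [threshold_config()].
#' @param transcript_type Optional filter: `"mRNA"`, `"lncRNA"` or `NULL`
#'   for both.
#' @return A list with elements `up`, `down` (row subsets of `results`) and
#'   `counts` (`up`, `down`, `total`).
#' @export
select_differential <- function(results, thresholds = threshold_config(),
                                transcript_type = NULL) {
  keep <- !results$degenerate & results$fold_change >= thresholds$fc_min
  if (thresholds$use_q) {
    keep <- keep & results$q_value <= thresholds$q_max
  } else {
    keep <- keep & results$p_value <= thresholds$p_max
  }
  if (!is.null(transcript_type)) {
    keep <- keep & results$transcript_type == transcript_type
  }
  keep[is.na(keep)] <- FALSE
  sel <- results[keep, , drop = FALSE]
  up <- sel[sel$direction == "up", , drop = FALSE]
  down <- sel[sel$direction == "down", , drop = FALSE]
  list(up = up, down = down,
       counts = c(up = nrow(up), down = nrow(down), total = nrow(sel)))
}
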