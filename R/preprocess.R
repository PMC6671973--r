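# Preprocessing: log2 transform, classic quantile normalization, and
# detection-flag filtering. The pipeline order is fixed as
# log2 -> quantile normalize -> flag filter: normalization is done on the
# full matrix ("initially"), and filtering afterwards cannot change the
# per-sample distributions it equalized.

#' Log2-transform raw intensities
#'
#' @param mat An [expression_matrix()] with `scale_tag = "raw"` and
#'   non-negative values.
#' @param offset Small positive pseudo-count added before the log (default 0).
#' @return The matrix with `scale_tag = "log2"`.
#' @export
log2_transform <- function(mat, offset = 0) {
  assert_scale(mat, "raw")
  assert_that(offset >= 0, "offset must be non-negative")
  assert_that(all(mat$values >= 0), "negative intensity encountered")
  out <- mat
  out$values <- log2(mat$values + offset)
  out$scale_tag <- "log2"
  out
}

#' Quantile-normalize an expression matrix
#'
#' Classic quantile normalization: the k-th smallest value in each sample is
#' replaced by the mean of the k-th smallest values across all samples.
#' Ties within a sample receive the mean of the reference values for their
#' tied ranks, which makes the result deterministic and independent of probe
#' order. Afterwards every sample has the identical empirical distribution.
#'
#' @param mat An [expression_matrix()] with `scale_tag` raw or log2 and at
#'   least two samples; missing values are not supported.
#' @return The matrix with `scale_tag = "normalized"`.
#' @export
quantile_normalize <- function(mat) {
  assert_scale(mat, c("raw", "log2"))
  v <- mat$values
  assert_that(ncol(v) >= 2, "quantile normalization needs at least 2 samples")
  assert_that(!anyNA(v), "missing values are not supported")
  ref <- rowMeans(apply(v, 2, sort, method = "quick"))
  cs <- c(0, cumsum(ref))
  out <- apply(v, 2, function(col) {
    # a tie group spanning ranks [lo, hi] gets mean(ref[lo:hi])
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  })
  dimnames(out) <- dimnames(v)
  res <- mat
  res$values <- out
  res$scale_tag <- "normalized"
  res
}

#' Detection-flag filter rule
#'
#' A probe is kept when, in at least one of the two conditions, the fraction
#' of that condition's samples carrying `required_flag` is at least
#' `min_fraction_per_condition`. The default (flag `P` in at least half of
#' one condition's samples) operationalizes the common "present in at least
#' one condition" criterion for paired designs.
#'
#' @param required_flag Detection call that counts as present (default `"P"`).
#' @param min_fraction_per_condition Fraction in \[0, 1\] (default 0.5).
#' @return A `FilterRule`.
#' @export
filter_rule <- function(required_flag = "P", min_fraction_per_condition = 0.5) {
  assert_that(required_flag %in% FLAG_LEVELS, "unknown flag category")
  assert_that(min_fraction_per_condition >= 0 && min_fraction_per_condition <= 1,
              "min_fraction_per_condition must lie in [0, 1]")
  structure(list(required_flag = required_flag,
                 min_fraction_per_condition = min_fraction_per_condition),
            class = "FilterRule")
}

#' Filter probes by detection flags
#'
#' @param mat An [expression_matrix()] with flags.
#' @param design A [sample_design()] covering the matrix samples.
#' @param rule A [filter_rule()].
#' @return The matrix restricted to retained probes (order preserved), with
#'   attribute `filter_report` recording probes before/after.
#' @export
filter_by_flags <- function(mat, design, rule = filter_rule()) {
  assert_design_matches(mat, design)
  keep_any <- rep(FALSE, nrow(mat$values))
  for (cond in c("control", "treated")) {
    ss <- design$sample_id[design$condition == cond]
    fl <- mat$flags[, ss, drop = FALSE]
    frac <- rowMeans(fl == rule$required_flag)
    keep_any <- keep_any | (frac >= rule$min_fraction_per_condition)
  }
  out <- subset_matrix(mat, probes = which(keep_any))
  attr(out, "filter_report") <- list(probes_before = nrow(mat$values),
                                     probes_after = nrow(out$values))
  out
}
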