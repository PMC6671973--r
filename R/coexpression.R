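# Genome-wide lncRNA-mRNA correlation screening and cis/trans module
# classification. Pairs are retained when strongly negatively correlated
# (r <= -0.9 by default, boundary inclusive) with a significant two-sided
# correlation test; a retained pair is cis when the mRNA locus falls within
# a 100-kb window around the lncRNA on the same chromosome and its
# correlation P clears the stricter cis threshold, otherwise trans.

#' Pearson product-moment correlation
#'
#' Hand-evaluated from sums so the test suite can cross-check against
#' `stats::cor` independently. Returns `NA` (with a note) when either
#' vector is constant.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return The correlation coefficient, or `NA` for a degenerate input.
#' @export
pearson_r <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  assert_that(length(x) >= 3, "need at least 3 observations")
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) {
    lrn_note("constant vector in correlation; returning NA")
    return(NA_real_)
  }
  sum(xc * yc) / (sx * sy)
}

#' Two-sided P-value for a Pearson correlation
#'
#' Uses the exact-null t transform `t = r * sqrt((n-2) / (1-r^2))` with
#' n-2 degrees of freedom. At `|r| = 1` the P-value is reported as 0 (the
#' limit of the test statistic).
#'
#' @param r Correlation coefficient in \[-1, 1\].
#' @param n Number of paired observations (>= 3).
#' @return Two-sided P-value.
#' @export
correlation_p <- function(r, n) {
  assert_that(all(n >= 3), "need n >= 3")
  assert_that(all(abs(r[!is.na(r)]) <= 1), "|r| must be <= 1")
  p <- rep(NA_real_, length(r))
  lim <- !is.na(r) & abs(r) == 1
  p[lim] <- 0
  ok <- !is.na(r) & abs(r) < 1
  tstat <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p
}

#' Pair-screen configuration
#'
#' @param corr_p_max Maximum correlation P for pair retention (default 0.05).
#' @param r_max Pairs kept when `r <= r_max`; must be negative
#'   (default -0.9, boundary inclusive).
#' @param cis_window Window in bp extended up- and downstream of the lncRNA
#'   interval (default 100,000).
#' @param cis_corr_p_max Stricter correlation-P threshold a cis call must
#'   clear (default 0.01); must not exceed `corr_p_max`.
#' @param restrict_to_differential Screen only probes in the supplied
#'   differential lists (default TRUE).
#' @return A `PairScreenConfig`.
#' @export
pair_screen_config <- function(corr_p_max = 0.05, r_max = -0.9,
                               cis_window = 100000, cis_corr_p_max = 0.01,
                               restrict_to_differential = TRUE) {
  assert_that(r_max < 0, "r_max must be negative")
  assert_that(cis_window > 0, "cis_window must be positive")
  assert_that(cis_corr_p_max <= corr_p_max,
              "cis_corr_p_max must not exceed corr_p_max")
  structure(list(corr_p_max = corr_p_max, r_max = r_max,
                 cis_window = cis_window, cis_corr_p_max = cis_corr_p_max,
                 restrict_to_differential = restrict_to_differential),
            class = "PairScreenConfig")
}

#' Screen for strongly negatively correlated lncRNA-mRNA pairs
#'
#' Computes the Pearson correlation across all samples (both conditions
#' jointly) for every lncRNA x mRNA combination and retains pairs with
#' `corr_p <= corr_p_max` and `r <= r_max`. Each retained pair is annotated
#' with same-chromosome status and the genomic gap between the two probe
#' intervals (0 when they overlap, `NA` across chromosomes).
#'
#' @param mat A normalized [expression_matrix()].
#' @param anno A [probe_annotation()] covering the probes screened.
#' @param de_lncrna,de_mrna Character vectors of differential probe ids;
#'   used when `config$restrict_to_differential`, otherwise all annotated
#'   lncRNA/mRNA probes in the matrix are screened.
#' @param config A [pair_screen_config()].
#' @return A data.frame of class `CoexpressionPairs` with columns
#'   `lncrna_probe_id`, `mrna_probe_id`, `r`, `corr_p`, `same_chromosome`,
#'   `genomic_gap`, `regulation_class` (filled by [classify_cis_trans()]).
#' @export
screen_negative_pairs <- function(mat, anno, de_lncrna = NULL, de_mrna = NULL,
                                  config = pair_screen_config()) {
  if (config$restrict_to_differential) {
    lnc <- intersect(de_lncrna, probe_ids(mat))
    mrna <- intersect(de_mrna, probe_ids(mat))
  } else {
    present <- anno[anno$probe_id %in% probe_ids(mat), ]
    lnc <- present$probe_id[present$transcript_type == "lncRNA"]
    mrna <- present$probe_id[present$transcript_type == "mRNA"]
  }
  empty <- data.frame(lncrna_probe_id = character(0),
                      mrna_probe_id = character(0),
                      r = numeric(0), corr_p = numeric(0),
                      same_chromosome = logical(0),
                      genomic_gap = numeric(0),
                      regulation_class = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("CoexpressionPairs", "data.frame")
  if (length(lnc) == 0 || length(mrna) == 0) return(empty)

  lv <- mat$values[lnc, , drop = FALSE]
  mv <- mat$values[mrna, , drop = FALSE]
  n <- ncol(lv)
  # drop constant rows (correlation undefined)
  lconst <- apply(lv, 1, stats::sd) == 0
  mconst <- apply(mv, 1, stats::sd) == 0
  if (any(lconst) || any(mconst)) {
    lrn_note(sum(lconst) + sum(mconst),
             " constant probe(s) skipped in pair screen")
    lv <- lv[!lconst, , drop = FALSE]
    mv <- mv[!mconst, , drop = FALSE]
    if (nrow(lv) == 0 || nrow(mv) == 0) return(empty)
  }
  lz <- lv - rowMeans(lv)
  mz <- mv - rowMeans(mv)
  lz <- lz / sqrt(rowSums(lz^2))
  mz <- mz / sqrt(rowSums(mz^2))
  rmat <- tcrossprod(lz, mz)              # lncRNA x mRNA correlation matrix
  rmat[rmat > 1] <- 1
  rmat[rmat < -1] <- -1
  hit <- which(rmat <= config$r_max, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  rr <- rmat[hit]
  pp <- correlation_p(rr, n)
  keep <- pp <= config$corr_p_max
  hit <- hit[keep, , drop = FALSE]
  if (nrow(hit) == 0) return(empty)
  pairs <- data.frame(lncrna_probe_id = rownames(lz)[hit[, 1]],
                      mrna_probe_id = rownames(mz)[hit[, 2]],
                      r = rr[keep], corr_p = pp[keep],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$corr_p, pairs$lncrna_probe_id,
                       pairs$mrna_probe_id), , drop = FALSE]
  rownames(pairs) <- NULL
  li <- match(pairs$lncrna_probe_id, anno$probe_id)
  mi <- match(pairs$mrna_probe_id, anno$probe_id)
  pairs$same_chromosome <- !is.na(li) & !is.na(mi) &
    anno$chromosome[li] == anno$chromosome[mi]
  pairs$genomic_gap <- ifelse(pairs$same_chromosome,
                              interval_gap(anno$start[li], anno$end[li],
                                           anno$start[mi], anno$end[mi]),
                              NA_real_)
  pairs$regulation_class <- "unclassified"
  class(pairs) <- c("CoexpressionPairs", "data.frame")
  pairs
}

# Gap between two 1-based inclusive intervals on the same chromosome:
# 0 when they overlap, otherwise the number of bases strictly between them.
interval_gap <- function(s1, e1, s2, e2) {
  lo <- pmax(s1, s2)
  hi <- pmin(e1, e2)
  pmax(0, lo - hi - 1)
}

#' Classify screened pairs as cis or trans
#'
#' A pair is `cis` when both probes lie on the same chromosome, the mRNA
#' interval overlaps the lncRNA interval extended by `cis_window` bp on both
#' sides, and `corr_p <= cis_corr_p_max`; any other retained pair is
#' `trans`. Pairs with a member missing from the annotation stay
#' `unclassified` with a note.
#'
#' @param pairs Output of [screen_negative_pairs()].
#' @param anno A [probe_annotation()].
#' @param config A [pair_screen_config()].
#' @return `pairs` with `regulation_class` filled in.
#' @export
classify_cis_trans <- function(pairs, anno, config = pair_screen_config()) {
  if (nrow(pairs) == 0) return(pairs)
  li <- match(pairs$lncrna_probe_id, anno$probe_id)
  mi <- match(pairs$mrna_probe_id, anno$probe_id)
  known <- !is.na(li) & !is.na(mi)
  if (any(!known)) {
    lrn_note(sum(!known), " pair(s) missing annotation; left unclassified")
  }
  within_window <- rep(FALSE, nrow(pairs))
  idx <- which(known & pairs$same_chromosome)
  if (length(idx) > 0) {
    within_window[idx] <-
      anno$start[mi[idx]] <= anno$end[li[idx]] + config$cis_window &
      anno$end[mi[idx]] >= anno$start[li[idx]] - config$cis_window
  }
  cls <- ifelse(within_window & pairs$corr_p <= config$cis_corr_p_max,
                "cis", "trans")
  cls[!known] <- "unclassified"
  pairs$regulation_class <- cls
  pairs
}

#' Per-chromosome counts of same-chromosome pairs
#'
#' @param pairs A classified pair table.
#' @param anno A [probe_annotation()] (chromosome looked up from the lncRNA
#'   member).
#' @return Named integer vector of counts keyed by chromosome; the sum
#'   equals the number of same-chromosome pairs.
#' @export
chromosome_distribution <- function(pairs, anno) {
  sc <- pairs[pairs$same_chromosome %in% TRUE, , drop = FALSE]
  if (nrow(sc) == 0) return(stats::setNames(integer(0), character(0)))
  chr <- anno$chromosome[match(sc$lncrna_probe_id, anno$probe_id)]
  tab <- table(chr)
  stats::setNames(as.integer(tab), names(tab))
}
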