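# ExpressionMatrix: the central container for probe x sample intensities.
# A light S3 wrapper around a numeric matrix plus an optional parallel flag
# matrix (Agilent-style P/A/M detection calls) and a scale tag recording
# where the values sit on the raw -> log2 -> normalized trajectory.

FLAG_LEVELS <- c("P", "A", "M")

#' Construct an ExpressionMatrix
#'
#' Bundles a probe-by-sample intensity matrix with per-cell detection flags
#' and a scale tag. Most users will obtain one from
#' [read_expression_matrix()] or [simulate_dataset()] rather than calling
#' this directly.
#'
#' @param values Numeric matrix, probes in rows, samples in columns. Row and
#'   column names are the probe and sample identifiers and must be unique.
#' @param flags Character matrix of identical dimensions with cells in
#'   `P` (present), `A` (absent), `M` (marginal), or `NULL` for all-present.
#' @param scale_tag One of `"raw"`, `"log2"`, `"normalized"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, flags = NULL, scale_tag = "raw") {
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values must carry probe (row) and sample (column) names")
  assert_that(!anyDuplicated(rownames(values)), "duplicate probe identifiers")
  assert_that(!anyDuplicated(colnames(values)), "duplicate sample identifiers")
  assert_that(scale_tag %in% names(SCALE_LEVELS),
              "scale_tag must be one of raw, log2, normalized")
  if (is.null(flags)) {
    flags <- matrix("P", nrow(values), ncol(values),
                    dimnames = dimnames(values))
  }
  assert_that(is.matrix(flags) && all(dim(flags) == dim(values)),
              "flags dimensions (", paste(dim(flags), collapse = "x"),
              ") differ from values (", paste(dim(values), collapse = "x"), ")")
  bad <- which(matrix(!(flags %in% FLAG_LEVELS), nrow(flags)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    lrn_abort("invalid flag '", flags[bad[1, 1], bad[1, 2]], "' at probe '",
              rownames(values)[bad[1, 1]], "', sample '",
              colnames(values)[bad[1, 2]], "' (flags must be P, A or M)")
  }
  dimnames(flags) <- dimnames(values)
  structure(list(values = values, flags = flags, scale_tag = scale_tag),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

probe_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# Subset probes and/or samples, keeping values and flags in lock-step.
subset_matrix <- function(x, probes = NULL, samples = NULL) {
  v <- x$values
  f <- x$flags
  if (!is.null(probes)) {
    v <- v[probes, , drop = FALSE]
    f <- f[probes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    f <- f[, samples, drop = FALSE]
  }
  structure(list(values = v, flags = f, scale_tag = x$scale_tag),
            class = "ExpressionMatrix")
}

#' Construct a paired sample design
#'
#' @param sample_id,patient_id,condition Equal-length vectors; `condition`
#'   must be `"control"` or `"treated"` and every patient must appear exactly
#'   once per condition (fully paired design).
#' @return A `data.frame` of class `SampleDesign`.
#' @export
sample_design <- function(sample_id, patient_id, condition) {
  d <- data.frame(sample_id = as.character(sample_id),
                  patient_id = as.character(patient_id),
                  condition = as.character(condition),
                  stringsAsFactors = FALSE)
  assert_that(all(d$condition %in% c("control", "treated")),
              "condition must be 'control' or 'treated'")
  assert_that(!anyDuplicated(d$sample_id), "duplicate sample_id in design")
  tab <- table(d$patient_id, d$condition)
  assert_that(ncol(tab) == 2 && all(tab == 1),
              "design is not fully paired: every patient_id must appear ",
              "exactly once per condition")
  class(d) <- c("SampleDesign", "data.frame")
  d
}

assert_design_matches <- function(mat, design) {
  missing <- setdiff(design$sample_id, sample_ids(mat))
  assert_that(length(missing) == 0,
              "design samples absent from matrix: ",
              paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Construct a probe annotation table
#'
#' One row per probe: transcript type (mRNA/lncRNA), gene symbol and a
#' 1-based inclusive genomic interval. Coordinates follow the printed
#' GRCh37-style convention (`chr9:2653919-2654254` spans 336 bp).
#'
#' @param df A data.frame with columns `probe_id`, `transcript_type`,
#'   `gene_symbol`, `chromosome`, `start`, `end`, `strand`.
#' @return The validated data.frame with class `ProbeAnnotation`.
#' @export
probe_annotation <- function(df) {
  req <- c("probe_id", "transcript_type", "gene_symbol", "chromosome",
           "start", "end", "strand")
  assert_that(all(req %in% names(df)),
              "annotation missing columns: ",
              paste(setdiff(req, names(df)), collapse = ", "))
  df <- df[, req]
  df$probe_id <- as.character(df$probe_id)
  df$gene_symbol <- as.character(df$gene_symbol)
  df$chromosome <- as.character(df$chromosome)
  df$strand <- as.character(df$strand)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  assert_that(!anyDuplicated(df$probe_id), "duplicate probe_id in annotation")
  assert_that(all(df$transcript_type %in% c("mRNA", "lncRNA")),
              "unknown transcript_type (must be mRNA or lncRNA)")
  assert_that(all(nzchar(df$chromosome)), "empty chromosome label")
  bad <- which(df$start > df$end)
  assert_that(length(bad) == 0,
              "start > end for probe ", if (length(bad)) df$probe_id[bad[1]] else "")
  assert_that(all(df$strand %in% c("+", "-", ".")),
              "strand must be '+', '-' or '.'")
  rownames(df) <- df$probe_id
  class(df) <- c("ProbeAnnotation", "data.frame")
  df
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols; names are set
#'   names, members are deduplicated. Optionally each element may carry a
#'   `description` attribute.
#' @param kind_tag `"function"` for functional terms (GO/KEGG stand-ins) or
#'   `"tf_targets"` for transcription-factor target sets.
#' @param descriptions Optional character vector parallel to `sets`.
#' @return A list of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, kind_tag = c("function", "tf_targets"),
                                descriptions = NULL) {
  kind_tag <- match.arg(kind_tag)
  assert_that(is.list(sets), "sets must be a named list")
  if (length(sets) > 0) {
    assert_that(!is.null(names(sets)) && all(nzchar(names(sets))),
                "every set needs a name")
    assert_that(!anyDuplicated(names(sets)), "duplicate set names")
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  assert_that(all(lengths(sets) > 0) || length(sets) == 0,
              "empty gene set not allowed")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  assert_that(length(descriptions) == length(sets),
              "descriptions length mismatch")
  structure(list(sets = sets, descriptions = stats::setNames(descriptions, names(sets)),
                 kind_tag = kind_tag),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection [%s]: %d sets, %d total members\n",
              x$kind_tag, length(x$sets), sum(lengths(x$sets))))
  invisible(x)
}
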