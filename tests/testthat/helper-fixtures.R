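# Shared fixture builders. Everything is generated in code; nothing binary.

# tiny expression matrix with named dims
tiny_matrix <- function(values, probes = NULL, samples = NULL, flags = NULL,
                        scale_tag = "raw") {
  if (is.null(probes)) probes <- sprintf("p%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(probes, samples)
  if (!is.null(flags)) dimnames(flags) <- list(probes, samples)
  expression_matrix(values, flags = flags, scale_tag = scale_tag)
}

# paired design for n patients; sample ids P<i>_control / P<i>_treated
paired_design <- function(n) {
  pats <- sprintf("P%d", seq_len(n))
  sample_design(sample_id = c(paste0(pats, "_control"), paste0(pats, "_treated")),
                patient_id = rep(pats, 2),
                condition = rep(c("control", "treated"), each = n))
}

# matrix whose per-patient treated-control differences are given rows;
# control values are drawn reproducibly so only the differences matter
matrix_from_diffs <- function(diffs, seed = 1) {
  set.seed(seed)
  n <- ncol(diffs)
  ctrl <- matrix(rnorm(length(diffs), 8, 1), nrow(diffs), n)
  vals <- cbind(ctrl, ctrl + diffs)
  probes <- sprintf("p%d", seq_len(nrow(diffs)))
  pats <- sprintf("P%d", seq_len(n))
  dimnames(vals) <- list(probes, c(paste0(pats, "_control"),
                                   paste0(pats, "_treated")))
  list(mat = expression_matrix(vals, scale_tag = "normalized"),
       design = paired_design(n))
}

# minimal annotation covering given probes
tiny_annotation <- function(probe_id,
                            transcript_type = rep("mRNA", length(probe_id)),
                            chromosome = rep("chr1", length(probe_id)),
                            start = seq(1e6, by = 1e6,
                                        length.out = length(probe_id)),
                            width = rep(1000L, length(probe_id))) {
  probe_annotation(data.frame(
    probe_id = probe_id,
    transcript_type = transcript_type,
    gene_symbol = paste0("g_", probe_id),
    chromosome = chromosome,
    start = as.integer(start),
    end = as.integer(start) + as.integer(width) - 1L,
    strand = ".",
    stringsAsFactors = FALSE))
}

# small targeted simulation where only TF modules are planted
module_only_config <- function(seed, n_modules = 5, module_size = 20) {
  simulation_config(
    seed = seed, n_mrna = 800, n_lncrna = 200,
    frac_de_mrna = 5 / 800, frac_de_lncrna = n_modules / 200,
    n_cis_pairs = 0, n_trans_pairs = 0,
    n_tf_modules = n_modules, tf_module_size = module_size)
}

# run preprocess chain with defaults
preprocess_default <- function(sim) {
  filter_by_flags(quantile_normalize(log2_transform(sim$matrix)), sim$design)
}
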