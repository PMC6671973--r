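# End-to-end orchestration: simulate (or read) -> preprocess -> differential
# expression -> pair screen and cis/trans classification -> enrichment ->
# TF network -> power analysis, driven by a single YAML config, with a JSON
# run manifest recording the seed, input checksums and per-stage counts.

#' Run the full analysis pipeline
#'
#' The config is a YAML file (or an equivalent named list) with blocks:
#' \describe{
#'   \item{simulate}{arguments for [simulation_config()]; alternatively an
#'     `inputs` block with paths `expression`, `flags`, `design`,
#'     `annotation`, `function_sets`, `tf_sets`.}
#'   \item{preprocess}{`log2_offset`, `required_flag`,
#'     `min_fraction_per_condition`.}
#'   \item{de}{arguments for [threshold_config()].}
#'   \item{coexpr}{arguments for [pair_screen_config()].}
#'   \item{enrich}{`max_lncrnas` cap on per-lncRNA functional prediction.}
#'   \item{network}{`q_max` for [associate_tfs()].}
#'   \item{power}{`sample_sizes`, `n_bootstrap`, `q_max`, `target_genes`.}
#'   \item{stages}{character vector selecting stages; defaults to all.}
#' }
#' A `seed` given at top level (or via the `seed` argument) drives every
#' stochastic stage.
#'
#' @param config Path to a YAML config, or a named list.
#' @param outdir Output directory for stage tables, networks and the
#'   manifest.
#' @param seed Overrides the config seed when non-NULL.
#' @return The run manifest (list), invisibly written to
#'   `outdir/manifest.json`.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  } else {
    cfg_path <- NA_character_
  }
  assert_that(is.list(config), "config must be a YAML path or a list")
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("simulate", "preprocess", "de", "coexpr",
                                 "enrich", "network", "power")
  manifest <- list(config_path = cfg_path, seed = config$seed,
                   stages = list(), software = "lncregnet 0.1.0")

  # --- inputs -----------------------------------------------------------
  truth <- NULL
  if ("simulate" %in% stages || is.null(config$inputs)) {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- config$seed
    sim_args$log2fc_range <- unlist(sim_args$log2fc_range) %||% c(1.0, 4.2)
    sim <- simulate_dataset(do.call(simulation_config, sim_args))
    mat <- sim$matrix; design <- sim$design; anno <- sim$annotation
    fn_sets <- sim$function_sets; tf_sets <- sim$tf_sets; truth <- sim$truth
    manifest$stages$simulate <- list(
      probes = nrow(mat$values), samples = ncol(mat$values),
      planted_de = nrow(truth$de), planted_pairs = nrow(truth$pairs),
      planted_tf_modules = length(truth$tf_modules))
  } else {
    ip <- config$inputs
    mat <- read_expression_matrix(ip$expression, ip$flags)
    design <- read_sample_design(ip$design)
    anno <- read_probe_annotation(ip$annotation)
    fn_sets <- read_gmt(ip$function_sets, "function")
    tf_sets <- read_gmt(ip$tf_sets, "tf_targets")
    manifest$input_checksums <- vapply(
      unlist(ip), function(p) unname(tools::md5sum(p)), "")
  }

  # --- preprocess -------------------------------------------------------
  pp <- config$preprocess %||% list()
  if ("preprocess" %in% stages) {
    mat <- log2_transform(mat, offset = pp$log2_offset %||% 0)
    mat <- quantile_normalize(mat)
    rule <- filter_rule(pp$required_flag %||% "P",
                        pp$min_fraction_per_condition %||% 0.5)
    before <- nrow(mat$values)
    mat <- filter_by_flags(mat, design, rule)
    manifest$stages$preprocess <- list(probes_in = before,
                                       probes_out = nrow(mat$values))
    write_expression_matrix(mat, file.path(outdir, "normalized.tsv"))
  }

  # --- differential expression -----------------------------------------
  de_res <- NULL; de_sel <- NULL
  if ("de" %in% stages) {
    th <- do.call(threshold_config, config$de %||% list())
    de_res <- differential_expression(mat, design, anno)
    de_sel <- select_differential(de_res, th)
    by_type <- lapply(c(mRNA = "mRNA", lncRNA = "lncRNA"), function(tt) {
      select_differential(de_res, th, transcript_type = tt)$counts
    })
    manifest$stages$de <- list(
      total = unname(de_sel$counts["total"]),
      mRNA = as.list(by_type$mRNA), lncRNA = as.list(by_type$lncRNA))
    write_result_table(de_res, file.path(outdir, "differential.tsv"))
  }

  # --- co-expression pair screen ---------------------------------------
  pairs <- NULL
  if ("coexpr" %in% stages) {
    assert_that(!is.null(de_res), "coexpr stage requires the de stage")
    pc <- do.call(pair_screen_config, config$coexpr %||% list())
    sel_all <- rbind(de_sel$up, de_sel$down)
    de_l <- sel_all$probe_id[sel_all$transcript_type == "lncRNA"]
    de_m <- sel_all$probe_id[sel_all$transcript_type == "mRNA"]
    pairs <- screen_negative_pairs(mat, anno, de_l, de_m, pc)
    pairs <- classify_cis_trans(pairs, anno, pc)
    chrom <- chromosome_distribution(pairs, anno)
    manifest$stages$coexpr <- list(
      pairs = nrow(pairs),
      same_chromosome = sum(pairs$same_chromosome),
      cis = sum(pairs$regulation_class == "cis"),
      trans = sum(pairs$regulation_class == "trans"),
      per_chromosome = as.list(chrom))
    write_result_table(pairs, file.path(outdir, "pairs.tsv"))
  }

  # --- functional enrichment per differential lncRNA --------------------
  coexpr_lists <- NULL
  if ("enrich" %in% stages || "network" %in% stages) {
    assert_that(!is.null(de_sel), "enrich/network stages require the de stage")
    sel_all <- rbind(de_sel$up, de_sel$down)
    de_l <- sel_all$probe_id[sel_all$transcript_type == "lncRNA"]
    cap <- (config$enrich %||% list())$max_lncrnas %||% length(de_l)
    de_l <- utils::head(de_l, cap)
    coexpr_lists <- lapply(stats::setNames(de_l, de_l), coexpressed_genes,
                           mat = mat, anno = anno)
  }
  if ("enrich" %in% stages) {
    universe <- unique(anno$gene_symbol[anno$transcript_type == "mRNA" &
                                          anno$probe_id %in% probe_ids(mat)])
    enr <- lapply(coexpr_lists, enrich, collection = fn_sets,
                  universe = universe)
    top <- vapply(enr, function(e) {
      if (nrow(e) == 0) NA_character_ else e$set_name[1]
    }, "")
    manifest$stages$enrich <- list(lncrnas_tested = length(enr),
                                   sets_tested = length(fn_sets$sets))
    enr_tab <- do.call(rbind, lapply(names(enr), function(l) {
      if (nrow(enr[[l]]) == 0) return(NULL)
      cbind(lncrna = l, enr[[l]])
    }))
    if (!is.null(enr_tab)) {
      write_result_table(enr_tab, file.path(outdir, "enrichment.tsv"))
    }
  }

  # --- TF association network ------------------------------------------
  if ("network" %in% stages) {
    universe <- unique(anno$gene_symbol[anno$transcript_type == "mRNA" &
                                          anno$probe_id %in% probe_ids(mat)])
    q_max <- (config$network %||% list())$q_max %||% 0.05
    assoc <- associate_tfs(coexpr_lists, tf_sets, universe, q_max = q_max)
    g2 <- build_lncrna_tf_network(assoc)
    g3 <- build_lncrna_tf_gene_network(assoc, tf_sets, coexpr_lists)
    s3 <- network_summary(g3)
    manifest$stages$network <- list(
      associations = nrow(assoc),
      nodes = s3$n_nodes, edges = s3$n_edges,
      components = s3$n_components)
    write_result_table(assoc, file.path(outdir, "tf_associations.tsv"))
    write_network(g2, file.path(outdir, "lncrna_tf.sif"), "SIF")
    write_network(g3, file.path(outdir, "lncrna_tf_gene.graphml"), "GraphML")
  }

  # --- power analysis ---------------------------------------------------
  if ("power" %in% stages) {
    pw <- config$power %||% list()
    targets <- pw$target_genes
    if (is.null(targets)) {
      sel_all <- rbind(de_sel$up, de_sel$down)
      targets <- utils::head(sel_all$gene_symbol[
        sel_all$transcript_type == "mRNA"], 5)
    }
    if (length(targets) > 0) {
      pcfg <- power_config(
        sample_sizes = unlist(pw$sample_sizes) %||% c(3, 4, 5),
        n_bootstrap = pw$n_bootstrap %||% 200,
        detection = threshold_config(use_q = TRUE,
                                     q_max = pw$q_max %||% 0.5),
        target_genes = targets,
        seed = config$seed)
      curve <- bootstrap_power(mat, design, anno, pcfg)
      mss <- minimum_sample_size(curve, pw$power_threshold %||% 0.8)
      manifest$stages$power <- list(
        genes = length(targets),
        sample_sizes = pcfg$sample_sizes,
        reached_power = sum(!is.na(mss$min_sample_size)))
      write_result_table(curve, file.path(outdir, "power_curve.tsv"))
    } else {
      manifest$stages$power <- list(genes = 0L)
    }
  }

  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Results-style summary of stage outputs
#'
#' Deterministic recount from the raw stage tables: differential counts by
#' direction and transcript type, pair totals, same-chromosome and
#' per-chromosome counts, cis/trans split.
#'
#' @param de_res Table from [differential_expression()] (or NULL).
#' @param de_sel Selection from [select_differential()] (or NULL).
#' @param pairs Classified pair table (or NULL).
#' @param anno A [probe_annotation()].
#' @return Nested list of counts.
#' @export
summarize_counts <- function(de_res = NULL, de_sel = NULL, pairs = NULL,
                             anno = NULL) {
  out <- list()
  if (!is.null(de_sel)) {
    sel <- rbind(de_sel$up, de_sel$down)
    out$de <- list(
      up = nrow(de_sel$up), down = nrow(de_sel$down), total = nrow(sel),
      mRNA = sum(sel$transcript_type == "mRNA"),
      lncRNA = sum(sel$transcript_type == "lncRNA"))
  }
  if (!is.null(pairs)) {
    out$pairs <- list(
      total = nrow(pairs),
      same_chromosome = sum(pairs$same_chromosome),
      cis = sum(pairs$regulation_class == "cis"),
      trans = sum(pairs$regulation_class == "trans"))
    if (!is.null(anno)) {
      out$pairs$per_chromosome <- as.list(chromosome_distribution(pairs, anno))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
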