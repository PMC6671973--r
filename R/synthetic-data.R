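# Synthetic paired two-condition microarray data with planted ground truth.
#
# Generative model, per probe g, patient i, condition c (log2 scale):
#   y_gic = baseline_g + patient_gi + Delta_g * 1[c = treated] + eps_gic
# with patient_gi ~ N(0, patient_effect_sd) shared across the patient's two
# arrays (so the paired t-test is the correctly specified analysis) and
# eps ~ N(0, residual_sd). Delta_g = 0 for null probes; planted differential
# probes draw |Delta_g| uniformly from log2fc_range with a random sign.
#
# Negatively coupled lncRNA-mRNA pairs (L, M) replace M's profile by an
# affine negative transform of L's realized profile plus noise calibrated so
# the across-sample Pearson r has expectation coupling_r_target:
#   y_M = baseline_M - (y_L - mean(y_L)) + eta,  sd(eta) = s_L sqrt(1/r^2 - 1)
# Cis pairs are placed on one chromosome at a gap below cis_max_gap; trans
# pairs on different chromosomes. TF modules couple member mRNAs positively
# to a driver lncRNA (weight-jittered), so members share the driver's effect
# sign; TF target sets list the members plus decoys.

#' Simulation configuration
#'
#' Defaults emulate the structure of a 5-patient paired FLS microarray
#' study at desk scale (2,000 mRNA + 1,000 lncRNA probes standing in for
#' the 30,656 + 78,243 of the full array); the planted |log2 fold change|
#' range \[1.0, 4.2\] covers linear fold changes 2.0-18.4.
#'
#' @param n_patients Paired patients (default 5).
#' @param n_mrna,n_lncrna Probe counts (defaults 2000 / 1000).
#' @param frac_de_mrna,frac_de_lncrna Fractions of probes planted as
#'   differential (defaults 0.03).
#' @param log2fc_range Interval for planted |log2 fold change|
#'   (default `c(1.0, 4.2)`).
#' @param patient_effect_sd Between-patient SD in log2 units (default 0.3).
#' @param residual_sd Residual SD in log2 units (default 0.15).
#' @param n_cis_pairs,n_trans_pairs Planted negatively coupled pair counts
#'   (defaults 10 / 10).
#' @param coupling_r_target Target Pearson r for planted pairs
#'   (default -0.95).
#' @param cis_max_gap Maximum planted genomic gap in bp for cis pairs; must
#'   stay below the 100,000 bp classification window (default 80,000).
#' @param n_tf_modules,tf_module_size TF-coregulated modules and genes per
#'   module (defaults 5 / 30).
#' @param module_r_target Target within-module driver-member correlation
#'   (default 0.9).
#' @param flag_absent_prob Per-cell probability of an `A` detection flag
#'   (default 0.02).
#' @param n_absent_probes Null probes flagged `A` on every array, exercising
#'   removal by the flag filter (default 0).
#' @param n_absent_one_condition Null probes flagged `A` on all control
#'   arrays only; the "present in at least one condition" rule retains them
#'   (default 0).
#' @param baseline_mean,baseline_sd Log2 baseline distribution
#'   (defaults 8 / 2).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return A `SimulationConfig`.
#' @export
simulation_config <- function(n_patients = 5,
                              n_mrna = 2000, n_lncrna = 1000,
                              frac_de_mrna = 0.03, frac_de_lncrna = 0.03,
                              log2fc_range = c(1.0, 4.2),
                              patient_effect_sd = 0.1, residual_sd = 0.15,
                              n_cis_pairs = 10, n_trans_pairs = 10,
                              coupling_r_target = -0.95,
                              cis_max_gap = 80000,
                              n_tf_modules = 5, tf_module_size = 30,
                              module_r_target = 0.9,
                              flag_absent_prob = 0.02,
                              n_absent_probes = 0,
                              n_absent_one_condition = 0,
                              baseline_mean = 8, baseline_sd = 2,
                              seed = 1L) {
  assert_that(n_patients >= 2, "need at least 2 patients")
  assert_that(frac_de_mrna >= 0 && frac_de_mrna <= 1 &&
                frac_de_lncrna >= 0 && frac_de_lncrna <= 1,
              "DE fractions must lie in [0, 1]")
  assert_that(patient_effect_sd > 0 && residual_sd > 0, "SDs must be positive")
  assert_that(length(log2fc_range) == 2 && log2fc_range[1] <= log2fc_range[2]
              && log2fc_range[1] > 0, "invalid log2fc_range")
  assert_that(coupling_r_target < 0 && coupling_r_target >= -1,
              "coupling_r_target must lie in [-1, 0)")
  assert_that(cis_max_gap > 0 && cis_max_gap < 100000,
              "cis_max_gap must stay below the 100,000 bp window")
  cfg <- list(n_patients = n_patients, n_mrna = n_mrna, n_lncrna = n_lncrna,
              frac_de_mrna = frac_de_mrna, frac_de_lncrna = frac_de_lncrna,
              log2fc_range = log2fc_range,
              patient_effect_sd = patient_effect_sd, residual_sd = residual_sd,
              n_cis_pairs = n_cis_pairs, n_trans_pairs = n_trans_pairs,
              coupling_r_target = coupling_r_target, cis_max_gap = cis_max_gap,
              n_tf_modules = n_tf_modules, tf_module_size = tf_module_size,
              module_r_target = module_r_target,
              flag_absent_prob = flag_absent_prob,
              n_absent_probes = n_absent_probes,
              n_absent_one_condition = n_absent_one_condition,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a paired two-condition dataset with planted ground truth
#'
#' @param config A [simulation_config()].
#' @return A list with elements `matrix` (raw-scale [expression_matrix()]
#'   with flags), `design`, `annotation`, `function_sets`, `tf_sets`, and
#'   `truth` (the ground-truth manifest: `de` table with planted log2fc,
#'   direction and role; `pairs` table with cis/trans label and target r;
#'   `tf_modules`; `null_probe_ids`).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  set.seed(config$seed)
  np <- config$n_patients
  n_mrna <- config$n_mrna
  n_lnc <- config$n_lncrna
  n_pairs <- config$n_cis_pairs + config$n_trans_pairs

  n_de_m <- round(config$frac_de_mrna * n_mrna)
  n_de_l <- round(config$frac_de_lncrna * n_lnc)
  assert_that(n_de_l >= n_pairs + config$n_tf_modules,
              "config plants more pairs/modules (", n_pairs, "+",
              config$n_tf_modules, ") than differential lncRNAs (", n_de_l, ")")
  assert_that(n_de_m >= n_pairs,
              "config plants more pairs than differential mRNAs")
  assert_that(n_mrna - n_de_m >=
                config$n_tf_modules * config$tf_module_size +
                config$n_absent_probes + config$n_absent_one_condition,
              "not enough null mRNA probes for TF modules / absent probes")

  mrna_ids <- sprintf("M%05d", seq_len(n_mrna))
  lnc_ids <- sprintf("L%05d", seq_len(n_lnc))
  probe_id <- c(mrna_ids, lnc_ids)
  gene_symbol <- c(sprintf("GM%05d", seq_len(n_mrna)),
                   sprintf("GL%05d", seq_len(n_lnc)))
  names(gene_symbol) <- probe_id
  n_probes <- length(probe_id)

  # --- role assignment --------------------------------------------------
  de_m <- sample(mrna_ids, n_de_m)
  de_l <- sample(lnc_ids, n_de_l)
  pair_l <- de_l[seq_len(n_pairs)]
  module_l <- de_l[n_pairs + seq_len(config$n_tf_modules)]
  pair_m <- de_m[seq_len(n_pairs)]
  free_m <- setdiff(mrna_ids, de_m)
  module_members <- list()
  if (config$n_tf_modules > 0) {
    picks <- sample(free_m, config$n_tf_modules * config$tf_module_size)
    module_members <- split(picks, rep(seq_len(config$n_tf_modules),
                                       each = config$tf_module_size))
    free_m <- setdiff(free_m, picks)
  }
  absent_probes <- character(0)
  if (config$n_absent_probes > 0) {
    absent_probes <- sample(free_m, config$n_absent_probes)
    free_m <- setdiff(free_m, absent_probes)
  }
  absent_one <- character(0)
  if (config$n_absent_one_condition > 0) {
    absent_one <- sample(free_m, config$n_absent_one_condition)
    free_m <- setdiff(free_m, absent_one)
  }

  # --- planted effect sizes --------------------------------------------
  draw_fc <- function(k) {
    stats::runif(k, config$log2fc_range[1], config$log2fc_range[2]) *
      sample(c(-1, 1), k, replace = TRUE)
  }
  delta <- stats::setNames(rep(0, n_probes), probe_id)
  delta[de_m] <- draw_fc(n_de_m)
  delta[de_l] <- draw_fc(n_de_l)

  # --- samples and base expression -------------------------------------
  patients <- sprintf("P%d", seq_len(np))
  design <- sample_design(
    sample_id = c(paste0(patients, "_control"), paste0(patients, "_treated")),
    patient_id = rep(patients, 2),
    condition = rep(c("control", "treated"), each = np))
  samples <- design$sample_id
  treated <- design$condition[match(samples, design$sample_id)] == "treated"
  pat_idx <- match(design$patient_id[match(samples, design$sample_id)],
                   patients)

  baseline <- stats::rnorm(n_probes, config$baseline_mean, config$baseline_sd)
  pat_eff <- matrix(stats::rnorm(n_probes * np, 0, config$patient_effect_sd),
                    n_probes, np)
  y <- baseline +
    pat_eff[, pat_idx] +
    outer(delta, as.numeric(treated)) +
    matrix(stats::rnorm(n_probes * length(samples), 0, config$residual_sd),
           n_probes, length(samples))
  dimnames(y) <- list(probe_id, samples)

  # --- negative coupling: overwrite pair mRNA profiles ------------------
  couple <- function(target_row, source_profile, r_target, sign) {
    s <- stats::sd(source_profile)
    sigma <- s * sqrt(1 / r_target^2 - 1)
    baseline[target_row] + sign * (source_profile - mean(source_profile)) +
      stats::rnorm(length(source_profile), 0, sigma)
  }
  for (i in seq_len(n_pairs)) {
    trow <- match(pair_m[i], probe_id)
    y[trow, ] <- couple(trow, y[pair_l[i], ], abs(config$coupling_r_target), -1)
    delta[pair_m[i]] <- -delta[pair_l[i]]   # inherited effect
  }

  # --- TF modules: couple members positively to the driver lncRNA -------
  for (m in seq_along(module_members)) {
    drv <- y[module_l[m], ]
    for (g in module_members[[m]]) {
      w <- stats::runif(1, 0.8, 1.2)       # magnitude jitter
      trow <- match(g, probe_id)
      s <- stats::sd(drv) * w
      sigma <- s * sqrt(1 / config$module_r_target^2 - 1)
      y[trow, ] <- baseline[trow] + w * (drv - mean(drv)) +
        stats::rnorm(length(drv), 0, sigma)
      delta[g] <- w * delta[module_l[m]]
    }
  }

  # --- flags ------------------------------------------------------------
  flags <- matrix(ifelse(stats::runif(n_probes * length(samples)) <
                           config$flag_absent_prob, "A", "P"),
                  n_probes, length(samples), dimnames = dimnames(y))
  if (length(absent_probes) > 0) flags[absent_probes, ] <- "A"
  if (length(absent_one) > 0) {
    flags[absent_one, samples[!treated]] <- "A"
    flags[absent_one, samples[treated]] <- "P"
  }
  # keep planted truth detectable: truth probes always present
  truth_probes <- c(de_m, de_l, unlist(module_members, use.names = FALSE))
  flags[truth_probes, ] <- "P"

  # --- annotation -------------------------------------------------------
  chroms <- paste0("chr", 1:22)
  chr <- sample(chroms, n_probes, replace = TRUE)
  names(chr) <- probe_id
  start <- sample.int(200000000L, n_probes, replace = TRUE)
  names(start) <- probe_id
  width <- sample(500:10000, n_probes, replace = TRUE)
  names(width) <- probe_id
  # cis pairs: same chromosome, gap below cis_max_gap
  for (i in seq_len(config$n_cis_pairs)) {
    l <- pair_l[i]; m <- pair_m[i]
    chr[m] <- chr[l]
    gap <- sample.int(config$cis_max_gap - 1L, 1)
    start[m] <- start[l] + width[l] + gap
  }
  # trans pairs: force different chromosomes
  for (i in config$n_cis_pairs + seq_len(config$n_trans_pairs)) {
    l <- pair_l[i]; m <- pair_m[i]
    if (chr[m] == chr[l]) chr[m] <- sample(setdiff(chroms, chr[l]), 1)
  }
  anno <- probe_annotation(data.frame(
    probe_id = probe_id,
    transcript_type = rep(c("mRNA", "lncRNA"), c(n_mrna, n_lnc)),
    gene_symbol = unname(gene_symbol),
    chromosome = unname(chr[probe_id]),
    start = unname(start[probe_id]),
    end = unname(start[probe_id] + width[probe_id] - 1L),
    strand = sample(c("+", "-"), n_probes, replace = TRUE),
    stringsAsFactors = FALSE))

  # --- gene sets --------------------------------------------------------
  null_m_symbols <- gene_symbol[free_m]
  tf_sets_list <- list()
  fn_sets_list <- list()
  for (m in seq_along(module_members)) {
    members <- unname(gene_symbol[module_members[[m]]])
    decoys <- sample(null_m_symbols, length(members))
    tf_sets_list[[sprintf("TF%02d", m)]] <- c(members, decoys)
    fn_sets_list[[sprintf("FN_MODULE%02d", m)]] <-
      c(members, sample(null_m_symbols, 5))
  }
  # one set enriched in the independently planted DE mRNAs, plus decoy sets
  de_only <- setdiff(de_m, pair_m)
  if (length(de_only) >= 5) {
    picked <- sample(de_only, max(5, round(0.8 * length(de_only))))
    fn_sets_list[["FN_DE_ENRICHED"]] <-
      c(unname(gene_symbol[picked]), sample(null_m_symbols, 10))
  }
  for (d in 1:5) {
    fn_sets_list[[sprintf("FN_DECOY%02d", d)]] <- sample(null_m_symbols, 40)
  }
  tf_sets <- gene_set_collection(tf_sets_list, kind_tag = "tf_targets")
  fn_sets <- gene_set_collection(fn_sets_list, kind_tag = "function")

  # --- manifest ---------------------------------------------------------
  de_tab <- data.frame(
    probe_id = c(de_m, de_l, unlist(module_members, use.names = FALSE)),
    stringsAsFactors = FALSE)
  de_tab$log2fc <- unname(delta[de_tab$probe_id])
  de_tab$direction <- ifelse(de_tab$log2fc > 0, "up", "down")
  de_tab$role <- c(ifelse(de_m %in% pair_m, "pair_mrna", "de_mrna"),
                   ifelse(de_l %in% pair_l, "pair_lncrna",
                          ifelse(de_l %in% module_l, "module_driver",
                                 "de_lncrna")),
                   rep("module_member",
                       length(unlist(module_members, use.names = FALSE))))
  pairs_tab <- data.frame(
    lncrna_probe_id = pair_l,
    mrna_probe_id = pair_m,
    class = rep(c("cis", "trans"), c(config$n_cis_pairs, config$n_trans_pairs)),
    target_r = rep(config$coupling_r_target, n_pairs),
    stringsAsFactors = FALSE)
  truth <- list(
    de = de_tab,
    pairs = pairs_tab,
    tf_modules = lapply(seq_along(module_members), function(m) {
      list(tf = sprintf("TF%02d", m),
           driver_lncrna = module_l[m],
           members = unname(gene_symbol[module_members[[m]]]))
    }),
    null_probe_ids = setdiff(probe_id,
                             c(de_tab$probe_id, absent_probes, absent_one)))

  mat <- expression_matrix(2^y, flags = flags, scale_tag = "raw")
  list(matrix = mat, design = design, annotation = anno,
       function_sets = fn_sets, tf_sets = tf_sets, truth = truth,
       config = config)
}

#' Realized effect sizes and pair correlations of a simulated dataset
#'
#' Recomputes, from the emitted matrix, the realized mean paired log2
#' difference of every planted differential probe and the realized Pearson
#' correlation of every planted pair, for use as recovery-test tolerances.
#'
#' @param mat The simulated [expression_matrix()] (raw or log2 scale).
#' @param design The matching [sample_design()].
#' @param truth The ground-truth manifest from [simulate_dataset()].
#' @return List with data.frames `de` (`probe_id`, `planted_log2fc`,
#'   `realized_log2fc`) and `pairs` (`lncrna_probe_id`, `mrna_probe_id`,
#'   `target_r`, `realized_r`).
#' @export
realized_truth_stats <- function(mat, design, truth) {
  unknown <- setdiff(c(truth$de$probe_id, truth$pairs$lncrna_probe_id,
                       truth$pairs$mrna_probe_id), probe_ids(mat))
  assert_that(length(unknown) == 0, "manifest references unknown probe(s): ",
              paste(utils::head(unknown, 3), collapse = ", "))
  v <- if (mat$scale_tag == "raw") log2(mat$values) else mat$values
  ctrl <- design[design$condition == "control", ]
  trt <- design[design$condition == "treated", ]
  trt <- trt[match(ctrl$patient_id, trt$patient_id), ]
  d <- v[, trt$sample_id, drop = FALSE] - v[, ctrl$sample_id, drop = FALSE]
  de <- truth$de
  de_out <- data.frame(probe_id = de$probe_id,
                       planted_log2fc = de$log2fc,
                       realized_log2fc = rowMeans(d[de$probe_id, , drop = FALSE]),
                       stringsAsFactors = FALSE)
  pr <- truth$pairs
  if (nrow(pr) > 0) {
    realized_r <- vapply(seq_len(nrow(pr)), function(i) {
      pearson_r(v[pr$lncrna_probe_id[i], ], v[pr$mrna_probe_id[i], ])
    }, 0)
  } else {
    realized_r <- numeric(0)
  }
  pairs_out <- data.frame(lncrna_probe_id = pr$lncrna_probe_id,
                          mrna_probe_id = pr$mrna_probe_id,
                          target_r = pr$target_r,
                          realized_r = realized_r,
                          stringsAsFactors = FALSE)
  list(de = de_out, pairs = pairs_out)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits the expression and flag matrices, design, annotation, both GMT
#' collections, the ground-truth manifest (JSON) and the configuration
#' (YAML) into `dir`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "expression.tsv"),
             flags = file.path(dir, "flags.tsv"),
             design = file.path(dir, "design.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             function_sets = file.path(dir, "function_sets.gmt"),
             tf_sets = file.path(dir, "tf_sets.gmt"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "config.yaml"))
  write_expression_matrix(sim$matrix, paths["matrix"], paths["flags"])
  write_sample_design(sim$design, paths["design"])
  write_probe_annotation(sim$annotation, paths["annotation"])
  write_gmt(sim$function_sets, paths["function_sets"])
  write_gmt(sim$tf_sets, paths["tf_sets"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  yaml::write_yaml(unclass(sim$config), paths["config"])
  invisible(paths)
}
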