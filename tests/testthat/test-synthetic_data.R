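# synthetic_data: determinism, planted structure, realized statistics

test_that("identical config and seed give byte-identical outputs", {
  cfg <- simulation_config(seed = 60, n_mrna = 300, n_lncrna = 100,
                           frac_de_mrna = 0.05, frac_de_lncrna = 0.1,
                           n_cis_pairs = 2, n_trans_pairs = 2,
                           n_tf_modules = 2, tf_module_size = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_dataset(simulate_dataset(cfg), d1)
  p2 <- write_dataset(simulate_dataset(cfg), d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }
  # different seed differs
  d3 <- simulate_dataset(simulation_config(seed = 61, n_mrna = 300,
                                           n_lncrna = 100,
                                           frac_de_mrna = 0.05,
                                           frac_de_lncrna = 0.1,
                                           n_cis_pairs = 2, n_trans_pairs = 2,
                                           n_tf_modules = 2,
                                           tf_module_size = 5))
  expect_false(identical(d3$matrix$values,
                         simulate_dataset(cfg)$matrix$values))
})

test_that("planted geometry honours the cis/trans predicates", {
  sim <- simulate_dataset(simulation_config(seed = 62, n_cis_pairs = 15,
                                            n_trans_pairs = 15,
                                            frac_de_mrna = 0.03,
                                            frac_de_lncrna = 0.05))
  anno <- sim$annotation
  tp <- sim$truth$pairs
  li <- match(tp$lncrna_probe_id, anno$probe_id)
  mi <- match(tp$mrna_probe_id, anno$probe_id)
  cis <- tp$class == "cis"
  # cis: same chromosome, mRNA interval within the 100 kb window
  expect_true(all(anno$chromosome[li][cis] == anno$chromosome[mi][cis]))
  expect_true(all(anno$start[mi][cis] <= anno$end[li][cis] + 100000 &
                    anno$end[mi][cis] >= anno$start[li][cis] - 100000))
  # trans: never same chromosome
  expect_true(all(anno$chromosome[li][!cis] != anno$chromosome[mi][!cis]))
  # every planted entity exists in the annotation
  expect_true(all(sim$truth$de$probe_id %in% anno$probe_id))
})

test_that("planted effect sizes and couplings are realized as stated", {
  # |log2fc| = 2, residual_sd = 0.1: mean paired diff within 0.15 of 2
  # for the vast majority of planted probes (SE = sqrt(2)*0.1/sqrt(5))
  cfg <- simulation_config(seed = 63, n_mrna = 1000, n_lncrna = 300,
                           frac_de_mrna = 0.1, frac_de_lncrna = 0.1,
                           log2fc_range = c(2, 2), residual_sd = 0.1,
                           n_cis_pairs = 5, n_trans_pairs = 5,
                           n_tf_modules = 0)
  sim <- simulate_dataset(cfg)
  rt <- realized_truth_stats(sim$matrix, sim$design, sim$truth)
  de <- rt$de[!(rt$de$probe_id %in% sim$truth$pairs$mrna_probe_id), ]
  expect_gte(mean(abs(abs(de$realized_log2fc) - 2) <= 0.15), 0.95)
  # realized pair correlations concentrate near the -0.95 target
  expect_gte(mean(rt$pairs$realized_r >= -1 & rt$pairs$realized_r <= -0.85),
             0.9)
  # null probes: realized effect within the normal tail bound
  v <- log2(sim$matrix$values)
  ctrl <- sim$design$sample_id[sim$design$condition == "control"]
  trt <- sub("_control", "_treated", ctrl)
  nd <- rowMeans(v[sim$truth$null_probe_ids, trt] -
                   v[sim$truth$null_probe_ids, ctrl])
  bound <- 3 * sqrt(2) * cfg$residual_sd / sqrt(cfg$n_patients)
  expect_gte(mean(abs(nd) < bound), 0.99)

  # manifest referencing an unknown probe errors
  bad <- sim$truth
  bad$de$probe_id[1] <- "missing"
  expect_error(realized_truth_stats(sim$matrix, sim$design, bad),
               "unknown probe")
  # empty manifest -> empty summary
  none <- list(de = sim$truth$de[0, ], pairs = sim$truth$pairs[0, ])
  empty <- realized_truth_stats(sim$matrix, sim$design, none)
  expect_equal(nrow(empty$de), 0L)
  expect_equal(nrow(empty$pairs), 0L)
})

test_that("flag options exercise the filter as designed", {
  cfg <- simulation_config(seed = 64, n_mrna = 300, n_lncrna = 100,
                           frac_de_mrna = 0.02, frac_de_lncrna = 0.05,
                           n_cis_pairs = 1, n_trans_pairs = 1,
                           n_tf_modules = 1, tf_module_size = 5,
                           n_absent_probes = 10, n_absent_one_condition = 10,
                           flag_absent_prob = 0)
  sim <- simulate_dataset(cfg)
  kept <- filter_by_flags(log2_transform(sim$matrix), sim$design)
  all_absent <- rownames(sim$matrix$values)[
    rowSums(sim$matrix$flags == "A") == ncol(sim$matrix$flags)]
  one_cond <- rownames(sim$matrix$values)[
    rowSums(sim$matrix$flags == "A") == cfg$n_patients]
  expect_length(all_absent, 10)
  expect_length(one_cond, 10)
  expect_false(any(all_absent %in% rownames(kept$values)))
  expect_true(all(one_cond %in% rownames(kept$values)))  # one condition P
})

test_that("impossible configurations are rejected", {
  expect_error(simulation_config(cis_max_gap = 2e5), "100,000")
  expect_error(
    simulate_dataset(simulation_config(n_lncrna = 100, frac_de_lncrna = 0.02,
                                       n_cis_pairs = 5, n_trans_pairs = 5)),
    "pairs")
})
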