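# coexpression: Pearson screening and cis/trans classification

test_that("pearson_r and correlation_p match oracles and examples", {
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.9819805, tolerance = 1e-6)
  # affine invariance / antisymmetry
  set.seed(20)
  x <- rnorm(10)
  expect_equal(pearson_r(x, 3 + 2 * x), 1)
  y <- rnorm(10)
  expect_equal(pearson_r(x, -y), -pearson_r(x, y))
  expect_message(expect_true(is.na(pearson_r(x, rep(1, 10)))), "constant")

  expect_equal(correlation_p(0, 10), 1)
  expect_equal(correlation_p(-0.9, 10), 3.871562e-4, tolerance = 1e-6)
  expect_equal(correlation_p(0.7, 8), correlation_p(-0.7, 8))
  expect_equal(correlation_p(1, 5), 0)

  # cor.test oracle on random instances
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    ct <- cor.test(x, y)
    r <- pearson_r(x, y)
    expect_equal(r, unname(ct$estimate), tolerance = 1e-10)
    expect_equal(correlation_p(r, n), ct$p.value, tolerance = 1e-10)
  }
})

test_that("screen_negative_pairs equals the brute-force all-pairs oracle", {
  set.seed(22)
  n <- 10
  nl <- 30; nm <- 40
  v <- matrix(rnorm((nl + nm) * n), nl + nm, n)
  # plant a few strong negatives
  for (i in 1:5) v[nl + i, ] <- -v[i, ] + rnorm(n, 0, 0.2)
  probes <- c(sprintf("L%02d", 1:nl), sprintf("M%02d", 1:nm))
  mat <- tiny_matrix(v, probes = probes, scale_tag = "normalized")
  anno <- tiny_annotation(probes,
                          transcript_type = rep(c("lncRNA", "mRNA"), c(nl, nm)),
                          chromosome = sample(paste0("chr", 1:5), nl + nm,
                                              replace = TRUE))
  cfgp <- pair_screen_config(restrict_to_differential = FALSE)
  got <- screen_negative_pairs(mat, anno, config = cfgp)

  # oracle: direct double loop with cor / cor.test
  oracle <- list()
  for (l in probes[1:nl]) for (m in probes[nl + 1:nm]) {
    r <- cor(v[match(l, probes), ], v[match(m, probes), ])
    p <- cor.test(v[match(l, probes), ], v[match(m, probes), ])$p.value
    if (r <= -0.9 && p <= 0.05) {
      oracle[[length(oracle) + 1]] <- data.frame(l = l, m = m, r = r, p = p)
    }
  }
  oracle <- do.call(rbind, oracle)
  expect_equal(nrow(got), nrow(oracle))
  key <- function(a, b) paste(a, b)
  expect_setequal(key(got$lncrna_probe_id, got$mrna_probe_id),
                  key(oracle$l, oracle$m))
  idx <- match(key(got$lncrna_probe_id, got$mrna_probe_id),
               key(oracle$l, oracle$m))
  expect_equal(got$r, oracle$r[idx], tolerance = 1e-12)
  expect_equal(got$corr_p, oracle$p[idx], tolerance = 1e-12)

  # boundary: r threshold is inclusive at -0.9, exclusive above
  expect_true(all(got$r <= -0.9))
})

test_that("cis/trans classification follows window, chromosome and P rules", {
  probes <- c("L", "M_near", "M_far", "M_other")
  anno <- probe_annotation(data.frame(
    probe_id = probes,
    transcript_type = c("lncRNA", "mRNA", "mRNA", "mRNA"),
    gene_symbol = paste0("g", probes),
    chromosome = c("chr1", "chr1", "chr1", "chr2"),
    start = c(200000L, 150000L, 320001L, 1000L),
    end = c(210000L, 160000L, 330000L, 2000L),
    strand = "+", stringsAsFactors = FALSE))
  pairs <- data.frame(
    lncrna_probe_id = "L",
    mrna_probe_id = c("M_near", "M_far", "M_other"),
    r = -0.95, corr_p = 0.005,
    same_chromosome = c(TRUE, TRUE, FALSE),
    genomic_gap = c(39999, 110000, NA),
    regulation_class = "unclassified", stringsAsFactors = FALSE)
  out <- classify_cis_trans(pairs, anno)
  expect_identical(out$regulation_class, c("cis", "trans", "trans"))

  # gap arithmetic from screen annotation: nearest-end distance
  mat <- tiny_matrix(rbind(c(1, 2, 3, 7, 5, 6, 4, 8, 9, 10) + rnorm(10, 0, .1),
                           -c(1, 2, 3, 7, 5, 6, 4, 8, 9, 10) + rnorm(10, 0, .1)),
                     probes = c("L", "M_far"), scale_tag = "normalized")
  scr <- screen_negative_pairs(mat, anno, de_lncrna = "L", de_mrna = "M_far")
  expect_equal(scr$genomic_gap, 110000)

  # cis needs the stricter correlation P
  loose <- pairs[1, ]; loose$corr_p <- 0.03
  expect_identical(classify_cis_trans(loose, anno)$regulation_class, "trans")

  # cis set shrinks monotonically with the window
  small <- pair_screen_config(cis_window = 10000)
  out_small <- classify_cis_trans(pairs, anno, small)
  expect_true(all(which(out_small$regulation_class == "cis") %in%
                    which(out$regulation_class == "cis")))

  # missing annotation -> unclassified
  orphan <- pairs[1, ]; orphan$mrna_probe_id <- "nope"
  expect_message(oc <- classify_cis_trans(orphan, anno), "unclassified")
  expect_identical(oc$regulation_class, "unclassified")
})

test_that("chromosome_distribution counts same-chromosome pairs", {
  anno <- tiny_annotation(c("L1", "L2", "L3", "M1"),
                          chromosome = c("chr6", "chr17", "chr6", "chr1"))
  pairs <- data.frame(
    lncrna_probe_id = c("L1", "L1", "L3", "L2", "L2", "L1"),
    mrna_probe_id = "M1", r = -0.95, corr_p = 0.001,
    same_chromosome = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    genomic_gap = NA, regulation_class = "trans", stringsAsFactors = FALSE)
  cd <- chromosome_distribution(pairs, anno)
  expect_equal(cd[["chr6"]], 3L)
  expect_equal(cd[["chr17"]], 2L)
  expect_equal(sum(cd), sum(pairs$same_chromosome))
  expect_length(chromosome_distribution(pairs[0, ], anno), 0)
})

test_that("planted pairs are recovered with exact cis/trans labels", {
  cfg <- simulation_config(seed = 31, n_mrna = 1000, n_lncrna = 400,
                           frac_de_mrna = 0.03, frac_de_lncrna = 0.06,
                           log2fc_range = c(1.5, 4),
                           n_cis_pairs = 10, n_trans_pairs = 10,
                           n_tf_modules = 2, tf_module_size = 10)
  sim <- simulate_dataset(cfg)
  m <- preprocess_default(sim)
  de <- differential_expression(m, sim$design, sim$annotation)
  sel <- select_differential(de)
  all_sel <- rbind(sel$up, sel$down)
  pairs <- screen_negative_pairs(
    m, sim$annotation,
    all_sel$probe_id[all_sel$transcript_type == "lncRNA"],
    all_sel$probe_id[all_sel$transcript_type == "mRNA"])
  pairs <- classify_cis_trans(pairs, sim$annotation)
  tp <- sim$truth$pairs
  key <- paste(pairs$lncrna_probe_id, pairs$mrna_probe_id)
  tkey <- paste(tp$lncrna_probe_id, tp$mrna_probe_id)
  hit <- tkey %in% key
  expect_gte(mean(hit), 0.9)
  # geometric predicate is deterministic: labels of recovered pairs exact
  expect_identical(pairs$regulation_class[match(tkey[hit], key)],
                   tp$class[hit])
})
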