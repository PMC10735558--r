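test_that("curation removes low-MAF, monomorphic, heterozygous and gappy markers", {
  n <- 50
  good <- function() sample(c(0, 2), n, replace = TRUE, prob = c(0.6, 0.4))
  d <- cbind(
    M_good1 = good(), M_good2 = good(),
    M_lowmaf = c(rep(0, 48), 2, 2),       # MAF 0.04
    M_mono = rep(0, n),                    # MAF 0
    M_het = c(rep(1, 10), rep(0, 30), rep(2, 10)),  # 20% het
    M_miss = c(rep(NA, 5), rep(c(0, 2), length.out = 45)))
  set.seed(20)
  panel <- make_panel(d)
  cur <- suppressMessages(curate_markers(panel))
  expect_setequal(colnames(cur$dosage), c("M_good1", "M_good2"))
  rep_tab <- attr(cur, "curation_report")
  expect_equal(rep_tab$removed[rep_tab$filter == "missing"], 1)
  expect_equal(rep_tab$removed[rep_tab$filter == "maf"], 2)
  expect_equal(rep_tab$removed[rep_tab$filter == "het"], 1)
})

test_that("planted MAF violators are removed exactly", {
  # deterministic panel: 190 polymorphic markers + 10 planted violators
  set.seed(21)
  n <- 100
  d <- matrix(sample(c(0, 2), n * 190, replace = TRUE), n, 190)
  bad <- matrix(0, n, 10)
  bad[1:2, ] <- 2                     # MAF 0.02 < 0.05
  panel <- make_panel(cbind(d, bad))
  cur <- suppressMessages(curate_markers(panel))
  expect_equal(ncol(cur$dosage), 190)
  expect_false(any(sprintf("M%03d", 191:200) %in% colnames(cur$dosage)))
})

test_that("kinship is PSD and duplicated genotypes have identical rows", {
  set.seed(22)
  d <- matrix(sample(0:2, 40 * 120, replace = TRUE,
                     prob = c(0.45, 0.1, 0.45)), 40, 120)
  d[2, ] <- d[1, ]                    # duplicate line
  sk <- structure_and_kinship(make_panel(d))
  expect_true(isSymmetric(sk$K))
  expect_gte(min(eigen(sk$K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_equal(unname(sk$K[1, ]), unname(sk$K[2, ]), tolerance = 1e-12)
  expect_equal(unname(sk$K[1, 2]), unname(sk$K[1, 1]), tolerance = 1e-12)
})

test_that("structure PCs separate drifted subpopulations", {
  cfg <- sim_config(n_genotypes = 60, n_markers = 400, n_subpopulations = 2,
                    drift = 0.45, seed = 23)
  g <- simulate_genotypes(cfg)
  sk <- structure_and_kinship(g)
  sil <- durumwp:::mean_silhouette(matrix(sk$Q[, 1]),
                                   g$subpop$subpopulation)
  expect_gt(sil, 0.5)
})

test_that("identical markers give r2 = 1 and independent panels decay to background", {
  set.seed(24)
  n <- 200
  x <- sample(c(0, 2), n, replace = TRUE)
  pair <- make_panel(cbind(A = x, B = x), position = c(1e6, 6e6))
  ld <- suppressWarnings(ld_decay(pair, critical_r2 = 0.05, n_bins = 2))
  expect_equal(ld$mean_r2, 1, tolerance = 1e-12)

  d_ind <- matrix(sample(c(0, 2), n * 80, replace = TRUE), n, 80)
  ld2 <- ld_decay(make_panel(d_ind), critical_r2 = 0.05)
  expect_gt(ld2$mean_r2, 0.5 / n)
  expect_lt(ld2$mean_r2, 2 / n)
})

test_that("block-copied LD yields a decay distance on the order of the block length", {
  hit <- 0
  for (s in 1:5) {
    cfg <- sim_config(n_genotypes = 150, n_markers = 300, n_chromosomes = 5,
                      chromosome_length = 4e8, ld_block_length = 4e7,
                      n_subpopulations = 1, n_founder_haplotypes = 4,
                      seed = 100 + s)
    g <- simulate_genotypes(cfg)
    n_g <- nrow(g$dosage)
    ld <- ld_decay(g, critical_r2 = critical_r2_for_n(n_g))
    if (is.finite(ld$ld_distance) &&
        ld$ld_distance > cfg$ld_block_length / 4 &&
        ld$ld_distance < cfg$ld_block_length * 4) hit <- hit + 1
  }
  expect_gte(hit, 4)
})

test_that("a noise-free monogenic phenotype is mapped exactly", {
  set.seed(25)
  n <- 80
  d <- matrix(sample(0:2, n * 50, replace = TRUE), n, 50)
  panel <- make_panel(d)
  d <- panel$dosage
  y <- tibble::tibble(genotype_id = rownames(d), value = 2 * d[, 17])
  scan <- gwas(panel, y, model = "GLM_Q", n_pc = 0)
  hit <- scan[scan$marker_id == "M017", ]
  expect_equal(hit$effect, 2, tolerance = 1e-8)
  expect_equal(hit$r2_marker, 1, tolerance = 1e-8)
  expect_lt(hit$p_value, 1e-200)
})

test_that("the mixed model with identity kinship reproduces the fixed model", {
  set.seed(26)
  n <- 60
  d <- matrix(sample(0:2, n * 100, replace = TRUE), n, 100)
  panel <- make_panel(d)
  d <- panel$dosage
  y <- tibble::tibble(genotype_id = rownames(d),
                      value = rnorm(n) + 0.4 * d[, 3])
  covar <- tibble::tibble(genotype_id = rownames(d), DTH = rnorm(n))
  K <- diag(n); dimnames(K) <- list(rownames(d), rownames(d))
  glm_scan <- gwas(panel, y, covariates = covar, model = "GLM_Q", n_pc = 0)
  mlm_scan <- gwas(panel, y, covariates = covar, model = "MLM_QK",
                   K = K, n_pc = 0)
  expect_equal(mlm_scan$p_value, glm_scan$p_value, tolerance = 1e-6)
  expect_equal(mlm_scan$effect, glm_scan$effect, tolerance = 1e-6)
})

test_that("collinear covariates are refused by name", {
  set.seed(27)
  n <- 40
  d <- matrix(sample(0:2, n * 20, replace = TRUE), n, 20)
  panel <- make_panel(d)
  d <- panel$dosage
  y <- tibble::tibble(genotype_id = rownames(d), value = rnorm(n))
  covar <- tibble::tibble(genotype_id = rownames(d),
                          DTH = rnorm(n))
  covar$DTH2 <- covar$DTH * 2
  expect_error(gwas(panel, y, covariates = covar, model = "GLM_Q",
                    n_pc = 0), "DTH2")
})

test_that("kinship correction shrinks structure-driven inflation", {
  closer <- 0
  for (s in 1:6) {
    cfg <- sim_config(n_genotypes = 100, n_markers = 300,
                      n_subpopulations = 2, drift = 0.5, n_qtl = 0,
                      seed = 200 + s)
    g <- simulate_genotypes(cfg)
    sk <- structure_and_kinship(g, n_pc = 2)
    # polygenic phenotype: confounded with structure, no single QTL
    set.seed(300 + s)
    alpha <- rnorm(ncol(g$dosage), 0, 1)
    dd <- g$dosage; dd[is.na(dd)] <- 1
    y <- tibble::tibble(genotype_id = rownames(dd),
                        value = as.numeric(scale(dd %*% alpha)) +
                          rnorm(nrow(dd), 0, 0.5))
    glm_scan <- gwas(g, y, model = "GLM_Q", Q = NULL, n_pc = 0)
    mlm_scan <- gwas(g, y, model = "MLM_QK", K = sk$K, n_pc = 0)
    l_glm <- attr(glm_scan, "lambda")[["GLM_Q"]]
    l_mlm <- attr(mlm_scan, "lambda")[["MLM_QK"]]
    if (abs(l_mlm - 1) < abs(l_glm - 1)) closer <- closer + 1
  }
  expect_gte(closer, 5)
})

test_that("MTA gates require both LOD and marker r2", {
  scan <- tibble::tibble(
    marker_id = c("A", "B", "C"),
    chromosome = "chr1", position = c(1, 2, 3) * 1e6,
    effect = 1, se = 1,
    p_value = c(1e-4, 1e-4, 0.5),
    lod = c(4, 4, 0.3),
    r2_marker = c(0.1, 0.01, 0.3),
    model_used = "GLM_Q", trait = "GY", context = "combined_stressed")
  out <- call_mtas(scan, lod_cutoff = 2.69, r2_cutoff = 0.024)
  expect_equal(out$marker_id, "A")
})

test_that("QTL assembly follows the merge, consistency and representative rules", {
  base <- tibble::tibble(
    trait = "GY", context = "E01", effect = 1, se = 1, p_value = 1e-4,
    model_used = "GLM_Q")
  mk <- function(marker, chrom, pos_mbp, lod = 4, r2 = 0.1, ctx = "E01") {
    dplyr::mutate(base, marker_id = marker, chromosome = chrom,
                  position = pos_mbp * 1e6, lod = lod, r2_marker = r2,
                  context = ctx)
  }
  merge_d <- 102.6e6

  q1 <- assemble_qtl(dplyr::bind_rows(mk("A", "chr1", 10),
                                      mk("B", "chr1", 50)), merge_d)
  expect_equal(nrow(q1), 1)
  q2 <- assemble_qtl(dplyr::bind_rows(mk("A", "chr1", 10),
                                      mk("B", "chr1", 150)), merge_d)
  expect_equal(nrow(q2), 2)

  # single-linkage transitivity: 10-100-190 chains into one 180 Mbp QTL
  q3 <- assemble_qtl(dplyr::bind_rows(mk("A", "chr1", 10),
                                      mk("B", "chr1", 100),
                                      mk("C", "chr1", 190)), merge_d)
  expect_equal(nrow(q3), 1)
  expect_equal(q3$span_end - q3$span_start, 180e6)

  # consistency: combined + >1 individual environment
  qc <- assemble_qtl(dplyr::bind_rows(
    mk("A", "chr1", 10, ctx = "combined_stressed"),
    mk("B", "chr1", 20, ctx = "E01"),
    mk("C", "chr1", 30, ctx = "E02")), merge_d)
  expect_true(qc$consistent)
  qc2 <- assemble_qtl(dplyr::bind_rows(
    mk("A", "chr1", 10, ctx = "combined_stressed"),
    mk("B", "chr1", 20, ctx = "E01")), merge_d)
  expect_false(qc2$consistent)

  # representative marker: max LOD, tie on r2, then lowest position
  qr <- assemble_qtl(dplyr::bind_rows(
    mk("A", "chr1", 10, lod = 4, r2 = 0.10),
    mk("B", "chr1", 20, lod = 5, r2 = 0.05),
    mk("C", "chr1", 30, lod = 5, r2 = 0.05)), merge_d)
  expect_equal(qr$representative_marker, "B")

  # input order invariance
  mtas <- dplyr::bind_rows(mk("A", "chr1", 10), mk("B", "chr2", 40),
                           mk("C", "chr1", 80), mk("D", "chr2", 200))
  qa <- assemble_qtl(mtas, merge_d)
  qb <- assemble_qtl(mtas[c(3, 1, 4, 2), ], merge_d)
  expect_equal(qa, qb)

  # true-positive flag from a second panel's overlapping QTL
  other <- tibble::tibble(chromosome = "chr1", span_start = 60e6,
                          span_end = 90e6)
  qt <- assemble_qtl(mtas, merge_d, other_panel_qtl = other)
  expect_true(qt$true_positive[qt$chromosome == "chr1"])
  expect_false(any(qt$true_positive[qt$chromosome == "chr2"]))
})
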