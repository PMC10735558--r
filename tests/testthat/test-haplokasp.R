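test_that("haplotype construction partitions complete homozygous genotypes", {
  d <- rbind(
    G1 = c(2, 2, 2),     # +++
    G2 = c(0, 0, 0),     # ---
    G3 = c(2, 0, 2),     # +-+
    G4 = c(2, 1, 2),     # het -> excluded
    G5 = c(2, NA, 2),    # missing -> excluded
    G6 = c(2, 0, 2))     # +-+ again
  colnames(d) <- c("M1", "M2", "M3")
  panel <- make_panel(d)
  fav <- c(M1 = "B", M2 = "B", M3 = "B")
  h <- suppressMessages(build_haplotypes(panel, c("M1", "M2", "M3"), fav))
  expect_setequal(h$genotype_id, c("G1", "G2", "G3", "G6"))
  expect_setequal(attr(h, "excluded"), c("G4", "G5"))
  # +++ and --- in distinct groups; identical patterns share one
  expect_false(h$haplotype_id[h$genotype_id == "G1"] ==
                 h$haplotype_id[h$genotype_id == "G2"])
  expect_equal(h$haplotype_id[h$genotype_id == "G3"],
               h$haplotype_id[h$genotype_id == "G6"])
  # numbering by descending favorable-allele count
  expect_equal(h$haplotype_id[h$genotype_id == "G1"], "Hap1")
  expect_equal(h$n_positive_alleles[h$genotype_id == "G1"], 3L)
  # a true partition: each genotype in exactly one group
  expect_equal(anyDuplicated(h$genotype_id), 0L)

  # flipping the favorable allele flips the pattern
  fav2 <- c(M1 = "A", M2 = "A", M3 = "A")
  h2 <- suppressMessages(build_haplotypes(panel, c("M1", "M2", "M3"), fav2))
  expect_equal(h2$pattern[h2$genotype_id == "G1"], "---")
})

test_that("identical calls give a single group and all-het panels error", {
  d <- matrix(2, 4, 2, dimnames = list(paste0("G", 1:4), c("M1", "M2")))
  panel <- make_panel(d)
  h <- suppressMessages(
    build_haplotypes(panel, c("M1", "M2"), c(M1 = "B", M2 = "B")))
  expect_equal(dplyr::n_distinct(h$haplotype_id), 1L)
  d_het <- matrix(1, 4, 2, dimnames = list(paste0("G", 1:4), c("M1", "M2")))
  expect_error(suppressMessages(
    build_haplotypes(make_panel(d_het), c("M1", "M2"),
                     c(M1 = "B", M2 = "B"))), "complete")
})

test_that("the LSD follows its closed form and letters mirror separation", {
  expect_equal(lsd_value(mse = 1, n_a = 5, n_b = 5, df = 8),
               qt(0.975, 8) * sqrt(0.4))
  expect_equal(round(lsd_value(1, 5, 5, 8), 3), 1.458)

  set.seed(30)
  haps <- tibble::tibble(
    genotype_id = sprintf("G%02d", 1:20),
    pattern = rep(c("++", "--"), each = 10),
    haplotype_id = rep(c("Hap1", "Hap2"), each = 10),
    n_positive_alleles = rep(c(2L, 0L), each = 10))
  # widely separated groups -> distinct letters
  ph_far <- tibble::tibble(genotype_id = haps$genotype_id,
                           value = rep(c(100, 50), each = 10) + rnorm(20))
  t_far <- haplotype_effect_test(haps, ph_far)
  expect_false(any(strsplit(t_far$lsd_letter[1], "")[[1]] %in%
                     strsplit(t_far$lsd_letter[2], "")[[1]]))
  # identical groups -> a shared letter
  ph_same <- tibble::tibble(genotype_id = haps$genotype_id,
                            value = rnorm(20, 100, 1))
  t_same <- haplotype_effect_test(haps, ph_same)
  expect_true(any(strsplit(t_same$lsd_letter[1], "")[[1]] %in%
                    strsplit(t_same$lsd_letter[2], "")[[1]]))
})

test_that("planted haplotype effects are recovered from simulated panels", {
  cfg <- sim_config(n_genotypes = 150, n_environments = 12, n_markers = 200,
                    n_qtl = 3, qtl_main_effect = 400,
                    qtl_moisture_interaction = 0, slope_dev_sd = 0,
                    frac_null = 0, het_rate = 0, missing_rate = 0,
                    seed = 31)
  sim <- suppressMessages(simulate_trials(cfg))
  qtl <- sim$truth$qtl
  fav <- setNames(rep("B", nrow(qtl)), qtl$marker_id)
  h <- suppressMessages(
    build_haplotypes(sim$genotypes, qtl$marker_id, fav, min_size = 1))
  gy <- sim$plots |>
    dplyr::group_by(genotype_id) |>
    dplyr::summarise(value = mean(GY))
  hp <- dplyr::inner_join(h, gy, by = "genotype_id")
  # each additional "+" is a homozygous favorable locus: 2 x 400 kg/ha
  slope <- coef(lm(value ~ n_positive_alleles, data = hp))[2]
  expect_equal(unname(slope), 800, tolerance = 0.25 * 800)
})

test_that("allele-yield correlations behave and flip with the favorable call", {
  d <- matrix(c(0, 1, 2), 3, 1, dimnames = list(paste0("G", 1:3), "M1"))
  panel <- make_panel(d)
  b <- tibble::tibble(genotype_id = paste0("G", 1:3),
                      environment_id = "E1", trait = "GY",
                      value = c(1, 2, 3))
  pr <- allele_gy_profile(panel, b, "M1", c(M1 = "B"), critical_r2 = 0.5)
  expect_equal(pr$r, 1, tolerance = 1e-12)
  pr2 <- allele_gy_profile(panel, b, "M1", c(M1 = "A"), critical_r2 = 0.5)
  expect_equal(pr2$r, -1, tolerance = 1e-12)

  d_mono <- matrix(2, 3, 1, dimnames = list(paste0("G", 1:3), "M1"))
  pr3 <- allele_gy_profile(make_panel(d_mono), b, "M1", c(M1 = "B"))
  expect_true(is.na(pr3$r))
})

test_that("validation metrics match the confusion-matrix arithmetic", {
  ids <- sprintf("G%03d", 1:60)
  gy <- tibble::tibble(genotype_id = ids,
                       value = seq(6000, 1000, length.out = 60))
  top <- ids[1:20]; worst <- ids[41:60]
  carrier <- rep(FALSE, 60)
  names(carrier) <- ids
  carrier[top[1:15]] <- TRUE            # 15/20 positives carry
  carrier[worst[1:2]] <- TRUE           # 18/20 negatives do not
  calls <- tibble::tibble(genotype_id = ids, marker_id = "K1",
                          carrier = unname(carrier))
  m <- kasp_validate(calls, gy, n_extreme = 20)
  expect_equal(m$accuracy, 0.825)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.90)
  expect_equal(m$tp, 15); expect_equal(m$tn, 18)

  # literal denominators divide by all extremes
  m2 <- kasp_validate(calls, gy, n_extreme = 20,
                      literal_denominators = TRUE)
  expect_equal(m2$sensitivity, 15 / 40)
  expect_equal(m2$specificity, 18 / 40)

  # a perfectly discriminating marker scores 1 everywhere
  calls_perfect <- tibble::tibble(genotype_id = ids, marker_id = "K2",
                                  carrier = ids %in% top)
  mp <- kasp_validate(calls_perfect, gy, n_extreme = 20)
  expect_equal(c(mp$accuracy, mp$sensitivity, mp$specificity), c(1, 1, 1))
})

test_that("balanced extremes force accuracy = (sensitivity + specificity) / 2", {
  set.seed(32)
  ids <- sprintf("G%03d", 1:50)
  gy <- tibble::tibble(genotype_id = ids, value = rnorm(50, 3000, 500))
  for (i in 1:100) {
    calls <- tibble::tibble(genotype_id = ids, marker_id = "K",
                            carrier = runif(50) < 0.5)
    m <- kasp_validate(calls, gy, n_extreme = 15)
    expect_equal(m$accuracy, (m$sensitivity + m$specificity) / 2,
                 tolerance = 1e-12)
  }
})

test_that("random calls validate at chance and AND-combination trades sensitivity for specificity", {
  set.seed(33)
  ids <- sprintf("G%03d", 1:60)
  gy <- tibble::tibble(genotype_id = ids, value = rnorm(60, 3000, 500))
  accs <- replicate(200, {
    calls <- tibble::tibble(genotype_id = ids, marker_id = "K",
                            carrier = runif(60) < 0.5)
    kasp_validate(calls, gy, n_extreme = 20)$accuracy
  })
  expect_equal(mean(accs), 0.5, tolerance = 0.05)

  for (i in 1:20) {
    calls <- dplyr::bind_rows(
      tibble::tibble(genotype_id = ids, marker_id = "K1",
                     carrier = runif(60) < 0.6),
      tibble::tibble(genotype_id = ids, marker_id = "K2",
                     carrier = runif(60) < 0.6))
    m <- kasp_validate(calls, gy, n_extreme = 20,
                       combine = c("K1", "K2"))
    both <- m[m$marker_id == "K1+K2", ]
    singles <- m[m$marker_id %in% c("K1", "K2"), ]
    expect_lte(both$sensitivity, min(singles$sensitivity) + 1e-12)
    expect_gte(both$specificity, max(singles$specificity) - 1e-12)
  }
})
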