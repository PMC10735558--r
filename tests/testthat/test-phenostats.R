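test_that("grain number components follow the defining quotients", {
  rec <- tibble::tibble(genotype_id = "G1", environment_id = "E1",
                        harvested_weight = 4000, plot_area = 4, TKW = 40,
                        SPK = 500)
  out <- derive_components(rec, quiet = TRUE)
  expect_equal(out$Grm2, 25000)
  expect_equal(out$GpS, 50)

  # unit-consistent rescaling of weight and kernel weight cancels
  rec2 <- dplyr::mutate(rec, harvested_weight = harvested_weight * 3,
                        TKW = TKW * 3)
  expect_equal(derive_components(rec2, quiet = TRUE)$Grm2, 25000)
})

test_that("missing inputs leave components absent without dropping rows", {
  rec <- tibble::tibble(genotype_id = c("G1", "G2"),
                        environment_id = "E1",
                        harvested_weight = c(4000, 4000),
                        plot_area = 4, TKW = c(NA, 40), SPK = c(500, 0))
  out <- suppressMessages(derive_components(rec))
  expect_equal(nrow(out), 2)
  expect_true(is.na(out$Grm2[1]))       # TKW absent
  expect_true(is.na(out$GpS[2]))        # SPK zero
  # a measured GpS is never overwritten
  rec$GpS <- c(99, 99)
  out2 <- suppressMessages(derive_components(rec))
  expect_equal(out2$GpS, c(99, 99))
})

test_that("augmented BLUEs apply the check-based block adjustment", {
  d <- augmented_env(
    values = c(10, 12, 20),
    genotype = c("CHK", "CHK", "T1"),
    block = c("B1", "B2", "B2"),
    is_check = c(TRUE, TRUE, FALSE))
  b <- compute_blues(d, design = "augmented", traits = "GY")
  expect_equal(b$value[b$genotype_id == "T1"], 19)
  expect_equal(b$value[b$genotype_id == "CHK"], 11)

  # a block without any check is a design error, named in the message
  d2 <- augmented_env(values = c(10, 20), genotype = c("CHK", "T1"),
                      block = c("B1", "B2"), is_check = c(TRUE, FALSE))
  expect_error(compute_blues(d2, design = "augmented", traits = "GY"), "B2")
})

test_that("replication within a block shrinks the augmented BLUE's standard error", {
  d <- augmented_env(
    values = c(10, 11, 12, 13, 20, 30, 31, 24),
    genotype = c("C1", "C2", "C1", "C2", "T1", "T2", "T2", "T3"),
    block = c("B1", "B1", "B2", "B2", "B1", "B2", "B2", "B1"),
    is_check = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  b <- compute_blues(d, design = "augmented", traits = "GY")
  se1 <- b$se[b$genotype_id == "T1"]
  se2 <- b$se[b$genotype_id == "T2"]
  expect_equal(se2, se1 / sqrt(2))
  expect_equal(nrow(b[b$genotype_id == "T2", ]), 1)
})

test_that("alpha-lattice BLUEs equal arithmetic means in a balanced design with no block variance", {
  set.seed(42)
  vals <- rnorm(8, 100, 10)
  d <- tibble::tibble(
    genotype_id = rep(c("G1", "G2", "G3", "G4"), 2),
    environment_id = "E1",
    block_id = rep(c("R1B1", "R2B1"), each = 4),
    replicate = rep(1:2, each = 4),
    is_check = FALSE,
    GY = vals)
  b <- compute_blues(d, design = "alpha_lattice", traits = "GY")
  raw <- tapply(d$GY, d$genotype_id, mean)
  expect_equal(b$value, as.numeric(raw[b$genotype_id]), tolerance = 1e-8)
})

test_that("variance shares are ratios of sums of squares and are conserved", {
  # additive 2x2: SS_E = 100, SS_G = 4, no interaction
  M <- matrix(c(0, 2, 10, 12), 2, 2,
              dimnames = list(c("G1", "G2"), c("E1", "E2")))
  vp <- variance_partition(blues_from_matrix(M))
  expect_equal(unname(vp$shares["E"]), 100 / 104)
  expect_equal(unname(vp$shares["G"]), 4 / 104)
  expect_equal(unname(vp$shares["GxE"]), 0)

  # conservation on an unbalanced random layout
  set.seed(7)
  d <- tidyr::expand_grid(genotype_id = sprintf("G%d", 1:8),
                          environment_id = sprintf("E%d", 1:5),
                          rep = 1:2) |>
    dplyr::slice_sample(prop = 0.8) |>
    dplyr::mutate(GY = rnorm(dplyr::n(), 100, 20))
  vp2 <- variance_partition(d, "GY")
  expect_equal(sum(vp2$ss[c("G", "E", "GxE", "resid")]),
               unname(vp2$ss["total"]), tolerance = 1e-8)
  expect_error(variance_partition(d[d$environment_id == "E1", ], "GY"),
               "single environment")
})

test_that("per-environment heritability follows s2g / (s2g + s2e/r)", {
  # crafted one-way layout: MSE = 2, MSG = 6, r = 2 -> H2 = 2/3
  delta <- sqrt(6)
  d <- tibble::tibble(
    genotype_id = rep(c("A", "B"), each = 2, times = 2),
    environment_id = rep(c("E1", "E2"), each = 4),
    GY = rep(c(-1, 1, delta - 1, delta + 1), 2))
  vp <- variance_partition(d, "GY")
  expect_equal(unname(vp$H2_by_env["E1"]), 2 / 3, tolerance = 1e-8)
  expect_equal(unname(vp$H2_by_env["E2"]), 2 / 3, tolerance = 1e-8)
})

test_that("ratio-to-max scales by the top entry and averages across environments", {
  M <- matrix(c(5, 10, 10, 10), 2, 2,
              dimnames = list(c("G1", "G2"), c("E1", "E2")))
  r <- ratio_to_max(blues_from_matrix(M), quiet = TRUE)
  expect_equal(r$gy_ratio[r$genotype_id == "G1"], 0.75)
  expect_equal(r$gy_ratio[r$genotype_id == "G2"], 1.0)

  # permuting environments changes nothing
  b <- blues_from_matrix(M)
  r2 <- ratio_to_max(b[sample(nrow(b)), ], quiet = TRUE)
  expect_equal(dplyr::arrange(r2, genotype_id), dplyr::arrange(r, genotype_id))
})

test_that("trait-yield correlations star perfect relations and dash degenerate ones", {
  set.seed(1)
  n <- 12
  b <- dplyr::bind_rows(
    tibble::tibble(genotype_id = sprintf("G%02d", 1:n), environment_id = "E1",
                   trait = "GY", value = seq(1000, 3000, length.out = n)),
    tibble::tibble(genotype_id = sprintf("G%02d", 1:n), environment_id = "E1",
                   trait = "TKW", value = seq(30, 50, length.out = n)),
    tibble::tibble(genotype_id = sprintf("G%02d", 1:n), environment_id = "E1",
                   trait = "SPK", value = rep(250, n)))
  ct <- trait_gy_correlations(b)
  expect_equal(ct$r[ct$trait == "TKW"], 1, tolerance = 1e-8)
  expect_equal(ct$code[ct$trait == "TKW"], "•")
  expect_equal(ct$code[ct$trait == "SPK"], "-")
})

test_that("independent noise rarely reaches the 0.001 star", {
  set.seed(2)
  n <- 120
  n_env <- 200
  b <- dplyr::bind_rows(lapply(seq_len(n_env), function(e) {
    tibble::tibble(
      genotype_id = rep(sprintf("G%03d", 1:n), 2),
      environment_id = sprintf("E%03d", e),
      trait = rep(c("GY", "TKW"), each = n),
      value = rnorm(2 * n))
  }))
  ct <- trait_gy_correlations(b)
  expect_gte(mean(ct$code != "•"), 0.985)
})
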