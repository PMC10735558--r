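test_that("water productivity is the yield-to-moisture quotient", {
  env <- tibble::tibble(environment_id = "wet_top_env",
                        total_moisture = 457.6)
  b <- tibble::tibble(genotype_id = "G1", environment_id = "wet_top_env",
                      trait = "GY", value = 6413.5)
  wp <- water_productivity(b, env)
  expect_equal(wp$wp_overall, 6413.5 / 457.6, tolerance = 1e-12)
  expect_equal(round(wp$wp_overall, 2), 14.02)

  # zero yield and scale invariance
  b0 <- dplyr::mutate(b, value = 0)
  expect_equal(water_productivity(b0, env)$wp_overall, 0)
  wp2 <- water_productivity(dplyr::mutate(b, value = value * 2),
                            dplyr::mutate(env, total_moisture =
                                            total_moisture * 2))
  expect_equal(wp2$wp_overall, wp$wp_overall)
})

test_that("environments without valid moisture are excluded with a note", {
  env <- tibble::tibble(environment_id = c("E1", "E2"),
                        total_moisture = c(400, NA))
  b <- blues_from_matrix(matrix(c(4000, 3000), 1, 2,
                                dimnames = list("G1", c("E1", "E2"))))
  expect_message(wp <- water_productivity(b, env), "E2")
  expect_equal(wp$wp_overall, 10)
})

test_that("group slopes recover an exact linear trend and OLS invariances hold", {
  env <- env_table(seq(220, 420, length.out = 6),
                   seq(460, 650, length.out = 5))
  gy <- tibble::tibble(
    environment_id = env$environment_id,
    mean_gy = ifelse(env$group == "moisture_stressed",
                     300 + 5.08 * env$total_moisture,
                     2500 + 4.85 * env$total_moisture))
  gs <- suppressWarnings(group_slopes(gy, env))
  expect_equal(gs$slope[gs$group == "moisture_stressed"], 5.08,
               tolerance = 1e-10)
  expect_equal(gs$slope[gs$group == "non_moisture_stressed"], 4.85,
               tolerance = 1e-10)

  gs_shift <- suppressWarnings(
    group_slopes(dplyr::mutate(gy, mean_gy = mean_gy + 777), env))
  expect_equal(gs_shift$slope, gs$slope, tolerance = 1e-10)

  gs_flat <- suppressWarnings(
    group_slopes(dplyr::mutate(gy, mean_gy = 1000), env))
  expect_equal(gs_flat$slope, c(0, 0), tolerance = 1e-10)

  expect_error(group_slopes(gy[c(1, 2, 7:11), ], env), "fewer than 3")
})

test_that("the quadrant rule assigns the four responsive classes", {
  env <- env_table(seq(220, 420, length.out = 7),
                   seq(460, 650, length.out = 6))
  # planted slopes per genotype: (stressed, non-stressed)
  b <- blues_with_slopes(
    slopes_st = c(6.0, 6.0, 4.0, 4.0, 5.08),
    slopes_ns = c(4.0, 6.0, 6.0, 4.0, 4.85),
    env = env)
  cls <- classify_genotypes(b, env,
                            slopes = c(stressed = 5.08, nonstressed = 4.85))
  expect_equal(cls$wp_class, c(2L, 4L, 3L, 1L, 1L))
  expect_equal(cls$class_name[1], "Responsive to low moisture")
  expect_equal(cls$class_name[2], "Highly water responsive")
  # exact boundary slopes went to the "<=" side (class 1)
  expect_equal(cls$b_stressed[5], 5.08, tolerance = 1e-8)
  # classes 1-4 and 5 partition all classified genotypes
  expect_true(all(cls$wp_class %in% 1:5))
})

test_that("the per-group gate option demands significance in both groups", {
  env <- env_table(seq(220, 420, length.out = 7),
                   seq(460, 650, length.out = 6))
  b <- blues_with_slopes(6.0, 4.0, env, noise = 30)
  cls_ov <- classify_genotypes(b, env,
                               slopes = c(stressed = 5.08,
                                          nonstressed = 4.85))
  cls_pg <- classify_genotypes(b, env,
                               slopes = c(stressed = 5.08,
                                          nonstressed = 4.85),
                               gate = "per_group")
  expect_equal(cls_ov$wp_class, 2L)
  expect_equal(cls_pg$wp_class, 2L)   # near-exact fits pass either gate

  # noisy genotype: overall trend clear, within-group trends drowned
  set.seed(8)
  b2 <- blues_with_slopes(5.08, 4.85, env, noise = 0)
  b2$value <- b2$value + rnorm(nrow(b2), 0, 400)
  pg <- classify_genotypes(b2, env,
                           slopes = c(stressed = 5.08, nonstressed = 4.85),
                           gate = "per_group")
  ov <- classify_genotypes(b2, env,
                           slopes = c(stressed = 5.08, nonstressed = 4.85))
  expect_equal(pg$wp_class, 5L)
  expect_equal(ov$wp_class %in% 1:4, TRUE)
})

test_that("unresponsive genotypes fall into class 5 and sparse ones are unclassifiable", {
  env <- env_table(seq(220, 420, length.out = 7),
                   seq(460, 650, length.out = 6))
  set.seed(9)
  n_null <- 150
  b <- dplyr::bind_rows(lapply(seq_len(n_null), function(i) {
    tibble::tibble(genotype_id = sprintf("N%03d", i),
                   environment_id = env$environment_id,
                   trait = "GY",
                   value = 2000 + rnorm(nrow(env), 0, 400))
  }))
  cls <- classify_genotypes(b, env,
                            slopes = c(stressed = 5.08, nonstressed = 4.85),
                            alpha = 0.01)
  expect_gte(mean(cls$wp_class == 5L), 0.95)

  # fewer than 3 environments in a group -> reported missing with reason
  b_sparse <- b[b$genotype_id == "N001" &
                  b$environment_id %in% env$environment_id[c(1, 2, 8:13)], ]
  cls2 <- classify_genotypes(b_sparse, env,
                             slopes = c(stressed = 5.08,
                                        nonstressed = 4.85))
  expect_true(is.na(cls2$wp_class))
  expect_match(cls2$reason, "fewer than 3")
})

test_that("classification is invariant to environment ordering", {
  env <- env_table(seq(220, 420, length.out = 7),
                   seq(460, 650, length.out = 6))
  b <- blues_with_slopes(c(6.0, 4.2), c(4.0, 5.6), env)
  set.seed(10)
  cls1 <- classify_genotypes(b, env,
                             slopes = c(stressed = 5.08, nonstressed = 4.85))
  cls2 <- classify_genotypes(b[sample(nrow(b)), ], env[sample(nrow(env)), ],
                             slopes = c(stressed = 5.08, nonstressed = 4.85))
  expect_equal(cls1, cls2)
})
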