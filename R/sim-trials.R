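#' Simulate plot-level multi-environment trial data
#'
#' Builds environments along a moisture gradient (split into a stressed and a
#' non-stressed group), a five-growth-stage climate table, and plot-level
#' phenotypes with the planted structure: grain yield is environment trend
#' (affine in moisture within each group, with the group slopes of `cfg`) +
#' genotype main effect + genotype-specific moisture-slope deviation + QTL
#' main and QTL x moisture effects + block effect + residual. TKW, SPK and
#' DTH are generated with configurable genetic correlation to yield. All
#' planted effects are recorded in the returned truth object.
#'
#' @param cfg a [sim_config()] object.
#' @param geno a `wp_geno` panel from [simulate_genotypes()]. If `NULL`, one
#'   is generated from `cfg`.
#'
#' @return A `wp_sim` object: list with `plots` (plot-level tibble),
#'   `climate` (long stage x variable tibble), `environments` (tibble with
#'   `environment_id`, `group`, `total_moisture`), `genotypes` (the panel)
#'   and `truth` (planted QTL, slopes, class labels, variance components).
#' @export
simulate_trials <- function(cfg, geno = NULL) {
  stopifnot(inherits(cfg, "wp_sim_config"))
  if (cfg$var_E == 0)
    wp_stop("var_E = 0 is not a valid configuration: the environment effect ",
            "carries the moisture response")
  if (is.null(geno)) geno <- simulate_genotypes(cfg)
  stopifnot(inherits(geno, "wp_geno"))

  withr::with_seed(derive_seed(cfg$seed, 2L), {
    ## ---- environments along the moisture gradient -------------------------
    n_env <- cfg$n_environments
    n_s <- max(1L, round(cfg$frac_stressed * n_env))
    n_n <- n_env - n_s
    rng <- cfg$moisture_range
    span <- diff(rng)
    m_s <- seq(rng[1], rng[1] + 0.50 * span, length.out = n_s)
    m_n <- if (n_n > 0) seq(rng[1] + 0.57 * span, rng[2], length.out = n_n)
           else numeric(0)
    moisture <- c(m_s, m_n)
    group <- rep(c("moisture_stressed", "non_moisture_stressed"), c(n_s, n_n))
    env_ids <- sprintf("E%02d", seq_len(n_env))
    environments <- tibble(environment_id = env_ids, group = group,
                           total_moisture = moisture)

    climate <- build_climate(env_ids, moisture, group)

    ## ---- environment effects (affine in moisture per group) ---------------
    slopes <- cfg$group_slopes
    icpts <- cfg$env_intercepts
    grp_key <- ifelse(group == "moisture_stressed", "stressed", "nonstressed")
    env_eff <- icpts[grp_key] + slopes[grp_key] * moisture
    var_E_emp <- var(env_eff)
    # anchor the absolute variance scale to the moisture-driven E variance
    scale_fct <- var_E_emp / cfg$var_E
    var_G_eff <- cfg$var_G * scale_fct
    var_GxE_eff <- cfg$var_GxE * scale_fct
    var_resid_eff <- cfg$var_resid * scale_fct

    geno_ids <- rownames(geno$dosage)
    n_g <- length(geno_ids)

    ## ---- QTL: main and moisture-interaction effects -----------------------
    dos <- geno$dosage
    dos_imp <- apply(dos, 2, function(x) {
      x[is.na(x)] <- mean(x, na.rm = TRUE); x })
    maf <- marker_stats(geno)$maf
    eligible <- which(maf >= 0.20)
    if (length(eligible) < cfg$n_qtl) eligible <- order(-maf)[seq_len(cfg$n_qtl)]
    qtl_idx <- if (cfg$n_qtl > 0) sort(sample(eligible, cfg$n_qtl)) else integer(0)
    beta_main <- rep(cfg$qtl_main_effect, cfg$n_qtl)
    beta_int <- rep(cfg$qtl_moisture_interaction, cfg$n_qtl)
    dos_q <- dos_imp[, qtl_idx, drop = FALSE]
    dos_qc <- scale(dos_q, center = TRUE, scale = FALSE)
    qtl_main_i <- if (cfg$n_qtl > 0) drop(dos_qc %*% beta_main) else rep(0, n_g)
    qtl_slope_i <- if (cfg$n_qtl > 0) drop(dos_qc %*% beta_int) else rep(0, n_g)

    ## ---- genotype main effects (polygenic or iid) -------------------------
    var_poly <- max(0, var_G_eff - var(qtl_main_i))
    if (cfg$polygenic && ncol(dos_imp) > 0 && var_poly > 0) {
      alpha <- rnorm(ncol(dos_imp))
      g_raw <- drop(scale(dos_imp) %*% alpha)
      g_raw[is.na(g_raw)] <- 0
      g_i <- if (sd(g_raw) > 0) g_raw / sd(g_raw) * sqrt(var_poly) else rep(0, n_g)
    } else if (var_poly > 0) {
      g_i <- rnorm(n_g, 0, sqrt(var_poly))
    } else g_i <- rep(0, n_g)
    g_i <- g_i - mean(g_i)

    ## ---- per-genotype slope deviations and true slopes --------------------
    if (!is.null(cfg$planted_slope_dev)) {
      dev <- cfg$planted_slope_dev
    } else if (cfg$slope_dev_sd > 0) {
      dev <- matrix(rnorm(2 * n_g, 0, cfg$slope_dev_sd), ncol = 2)
    } else dev <- matrix(0, n_g, 2)
    colnames(dev) <- c("stressed", "nonstressed")
    is_null <- rep(FALSE, n_g)
    if (cfg$frac_null > 0)
      is_null[sample.int(n_g, round(cfg$frac_null * n_g))] <- TRUE
    f_null <- mean(is_null)
    # responsive genotypes carry the group trend inflated by 1/(1 - f), so
    # that the environment means (nulls included) recover the configured
    # group slopes and the moisture-driven E variance exactly
    infl <- 1 / (1 - f_null)
    b_true <- cbind(
      stressed = infl * slopes[["stressed"]] + dev[, 1] + qtl_slope_i,
      nonstressed = infl * slopes[["nonstressed"]] + dev[, 2] + qtl_slope_i)
    b_true[is_null, ] <- 0    # a null genotype has no moisture response at all
    class_true <- ifelse(
      is_null, 5L,
      ifelse(b_true[, 1] > slopes[["stressed"]],
             ifelse(b_true[, 2] > slopes[["nonstressed"]], 4L, 2L),
             ifelse(b_true[, 2] > slopes[["nonstressed"]], 3L, 1L)))

    ## ---- cell-level GY ----------------------------------------------------
    m_bar_grp <- tapply(moisture, grp_key, mean)
    m_dev_env <- moisture - m_bar_grp[grp_key]          # within-group centering
    env_bar <- mean(env_eff)
    # environment response per genotype: nulls are flat at the average
    # environment level; responsive genotypes get the inflated trend
    env_resp <- matrix(env_bar, n_g, n_env)
    env_resp[!is_null, ] <- rep(1, sum(!is_null)) %o%
      (env_bar + infl * (env_eff - env_bar))
    slope_dev_tot <- cbind(stressed = dev[, 1] + qtl_slope_i,
                           nonstressed = dev[, 2] + qtl_slope_i)
    slope_dev_tot[is_null, ] <- 0
    S <- slope_dev_tot[, match(grp_key, colnames(slope_dev_tot)), drop = FALSE]
    # structured GxE: the genotype-specific extra moisture response, QTL
    # interaction included (qtl_slope_i entered slope_dev_tot)
    S <- sweep(S, 2, m_dev_env, `*`)
    var_S <- var(as.vector(S))
    unstr_sd <- sqrt(max(0, var_GxE_eff - var_S))
    gxe_noise <- matrix(rnorm(n_g * n_env, 0, unstr_sd), n_g, n_env)
    cells <- env_resp + (g_i + qtl_main_i) + S + gxe_noise
    dimnames(cells) <- list(geno_ids, env_ids)

    ## ---- correlated secondary traits (genotype components) ----------------
    z_g <- if (sd(g_i + qtl_main_i) > 0) scale(g_i + qtl_main_i)[, 1] else rep(0, n_g)
    mix <- function(rho, sd_g) sd_g * (rho * z_g + sqrt(1 - rho^2) * rnorm(n_g))
    tkw_g <- mix(cfg$trait_cor[["TKW"]], 3)
    spk_g <- mix(cfg$trait_cor[["SPK"]], 25)
    subpop_num <- as.integer(factor(geno$subpop$subpopulation))
    dth_g <- mix(cfg$trait_cor[["DTH"]], 3) + 2 * (subpop_num - mean(subpop_num))
    m_std <- (moisture - mean(moisture)) / sd(moisture)
    h2 <- cfg$heritability_target
    noise_sd <- function(sd_g) sd_g * sqrt((1 - h2) / h2)

    ## ---- field layout -----------------------------------------------------
    layout <- build_layout(cfg, geno_ids, env_ids)
    block_sd <- 0.5 * sqrt(var_resid_eff)
    blocks <- unique(layout[c("environment_id", "block_id")])
    blocks$block_eff <- rnorm(nrow(blocks), 0, block_sd)
    plots <- layout |>
      left_join(blocks, by = c("environment_id", "block_id"))
    gi <- match(plots$genotype_id, geno_ids)
    ei <- match(plots$environment_id, env_ids)
    plots$GY <- pmax(0, cells[cbind(gi, ei)] + plots$block_eff +
                        rnorm(nrow(plots), 0, sqrt(var_resid_eff)))
    plots$plot_area <- 6
    plots$harvested_weight <- plots$GY * plots$plot_area / 10   # grams
    plots$TKW <- pmax(5, 35 + tkw_g[gi] + 4 * m_std[ei] +
                        rnorm(nrow(plots), 0, noise_sd(3)))
    plots$SPK <- pmax(10, 250 + spk_g[gi] + 30 * m_std[ei] +
                        rnorm(nrow(plots), 0, noise_sd(25)))
    plots$DTH <- round(120 + dth_g[gi] - 6 * m_std[ei] +
                         rnorm(nrow(plots), 0, noise_sd(3) / 2))
    plots$block_eff <- NULL
    plots <- as_tibble(plots)

    truth <- list(
      qtl = tibble(
        marker_id = colnames(dos)[qtl_idx],
        chromosome = geno$map$chromosome[match(colnames(dos)[qtl_idx],
                                               geno$map$marker_id)],
        position = geno$map$position[match(colnames(dos)[qtl_idx],
                                           geno$map$marker_id)],
        main_effect = beta_main,
        interaction_effect = beta_int,
        favorable_allele = "B"
      ),
      genotype_slopes = tibble(
        genotype_id = geno_ids,
        b_stressed = b_true[, 1],
        b_nonstressed = b_true[, 2],
        is_null = is_null
      ),
      class_labels = tibble(genotype_id = geno_ids, wp_class = class_true),
      subpopulation = geno$subpop,
      environments = environments,
      genotype_effects = setNames(g_i + qtl_main_i, geno_ids),
      environment_effects = setNames(env_eff, env_ids),
      variance_components = c(G = var_G_eff, E = var_E_emp,
                              GxE = var_GxE_eff, resid = var_resid_eff)
    )

    structure(list(plots = plots, climate = climate,
                   environments = environments, genotypes = geno,
                   truth = truth, config = cfg),
              class = "wp_sim")
  })
}

# five-growth-stage climate table; the in-season stage moistures sum exactly
# to the environment total, with Dirichlet noise on the stage shares.
# Moisture-stressed environments show the agronomic stress signature:
# depleted flowering and grain-fill moisture relative to the vegetative stage.
build_climate <- function(env_ids, moisture, group) {
  stages_in <- c("vegetative", "flowering", "grain_fill", "maturity")
  alpha_by_group <- list(
    moisture_stressed = c(vegetative = 60, flowering = 8,
                          grain_fill = 12, maturity = 20),
    non_moisture_stressed = c(vegetative = 34, flowering = 24,
                              grain_fill = 30, maturity = 12))
  temp_base <- c(pre_sowing = 18, vegetative = 15, flowering = 22,
                 grain_fill = 27, maturity = 31)
  rows <- lapply(seq_along(env_ids), function(i) {
    sh <- rgamma(4, shape = alpha_by_group[[group[i]]])
    sh <- sh / sum(sh)
    stage_m <- c(pre_sowing = runif(1, 30, 90), setNames(sh * moisture[i], stages_in))
    stage_t <- temp_base + 0.012 * (450 - moisture[i]) + rnorm(5, 0, 1)
    tibble(environment_id = env_ids[i],
           stage = rep(names(stage_m), 2),
           variable = rep(c("moisture", "max_temperature"), each = 5),
           value = c(unname(stage_m), unname(stage_t)),
           total_moisture = moisture[i])
  })
  bind_rows(rows)
}

build_layout <- function(cfg, geno_ids, env_ids) {
  out <- lapply(env_ids, function(e) {
    if (cfg$design == "augmented") {
      checks <- geno_ids[seq_len(min(cfg$n_checks, length(geno_ids)))]
      tests <- setdiff(geno_ids, checks)
      blk <- sprintf("B%02d", seq_len(cfg$n_blocks))
      test_blk <- sample(rep_len(blk, length(tests)))
      rbind(
        data.frame(genotype_id = rep(checks, each = cfg$n_blocks),
                   block_id = rep(blk, length(checks)),
                   replicate = 1L, is_check = TRUE),
        data.frame(genotype_id = tests, block_id = test_blk,
                   replicate = 1L, is_check = FALSE)
      )
    } else {
      do.call(rbind, lapply(1:2, function(r) {
        blk <- sample(rep_len(seq_len(cfg$n_blocks), length(geno_ids)))
        data.frame(genotype_id = sample(geno_ids),
                   block_id = sprintf("R%d-B%02d", r, blk),
                   replicate = r, is_check = FALSE)
      }))
    }
  })
  layout <- do.call(rbind, Map(function(d, e) {
    d$environment_id <- e; d }, out, env_ids))
  layout[c("genotype_id", "environment_id", "block_id", "replicate", "is_check")]
}
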