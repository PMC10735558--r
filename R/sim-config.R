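#' Configuration for the synthetic multi-environment trial generator
#'
#' Bundles and validates every knob of the simulator. Defaults emulate the
#' statistical structure of a Mediterranean durum wheat trial series: a panel
#' of inbred lines evaluated across 18 environments whose in-season moisture
#' spans roughly 210-650 mm, with environment explaining the bulk of grain
#' yield variation (E >> GxE > G), per-genotype moisture-response slopes
#' centred on the moisture-group trends (5.08 and 4.85 kg/ha/mm), and a
#' handful of biallelic QTL whose effects interact with moisture.
#'
#' The `var_*` arguments are relative shares of the total sum of squares
#' (defaults 0.10 / 0.73 / 0.12 / 0.05 for G / E / GxE / residual). The
#' absolute scale in kg^2/ha^2 is anchored to the environment variance implied
#' by the moisture spread and the group slopes, so that both the planted
#' slopes and the planted variance structure hold simultaneously.
#'
#' @param n_genotypes number of panel entries.
#' @param n_environments number of trial environments.
#' @param moisture_range total in-season moisture range (mm), min < max.
#' @param n_markers number of biallelic SNP markers.
#' @param n_chromosomes number of chromosomes (durum wheat has 14).
#' @param chromosome_length chromosome length in bp.
#' @param n_qtl number of planted yield QTL (must be <= n_markers).
#' @param qtl_main_effect additive main effect per favorable allele (kg/ha).
#' @param qtl_moisture_interaction allele x moisture interaction (kg/ha/mm).
#' @param n_subpopulations number of drifted subpopulations.
#' @param var_G,var_E,var_GxE,var_resid relative variance shares (see above).
#' @param heritability_target broad-sense heritability aimed for within
#'   environments, in (0, 1]; informs the residual scaling of non-yield traits.
#' @param design `"augmented"` (unreplicated entries + replicated checks) or
#'   `"alpha_lattice"` (2 replicates, resolvable incomplete blocks).
#' @param n_checks number of replicated check entries (augmented design).
#' @param n_blocks blocks per environment (augmented) or incomplete blocks per
#'   replicate (alpha-lattice).
#' @param group_slopes named vector of planted average slopes (kg/ha/mm) for
#'   the stressed / non-stressed moisture groups.
#' @param env_intercepts named vector of group intercepts (kg/ha) of the
#'   environment-mean trend on moisture.
#' @param frac_stressed fraction of environments in the moisture-stressed group.
#' @param slope_dev_sd SD of per-genotype slope deviations (kg/ha/mm).
#' @param frac_null fraction of genotypes planted with no moisture response
#'   (true slope 0 in both groups; ground truth for class 5).
#' @param planted_slope_dev optional n_genotypes x 2 matrix of exact slope
#'   deviations (columns: stressed, non-stressed) overriding the random draw.
#' @param ld_block_length haplotype-block length (bp) used to induce local LD.
#' @param n_founder_haplotypes founder haplotypes per block per subpopulation.
#' @param drift SD of subpopulation allele-frequency drift.
#' @param het_rate probability a call is heterozygous (inbred lines: small).
#' @param missing_rate probability a call is missing.
#' @param maf_floor minor-allele-frequency floor used by the curation pass.
#' @param n_violating_markers markers deliberately planted to violate the MAF
#'   filter, so the curation step is exercised.
#' @param polygenic if `TRUE`, the genotype main effect is a sum of many small
#'   marker effects (kinship-structured); if `FALSE` it is iid normal.
#' @param trait_cor named vector of genetic correlations of TKW, SPK, DTH
#'   with grain yield.
#' @param seed integer seed; every downstream draw derives from it.
#'
#' @return A validated list of class `wp_sim_config`.
#' @export
sim_config <- function(n_genotypes = 200,
                       n_environments = 18,
                       moisture_range = c(210, 650),
                       n_markers = 600,
                       n_chromosomes = 14,
                       chromosome_length = 6e8,
                       n_qtl = 6,
                       qtl_main_effect = 260,
                       qtl_moisture_interaction = 0.5,
                       n_subpopulations = 4,
                       var_G = 0.10, var_E = 0.73,
                       var_GxE = 0.12, var_resid = 0.05,
                       heritability_target = 0.8,
                       design = c("augmented", "alpha_lattice"),
                       n_checks = 4, n_blocks = 6,
                       group_slopes = c(stressed = 5.08, nonstressed = 4.85),
                       env_intercepts = c(stressed = 0, nonstressed = 2540),
                       frac_stressed = 11 / 18,
                       slope_dev_sd = 1.0,
                       frac_null = 0.05,
                       planted_slope_dev = NULL,
                       ld_block_length = 2e7,
                       n_founder_haplotypes = 3,
                       drift = 0.10,
                       het_rate = 0.02,
                       missing_rate = 0.002,
                       maf_floor = 0.05,
                       n_violating_markers = 0,
                       polygenic = TRUE,
                       trait_cor = c(TKW = 0.5, SPK = 0.4, DTH = -0.3),
                       seed = 1L) {
  design <- match.arg(design)
  cfg <- as.list(environment())
  cfg$design <- design
  validate_sim_config(cfg)
  structure(cfg, class = "wp_sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(c(var_G, var_E, var_GxE, var_resid) < 0))
      wp_stop("all variance shares must be >= 0")
    if (n_qtl > n_markers)
      wp_stop("n_qtl (", n_qtl, ") must not exceed n_markers (", n_markers, ")")
    if (moisture_range[1] >= moisture_range[2])
      wp_stop("moisture_range must satisfy min < max")
    if (heritability_target <= 0 || heritability_target > 1)
      wp_stop("heritability_target must be in (0, 1]")
    if (!is.null(planted_slope_dev) &&
        (!is.matrix(planted_slope_dev) ||
         nrow(planted_slope_dev) != n_genotypes || ncol(planted_slope_dev) != 2))
      wp_stop("planted_slope_dev must be an n_genotypes x 2 matrix")
    if (frac_null < 0 || frac_null >= 1) wp_stop("frac_null must be in [0, 1)")
  })
  invisible(cfg)
}

#' @export
print.wp_sim_config <- function(x, ...) {
  cat("<wp_sim_config>\n")
  cat(sprintf("  %d genotypes x %d environments, %s design\n",
              x$n_genotypes, x$n_environments, x$design))
  cat(sprintf("  %d markers on %d chromosomes, %d QTL, %d subpopulations\n",
              x$n_markers, x$n_chromosomes, x$n_qtl, x$n_subpopulations))
  cat(sprintf("  moisture %g-%g mm; variance shares G/E/GxE/res = %g/%g/%g/%g\n",
              x$moisture_range[1], x$moisture_range[2],
              x$var_G, x$var_E, x$var_GxE, x$var_resid))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
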