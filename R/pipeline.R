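#' Build a validated pipeline configuration
#'
#' Collects the inputs and tuning parameters of the end-to-end analysis.
#' Inputs may be in-memory objects (tibbles / a `wp_geno` panel) or file
#' paths (CSV for phenotypes and climate, HapMap-style TSV or VCF for
#' genotypes). Referenced files must exist; alpha levels must lie in (0, 1).
#'
#' @param plots plot-level phenotype tibble or CSV path.
#' @param climate long climate tibble or CSV path.
#' @param genotypes `wp_geno` panel or genotype file path (`.vcf` or
#'   HapMap-style TSV).
#' @param design trial design passed to [compute_blues()].
#' @param k number of mega-environments.
#' @param alpha_class WP classification significance gate (default 0.01).
#' @param alpha_ammi IPC F-test level (default 0.05).
#' @param alpha_lsd LSD test level (default 0.05).
#' @param lod_cutoff,r2_cutoff MTA significance gates (defaults 2.69, 0.024).
#' @param merge_distance QTL merge distance in bp; `NULL` uses twice the
#'   estimated LD decay distance.
#' @param ld_critical_r2 background r-squared defining the LD decay distance
#'   (default the frozen 0.05); `NULL` derives it from the panel size via
#'   [critical_r2_for_n()].
#' @param frozen_slopes optional named vector `c(stressed=, nonstressed=)`
#'   of reference slopes (e.g. `c(stressed = 5.08, nonstressed = 4.85)`);
#'   `NULL` recomputes them from the data.
#' @param gwas_model model passed to [gwas()].
#' @param n_extreme extremes size for KASP validation.
#' @param qtl_prefix identifier prefix for QTL names.
#' @param seed integer seed for any stochastic step.
#' @param out_dir optional output directory for per-stage artifacts.
#' @return a `wp_pipeline_config` list.
#' @export
wp_pipeline_config <- function(plots, climate, genotypes,
                               design = c("augmented", "alpha_lattice"),
                               k = 2, alpha_class = 0.01, alpha_ammi = 0.05,
                               alpha_lsd = 0.05, lod_cutoff = 2.69,
                               r2_cutoff = 0.024, merge_distance = NULL,
                               ld_critical_r2 = 0.05,
                               frozen_slopes = NULL,
                               gwas_model = "auto", n_extreme = 20,
                               qtl_prefix = "SIM", seed = 1L,
                               out_dir = NULL) {
  design <- match.arg(design)
  for (nm in c("plots", "climate", "genotypes")) {
    x <- get(nm)
    if (is.character(x) && !file.exists(x))
      wp_stop("config: ", nm, " file not found: ", x, stage = "config")
  }
  for (a in c(alpha_class, alpha_ammi, alpha_lsd))
    if (a <= 0 || a >= 1) wp_stop("alpha levels must be in (0, 1)",
                                  stage = "config")
  cfg <- as.list(environment())
  cfg$nm <- NULL; cfg$x <- NULL; cfg$a <- NULL
  structure(cfg, class = "wp_pipeline_config")
}

#' Run the full water-productivity analysis pipeline
#'
#' Chains every stage: derived yield components, per-environment BLUEs,
#' variance partition, climate regression, mega-environment clustering,
#' AMMI + AWAI + selection surface, water-productivity classification,
#' marker curation, structure/kinship, LD decay, GWAS per context (each
#' environment plus the two combined mega-environment means, with DTH as
#' covariate), MTA calling, QTL assembly, haplotype construction and effect
#' test, and KASP-style validation of the representative markers. Any stage
#' failure halts with a stage-named error. If `out_dir` is set, per-stage
#' CSV/JSON artifacts and a manifest (inputs, seed, thresholds, package
#' version) are written.
#'
#' @param config a [wp_pipeline_config()] object.
#' @param quiet suppress per-stage progress messages.
#' @return a named list with every stage result.
#' @export
run_wp_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "wp_pipeline_config"))
  res <- list(config = config)
  say <- function(...) if (!quiet) wp_note("pipeline: ", ...)
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      wp_stop(conditionMessage(e), stage = stage)
    })
  }

  ## ---- load inputs ------------------------------------------------------
  plots <- run("load", {
    if (is.character(config$plots))
      readr::read_csv(config$plots, show_col_types = FALSE)
    else as_tibble(config$plots)
  })
  climate <- run("envclim", {
    if (is.character(config$climate)) {
      if (!file.exists(config$climate))
        wp_stop("climate file not found: ", config$climate)
      readr::read_csv(config$climate, show_col_types = FALSE)
    } else as_tibble(config$climate)
  })
  panel <- run("load", {
    g <- config$genotypes
    if (inherits(g, "wp_geno")) g
    else if (grepl("\\.vcf(\\.gz)?$", g)) read_genotypes_vcf(g)
    else read_hapmap(g)
  })

  ## ---- phenotype stages -------------------------------------------------
  say("deriving yield components")
  plots <- run("phenostats", derive_components(plots, quiet = TRUE))
  say("computing BLUEs (", config$design, ")")
  res$blues <- run("phenostats", compute_blues(plots, design = config$design))
  res$varpart <- run("phenostats", variance_partition(plots, "GY"))

  env_mean_gy <- res$blues |>
    filter(.data$trait == "GY") |>
    group_by(.data$environment_id) |>
    summarise(mean_gy = mean(.data$value), .groups = "drop")

  ## ---- environment stages -----------------------------------------------
  say("climate regression and mega-environment clustering")
  res$climate_factors <- run("envclim",
    climate_regression(climate, env_mean_gy, quiet = TRUE))
  res$assignment <- run("envclim",
    cluster_environments(climate, res$climate_factors, k = config$k))
  res$correlations <- run("phenostats",
    trait_gy_correlations(res$blues, res$assignment))

  ## ---- stability and water productivity ---------------------------------
  say("AMMI / AWAI and selection surface")
  res$ammi <- run("ammi_stability",
    fit_ammi(res$blues, trait = "GY", alpha = config$alpha_ammi))
  res$awai <- run("ammi_stability", awai(res$ammi))
  res$gy_ratio <- run("phenostats", ratio_to_max(res$blues, quiet = TRUE))
  res$selection <- run("ammi_stability",
    selection_surface(res$gy_ratio, res$awai))

  say("water-productivity classification")
  res$group_slopes <- run("waterprod",
    group_slopes(env_mean_gy, res$assignment))
  res$wp_classes <- run("waterprod",
    classify_genotypes(res$blues, res$assignment,
                       slopes = config$frozen_slopes,
                       alpha = config$alpha_class))

  ## ---- association stages ----------------------------------------------
  say("marker curation, structure, kinship, LD")
  res$panel <- run("assoc", curate_markers(panel, quiet = TRUE))
  res$structure <- run("assoc", structure_and_kinship(res$panel))
  res$ld <- run("assoc", {
    crit <- config$ld_critical_r2 %||%
      critical_r2_for_n(nrow(res$panel$dosage))
    ld_decay(res$panel, critical_r2 = crit)
  })
  merge_dist <- config$merge_distance %||% (2 * res$ld$ld_distance)
  if (!is.finite(merge_dist))
    merge_dist <- 2 * max(res$panel$map$position) / 10

  say("GWAS per context")
  dth <- res$blues |>
    filter(.data$trait == "DTH") |>
    group_by(.data$genotype_id) |>
    summarise(DTH = mean(.data$value), .groups = "drop")
  contexts <- gwas_contexts(res$blues, res$assignment)
  res$scans <- run("assoc", purrr::imap(contexts, function(ph, ctx) {
    gwas(res$panel, ph,
         covariates = if (nrow(dth) > 0) dth else NULL,
         model = config$gwas_model, Q = res$structure$Q,
         K = res$structure$K, trait = "GY", context = ctx)
  }))
  res$mtas <- run("assoc", bind_rows(lapply(res$scans, call_mtas,
                                            lod_cutoff = config$lod_cutoff,
                                            r2_cutoff = config$r2_cutoff)))
  say(nrow(res$mtas), " MTA(s); assembling QTL")
  res$qtl <- run("assoc", assemble_qtl(res$mtas, merge_dist,
                                       prefix = config$qtl_prefix))

  ## ---- haplotypes and validation ----------------------------------------
  rep_markers <- res$qtl$representative_marker
  if (length(rep_markers) > 0) {
    say("haplotypes over ", length(rep_markers), " representative marker(s)")
    fav <- run("haplokasp", favorable_alleles(res$mtas, rep_markers))
    res$favorable <- fav
    gy_combined <- combined_gy(res$blues, res$assignment,
                               "moisture_stressed")
    res$haplotypes <- run("haplokasp",
      build_haplotypes(res$panel, rep_markers, fav, quiet = TRUE))
    res$haplotype_test <- run("haplokasp", {
      ht <- try(haplotype_effect_test(res$haplotypes, gy_combined,
                                      alpha = config$alpha_lsd),
                silent = TRUE)
      if (inherits(ht, "try-error")) NULL else ht
    })
    res$kasp <- run("haplokasp", {
      calls <- carrier_calls(res$panel, rep_markers, fav)
      n_ext <- min(config$n_extreme,
                   floor(dplyr::n_distinct(gy_combined$genotype_id) / 2))
      kasp_validate(calls, gy_combined, n_extreme = n_ext,
                    combine = if (length(rep_markers) > 1) rep_markers)
    })
  } else say("no QTL found; haplotype and KASP stages skipped")

  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config)
  res
}

# per-context GY phenotypes: each environment + combined group means
gwas_contexts <- function(blues, assignment) {
  gy <- filter(blues, .data$trait == "GY")
  per_env <- split(gy[c("genotype_id", "value")], gy$environment_id)
  grp <- gy |>
    inner_join(assignment[c("environment_id", "group")],
               by = "environment_id") |>
    group_by(.data$group, .data$genotype_id) |>
    summarise(value = mean(.data$value), .groups = "drop")
  comb <- split(grp[c("genotype_id", "value")], grp$group)
  names(comb) <- paste0("combined_", names(comb))
  c(per_env, comb)
}

# mean GY BLUE within one mega-environment group
combined_gy <- function(blues, assignment, group) {
  blues |>
    filter(.data$trait == "GY") |>
    inner_join(assignment[c("environment_id", "group")],
               by = "environment_id") |>
    filter(.data$group == !!group) |>
    group_by(.data$genotype_id) |>
    summarise(value = mean(.data$value), .groups = "drop")
}

# favorable allele per marker from the MTA effect sign in its best context
favorable_alleles <- function(mtas, markers) {
  fav <- vapply(markers, function(m) {
    rows <- mtas[mtas$marker_id == m, ]
    if (nrow(rows) == 0) return("B")
    best <- rows[which.max(rows$lod), ]
    if (best$effect >= 0) "B" else "A"
  }, character(1))
  setNames(fav, markers)
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  readr::write_csv(res$blues, out("blues.csv"))
  jsonlite::write_json(
    list(trait = res$varpart$trait,
         ss = as.list(res$varpart$ss),
         shares = as.list(res$varpart$shares),
         H2_by_env = as.list(res$varpart$H2_by_env)),
    out("variance_partition.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(res$climate_factors, out("climate_factors.csv"))
  readr::write_csv(res$assignment, out("mega_environments.csv"))
  readr::write_csv(res$correlations, out("trait_gy_correlations.csv"))
  readr::write_csv(tidy(res$ammi), out("ammi_ipcs.csv"))
  stab <- res$awai |>
    left_join(res$gy_ratio, by = "genotype_id") |>
    left_join(res$selection[c("genotype_id", "selected")], by = "genotype_id")
  readr::write_csv(stab, out("stability.csv"))
  readr::write_csv(res$group_slopes, out("group_slopes.csv"))
  readr::write_csv(res$wp_classes, out("wp_classes.csv"))
  cls_freq <- res$wp_classes |>
    filter(!is.na(.data$wp_class)) |>
    dplyr::count(.data$wp_class, .data$class_name)
  jsonlite::write_json(cls_freq, out("wp_class_frequencies.json"),
                       digits = NA)
  readr::write_csv(res$mtas, out("mtas.csv"))
  readr::write_csv(select(res$qtl, -"member_mtas"), out("qtl.csv"))
  if (!is.null(res$haplotypes))
    readr::write_csv(res$haplotypes, out("haplotypes.csv"))
  if (!is.null(res$kasp)) readr::write_csv(res$kasp, out("kasp_metrics.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("durumwp")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    design = config$design,
    k = config$k,
    alphas = list(classification = config$alpha_class,
                  ammi = config$alpha_ammi, lsd = config$alpha_lsd),
    thresholds = list(lod = config$lod_cutoff, r2 = config$r2_cutoff),
    merge_distance = config$merge_distance,
    frozen_slopes = config$frozen_slopes,
    inputs = list(
      plots = if (is.character(config$plots)) config$plots else "in-memory",
      climate = if (is.character(config$climate)) config$climate
                else "in-memory",
      genotypes = if (is.character(config$genotypes)) config$genotypes
                  else "in-memory")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML carries the same fields as [wp_pipeline_config()]; file paths
#' are resolved relative to the YAML's directory.
#'
#' @param path YAML file path.
#' @return a `wp_pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (nm in c("plots", "climate", "genotypes")) {
    if (!is.null(y[[nm]]) && !grepl("^/", y[[nm]]))
      y[[nm]] <- file.path(base, y[[nm]])
  }
  if (!is.null(y$frozen_slopes)) y$frozen_slopes <- unlist(y$frozen_slopes)
  do.call(wp_pipeline_config, y)
}
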