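#' Water productivity per genotype and moisture group
#'
#' Water productivity is grain yield divided by total in-season moisture
#' (kg/ha per mm). Computes WP per genotype x environment from GY BLUEs and
#' averages it over the stressed, non-stressed and all environments.
#' Environments with missing or non-positive moisture are excluded with a
#' log message.
#'
#' @param blues BLUE tibble with GY rows (`genotype_id`, `environment_id`,
#'   `trait`, `value`).
#' @param environments tibble `environment_id`, `total_moisture` and
#'   optionally `group` (from [cluster_environments()] or the simulator).
#' @param quiet suppress log messages.
#' @return tibble `genotype_id`, `wp_overall`, `wp_stressed`,
#'   `wp_nonstressed` (group columns NA when no group information is given).
#' @export
water_productivity <- function(blues, environments, quiet = FALSE) {
  env <- as_tibble(environments)
  bad <- env$environment_id[is.na(env$total_moisture) | env$total_moisture <= 0]
  if (length(bad) > 0) {
    if (!quiet)
      wp_note("water_productivity: excluded environment(s) without valid ",
              "moisture: ", paste(bad, collapse = ", "))
    env <- env[!env$environment_id %in% bad, ]
  }
  d <- as_tibble(blues) |>
    filter(.data$trait == "GY", !is.na(.data$value)) |>
    inner_join(env, by = "environment_id") |>
    mutate(wp = .data$value / .data$total_moisture)
  has_grp <- "group" %in% names(d)
  d |>
    group_by(.data$genotype_id) |>
    summarise(
      wp_overall = mean(.data$wp),
      wp_stressed = if (has_grp)
        mean(.data$wp[.data$group == "moisture_stressed"]) else NA_real_,
      wp_nonstressed = if (has_grp)
        mean(.data$wp[.data$group == "non_moisture_stressed"]) else NA_real_,
      .groups = "drop"
    )
}

#' Average moisture-response slope of each mega-environment group
#'
#' Ordinary least-squares slope of environment-mean grain yield on
#' environment total moisture, fitted separately within the stressed and
#' non-stressed groups. These group slopes are the reference trends against
#' which per-genotype slopes are classified.
#'
#' @param env_mean_gy tibble `environment_id`, `mean_gy`.
#' @param environments tibble `environment_id`, `total_moisture`, `group`.
#' @return tibble `group`, `n_env`, `slope`, `r2`.
#' @export
group_slopes <- function(env_mean_gy, environments) {
  env_mean_gy <- as_tibble(env_mean_gy)
  if (!"mean_gy" %in% names(env_mean_gy)) {
    num <- setdiff(names(env_mean_gy), "environment_id")
    env_mean_gy <- rename(env_mean_gy, mean_gy = !!num[1])
  }
  d <- env_mean_gy |>
    inner_join(as_tibble(environments), by = "environment_id")
  res <- d |>
    group_by(.data$group) |>
    summarise(n_env = dplyr::n(),
              slope = {
                if (dplyr::n() < 3)
                  wp_stop("group_slopes: group '", .data$group[1],
                          "' has fewer than 3 environments")
                unname(coef(lm(mean_gy ~ total_moisture,
                               data = dplyr::pick(dplyr::everything())))[2])
              },
              r2 = summary(lm(mean_gy ~ total_moisture,
                              data = dplyr::pick(dplyr::everything())))$r.squared,
              .groups = "drop")
  res
}

#' Assign genotypes to water productivity classes
#'
#' For every genotype, fits the OLS regression of its per-environment GY
#' BLUE on environment total moisture within each moisture group, giving the
#' actual slopes `b_i` (kg/ha/mm). Genotypes whose GY-on-moisture regression
#' is not significant (p >= `alpha`) form class 5 ("No water response"); the
#' rest fall in the four quadrants around the group slopes:
#'
#' \describe{
#'   \item{1 Stable water response}{b_stressed <= group, b_nonstressed <= group}
#'   \item{2 Responsive to low moisture}{b_stressed > group, b_nonstressed <= group}
#'   \item{3 Responsive to high moisture}{b_stressed <= group, b_nonstressed > group}
#'   \item{4 Highly water responsive}{both > group}
#' }
#'
#' Boundary ties (b_i exactly equal to the group slope) deterministically go
#' to the "<=" side. Genotypes observed in fewer than 3 environments in a
#' group are reported with `wp_class = NA` and a reason.
#'
#' The significance gate has two flavours. `gate = "overall"` (default)
#' tests the single regression of the genotype's GY on moisture across all
#' environments — one r-squared per genotype, matching the one-column
#' presentation of the class table and the fact that group trends share most
#' of their signal. `gate = "per_group"` instead requires both group
#' regressions to be individually significant, a stricter reading that
#' reclassifies many genotypes as unresponsive when within-group moisture
#' spans are short.
#'
#' @param blues GY BLUE tibble.
#' @param environments tibble `environment_id`, `total_moisture`, `group`.
#' @param slopes optional reference slopes: a `group_slopes()` result or a
#'   named vector `c(stressed = , nonstressed = )` (e.g. the frozen values
#'   5.08 / 4.85). Default `NULL` recomputes them from the data.
#' @param alpha regression significance gate (default 0.01).
#' @param gate `"overall"` (single regression across all environments) or
#'   `"per_group"` (both group regressions must be significant).
#' @return tibble with one row per genotype: WP means, `b_stressed`,
#'   `b_nonstressed`, `r2_stressed`, `r2_nonstressed`, `p_stressed`,
#'   `p_nonstressed`, `r2_overall`, `p_overall`, `wp_class`, `class_name`,
#'   `reason`.
#' @export
classify_genotypes <- function(blues, environments, slopes = NULL,
                               alpha = 0.01,
                               gate = c("overall", "per_group")) {
  gate <- match.arg(gate)
  env <- as_tibble(environments)
  stopifnot(all(c("group", "total_moisture") %in% names(env)))
  d <- as_tibble(blues) |>
    filter(.data$trait == "GY", !is.na(.data$value)) |>
    inner_join(env[c("environment_id", "group", "total_moisture")],
               by = "environment_id")

  ref <- resolve_group_slopes(slopes, d)

  reg_stats <- function(dd) {
    if (nrow(dd) < 3 || sd(dd$total_moisture) == 0) {
      return(tibble(b = NA_real_, r2 = NA_real_, p = NA_real_, n = nrow(dd)))
    }
    fit <- lm(value ~ total_moisture, data = dd)
    sm <- summary(fit)
    tibble(b = unname(coef(fit)[2]), r2 = sm$r.squared,
           p = sm$coefficients[2, 4], n = nrow(dd))
  }

  res <- d |>
    tidyr::nest(data = -"genotype_id") |>
    mutate(
      st = purrr::map(.data$data, ~ reg_stats(
        .x[.x$group == "moisture_stressed", ])),
      ns = purrr::map(.data$data, ~ reg_stats(
        .x[.x$group == "non_moisture_stressed", ])),
      ov = purrr::map(.data$data, reg_stats)
    ) |>
    select(-"data") |>
    tidyr::unnest_wider("st", names_sep = "_") |>
    tidyr::unnest_wider("ns", names_sep = "_") |>
    tidyr::unnest_wider("ov", names_sep = "_")

  cls <- purrr::pmap(res, function(genotype_id, st_b, st_r2, st_p, st_n,
                                   ns_b, ns_r2, ns_p, ns_n,
                                   ov_b, ov_r2, ov_p, ov_n) {
    if (is.na(st_b) || is.na(ns_b)) {
      return(list(wp_class = NA_integer_,
                  reason = sprintf("fewer than 3 environments in a group (%d stressed, %d non-stressed)",
                                   st_n, ns_n)))
    }
    unresponsive <- if (gate == "overall") is.na(ov_p) || ov_p >= alpha
                    else st_p >= alpha || ns_p >= alpha
    if (unresponsive) return(list(wp_class = 5L, reason = NA_character_))
    # ties at the group slope go to the "<=" side; the small tolerance keeps
    # that deterministic under floating point
    tol_s <- 1e-8 * max(1, abs(ref[["stressed"]]))
    tol_n <- 1e-8 * max(1, abs(ref[["nonstressed"]]))
    hi_s <- st_b > ref[["stressed"]] + tol_s
    hi_n <- ns_b > ref[["nonstressed"]] + tol_n
    list(wp_class = if (hi_s && hi_n) 4L else if (hi_s) 2L
         else if (hi_n) 3L else 1L,
         reason = NA_character_)
  })
  class_names <- c("Stable water response", "Responsive to low moisture",
                   "Responsive to high moisture", "Highly water responsive",
                   "No water response")
  wp <- water_productivity(blues, env, quiet = TRUE)
  res |>
    mutate(wp_class = purrr::map_int(cls, "wp_class"),
           reason = purrr::map_chr(cls, "reason"),
           class_name = ifelse(is.na(.data$wp_class), NA_character_,
                               class_names[.data$wp_class])) |>
    rename(b_stressed = "st_b", r2_stressed = "st_r2", p_stressed = "st_p",
           n_stressed = "st_n", b_nonstressed = "ns_b",
           r2_nonstressed = "ns_r2", p_nonstressed = "ns_p",
           n_nonstressed = "ns_n", r2_overall = "ov_r2",
           p_overall = "ov_p") |>
    left_join(wp, by = "genotype_id") |>
    select("genotype_id", "wp_overall", "wp_stressed", "wp_nonstressed",
           "b_stressed", "b_nonstressed", "r2_stressed", "r2_nonstressed",
           "p_stressed", "p_nonstressed", "r2_overall", "p_overall",
           "wp_class", "class_name", "reason")
}

resolve_group_slopes <- function(slopes, d) {
  if (is.null(slopes)) {
    em <- d |>
      group_by(.data$environment_id, .data$group, .data$total_moisture) |>
      summarise(mean_gy = mean(.data$value), .groups = "drop")
    gs <- group_slopes(em[c("environment_id", "mean_gy")],
                       em[c("environment_id", "group", "total_moisture")])
    ref <- setNames(gs$slope, ifelse(gs$group == "moisture_stressed",
                                     "stressed", "nonstressed"))
  } else if (is.data.frame(slopes)) {
    ref <- setNames(slopes$slope, ifelse(slopes$group == "moisture_stressed",
                                         "stressed", "nonstressed"))
  } else {
    ref <- slopes
  }
  if (!all(c("stressed", "nonstressed") %in% names(ref)))
    wp_stop("reference slopes must provide 'stressed' and 'nonstressed'")
  ref
}
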