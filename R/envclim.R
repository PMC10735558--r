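#' Regress environment-mean grain yield on climate factors
#'
#' For every (growth stage, climate variable) pair, fits a simple linear
#' regression of environment-mean GY on the factor across environments and
#' reports slope, r-squared and a two-sided p-value. Factors with p below
#' `alpha` are flagged significant; constant factors are skipped with a log
#' message.
#'
#' @param climate long climate tibble: `environment_id`, `stage`, `variable`,
#'   `value` (one row per environment x stage x variable).
#' @param env_mean_gy tibble `environment_id`, `mean_gy` (environment means).
#' @param alpha significance level (default 0.05).
#' @param quiet suppress log messages.
#' @return tibble `stage`, `variable`, `n`, `slope`, `r2`, `p_value`,
#'   `significant`.
#' @export
climate_regression <- function(climate, env_mean_gy, alpha = 0.05,
                               quiet = FALSE) {
  climate <- as_tibble(climate)
  env_mean_gy <- as_tibble(env_mean_gy)
  if (!"mean_gy" %in% names(env_mean_gy)) {
    num <- setdiff(names(env_mean_gy), "environment_id")
    env_mean_gy <- rename(env_mean_gy, mean_gy = !!num[1])
  }
  n_env <- dplyr::n_distinct(env_mean_gy$environment_id)
  if (n_env < 3)
    wp_stop("climate_regression needs at least 3 environments (got ",
            n_env, ")")
  d <- climate |>
    inner_join(env_mean_gy, by = "environment_id")
  fit_one <- function(dd) {
    if (sd(dd$value) == 0) {
      return(tibble(n = nrow(dd), constant = TRUE, slope = NA_real_,
                    r2 = NA_real_, p_value = NA_real_))
    }
    # a factor may fit exactly in degenerate inputs; only r2/p are kept
    sm <- suppressWarnings(summary(lm(mean_gy ~ value, data = dd)))
    tibble(n = nrow(dd), constant = FALSE,
           slope = unname(sm$coefficients[2, 1]),
           r2 = sm$r.squared,
           p_value = sm$coefficients[2, 4])
  }
  res <- d |>
    tidyr::nest(data = c(-"stage", -"variable")) |>
    mutate(fit = purrr::map(.data$data, fit_one)) |>
    select(-"data") |>
    tidyr::unnest("fit") |>
    arrange(.data$stage, .data$variable)
  skipped <- res[res$constant, ]
  if (nrow(skipped) > 0 && !quiet)
    wp_note("climate_regression: skipped constant factor(s): ",
            paste(paste(skipped$stage, skipped$variable), collapse = ", "))
  res |>
    mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha) |>
    select(-"constant")
}

#' Cluster environments into mega-environments
#'
#' Standardizes the significant climate factors, projects environments onto
#' the principal components retaining at least `var_retained` of the
#' variance, and applies Ward-linkage hierarchical clustering cut at `k`
#' groups. The group with the lower mean total moisture is labelled
#' `moisture_stressed`; with `k = 1` all environments form one group
#' labelled by their overall mean moisture against `moisture_pivot`.
#'
#' @param climate long climate tibble (as in [climate_regression()]); total
#'   moisture per environment is taken from a `total_moisture` column if
#'   present, otherwise as the sum of the in-season stage moistures.
#' @param factors optional result of [climate_regression()]; only rows with
#'   `significant == TRUE` are used. `NULL` uses every factor.
#' @param k number of mega-environments (default 2).
#' @param var_retained minimum cumulative PC variance retained (default 0.8).
#' @param moisture_pivot mm pivot used to label the single group when k = 1.
#' @return tibble `environment_id`, `group`, `total_moisture`; PC scores and
#'   the dendrogram are attached as attributes `scores` and `hclust`.
#' @export
cluster_environments <- function(climate, factors = NULL, k = 2,
                                 var_retained = 0.8, moisture_pivot = 400) {
  climate <- as_tibble(climate)
  total_m <- env_total_moisture(climate)
  n_env <- nrow(total_m)
  if (k > n_env) wp_stop("k (", k, ") exceeds number of environments (", n_env, ")")

  use <- climate
  if (!is.null(factors)) {
    sig <- dplyr::filter(as_tibble(factors), .data$significant)
    if (nrow(sig) == 0) wp_stop("no significant climate factors to cluster on")
    use <- climate |>
      inner_join(sig[c("stage", "variable")], by = c("stage", "variable"))
  }
  wide <- use |>
    mutate(factor_id = paste(.data$stage, .data$variable, sep = ".")) |>
    select("environment_id", "factor_id", "value") |>
    tidyr::pivot_wider(names_from = "factor_id", values_from = "value")
  X <- as.matrix(wide[-1])
  rownames(X) <- wide$environment_id
  X <- X[, apply(X, 2, sd) > 0, drop = FALSE]

  if (k == 1) {
    grp <- if (mean(total_m$total_moisture) < moisture_pivot)
      "moisture_stressed" else "non_moisture_stressed"
    out <- tibble(environment_id = total_m$environment_id, group = grp) |>
      left_join(total_m, by = "environment_id")
    return(out)
  }

  pc <- prcomp(X, scale. = TRUE)
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_pc <- max(1L, min(which(cumvar >= var_retained)))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  hc <- hclust(dist(scores), method = "ward.D2")
  cl <- cutree(hc, k = k)

  m_by_cl <- tapply(total_m$total_moisture[match(names(cl),
                                                 total_m$environment_id)],
                    cl, mean)
  labels <- rep("non_moisture_stressed", k)
  labels[which.min(m_by_cl)] <- "moisture_stressed"
  out <- tibble(environment_id = names(cl),
                group = labels[cl]) |>
    left_join(total_m, by = "environment_id")
  attr(out, "scores") <- scores
  attr(out, "hclust") <- hc
  out
}

env_total_moisture <- function(climate) {
  if ("total_moisture" %in% names(climate)) {
    distinct(climate, .data$environment_id, .data$total_moisture)
  } else {
    climate |>
      filter(.data$variable == "moisture", .data$stage != "pre_sowing") |>
      group_by(.data$environment_id) |>
      summarise(total_moisture = sum(.data$value), .groups = "drop")
  }
}
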