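#' Partition genotypes into haplotype groups at representative markers
#'
#' A haplotype here is the +/- pattern of favorable alleles at the
#' representative markers of selected QTL. A genotype is "+" at a marker
#' when homozygous for the favorable allele and "-" when homozygous for the
#' other; genotypes heterozygous or missing at any representative marker are
#' excluded (and logged). Haplotypes are numbered by descending count of
#' favorable alleles, then lexicographic pattern.
#'
#' @param panel `wp_geno` panel.
#' @param markers character vector of representative marker ids.
#' @param favorable named vector over `markers`: `"B"` if the dosage-counted
#'   (alternate) allele is favorable, `"A"` if the reference allele is.
#'   Inherited from the MTA effect sign in the discovery context.
#' @param min_size groups smaller than this are flagged (default 3).
#' @param quiet suppress log messages.
#' @return tibble `genotype_id`, `pattern` (e.g. `"+-+"`), `haplotype_id`,
#'   `n_positive_alleles`; excluded genotypes are reported in attribute
#'   `excluded`.
#' @export
build_haplotypes <- function(panel, markers, favorable, min_size = 3,
                             quiet = FALSE) {
  stopifnot(inherits(panel, "wp_geno"))
  miss <- setdiff(markers, colnames(panel$dosage))
  if (length(miss) > 0)
    wp_stop("markers not in panel: ", paste(miss, collapse = ", "))
  d <- panel$dosage[, markers, drop = FALSE]
  fav <- favorable[markers]
  # favorable-allele dosage: flip when the reference allele is favorable
  for (j in seq_along(markers)) if (fav[j] == "A") d[, j] <- 2 - d[, j]
  complete <- rowSums(is.na(d)) == 0 & apply(d != 1, 1, all)
  excluded <- rownames(d)[!complete]
  if (length(excluded) > 0 && !quiet)
    wp_note("build_haplotypes: excluded ", length(excluded),
            " genotype(s) with heterozygous or missing calls")
  if (!any(complete))
    wp_stop("no genotype with complete homozygous calls at the ",
            "representative markers")
  d <- d[complete, , drop = FALSE]
  pattern <- unname(apply(d, 1, function(x) paste(ifelse(x == 2, "+", "-"),
                                                  collapse = "")))
  n_pos <- unname(rowSums(d == 2))
  pat_levels <- unique(tibble(pattern = pattern, n_pos = n_pos)) |>
    arrange(dplyr::desc(.data$n_pos), .data$pattern)
  hap_ids <- setNames(sprintf("Hap%d", seq_len(nrow(pat_levels))),
                      pat_levels$pattern)
  out <- tibble(genotype_id = rownames(d), pattern = pattern,
                haplotype_id = unname(hap_ids[pattern]),
                n_positive_alleles = as.integer(n_pos))
  sizes <- table(out$haplotype_id)
  small <- names(sizes)[sizes < min_size]
  if (length(small) > 0 && !quiet)
    wp_note("build_haplotypes: group(s) below min_size: ",
            paste(small, collapse = ", "))
  attr(out, "excluded") <- excluded
  out
}

#' Test haplotype group effects with LSD letters
#'
#' One-way fixed-effects fit of a phenotype on haplotype group, followed by
#' pairwise least-significant-difference comparisons:
#' `LSD = t(1 - alpha/2, df_error) * sqrt(MSE * (1/n_a + 1/n_b))` (the
#' unequal-n form). A compact letter display is assigned so that groups
#' sharing no letter differ at `alpha`.
#'
#' @param haplotypes tibble from [build_haplotypes()].
#' @param phenotype tibble `genotype_id`, `value` (e.g. mean GY or WP).
#' @param alpha significance level (default 0.05).
#' @param min_members groups with fewer members are dropped from the test.
#' @return object of class `wp_lsd`: tibble `haplotype_id`, `pattern`, `n`,
#'   `mean`, `se`, `lsd_letter`, with attributes `mse`, `df_error` and the
#'   pairwise table `pairs`.
#' @export
haplotype_effect_test <- function(haplotypes, phenotype, alpha = 0.05,
                                  min_members = 2) {
  d <- as_tibble(haplotypes) |>
    inner_join(as_tibble(phenotype), by = "genotype_id") |>
    filter(!is.na(.data$value))
  sizes <- table(d$haplotype_id)
  keep <- names(sizes)[sizes >= min_members]
  if (length(keep) < 2)
    wp_stop("haplotype_effect_test needs >= 2 groups with >= ",
            min_members, " members")
  d <- d[d$haplotype_id %in% keep, ]
  fit <- lm(value ~ haplotype_id, data = d)
  df_err <- fit$df.residual
  if (df_err <= 0) wp_stop("zero error degrees of freedom")
  mse <- sum(resid(fit)^2) / df_err

  grp <- d |>
    group_by(.data$haplotype_id) |>
    summarise(pattern = first(.data$pattern), n = dplyr::n(),
              mean = mean(.data$value), .groups = "drop") |>
    arrange(dplyr::desc(.data$mean)) |>
    mutate(se = sqrt(mse / .data$n))

  k <- nrow(grp)
  tcrit <- qt(1 - alpha / 2, df_err)
  diff_mat <- matrix(FALSE, k, k, dimnames = list(grp$haplotype_id,
                                                  grp$haplotype_id))
  pairs <- list()
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    lsd_ab <- tcrit * sqrt(mse * (1 / grp$n[a] + 1 / grp$n[b]))
    delta <- abs(grp$mean[a] - grp$mean[b])
    diff_mat[a, b] <- diff_mat[b, a] <- delta > lsd_ab
    pairs[[length(pairs) + 1]] <- tibble(
      group_a = grp$haplotype_id[a], group_b = grp$haplotype_id[b],
      difference = grp$mean[a] - grp$mean[b], lsd = lsd_ab,
      significant = delta > lsd_ab)
  }
  grp$lsd_letter <- compact_letters(diff_mat, grp$mean)
  out <- grp
  attr(out, "mse") <- mse
  attr(out, "df_error") <- df_err
  attr(out, "alpha") <- alpha
  attr(out, "pairs") <- bind_rows(pairs)
  class(out) <- c("wp_lsd", class(out))
  out
}

#' Least significant difference between two group means
#'
#' `LSD = t(1 - alpha/2, df) * sqrt(MSE * (1/n_a + 1/n_b))`.
#'
#' @param mse pooled error mean square.
#' @param n_a,n_b group sizes.
#' @param df error degrees of freedom.
#' @param alpha significance level (default 0.05).
#' @return numeric LSD.
#' @export
lsd_value <- function(mse, n_a, n_b, df, alpha = 0.05) {
  qt(1 - alpha / 2, df) * sqrt(mse * (1 / n_a + 1 / n_b))
}

#' Per-environment correlation of favorable-allele dosage with grain yield
#'
#' For each marker and environment, the Pearson correlation between the
#' favorable-allele dosage and the GY BLUE, plus per mega-environment-group
#' averages; significance is judged against the panel's critical r (the
#' square root of `critical_r2`). Monomorphic markers in the tested subset
#' yield `NA` with code `"-"`.
#'
#' @param panel `wp_geno` panel.
#' @param blues GY BLUE tibble.
#' @param markers marker ids to profile.
#' @param favorable named vector as in [build_haplotypes()].
#' @param critical_r2 significance threshold on r-squared (default 0.024).
#' @param assignment optional `environment_id`/`group` tibble for group
#'   averages.
#' @return tibble `marker_id`, `environment_id`, `n`, `r`, `significant`.
#' @export
allele_gy_profile <- function(panel, blues, markers, favorable,
                              critical_r2 = 0.024, assignment = NULL) {
  stopifnot(inherits(panel, "wp_geno"))
  d <- panel$dosage[, markers, drop = FALSE]
  fav <- favorable[markers]
  for (j in seq_along(markers)) if (fav[j] == "A") d[, j] <- 2 - d[, j]
  gy <- as_tibble(blues) |>
    filter(.data$trait == "GY", !is.na(.data$value))
  if (!is.null(assignment)) {
    grp_means <- gy |>
      inner_join(as_tibble(assignment)[c("environment_id", "group")],
                 by = "environment_id") |>
      group_by(genotype_id = .data$genotype_id,
               environment_id = paste0("average_", .data$group)) |>
      summarise(value = mean(.data$value), .groups = "drop")
    gy <- bind_rows(gy[c("genotype_id", "environment_id", "value")],
                    grp_means)
  }
  rcrit <- sqrt(critical_r2)
  combos <- tidyr::expand_grid(marker_id = markers,
                               environment_id = unique(gy$environment_id))
  purrr::pmap(combos, function(marker_id, environment_id) {
    sub <- gy[gy$environment_id == environment_id, ]
    x <- d[match(sub$genotype_id, rownames(d)), marker_id]
    ok <- !is.na(x) & !is.na(sub$value)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(sub$value[ok]) == 0) {
      return(tibble(marker_id = marker_id, environment_id = environment_id,
                    n = sum(ok), r = NA_real_, significant = NA))
    }
    r <- cor(x[ok], sub$value[ok])
    tibble(marker_id = marker_id, environment_id = environment_id,
           n = sum(ok), r = r, significant = abs(r) > rcrit)
  }) |> bind_rows()
}

#' KASP-style marker validation over phenotypic extremes
#'
#' Ranks genotypes by grain yield; the top `n_extreme` are the positive
#' cases and the bottom `n_extreme` the negative cases (ties at the rank
#' boundary broken deterministically by genotype id). For each marker,
#' carrying the favorable allele among the positives is a true positive and
#' not carrying it among the negatives a true negative; then
#' `accuracy = (TP + TN) / (n_pos + n_neg)`, `sensitivity = TP / n_pos`,
#' `specificity = TN / n_neg`. With `literal_denominators = TRUE`,
#' sensitivity and specificity are instead divided by all extremes
#' (`n_pos + n_neg`). `r2_vs_gy` is the r-squared of GY on the carrier call
#' over the full panel. When `combine` names several markers, a combined
#' AND-rule row (carrier at all of them) is appended.
#'
#' @param calls long tibble `genotype_id`, `marker_id`, `carrier` (logical:
#'   carries the favorable allele). See [carrier_calls()].
#' @param gy tibble `genotype_id`, `value` (grain yield).
#' @param n_extreme extremes size per tail (default 20).
#' @param combine optional character vector of marker ids for the AND-rule.
#' @param literal_denominators use all extremes as the denominator of
#'   sensitivity and specificity (default `FALSE`).
#' @return tibble `marker_id`, `n_top`, `n_worst`, `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`, `r2_vs_gy`.
#' @export
kasp_validate <- function(calls, gy, n_extreme = 20, combine = NULL,
                          literal_denominators = FALSE) {
  calls <- as_tibble(calls); gy <- as_tibble(gy)
  gy <- gy[!is.na(gy$value), ]
  if (nrow(gy) < 2 * n_extreme)
    wp_stop("kasp_validate needs at least 2 * n_extreme genotypes with GY")
  ord <- order(-gy$value, gy$genotype_id)
  top <- gy$genotype_id[head(ord, n_extreme)]
  worst <- gy$genotype_id[tail(ord, n_extreme)]

  if (!is.null(combine)) {
    comb <- calls |>
      filter(.data$marker_id %in% combine) |>
      group_by(.data$genotype_id) |>
      summarise(carrier = all(.data$carrier) & dplyr::n() == length(combine),
                .groups = "drop") |>
      mutate(marker_id = paste(combine, collapse = "+"))
    calls <- bind_rows(calls, comb)
  }

  one_marker <- function(cc) {
    cc <- cc[!is.na(cc$carrier), ]
    pos <- cc[cc$genotype_id %in% top, ]
    neg <- cc[cc$genotype_id %in% worst, ]
    tp <- sum(pos$carrier); fn <- sum(!pos$carrier)
    tn <- sum(!neg$carrier); fp <- sum(neg$carrier)
    n_pos <- nrow(pos); n_neg <- nrow(neg)
    den_s <- if (literal_denominators) n_pos + n_neg else n_pos
    den_p <- if (literal_denominators) n_pos + n_neg else n_neg
    full <- inner_join(cc, gy, by = "genotype_id")
    r2 <- if (dplyr::n_distinct(full$carrier) > 1)
      summary(lm(value ~ carrier, data = full))$r.squared else NA_real_
    tibble(n_top = n_pos, n_worst = n_neg, tp = tp, fp = fp, tn = tn,
           fn = fn,
           accuracy = (tp + tn) / (n_pos + n_neg),
           sensitivity = tp / den_s,
           specificity = tn / den_p,
           r2_vs_gy = r2)
  }
  calls |>
    group_by(.data$marker_id) |>
    dplyr::group_modify(~ one_marker(.x)) |>
    ungroup()
}

#' Carrier calls for favorable alleles
#'
#' Converts a dosage panel into the long carrier-call format consumed by
#' [kasp_validate()]: a genotype carries the favorable allele at a marker
#' when its favorable-allele dosage is at least `min_dosage`.
#'
#' @param panel `wp_geno` panel.
#' @param markers marker ids.
#' @param favorable named `"A"`/`"B"` vector as in [build_haplotypes()].
#' @param min_dosage dosage threshold to call a carrier (default 2,
#'   homozygous favorable, matching inbred-line material).
#' @return tibble `genotype_id`, `marker_id`, `carrier`.
#' @export
carrier_calls <- function(panel, markers, favorable, min_dosage = 2) {
  d <- panel$dosage[, markers, drop = FALSE]
  fav <- favorable[markers]
  for (j in seq_along(markers)) if (fav[j] == "A") d[, j] <- 2 - d[, j]
  tibble(genotype_id = rep(rownames(d), times = length(markers)),
         marker_id = rep(markers, each = nrow(d)),
         carrier = as.vector(d >= min_dosage))
}
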