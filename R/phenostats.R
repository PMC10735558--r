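#' Derive grain number components from plot records
#'
#' Adds the two derived yield components to a plot-level table:
#' grains per square metre, `Grm2 = harvested_weight / (plot_area * TKW/1000)`,
#' and grains per spike, `GpS = Grm2 / SPK`. Harvested weight and 1000-kernel
#' weight are in grams, plot area in square metres. A measured `GpS` column,
#' if present, is never overwritten; rows with missing inputs keep the
#' component absent (NA) and are counted in a log message rather than
#' raising an error. `SPK = 0` leaves `GpS` absent.
#'
#' @param records plot-level data frame with columns `harvested_weight`,
#'   `plot_area`, `TKW` (for `Grm2`) and `SPK` (for `GpS`).
#' @param quiet suppress the log message about skipped rows.
#' @return the input as a tibble with `Grm2` and `GpS` columns added/filled.
#' @export
derive_components <- function(records, quiet = FALSE) {
  records <- as_tibble(records)
  has <- function(col) col %in% names(records)
  if (!has("Grm2")) records$Grm2 <- NA_real_
  if (!has("GpS")) records$GpS <- NA_real_

  if (all(c("harvested_weight", "plot_area", "TKW") %in% names(records))) {
    ok <- is.na(records$Grm2) &
      !is.na(records$harvested_weight) & !is.na(records$plot_area) &
      !is.na(records$TKW) & records$plot_area > 0 & records$TKW > 0
    records$Grm2[ok] <- records$harvested_weight[ok] /
      (records$plot_area[ok] * records$TKW[ok] / 1000)
    n_skip <- sum(is.na(records$Grm2))
    if (n_skip > 0 && !quiet)
      wp_note("derive_components: Grm2 left absent for ", n_skip, " row(s)")
  } else if (!quiet) {
    wp_note("derive_components: inputs for Grm2 missing; column left absent")
  }

  if (has("SPK")) {
    ok <- is.na(records$GpS) & !is.na(records$Grm2) &
      !is.na(records$SPK) & records$SPK > 0
    records$GpS[ok] <- records$Grm2[ok] / records$SPK[ok]
  } else if (!quiet) {
    wp_note("derive_components: SPK missing; GpS left absent")
  }
  records
}

#' Design-adjusted genotype means (BLUEs) per environment
#'
#' Computes per-environment best linear unbiased estimates with genotypes as
#' fixed effects. For the augmented design, block effects are estimated from
#' the replicated checks (each block's check mean minus the overall check
#' mean, the classic Federer adjustment) and subtracted from every entry; for
#' the alpha-lattice design a fixed-effects least-squares fit
#' `trait ~ genotype + replicate + block-within-replicate` is used and the
#' genotype adjusted means are extracted via [emmeans::emmeans()].
#'
#' @param records plot-level tibble with `genotype_id`, `environment_id`,
#'   `block_id`, `replicate`, `is_check` and the trait columns.
#' @param design `"augmented"` or `"alpha_lattice"`.
#' @param traits character vector of trait columns to process; defaults to
#'   the standard traits present in the table.
#' @return tibble with `genotype_id`, `environment_id`, `trait`, `value`, `se`.
#' @export
compute_blues <- function(records,
                          design = c("augmented", "alpha_lattice"),
                          traits = NULL) {
  design <- match.arg(design)
  records <- as_tibble(records)
  if (is.null(traits)) {
    traits <- intersect(c("GY", "TKW", "SPK", "DTH", "GpS", "Grm2"),
                        names(records))
    traits <- traits[vapply(traits, function(t) any(!is.na(records[[t]])),
                            logical(1))]
  }
  out <- lapply(split(records, records$environment_id), function(env_dat) {
    bind_rows(lapply(traits, function(tr) {
      d <- env_dat[!is.na(env_dat[[tr]]), ]
      if (nrow(d) == 0) return(NULL)
      res <- if (design == "augmented") blue_augmented(d, tr)
             else blue_alpha_lattice(d, tr)
      res$environment_id <- env_dat$environment_id[1]
      res$trait <- tr
      res
    }))
  })
  bind_rows(out) |>
    select("genotype_id", "environment_id", "trait", "value", "se") |>
    arrange(.data$trait, .data$environment_id, .data$genotype_id)
}

# Federer check-based adjustment: block effect = block check mean - overall
# check mean; entries adjusted by subtracting their block's effect
blue_augmented <- function(d, trait) {
  y <- d[[trait]]
  if (!any(d$is_check)) {
    # no checks at all: fall back to raw means (single-rep unadjusted)
    agg <- tapply(y, d$genotype_id, mean)
    return(tibble(genotype_id = names(agg), value = as.numeric(agg),
                  se = NA_real_))
  }
  blocks <- unique(d$block_id)
  chk <- d[d$is_check, ]
  missing_chk <- setdiff(blocks, unique(chk$block_id))
  if (length(missing_chk) > 0)
    wp_stop("augmented design: no check present in block(s) ",
            paste(missing_chk, collapse = ", "))
  blk_mean <- tapply(chk[[trait]], chk$block_id, mean)
  blk_eff <- blk_mean - mean(chk[[trait]])
  adj <- y - blk_eff[d$block_id]
  # residual variance from checks after block + check effects
  mse <- {
    terms <- c(if (dplyr::n_distinct(chk$genotype_id) > 1) "factor(genotype_id)",
               if (dplyr::n_distinct(chk$block_id) > 1) "factor(block_id)")
    if (is.null(terms)) terms <- "1"
    fit <- lm(stats::reformulate(terms, response = trait), data = chk)
    df <- fit$df.residual
    if (df > 0) sum(resid(fit)^2) / df else NA_real_
  }
  n_rep <- tapply(adj, d$genotype_id, length)
  val <- tapply(adj, d$genotype_id, mean)
  nchk_blk <- mean(tapply(chk$block_id, chk$block_id, length))
  se <- sqrt(mse * (1 + 1 / nchk_blk)) / sqrt(n_rep)
  tibble(genotype_id = names(val), value = as.numeric(val),
         se = as.numeric(se[names(val)]))
}

blue_alpha_lattice <- function(d, trait) {
  if (max(table(d$genotype_id, d$replicate)) < 1 ||
      dplyr::n_distinct(d$replicate) < 2)
    wp_stop("alpha-lattice design requires >= 2 replications")
  d$genotype_id <- factor(d$genotype_id)
  d$replicate <- factor(d$replicate)
  d$block_id <- factor(d$block_id)
  terms <- c("genotype_id", "replicate")
  if (dplyr::n_distinct(d$block_id) > dplyr::n_distinct(d$replicate))
    terms <- c(terms, "block_id")
  fit <- lm(stats::reformulate(terms, response = trait), data = d)
  em <- suppressMessages(
    as.data.frame(emmeans::emmeans(fit, "genotype_id")))
  tibble(genotype_id = as.character(em$genotype_id),
         value = em$emmean, se = em$SE)
}

#' Two-way variance partition and broad-sense heritability
#'
#' Partitions the total sum of squares of a trait into genotype (G),
#' environment (E), GxE and residual components using mean-based two-way
#' sums of squares, and reports each source's share of the total SS. When
#' plot-level replicates are present, a per-environment broad-sense
#' heritability is computed as `H2 = s2_g / (s2_g + s2_e / r)` from the
#' one-way genotype ANOVA within each environment (`r` = mean replicate
#' count).
#'
#' @param data plot records (replicated) or a BLUE table with columns
#'   `genotype_id`, `environment_id` and either a `trait`/`value` pair or a
#'   column named after `trait`.
#' @param trait trait name (default `"GY"`).
#' @return object of class `wp_varpart` with `ss`, `shares`, `H2_by_env`;
#'   has a [tidy()] method.
#' @export
variance_partition <- function(data, trait = "GY") {
  data <- as_tibble(data)
  if ("trait" %in% names(data) && "value" %in% names(data)) {
    data <- data[data$trait == trait, ]
    y <- data$value
  } else {
    if (!trait %in% names(data)) wp_stop("trait column '", trait, "' not found")
    y <- data[[trait]]
  }
  keep <- !is.na(y)
  data <- data[keep, ]; y <- y[keep]
  g <- factor(data$genotype_id); e <- factor(data$environment_id)
  if (nlevels(g) < 2 || nlevels(e) < 2)
    wp_stop("variance_partition needs >= 2 genotypes and >= 2 environments",
            if (nlevels(e) < 2) " (single environment: GxE undefined)" else "")

  ybar <- mean(y)
  ss_total <- sum((y - ybar)^2)
  ss_of <- function(f) {
    m <- tapply(y, f, mean); n <- tapply(y, f, length)
    sum(n * (m - ybar)^2)
  }
  ss_G <- ss_of(g); ss_E <- ss_of(e)
  cell <- interaction(g, e, drop = TRUE)
  ss_cells <- ss_of(cell)
  ss_GxE <- max(0, ss_cells - ss_G - ss_E)
  ss_resid <- max(0, ss_total - ss_cells)

  # per-environment H2 where replication exists
  H2 <- vapply(levels(e), function(ev) {
    d <- data[e == ev, ]; yy <- y[e == ev]
    reps <- table(d$genotype_id)
    reps <- reps[reps > 0]
    if (!any(reps > 1)) return(NA_real_)
    keep2 <- d$genotype_id %in% names(reps[reps > 1])
    d <- d[keep2, ]; yy <- yy[keep2]
    if (dplyr::n_distinct(d$genotype_id) < 2) return(NA_real_)
    fit <- stats::aov(yy ~ factor(d$genotype_id))
    tab <- summary(fit)[[1]]
    if (nrow(tab) < 2) return(NA_real_)
    msq <- tab[["Mean Sq"]]
    msg <- msq[1]; mse <- msq[2]
    r <- mean(table(d$genotype_id))
    s2g <- max(0, (msg - mse) / r)
    h2 <- s2g / (s2g + mse / r)
    min(max(h2, 0), 1)
  }, numeric(1))

  structure(list(
    trait = trait,
    ss = c(G = ss_G, E = ss_E, GxE = ss_GxE, resid = ss_resid,
           total = ss_total),
    shares = c(G = ss_G, E = ss_E, GxE = ss_GxE) / ss_total,
    H2_by_env = H2
  ), class = "wp_varpart")
}

#' @export
print.wp_varpart <- function(x, ...) {
  cat("<wp_varpart> trait:", x$trait, "\n")
  cat(sprintf("  shares: G %.3f | E %.3f | GxE %.3f\n",
              x$shares["G"], x$shares["E"], x$shares["GxE"]))
  h <- x$H2_by_env[!is.na(x$H2_by_env)]
  if (length(h))
    cat(sprintf("  H2 per environment: %.2f-%.2f (median %.2f)\n",
                min(h), max(h), median(h)))
  invisible(x)
}

#' @rdname variance_partition
#' @param x a `wp_varpart` object.
#' @param ... unused.
#' @export
tidy.wp_varpart <- function(x, ...) {
  tibble(source = c("G", "E", "GxE", "resid"),
         ss = as.numeric(x$ss[c("G", "E", "GxE", "resid")]),
         share = as.numeric(x$ss[c("G", "E", "GxE", "resid")] / x$ss["total"]))
}

#' Ratio-to-maximum scaling of genotype means
#'
#' Converts genotype values to a ratio of the top-performing entry within
#' each environment, then averages the ratios across environments per
#' genotype. The best entry of every environment scores 1, so the result is
#' a range-free measure of the genetic (G) component. Environments whose
#' maximum is not positive are excluded with a log message.
#'
#' @param blues BLUE table (`genotype_id`, `environment_id`, `trait`, `value`).
#' @param trait trait to scale (default `"GY"`).
#' @param quiet suppress log messages.
#' @return tibble `genotype_id`, `gy_ratio` (mean ratio-to-max), `n_env`.
#' @export
ratio_to_max <- function(blues, trait = "GY", quiet = FALSE) {
  d <- dplyr::filter(as_tibble(blues), .data$trait == !!trait, !is.na(.data$value))
  if (nrow(d) == 0) wp_stop("no data for trait ", trait)
  mx <- d |> group_by(.data$environment_id) |>
    summarise(mx = max(.data$value), .groups = "drop")
  bad <- mx$environment_id[mx$mx <= 0]
  if (length(bad) > 0) {
    if (!quiet)
      wp_note("ratio_to_max: excluded environment(s) with max <= 0: ",
              paste(bad, collapse = ", "))
    d <- d[!d$environment_id %in% bad, ]
    mx <- mx[!mx$environment_id %in% bad, ]
  }
  d |>
    left_join(mx, by = "environment_id") |>
    mutate(ratio = .data$value / .data$mx) |>
    group_by(.data$genotype_id) |>
    summarise(gy_ratio = mean(.data$ratio), n_env = dplyr::n(),
              .groups = "drop")
}

#' Per-environment correlations of component traits with grain yield
#'
#' Pearson correlations of DTH, TKW, SPK and GpS (those available) against
#' GY, per environment and averaged per mega-environment group, with a
#' single-level significance code at P < 0.001 (`"•"` significant,
#' `"ns"` not, `"-"` trait unavailable or degenerate).
#'
#' @param blues BLUE table with traits GY plus components.
#' @param assignment optional tibble `environment_id`, `group` (from
#'   [cluster_environments()]); adds per-group average rows.
#' @param min_genotypes environments with fewer genotypes are skipped.
#' @param alpha significance level for the star code (default 0.001).
#' @return tibble `environment_id`, `trait`, `n`, `r`, `p_value`, `code`.
#' @export
trait_gy_correlations <- function(blues, assignment = NULL,
                                  min_genotypes = 10, alpha = 0.001) {
  wide <- as_tibble(blues) |>
    select("genotype_id", "environment_id", "trait", "value") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
  if (!"GY" %in% names(wide)) wp_stop("GY BLUEs required")
  comp <- intersect(c("DTH", "TKW", "SPK", "GpS"), names(wide))

  corr_block <- function(d, label) {
    bind_rows(lapply(comp, function(tr) {
      ok <- complete.cases(d$GY, d[[tr]])
      if (sum(ok) < min_genotypes || sd(d[[tr]][ok]) == 0 ||
          sd(d$GY[ok]) == 0) {
        return(tibble(environment_id = label, trait = tr, n = sum(ok),
                      r = NA_real_, p_value = NA_real_, code = "-"))
      }
      ct <- suppressWarnings(cor.test(d$GY[ok], d[[tr]][ok]))
      tibble(environment_id = label, trait = tr, n = sum(ok),
             r = unname(ct$estimate), p_value = ct$p.value,
             code = if (!is.finite(ct$p.value)) "-"
                    else if (ct$p.value < alpha) "•" else "ns")
    }))
  }

  per_env <- bind_rows(lapply(split(wide, wide$environment_id), function(d) {
    corr_block(d, d$environment_id[1])
  }))

  if (!is.null(assignment)) {
    grp <- wide |>
      left_join(as_tibble(assignment)[c("environment_id", "group")],
                by = "environment_id") |>
      filter(!is.na(.data$group)) |>
      group_by(.data$group, .data$genotype_id) |>
      summarise(across(dplyr::all_of(c("GY", comp)),
                       ~ mean(.x, na.rm = TRUE)), .groups = "drop")
    avg <- bind_rows(lapply(split(grp, grp$group), function(d) {
      corr_block(d, paste0("average_", d$group[1]))
    }))
    per_env <- bind_rows(per_env, avg)
  }
  per_env
}
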