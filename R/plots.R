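#' AMMI biplot
#'
#' Genotype and environment scores on the first two interaction principal
#' components.
#'
#' @param object a `wp_ammi` fit.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wp_ammi <- function(object, ...) {
  gs <- as_tibble(object$ipc_genotype_scores, rownames = "id") |>
    mutate(role = "genotype")
  es <- as_tibble(object$ipc_environment_scores, rownames = "id") |>
    mutate(role = "environment")
  d <- bind_rows(gs, es)
  if (!"IPC2" %in% names(d)) d$IPC2 <- 0
  ggplot(d, aes(.data$IPC1, .data$IPC2, colour = .data$role)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    geom_point() +
    labs(title = "AMMI interaction biplot",
         x = sprintf("IPC1 (%.1f%% of GxE)", 100 * object$s[1]),
         y = sprintf("IPC2 (%.1f%% of GxE)",
                     if (length(object$s) > 1) 100 * object$s[2] else 0)) +
    theme_minimal()
}

#' Manhattan plot of a GWAS scan
#'
#' @param object a `wp_gwas` result.
#' @param lod_cutoff optional horizontal threshold line.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wp_gwas <- function(object, lod_cutoff = 2.69, ...) {
  d <- as_tibble(object)
  p <- ggplot(d, aes(.data$position / 1e6, .data$lod,
                     colour = .data$chromosome)) +
    geom_point(show.legend = FALSE) +
    facet_wrap(~chromosome, nrow = 1, scales = "free_x") +
    labs(x = "position (Mbp)", y = "LOD",
         title = sprintf("GWAS scan (%s, %s)", d$trait[1], d$context[1])) +
    theme_minimal()
  if (!is.null(lod_cutoff))
    p <- p + geom_hline(yintercept = lod_cutoff, linetype = 2)
  p
}

#' Quantile-quantile plot of association p-values
#'
#' Observed against expected -log10(p) under the uniform null, annotated
#' with the genomic inflation factor.
#'
#' @param scan a `wp_gwas` result.
#' @return a ggplot object.
#' @export
plot_gwas_qq <- function(scan) {
  p <- sort(scan$p_value[is.finite(scan$p_value)])
  d <- tibble(expected = -log10(stats::ppoints(length(p))),
              observed = -log10(p))
  lam <- inflation_factor(p)
  ggplot(d, aes(.data$expected, .data$observed)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_point() +
    labs(x = expression(Expected ~ -log[10](p)),
         y = expression(Observed ~ -log[10](p)),
         title = sprintf("QQ plot (lambda = %.2f)", lam)) +
    theme_minimal()
}

#' LD decay curve
#'
#' Binned mean pairwise r-squared against physical distance with the fitted
#' decay curve and the critical r-squared crossing.
#'
#' @param ld a `wp_ld` result from [ld_decay()].
#' @return a ggplot object.
#' @export
plot_ld_decay <- function(ld) {
  p <- ggplot(ld$bins, aes(.data$dist / 1e6, .data$r2)) +
    geom_point() +
    geom_hline(yintercept = ld$critical_r2, linetype = 2) +
    labs(x = "distance (Mbp)", y = expression(mean ~ r^2),
         title = "LD decay") +
    theme_minimal()
  if (!is.null(ld$curve)) {
    cv <- ld$curve
    xs <- seq(0, max(ld$bins$dist), length.out = 200)
    fitted <- tibble(dist = xs,
                     r2 = (cv$r0 - cv$fl) * exp(-xs / cv$tau) + cv$fl)
    p <- p + geom_line(data = fitted, aes(.data$dist / 1e6, .data$r2),
                       colour = "steelblue")
  }
  if (is.finite(ld$ld_distance))
    p <- p + geom_vline(xintercept = ld$ld_distance / 1e6, linetype = 3)
  p
}

#' Yield-potential vs stability selection surface
#'
#' Ratio-to-max yield against AWAI with panel-average guides; genotypes
#' beating both averages are highlighted.
#'
#' @param surface tibble from [selection_surface()].
#' @return a ggplot object.
#' @export
plot_selection_surface <- function(surface) {
  ggplot(surface, aes(.data$awai, .data$gy_ratio,
                      colour = .data$selected)) +
    geom_vline(xintercept = mean(surface$awai), linetype = 2,
               colour = "grey60") +
    geom_hline(yintercept = mean(surface$gy_ratio), linetype = 2,
               colour = "grey60") +
    geom_point() +
    labs(x = "AWAI (0 = most stable)", y = "GY ratio-to-max",
         title = "Selection surface: yield potential vs stability") +
    theme_minimal()
}

#' Water-productivity trendlines per class
#'
#' Per-genotype GY BLUEs against environment moisture, coloured by WP class,
#' with the group-average trends.
#'
#' @param blues GY BLUE tibble.
#' @param environments `environment_id`/`group`/`total_moisture` tibble.
#' @param classes result of [classify_genotypes()].
#' @return a ggplot object.
#' @export
plot_wp_classes <- function(blues, environments, classes) {
  d <- as_tibble(blues) |>
    filter(.data$trait == "GY") |>
    inner_join(as_tibble(environments), by = "environment_id") |>
    inner_join(classes[c("genotype_id", "wp_class")], by = "genotype_id") |>
    filter(!is.na(.data$wp_class))
  ggplot(d, aes(.data$total_moisture, .data$value,
                colour = factor(.data$wp_class))) +
    geom_point(alpha = 0.4, size = 0.8) +
    facet_wrap(~group, scales = "free_x") +
    labs(x = "total moisture (mm)", y = "GY BLUE (kg/ha)",
         colour = "WP class",
         title = "Water productivity classes") +
    theme_minimal()
}
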