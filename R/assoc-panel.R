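#' Curate a marker panel
#'
#' Removes markers that violate the standard array-curation rules: missing
#' rate at or above `max_missing`, minor allele frequency below `min_maf`,
#' or heterozygosity above `max_het`. Counts per filter are logged.
#'
#' @param panel a `wp_geno` object.
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param max_het maximum heterozygous-call rate (default 0.05).
#' @param max_missing maximum missing-call rate (default 0.01).
#' @param quiet suppress the filter report.
#' @return the curated `wp_geno` panel; the report is attached as attribute
#'   `curation_report`.
#' @export
curate_markers <- function(panel, min_maf = 0.05, max_het = 0.05,
                           max_missing = 0.01, quiet = FALSE) {
  stopifnot(inherits(panel, "wp_geno"))
  st <- marker_stats(panel)
  fail_missing <- st$missing_rate >= max_missing
  fail_maf <- !fail_missing & st$maf < min_maf
  fail_het <- !fail_missing & !fail_maf & st$het_rate > max_het
  keep <- !(fail_missing | fail_maf | fail_het)
  if (!any(keep)) wp_stop("curation removed every marker")
  if (!quiet)
    wp_note(sprintf(
      "curate_markers: kept %d/%d (removed %d missing>=%.2g, %d MAF<%.2g, %d het>%.2g)",
      sum(keep), nrow(st), sum(fail_missing), max_missing,
      sum(fail_maf), min_maf, sum(fail_het), max_het))
  out <- new_wp_geno(panel$dosage[, keep, drop = FALSE],
                     panel$map[keep, , drop = FALSE], panel$subpop)
  attr(out, "curation_report") <- tibble(
    filter = c("missing", "maf", "het"),
    removed = c(sum(fail_missing), sum(fail_maf), sum(fail_het))
  )
  out
}

#' Population structure covariates and genomic kinship
#'
#' Q covariates are the leading principal components of the centered,
#' mean-imputed dosage matrix (count chosen by the eigenvalue elbow —
#' components above the average eigenvalue — unless `n_pc` is given). K is
#' the VanRaden genomic relationship matrix
#' `K = W W' / (2 * sum p(1-p))` with `W` the dosage matrix centered by twice
#' the allele frequencies; it is symmetric positive semidefinite.
#'
#' @param panel curated `wp_geno` panel.
#' @param n_pc number of structure PCs to return (default: elbow rule, max 10).
#' @return list with `Q` (genotype x PC matrix), `K` (genotype x genotype
#'   kinship), `eigenvalues` (PCA variances).
#' @export
structure_and_kinship <- function(panel, n_pc = NULL) {
  stopifnot(inherits(panel, "wp_geno"))
  d <- impute_dosages(panel$dosage)
  if (ncol(d) < nrow(d) / 10)
    warn("structure_and_kinship: fewer markers than genotypes/10; ",
         "structure estimates will be noisy")
  p <- colMeans(d) / 2
  keep <- p > 0 & p < 1
  d <- d[, keep, drop = FALSE]; p <- p[keep]
  W <- sweep(d, 2, 2 * p)
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(rownames(d), rownames(d))
  pc <- prcomp(d, center = TRUE)
  ev <- pc$sdev^2
  if (is.null(n_pc)) n_pc <- max(1L, min(10L, sum(ev > mean(ev))))
  Q <- pc$x[, seq_len(min(n_pc, ncol(pc$x))), drop = FALSE]
  rownames(Q) <- rownames(d)
  list(Q = Q, K = K, eigenvalues = ev)
}

impute_dosages <- function(d) {
  if (!anyNA(d)) return(d)
  cm <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- cm[idx[, 2]]
  d
}

#' Linkage disequilibrium decay over physical distance
#'
#' Computes within-chromosome pairwise allelic r-squared (squared Pearson
#' correlation of dosages), bins it by physical distance, fits an
#' exponential-plus-floor decay curve to the bin means, and reports the
#' distance at which the fitted curve crosses `critical_r2`.
#'
#' @param panel curated `wp_geno` panel.
#' @param critical_r2 background r-squared threshold defining the decay
#'   distance (e.g. the squared Pearson critical value for the panel size).
#' @param n_bins number of distance bins.
#' @param max_pairs cap on marker pairs per chromosome (subsampled above it).
#' @return object of class `wp_ld`: list with `bins` (distance-binned mean
#'   r-squared), `pairs` (pair count), `ld_distance` (bp), `critical_r2`,
#'   and the fitted curve parameters.
#' @export
ld_decay <- function(panel, critical_r2 = 0.05, n_bins = 40,
                     max_pairs = 2e5) {
  stopifnot(inherits(panel, "wp_geno"))
  d <- impute_dosages(panel$dosage)
  map <- panel$map
  pair_list <- lapply(split(seq_len(nrow(map)), map$chromosome), function(ix) {
    if (length(ix) < 2) return(NULL)
    cmb <- utils::combn(ix, 2)
    tibble(i = cmb[1, ], j = cmb[2, ],
           dist = abs(map$position[cmb[2, ]] - map$position[cmb[1, ]]))
  })
  pairs <- bind_rows(pair_list)
  if (is.null(pairs) || nrow(pairs) == 0)
    wp_stop("ld_decay: no within-chromosome marker pair available")
  if (nrow(pairs) > max_pairs)
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), ]
  sds <- apply(d, 2, sd)
  ok <- sds[pairs$i] > 0 & sds[pairs$j] > 0
  pairs <- pairs[ok, ]
  r <- vapply(seq_len(nrow(pairs)),
              function(k) cor(d[, pairs$i[k]], d[, pairs$j[k]]),
              numeric(1))
  pairs$r2 <- r^2

  brk <- seq(0, max(pairs$dist), length.out = n_bins + 1)
  pairs$bin <- cut(pairs$dist, brk, include.lowest = TRUE)
  bins <- pairs |>
    group_by(.data$bin) |>
    summarise(dist = mean(.data$dist), r2 = mean(.data$r2),
              n = dplyr::n(), .groups = "drop") |>
    filter(!is.na(.data$dist))

  fitpar <- fit_ld_curve(bins)
  ld_dist <- ld_crossing(fitpar, bins, critical_r2)
  structure(list(bins = bins, pairs = nrow(pairs), ld_distance = ld_dist,
                 critical_r2 = critical_r2, curve = fitpar,
                 mean_r2 = mean(pairs$r2)),
            class = "wp_ld")
}

# r2(d) = (r0 - floor) * exp(-d / tau) + floor, least squares on bin means
fit_ld_curve <- function(bins) {
  floor0 <- min(bins$r2)
  r00 <- max(bins$r2)
  tau0 <- max(bins$dist) / 4
  fit <- try(suppressWarnings(
    stats::nls(r2 ~ (r0 - fl) * exp(-dist / tau) + fl,
               data = bins,
               start = list(r0 = r00, fl = floor0, tau = tau0),
               control = stats::nls.control(warnOnly = TRUE))),
    silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  as.list(coef(fit))
}

ld_crossing <- function(par, bins, critical_r2) {
  if (!is.null(par) && par$r0 > critical_r2 && critical_r2 > par$fl &&
      par$tau > 0) {
    return(-par$tau * log((critical_r2 - par$fl) / (par$r0 - par$fl)))
  }
  # fallback: first linear-interpolated crossing of the bin means
  above <- bins$r2 > critical_r2
  if (!any(above)) return(NA_real_)
  if (all(above)) return(max(bins$dist))
  k <- max(which(above))
  if (k == nrow(bins)) return(max(bins$dist))
  x1 <- bins$dist[k]; x2 <- bins$dist[k + 1]
  y1 <- bins$r2[k]; y2 <- bins$r2[k + 1]
  x1 + (critical_r2 - y1) * (x2 - x1) / (y2 - y1)
}

#' @export
print.wp_ld <- function(x, ...) {
  cat("<wp_ld> ", x$pairs, " pairs; mean r2 ", signif(x$mean_r2, 3),
      "; decay distance ", format(x$ld_distance, big.mark = ","),
      " bp at critical r2 ", x$critical_r2, "\n", sep = "")
  invisible(x)
}

#' Critical r-squared derived from the Pearson critical value
#'
#' Squared two-sided critical Pearson correlation for `n` observations at
#' level `alpha`: the r-squared above which a marker explains a significant
#' share of phenotypic variation.
#'
#' @param n panel size (number of genotypes).
#' @param alpha significance level (default 0.01).
#' @return numeric critical r-squared.
#' @export
critical_r2_for_n <- function(n, alpha = 0.01) {
  tcrit <- qt(1 - alpha / 2, df = n - 2)
  (tcrit^2 / (tcrit^2 + n - 2))
}
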