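#' Single-marker genome-wide association scan
#'
#' Tests every marker of a curated panel against a phenotype for one context
#' (a single environment or a combined mega-environment mean), with days to
#' heading and population-structure PCs as fixed covariates.
#'
#' Two models are available. `GLM_Q` is a fixed-effects regression of the
#' phenotype on covariates plus marker dosage. `MLM_QK` adds a single random
#' polygenic term with covariance proportional to the kinship matrix `K`;
#' its variance components are estimated once on the null (covariates-only)
#' model via REML on the eigendecomposition of `K` and reused for every
#' marker (the population-parameters-previously-determined approximation).
#' `auto` runs both and keeps the model whose genomic inflation factor
#' lambda is nearer 1 (the quantile-quantile calibration criterion).
#'
#' Missing dosages are mean-imputed per marker for testing only. The marker
#' effect is per alternate-allele copy; `r2_marker` is the incremental
#' r-squared of the marker after the covariates, as a fraction of total
#' phenotypic variance; `lod = -log10(p)`.
#'
#' @param panel curated `wp_geno` panel.
#' @param phenotype tibble `genotype_id`, `value` for one context.
#' @param covariates optional tibble `genotype_id` plus numeric covariate
#'   columns (e.g. `DTH`).
#' @param model `"GLM_Q"`, `"MLM_QK"` or `"auto"`.
#' @param Q optional structure covariate matrix (rownames = genotype ids);
#'   computed from the panel when `NULL` and `n_pc > 0`.
#' @param K optional kinship matrix for `MLM_QK`; VanRaden matrix computed
#'   from the panel when `NULL`.
#' @param n_pc number of structure PCs when `Q` is `NULL` (0 disables Q).
#' @param trait,context labels attached to the result rows.
#' @return object of class `wp_gwas`: tibble of per-marker results
#'   (`marker_id`, `chromosome`, `position`, `effect`, `se`, `p_value`,
#'   `lod`, `r2_marker`, `model_used`) with attributes `lambda` (named,
#'   per fitted model) and `model_used`.
#' @export
gwas <- function(panel, phenotype, covariates = NULL,
                 model = c("auto", "GLM_Q", "MLM_QK"),
                 Q = NULL, K = NULL, n_pc = 3,
                 trait = "GY", context = "combined") {
  model <- match.arg(model)
  stopifnot(inherits(panel, "wp_geno"))
  phenotype <- as_tibble(phenotype)
  ids <- intersect(rownames(panel$dosage),
                   phenotype$genotype_id[!is.na(phenotype$value)])
  if (length(ids) < 10) wp_stop("gwas: fewer than 10 genotypes with ",
                                "phenotype and genotype data")
  y <- phenotype$value[match(ids, phenotype$genotype_id)]
  G <- impute_dosages(panel$dosage[ids, , drop = FALSE])

  X0 <- matrix(1, length(ids), 1, dimnames = list(ids, "intercept"))
  if (is.null(Q) && n_pc > 0) {
    Q <- structure_and_kinship(panel, n_pc = n_pc)$Q
  }
  if (!is.null(Q)) X0 <- cbind(X0, Q[ids, , drop = FALSE])
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    cv <- as.matrix(covariates[match(ids, covariates$genotype_id),
                               setdiff(names(covariates), "genotype_id"),
                               drop = FALSE])
    X0 <- cbind(X0, cv)
  }
  drop_collinear(X0)

  run_glm <- function() gwas_glm(y, X0, G)
  run_mlm <- function() {
    Km <- K %||% structure_and_kinship(panel)$K
    gwas_mlm(y, X0, G, Km[ids, ids])
  }
  scans <- switch(model,
    GLM_Q = list(GLM_Q = run_glm()),
    MLM_QK = list(MLM_QK = run_mlm()),
    auto = list(GLM_Q = run_glm(), MLM_QK = run_mlm()))
  lambdas <- vapply(scans, function(s) inflation_factor(s$p_value), numeric(1))
  used <- names(scans)[which.min(abs(lambdas - 1))]
  res <- scans[[used]]

  out <- bind_cols(
    panel$map[match(colnames(G), panel$map$marker_id),
              c("marker_id", "chromosome", "position")],
    res
  ) |>
    mutate(lod = -log10(pmax(.data$p_value, .Machine$double.xmin)),
           model_used = used, trait = trait, context = context)
  attr(out, "lambda") <- lambdas
  attr(out, "model_used") <- used
  class(out) <- c("wp_gwas", class(out))
  out
}

drop_collinear <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    wp_stop("gwas: collinear covariate column(s): ",
            paste(bad, collapse = ", "))
  }
  invisible(X)
}

# fixed-effects scan: residualize y and markers on X0, per-marker t-test
gwas_glm <- function(y, X0, G) {
  n <- length(y); p0 <- ncol(X0)
  qr0 <- qr(X0)
  ry <- qr.resid(qr0, y)
  RG <- qr.resid(qr0, G)
  sxx <- colSums(RG^2)
  sxy <- colSums(RG * ry)
  tss <- sum((y - mean(y))^2)
  rss0 <- sum(ry^2)
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss1 <- rss0 - ifelse(sxx > 0, beta^2 * sxx, 0)
  df <- n - p0 - 1
  sigma2 <- pmax(rss1, 0) / df
  se <- sqrt(sigma2 / sxx)
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[!is.finite(p)] <- NA_real_
  tibble(effect = as.numeric(beta), se = as.numeric(se),
         p_value = as.numeric(p),
         r2_marker = as.numeric((rss0 - pmax(rss1, 0)) / tss))
}

# mixed-model scan: null-model REML variance components on the eigenspace of
# K, then per-marker generalized least squares with those components fixed
gwas_mlm <- function(y, X0, G, K) {
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  U <- eg$vectors
  dvals <- pmax(eg$values, 0)
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X0)
  Gt <- crossprod(U, G)

  lambda <- reml_lambda(yt, Xt, dvals)
  w <- 1 / (lambda * dvals + 1)
  sw <- sqrt(w)
  yw <- drop(yt * sw)
  Xw <- Xt * sw
  Gw <- Gt * sw
  res <- gwas_glm(yw, Xw, Gw)
  res
}

# profile REML log-likelihood in lambda = sigma_g^2 / sigma_e^2
reml_lambda <- function(yt, Xt, dvals) {
  n <- length(yt); p <- ncol(Xt)
  negll <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * dvals + 1)
    sw <- sqrt(w)
    Xw <- Xt * sw; yw <- yt * sw
    qrX <- qr(Xw)
    r <- qr.resid(qrX, yw)
    rss <- sum(r^2)
    ldetV <- -sum(log(w))
    ldetX <- determinant(crossprod(Xw), logarithm = TRUE)$modulus
    0.5 * ((n - p) * log(rss) + ldetV + as.numeric(ldetX))
  }
  grid <- seq(-8, 8, length.out = 33)
  vals <- vapply(grid, negll, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- optimize(negll, c(lo, hi))
  exp(opt$minimum)
}

#' Genomic inflation factor
#'
#' `lambda = median(chi2(p)) / qchisq(0.5, 1)` over a vector of association
#' p-values; 1 indicates a well-calibrated scan.
#'
#' @param p vector of p-values.
#' @return numeric lambda.
#' @export
inflation_factor <- function(p) {
  p <- p[is.finite(p) & p > 0 & p <= 1]
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Filter a scan to significant marker-trait associations
#'
#' Applies the dual significance gate: `lod >= lod_cutoff` (a Bonferroni-by-
#' LD type threshold) and `r2_marker >= r2_cutoff` (the squared Pearson
#' critical value). Both gates must pass for a valid MTA.
#'
#' @param scan a `wp_gwas` result (or a bound table of several).
#' @param lod_cutoff minimum LOD (default 2.69, a discovery-panel value).
#' @param r2_cutoff minimum marker r-squared (default 0.024).
#' @return MTA tibble (subset of the scan rows).
#' @export
call_mtas <- function(scan, lod_cutoff = 2.69, r2_cutoff = 0.024) {
  out <- as_tibble(scan) |>
    filter(!is.na(.data$p_value),
           .data$lod >= lod_cutoff, .data$r2_marker >= r2_cutoff)
  out
}
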