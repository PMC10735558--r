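#' Fit the AMMI model to a genotype x environment table
#'
#' Additive main effects (row/column means of the two-way table) plus a
#' multiplicative interaction decomposition: the doubly-centered residual is
#' factored by SVD, giving interaction principal components (IPCs). IPC
#' scores are scaled so that the sum over IPCs of genotype score x
#' environment score reconstructs the interaction residual exactly. The
#' fraction of GxE variance carried by the i-th IPC is
#' `s_i = lambda_i^2 / sum(lambda^2)`. The number of significant IPCs is
#' determined by a sequential Gollob F-test (`df_k = g + e - 1 - 2k`) at
#' `alpha`, against a supplied error mean square or, by default, the pooled
#' mean square of the trailing (untested) IPCs.
#'
#' Missing cells are imputed by iterated row+column expectation (EM-style)
#' before decomposition; the iteration count is logged.
#'
#' @param data BLUE tibble (`genotype_id`, `environment_id`, `value`, with an
#'   optional `trait` column filtered to `trait`) or a numeric genotype x
#'   environment matrix.
#' @param trait trait to use when `data` is a BLUE table (default `"GY"`).
#' @param alpha significance level of the IPC F-test (default 0.05).
#' @param error_ms,error_df optional pooled plot-level error mean square and
#'   its degrees of freedom to test IPCs against.
#' @param tol EM imputation convergence tolerance.
#' @return An object of class `wp_ammi` with components `grand_mean`,
#'   `genotype_effects`, `environment_effects`, `ipc_genotype_scores`,
#'   `ipc_environment_scores`, `singular_values`, `s` (per-IPC GxE variance
#'   fractions), `ss_interaction`, `significant_ipcs`, `ipc_tests`.
#' @export
fit_ammi <- function(data, trait = "GY", alpha = 0.05,
                     error_ms = NULL, error_df = NULL, tol = 1e-6) {
  M <- two_way_matrix(data, trait)
  g <- nrow(M); e <- ncol(M)
  if (g < 3 || e < 3)
    wp_stop("fit_ammi needs at least 3 genotypes and 3 environments")

  if (anyNA(M)) M <- impute_two_way(M, tol = tol)

  mu <- mean(M)
  g_eff <- rowMeans(M) - mu
  e_eff <- colMeans(M) - mu
  R <- M - outer(g_eff, rep(1, e)) - outer(rep(1, g), e_eff) - mu
  sv <- svd(R)
  K <- min(g, e) - 1L
  d <- sv$d[seq_len(K)]
  ss_int <- sum(R^2)
  s_i <- if (ss_int > 0) d^2 / sum(sv$d^2) else rep(0, K)
  gs <- sv$u[, seq_len(K), drop = FALSE] %*% diag(sqrt(d), K)
  es <- sv$v[, seq_len(K), drop = FALSE] %*% diag(sqrt(d), K)
  dimnames(gs) <- list(rownames(M), paste0("IPC", seq_len(K)))
  dimnames(es) <- list(colnames(M), paste0("IPC", seq_len(K)))

  tests <- ipc_f_tests(d^2, g, e, alpha, error_ms, error_df,
                       ss_int_tol = max(1e-10, 1e-12 * mu^2))
  structure(list(
    grand_mean = mu,
    genotype_effects = g_eff,
    environment_effects = e_eff,
    ipc_genotype_scores = gs,
    ipc_environment_scores = es,
    singular_values = d,
    s = s_i,
    ss_interaction = ss_int,
    significant_ipcs = sum(tests$significant),
    ipc_tests = tests,
    alpha = alpha,
    trait = trait
  ), class = "wp_ammi")
}

two_way_matrix <- function(data, trait) {
  if (is.matrix(data)) return(data)
  d <- as_tibble(data)
  if ("trait" %in% names(d)) d <- d[d$trait == trait, ]
  wide <- d |>
    select("genotype_id", "environment_id", "value") |>
    tidyr::pivot_wider(names_from = "environment_id", values_from = "value")
  M <- as.matrix(wide[-1])
  rownames(M) <- wide$genotype_id
  M
}

impute_two_way <- function(M, tol = 1e-6, max_iter = 200) {
  miss <- is.na(M)
  M[miss] <- mean(M, na.rm = TRUE)
  for (it in seq_len(max_iter)) {
    mu <- mean(M)
    fit <- outer(rowMeans(M) - mu, rep(1, ncol(M))) +
      outer(rep(1, nrow(M)), colMeans(M) - mu) + mu
    new <- M
    new[miss] <- fit[miss]
    delta <- max(abs(new - M))
    M <- new
    if (delta < tol) break
  }
  wp_note("fit_ammi: imputed ", sum(miss), " missing cell(s) in ", it,
          " iteration(s)")
  M
}

# sequential Gollob F-tests of the IPC sums of squares
ipc_f_tests <- function(ss_k, g, e, alpha, error_ms, error_df, ss_int_tol) {
  K <- length(ss_k)
  df_k <- (g - 1) + (e - 1) - (2 * seq_len(K) - 1)
  sig <- logical(K); pval <- rep(NA_real_, K); fval <- rep(NA_real_, K)
  if (sum(ss_k) < ss_int_tol) {
    return(tibble(ipc = seq_len(K), ss = ss_k, df = df_k, f = fval,
                  p_value = pval, significant = sig))
  }
  for (k in seq_len(K)) {
    ms_k <- ss_k[k] / df_k[k]
    if (!is.null(error_ms)) {
      edf <- error_df %||% Inf
      fval[k] <- ms_k / error_ms
      pval[k] <- pf(fval[k], df_k[k], edf, lower.tail = FALSE)
    } else if (k < K) {
      ss_rem <- sum(ss_k[(k + 1):K])
      df_rem <- sum(df_k[(k + 1):K])
      if (df_rem <= 0) break
      if (ss_rem / df_rem <= ss_int_tol) {
        # remaining interaction is numerically zero: axis carries all of it
        fval[k] <- Inf; pval[k] <- 0
      } else {
        fval[k] <- ms_k / (ss_rem / df_rem)
        pval[k] <- pf(fval[k], df_k[k], df_rem, lower.tail = FALSE)
      }
    } else break  # last axis untestable without an external error term
    if (is.na(pval[k]) || pval[k] >= alpha) break
    sig[k] <- TRUE
  }
  tibble(ipc = seq_len(K), ss = ss_k, df = df_k, f = fval,
         p_value = pval, significant = sig)
}

#' @export
print.wp_ammi <- function(x, ...) {
  cat("<wp_ammi> ", length(x$genotype_effects), " genotypes x ",
      length(x$environment_effects), " environments (", x$trait, ")\n",
      sep = "")
  cat(sprintf("  interaction SS %.4g; %d significant IPC(s) at alpha = %g\n",
              x$ss_interaction, x$significant_ipcs, x$alpha))
  if (length(x$s) >= 3)
    cat(sprintf("  first three IPCs carry %.1f%% of GxE\n",
                100 * sum(x$s[1:3])))
  invisible(x)
}

#' @rdname fit_ammi
#' @param x a `wp_ammi` object.
#' @param ... unused.
#' @export
tidy.wp_ammi <- function(x, ...) x$ipc_tests

#' @rdname fit_ammi
#' @export
glance.wp_ammi <- function(x, ...) {
  tibble(grand_mean = x$grand_mean,
         n_genotypes = length(x$genotype_effects),
         n_environments = length(x$environment_effects),
         ss_interaction = x$ss_interaction,
         significant_ipcs = x$significant_ipcs)
}

#' AMMI wide adaptation index (AWAI)
#'
#' For each genotype, `AWAI = sum over significant IPCs of s_i * |PC_i|`,
#' where `s_i` is the fraction of GxE variance explained by the i-th IPC and
#' `PC_i` the genotype's score on it. AWAI near 0 marks the most widely
#' adapted, stable genotypes. A ratio-to-minimum rescaling is also emitted:
#' the minimum positive AWAI divided by each genotype's AWAI, clipped to
#' [0, 1], with zero-AWAI genotypes mapped to 1 (so 1 = most stable).
#'
#' @param fit a `wp_ammi` object from [fit_ammi()].
#' @return tibble `genotype_id`, `awai`, `awai_ratio_to_min`.
#' @export
awai <- function(fit) {
  stopifnot(inherits(fit, "wp_ammi"))
  k <- fit$significant_ipcs
  ids <- rownames(fit$ipc_genotype_scores)
  if (k < 1) {
    return(tibble(genotype_id = ids, awai = 0, awai_ratio_to_min = 1))
  }
  w <- fit$s[seq_len(k)]
  A <- abs(fit$ipc_genotype_scores[, seq_len(k), drop = FALSE]) %*% w
  a <- drop(A)
  pos <- a[a > 0]
  ratio <- if (length(pos) == 0) rep(1, length(a)) else {
    r <- min(pos) / a
    r[a == 0] <- 1
    pmin(pmax(r, 0), 1)
  }
  tibble(genotype_id = ids, awai = unname(a),
         awai_ratio_to_min = unname(ratio))
}

#' Yield-potential vs stability selection surface
#'
#' Joins the genetic component of yield (ratio-to-max, higher = better) with
#' the GxE component (AWAI, lower = better) and flags genotypes that beat
#' the panel average on both axes.
#'
#' @param gy_ratio tibble from [ratio_to_max()] (`genotype_id`, `gy_ratio`).
#' @param awai_tbl tibble from [awai()] (`genotype_id`, `awai`).
#' @return tibble `genotype_id`, `gy_ratio`, `awai`, `selected`.
#' @export
selection_surface <- function(gy_ratio, awai_tbl) {
  gy_ratio <- as_tibble(gy_ratio); awai_tbl <- as_tibble(awai_tbl)
  only_a <- setdiff(gy_ratio$genotype_id, awai_tbl$genotype_id)
  only_b <- setdiff(awai_tbl$genotype_id, gy_ratio$genotype_id)
  if (length(only_a) || length(only_b))
    wp_stop("genotype sets differ between yield and stability inputs: ",
            paste(head(c(only_a, only_b), 10), collapse = ", "))
  d <- inner_join(gy_ratio[c("genotype_id", "gy_ratio")],
                  awai_tbl[c("genotype_id", "awai")], by = "genotype_id")
  d |> mutate(selected = .data$gy_ratio > mean(.data$gy_ratio) &
                .data$awai < mean(.data$awai))
}
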