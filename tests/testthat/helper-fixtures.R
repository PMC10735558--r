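# fixtures built in code; no data files

# small hand-built dosage panel
make_panel <- function(dosage, chromosome = NULL, position = NULL) {
  n_m <- ncol(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("M%03d", seq_len(n_m))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("G%03d", seq_len(nrow(dosage)))
  map <- tibble::tibble(
    marker_id = colnames(dosage),
    chromosome = chromosome %||% rep("chr1", n_m),
    position = position %||% seq(1e6, by = 1e6, length.out = n_m),
    alleles = "A/B"
  )
  durumwp:::new_wp_geno(dosage, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# BLUE tibble from a genotype x environment matrix
blues_from_matrix <- function(M, trait = "GY") {
  tidyr::expand_grid(genotype_id = rownames(M),
                     environment_id = colnames(M)) |>
    dplyr::mutate(trait = trait,
                  value = M[cbind(genotype_id, environment_id)],
                  se = NA_real_)
}

# environments table for waterprod tests
env_table <- function(moisture_stressed, moisture_nonstressed) {
  n_s <- length(moisture_stressed); n_n <- length(moisture_nonstressed)
  tibble::tibble(
    environment_id = sprintf("E%02d", seq_len(n_s + n_n)),
    group = rep(c("moisture_stressed", "non_moisture_stressed"), c(n_s, n_n)),
    total_moisture = c(moisture_stressed, moisture_nonstressed)
  )
}

# GY BLUEs with exact per-genotype slopes: residual noise is constructed
# orthogonal to the moisture regressor within each group, so OLS recovers
# the planted slope exactly while p-values stay finite
blues_with_slopes <- function(slopes_st, slopes_ns, env, intercept = 2000,
                              noise = 30) {
  stopifnot(length(slopes_st) == length(slopes_ns))
  ids <- sprintf("G%03d", seq_along(slopes_st))
  rows <- lapply(seq_along(ids), function(i) {
    vals <- lapply(split(env, env$group), function(eg) {
      m <- eg$total_moisture
      b <- if (eg$group[1] == "moisture_stressed") slopes_st[i] else slopes_ns[i]
      # orthogonalize a fixed wiggle against [1, m]
      r <- sin(seq_along(m) + i)
      X <- cbind(1, m)
      r <- r - X %*% solve(crossprod(X), crossprod(X, r))
      tibble::tibble(environment_id = eg$environment_id,
                     value = intercept + b * m + noise * as.numeric(r))
    })
    dplyr::bind_rows(vals) |>
      dplyr::mutate(genotype_id = ids[i], trait = "GY", se = NA_real_)
  })
  dplyr::bind_rows(rows)
}

# plot records for one environment of an augmented design
augmented_env <- function(values, genotype, block, is_check,
                          environment_id = "E01") {
  tibble::tibble(genotype_id = genotype, environment_id = environment_id,
                 block_id = block, replicate = 1L, is_check = is_check,
                 GY = values)
}

# marker eligible as a planted QTL for power scenarios: common (MAF > 0.2)
# and segregating within subpopulations (low loading on the structure PCs)
pick_unconfounded_marker <- function(panel, dos, mafs, max_loading = 0.2) {
  Q2 <- structure_and_kinship(panel, n_pc = 2)$Q
  X0 <- cbind(1, Q2)
  cand <- which(mafs > 0.2)
  rr <- qr.resid(qr(X0), dos[, cand, drop = FALSE])
  css <- colSums(scale(dos[, cand], scale = FALSE)^2)
  loading <- 1 - colSums(rr^2) / css
  cand[which(loading < max_loading)[1]]
}
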