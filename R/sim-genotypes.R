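#' Simulate a biallelic inbred-line genotype panel
#'
#' Generates a dosage matrix (0/1/2 counts of the alternate allele) for a
#' panel of near-fully homozygous lines, with markers placed on chromosomes,
#' subpopulation structure induced by allele-frequency drift, and local
#' linkage disequilibrium induced by copying founder haplotype blocks within
#' each subpopulation.
#'
#' @param cfg a [sim_config()] object.
#' @param curate if `TRUE` (default), the built-in curation pass
#'   ([curate_markers()]) is applied so every retained marker satisfies the
#'   MAF / heterozygosity / missingness filters by construction. Set to
#'   `FALSE` to obtain the raw panel (e.g. to exercise the filter on planted
#'   violators).
#'
#' @return A `wp_geno` object: a list with
#'   \describe{
#'     \item{dosage}{genotype x marker matrix of 0/1/2 dosages (NA = missing)}
#'     \item{map}{tibble: `marker_id`, `chromosome`, `position`, `alleles`,
#'       `planted_violation`}
#'     \item{subpop}{tibble: `genotype_id`, `subpopulation`}
#'   }
#' @export
simulate_genotypes <- function(cfg, curate = TRUE) {
  stopifnot(inherits(cfg, "wp_sim_config"))
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    geno_ids <- sprintf("G%03d", seq_len(cfg$n_genotypes))
    subpop <- sample(rep_len(seq_len(cfg$n_subpopulations), cfg$n_genotypes))

    # marker map: markers spread over chromosomes, positions sorted ascending
    chrom <- sort(rep_len(seq_len(cfg$n_chromosomes), cfg$n_markers))
    pos <- unlist(lapply(split(chrom, chrom), function(ch) {
      sort(round(runif(length(ch), 1, cfg$chromosome_length)))
    }), use.names = FALSE)
    marker_ids <- sprintf("AX-%05d", seq_len(cfg$n_markers))
    map <- tibble(
      marker_id = marker_ids,
      chromosome = paste0("chr", chrom),
      position = pos,
      alleles = "A/B",
      planted_violation = FALSE
    )

    # base allele frequencies + subpopulation drift
    p0 <- runif(cfg$n_markers, 0.15, 0.85)
    psub <- vapply(seq_len(cfg$n_subpopulations), function(s) {
      pmin(pmax(p0 + rnorm(cfg$n_markers, 0, cfg$drift), 0.02), 0.98)
    }, numeric(cfg$n_markers))

    # haplotype blocks: founder haplotypes per (subpop, chromosome block)
    block <- paste(chrom, ceiling(pos / cfg$ld_block_length))
    dosage <- matrix(0L, cfg$n_genotypes, cfg$n_markers,
                     dimnames = list(geno_ids, marker_ids))
    for (b in unique(block)) {
      cols <- which(block == b)
      for (s in seq_len(cfg$n_subpopulations)) {
        rows <- which(subpop == s)
        if (!length(rows)) next
        founders <- matrix(
          rbinom(cfg$n_founder_haplotypes * length(cols), 1,
                 rep(psub[cols, s], each = cfg$n_founder_haplotypes)),
          nrow = cfg$n_founder_haplotypes
        )
        pick <- sample.int(cfg$n_founder_haplotypes, length(rows), replace = TRUE)
        hap <- founders[pick, , drop = FALSE]
        # rare mutations decouple perfect block identity
        mut <- matrix(rbinom(length(hap), 1, 0.02), nrow = nrow(hap))
        hap <- abs(hap - mut)
        dosage[rows, cols] <- 2L * hap
      }
    }

    # inbred lines: a small fraction of residual heterozygous calls
    if (cfg$het_rate > 0) {
      het <- matrix(runif(length(dosage)) < cfg$het_rate, nrow = nrow(dosage))
      dosage[het] <- 1L
    }
    if (cfg$missing_rate > 0) {
      miss <- matrix(runif(length(dosage)) < cfg$missing_rate, nrow = nrow(dosage))
      dosage[miss] <- NA_integer_
    }

    # plant markers that violate the MAF filter, to exercise curation
    if (cfg$n_violating_markers > 0) {
      viol <- sample.int(cfg$n_markers, cfg$n_violating_markers)
      n_minor <- pmax(0L, round(cfg$n_genotypes * 0.02))
      for (j in viol) {
        dosage[, j] <- 0L
        if (n_minor > 0) dosage[sample.int(cfg$n_genotypes, n_minor), j] <- 2L
      }
      map$planted_violation[viol] <- TRUE
    }

    panel <- new_wp_geno(dosage, map,
                         tibble(genotype_id = geno_ids,
                                subpopulation = paste0("S", subpop)))
    if (curate) {
      panel <- curate_markers(panel, min_maf = cfg$maf_floor,
                              max_het = 0.05, max_missing = 0.01,
                              quiet = TRUE)
    }
    panel
  })
}

new_wp_geno <- function(dosage, map, subpop = NULL) {
  structure(list(dosage = dosage, map = map, subpop = subpop),
            class = "wp_geno")
}

#' @export
print.wp_geno <- function(x, ...) {
  cat("<wp_geno> ", nrow(x$dosage), " genotypes x ", ncol(x$dosage),
      " markers on ", dplyr::n_distinct(x$map$chromosome), " chromosomes\n",
      sep = "")
  invisible(x)
}

#' Per-marker summary statistics of a genotype panel
#'
#' @param panel a `wp_geno` object.
#' @return tibble with `marker_id`, `maf`, `het_rate`, `missing_rate`.
#' @export
marker_stats <- function(panel) {
  d <- panel$dosage
  n <- colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  tibble(
    marker_id = colnames(d),
    maf = pmin(p, 1 - p),
    het_rate = colMeans(d == 1L, na.rm = TRUE),
    missing_rate = 1 - n / nrow(d)
  )
}
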