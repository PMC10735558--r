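#' Read and write HapMap-style genotype tables
#'
#' The HapMap-style TSV carries one row per marker: `rs` (marker id),
#' `alleles` (`ref/alt`), `chrom`, `pos`, then one column per genotype with
#' diploid calls (`AA`, `AB`, `BB`, `NN` for missing). Dosage counts the
#' alternate (second) allele.
#'
#' @param path file path.
#' @return for `read_hapmap()`, a `wp_geno` object.
#' @export
read_hapmap <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("rs", "alleles", "chrom", "pos")
  if (!all(need %in% names(d)))
    wp_stop("HapMap table must have columns ", paste(need, collapse = ", "))
  geno_cols <- setdiff(names(d), need)
  alle <- strsplit(d$alleles, "/", fixed = TRUE)
  refs <- vapply(alle, `[`, "", 1)
  alts <- vapply(alle, `[`, "", 2)
  dosage <- vapply(geno_cols, function(g) {
    calls <- strsplit(d[[g]], "")
    vapply(seq_along(calls), function(i) {
      cc <- calls[[i]]
      if (any(cc == "N")) return(NA_integer_)
      sum(cc == alts[i])
    }, integer(1))
  }, integer(nrow(d)))
  dosage <- t(dosage)                      # genotypes x markers
  colnames(dosage) <- d$rs
  rownames(dosage) <- geno_cols
  new_wp_geno(dosage,
              tibble(marker_id = d$rs, chromosome = as.character(d$chrom),
                     position = d$pos, alleles = d$alleles))
}

#' @rdname read_hapmap
#' @param panel a `wp_geno` object.
#' @export
write_hapmap <- function(panel, path) {
  stopifnot(inherits(panel, "wp_geno"))
  alle <- strsplit(panel$map$alleles, "/", fixed = TRUE)
  refs <- vapply(alle, `[`, "", 1)
  alts <- vapply(alle, `[`, "", 2)
  calls <- apply(panel$dosage, 1, function(x) {
    out <- character(length(x))
    out[is.na(x)] <- "NN"
    out[!is.na(x) & x == 0] <- paste0(refs, refs)[!is.na(x) & x == 0]
    out[!is.na(x) & x == 1] <- paste0(refs, alts)[!is.na(x) & x == 1]
    out[!is.na(x) & x == 2] <- paste0(alts, alts)[!is.na(x) & x == 2]
    out
  })
  tab <- bind_cols(
    tibble(rs = panel$map$marker_id, alleles = panel$map$alleles,
           chrom = panel$map$chromosome, pos = panel$map$position),
    as_tibble(calls, .name_repair = "minimal")
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read a biallelic VCF into a dosage panel
#'
#' Extracts GT calls from a VCF (plain or gzipped) and converts them to
#' alternate-allele dosages; multi-allelic sites are dropped with a message.
#'
#' @param path VCF file path.
#' @return a `wp_geno` object.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT %||% "")
  if (!all(biallelic))
    wp_note("read_genotypes_vcf: dropped ", sum(!biallelic),
            " multi-allelic site(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  count_alt <- function(x) {
    ifelse(is.na(x), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) if (any(a == ".")) NA_integer_
                              else sum(a == "1"), integer(1)))
  }
  dosage <- t(apply(gt, 2, count_alt))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[
    is.na(ids) | ids == "."]
  colnames(dosage) <- ids
  new_wp_geno(dosage,
              tibble(marker_id = ids, chromosome = fix$CHROM,
                     position = as.numeric(fix$POS),
                     alleles = paste0(fix$REF, "/", fix$ALT)))
}

#' Write a dosage panel as a minimal VCF text file
#'
#' @param panel `wp_geno` object.
#' @param path output path (plain text).
#' @export
write_genotypes_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "wp_geno"))
  alle <- strsplit(panel$map$alleles, "/", fixed = TRUE)
  refs <- vapply(alle, `[`, "A", 1)
  alts <- vapply(alle, `[`, "B", 2)
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(panel$map)), function(i) {
    calls <- panel$dosage[, i]
    gt <- ifelse(is.na(calls), "./.", gt_of[as.character(calls)])
    paste(c(panel$map$chromosome[i], panel$map$position[i],
            panel$map$marker_id[i], refs[i], alts[i], ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(panel$dosage)),
                    collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a simulated study to disk
#'
#' Emits the plot phenotypes and climate tables as CSV, the genotypes as a
#' HapMap-style TSV (and optionally VCF), and the simulation truth as JSON.
#'
#' @param sim a `wp_sim` object.
#' @param dir output directory (created if needed).
#' @param vcf also write a VCF copy of the genotypes.
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, dir, vcf = FALSE) {
  stopifnot(inherits(sim, "wp_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(sim$plots, file.path(dir, "plots.csv"))
  readr::write_csv(sim$climate, file.path(dir, "climate.csv"))
  readr::write_csv(sim$environments, file.path(dir, "environments.csv"))
  write_hapmap(sim$genotypes, file.path(dir, "genotypes.hmp.txt"))
  if (vcf) write_genotypes_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  truth <- sim$truth
  truth$genotype_effects <- as.list(truth$genotype_effects)
  truth$environment_effects <- as.list(truth$environment_effects)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
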