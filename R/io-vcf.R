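# VCF plumbing. Reading goes through vcfR; writing is a minimal VCF 4.2 text
# writer sufficient for round-tripping the package's own containers.

vcf_variants_from_vcfr <- function(vcf) {
  fix <- vcf@fix
  id <- fix[, "ID"]
  blank <- is.na(id) | id == "." | id == ""
  id[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  v <- tibble(
    id = as.character(id),
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    alleleA = as.character(fix[, "REF"]),
    alleleB = as.character(fix[, "ALT"])
  )
  if (any(grepl(",", v$alleleB)))
    abort("multiallelic records are not supported; split them first")
  assert_variant_tbl(v)
  v
}

#' Read a phased haplotype panel from a VCF file
#'
#' Every GT must be phased (`|` separator) and non-missing; the first
#' offending record is named otherwise. Haplotypes are stored as two
#' consecutive rows per sample in VCF sample order.
#'
#' @param path Path to a VCF (optionally gzipped) with phased GT fields.
#' @return A [haplotype_panel()].
#' @export
read_panel_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) abort("empty VCF: no variant records")
  v <- vcf_variants_from_vcfr(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) abort("VCF has no sample genotypes")
  bad <- which(is.na(gt) | !grepl("^[01]\\|[01]$", gt), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]
    abort(paste0("unphased input: record ", v$id[i], " (", v$chrom[i], ":",
                 v$pos[i], ") has unphased or missing GT; phased '0|1'-style ",
                 "genotypes are required"))
  }
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  n <- ncol(gt)
  haps <- matrix(0L, nrow = 2L * n, ncol = nrow(v))
  haps[seq(1L, 2L * n, 2L), ] <- t(a1)
  haps[seq(2L, 2L * n, 2L), ] <- t(a2)
  haplotype_panel(v, colnames(gt), haps)
}

write_vcf_body <- function(variants, sample_ids, gt_strings, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=tagarray",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  ), con)
  body <- paste(variants$chrom, variants$pos, variants$id,
                variants$alleleA, variants$alleleB, ".", "PASS", ".", "GT",
                sep = "\t")
  writeLines(paste(body, gt_strings, sep = "\t"), con)
  invisible(path)
}

#' Write a haplotype panel to a phased VCF
#'
#' @param panel A `haplotype_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- length(panel$sample_ids)
  h1 <- panel$haplotypes[seq(1L, 2L * n, 2L), , drop = FALSE]
  h2 <- panel$haplotypes[seq(2L, 2L * n, 2L), , drop = FALSE]
  gt <- matrix(paste0(h1, "|", h2), nrow = n)  # samples x variants
  gt_strings <- apply(gt, 2, paste, collapse = "\t")
  write_vcf_body(panel$variants, panel$sample_ids, gt_strings, path)
}

#' Read hard-call genotypes from a VCF or TSV file
#'
#' VCF GT fields may be phased or unphased; `./.` (or `.|.`) maps to the
#' missing code. The TSV layout is the one written by
#' [write_genotypes_tsv()]: variant columns `id`, `chrom`, `pos`, `alleleA`,
#' `alleleB` followed by one column per sample holding 0/1/2/NA counts of
#' alleleB.
#'
#' @param path Input path; format is inferred from the `.vcf`/`.vcf.gz`
#'   extension (anything else is read as TSV).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_genotypes_vcf(path)
  else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) abort("empty VCF: no variant records")
  v <- vcf_variants_from_vcfr(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) abort("VCF has no sample genotypes")
  core <- sub("^([.01])[/|]([.01])$", "\\1\\2", gt)
  ok <- is.na(gt) | core %in% c("00", "01", "10", "11", "..")
  if (!all(ok)) {
    i <- which(!ok, arr.ind = TRUE)[1, 1]
    abort(paste0("unsupported GT at record ", v$id[i]))
  }
  calls <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  calls[core == "00"] <- 0L
  calls[core %in% c("01", "10")] <- 1L
  calls[core == "11"] <- 2L
  genotype_matrix(v, colnames(gt), t(calls))
}

read_genotypes_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(d) == 0) abort("empty genotype file")
  need <- c("id", "chrom", "pos", "alleleA", "alleleB")
  if (!all(need %in% names(d)))
    abort(paste0("genotype TSV must have columns ",
                 paste(need, collapse = ", "), " then one column per sample"))
  samp <- setdiff(names(d), need)
  if (length(samp) == 0) abort("genotype TSV has no sample columns")
  calls <- t(as.matrix(d[, samp]))
  genotype_matrix(variant_tbl(d$id, d$chrom, d$pos, d$alleleA, d$alleleB),
                  samp, calls)
}

#' Write hard-call genotypes to TSV
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- dplyr::bind_cols(geno$variants,
                        as_tibble(t(geno$calls), .name_repair = "minimal"))
  names(d) <- c(names(geno$variants), geno$sample_ids)
  readr::write_tsv(d, path, progress = FALSE)
  invisible(path)
}

#' Write hard-call genotypes to VCF (unphased)
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = length(geno$sample_ids), ncol = nrow(geno$variants))
  ok <- !is.na(geno$calls)
  gt[ok] <- codes[geno$calls[ok] + 1L]
  gt_strings <- apply(gt, 2, paste, collapse = "\t")
  write_vcf_body(geno$variants, geno$sample_ids, gt_strings, path)
}
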