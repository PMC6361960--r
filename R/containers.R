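#' Phased haplotype panel
#'
#' The LD substrate for tagging, imputation and coverage. Rows of
#' `haplotypes` are phased haplotypes (two consecutive rows per sample, in
#' `sample_ids` order), columns are variants; entries are 0 (alleleA) or 1
#' (alleleB) with no missingness.
#'
#' @param variants A variant table (see [variant_tbl()]), ordered by
#'   (chrom, pos).
#' @param sample_ids Character vector of sample identifiers.
#' @param haplotypes Integer/numeric matrix in \{0,1\}, `2 * length(sample_ids)`
#'   rows and `nrow(variants)` columns.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(variants, sample_ids, haplotypes) {
  assert_variant_tbl(variants)
  haplotypes <- as.matrix(haplotypes)
  sample_ids <- as.character(sample_ids)
  if (nrow(haplotypes) != 2L * length(sample_ids))
    abort("haplotype row count must equal 2 * number of samples")
  if (ncol(haplotypes) != nrow(variants))
    abort("haplotype column count must equal variant count")
  if (anyNA(haplotypes)) abort("haplotype panel must have no missing entries")
  if (!all(haplotypes %in% c(0, 1)))
    abort("haplotype entries must be 0 or 1")
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids")
  if (is.unsorted(order(variants$chrom, variants$pos), strictly = FALSE)) {
    o <- order(variants$chrom, variants$pos)
    variants <- variants[o, , drop = FALSE]
    haplotypes <- haplotypes[, o, drop = FALSE]
  }
  storage.mode(haplotypes) <- "integer"
  colnames(haplotypes) <- variants$id
  structure(list(variants = as_tibble(variants), sample_ids = sample_ids,
                 haplotypes = haplotypes),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes (%d samples) x %d variants\n",
              nrow(x$haplotypes), length(x$sample_ids), nrow(x$variants)))
  invisible(x)
}

#' Alternate-allele frequencies of a panel
#'
#' @param panel A `haplotype_panel`.
#' @return Numeric vector (one per variant) of alleleB frequencies in [0,1].
#' @export
panel_freqs <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  colMeans(panel$haplotypes)
}

#' Minor allele frequencies of a panel
#'
#' @param panel A `haplotype_panel`.
#' @return Numeric vector of `min(p, 1 - p)` per variant.
#' @export
panel_maf <- function(panel) {
  p <- panel_freqs(panel)
  pmin(p, 1 - p)
}

#' Subset a panel by variants and/or samples
#'
#' @param panel A `haplotype_panel`.
#' @param variant_ids Variant ids to keep (default all), in panel order.
#' @param sample_ids Sample ids to keep (default all).
#' @return A `haplotype_panel`.
#' @export
subset_panel <- function(panel, variant_ids = NULL, sample_ids = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  vi <- if (is.null(variant_ids)) seq_len(nrow(panel$variants)) else {
    idx <- match(variant_ids, panel$variants$id)
    if (anyNA(idx)) abort("unknown variant id(s) in subset_panel()")
    sort(idx)
  }
  si <- if (is.null(sample_ids)) seq_along(panel$sample_ids) else {
    idx <- match(sample_ids, panel$sample_ids)
    if (anyNA(idx)) abort("unknown sample id(s) in subset_panel()")
    idx
  }
  hrows <- as.vector(rbind(2L * si - 1L, 2L * si))
  haplotype_panel(panel$variants[vi, , drop = FALSE],
                  panel$sample_ids[si],
                  panel$haplotypes[hrows, vi, drop = FALSE])
}

#' Hard-call genotypes implied by a phased panel
#'
#' Sums each sample's two haplotypes; no error or missingness is introduced
#' (see [simulate_genotyping()] for a platform error model).
#'
#' @param panel A `haplotype_panel`.
#' @return A `genotype_matrix`.
#' @export
panel_genotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- length(panel$sample_ids)
  h <- panel$haplotypes
  calls <- h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  genotype_matrix(panel$variants, panel$sample_ids, calls)
}

#' Hard-call genotype matrix
#'
#' Per sample x variant counts of alleleB in \{0,1,2\}; missing calls are `NA`
#' (a distinct sentinel, never conflated with 0).
#'
#' @param variants A variant table.
#' @param sample_ids Character vector of sample identifiers.
#' @param calls Matrix, samples x variants, entries in \{0,1,2,NA\}.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, sample_ids, calls) {
  assert_variant_tbl(variants)
  calls <- as.matrix(calls)
  sample_ids <- as.character(sample_ids)
  if (nrow(calls) != length(sample_ids))
    abort("call row count must equal number of samples")
  if (ncol(calls) != nrow(variants))
    abort("call column count must equal variant count")
  if (!all(calls %in% c(0, 1, 2) | is.na(calls)))
    abort("genotype calls must be 0, 1, 2 or NA")
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids")
  storage.mode(calls) <- "integer"
  rownames(calls) <- sample_ids
  colnames(calls) <- variants$id
  structure(list(variants = as_tibble(variants), sample_ids = sample_ids,
                 calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (call rate %.3f)\n",
              length(x$sample_ids), nrow(x$variants),
              mean(!is.na(x$calls))))
  invisible(x)
}

#' Per-variant call rate
#'
#' @param geno A `genotype_matrix`.
#' @return Numeric vector: non-missing fraction per variant.
#' @export
call_rate <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  colMeans(!is.na(geno$calls))
}

#' Per-variant alternate-allele frequency from hard calls
#'
#' Frequencies use non-missing denominators.
#'
#' @param geno A `genotype_matrix`.
#' @return Numeric vector of alleleB frequencies (NaN where all calls missing).
#' @export
geno_freqs <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  colMeans(geno$calls, na.rm = TRUE) / 2
}

#' Imputation posterior matrix
#'
#' Per sample x variant genotype posteriors (p0, p1, p2); each triple is
#' non-negative and sums to 1 within 1e-6.
#'
#' @param variants A variant table.
#' @param sample_ids Character vector of sample identifiers.
#' @param p0,p1,p2 Matrices (samples x variants) of posterior probabilities
#'   for genotypes 0, 1 and 2 copies of alleleB.
#' @param typed Optional logical vector marking directly typed variants.
#' @return An object of class `posterior_matrix`.
#' @export
posterior_matrix <- function(variants, sample_ids, p0, p1, p2, typed = NULL) {
  assert_variant_tbl(variants)
  sample_ids <- as.character(sample_ids)
  p0 <- as.matrix(p0); p1 <- as.matrix(p1); p2 <- as.matrix(p2)
  dims <- c(length(sample_ids), nrow(variants))
  for (m in list(p0, p1, p2)) {
    if (!identical(dim(m), as.integer(dims)))
      abort("posterior matrices must be samples x variants")
    if (anyNA(m) || any(m < 0)) abort("malformed posterior triple")
  }
  tot <- p0 + p1 + p2
  if (any(abs(tot - 1) > 1e-6)) abort("posterior triples must sum to 1")
  if (is.null(typed)) typed <- rep(FALSE, nrow(variants))
  structure(list(variants = as_tibble(variants), sample_ids = sample_ids,
                 p0 = p0, p1 = p1, p2 = p2, typed = typed),
            class = "posterior_matrix")
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat(sprintf("<posterior_matrix> %d samples x %d variants (%d typed)\n",
              length(x$sample_ids), nrow(x$variants), sum(x$typed)))
  invisible(x)
}

#' Expected alternate-allele dosages from posteriors
#'
#' @param post A `posterior_matrix`.
#' @return Matrix (samples x variants) of expected dosages in [0,2].
#' @export
posterior_dosage <- function(post) {
  stopifnot(inherits(post, "posterior_matrix"))
  post$p1 + 2 * post$p2
}

#' Most-likely genotypes from posteriors
#'
#' Ties break toward the smaller genotype.
#'
#' @param post A `posterior_matrix`.
#' @return A `genotype_matrix` of posterior modes.
#' @export
posterior_hard_calls <- function(post) {
  stopifnot(inherits(post, "posterior_matrix"))
  g <- (post$p1 > post$p0 & post$p1 >= post$p2) * 1L +
    (post$p2 > post$p0 & post$p2 > post$p1) * 2L
  genotype_matrix(post$variants, post$sample_ids, g)
}
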