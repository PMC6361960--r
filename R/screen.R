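# Variant-level QC and the validation filters that decide which candidates
# are eligible for array content.

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the allele totals, the P value is the sum of
#' probabilities of every heterozygote count no more probable than the
#' observed one under the exact conditional distribution
#' \deqn{P(n_{Aa}) = \frac{n!\,2^{n_{Aa}}\,n_A!\,n_a!}{n_{AA}!\,n_{Aa}!\,n_{aa}!\,(2n)!}.}
#' No mid-p correction is applied. Monomorphic samples return 1 (the single
#' attainable configuration).
#'
#' @param nAA,nAa,naa Genotype counts (non-negative, total > 0).
#' @return P value in (0, 1].
#' @export
hwe_exact_test <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) abort("genotype counts must be >= 0")
  n <- nAA + nAa + naa
  if (n == 0) abort("total genotype count must be > 0")
  nA <- 2L * nAA + nAa
  na <- 2L * naa + nAa
  if (nA == 0 || na == 0) return(1)
  # attainable heterozygote counts share the parity of the minor allele total
  nmin <- min(nA, na)
  hets <- seq.int(nmin %% 2L, nmin, by = 2L)
  logp <- lfactorial(n) + hets * log(2) + lfactorial(nA) + lfactorial(na) -
    lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) - lfactorial(2L * n)
  prob <- exp(logp)
  obs <- prob[match(nAa, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Per-variant QC filter
#'
#' A variant is removed iff its call rate is below `callrate_min`, its HWE
#' exact-test P is below `hwe_p_min`, or its frequency is too low:
#' MAF below `maf_min` by default, or minor allele count below `mac_min` when
#' `use_mac = TRUE` (the exome-style rule for rare-variant content).
#' Every violated rule is listed in `fail_reasons`.
#'
#' @param geno A `genotype_matrix`.
#' @param cfg A [threshold_config()].
#' @param use_mac Use the MAC rule instead of the MAF rule.
#' @return A tibble of class `qc_report`: `id`, `call_rate`, `maf`, `mac`,
#'   `hwe_p`, `pass`, `fail_reasons` (list-column).
#' @export
qc_filter <- function(geno, cfg = threshold_config(), use_mac = FALSE) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(cfg, "threshold_config"))
  if (nrow(geno$variants) == 0 || length(geno$sample_ids) == 0)
    abort("empty genotype matrix")
  calls <- geno$calls
  cr <- colMeans(!is.na(calls))
  n2 <- colSums(calls == 2L, na.rm = TRUE)
  n1 <- colSums(calls == 1L, na.rm = TRUE)
  n0 <- colSums(calls == 0L, na.rm = TRUE)
  altc <- 2L * n2 + n1
  refc <- 2L * n0 + n1
  tot <- altc + refc
  maf <- ifelse(tot > 0, pmin(altc, refc) / tot, NaN)
  mac <- pmin(altc, refc)
  hwe <- vapply(seq_along(cr), function(j) {
    if (tot[j] == 0) return(NA_real_)
    hwe_exact_test(n0[j], n1[j], n2[j])
  }, numeric(1))
  reasons <- lapply(seq_along(cr), function(j) {
    r <- character(0)
    if (cr[j] < cfg$callrate_min) r <- c(r, "call_rate")
    if (is.na(hwe[j]) || hwe[j] < cfg$hwe_p_min) r <- c(r, "hwe")
    if (use_mac) {
      if (mac[j] < cfg$mac_min) r <- c(r, "mac")
    } else if (is.nan(maf[j]) || maf[j] < cfg$maf_min) r <- c(r, "maf")
    r
  })
  out <- tibble(id = geno$variants$id, call_rate = cr, maf = maf,
                mac = as.integer(mac), hwe_p = hwe,
                pass = lengths(reasons) == 0, fail_reasons = reasons)
  class(out) <- c("qc_report", class(out))
  out
}

#' Dosage r-squared
#'
#' Squared Pearson correlation between dosages (continuous, 0--2) and true
#' genotypes (0/1/2). Pairs with a missing value on either side are dropped.
#' The statistic is sign-blind: a perfectly allele-flipped assay scores 1.
#'
#' @param dosages Numeric vector in [0, 2].
#' @param truth Integer genotype vector (0/1/2, NA allowed).
#' @return r-squared in [0, 1].
#' @export
dosage_r2 <- function(dosages, truth) {
  if (length(dosages) != length(truth))
    abort("dosages and truth must have equal length")
  keep <- !is.na(dosages) & !is.na(truth)
  x <- dosages[keep]; y <- truth[keep]
  if (length(x) < 2) abort("need >= 2 complete pairs for dosage r2")
  if (sd(x) == 0 || sd(y) == 0)
    abort("undefined correlation: constant vector in dosage r2")
  cor(x, y)^2
}

#' Per-variant Fst between two platforms' call sets
#'
#' Treats the two call sets as two populations. The default Nei estimator
#' uses unweighted expected heterozygosities: `HS = mean(2 p (1 - p))` over
#' the two sets, `HT = 2 pbar (1 - pbar)` with `pbar = (pA + pB) / 2`, and
#' `Fst = (HT - HS) / HT` (0 when `HT = 0`). The Weir-Cockerham two-level
#' estimator (sample-size weighted, from genotype counts) is available as an
#' alternative. Variants are matched by the order-insensitive identity key;
#' frequencies use non-missing denominators.
#'
#' @param genoA,genoB `genotype_matrix` objects sharing variants.
#' @param method `"nei"` (default) or `"wc"`.
#' @return A tibble: `id`, `chrom`, `pos`, `pA`, `pB`, `fst`.
#' @export
platform_fst <- function(genoA, genoB, method = c("nei", "wc")) {
  stopifnot(inherits(genoA, "genotype_matrix"),
            inherits(genoB, "genotype_matrix"))
  method <- match.arg(method)
  keyA <- variant_key(genoA$variants)
  keyB <- variant_key(genoB$variants)
  shared <- intersect(keyA, keyB)
  if (length(shared) == 0) abort("no shared variants between platforms")
  ia <- match(shared, keyA); ib <- match(shared, keyB)
  ca <- genoA$calls[, ia, drop = FALSE]
  cb <- genoB$calls[, ib, drop = FALSE]
  nA <- colSums(!is.na(ca)); nB <- colSums(!is.na(cb))
  if (any(nA == 0) || any(nB == 0))
    abort("each platform needs >= 1 non-missing call per shared variant")
  pA <- colMeans(ca, na.rm = TRUE) / 2
  pB <- colMeans(cb, na.rm = TRUE) / 2
  if (method == "nei") {
    hs <- (2 * pA * (1 - pA) + 2 * pB * (1 - pB)) / 2
    pbar <- (pA + pB) / 2
    ht <- 2 * pbar * (1 - pbar)
    fst <- ifelse(ht == 0, 0, (ht - hs) / ht)
  } else {
    fst <- wc_fst(pA, pB, nA, nB,
                  colMeans(ca == 1L, na.rm = TRUE),
                  colMeans(cb == 1L, na.rm = TRUE))
  }
  tibble(id = genoA$variants$id[ia],
         chrom = genoA$variants$chrom[ia],
         pos = genoA$variants$pos[ia],
         pA = unname(pA), pB = unname(pB), fst = unname(fst))
}

# Weir & Cockerham (1984) theta-hat for two populations at one biallelic
# locus, from allele frequencies, sample sizes and heterozygote fractions.
wc_fst <- function(p1, p2, n1, n2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  ifelse(a + b + cc == 0, 0, a / (a + b + cc))
}

#' Validate candidate variants against a truth platform
#'
#' Computes per-variant dosage r-squared (screening-array hard calls used as
#' dosages) and cross-platform Fst between the screening and truth call sets,
#' over the samples genotyped on both. A variant is validated iff
#' `r2 >= dosage_r2_min` AND `fst <= fst_max` (both thresholds inclusive).
#' Variants whose correlation is undefined (a constant side) are reported
#' with `dosage_r2 = NA` and fail validation.
#'
#' @param screen_geno Screening-platform `genotype_matrix`.
#' @param truth_geno Truth-platform `genotype_matrix` (e.g. sequencing).
#' @param cfg A [threshold_config()].
#' @return A tibble of class `validation_report`: `id`, `chrom`, `pos`,
#'   `alleleA`, `alleleB`, `dosage_r2`, `fst`, `validated`.
#' @export
validate_variants <- function(screen_geno, truth_geno,
                              cfg = threshold_config()) {
  stopifnot(inherits(screen_geno, "genotype_matrix"),
            inherits(truth_geno, "genotype_matrix"),
            inherits(cfg, "threshold_config"))
  samp <- intersect(screen_geno$sample_ids, truth_geno$sample_ids)
  if (length(samp) == 0) abort("sample sets are disjoint across platforms")
  keyS <- variant_key(screen_geno$variants)
  keyT <- variant_key(truth_geno$variants)
  shared <- intersect(keyS, keyT)
  if (length(shared) == 0) abort("no shared variants between platforms")
  is_ <- match(shared, keyS); it <- match(shared, keyT)
  cs <- screen_geno$calls[match(samp, screen_geno$sample_ids), is_, drop = FALSE]
  ct <- truth_geno$calls[match(samp, truth_geno$sample_ids), it, drop = FALSE]
  r2 <- vapply(seq_along(shared), function(j) {
    ok <- !is.na(cs[, j]) & !is.na(ct[, j])
    if (sum(ok) < 2) return(NA_real_)
    x <- cs[ok, j]; y <- ct[ok, j]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)^2
  }, numeric(1))
  vs <- screen_geno$variants[is_, , drop = FALSE]
  gs <- genotype_matrix(vs, samp, cs)
  gt <- genotype_matrix(truth_geno$variants[it, , drop = FALSE], samp, ct)
  fst <- platform_fst(gs, gt)$fst
  out <- dplyr::bind_cols(
    vs,
    tibble(dosage_r2 = r2, fst = fst,
           validated = !is.na(r2) & r2 >= cfg$dosage_r2_min &
             fst <= cfg$fst_max)
  )
  class(out) <- c("validation_report", class(out))
  out
}

#' Strand-ambiguity inclusion policy
#'
#' A/T and C/G allele pairs cannot be strand-resolved on an array and are
#' excluded from content unless one of the exceptions holds: the variant is
#' an indispensable tagging variant, a nonsynonymous SNP with design-
#' population MAF at or above `func_maf_common` (0.1%), or a member of a
#' previously known interest list. Non-ambiguous variants are always kept.
#'
#' @param alleleA,alleleB The variant's alleles.
#' @param categories Character vector of candidate categories for the variant
#'   (`tag`, `functional`, `interest:<name>`).
#' @param nonsynonymous Is the variant annotated nonsynonymous?
#' @param maf Design-population MAF (used only for the nonsynonymous clause).
#' @param indispensable_tag Is it a tag whose removal would strand some
#'   target without a substitute?
#' @param cfg A [threshold_config()].
#' @return `TRUE` to keep, `FALSE` to exclude.
#' @export
ambiguity_policy <- function(alleleA, alleleB, categories = character(0),
                             nonsynonymous = FALSE, maf = NA_real_,
                             indispensable_tag = FALSE,
                             cfg = threshold_config()) {
  if (!is_ambiguous_pair(alleleA, alleleB)) return(TRUE)
  if (isTRUE(indispensable_tag)) return(TRUE)
  if (isTRUE(nonsynonymous) && !is.na(maf) && maf >= cfg$func_maf_common)
    return(TRUE)
  any(grepl("^interest:", categories))
}
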