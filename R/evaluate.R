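# Array evaluation: haplotype-copying imputation, info scores, genomic
# coverage, concordance, and cross-array content comparison.

#' Haplotype-copying genotype imputation
#'
#' A minimal Li-Stephens hidden Markov model. Each target haplotype is
#' modelled as a mosaic copy of the reference haplotypes: the hidden state at
#' every reference site is the haplotype being copied; between adjacent sites
#' at distance `d` bp the chain switches to a uniformly chosen haplotype with
#' probability `1 - exp(-rho_per_bp * d)`; at typed sites the observed target
#' allele mismatches the copied allele with probability `eps`; untyped sites
#' emit nothing. Forward-backward posteriors over the copied haplotype give,
#' at every reference site, the probability that the target haplotype carries
#' the alternate allele; the two haplotypes of a sample run as independent
#' chains (targets are phased by construction in this toolkit) and their
#' allele posteriors convolve into the genotype triple (p0, p1, p2).
#'
#' @param ref Reference `haplotype_panel` (>= 2 haplotypes).
#' @param typed Target `haplotype_panel` observed at the typed (array)
#'   variants only; its variants must be a subset of `ref`'s by identity key.
#' @param rho_per_bp Per-bp switch rate (> 0); default 1e-6.
#' @param eps Allele mismatch probability in (0, 0.5); default 1e-3.
#' @return A [posterior_matrix()] over all `ref` variants, with `typed`
#'   marking the array sites.
#' @export
ls_impute <- function(ref, typed, rho_per_bp = 1e-6, eps = 1e-3) {
  stopifnot(inherits(ref, "haplotype_panel"),
            inherits(typed, "haplotype_panel"))
  if (rho_per_bp <= 0) abort("rho_per_bp must be > 0")
  if (eps <= 0 || eps >= 0.5) abort("eps must lie in (0, 0.5)")
  K <- nrow(ref$haplotypes)
  if (K < 2) abort("reference panel needs >= 2 haplotypes")
  key_ref <- variant_key(ref$variants)
  key_typ <- variant_key(typed$variants)
  tix <- match(key_typ, key_ref)
  if (anyNA(tix)) abort("typed variants must be a subset of the reference")
  # align typed allele coding with the reference orientation
  flip <- typed$variants$alleleB[order(tix)] !=
    ref$variants$alleleB[sort(tix)]
  obs_typed <- typed$haplotypes[, order(tix), drop = FALSE]
  if (any(flip)) obs_typed[, flip] <- 1L - obs_typed[, flip]
  S <- nrow(ref$variants)
  C <- nrow(typed$haplotypes)
  obs <- matrix(NA_integer_, nrow = C, ncol = S)
  obs[, sort(tix)] <- obs_typed
  A <- t(ref$haplotypes)                      # S x K copied alleles
  d <- diff(ref$variants$pos)
  same_chrom <- ref$variants$chrom[-1] == ref$variants$chrom[-S]
  r <- ifelse(same_chrom, 1 - exp(-rho_per_bp * pmax(d, 0)), 1)
  q <- matrix(0, nrow = C, ncol = S)          # P(copied allele = 1)
  for (ch in seq_len(C)) {
    o <- obs[ch, ]
    emis <- function(j) {
      if (is.na(o[j])) rep(1, K) else eps + (1 - 2 * eps) * (A[j, ] == o[j])
    }
    alpha <- matrix(0, nrow = K, ncol = S)
    a <- rep(1 / K, K) * emis(1)
    alpha[, 1] <- a / sum(a)
    if (S == 1) {
      q[ch, 1] <- sum(alpha[, 1] * A[1, ])
      next
    }
    for (j in 2:S) {
      a <- ((1 - r[j - 1]) * alpha[, j - 1] + r[j - 1] / K) * emis(j)
      alpha[, j] <- a / sum(a)
    }
    b <- rep(1, K)
    post <- alpha[, S]
    q[ch, S] <- sum(post * A[S, ]) / sum(post)
    for (j in (S - 1):1) {
      eb <- emis(j + 1) * b
      b <- (1 - r[j]) * eb + r[j] * mean(eb)
      b <- b / sum(b)
      post <- alpha[, j] * b
      q[ch, j] <- sum(post * A[j, ]) / sum(post)
    }
  }
  n <- C / 2
  q1 <- q[seq(1, C, 2), , drop = FALSE]
  q2 <- q[seq(2, C, 2), , drop = FALSE]
  posterior_matrix(ref$variants, typed$sample_ids,
                   p0 = (1 - q1) * (1 - q2),
                   p1 = q1 * (1 - q2) + (1 - q1) * q2,
                   p2 = q1 * q2,
                   typed = seq_len(S) %in% tix)
}

#' IMPUTE-style info score
#'
#' Compares the observed variance of imputed dosages with its binomial
#' expectation. With per-sample `e = p1 + 2 p2`, `f = p1 + 4 p2` and
#' `theta = sum(e) / 2N`:
#' `info = 1 - sum(f - e^2) / (2 N theta (1 - theta))`,
#' and 1 by convention when `theta` is 0 or 1. Hard calls give 1; posteriors
#' equal to the Hardy-Weinberg genotype distribution carry no information and
#' give 0. Values below 0 are possible and reported unclamped.
#'
#' @param post A `posterior_matrix`.
#' @return Named numeric vector of info scores, one per variant.
#' @export
info_scores <- function(post) {
  stopifnot(inherits(post, "posterior_matrix"))
  e <- post$p1 + 2 * post$p2
  f <- post$p1 + 4 * post$p2
  n <- length(post$sample_ids)
  theta <- colSums(e) / (2 * n)
  num <- colSums(f - e^2)
  info <- ifelse(theta <= 0 | theta >= 1, 1,
                 1 - num / (2 * n * theta * (1 - theta)))
  setNames(info, post$variants$id)
}

#' @rdname info_scores
#' @param variant A variant id present in `post`.
#' @export
info_score <- function(post, variant) {
  s <- info_scores(post)
  if (!variant %in% names(s)) abort("unknown variant id")
  unname(s[variant])
}

#' Imputation-based genomic coverage
#'
#' The fraction of reference variants (MAF at or above `maf_min`) captured by
#' the array: directly typed variants count as covered (info 1), untyped
#' variants count when their imputation info score is at or above
#' `info_coverage_min`. Reported overall, per MAF stratum (common: MAF >= 5%;
#' low-frequency: 1% <= MAF < 5%), and per genomic window
#' (`coverage_window_bp`-wide half-open bins from position 1; the final
#' partial bin reports its own mean).
#'
#' @param ref_variants Variant table of the reference panel.
#' @param infos Numeric vector of info scores aligned to `ref_variants`
#'   (typed variants may be NA; they are covered regardless).
#' @param mafs Numeric vector of reference MAFs aligned to `ref_variants`.
#' @param manifest An `array_manifest` (typed content).
#' @param cfg A [threshold_config()].
#' @return An object of class `coverage_report`: `overall`, `by_stratum`
#'   tibble, `by_window` tibble, `n_reference`.
#' @export
genomic_coverage <- function(ref_variants, infos, mafs, manifest,
                             cfg = threshold_config()) {
  assert_variant_tbl(ref_variants)
  stopifnot(length(infos) == nrow(ref_variants),
            length(mafs) == nrow(ref_variants))
  typed <- variant_key(ref_variants) %in% variant_key(manifest)
  denom <- mafs >= cfg$maf_min
  if (!any(denom)) abort("empty coverage denominator (no variants with MAF >= maf_min)")
  covered <- typed | (!is.na(infos) & infos >= cfg$info_coverage_min)
  v <- ref_variants[denom, , drop = FALSE]
  cov <- covered[denom]
  maf <- mafs[denom]
  stratum <- ifelse(maf >= 0.05, "common", "low_frequency")
  by_stratum <- tibble(stratum = c("common", "low_frequency")) |>
    dplyr::left_join(
      tibble(stratum = stratum, covered = cov) |>
        dplyr::group_by(.data$stratum) |>
        dplyr::summarise(n = dplyr::n(), coverage = mean(.data$covered)),
      by = "stratum")
  w <- cfg$coverage_window_bp
  by_window <- tibble(chrom = v$chrom,
                      window_start = 1 + floor((v$pos - 1) / w) * w,
                      covered = cov) |>
    dplyr::group_by(.data$chrom, .data$window_start) |>
    dplyr::summarise(n = dplyr::n(), coverage = mean(.data$covered),
                     .groups = "drop")
  structure(list(overall = mean(cov),
                 by_stratum = by_stratum,
                 by_window = by_window,
                 n_reference = sum(denom)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> overall %.2f%% of %d reference variants\n",
              100 * x$overall, x$n_reference))
  print(x$by_stratum)
  invisible(x)
}

#' Evaluate array coverage by imputation from a reference panel
#'
#' Convenience pipeline: holds out `n_target` panel samples as imputation
#' targets, types them at the manifest variants, imputes the rest of the
#' panel sites with [ls_impute()], scores every untyped variant with
#' [info_scores()], and summarises with [genomic_coverage()]. Reference MAFs
#' are taken from the remaining (reference) samples.
#'
#' @param panel Full `haplotype_panel`.
#' @param manifest An `array_manifest`.
#' @param n_target Number of panel samples to hold out as targets.
#' @param cfg A [threshold_config()].
#' @param rho_per_bp,eps [ls_impute()] parameters.
#' @return A `coverage_report`; the posterior matrix is attached as
#'   attribute `posteriors`.
#' @export
evaluate_coverage <- function(panel, manifest, n_target = 20,
                              cfg = threshold_config(),
                              rho_per_bp = 1e-6, eps = 1e-3) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (n_target >= length(panel$sample_ids))
    abort("n_target must leave at least one reference sample")
  tgt <- tail(panel$sample_ids, n_target)
  refs <- setdiff(panel$sample_ids, tgt)
  ref <- subset_panel(panel, sample_ids = refs)
  typed_ids <- intersect(panel$variants$id[
    variant_key(panel$variants) %in% variant_key(manifest)], panel$variants$id)
  if (length(typed_ids) == 0) abort("manifest shares no variants with panel")
  typed <- subset_panel(panel, variant_ids = typed_ids, sample_ids = tgt)
  post <- ls_impute(ref, typed, rho_per_bp = rho_per_bp, eps = eps)
  infos <- info_scores(post)
  rep <- genomic_coverage(ref$variants, infos, panel_maf(ref), manifest, cfg)
  attr(rep, "posteriors") <- post
  rep
}

#' Genotype concordance between two platforms
#'
#' Fraction of identical calls over shared (variant, sample) pairs with both
#' sides non-missing. Variants match by the order-insensitive identity key;
#' samples match by name or through `sample_map`. The heterozygote-restricted
#' rate (pairs where the reference side `genoB` is heterozygous) probes
#' accuracy where rare alleles live.
#'
#' @param genoA Test platform `genotype_matrix`.
#' @param genoB Reference platform `genotype_matrix`.
#' @param sample_map Optional named character vector mapping `genoA` sample
#'   ids to `genoB` sample ids (default: identical names).
#' @return An object of class `concordance_report`: `n_compared`,
#'   `n_concordant`, `rate`, `het` (same triple restricted to reference-side
#'   heterozygotes), `per_variant` tibble.
#' @export
concordance <- function(genoA, genoB, sample_map = NULL) {
  stopifnot(inherits(genoA, "genotype_matrix"),
            inherits(genoB, "genotype_matrix"))
  if (is.null(sample_map)) {
    shared <- intersect(genoA$sample_ids, genoB$sample_ids)
    sample_map <- setNames(shared, shared)
  }
  ia <- match(names(sample_map), genoA$sample_ids)
  ib <- match(unname(sample_map), genoB$sample_ids)
  if (anyNA(ia) || anyNA(ib)) abort("sample_map names unknown samples")
  if (length(ia) == 0) abort("no mapped samples")
  keyA <- variant_key(genoA$variants)
  keyB <- variant_key(genoB$variants)
  shared_v <- intersect(keyA, keyB)
  if (length(shared_v) == 0) abort("no shared variants")
  va <- match(shared_v, keyA); vb <- match(shared_v, keyB)
  ca <- genoA$calls[ia, va, drop = FALSE]
  cb <- genoB$calls[ib, vb, drop = FALSE]
  ok <- !is.na(ca) & !is.na(cb)
  if (!any(ok)) abort("zero comparable genotype pairs")
  agree <- ok & ca == cb
  het <- ok & cb == 1L
  per_variant <- tibble(
    id = genoA$variants$id[va],
    n = colSums(ok), concordant = colSums(agree),
    rate = ifelse(colSums(ok) > 0, colSums(agree) / colSums(ok), NA_real_))
  structure(list(n_compared = sum(ok), n_concordant = sum(agree),
                 rate = sum(agree) / sum(ok),
                 het = list(n_compared = sum(het),
                            n_concordant = sum(agree & het),
                            rate = if (sum(het)) sum(agree & het) / sum(het)
                                   else NA_real_),
                 per_variant = per_variant),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %.4f (%d/%d); het-only %.4f (%d/%d)\n",
              x$rate, x$n_concordant, x$n_compared,
              x$het$rate, x$het$n_concordant, x$het$n_compared))
  invisible(x)
}

#' Shared content between two array manifests
#'
#' Markers match iff chromosome, position and the unordered allele pair are
#' exactly identical; strand flips are not reconciled.
#'
#' @param manifestA,manifestB `array_manifest` objects.
#' @return A list: `count` (distinct matches) and `pairs` (tibble of matched
#'   ids from each side).
#' @export
shared_content <- function(manifestA, manifestB) {
  keyA <- variant_key(manifestA)
  keyB <- variant_key(manifestB)
  shared <- intersect(keyA, keyB)
  list(count = length(shared),
       pairs = tibble(key = shared,
                      id_A = manifestA$id[match(shared, keyA)],
                      id_B = manifestB$id[match(shared, keyB)]))
}

#' Count nonsynonymous (and population-observed damaging) manifest content
#'
#' `nonsyn` counts manifest entries annotated nonsynonymous. The second
#' count additionally requires the population's MAF to be > 0 and the chosen
#' damaging rule: `any_predictor` (at least one of SIFT / PolyPhen-2 HDIV /
#' PolyPhen-2 HVAR flags) or `more_than_one` (at least two).
#'
#' @param manifest An `array_manifest`.
#' @param annot Annotation tibble covering the manifest.
#' @param pop Population label for the `maf_<pop> > 0` requirement.
#' @param rule `"any_predictor"` or `"more_than_one"`.
#' @return A named list: `nonsyn`, `nonsyn_pop_observed_damaging`.
#' @export
count_nonsyn <- function(manifest, annot, pop,
                         rule = c("any_predictor", "more_than_one")) {
  stopifnot(inherits(manifest, "array_manifest"))
  rule <- match.arg(rule)
  validate_annotations(annot)
  ai <- match(variant_key(manifest), variant_key(annot))
  if (anyNA(ai)) abort("annotation table does not cover the manifest")
  maf <- annotation_maf(annot, pop)[ai]
  ns <- annot$consequence[ai] == "nonsynonymous"
  nflags <- rowSums(cbind(annot$sift_damaging[ai],
                          annot$polyphen_hdiv_damaging[ai],
                          annot$polyphen_hvar_damaging[ai]), na.rm = TRUE)
  need <- if (rule == "any_predictor") 1 else 2
  list(nonsyn = sum(ns),
       nonsyn_pop_observed_damaging =
         sum(ns & !is.na(maf) & maf > 0 & nflags >= need))
}
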