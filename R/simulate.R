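# Synthetic-data generators. Everything the pipeline consumes can be built
# here with known truth: a block-LD haplotype panel (founder-mosaic model),
# a drifted second population (Balding-Nichols), platform genotyping with
# error/missingness and blind duplicates, a functional annotation layer, and
# additive quantitative phenotypes.

#' Simulation configuration
#'
#' @param n_founders Number of founder haplotypes the mosaic copies from
#'   (>= 2).
#' @param n_haplotypes Number of output haplotypes (even; two per sample).
#' @param n_variants Number of variant sites.
#' @param region_bp Length of the simulated region in bp; positions are
#'   uniform, sorted, distinct within it.
#' @param switch_rate Per-bp probability rate of switching founder template
#'   between adjacent sites (in (0,1)); 1/switch_rate is the expected LD
#'   block length in bp.
#' @param maf_spectrum Function `n -> n` alternate-allele founder frequencies
#'   in (0,1); default uniform on (0.05, 0.95).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 24,
                       n_haplotypes = 200,
                       n_variants = 2000,
                       region_bp = 10e6,
                       switch_rate = 2e-6,
                       maf_spectrum = function(n) runif(n, 0.05, 0.95),
                       seed = 1L) {
  if (n_founders < 2) abort("n_founders must be >= 2")
  if (n_haplotypes %% 2 != 0) abort("n_haplotypes must be even")
  if (switch_rate <= 0 || switch_rate >= 1)
    abort("switch_rate must lie in (0, 1)")
  if (n_variants > region_bp)
    abort("n_variants cannot exceed region_bp (positions must be distinct)")
  if (!is.function(maf_spectrum)) abort("maf_spectrum must be a function")
  structure(list(n_founders = as.integer(n_founders),
                 n_haplotypes = as.integer(n_haplotypes),
                 n_variants = as.integer(n_variants),
                 region_bp = as.integer(region_bp),
                 switch_rate = switch_rate,
                 maf_spectrum = maf_spectrum,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, n, replace = TRUE)
  b <- vapply(a, function(x) sample(setdiff(bases, x), 1), character(1))
  list(a = a, b = unname(b))
}

#' Simulate a phased haplotype panel with block LD
#'
#' Founder haplotypes are drawn site-independently at frequencies from the
#' configured spectrum; each output haplotype is a founder mosaic that
#' switches template between adjacent sites with probability
#' `1 - exp(-switch_rate * distance)`. Copying long founder segments is what
#' creates LD blocks; the coalescent detail real panels carry (recombination
#' hotspots, demography, allele age) is deliberately absent.
#'
#' @param cfg A [sim_config()].
#' @param chrom Chromosome label for all variants.
#' @return A [haplotype_panel()] with samples `S1`, `S2`, ...
#' @export
simulate_panel <- function(cfg, chrom = "1") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pos <- sort(sample.int(cfg$region_bp, cfg$n_variants))
  p <- cfg$maf_spectrum(cfg$n_variants)
  if (any(p <= 0 | p >= 1)) abort("maf_spectrum must return values in (0,1)")
  founders <- matrix(rbinom(cfg$n_founders * cfg$n_variants, 1L,
                            rep(p, each = cfg$n_founders)),
                     nrow = cfg$n_founders)
  d <- diff(pos)
  switch_p <- 1 - exp(-cfg$switch_rate * d)
  haps <- matrix(0L, nrow = cfg$n_haplotypes, ncol = cfg$n_variants)
  for (h in seq_len(cfg$n_haplotypes)) {
    sw <- runif(cfg$n_variants - 1) < switch_p
    seg <- cumsum(c(1L, sw))            # segment index per site
    draws <- sample.int(cfg$n_founders, max(seg), replace = TRUE)
    tmpl <- draws[seg]
    haps[h, ] <- founders[cbind(tmpl, seq_len(cfg$n_variants))]
  }
  al <- sim_alleles(cfg$n_variants)
  v <- variant_tbl(sprintf("var%05d", seq_len(cfg$n_variants)),
                   chrom, pos, al$a, al$b)
  haplotype_panel(v, sprintf("S%04d", seq_len(cfg$n_haplotypes / 2)), haps)
}

#' Drift a panel into a diverged population
#'
#' Per-variant frequencies are redrawn from a Balding-Nichols distribution,
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, around the source frequency `p`, and
#' haplotypes are resampled site-independently at the drifted frequencies
#' (LD is not preserved; the output is a frequency-drift fixture, which is
#' all the cross-platform Fst machinery needs).
#'
#' @param panel Source `haplotype_panel`.
#' @param F Drift parameter in (0,1); the expected Fst between source and
#'   drifted frequencies.
#' @param seed Integer seed.
#' @param n_haplotypes Number of output haplotypes (default: same as source).
#' @return A `haplotype_panel` with samples `D1`, `D2`, ...
#' @export
diverge_populations <- function(panel, F, seed = 1L, n_haplotypes = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!is.numeric(F) || length(F) != 1 || F <= 0 || F >= 1)
    abort("F must lie in (0, 1)")
  set.seed(seed)
  n_h <- n_haplotypes %||% nrow(panel$haplotypes)
  p <- panel_freqs(panel)
  # Balding-Nichols; degenerate at p = 0 or 1 (stays fixed)
  shape1 <- p * (1 - F) / F
  shape2 <- (1 - p) * (1 - F) / F
  p_drift <- ifelse(p %in% c(0, 1), p, rbeta(length(p), shape1, shape2))
  haps <- matrix(rbinom(n_h * length(p), 1L, rep(p_drift, each = n_h)),
                 nrow = n_h)
  haplotype_panel(panel$variants, sprintf("D%04d", seq_len(n_h / 2)), haps)
}

#' Simulate platform genotyping with error, missingness and blind duplicates
#'
#' The true genotype of each sample is its haplotype-pair sum in `panel`.
#' Each call is independently missing with probability `missing_rate`;
#' otherwise it is perturbed to one of the two other genotype states
#' (chosen uniformly -- a symmetric error model) with probability
#' `error_rate`. Entries of `duplicate_of` create blind duplicate samples:
#' the named new sample shares the source sample's truth but gets
#' independent error/missingness draws.
#'
#' @param panel A `haplotype_panel` holding the truth.
#' @param sample_ids Samples to genotype (default: all panel samples).
#' @param error_rate,missing_rate Per-call rates in [0, 1).
#' @param duplicate_of Optional named character vector: names are new
#'   duplicate sample ids, values are existing source sample ids.
#' @param seed Integer seed.
#' @return A [genotype_matrix()] over `c(sample_ids, names(duplicate_of))`.
#' @export
simulate_genotyping <- function(panel, sample_ids = NULL, error_rate = 0,
                                missing_rate = 0, duplicate_of = NULL,
                                seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (error_rate < 0 || error_rate >= 1 || missing_rate < 0 || missing_rate >= 1)
    abort("error_rate and missing_rate must lie in [0, 1)")
  sample_ids <- sample_ids %||% panel$sample_ids
  idx <- match(sample_ids, panel$sample_ids)
  if (anyNA(idx)) abort("unknown sample id(s) in sample_ids")
  if (!is.null(duplicate_of)) {
    src <- match(unname(duplicate_of), panel$sample_ids)
    if (anyNA(src))
      abort(paste0("duplicate_of references unknown sample(s): ",
                   paste(unname(duplicate_of)[is.na(src)], collapse = ", ")))
    if (is.null(names(duplicate_of)) || any(names(duplicate_of) == ""))
      abort("duplicate_of must be a named vector (new id = source id)")
    idx <- c(idx, src)
    sample_ids <- c(sample_ids, names(duplicate_of))
  }
  set.seed(seed)
  h <- panel$haplotypes
  truth <- h[2L * idx - 1L, , drop = FALSE] + h[2L * idx, , drop = FALSE]
  calls <- truth
  nc <- length(calls)
  if (error_rate > 0) {
    err <- runif(nc) < error_rate
    if (any(err)) {
      # symmetric: jump to one of the two other genotype states
      shift <- sample(1:2, sum(err), replace = TRUE)
      calls[err] <- (calls[err] + shift) %% 3L
    }
  }
  if (missing_rate > 0) calls[runif(nc) < missing_rate] <- NA_integer_
  genotype_matrix(panel$variants, sample_ids, calls)
}

#' Simulate a functional annotation layer for a panel
#'
#' Assigns consequence classes, damaging-prediction flags for nonsynonymous
#' variants, and per-population MAF columns. The design population's MAF is
#' taken from the panel itself; other populations get drifted frequencies so
#' population-restricted counting rules are exercised (a configurable
#' fraction is zeroed, emulating population-specific variants).
#'
#' @param panel A `haplotype_panel`.
#' @param pops Character vector of population labels; the first is the
#'   design population and uses panel frequencies.
#' @param prop_nonsyn,prop_syn Expected fractions of nonsynonymous and
#'   synonymous consequences (the rest are `other`).
#' @param p_damaging Per-predictor probability that a nonsynonymous variant
#'   is flagged damaging.
#' @param p_absent Probability that a non-design population's MAF is zero.
#' @param seed Integer seed.
#' @return An annotation tibble (see [read_annotations()]).
#' @export
simulate_annotations <- function(panel, pops = c("KOR", "EAS"),
                                 prop_nonsyn = 0.25, prop_syn = 0.25,
                                 p_damaging = 0.3, p_absent = 0.15,
                                 seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  set.seed(seed)
  nv <- nrow(panel$variants)
  cons <- sample(c("nonsynonymous", "synonymous", "other"), nv, replace = TRUE,
                 prob = c(prop_nonsyn, prop_syn, 1 - prop_nonsyn - prop_syn))
  ns <- cons == "nonsynonymous"
  flag <- function() ifelse(ns, runif(nv) < p_damaging, NA)
  d <- dplyr::bind_cols(
    panel$variants,
    tibble(consequence = cons,
           sift_damaging = flag(),
           polyphen_hdiv_damaging = flag(),
           polyphen_hvar_damaging = flag())
  )
  maf <- panel_maf(panel)
  d[[paste0("maf_", pops[1])]] <- maf
  for (pop in pops[-1]) {
    drift <- maf * exp(rnorm(nv, 0, 0.5))
    drift[runif(nv) < p_absent] <- 0
    d[[paste0("maf_", pop)]] <- pmin(drift, 0.5)
  }
  validate_annotations(d)
  d
}

#' Simulate additive quantitative phenotypes
#'
#' `phenotype = sum(beta * dosage) + covariate terms + N(0, noise_sd)`.
#' Missing genotype calls contribute the variant's mean observed dosage, so
#' sporadic missingness does not shift the phenotype scale.
#'
#' @param geno A `genotype_matrix`.
#' @param effects Named numeric vector: variant id -> per-allele effect beta.
#' @param covariates Optional tibble of per-sample covariates (row order =
#'   sample order); numeric columns contribute via `covariate_effects`.
#' @param covariate_effects Named numeric vector of weights for covariate
#'   columns (default: none contribute).
#' @param noise_sd Standard deviation of the Gaussian noise (>= 0).
#' @param seed Integer seed.
#' @return A tibble with `sample_id`, `phenotype`, and any covariates.
#' @export
simulate_phenotypes <- function(geno, effects, covariates = NULL,
                                covariate_effects = NULL, noise_sd = 1,
                                seed = 1L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  miss <- setdiff(names(effects), geno$variants$id)
  if (length(miss))
    abort(paste0("effect variant(s) not in genotype matrix: ",
                 paste(miss, collapse = ", ")))
  set.seed(seed)
  n <- length(geno$sample_ids)
  y <- numeric(n)
  if (length(effects)) {
    g <- geno$calls[, names(effects), drop = FALSE]
    mu <- colMeans(g, na.rm = TRUE)
    for (k in seq_along(effects)) {
      gv <- g[, k]
      gv[is.na(gv)] <- mu[k]
      y <- y + effects[[k]] * gv
    }
  }
  if (!is.null(covariates) && !is.null(covariate_effects)) {
    for (cn in names(covariate_effects))
      y <- y + covariate_effects[[cn]] * as.numeric(covariates[[cn]])
  }
  y <- y + rnorm(n, 0, noise_sd)
  out <- tibble(sample_id = geno$sample_ids, phenotype = y)
  if (!is.null(covariates)) out <- dplyr::bind_cols(out, covariates)
  out
}
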