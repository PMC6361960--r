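# Phenotype preparation, additive association, post-imputation filtering,
# signal selection and novelty annotation for quantitative-trait GWAS.

#' LDL cholesterol by the Friedewald formula
#'
#' `LDL = TC - HDL - TG / 5` (all mg/dL). The formula is invalid at high
#' triglycerides: results are missing when TG exceeds `tg_mask` (strict, so
#' TG = 400 still computes) or when any input is missing.
#'
#' @param tc,hdl,tg Total cholesterol, HDL cholesterol and triglycerides in
#'   mg/dL (vectors recycle; values must be >= 0 or NA).
#' @param tg_mask TG ceiling in mg/dL (default 400).
#' @return Numeric vector of LDL cholesterol (mg/dL), NA where undefined.
#' @export
friedewald_ldl <- function(tc, hdl, tg, tg_mask = 400) {
  if (any(c(tc, hdl, tg) < 0, na.rm = TRUE))
    abort("lipid concentrations must be >= 0")
  ldl <- tc - hdl - tg / 5
  ldl[!is.na(tg) & tg > tg_mask] <- NA_real_
  ldl
}

#' Prepare biochemical traits for association analysis
#'
#' Recomputes LDL cholesterol with [friedewald_ldl()] (when TC/HDL/TG are
#' present), blanks lipid traits (LDLc, HDLc, TG) for samples on
#' lipid-lowering therapy and liver-enzyme traits (AST, ALT) for samples on
#' liver-affecting medication, then natural-log transforms every trait
#' except total cholesterol (TCHL), which stays on its raw scale.
#' Non-positive values reaching a log transform become missing, with a
#' warning giving the count.
#'
#' @param pheno Phenotype tibble with `sample_id`, any of the trait columns
#'   `TCHL`, `HDLc`, `TG`, `LDLc`, `AST`, `ALT`, optional logical medication
#'   flags `lipid_med`, `liver_med`, and covariates.
#' @param cfg A [threshold_config()] (uses `tg_mask_mgdl`).
#' @return A tibble with the transformed trait columns (same names),
#'   untouched covariates, and attribute `n_nonpositive` (per-trait counts
#'   of values lost to the log transform).
#' @export
prepare_traits <- function(pheno, cfg = threshold_config()) {
  stopifnot(is.data.frame(pheno), "sample_id" %in% names(pheno))
  d <- as_tibble(pheno)
  if (all(c("TCHL", "HDLc", "TG") %in% names(d)))
    d$LDLc <- friedewald_ldl(d$TCHL, d$HDLc, d$TG, tg_mask = cfg$tg_mask_mgdl)
  if (isTRUE("lipid_med" %in% names(d))) {
    on_med <- !is.na(d$lipid_med) & d$lipid_med
    for (tr in intersect(c("LDLc", "HDLc", "TG"), names(d)))
      d[[tr]][on_med] <- NA_real_
  }
  if (isTRUE("liver_med" %in% names(d))) {
    on_med <- !is.na(d$liver_med) & d$liver_med
    for (tr in intersect(c("AST", "ALT"), names(d)))
      d[[tr]][on_med] <- NA_real_
  }
  lost <- integer(0)
  for (tr in intersect(c("HDLc", "LDLc", "TG", "AST", "ALT"), names(d))) {
    bad <- !is.na(d[[tr]]) & d[[tr]] <= 0
    lost[tr] <- sum(bad)
    d[[tr]][bad] <- NA_real_
    d[[tr]] <- log(d[[tr]])
  }
  if (sum(lost) > 0)
    warn(paste0(sum(lost), " non-positive trait value(s) set missing before ",
                "log transform"))
  attr(d, "n_nonpositive") <- lost
  d
}

build_design <- function(covariates) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0)
    return(matrix(nrow = 0, ncol = 0))
  cv <- as.data.frame(covariates)
  # categorical covariates (e.g. recruitment area) one-hot, first level ref
  mm <- model.matrix(~ ., data = cv)
  mm[, -1, drop = FALSE]
}

#' Additive-model association for a single variant
#'
#' Least-squares fit of the (transformed) trait on allele dosage plus
#' covariates; categorical covariates are one-hot encoded against their
#' first level. Reports the dosage term's beta and SE with a two-sided P
#' from the t distribution at the residual degrees of freedom.
#'
#' @param dosages Per-sample dosages in [0, 2] (NA allowed).
#' @param y Trait values (NA allowed).
#' @param covariates Optional data frame of covariates (age, sex, area, ...).
#' @return A one-row tibble of class `assoc_fit`: `beta`, `se`, `p`, `eaf`,
#'   `n`; the underlying `lm` fit is attached as attribute `fit`.
#' @export
additive_assoc <- function(dosages, y, covariates = NULL) {
  n0 <- length(y)
  if (length(dosages) != n0) abort("dosages and y must have equal length")
  X <- build_design(covariates)
  df <- data.frame(y = y, dosage = dosages)
  if (nrow(X) > 0) df <- cbind(df, as.data.frame(X))
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < ncol(df) + 2)
    abort("too few complete cases for the additive model")
  fit <- lm(y ~ ., data = df)
  if (anyNA(coef(fit))) {
    drop <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("collinear design: ", paste(drop, collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  out <- tibble(beta = sm["dosage", 1], se = sm["dosage", 2],
                p = sm["dosage", 4],
                eaf = mean(df$dosage) / 2, n = nrow(df))
  attr(out, "fit") <- fit
  class(out) <- c("assoc_fit", class(out))
  out
}

#' Genome-wide additive association scan
#'
#' Runs the additive model of [additive_assoc()] across every variant of a
#' genotype matrix, vectorized: the trait and dosages are residualized
#' against the covariates once (Frisch-Waugh-Lovell), then each variant is a
#' single regression on its residualized dosage. Missing dosages are mean-
#' imputed per variant (samples with missing trait/covariates are dropped).
#'
#' @param geno A `genotype_matrix`.
#' @param pheno Tibble with `sample_id`, the trait column and covariates.
#' @param trait Name of the trait column in `pheno`.
#' @param covariates Character vector of covariate column names.
#' @return A `summary_stats` tibble: `id`, `chrom`, `pos`, `trait`, `ea`,
#'   `eaf`, `beta`, `se`, `p`, `n`.
#' @export
assoc_scan <- function(geno, pheno, trait, covariates = character(0)) {
  stopifnot(inherits(geno, "genotype_matrix"))
  idx <- match(pheno$sample_id, geno$sample_ids)
  if (anyNA(idx)) abort("phenotype samples missing from genotype matrix")
  y <- pheno[[trait]]
  X <- build_design(pheno[, covariates, drop = FALSE])
  keep <- !is.na(y) & (if (nrow(X)) complete.cases(X) else TRUE)
  y <- y[keep]
  G <- geno$calls[idx[keep], , drop = FALSE]
  storage.mode(G) <- "double"
  n <- length(y)
  # mean-impute missing dosages per variant
  mu <- colMeans(G, na.rm = TRUE)
  nas <- which(is.na(G), arr.ind = TRUE)
  if (nrow(nas)) G[nas] <- mu[nas[, 2]]
  if (nrow(X)) {
    Xf <- cbind(1, X[keep, , drop = FALSE])
  } else {
    Xf <- matrix(1, nrow = n, ncol = 1)
  }
  qX <- qr(Xf)
  ry <- qr.resid(qX, y)
  rG <- qr.resid(qX, G)
  sxx <- colSums(rG^2)
  sxy <- as.vector(crossprod(rG, ry))
  dfree <- n - ncol(Xf) - 1
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss <- sum(ry^2) - ifelse(sxx > 0, sxy^2 / sxx, 0)
  sigma2 <- rss / dfree
  se <- ifelse(sxx > 0, sqrt(sigma2 / sxx), NA_real_)
  p <- 2 * pt(abs(beta / se), df = dfree, lower.tail = FALSE)
  out <- dplyr::bind_cols(
    geno$variants[, c("id", "chrom", "pos")],
    tibble(trait = trait, ea = geno$variants$alleleB,
           eaf = unname(mu) / 2, beta = unname(beta), se = unname(se),
           p = unname(p), n = n))
  class(out) <- c("summary_stats", class(out))
  out
}

#' Post-imputation variant filter
#'
#' Drops variants with imputation info below `info_keep_min` (when an `info`
#' column is present and non-missing) or MAF below `maf_min`, where
#' `MAF = min(EAF, 1 - EAF)`. Both thresholds are inclusive on the keep
#' side: info = 0.4 and MAF = 0.01 survive.
#'
#' @param stats A `summary_stats` tibble.
#' @param cfg A [threshold_config()].
#' @return The filtered tibble (row order preserved).
#' @export
post_impute_filter <- function(stats, cfg = threshold_config()) {
  stopifnot(is.data.frame(stats))
  maf <- pmin(stats$eaf, 1 - stats$eaf)
  drop <- maf < cfg$maf_min
  if ("info" %in% names(stats))
    drop <- drop | (!is.na(stats$info) & stats$info < cfg$info_keep_min)
  stats[!drop, , drop = FALSE]
}

#' Select top association signals
#'
#' Two selection clauses over post-imputation-filtered summary statistics,
#' per trait:
#' \itemize{
#' \item leads: `P <= lead_p` (5e-8) and MAF >= `maf_min` (1%);
#' \item nonsynonymous candidates: nonsynonymous variants with
#'   `P < support_p` (1e-4) and MAF > 0 lying inside a qualifying locus. A
#'   locus is the `locus_halfwidth_bp` window centred on any variant with
#'   `P <= locus_lead_p` (5e-7); it qualifies iff it also contains at least
#'   one distinct supporting variant with `P <= support_p`.
#' }
#'
#' @param stats A `summary_stats` tibble (already through
#'   [post_impute_filter()]).
#' @param annot Optional annotation tibble; without it, a `consequence`
#'   column in `stats` is used.
#' @param cfg A [threshold_config()].
#' @param locus_halfwidth_bp Locus half-width (default: half the novelty
#'   window, i.e. 500 kb).
#' @return A list of tibbles: `leads`, `nonsyn_candidates`.
#' @export
select_signals <- function(stats, annot = NULL, cfg = threshold_config(),
                           locus_halfwidth_bp = cfg$novelty_window_bp / 2) {
  stopifnot(is.data.frame(stats))
  maf <- pmin(stats$eaf, 1 - stats$eaf)
  leads <- stats[stats$p <= cfg$lead_p & maf >= cfg$maf_min, , drop = FALSE]
  cons <- if (!is.null(annot)) {
    # match on the identity key when stats carry alleles, else on id
    m <- if (all(c("alleleA", "alleleB") %in% names(stats)))
      match(variant_key(stats), variant_key(annot))
    else match(stats$id, annot$id)
    annot$consequence[m]
  } else if ("consequence" %in% names(stats)) {
    stats$consequence
  } else rep(NA_character_, nrow(stats))
  is_ns <- !is.na(cons) & cons == "nonsynonymous"
  cand_idx <- which(is_ns & stats$p < cfg$support_p & maf > 0)
  selected <- logical(nrow(stats))
  for (k in cand_idx) {
    same <- stats$trait == stats$trait[k] & stats$chrom == stats$chrom[k]
    centers <- which(same & stats$p <= cfg$locus_lead_p &
                       abs(stats$pos - stats$pos[k]) <= locus_halfwidth_bp)
    for (ctr in centers) {
      support <- same & stats$p <= cfg$support_p &
        abs(stats$pos - stats$pos[ctr]) <= locus_halfwidth_bp &
        seq_len(nrow(stats)) != ctr
      if (any(support)) { selected[k] <- TRUE; break }
    }
  }
  list(leads = as_tibble(leads),
       nonsyn_candidates = as_tibble(stats[selected, , drop = FALSE]))
}

#' Annotate hits for novelty against a known-association catalog
#'
#' A hit is not novel iff a catalog entry for the same trait lies within the
#' centred novelty window (default 1 Mb wide, i.e. within 500 kb on either
#' side, boundary inclusive). Entries for other traits are ignored.
#'
#' @param hits Summary-stat tibble with `trait`, `chrom`, `pos`.
#' @param catalog Tibble of known signals with `trait`, `chrom`, `pos`.
#' @param cfg A [threshold_config()].
#' @return `hits` with a logical `novel` column appended.
#' @export
annotate_novelty <- function(hits, catalog, cfg = threshold_config()) {
  stopifnot(is.data.frame(hits), is.data.frame(catalog))
  half <- cfg$novelty_window_bp / 2
  hits$novel <- vapply(seq_len(nrow(hits)), function(k) {
    !any(catalog$trait == hits$trait[k] &
           catalog$chrom == hits$chrom[k] &
           abs(catalog$pos - hits$pos[k]) <= half)
  }, logical(1))
  hits
}

#' Merge discovery hits with replication results
#'
#' Joins on the variant identity key plus trait; a hit replicates iff the
#' replication P is below 0.05 and the effect direction matches.
#'
#' @param discovery,replication Summary-stat tibbles (replication needs
#'   `beta` and `p`).
#' @param alpha Replication significance threshold (default 0.05, strict).
#' @return `discovery` with `rep_beta`, `rep_p`, `replicated` appended
#'   (NA where no replication row matches).
#' @export
merge_replication <- function(discovery, replication, alpha = 0.05) {
  keyd <- paste(variant_key(discovery), discovery$trait)
  keyr <- paste(variant_key(replication), replication$trait)
  m <- match(keyd, keyr)
  discovery$rep_beta <- replication$beta[m]
  discovery$rep_p <- replication$p[m]
  discovery$replicated <- !is.na(m) & discovery$rep_p < alpha &
    sign(discovery$rep_beta) == sign(discovery$beta)
  discovery
}
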