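#' Threshold configuration
#'
#' One object holds every filter threshold the pipeline uses, so each cutoff
#' is stated (and overridable) in exactly one place. Defaults are the
#' operating points of the array-design protocol the package implements.
#'
#' @param dosage_r2_min Validation: minimum squared Pearson correlation
#'   between screening-array dosages and truth genotypes (default 0.7,
#'   inclusive).
#' @param fst_max Validation: maximum cross-platform Fst (default 0.025,
#'   inclusive).
#' @param callrate_min Variant QC: minimum genotype call rate (default 0.95;
#'   variants *below* it are removed).
#' @param hwe_p_min Variant QC: minimum Hardy-Weinberg exact-test P
#'   (default 1e-6; variants below it are removed).
#' @param maf_min Variant QC and coverage denominator: minimum minor allele
#'   frequency (default 0.01; variants below it are removed / excluded).
#' @param mac_min Exome-style QC: minimum minor allele count (default 2).
#' @param func_maf_common Functional module: MAF cutoff separating the
#'   unconditional nonsynonymous clause from the damaging-only clause
#'   (default 0.001, i.e. 0.1%).
#' @param tag_r2 LD threshold at which a target counts as tagged
#'   (default 0.8).
#' @param tag_window_bp Half-width of the window within which LD is computed
#'   and tagging credited (default 250000 bp).
#' @param info_keep_min Post-imputation filter: minimum info score
#'   (default 0.4; variants *below* it are dropped).
#' @param info_coverage_min Coverage: info score at or above which an imputed
#'   variant counts as covered (default 0.8).
#' @param coverage_window_bp Window size for per-window coverage
#'   (default 5e6 bp).
#' @param lead_p Genome-wide significance for lead signals (default 5e-8,
#'   inclusive).
#' @param locus_lead_p P threshold defining locus centers for the
#'   nonsynonymous-candidate rule (default 5e-7, inclusive).
#' @param support_p Supporting-signal threshold (default 1e-4, inclusive for
#'   support; the nonsynonymous candidate itself must be strictly below it).
#' @param novelty_window_bp Width of the novelty window centred on a hit
#'   (default 1e6 bp; a same-trait known signal within half this distance
#'   makes the hit non-novel).
#' @param tg_mask_mgdl Triglyceride level above which LDL cholesterol cannot
#'   be computed by the Friedewald formula (default 400 mg/dL, strict).
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(dosage_r2_min = 0.7,
                             fst_max = 0.025,
                             callrate_min = 0.95,
                             hwe_p_min = 1e-6,
                             maf_min = 0.01,
                             mac_min = 2,
                             func_maf_common = 0.001,
                             tag_r2 = 0.8,
                             tag_window_bp = 250000,
                             info_keep_min = 0.4,
                             info_coverage_min = 0.8,
                             coverage_window_bp = 5e6,
                             lead_p = 5e-8,
                             locus_lead_p = 5e-7,
                             support_p = 1e-4,
                             novelty_window_bp = 1e6,
                             tg_mask_mgdl = 400) {
  cfg <- list(
    dosage_r2_min = dosage_r2_min, fst_max = fst_max,
    callrate_min = callrate_min, hwe_p_min = hwe_p_min,
    maf_min = maf_min, mac_min = mac_min,
    func_maf_common = func_maf_common,
    tag_r2 = tag_r2, tag_window_bp = tag_window_bp,
    info_keep_min = info_keep_min, info_coverage_min = info_coverage_min,
    coverage_window_bp = coverage_window_bp,
    lead_p = lead_p, locus_lead_p = locus_lead_p, support_p = support_p,
    novelty_window_bp = novelty_window_bp, tg_mask_mgdl = tg_mask_mgdl
  )
  bad <- names(cfg)[!vapply(cfg, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0, logical(1))]
  if (length(bad)) abort(paste0("invalid threshold value(s): ",
                                paste(bad, collapse = ", ")))
  frac <- c("dosage_r2_min", "fst_max", "callrate_min", "maf_min",
            "func_maf_common", "tag_r2", "info_keep_min", "info_coverage_min")
  out <- frac[vapply(frac, function(f) cfg[[f]] > 1, logical(1))]
  if (length(out)) abort(paste0("threshold(s) must be in [0,1]: ",
                                paste(out, collapse = ", ")))
  structure(cfg, class = "threshold_config")
}

#' Read a threshold configuration from a YAML key-value file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path Path to a YAML file of `name: value` pairs.
#' @return A `threshold_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(threshold_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", "),
                 "; allowed: ", paste(known, collapse = ", ")))
  }
  do.call(threshold_config, vals)
}

#' Write a threshold configuration to YAML
#'
#' @param cfg A `threshold_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "threshold_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}
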