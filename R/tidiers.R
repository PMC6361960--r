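# broom-style tidy()/glance() methods for the package's result objects.

#' @exportS3Method generics::tidy
tidy.assoc_fit <- function(x, ...) {
  fit <- attr(x, "fit")
  sm <- summary(fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

#' @exportS3Method generics::glance
glance.assoc_fit <- function(x, ...) {
  fit <- attr(x, "fit")
  sm <- summary(fit)
  tibble(r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
         sigma = sm$sigma, df.residual = fit$df.residual,
         nobs = length(fit$residuals))
}

#' @exportS3Method generics::tidy
tidy.qc_report <- function(x, ...) {
  out <- as_tibble(x)
  out$fail_reasons <- vapply(x$fail_reasons, paste, character(1),
                             collapse = ";")
  out
}

#' @exportS3Method generics::glance
glance.qc_report <- function(x, ...) {
  reasons <- unlist(x$fail_reasons)
  tibble(n_variants = nrow(x), n_pass = sum(x$pass),
         n_removed = sum(!x$pass),
         n_fail_call_rate = sum(reasons == "call_rate"),
         n_fail_hwe = sum(reasons == "hwe"),
         n_fail_maf = sum(reasons == "maf"),
         n_fail_mac = sum(reasons == "mac"))
}

#' @exportS3Method generics::tidy
tidy.validation_report <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.validation_report <- function(x, ...) {
  tibble(n_variants = nrow(x), n_validated = sum(x$validated),
         mean_dosage_r2 = mean(x$dosage_r2, na.rm = TRUE),
         mean_fst = mean(x$fst, na.rm = TRUE))
}

#' @exportS3Method generics::tidy
tidy.tag_selection <- function(x, ...) x$trace

#' @exportS3Method generics::glance
glance.tag_selection <- function(x, ...) {
  tibble(n_selected = length(x$selected), n_targets = length(x$targets),
         n_covered = length(x$covered), coverage = x$coverage)
}

#' @exportS3Method generics::tidy
tidy.coverage_report <- function(x, ...) x$by_window

#' @exportS3Method generics::glance
glance.coverage_report <- function(x, ...) {
  s <- x$by_stratum
  tibble(overall = x$overall,
         common = s$coverage[s$stratum == "common"],
         low_frequency = s$coverage[s$stratum == "low_frequency"],
         n_reference = x$n_reference)
}

#' @exportS3Method generics::tidy
tidy.concordance_report <- function(x, ...) x$per_variant

#' @exportS3Method generics::glance
glance.concordance_report <- function(x, ...) {
  tibble(rate = x$rate, n_compared = x$n_compared,
         het_rate = x$het$rate, het_n_compared = x$het$n_compared)
}

#' @exportS3Method generics::tidy
tidy.array_manifest <- function(x, ...) {
  out <- as_tibble(x)
  out$categories <- vapply(x$categories, paste, character(1), collapse = ";")
  out
}

#' @exportS3Method generics::glance
glance.array_manifest <- function(x, ...) {
  cnt <- manifest_counts(x)
  out <- tibble(total = nrow(x))
  for (k in seq_len(nrow(cnt))) out[[cnt$category[k]]] <- cnt$n[k]
  out
}
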