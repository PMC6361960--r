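# Tabular readers/writers: array manifests, annotation tables, phenotype
# tables, summary statistics, known-association catalogs. All plain TSV.

manifest_category_ok <- function(x) {
  x %in% c("tag", "functional") | grepl("^interest:.+$", x)
}

#' Construct an array manifest
#'
#' The designed marker set: one row per distinct variant, a set of category
#' labels (`tag`, `functional`, `interest:<listname>`; categories may
#' overlap) and a free-text selection provenance. The total marker count is
#' the number of distinct rows, never the sum over categories.
#'
#' @param variants A variant table.
#' @param categories List-column (or list) of character vectors of category
#'   labels, one element per variant.
#' @param provenance Character vector of per-variant provenance notes.
#' @return A tibble of class `array_manifest` with columns `id`, `chrom`,
#'   `pos`, `alleleA`, `alleleB`, `categories` (list), `provenance`.
#' @export
array_manifest <- function(variants, categories, provenance = "") {
  assert_variant_tbl(variants)
  categories <- lapply(categories, as.character)
  if (length(categories) != nrow(variants))
    abort("one category set per variant is required")
  bad <- unique(unlist(categories))
  bad <- bad[!manifest_category_ok(bad)]
  if (length(bad))
    abort(paste0("unknown manifest category label(s): ",
                 paste(bad, collapse = ", "),
                 "; allowed: tag, functional, interest:<name>"))
  m <- as_tibble(variants)
  m$categories <- categories
  m$provenance <- rep_len(as.character(provenance), nrow(m))
  class(m) <- c("array_manifest", class(m))
  m
}

#' Write an array manifest to TSV
#'
#' Categories are semicolon-joined in the `categories` column.
#'
#' @param manifest An `array_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "array_manifest"))
  d <- as_tibble(manifest)
  d$categories <- vapply(manifest$categories, paste, character(1),
                         collapse = ";")
  readr::write_tsv(d[, c("id", "chrom", "pos", "alleleA", "alleleB",
                         "categories", "provenance")], path, progress = FALSE)
  invisible(path)
}

#' Read an array manifest from TSV
#'
#' @param path Path to a TSV written by [write_manifest()].
#' @return An `array_manifest`.
#' @export
read_manifest <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         alleleA = readr::col_character(),
                         alleleB = readr::col_character(),
                         provenance = readr::col_character()))
  cats <- strsplit(ifelse(is.na(d$categories), "", d$categories), ";",
                   fixed = TRUE)
  d$provenance[is.na(d$provenance)] <- ""
  array_manifest(d[, c("id", "chrom", "pos", "alleleA", "alleleB")],
                 cats, d$provenance)
}

#' Read a variant annotation table
#'
#' Expected columns: the five variant columns, `consequence`
#' (`nonsynonymous` / `synonymous` / `other`), logical `sift_damaging`,
#' `polyphen_hdiv_damaging`, `polyphen_hvar_damaging`, and one `maf_<POP>`
#' column per population (values in [0, 0.5]).
#'
#' @param path Path to a TSV.
#' @return A tibble (annotation table).
#' @export
read_annotations <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_annotations(d)
  d
}

validate_annotations <- function(d) {
  need <- c("id", "chrom", "pos", "alleleA", "alleleB", "consequence",
            "sift_damaging", "polyphen_hdiv_damaging",
            "polyphen_hvar_damaging")
  miss <- setdiff(need, names(d))
  if (length(miss))
    abort(paste0("annotation table missing column(s): ",
                 paste(miss, collapse = ", ")))
  if (!all(d$consequence %in% c("nonsynonymous", "synonymous", "other")))
    abort("consequence must be nonsynonymous, synonymous or other")
  ns <- d$consequence == "nonsynonymous"
  flags <- c("sift_damaging", "polyphen_hdiv_damaging", "polyphen_hvar_damaging")
  if (any(vapply(flags, function(f) anyNA(d[[f]][ns]), logical(1))))
    abort("damaging-prediction flags must be defined for nonsynonymous records")
  mafcols <- grep("^maf_", names(d), value = TRUE)
  for (mc in mafcols) {
    v <- d[[mc]]
    if (any(v < 0 | v > 0.5, na.rm = TRUE))
      abort(paste0(mc, " values must lie in [0, 0.5]"))
  }
  invisible(d)
}

annotation_maf <- function(annot, pop) {
  col <- paste0("maf_", pop)
  if (!col %in% names(annot))
    abort(paste0("population '", pop, "' absent from annotation table ",
                 "(no column ", col, ")"))
  annot[[col]]
}

#' Write an annotation table to TSV
#'
#' @param annot Annotation tibble (see [read_annotations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annot, path) {
  validate_annotations(annot)
  readr::write_tsv(annot, path, progress = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' @param path Path to a TSV with a `sample_id` column, raw trait columns
#'   (mg/dL for lipids, IU/L for enzymes), covariates (`age`, `sex`, `area`)
#'   and optional medication flags (`lipid_med`, `liver_med`).
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(d)) abort("phenotype table needs sample_id")
  d
}

#' Read GWAS summary statistics
#'
#' @param path Path to a TSV with columns `id`, `chrom`, `pos`, `trait`,
#'   `ea` (effect allele), `eaf`, `beta`, `se`, `p` and optionally `info`,
#'   `consequence`.
#' @return A tibble of class `summary_stats`.
#' @export
read_summary_stats <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "chrom", "pos", "trait", "ea", "eaf", "beta", "se", "p")
  miss <- setdiff(need, names(d))
  if (length(miss))
    abort(paste0("summary statistics missing column(s): ",
                 paste(miss, collapse = ", ")))
  if (any(d$p <= 0 | d$p > 1, na.rm = TRUE)) abort("p must lie in (0, 1]")
  if (any(d$se <= 0, na.rm = TRUE)) abort("se must be positive")
  class(d) <- c("summary_stats", class(d))
  d
}

#' Read a known-association catalog
#'
#' @param path Path to a TSV with columns `trait`, `chrom`, `pos` and
#'   optionally `id`.
#' @return A tibble.
#' @export
read_catalog <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("trait", "chrom", "pos")
  miss <- setdiff(need, names(d))
  if (length(miss))
    abort(paste0("catalog missing column(s): ", paste(miss, collapse = ", ")))
  d
}
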