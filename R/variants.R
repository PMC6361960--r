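#' Build a variant table
#'
#' Variants are the common currency of the toolkit: every container (panel,
#' genotype matrix, manifest, annotation table, summary statistics) carries a
#' variant table with the same five columns. Positions are 1-based base pairs
#' (VCF convention); alleles are SNV bases from A/C/G/T or indel strings.
#'
#' @param id Character vector of variant identifiers (unique).
#' @param chrom Chromosome labels.
#' @param pos 1-based positions in bp.
#' @param alleleA,alleleB The two alleles; `alleleB` is the counted
#'   (alternate) allele everywhere a dosage or frequency is reported.
#' @return A tibble with columns `id`, `chrom`, `pos`, `alleleA`, `alleleB`.
#' @export
variant_tbl <- function(id, chrom, pos, alleleA, alleleB) {
  v <- tibble(
    id = as.character(id), chrom = as.character(chrom),
    pos = as.integer(pos),
    alleleA = as.character(alleleA), alleleB = as.character(alleleB)
  )
  assert_variant_tbl(v)
  v
}

assert_variant_tbl <- function(v) {
  stopifnot(is.data.frame(v),
            all(c("id", "chrom", "pos", "alleleA", "alleleB") %in% names(v)))
  if (any(v$pos < 1L)) abort("variant positions must be >= 1")
  if (any(v$alleleA == v$alleleB)) abort("alleleA and alleleB must differ")
  if (anyDuplicated(v$id)) abort("duplicate variant ids")
  key <- variant_key(v)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(paste0("duplicate variant (chrom,pos,alleles): ", dup))
  }
  invisible(v)
}

#' Order-insensitive variant identity key
#'
#' Cross-platform matching uses (chrom, pos, unordered allele pair): the pair
#' (A,G) matches (G,A) at the same position, but never (A,C). Strand flips are
#' deliberately NOT reconciled -- matching requires literal allele identity.
#'
#' @param v A variant table (or any data frame with the five variant columns).
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(v) {
  paste(v$chrom, v$pos,
        pmin(v$alleleA, v$alleleB), pmax(v$alleleA, v$alleleB),
        sep = ":")
}

#' Is the allele pair strand-ambiguous (A/T or C/G)?
#'
#' @param alleleA,alleleB Allele vectors.
#' @return Logical vector; `TRUE` for A/T and C/G SNVs, `FALSE` otherwise
#'   (including indels).
#' @export
is_ambiguous_pair <- function(alleleA, alleleB) {
  a <- pmin(alleleA, alleleB)
  b <- pmax(alleleA, alleleB)
  (a == "A" & b == "T") | (a == "C" & b == "G")
}
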