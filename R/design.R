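# Array content selection: greedy maximum-coverage tagging over pairwise LD,
# functional (nonsynonymous/damaging) modules, and manifest assembly.

#' Pairwise LD (r-squared) within a genomic window
#'
#' For every pair of variants on the same chromosome within `window_bp`,
#' computes `r2 = (pAB - pA pB)^2 / (pA (1 - pA) pB (1 - pB))` from phased
#' haplotype counts. Pairs with a monomorphic member are omitted. Both
#' orientations of each pair are returned, so the index is symmetric.
#'
#' @param panel A `haplotype_panel`.
#' @param window_bp Window half-width in bp (> 0); pairs farther apart are
#'   not computed.
#' @return A tibble of class `ld_index`: `id_i`, `id_j`, `dist_bp`, `r2`.
#' @export
compute_pairwise_r2 <- function(panel, window_bp = 250000) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (window_bp <= 0) abort("window_bp must be > 0")
  v <- panel$variants
  if (nrow(v) == 0) abort("empty panel")
  h <- panel$haplotypes
  storage.mode(h) <- "double"
  n <- nrow(h)
  p <- colMeans(h)
  poly <- p > 0 & p < 1
  acc_i <- list(); acc_j <- list(); acc_r2 <- list(); k <- 0L
  for (chr in unique(v$chrom)) {
    ix <- which(v$chrom == chr & poly)
    if (length(ix) < 2) next
    pos <- v$pos[ix]
    # window upper bound per left member
    hi <- findInterval(pos + window_bp, pos)
    for (a in seq_along(ix)) {
      if (hi[a] <= a) next
      b <- seq.int(a + 1L, hi[a])
      i <- ix[a]; j <- ix[b]
      pAB <- as.vector(crossprod(h[, i], h[, j, drop = FALSE])) / n
      num <- (pAB - p[i] * p[j])^2
      den <- p[i] * (1 - p[i]) * p[j] * (1 - p[j])
      k <- k + 1L
      acc_i[[k]] <- rep.int(i, length(j))
      acc_j[[k]] <- j
      acc_r2[[k]] <- num / den
    }
  }
  res_i <- unlist(acc_i) %||% integer(0)
  res_j <- unlist(acc_j) %||% integer(0)
  res_r2 <- unlist(acc_r2) %||% numeric(0)
  out <- tibble(
    id_i = c(v$id[res_i], v$id[res_j]),
    id_j = c(v$id[res_j], v$id[res_i]),
    dist_bp = abs(c(v$pos[res_j] - v$pos[res_i], v$pos[res_i] - v$pos[res_j])),
    r2 = unname(c(res_r2, res_r2))
  )
  class(out) <- c("ld_index", class(out))
  out
}

# targets covered by each candidate: a candidate covers itself (if a target)
# plus every target with r2 >= tag_r2 within the window.
coverage_sets <- function(candidates, targets, ld, tag_r2) {
  link <- ld[ld$r2 >= tag_r2 & ld$id_i %in% candidates &
               ld$id_j %in% targets, c("id_i", "id_j")]
  sets <- split(link$id_j, factor(link$id_i, levels = candidates))
  sets <- lapply(sets, unique)
  names(sets) <- candidates
  for (cand in intersect(candidates, targets))
    sets[[cand]] <- union(sets[[cand]], cand)
  sets
}

#' Greedy maximum-coverage tag selection
#'
#' Targets are the panel variants with MAF at or above `maf_min`. A target
#' counts as covered iff it is itself selected or has `r2 >= tag_r2` with a
#' selected candidate within `tag_window_bp`. Each step adds the candidate
#' covering the most currently-uncovered targets; ties break by higher
#' candidate MAF, then smaller position (fully deterministic). Selection
#' stops at `budget` or when no candidate adds coverage. Greedy
#' maximum-coverage guarantees at least `1 - 1/e` of the optimal coverage at
#' the same budget.
#'
#' @param panel A `haplotype_panel`.
#' @param candidates Character vector of candidate variant ids (subset of
#'   panel variants).
#' @param cfg A [threshold_config()] (uses `tag_r2`, `tag_window_bp`,
#'   `maf_min`).
#' @param budget Optional maximum number of tags.
#' @param ld Optional precomputed [compute_pairwise_r2()] index at
#'   `tag_window_bp` (computed if missing).
#' @return An object of class `tag_selection`: `selected` (ordered ids),
#'   `covered` (target ids), `targets`, `trace` (per-step tibble
#'   `step`, `id`, `newly_covered`), `coverage` (fraction).
#' @export
greedy_tag_select <- function(panel, candidates, cfg = threshold_config(),
                              budget = NULL, ld = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(cfg, "threshold_config"))
  candidates <- as.character(candidates)
  if (length(candidates) == 0) abort("empty candidate set")
  if (!all(candidates %in% panel$variants$id))
    abort("candidates must be panel variants")
  maf <- setNames(panel_maf(panel), panel$variants$id)
  pos <- setNames(panel$variants$pos, panel$variants$id)
  targets <- panel$variants$id[maf >= cfg$maf_min]
  if (is.null(ld)) ld <- compute_pairwise_r2(panel, cfg$tag_window_bp)
  sets <- coverage_sets(candidates, targets, ld, cfg$tag_r2)
  covered <- setNames(rep(FALSE, length(targets)), targets)
  remaining <- candidates
  selected <- character(0)
  trace <- list()
  budget <- budget %||% length(candidates)
  while (length(selected) < budget && length(remaining) > 0) {
    gain <- vapply(remaining, function(cand)
      sum(!covered[sets[[cand]]]), integer(1))
    if (all(gain == 0)) break
    best <- remaining[gain == max(gain)]
    best <- best[order(-maf[best], pos[best])][1]
    selected <- c(selected, best)
    newly <- sets[[best]][!covered[sets[[best]]]]
    covered[newly] <- TRUE
    trace[[length(trace) + 1]] <-
      tibble(step = length(selected), id = best,
             newly_covered = length(newly))
    remaining <- setdiff(remaining, best)
  }
  structure(list(selected = selected,
                 covered = names(covered)[covered],
                 targets = targets,
                 trace = if (length(trace)) dplyr::bind_rows(trace) else
                   tibble(step = integer(), id = character(),
                          newly_covered = integer()),
                 coverage = if (length(targets)) mean(covered) else NaN,
                 tag_r2 = cfg$tag_r2),
            class = "tag_selection")
}

#' @export
print.tag_selection <- function(x, ...) {
  cat(sprintf("<tag_selection> %d tags covering %d/%d targets (%.1f%%)\n",
              length(x$selected), length(x$covered), length(x$targets),
              100 * x$coverage))
  invisible(x)
}

#' Indispensable tags in a selection
#'
#' A selected tag is indispensable iff removing it leaves at least one of its
#' covered targets with no alternative candidate at `r2 >= tag_r2` (and the
#' target is not itself another selected variant). Such tags are the ones the
#' strand-ambiguity policy may not drop.
#'
#' @param selection A [greedy_tag_select()] result.
#' @param candidates The candidate set the selection was drawn from.
#' @param ld The LD index used for selection.
#' @param cfg A [threshold_config()].
#' @return Character vector of indispensable tag ids.
#' @export
indispensable_tags <- function(selection, candidates, ld,
                               cfg = threshold_config()) {
  stopifnot(inherits(selection, "tag_selection"))
  sets <- coverage_sets(as.character(candidates), selection$targets, ld,
                        cfg$tag_r2)
  sel <- selection$selected
  indis <- vapply(sel, function(tag) {
    tagged <- sets[[tag]]
    if (is.null(tagged) || length(tagged) == 0) return(FALSE)
    others <- setdiff(names(sets), tag)
    alt <- unique(c(unlist(sets[others]), setdiff(sel, tag)))
    any(!tagged %in% alt)
  }, logical(1))
  sel[indis]
}

#' Select functional array content
#'
#' Nonsynonymous variants enter unconditionally when the design-population
#' MAF is at or above `func_maf_common` (0.1%); below that they enter only if
#' predicted damaging by SIFT or either PolyPhen-2 model (HDIV or HVAR).
#' Provenance records which clause admitted each variant.
#'
#' @param annot Annotation tibble (see [read_annotations()]).
#' @param design_pop Population label whose `maf_<pop>` column drives the
#'   frequency clauses.
#' @param cfg A [threshold_config()].
#' @return A tibble: variant columns plus `maf`, `clause`, `provenance`.
#' @export
select_functional <- function(annot, design_pop, cfg = threshold_config()) {
  validate_annotations(annot)
  maf <- annotation_maf(annot, design_pop)
  ns <- annot$consequence == "nonsynonymous"
  damaging <- ns & (annot$sift_damaging | annot$polyphen_hdiv_damaging |
                      annot$polyphen_hvar_damaging)
  common <- ns & !is.na(maf) & maf >= cfg$func_maf_common
  rare_dmg <- ns & !is.na(maf) & maf < cfg$func_maf_common & damaging
  keep <- common | rare_dmg
  out <- annot[keep, c("id", "chrom", "pos", "alleleA", "alleleB")]
  out$maf <- maf[keep]
  out$clause <- ifelse(common[keep], "nonsyn_maf_ge_0.1pct",
                       "nonsyn_rare_damaging")
  out$provenance <- paste0("functional:", out$clause)
  out
}

#' Assemble an array manifest from content sources
#'
#' Takes the union of tagging, functional and interest-list content, keeps
#' per-variant category sets (a variant in several sources gets one entry
#' with several categories), admits only variants that passed validation, and
#' applies the strand-ambiguity policy with each variant's categories and
#' indispensability. Excluded variants are reported in the `excluded`
#' attribute with the reason.
#'
#' @param variants Variant table covering every referenced id (e.g. the
#'   panel's).
#' @param tags A [greedy_tag_select()] result, or character vector of tag ids.
#' @param functional A [select_functional()] result, or character vector of
#'   ids.
#' @param interest_lists Named list of character vectors of variant ids.
#' @param validation A [validate_variants()] report; variants absent from it
#'   or not validated are excluded. `NULL` skips the validation gate (all
#'   candidates treated as validated).
#' @param annot Optional annotation tibble (drives the nonsynonymous clause
#'   of the ambiguity policy).
#' @param design_pop Population for the ambiguity policy's MAF clause.
#' @param indispensable Character vector of indispensable tag ids (see
#'   [indispensable_tags()]).
#' @param cfg A [threshold_config()].
#' @return An [array_manifest()]; attribute `excluded` is a tibble of
#'   rejected variants with reasons.
#' @export
assemble_manifest <- function(variants, tags = character(0),
                              functional = character(0),
                              interest_lists = list(),
                              validation = NULL, annot = NULL,
                              design_pop = NULL,
                              indispensable = character(0),
                              cfg = threshold_config()) {
  assert_variant_tbl(variants)
  tag_ids <- if (inherits(tags, "tag_selection")) tags$selected
             else as.character(tags)
  func_ids <- if (is.data.frame(functional)) functional$id
              else as.character(functional)
  cats <- list()
  add <- function(ids, label) {
    for (id in ids) cats[[id]] <<- union(cats[[id]], label)
  }
  add(tag_ids, "tag")
  add(func_ids, "functional")
  for (nm in names(interest_lists))
    add(as.character(interest_lists[[nm]]), paste0("interest:", nm))
  ids <- names(cats)
  miss <- setdiff(ids, variants$id)
  if (length(miss))
    abort(paste0("content ids missing from variant table: ",
                 paste(head(miss, 5), collapse = ", ")))
  v <- variants[match(ids, variants$id), , drop = FALSE]
  validated <- if (is.null(validation)) rep(TRUE, length(ids)) else {
    ok_ids <- validation$id[validation$validated]
    ids %in% ok_ids
  }
  ns <- maf <- NULL
  if (!is.null(annot)) {
    ai <- match(ids, annot$id)
    ns <- !is.na(ai) & annot$consequence[ai] == "nonsynonymous"
    maf <- if (!is.null(design_pop)) annotation_maf(annot, design_pop)[ai]
           else rep(NA_real_, length(ids))
  } else {
    ns <- rep(FALSE, length(ids))
    maf <- rep(NA_real_, length(ids))
  }
  keep_policy <- vapply(seq_along(ids), function(k) {
    ambiguity_policy(v$alleleA[k], v$alleleB[k], cats[[ids[k]]],
                     nonsynonymous = ns[k], maf = maf[k],
                     indispensable_tag = ids[k] %in% indispensable,
                     cfg = cfg)
  }, logical(1))
  keep <- validated & keep_policy
  excluded <- tibble(
    id = ids[!keep],
    reason = ifelse(!validated[!keep], "failed validation",
                    "ambiguous alleles (A/T or C/G), no exception")
  )
  m <- array_manifest(v[keep, , drop = FALSE], cats[keep],
                      provenance = vapply(cats[keep], paste, character(1),
                                          collapse = "+"))
  attr(m, "excluded") <- excluded
  m
}

#' Per-category content counts of a manifest
#'
#' Categories may overlap, so per-category counts can exceed the distinct
#' total (which is the number of manifest rows).
#'
#' @param manifest An `array_manifest`.
#' @return A tibble: `category`, `n`, plus a `total_distinct` attribute.
#' @export
manifest_counts <- function(manifest) {
  stopifnot(inherits(manifest, "array_manifest"))
  cats <- unlist(manifest$categories)
  out <- tibble(category = names(table(cats)),
                n = as.integer(table(cats)))
  attr(out, "total_distinct") <- nrow(manifest)
  out
}
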