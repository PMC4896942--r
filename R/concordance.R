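#' Canonical variant keys
#'
#' A variant key is `chrom:pos:ref:alt-set` with alternate alleles in
#' canonical (sorted) order, the identity used for caller concordance.
#'
#' @param variants a [variant_table]
#' @return character vector of keys
#' @export
variant_key <- function(variants) {
  stopifnot(inherits(variants, "variant_table"))
  alt <- vapply(variants$alt, function(a) paste(sort(a), collapse = ","),
                character(1))
  sprintf("%s:%d:%s:%s", variants$chrom, variants$pos, variants$ref, alt)
}

#' Caller concordance and union/intersection sets
#'
#' Given two or more named sets of variant keys (one per caller), computes
#' every Venn region count, the non-redundant union, and the concordant
#' set (keys called by all callers) — the retention rule used for InDels,
#' where only concordant sites are kept.
#'
#' @param sets named list (length >= 2) of character key vectors
#' @return list with `membership` (logical matrix keys x callers),
#'   `regions` (named integer vector, names like `"gatk&samtools"`),
#'   `union` (character), `concordant` (character)
#' @export
concordance_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)),
            all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  keys <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) keys %in% s,
                       logical(length(keys)))
  if (length(keys) == 1L) membership <- matrix(membership, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  rownames(membership) <- keys
  region_of <- apply(membership, 1L, function(r)
    paste(names(sets)[r], collapse = "&"))
  # all non-empty caller combinations, fixed order
  combos <- unlist(lapply(seq_along(sets), function(k)
    utils::combn(names(sets), k, paste, collapse = "&", simplify = FALSE)))
  regions <- stats::setNames(integer(length(combos)), combos)
  tab <- table(region_of)
  regions[names(tab)] <- as.integer(tab)
  list(membership = membership,
       regions = regions,
       union = keys,
       concordant = keys[rowSums(membership) == length(sets)])
}
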