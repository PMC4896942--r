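#' Transition/transversion ratio
#'
#' Classifies ref->alt single-nucleotide changes as transitions (A<->G,
#' C<->T) or transversions and returns their ratio.  Multi-allelic sites
#' are decomposed into one ref->alt pair per alternate allele.  With zero
#' transversions the ratio is `Inf` and flagged.
#'
#' @param variants a [variant_table], or a data.frame with `ref` and
#'   `alt` character columns (single bases)
#' @return list with `ratio`, `ts`, `tv`, `infinite` (logical flag)
#' @export
ts_tv_ratio <- function(variants) {
  if (inherits(variants, "variant_table")) {
    ref <- rep(variants$ref, lengths(variants$alt))
    alt <- unlist(variants$alt, use.names = FALSE)
  } else {
    ref <- variants$ref
    alt <- variants$alt
  }
  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% DNA_BASES & alt %in% DNA_BASES & ref != alt
  ref <- ref[snv]; alt <- alt[snv]
  is_ts <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  ts <- sum(is_ts); tv <- sum(!is_ts)
  list(ratio = if (tv == 0L) Inf else ts / tv,
       ts = ts, tv = tv, infinite = tv == 0L)
}
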