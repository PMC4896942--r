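#' Hard-filter configuration
#'
#' Thresholds of the six-rule hard-filter cascade applied to multi-caller
#' variant sets, in the printed order: (1) mapping quality > `min_mq`;
#' (2) base quality > `min_bq`; (3) alternate-supporting reads per
#' accession carrying the alternate > `min_alt_reads`; (4) summed depth
#' across accessions < `max_total_depth`; (5) summed depth across
#' accessions > `min_total_depth`; (6) site QUAL > `min_qual`.  All
#' comparisons are strict, as printed.
#'
#' Rule (5) is stated ambiguously in its source ("overall minimum depth
#' ... quality >600"); the default reading is a depth sum, symmetric with
#' rule (4).  Set `rule5 = "qual_sum"` to instead require the summed
#' per-accession QUAL-scaled depth — kept only for completeness.
#'
#' @param min_mq,min_bq,min_alt_reads,max_total_depth,min_total_depth,min_qual
#'   thresholds (defaults 30, 20, 2, 3000, 600, 80)
#' @param rule5 `"depth_sum"` (default) or `"qual_sum"`
#' @param alt_rule which accessions rule (3) applies to:
#'   `"carriers"` (default: only accessions with at least one
#'   alternate-supporting read) or `"all"`
#' @return an object of class `filter_config`
#' @export
filter_config <- function(min_mq = 30, min_bq = 20, min_alt_reads = 2,
                          max_total_depth = 3000, min_total_depth = 600,
                          min_qual = 80, rule5 = c("depth_sum", "qual_sum"),
                          alt_rule = c("carriers", "all")) {
  stopifnot(min_mq >= 0, min_bq >= 0, min_alt_reads >= 0,
            max_total_depth >= 0, min_total_depth >= 0, min_qual >= 0)
  structure(list(min_mq = min_mq, min_bq = min_bq,
                 min_alt_reads = min_alt_reads,
                 max_total_depth = max_total_depth,
                 min_total_depth = min_total_depth, min_qual = min_qual,
                 rule5 = match.arg(rule5), alt_rule = match.arg(alt_rule)),
            class = "filter_config")
}

#' Apply the six-rule hard-filter cascade
#'
#' A record passes iff all six predicates hold (conjunctive, order-free);
#' the printed rule order is used only to attribute each rejected record
#' to its first failing rule in the tally.  Records tagged `unfilterable`
#' (missing required annotation) are routed to a separate bucket and never
#' counted as passed.
#'
#' @param variants a [variant_table]
#' @param config a [filter_config()]
#' @return list with `passed`, `rejected`, `unfilterable` (variant
#'   tables) and `tally` (named integer: rejections attributed to rules
#'   `mq`, `bq`, `alt_reads`, `max_depth`, `min_depth`, `qual`)
#' @export
apply_hard_filters <- function(variants, config = filter_config()) {
  stopifnot(inherits(variants, "variant_table"),
            inherits(config, "filter_config"))
  n <- nrow(variants)
  unf <- variants$unfilterable
  depth_sum <- vapply(variants$ad, function(m) sum(m, na.rm = TRUE),
                      numeric(1))
  r1 <- variants$mq > config$min_mq
  r2 <- variants$bq > config$min_bq
  r3 <- vapply(seq_len(n), function(i) {
    m <- variants$ad[[i]]
    if (nrow(m) < 2L) return(TRUE)
    alt <- colSums(m[-1L, , drop = FALSE], na.rm = TRUE)
    miss <- apply(m, 2L, function(col) all(is.na(col)))
    alt <- alt[!miss]
    if (config$alt_rule == "carriers") alt <- alt[alt > 0]
    all(alt > config$min_alt_reads)
  }, logical(1))
  r4 <- depth_sum < config$max_total_depth
  r5 <- if (config$rule5 == "depth_sum") {
    depth_sum > config$min_total_depth
  } else {
    variants$qual * depth_sum > config$min_total_depth
  }
  r6 <- variants$qual > config$min_qual
  rules <- cbind(mq = r1, bq = r2, alt_reads = r3,
                 max_depth = r4, min_depth = r5, qual = r6)
  rules[is.na(rules)] <- FALSE
  pass <- rowSums(rules) == 6L & !unf
  rej <- !pass & !unf
  first_fail <- apply(rules[rej, , drop = FALSE], 1L,
                      function(r) which(!r)[1])
  tally <- table(factor(colnames(rules)[first_fail],
                        levels = colnames(rules)))
  list(passed = subset_vt(variants, pass),
       rejected = subset_vt(variants, rej),
       unfilterable = subset_vt(variants, unf),
       tally = stats::setNames(as.integer(tally), names(tally)))
}

subset_vt <- function(variants, idx) {
  new_variant_table(variants[idx, ], attr(variants, "samples"))
}
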