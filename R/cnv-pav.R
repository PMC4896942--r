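#' Normalized per-gene read depth
#'
#' `depth = 1e9 * reads / (total_mapped * gene_length)` — reads per
#' gigabase of mapped sequence per base of gene, removing library-size and
#' gene-length effects.
#'
#' @param reads reads mapped to the gene (>= 0)
#' @param total_mapped total mapped reads of the accession (> 0)
#' @param gene_length gene length in bp (> 0)
#' @return normalized depth (vectorized)
#' @export
normalize_depth <- function(reads, total_mapped, gene_length) {
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  if (any(gene_length <= 0)) stop("gene_length must be > 0")
  if (any(reads < 0)) stop("reads must be >= 0")
  1e9 * as.numeric(reads) / (as.numeric(total_mapped) * gene_length)
}

#' Build the per-gene depth table for an accession pair
#'
#' @param depths data.table from [simulate_gene_depths()] or read via
#'   [read_tsv_table()] with columns `gene_id`, `length`, `accession`,
#'   `reads`, `total_mapped`
#' @param query,subject accession names
#' @param ploidy_map optional named vector accession -> ploidy; when given,
#'   normalized depths are additionally divided by ploidy before the ratio
#'   (off by default: the normalization formula itself omits it)
#' @return data.table with per-gene raw and normalized depths for both
#'   accessions and `log2_ratio` (query/subject; `NA` unless both
#'   normalized depths are > 0)
#' @export
gene_depth_pairs <- function(depths, query, subject, ploidy_map = NULL) {
  dt <- data.table::as.data.table(depths)
  q <- dt[dt$accession == query, ]
  s <- dt[dt$accession == subject, ]
  if (!nrow(q) || !nrow(s)) stop("missing accession in depth table")
  merged <- merge(q[, c("gene_id", "length", "reads", "total_mapped")],
                  s[, c("gene_id", "reads", "total_mapped")],
                  by = "gene_id", suffixes = c("_query", "_subject"))
  merged[, "norm_query" := normalize_depth(
    merged$reads_query, merged$total_mapped_query, merged$length)]
  merged[, "norm_subject" := normalize_depth(
    merged$reads_subject, merged$total_mapped_subject, merged$length)]
  if (!is.null(ploidy_map)) {
    merged[, "norm_query" := merged$norm_query / ploidy_map[[query]]]
    merged[, "norm_subject" := merged$norm_subject / ploidy_map[[subject]]]
  }
  merged[, "log2_ratio" := ifelse(
    merged$norm_query > 0 & merged$norm_subject > 0,
    log2(merged$norm_query / merged$norm_subject), NA_real_)]
  data.table::setattr(merged, "pair", c(query = query, subject = subject))
  merged[]
}

#' Call copy-number variations from an accession-pair depth table
#'
#' Over all genes with a defined log2 depth ratio (both normalized depths
#' positive), up-CNVs are genes strictly above the 99th percentile of the
#' empirical ratio distribution and down-CNVs strictly below the mirrored
#' subject-side cut-off (the 1st percentile of the query/subject ratio).
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).  Genes with zero depth on either side are
#' excluded here and handled by [call_pav()].
#'
#' @param pairs output of [gene_depth_pairs()]
#' @param percentile upper percentile cut-off (default 99)
#' @param min_genes minimum eligible genes for the percentile to be
#'   meaningful (default 100)
#' @return data.table of calls: gene_id, type (`up_cnv` / `down_cnv`),
#'   statistic (the log2 ratio); thresholds in attributes `p_up`, `p_down`
#' @export
call_cnv <- function(pairs, percentile = 99, min_genes = 100L) {
  eligible <- pairs[!is.na(pairs$log2_ratio), ]
  if (nrow(eligible) < min_genes) {
    stop("only ", nrow(eligible), " genes with defined log2 ratio; need >= ",
         min_genes)
  }
  r <- eligible$log2_ratio
  p_up <- stats::quantile(r, percentile / 100, names = FALSE, type = 7)
  p_down <- stats::quantile(r, 1 - percentile / 100, names = FALSE, type = 7)
  up <- eligible[r > p_up, c("gene_id", "log2_ratio")]
  down <- eligible[r < p_down, c("gene_id", "log2_ratio")]
  out <- data.table::rbindlist(list(
    data.table::data.table(gene_id = up$gene_id, type = "up_cnv",
                           statistic = up$log2_ratio),
    data.table::data.table(gene_id = down$gene_id, type = "down_cnv",
                           statistic = down$log2_ratio)))
  data.table::setattr(out, "p_up", p_up)
  data.table::setattr(out, "p_down", p_down)
  data.table::setattr(out, "pair", attr(pairs, "pair"))
  out[]
}

#' Call presence/absence variations from an accession-pair depth table
#'
#' A gene is absent in the query iff (1) zero reads aligned in the query
#' and (2) at least `min_subject_reads` reads aligned in the subject with
#' normalized depth at least `min_subject_norm_depth`.  The symmetric rule
#' gives absences in the subject.
#'
#' @param pairs output of [gene_depth_pairs()]
#' @param min_subject_reads minimum reads on the present side (default 10)
#' @param min_subject_norm_depth minimum normalized depth on the present
#'   side (default 0.1)
#' @return data.table of calls: gene_id, type (`pav_absent_in_query` /
#'   `pav_absent_in_subject`), statistic (normalized depth on the present
#'   side)
#' @export
call_pav <- function(pairs, min_subject_reads = 10,
                     min_subject_norm_depth = 0.1) {
  absent_q <- pairs$reads_query == 0 &
    pairs$reads_subject >= min_subject_reads &
    pairs$norm_subject >= min_subject_norm_depth
  absent_s <- pairs$reads_subject == 0 &
    pairs$reads_query >= min_subject_reads &
    pairs$norm_query >= min_subject_norm_depth
  out <- data.table::rbindlist(list(
    data.table::data.table(gene_id = pairs$gene_id[absent_q],
                           type = "pav_absent_in_query",
                           statistic = pairs$norm_subject[absent_q]),
    data.table::data.table(gene_id = pairs$gene_id[absent_s],
                           type = "pav_absent_in_subject",
                           statistic = pairs$norm_query[absent_s])))
  data.table::setattr(out, "pair", attr(pairs, "pair"))
  out[]
}

#' Pairwise CNV/PAV summary matrix
#'
#' Formats per-pair call counts as `"up/down (present/absent)"` cells of a
#' query-by-subject matrix: up- and down-CNV counts in the query, then
#' genes present/absent in the query relative to the subject.
#'
#' @param calls named list: for each pair `"Q|S"`, a list with elements
#'   `cnv` and `pav` (outputs of [call_cnv()] / [call_pav()])
#' @param accessions character vector of accession names
#' @return character matrix (queries in rows); missing pairs are an error
#' @export
pairwise_matrix <- function(calls, accessions) {
  n <- length(accessions)
  out <- matrix("", n, n, dimnames = list(accessions, accessions))
  for (q in accessions) {
    for (s in accessions) {
      if (q == s) { out[q, s] <- "-"; next }
      key <- paste(q, s, sep = "|")
      rkey <- paste(s, q, sep = "|")
      if (!is.null(calls[[key]])) {
        cnv <- calls[[key]]$cnv; pav <- calls[[key]]$pav
        up <- sum(cnv$type == "up_cnv")
        down <- sum(cnv$type == "down_cnv")
        pres <- sum(pav$type == "pav_absent_in_subject")  # present in query
        abs_ <- sum(pav$type == "pav_absent_in_query")
      } else if (!is.null(calls[[rkey]])) {
        # unordered storage: flip roles by antisymmetry
        cnv <- calls[[rkey]]$cnv; pav <- calls[[rkey]]$pav
        up <- sum(cnv$type == "down_cnv")
        down <- sum(cnv$type == "up_cnv")
        pres <- sum(pav$type == "pav_absent_in_query")
        abs_ <- sum(pav$type == "pav_absent_in_subject")
      } else {
        stop("missing calls for pair ", key)
      }
      out[q, s] <- sprintf("%d/%d (%d/%d)", up, down, pres, abs_)
    }
  }
  out
}
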