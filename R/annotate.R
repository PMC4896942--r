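#' Classify a variant position against gene models
#'
#' Exact containment tests per overlapping gene, mutually exclusive
#' classes in priority order: CDS exon > UTR > splice site > intron;
#' positions inside an exon but annotated UTR are classed UTR (so the
#' class percentages partition).  A splice site is the first 2 intronic
#' bases on either side of an exon-intron junction.  Variants overlapping
#' several genes are assigned to all; the primary gene is the one with the
#' longest total CDS.
#'
#' @param pos0 0-based genomic position of the variant (VCF `pos - 1`)
#' @param chrom chromosome
#' @param models list of [gene_model()]
#' @param splice_window intronic bases on each side of a junction counted
#'   as splice site (default 2, the canonical donor/acceptor dinucleotide)
#' @return list with `region` (primary class: one of `exon`, `utr5`,
#'   `utr3`, `splice_site`, `intron`, `intergenic`), `gene_id` (primary
#'   gene or `NA`), `all_hits` (data.frame gene_id/region for every
#'   overlapping gene)
#' @export
classify_region <- function(pos0, chrom, models, splice_window = 2L) {
  hits <- list()
  for (m in models) {
    if (m$chrom != chrom || pos0 < m$start || pos0 >= m$end) next
    inside <- function(df) nrow(df) > 0 &&
      any(df$start <= pos0 & pos0 < df$end)
    region <- if (inside(m$cds)) {
      "exon"
    } else if (inside(m$utr5)) {
      "utr5"
    } else if (inside(m$utr3)) {
      "utr3"
    } else if (inside(m$exons)) {
      "exon"  # exonic but neither CDS nor annotated UTR
    } else {
      # intronic: distance to nearest exon boundary
      dist_right <- min(m$exons$start[m$exons$start > pos0] - pos0, Inf)
      dist_left <- min(pos0 - m$exons$end[m$exons$end <= pos0] + 1L, Inf)
      if (min(dist_left, dist_right) <= splice_window) "splice_site"
      else "intron"
    }
    hits[[length(hits) + 1L]] <- data.frame(
      gene_id = m$gene_id, region = region,
      cds_len = sum(m$cds$end - m$cds$start), stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(list(region = "intergenic", gene_id = NA_character_,
                all_hits = data.frame(gene_id = character(),
                                      region = character())))
  }
  hits <- do.call(rbind, hits)
  primary <- which.max(hits$cds_len)
  list(region = hits$region[primary], gene_id = hits$gene_id[primary],
       all_hits = hits[, c("gene_id", "region")])
}

# spliced CDS of a model on the transcript strand, plus a map from
# genomic position to CDS coordinate (0-based)
spliced_cds <- function(model, genome) {
  seqs <- vapply(seq_len(nrow(model$cds)), function(i) {
    substr(genome[[model$chrom]], model$cds$start[i] + 1L, model$cds$end[i])
  }, character(1))
  cds_plus <- paste(seqs, collapse = "")
  if (model$strand == "-") revcomp(cds_plus) else cds_plus
}

genomic_to_cds <- function(model, pos0) {
  off <- 0L
  plus_coord <- NA_integer_
  for (i in seq_len(nrow(model$cds))) {
    s <- model$cds$start[i]; e <- model$cds$end[i]
    if (pos0 >= s && pos0 < e) {
      plus_coord <- off + (pos0 - s)
      break
    }
    off <- off + (e - s)
  }
  if (is.na(plus_coord)) return(NA_integer_)
  total <- sum(model$cds$end - model$cds$start)
  if (model$strand == "-") total - 1L - plus_coord else plus_coord
}

#' Coding effect of a SNP
#'
#' Builds the affected codon from the spliced CDS honoring strand and
#' phase, translates reference and alternate codons, and reports
#' `synonymous`, `nonsynonymous`, `stop_gained` (alternate codon is a stop
#' and the reference codon is not), or `start_lost` (the reference ATG
#' start codon is disrupted).  `ref` and `alt` are given on the genome
#' (plus) strand and complemented internally for minus-strand genes.
#'
#' @param pos0 0-based genomic position (must fall in the model's CDS)
#' @param ref,alt single bases on the genome strand
#' @param model a [gene_model()]
#' @param genome named character vector (or list) of contig sequences
#' @return list with `effect`, `codon_ref`, `codon_alt`, `aa_ref`,
#'   `aa_alt`; effect `"unknown"` (flagged) when the CDS length is not a
#'   multiple of 3
#' @export
coding_effect <- function(pos0, ref, alt, model, genome) {
  stopifnot(nchar(ref) == 1L, nchar(alt) == 1L)
  cds <- spliced_cds(model, genome)
  if (nchar(cds) %% 3L != 0L) {
    return(list(effect = "unknown", codon_ref = NA, codon_alt = NA,
                aa_ref = NA, aa_alt = NA))
  }
  cpos <- genomic_to_cds(model, pos0)
  if (is.na(cpos)) stop("position ", pos0, " not inside the CDS of ",
                        model$gene_id)
  tx_ref <- if (model$strand == "-") revcomp(ref) else ref
  tx_alt <- if (model$strand == "-") revcomp(alt) else alt
  if (substr(cds, cpos + 1L, cpos + 1L) != tx_ref) {
    stop("reference mismatch at CDS position ", cpos, " of ",
         model$gene_id, ": CDS has ", substr(cds, cpos + 1L, cpos + 1L),
         ", variant says ", tx_ref)
  }
  cpos <- cpos - model$phase
  if (cpos < 0L) {
    return(list(effect = "unknown", codon_ref = NA, codon_alt = NA,
                aa_ref = NA, aa_alt = NA))
  }
  codon_idx <- cpos %/% 3L
  in_codon <- cpos %% 3L
  codon_start <- model$phase + codon_idx * 3L
  codon_ref <- substr(cds, codon_start + 1L, codon_start + 3L)
  codon_alt <- codon_ref
  substr(codon_alt, in_codon + 1L, in_codon + 1L) <- tx_alt
  aa_ref <- translate_codon(codon_ref)
  aa_alt <- translate_codon(codon_alt)
  effect <- if (codon_idx == 0L && model$phase == 0L &&
                codon_ref == "ATG" && codon_alt != "ATG") {
    "start_lost"
  } else if (codon_alt %in% STOP_CODONS && !(codon_ref %in% STOP_CODONS)) {
    "stop_gained"
  } else if (aa_ref == aa_alt) {
    "synonymous"
  } else {
    "nonsynonymous"
  }
  list(effect = effect, codon_ref = codon_ref, codon_alt = codon_alt,
       aa_ref = aa_ref, aa_alt = aa_alt)
}

#' Frame class of an InDel
#'
#' Inside a CDS an insertion/deletion whose length is a multiple of 3 bp
#' is `in_frame`, otherwise `frameshift`; outside any CDS the class is
#' `none`.
#'
#' @param pos0 0-based genomic position
#' @param ref,alt VCF-style ref/alt allele strings (one is longer)
#' @param models list of [gene_model()]
#' @param chrom chromosome
#' @return `"in_frame"`, `"frameshift"` or `"none"`
#' @export
indel_frame_class <- function(pos0, ref, alt, models, chrom) {
  len <- abs(nchar(ref) - nchar(alt))
  if (len == 0L) stop("not an InDel: ref and alt have equal length")
  in_cds <- any(vapply(models, function(m) {
    m$chrom == chrom && nrow(m$cds) > 0 &&
      any(m$cds$start <= pos0 & pos0 < m$cds$end)
  }, logical(1)))
  if (!in_cds) return("none")
  if (len %% 3L == 0L) "in_frame" else "frameshift"
}

#' Variant density summaries
#'
#' Counts variants in fixed non-overlapping windows per chromosome and
#' per gene, with densities reported both as bases-per-variant and
#' variants-per-kb.
#'
#' @param variants data.frame with `chrom` and `pos` (1-based)
#' @param window_size window size in bp (> 0)
#' @param models optional list of [gene_model()] for per-gene counts
#' @param chrom_lengths optional named vector; defaults to max position
#'   per chromosome
#' @return list with `windows` (chrom, window_start, count, variants_per_kb)
#'   and `genes` (gene_id, length, count, bases_per_variant)
#' @export
density_summary <- function(variants, window_size = 1e6, models = NULL,
                            chrom_lengths = NULL) {
  if (window_size <= 0) stop("window_size must be > 0")
  dt <- data.table::as.data.table(variants)
  if (nrow(dt)) {
    win <- dt[, list(count = .N),
              by = list(chrom = dt$chrom,
                        window_start = (dt$pos - 1L) %/% window_size *
                          window_size)]
  } else {
    win <- data.table::data.table(chrom = character(),
                                  window_start = numeric(), count = integer())
  }
  win[, "variants_per_kb" := win$count / (window_size / 1000)]
  genes <- NULL
  if (!is.null(models)) {
    genes <- data.table::rbindlist(lapply(models, function(m) {
      cnt <- sum(dt$chrom == m$chrom & dt$pos - 1L >= m$start &
                   dt$pos - 1L < m$end)
      data.table::data.table(
        gene_id = m$gene_id, length = m$end - m$start, count = cnt,
        bases_per_variant = if (cnt > 0) (m$end - m$start) / cnt else NA_real_)
    }))
  }
  list(windows = win[], genes = genes)
}
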