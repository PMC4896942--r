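#' Simulate per-gene capture read counts with planted CNV and PAV
#'
#' Baseline per-gene expected reads are proportional to gene length times
#' a lognormal capture efficiency, scaled to `mean_gene_reads`.  In the
#' designated query accession (the first accession), `cnv_fraction` of
#' genes get their rate multiplied by `2^(+/- cnv_log2_effect)` (half up,
#' half down) and `pav_fraction` of genes are planted absent (rate 0) in
#' one side of the first accession pair (half absent in the query, half in
#' the subject).  Counts are Poisson (negative binomial when
#' `overdispersion < Inf`).  Deterministic under the config seed.
#'
#' @param config a [sim_config()]
#' @return list with `depths` (data.table: gene_id, length, accession,
#'   reads, total_mapped), `truth` (data.table: gene_id, accession,
#'   log2_copy_ratio, present)
#' @export
simulate_gene_depths <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$cnv_fraction + config$pav_fraction > 1) {
    stop("cnv_fraction + pav_fraction must be <= 1")
  }
  set.seed(derive_seed(config$seed, 3L))
  ng <- config$n_genes
  acc <- names(config$accessions)
  if (length(acc) < 2L) stop("need at least 2 accessions for gene depths")
  glen <- pmax(300L, round(stats::rlnorm(ng, log(1500), 0.5)))
  eff <- stats::rlnorm(ng, 0, 0.4)  # shared capture efficiency per gene
  base <- glen * eff
  base <- base * (config$mean_gene_reads / mean(base))

  n_cnv <- round(config$cnv_fraction * ng)
  n_pav <- round(config$pav_fraction * ng)
  special <- sample.int(ng, n_cnv + n_pav)
  cnv_genes <- utils::head(special, n_cnv)
  pav_genes <- utils::tail(special, n_pav)
  cnv_dir <- rep_len(c(1, -1), n_cnv)              # up / down in query
  pav_side <- rep_len(c(1L, 2L), n_pav)            # absent in acc1 / acc2

  log2cr <- matrix(0, nrow = ng, ncol = length(acc),
                   dimnames = list(NULL, acc))
  present <- matrix(TRUE, nrow = ng, ncol = length(acc),
                    dimnames = list(NULL, acc))
  log2cr[cnv_genes, 1L] <- cnv_dir * config$cnv_log2_effect
  present[pav_genes[pav_side == 1L], 1L] <- FALSE
  present[pav_genes[pav_side == 2L], 2L] <- FALSE

  depths <- vector("list", length(acc))
  for (a in seq_along(acc)) {
    lambda <- base * 2^log2cr[, a] * present[, a]
    reads <- if (is.finite(config$overdispersion)) {
      stats::rnbinom(ng, size = config$overdispersion, mu = lambda)
    } else {
      stats::rpois(ng, lambda)
    }
    depths[[a]] <- data.table::data.table(
      gene_id = sprintf("gene%05d", seq_len(ng)), length = glen,
      accession = acc[a], reads = reads, total_mapped = sum(reads))
  }
  truth <- data.table::data.table(
    gene_id = rep(sprintf("gene%05d", seq_len(ng)), length(acc)),
    accession = rep(acc, each = ng),
    log2_copy_ratio = as.vector(log2cr),
    present = as.vector(present))
  list(depths = data.table::rbindlist(depths), truth = truth)
}

#' @importFrom stats rnbinom
NULL
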