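#' Simulation configuration
#'
#' One configuration object drives every generator.  Defaults describe a
#' realistic target-capture study of the *Saccharum* complex: 12
#' accessions at ploidies 6, 8 and 12, deep per-locus capture coverage
#' (mean 150 reads), a 1% per-read miscall rate, genotype classes
#' dominated by homozygotes (heterozygous fraction under 25%, single-dose
#' classes the most common heterozygous classes), 120-nucleotide probes,
#' and ~1% planted CNV / PAV gene fractions.
#'
#' @param seed integer seed; identical config + seed gives byte-identical
#'   outputs
#' @param accessions named integer vector: accession name -> ploidy (even,
#'   from \{6, 8, 12\})
#' @param n_loci number of bi-allelic SNP loci
#' @param mean_depth mean reads per locus (Poisson)
#' @param error_rate per-read miscall probability
#' @param dosage_distribution either `NULL` (per-ploidy default, see
#'   Details) or a function `function(m)` returning weights over dosages
#'   `0..m`
#' @param n_genes number of genes for depth simulation
#' @param mean_gene_reads mean reads per gene at copy ratio 1
#' @param cnv_fraction fraction of genes with a planted copy-number change
#' @param cnv_log2_effect planted log2 copy-ratio effect (applied as +/-)
#' @param pav_fraction fraction of genes planted absent in one accession
#' @param probe_count number of capture probes
#' @param probe_length probe length in nt (>= 20; default 120)
#' @param probe_noise_sd Gaussian noise s.d. on probe read counts
#' @param cds_pairs data.frame with columns `length_codons`, `target_ks`
#' @param overdispersion optional negative-binomial size parameter for
#'   gene depths (`Inf` = Poisson, the default)
#'
#' @details The default dosage distribution at ploidy `m` puts 0.55 on
#' dosage 0 (homozygous reference), 0.20 on dosage `m` (homozygous
#' alternate), 0.10 on dosage 1 and 0.05 on dosage `m - 1` (the
#' single-dose classes), and spreads the remaining 0.10 uniformly over the
#' interior dosages, matching the observed predominance of homozygotes and
#' of single-dose classes among heterozygotes in capture data of this
#' kind.
#'
#' @return an object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       accessions = stats::setNames(
                         rep(c(6L, 8L, 12L), times = c(2L, 8L, 2L)),
                         sprintf("ACC%02d", 1:12)),
                       n_loci = 2000L,
                       mean_depth = 150,
                       error_rate = 0.01,
                       dosage_distribution = NULL,
                       n_genes = 5000L,
                       mean_gene_reads = 200,
                       cnv_fraction = 0.01,
                       cnv_log2_effect = 2,
                       pav_fraction = 0.01,
                       probe_count = 500L,
                       probe_length = 120L,
                       probe_noise_sd = 10,
                       cds_pairs = data.frame(
                         length_codons = c(2000L, 2000L, 2000L),
                         target_ks = c(0.01, 0.05, 0.1)),
                       overdispersion = Inf) {
  stopifnot(is.numeric(accessions), length(accessions) >= 1,
            !is.null(names(accessions)), all(nzchar(names(accessions))))
  if (any(accessions %% 2L != 0L) || any(accessions < 2L)) {
    stop("ploidy must be even and >= 2")
  }
  stopifnot(error_rate >= 0, error_rate < 0.5,
            cnv_fraction >= 0, pav_fraction >= 0)
  if (cnv_fraction + pav_fraction > 1) {
    stop("cnv_fraction + pav_fraction must be <= 1")
  }
  if (probe_length < 20L) stop("probe_length must be >= 20")
  if (!is.null(dosage_distribution)) {
    stopifnot(is.function(dosage_distribution))
  }
  structure(list(
    seed = as.integer(seed), accessions = accessions,
    n_loci = as.integer(n_loci), mean_depth = mean_depth,
    error_rate = error_rate,
    dosage_distribution = dosage_distribution %||% default_dosage_weights,
    n_genes = as.integer(n_genes), mean_gene_reads = mean_gene_reads,
    cnv_fraction = cnv_fraction, cnv_log2_effect = cnv_log2_effect,
    pav_fraction = pav_fraction,
    probe_count = as.integer(probe_count),
    probe_length = as.integer(probe_length),
    probe_noise_sd = probe_noise_sd,
    cds_pairs = cds_pairs,
    overdispersion = overdispersion
  ), class = "sim_config")
}

# hom-ref heavy genotype-class prior; see ?sim_config Details
default_dosage_weights <- function(m) {
  w <- numeric(m + 1)
  w[1] <- 0.55            # dosage 0
  w[m + 1] <- 0.20        # dosage m
  w[2] <- 0.10            # dosage 1
  w[m] <- w[m] + 0.05     # dosage m-1
  interior <- setdiff(seq_len(m + 1), c(1, 2, m, m + 1))
  if (length(interior)) w[interior] <- 0.10 / length(interior) else {
    w[2] <- w[2] + 0.10 / 2
    w[m] <- w[m] + 0.10 / 2
  }
  w / sum(w)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> seed=%d | %d accessions (ploidies %s)\n",
    "  loci: %d @ depth %g, error %g | genes: %d @ %g reads",
    " (cnv %g%% @ 2^%g, pav %g%%)\n  probes: %d x %d nt | cds pairs: %d\n"),
    x$seed, length(x$accessions),
    paste(sort(unique(x$accessions)), collapse = "/"),
    x$n_loci, x$mean_depth, x$error_rate, x$n_genes, x$mean_gene_reads,
    100 * x$cnv_fraction, x$cnv_log2_effect, 100 * x$pav_fraction,
    x$probe_count, x$probe_length, nrow(x$cds_pairs)))
  invisible(x)
}
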