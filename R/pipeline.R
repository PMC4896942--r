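#' Run the full analysis pipeline on simulated data
#'
#' Exercises every stage end to end from one configuration: simulate ->
#' hard filter -> dosage genotyping / SDM -> CNV + PAV -> annotation ->
#' probe model -> Ka/Ks dating -> bootstrap NJ tree, writing parseable
#' outputs for every stage under `outdir`.
#'
#' @param config a [sim_config()]
#' @param outdir output directory (created if needed)
#' @param boot_replicates bootstrap replicates for the tree (default 100)
#' @return named list of output file paths and in-memory summaries
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         boot_replicates = 100L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  out <- list()

  # 1. variants: simulate, write VCF, read back, hard filter
  vt <- simulate_variant_table(n = 2000L,
                               n_accessions = length(config$accessions),
                               seed = config$seed)
  write_vcf(vt, p("variants.vcf"))
  vt2 <- read_vcf_subset(p("variants.vcf"))
  filt <- apply_hard_filters(vt2, filter_config())
  write_vcf(filt$passed, p("variants.passed.vcf"))
  write_tsv_table(data.frame(rule = names(filt$tally),
                             rejected = filt$tally), p("filter_tally.tsv"))
  out$filter <- list(n_in = nrow(vt2), n_passed = nrow(filt$passed),
                     tally = filt$tally)
  out$tstv <- ts_tv_ratio(filt$passed)

  # 2. dosage genotyping and single-dose markers
  sim <- simulate_locus_counts(config)
  write_tsv_table(sim$counts, p("allele_counts.tsv"))
  counts <- read_tsv_table(p("allele_counts.tsv"))
  geno <- counts[, c("locus", "accession", "ploidy")]
  calls <- vector("list", length(config$accessions))
  for (a in seq_along(config$accessions)) {
    acc <- names(config$accessions)[a]
    rows <- counts[counts$accession == acc, ]
    dc <- call_dosage(rows$ref_count, rows$alt_count,
                      config$accessions[[a]],
                      dosage_config(error_rate = config$error_rate))
    calls[[a]] <- cbind(rows[, c("locus", "accession")], dc)
  }
  geno <- data.table::rbindlist(calls)
  write_tsv_table(geno, p("genotypes.tsv"))
  out$sdm <- sdm_table(geno)
  aligned_len <- max(counts$pos)
  out$heterozygosity <- geno[, list(
    het_rate = heterozygosity_rate(sum(class == "het" & !no_call,
                                       na.rm = TRUE), aligned_len)),
    by = "accession"]

  # 3. gene CNV / PAV on the first accession pair
  gd <- simulate_gene_depths(config)
  write_tsv_table(gd$depths, p("gene_depths.tsv"))
  pair <- gene_depth_pairs(gd$depths, names(config$accessions)[1],
                           names(config$accessions)[2])
  cnv <- call_cnv(pair)
  pav <- call_pav(pair)
  write_tsv_table(cnv, p("cnv_calls.tsv"))
  write_tsv_table(pav, p("pav_calls.tsv"))
  out$cnv <- cnv; out$pav <- pav

  # 4. annotation on a synthetic genome
  ga <- simulate_gene_models(n_genes = 10L, seed = config$seed)
  write_fasta(ga$genome, p("genome.fa"))
  write_gff3(ga$models, p("genes.gff3"))
  models <- read_gff3(p("genes.gff3"))
  set.seed(derive_seed(config$seed, 9L))
  ann <- annotate_random_snps(models, ga$genome, n = 200L)
  write_tsv_table(ann, p("annotation.tsv"))
  out$annotation <- table(ann$region)

  # 5. probe features and capture model
  pr <- simulate_probes(config)
  write_fasta(pr$sequences, p("probes.fa"))
  write_tsv_table(pr$counts, p("probe_counts.tsv"))
  feats <- pr$features
  feats$reads <- pr$counts$reads
  ok <- select_successful_probes(feats)
  pruned <- prune_correlated(ok[, c("gc", "tm", "pmfe", "phfe",
                                    "hairpin", "dimer")])
  model <- fit_capture_model(ok[, pruned$keep, drop = FALSE], ok$reads)
  jsonlite::write_json(list(coefficients = as.list(model$coefficients),
                            r_squared = model$r_squared,
                            importance = as.list(model$importance)),
                       p("capture_model.json"), auto_unbox = TRUE,
                       digits = NA)
  out$capture_model <- model

  # 6. Ka/Ks divergence dating
  div <- lapply(seq_len(nrow(config$cds_pairs)), function(i) {
    pairi <- simulate_cds_pair(config$cds_pairs$length_codons[i],
                               config$cds_pairs$target_ks[i],
                               seed = config$seed + i)
    kk <- kaks_counting(pairi$ancestor, pairi$derived,
                        label = sprintf("pair%d", i))
    data.frame(label = kk$label, Ks = kk$Ks, Ka = kk$Ka,
               Ka_Ks = kk$Ka_Ks, time_years = divergence_time(kk$Ks))
  })
  div <- do.call(rbind, div)
  write_tsv_table(div, p("divergence.tsv"))
  out$divergence <- div

  # 7. bootstrap NJ tree from the dosage genotype matrix
  gm <- data.table::dcast(geno, locus ~ accession, value.var = "dosage")
  gmat <- as.matrix(gm[, -1L])
  tree <- nj_tree_with_bootstrap(gmat, replicates = boot_replicates,
                                 seed = config$seed)
  write_newick(tree, p("tree.nwk"))
  out$tree <- tree

  out$files <- list.files(outdir, full.names = TRUE)
  out
}

# classify + coding effects for random positions inside gene spans;
# used by the pipeline and the CLI annotate command
annotate_random_snps <- function(models, genome, n = 200L) {
  spans <- do.call(rbind, lapply(models, function(m)
    data.frame(chrom = m$chrom, start = m$start, end = m$end)))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    g <- sample.int(nrow(spans), 1L)
    pos0 <- sample(spans$start[g]:(spans$end[g] - 1L), 1L)
    ref <- substr(genome[[spans$chrom[g]]], pos0 + 1L, pos0 + 1L)
    alt <- sample(setdiff(DNA_BASES, ref), 1L)
    cl <- classify_region(pos0, spans$chrom[g], models)
    effect <- "none"
    if (cl$region == "exon" && !is.na(cl$gene_id)) {
      m <- models[[cl$gene_id]]
      if (nrow(m$cds) && any(m$cds$start <= pos0 & pos0 < m$cds$end)) {
        effect <- coding_effect(pos0, ref, alt, m, genome)$effect
      }
    }
    rows[[i]] <- data.frame(chrom = spans$chrom[g], pos = pos0 + 1L,
                            ref = ref, alt = alt, region = cl$region,
                            gene_id = cl$gene_id, effect = effect,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
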