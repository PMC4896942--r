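test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(seed = 42, n_loci = 200L, n_genes = 300L,
                    probe_count = 30L)
  expect_identical(simulate_locus_counts(cfg), simulate_locus_counts(cfg))
  expect_identical(simulate_gene_depths(cfg), simulate_gene_depths(cfg))
  expect_identical(simulate_probes(cfg)$sequences,
                   simulate_probes(cfg)$sequences)
  expect_identical(simulate_cds_pair(100, 0.05, seed = 3),
                   simulate_cds_pair(100, 0.05, seed = 3))
})

test_that("locus counts follow the dosage model at the boundaries", {
  fix_d <- function(d_target) function(m) {
    w <- numeric(m + 1); w[d_target + 1] <- 1; w
  }
  cfg0 <- sim_config(seed = 1, accessions = c(X = 8L), n_loci = 300L,
                     error_rate = 1e-12, dosage_distribution = fix_d(0))
  sim0 <- simulate_locus_counts(cfg0)
  expect_true(all(sim0$counts$alt_count == 0L))

  cfg8 <- sim_config(seed = 1, accessions = c(X = 8L), n_loci = 300L,
                     error_rate = 1e-12, dosage_distribution = fix_d(8))
  sim8 <- simulate_locus_counts(cfg8)
  expect_true(all(sim8$counts$ref_count == 0L))

  # binomial expectation at d = 1, m = 8, e = 0
  cfg1 <- sim_config(seed = 2, accessions = c(X = 8L), n_loci = 100000L,
                     error_rate = 1e-12, dosage_distribution = fix_d(1))
  sim1 <- simulate_locus_counts(cfg1)
  frac <- with(sim1$counts, alt_count / (ref_count + alt_count))
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.125), 3 * se + 1e-6)
})

test_that("odd ploidy and invalid fractions are rejected", {
  expect_error(sim_config(accessions = c(X = 7L)), "even")
  expect_error(sim_config(cnv_fraction = 0.6, pav_fraction = 0.6), "<= 1")
})

test_that("gene depth simulation plants PAV and CNV as configured", {
  cfg <- sim_config(seed = 5, n_genes = 2000L, cnv_fraction = 0.02,
                    cnv_log2_effect = 1, pav_fraction = 0.02)
  gd <- simulate_gene_depths(cfg)
  acc <- names(cfg$accessions)[1:2]
  tr <- gd$truth
  # absent genes have exactly zero reads
  absent <- tr[!tr$present, ]
  for (i in seq_len(nrow(absent))) {
    r <- gd$depths[gd$depths$gene_id == absent$gene_id[i] &
                     gd$depths$accession == absent$accession[i], ]
    expect_identical(r$reads, 0L)
  }
  # planted 2-fold genes: mean observed log2 ratio ~ 1 +/- 0.1
  pair <- gene_depth_pairs(gd$depths, acc[1], acc[2])
  up_genes <- tr$gene_id[tr$accession == acc[1] & tr$log2_copy_ratio == 1]
  obs <- pair$log2_ratio[match(up_genes, pair$gene_id)]
  expect_lt(abs(mean(obs, na.rm = TRUE) - 1), 0.1)

  # zero effect size leaves no trace
  cfg0 <- sim_config(seed = 5, n_genes = 2000L, cnv_fraction = 0.02,
                     cnv_log2_effect = 0, pav_fraction = 0)
  gd0 <- simulate_gene_depths(cfg0)
  expect_true(all(gd0$truth$log2_copy_ratio == 0))
})

test_that("ground-truth dosage marginals match configured weights", {
  cfg <- sim_config(seed = 10, accessions = c(X = 8L), n_loci = 10000L)
  sim <- simulate_locus_counts(cfg)
  w <- cfg$dosage_distribution(8L)
  obs <- tabulate(sim$truth$dosage + 1L, 9L) / 10000
  # each class within 4 binomial s.e.
  se <- sqrt(w * (1 - w) / 10000)
  expect_true(all(abs(obs - w) < 4 * se + 1e-3))
})

test_that("probe simulation: GC span, planted stems, noiseless surface", {
  cfg <- sim_config(seed = 6, probe_count = 40L, probe_noise_sd = 0)
  pr <- simulate_probes(cfg)
  expect_true(all(pr$features$gc >= 10 & pr$features$gc <= 90))
  planted <- pr$truth$planted_hairpin
  expect_gt(sum(planted), 0)
  expect_true(all(pr$features$hairpin[planted] >= 10))
  # sigma = 0: counts sit exactly on the configured linear surface
  expect_identical(pr$counts$reads,
                   as.integer(pmax(0, round(pr$truth$expected_reads))))
  # too-short probes for stem planting
  expect_error(
    simulate_probes(sim_config(probe_length = 20L), stem_length = 10L),
    "too short")
})

test_that("CDS pair simulation respects target Ks and purity", {
  p0 <- simulate_cds_pair(200, 0, seed = 1)
  expect_identical(p0$ancestor, p0$derived)

  p <- simulate_cds_pair(500, 0.05, seed = 2)
  for (s in c(p$ancestor, p$derived)) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
  # only synonymous change was applied
  kk <- kaks_counting(p$ancestor, p$derived)
  expect_identical(kk$Nd, 0)
  # unrealizable Ks errors with the achievable maximum
  expect_error(simulate_cds_pair(10, 50, seed = 1), "achievable maximum")
})

test_that("every generated file parses back with zero warnings", {
  cfg <- sim_config(seed = 3, n_loci = 50L, n_genes = 120L,
                    probe_count = 25L)
  td <- withr::local_tempdir()
  sim <- simulate_locus_counts(cfg)
  write_tsv_table(sim$counts, file.path(td, "c.tsv"))
  vt <- simulate_variant_table(60L, seed = 3)
  write_vcf(vt, file.path(td, "v.vcf"))
  pr <- simulate_probes(cfg)
  write_fasta(pr$sequences, file.path(td, "p.fa"))
  ga <- simulate_gene_models(4L, seed = 3)
  write_gff3(ga$models, file.path(td, "g.gff3"))
  expect_no_warning({
    read_tsv_table(file.path(td, "c.tsv"))
    read_vcf_subset(file.path(td, "v.vcf"))
    read_fasta(file.path(td, "p.fa"))
    read_gff3(file.path(td, "g.gff3"))
  })
})

test_that("SNP matrices follow the generating topology", {
  tc <- simulate_two_clades(3, 3, n_loci = 400, seed = 9)
  g <- tc$genotypes
  within_d <- mean(g[, "A1"] != g[, "A2"])
  between_d <- mean(g[, "A1"] != g[, "B1"])
  expect_gt(between_d, 3 * within_d)
  expect_identical(simulate_snp_matrix(tc$tree, 100, seed = 2),
                   simulate_snp_matrix(tc$tree, 100, seed = 2))
})
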