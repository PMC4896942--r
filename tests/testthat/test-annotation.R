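# hand-built plus-strand gene: 10 bp UTR5, two CDS exons, intron, UTR3
# genome layout (0-based): [0,10) utr5+ [10,22) cds1 + [22,80) intron +
# [80,110) cds2 + [110,120) utr3, all inside one exon pair
fixture_gene <- function() {
  utr5 <- "TTTTTTTTTT"
  cds1 <- "ATGAAATTTCCC"          # M K F P...
  intron <- paste(rep("G", 58), collapse = "")
  cds2 <- c("GGG", "TAT", "CAC", "GAT", "TGC", "AAA", "CCC", "GGG", "ACT",
            "TAA")
  cds2 <- paste(cds2, collapse = "")
  utr3 <- "CCCCCCCCCC"
  genome <- c(chr1 = paste0(utr5, cds1, intron, cds2, utr3))
  model <- gene_model("gX", "chr1", 0L, 120L, "+",
                      exons = data.frame(start = c(0L, 80L),
                                         end = c(22L, 120L)),
                      cds = data.frame(start = c(10L, 80L),
                                       end = c(22L, 110L)),
                      utr5 = data.frame(start = 0L, end = 10L),
                      utr3 = data.frame(start = 110L, end = 120L))
  list(genome = genome, model = model)
}

test_that("region classification honors the priority and splice window", {
  fx <- fixture_gene()
  models <- list(gX = fx$model)
  cls <- function(p) classify_region(p, "chr1", models)$region
  expect_equal(cls(15), "exon")         # CDS
  expect_equal(cls(5), "utr5")          # UTR beats plain exon
  expect_equal(cls(115), "utr3")
  expect_equal(cls(22), "splice_site")  # 1st intron base after exon
  expect_equal(cls(23), "splice_site")  # 2nd intron base
  expect_equal(cls(24), "intron")       # 3rd intron base
  expect_equal(cls(79), "splice_site")  # 1 bp before next exon
  expect_equal(cls(50), "intron")
  expect_equal(classify_region(500, "chr1", models)$region, "intergenic")
  expect_equal(classify_region(15, "chr2", models)$region, "intergenic")
})

test_that("coding effects on the plus strand match the genetic code", {
  fx <- fixture_gene()
  # codon 2 = AAA (Lys) at genomic 13..15; AAA->AAG synonymous
  eff <- coding_effect(15, "A", "G", fx$model, fx$genome)
  expect_equal(eff$effect, "synonymous")
  expect_equal(eff$codon_ref, "AAA")
  expect_equal(eff$codon_alt, "AAG")
  # TAT (Tyr) at genomic 83..85; T->A at 3rd base gives TAA stop
  eff2 <- coding_effect(85, "T", "A", fx$model, fx$genome)
  expect_equal(eff2$effect, "stop_gained")
  # ATG start at 10..12 disrupted
  eff3 <- coding_effect(10, "A", "C", fx$model, fx$genome)
  expect_equal(eff3$effect, "start_lost")
  # AAA->ACA nonsynonymous
  eff4 <- coding_effect(14, "A", "C", fx$model, fx$genome)
  expect_equal(eff4$effect, "nonsynonymous")
  # reference mismatch is an error
  expect_error(coding_effect(15, "C", "G", fx$model, fx$genome), "mismatch")
})

test_that("effects agree with the translate-both-sequences oracle", {
  ga <- simulate_gene_models(n_genes = 8L, seed = 17)
  set.seed(17)
  n_checked <- 0
  for (rep in 1:400) {
    m <- ga$models[[sample(length(ga$models), 1)]]
    if (!nrow(m$cds)) next
    seg <- m$cds[sample(nrow(m$cds), 1), ]
    pos0 <- sample(seg$start:(seg$end - 1), 1)
    ref <- substr(ga$genome[[m$chrom]], pos0 + 1, pos0 + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- coding_effect(pos0, ref, alt, m, ga$genome)$effect
    want <- oracle_coding_effect(pos0, ref, alt, m, ga$genome)
    expect_equal(got, want,
                 info = sprintf("%s pos %d %s>%s", m$gene_id, pos0, ref, alt))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 300)
  # both strands exercised
  strands <- vapply(ga$models, `[[`, character(1), "strand")
  expect_setequal(unique(strands), c("+", "-"))
})

test_that("InDel frame classes follow length mod 3 inside CDS", {
  fx <- fixture_gene()
  models <- list(gX = fx$model)
  expect_equal(indel_frame_class(12, "AAAA", "A", models, "chr1"),
               "in_frame")                      # 3-bp deletion in CDS
  expect_equal(indel_frame_class(12, "A", "ATT", models, "chr1"),
               "frameshift")                    # 2-bp insertion
  expect_equal(indel_frame_class(3, "AGGGG", "A", models, "chr1"), "none")
  expect_equal(indel_frame_class(50, "AG", "A", models, "chr1"), "none")
  expect_error(indel_frame_class(12, "A", "G", models, "chr1"), "not an InDel")
})

test_that("density summaries partition counts", {
  v <- data.frame(chrom = "chr1", pos = c(1, 5, 10, 150, 2e6 + 1))
  d <- density_summary(v, window_size = 1e6)
  expect_equal(sum(d$windows$count), nrow(v))

  fx <- fixture_gene()
  v2 <- data.frame(chrom = "chr1", pos = seq(5, 95, by = 10))
  d2 <- density_summary(v2, window_size = 1e6, models = list(fx$model))
  expect_equal(d2$genes$count, 10L)
  expect_equal(d2$genes$bases_per_variant, 12)  # 120 bp / 10 variants

  d0 <- density_summary(v[0, ], window_size = 1e6)
  expect_equal(nrow(d0$windows), 0L)
})

test_that("multi-gene overlap resolves to the longest CDS", {
  fx <- fixture_gene()
  small <- gene_model("gY", "chr1", 0L, 40L, "+",
                      exons = data.frame(start = 0L, end = 40L),
                      cds = data.frame(start = 10L, end = 22L))
  res <- classify_region(15, "chr1", list(gX = fx$model, gY = small))
  expect_equal(res$gene_id, "gX")  # 42 bp CDS beats 12 bp
  expect_equal(nrow(res$all_hits), 2L)
})
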