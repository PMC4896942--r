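test_that("normalized depth formula and homogeneity", {
  expect_identical(normalize_depth(100, 1e7, 1000), 10)
  expect_identical(normalize_depth(0, 1e7, 1000), 0)
  expect_equal(normalize_depth(100, 1e7, 1000),
               normalize_depth(100 * 7, 1e7 * 7, 1000))
  expect_error(normalize_depth(10, 0, 100), "total_mapped")
  expect_error(normalize_depth(10, 100, 0), "gene_length")
  expect_error(normalize_depth(-1, 100, 100), "reads")
})

# helper: depth table for two accessions from per-gene read vectors
depth_pair_table <- function(q_reads, s_reads, len = 1000L) {
  ng <- length(q_reads)
  ids <- sprintf("g%04d", seq_len(ng))
  data.table::rbindlist(list(
    data.table::data.table(gene_id = ids, length = len, accession = "Q",
                           reads = q_reads, total_mapped = sum(q_reads)),
    data.table::data.table(gene_id = ids, length = len, accession = "S",
                           reads = s_reads, total_mapped = sum(s_reads))))
}

test_that("CNV calling: degenerate, planted, antisymmetric", {
  # all ratios identical -> strict inequality yields zero calls
  tab <- depth_pair_table(rep(100L, 200), rep(100L, 200))
  pair <- gene_depth_pairs(tab, "Q", "S")
  expect_equal(nrow(call_cnv(pair)), 0L)

  # planted +3 sigma outliers are recovered
  set.seed(51)
  q <- rpois(1000, 200); s <- rpois(1000, 200)
  q[1:10] <- rpois(10, 200 * 8)
  tab2 <- depth_pair_table(q, s)
  pair2 <- gene_depth_pairs(tab2, "Q", "S")
  calls <- call_cnv(pair2)
  up <- calls$gene_id[calls$type == "up_cnv"]
  expect_gte(sum(sprintf("g%04d", 1:10) %in% up), 9L)

  # antisymmetry: up on (Q,S) equals down on (S,Q)
  rev_calls <- call_cnv(gene_depth_pairs(tab2, "S", "Q"))
  expect_setequal(up, rev_calls$gene_id[rev_calls$type == "down_cnv"])
  expect_setequal(calls$gene_id[calls$type == "down_cnv"],
                  rev_calls$gene_id[rev_calls$type == "up_cnv"])

  # too few eligible genes
  small <- gene_depth_pairs(depth_pair_table(rep(50L, 20), rep(50L, 20)),
                            "Q", "S")
  expect_error(call_cnv(small), "20")
})

test_that("PAV criteria match the brute-force predicate on a grid", {
  grid <- expand.grid(q = 0:2, s = 0:15, nd = seq(0, 0.2, by = 0.01))
  # build one fake pair row per grid point; use length/total so that
  # norm_subject equals nd exactly: nd = 1e9 * s / (total * len)
  for (i in seq_len(nrow(grid))) {
    q <- grid$q[i]; s <- grid$s[i]; nd <- grid$nd[i]
    total <- 1e9; len <- if (nd > 0 && s > 0) 1e9 * s / (total * nd) else 1e6
    pair <- data.table::data.table(
      gene_id = "g", length = len, reads_query = q, total_mapped_query = total,
      reads_subject = s, total_mapped_subject = total,
      norm_query = normalize_depth(q, total, len),
      norm_subject = normalize_depth(s, total, len))
    pair$log2_ratio <- NA_real_
    got <- call_pav(pair)
    want_q <- (q == 0) && (s >= 10) && (pair$norm_subject >= 0.1)
    want_s <- (s == 0) && (q >= 10) && (pair$norm_query >= 0.1)
    expect_equal(sum(got$type == "pav_absent_in_query"), as.integer(want_q))
    expect_equal(sum(got$type == "pav_absent_in_subject"), as.integer(want_s))
  }
})

test_that("PAV examples as printed", {
  mk <- function(q_reads, s_reads, nd_subject) {
    len <- 1000; total_s <- 1e9 * s_reads / (nd_subject * len)
    data.table::data.table(
      gene_id = "g", length = len, reads_query = q_reads,
      total_mapped_query = 1e7, reads_subject = s_reads,
      total_mapped_subject = total_s,
      norm_query = normalize_depth(q_reads, 1e7, len),
      norm_subject = nd_subject, log2_ratio = NA_real_)
  }
  expect_equal(call_pav(mk(0, 12, 0.15))$type, "pav_absent_in_query")
  expect_equal(nrow(call_pav(mk(0, 12, 0.05))), 0L)
  expect_equal(nrow(call_pav(mk(1, 500, 5))), 0L)
})

test_that("CNV and PAV call sets are disjoint by construction", {
  cfg <- sim_config(seed = 52, n_genes = 2000L)
  gd <- simulate_gene_depths(cfg)
  acc <- names(cfg$accessions)[1:2]
  pair <- gene_depth_pairs(gd$depths, acc[1], acc[2])
  cnv <- call_cnv(pair)
  pav <- call_pav(pair)
  expect_length(intersect(cnv$gene_id, pav$gene_id), 0L)
})

test_that("pairwise matrix formats Table-2 style cells", {
  empty <- list(cnv = data.table::data.table(gene_id = character(),
                                             type = character()),
                pav = data.table::data.table(gene_id = character(),
                                             type = character()))
  calls <- list("A|B" = empty, "B|A" = empty)
  m <- pairwise_matrix(calls, c("A", "B"))
  expect_equal(m["A", "B"], "0/0 (0/0)")

  one_up <- empty
  one_up$cnv <- data.table::data.table(gene_id = "g1", type = "up_cnv")
  m2 <- pairwise_matrix(list("A|B" = one_up, "B|A" = empty), c("A", "B"))
  expect_equal(m2["A", "B"], "1/0 (0/0)")
  # reverse direction derived by antisymmetry when stored once
  m3 <- pairwise_matrix(list("A|B" = one_up), c("A", "B"))
  expect_equal(m3["B", "A"], "0/1 (0/0)")

  expect_error(pairwise_matrix(list(), c("A", "B")), "missing calls")

  # cell counts equal per-pair call list lengths on simulated calls
  cfg <- sim_config(seed = 53, n_genes = 1500L)
  gd <- simulate_gene_depths(cfg)
  acc <- names(cfg$accessions)[1:2]
  pair <- gene_depth_pairs(gd$depths, acc[1], acc[2])
  cl <- list(cnv = call_cnv(pair), pav = call_pav(pair))
  key <- paste(acc[1], acc[2], sep = "|")
  mm <- pairwise_matrix(stats::setNames(list(cl), key), acc)
  want <- sprintf("%d/%d (%d/%d)",
                  sum(cl$cnv$type == "up_cnv"),
                  sum(cl$cnv$type == "down_cnv"),
                  sum(cl$pav$type == "pav_absent_in_subject"),
                  sum(cl$pav$type == "pav_absent_in_query"))
  expect_equal(mm[acc[1], acc[2]], want)
})
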