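#' Simulate a small genome with gene models
#'
#' Builds a synthetic contig carrying non-overlapping genes on both
#' strands.  Each gene has a translatable CDS (ATG start, sense codons, a
#' terminal stop), optional UTRs, and 1--3 exons with introns of 30--200
#' bp.  Used for annotation tests and the end-to-end pipeline; the
#' returned models round-trip through [write_gff3()] / [read_gff3()].
#'
#' @param n_genes number of genes
#' @param seed integer seed
#' @param chrom contig name
#' @return list with `genome` (named character vector of length 1) and
#'   `models` (list of [gene_model()])
#' @export
simulate_gene_models <- function(n_genes = 20L, seed = 1L, chrom = "chr1") {
  set.seed(derive_seed(seed, 6L))
  models <- vector("list", n_genes)
  pieces <- character()
  offset <- 0L
  for (g in seq_len(n_genes)) {
    gap <- random_dna(1L, sample(100:500, 1L))
    pieces <- c(pieces, gap)
    offset <- offset + nchar(gap)

    n_codons <- sample(20:100, 1L)
    cds_seq <- paste0("ATG",
                      paste(sample(SENSE_CODONS, n_codons - 2L, TRUE),
                            collapse = ""),
                      sample(STOP_CODONS, 1L))
    u5 <- random_dna(1L, sample(0:60, 1L))
    u3 <- random_dna(1L, sample(0:60, 1L))
    tx <- paste0(u5, cds_seq, u3)
    txlen <- nchar(tx)
    n_exons <- sample(1:3, 1L)
    cuts <- if (n_exons > 1L) {
      sort(sample(seq_len(txlen - 1L), n_exons - 1L))
    } else integer()
    ex_start <- c(0L, cuts)          # tx coordinates, 0-based half-open
    ex_end <- c(cuts, txlen)
    introns <- vapply(seq_len(max(0L, n_exons - 1L)),
                      function(i) random_dna(1L, sample(30:200, 1L)),
                      character(1))

    # plus-layout genomic arrangement: exon1 intron1 exon2 ...
    glen <- txlen + sum(nchar(introns))
    gstart_in_layout <- integer(n_exons)   # genomic (layout) exon starts
    cum <- 0L
    layout_seq <- character()
    for (i in seq_len(n_exons)) {
      gstart_in_layout[i] <- cum
      layout_seq <- c(layout_seq, substr(tx, ex_start[i] + 1L, ex_end[i]))
      cum <- cum + (ex_end[i] - ex_start[i])
      if (i < n_exons) {
        layout_seq <- c(layout_seq, introns[i])
        cum <- cum + nchar(introns[i])
      }
    }
    layout_seq <- paste(layout_seq, collapse = "")

    tx2layout <- function(p) {  # tx coord -> layout coord
      i <- findInterval(p, ex_start)
      gstart_in_layout[i] + (p - ex_start[i])
    }
    # map a tx-interval [s,e) to layout intervals, split at exon borders
    map_feature <- function(s, e) {
      segs <- list()
      for (i in seq_len(n_exons)) {
        a <- max(s, ex_start[i]); b <- min(e, ex_end[i])
        if (a < b) segs[[length(segs) + 1L]] <-
            c(tx2layout(a), tx2layout(a) + (b - a))
      }
      if (!length(segs)) return(data.frame(start = integer(), end = integer()))
      m <- do.call(rbind, segs)
      data.frame(start = m[, 1], end = m[, 2])
    }
    cds_tx <- c(nchar(u5), nchar(u5) + nchar(cds_seq))
    ex_layout <- data.frame(start = gstart_in_layout,
                            end = gstart_in_layout + (ex_end - ex_start))
    feat <- list(exons = ex_layout,
                 cds = map_feature(cds_tx[1], cds_tx[2]),
                 utr5 = map_feature(0L, nchar(u5)),
                 utr3 = map_feature(cds_tx[2], txlen))
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") {
      layout_seq <- revcomp(layout_seq)
      flip <- function(df) {
        if (!nrow(df)) return(df)
        out <- data.frame(start = glen - df$end, end = glen - df$start)
        out[order(out$start), , drop = FALSE]
      }
      feat <- lapply(feat, flip)
    }
    models[[g]] <- gene_model(sprintf("g%03d", g), chrom,
                              offset, offset + glen, strand,
                              exons = feat$exons + offset,
                              cds = feat$cds + offset,
                              utr5 = feat$utr5 + offset,
                              utr3 = feat$utr3 + offset)
    pieces <- c(pieces, layout_seq)
    offset <- offset + glen
  }
  pieces <- c(pieces, random_dna(1L, 200L))
  genome <- stats::setNames(paste(pieces, collapse = ""), chrom)
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  list(genome = genome, models = models)
}

#' Simulate a binary SNP matrix down a known topology
#'
#' Starting from an all-reference root, each locus is flipped along each
#' branch with probability `1 - exp(-branch_length)`, giving a genotype
#' matrix whose expected divergence structure reflects the tree.  Used to
#' make tree-recovery tests exact against a ground-truth topology.
#'
#' @param tree a `phylo` with branch lengths
#' @param n_loci number of loci
#' @param seed integer seed
#' @return integer matrix, loci in rows, tips (accessions) in columns
#' @export
simulate_snp_matrix <- function(tree, n_loci = 500L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  set.seed(derive_seed(seed, 7L))
  tree <- stats::reorder(tree, "cladewise")  # parent before child
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(0L, nrow = n_loci, ncol = nnode)
  root <- ntip + 1L
  for (k in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    p <- 1 - exp(-tree$edge.length[k])
    flips <- stats::rbinom(n_loci, 1L, p)
    states[, child] <- (states[, parent] + flips) %% 2L
  }
  out <- states[, seq_len(ntip), drop = FALSE]
  colnames(out) <- tree$tip.label
  out
}

#' Simulate SNPs for two well-separated clades
#'
#' Convenience wrapper around [simulate_snp_matrix()] on a two-clade
#' topology whose between-clade branch is `ratio` times the within-clade
#' branches.
#'
#' @param n1,n2 tips per clade
#' @param n_loci number of loci
#' @param within within-clade branch length
#' @param ratio between/within branch-length ratio (default 10)
#' @param seed integer seed
#' @return list with `genotypes` (matrix) and `tree` (the generating
#'   `phylo`)
#' @export
simulate_two_clades <- function(n1 = 4L, n2 = 4L, n_loci = 500L,
                                within = 0.02, ratio = 10, seed = 1L) {
  mk <- function(labs, bl) paste0(
    "(", paste(sprintf("%s:%g", labs, bl), collapse = ","), ")")
  between <- within * ratio / 2
  txt <- sprintf("(%s:%g,%s:%g);",
                 mk(sprintf("A%d", seq_len(n1)), within), between,
                 mk(sprintf("B%d", seq_len(n2)), within), between)
  tree <- ape::read.tree(text = txt)
  list(genotypes = simulate_snp_matrix(tree, n_loci, seed), tree = tree)
}
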