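#' Pairwise SNP distance matrix
#'
#' Distances between accessions over bi-allelic loci without missing data
#' (complete cases).  `method = "mismatch"` (default) is the fraction of
#' loci with differing genotype calls; `method = "dosage"` is the mean
#' absolute difference of dosage fractions `|d_i/m_i - d_j/m_j|`
#' (requires a `ploidy` vector).
#'
#' @param genotypes matrix with loci in rows and accessions in columns
#'   (genotype calls: any comparable coding for `"mismatch"`, alternate
#'   dosage for `"dosage"`)
#' @param method `"mismatch"` or `"dosage"`
#' @param ploidy named vector accession -> ploidy (only for `"dosage"`)
#' @return object of class `dist`, with attribute `n_loci` (shared loci
#'   used)
#' @export
snp_distance_matrix <- function(genotypes, method = c("mismatch", "dosage"),
                                ploidy = NULL) {
  method <- match.arg(method)
  g <- as.matrix(genotypes)
  if (ncol(g) < 2L) stop("need at least 2 accessions")
  g <- g[stats::complete.cases(g), , drop = FALSE]
  if (!nrow(g)) stop("no loci without missing data shared by all accessions")
  acc <- colnames(g) %||% sprintf("acc%d", seq_len(ncol(g)))
  n <- ncol(g)
  d <- matrix(0, n, n, dimnames = list(acc, acc))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- if (method == "mismatch") {
        mean(g[, i] != g[, j])
      } else {
        stopifnot(!is.null(ploidy))
        mean(abs(g[, i] / ploidy[[acc[i]]] - g[, j] / ploidy[[acc[j]]]))
      }
    }
  }
  out <- stats::as.dist(d)
  attr(out, "n_loci") <- nrow(g)
  out
}

#' Neighbor-joining SNP tree with bootstrap support
#'
#' Builds a neighbor-joining tree from the SNP distance matrix and, when
#' `replicates > 0`, resamples loci with replacement, rebuilds the tree
#' per replicate, and records split frequencies (in %) as internal node
#' labels.  Deterministic for a given seed.
#'
#' @param genotypes matrix, loci in rows, accessions in columns
#' @param replicates bootstrap replicates (default 1000; 0 = no support
#'   values)
#' @param seed integer seed for the resampling
#' @param method distance method, see [snp_distance_matrix()]
#' @param ploidy see [snp_distance_matrix()]
#' @return a `phylo` tree; `node.label` holds bootstrap percentages when
#'   `replicates > 0`
#' @export
nj_tree_with_bootstrap <- function(genotypes, replicates = 1000L, seed = 1L,
                                   method = "mismatch", ploidy = NULL) {
  g <- as.matrix(genotypes)
  if (ncol(g) < 3L) stop("need at least 3 accessions")
  d <- snp_distance_matrix(g, method = method, ploidy = ploidy)
  if (any(!is.finite(d))) stop("non-finite distances")
  tree <- ape::nj(d)
  if (replicates > 0L) {
    set.seed(derive_seed(seed, 8L))
    boot <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      idx <- sample.int(nrow(g), nrow(g), replace = TRUE)
      db <- snp_distance_matrix(g[idx, , drop = FALSE], method = method,
                                ploidy = ploidy)
      boot[[r]] <- ape::nj(db)
    }
    counts <- ape::prop.clades(tree, boot, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    tree$node.label <- round(100 * counts / replicates)
  }
  tree
}
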