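# Independent brute-force oracles.  These deliberately re-derive every
# quantity from first principles, sharing no code path with the package.

# --- six-predicate hard filter, one record at a time -------------------
oracle_filter_pass <- function(variants, min_mq = 30, min_bq = 20,
                               min_alt = 2, max_dp = 3000, min_dp = 600,
                               min_qual = 80) {
  vapply(seq_len(nrow(variants)), function(i) {
    if (variants$unfilterable[i]) return(FALSE)
    mq <- variants$mq[i]; bq <- variants$bq[i]; q <- variants$qual[i]
    ad <- variants$ad[[i]]
    if (is.na(mq) || is.na(bq) || is.na(q)) return(FALSE)
    dp <- sum(ad, na.rm = TRUE)
    ok_alt <- TRUE
    if (nrow(ad) >= 2) {
      for (s in seq_len(ncol(ad))) {
        col <- ad[, s]
        if (all(is.na(col))) next
        a <- sum(col[-1], na.rm = TRUE)
        if (a > 0 && a <= min_alt) ok_alt <- FALSE
      }
    }
    mq > min_mq && bq > min_bq && ok_alt && dp < max_dp && dp > min_dp &&
      q > min_qual
  }, logical(1))
}

# --- hairpin / dimer scores by exhaustive placement --------------------
BASES <- c("A", "C", "G", "T")
comp_of <- c(A = "T", C = "G", G = "C", T = "A")

oracle_hairpin <- function(s, minloop = 3) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  best <- 0
  for (i in seq_len(n)) {       # left stem start
    for (j in seq_len(n)) {     # right stem start
      for (L in seq_len(n)) {
        if (j + L - 1 > n) break
        if (j - (i + L - 1) - 1 < minloop) break  # loop between inner ends
        ok <- all(vapply(0:(L - 1), function(t)
          comp_of[[v[i + t]]] == v[j + L - 1 - t], logical(1)))
        if (ok && L > best) best <- L
      }
    }
  }
  best
}

oracle_dimer <- function(s) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  best <- 0
  rc <- function(x) rev(unname(comp_of[x]))
  for (i in seq_len(n)) {
    for (L in seq_len(n - i + 1)) {
      seg <- v[i:(i + L - 1)]
      pat <- paste(rc(seg), collapse = "")
      if (grepl(pat, s, fixed = TRUE)) {
        if (L > best) best <- L
      }
    }
  }
  best
}

# --- PMFE: exhaustive enumeration of all non-crossing structures -------
# (C++ enum in the package is itself an oracle; this R version cross-checks
# it on very short sequences)
oracle_pmfe_r <- function(s, minloop = 3) {
  v <- strsplit(s, "")[[1]]
  w <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3)
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(2)
    if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(1)
    0
  }
  rec <- function(i, j) {
    if (j - i < minloop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + minloop + 1):j) {
      wk <- w(v[i], v[k])
      if (wk == 0) next
      cand <- wk + rec(i + 1, k - 1) + rec(k + 1, j)
      if (cand > best) best <- cand
    }
    best
  }
  -rec(1, length(v))
}

# --- NG86 pathway counting, independent recursion ----------------------
GEN_CODE <- Biostrings::GENETIC_CODE
oracle_path_counts <- function(c1, c2) {
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(d)) return(c(0, 0))
  paths <- list()
  walk <- function(cur, remaining, sy, ns, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sy, ns, blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      is_stop <- GEN_CODE[[nxt]] == "*" && nxt != c2
      step_syn <- GEN_CODE[[cur]] == GEN_CODE[[nxt]]
      walk(nxt, setdiff(remaining, p),
           sy + as.integer(step_syn), ns + as.integer(!step_syn),
           blocked || is_stop)
    }
  }
  walk(c1, d, 0L, 0L, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(mean(m[ok, 1]), mean(m[ok, 2]))
}

oracle_syn_sites <- function(codon) {
  aa <- GEN_CODE[[codon]]
  tot <- 0
  for (p in 1:3) {
    for (b in setdiff(BASES, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      if (GEN_CODE[[alt]] != "*" && GEN_CODE[[alt]] == aa) tot <- tot + 1 / 3
    }
  }
  tot
}

# --- coding effect by translating both full CDS copies -----------------
oracle_coding_effect <- function(pos0, ref, alt, model, genome) {
  splice <- function(base_override = NULL) {
    g <- genome[[model$chrom]]
    if (!is.null(base_override)) {
      substr(g, pos0 + 1, pos0 + 1) <- base_override
    }
    segs <- vapply(seq_len(nrow(model$cds)), function(i)
      substr(g, model$cds$start[i] + 1, model$cds$end[i]), character(1))
    out <- paste(segs, collapse = "")
    if (model$strand == "-") {
      out <- paste(rev(strsplit(chartr("ACGT", "TGCA", out), "")[[1]]),
                   collapse = "")
    }
    out
  }
  cds_ref <- splice()
  cds_alt <- splice(alt)
  aa_ref <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds_ref), no.init.codon = TRUE)), "")[[1]]
  aa_alt <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(cds_alt), no.init.codon = TRUE)), "")[[1]]
  d <- which(aa_ref != aa_alt)
  if (!length(d)) return("synonymous")
  if (d[1] == 1 && substr(cds_ref, 1, 3) == "ATG") return("start_lost")
  if (aa_alt[d[1]] == "*") return("stop_gained")
  "nonsynonymous"
}

# --- multinomial dosage by exhaustive grid -----------------------------
oracle_multiallelic <- function(counts, m, e) {
  k <- length(counts)
  grid <- expand.grid(rep(list(0:m), k))
  grid <- grid[rowSums(grid) == m, , drop = FALSE]
  # lexicographic by first allele, matching the package's tie rule
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  ll <- apply(grid, 1, function(d) {
    f <- (d / m) * (1 - e) + (1 - d / m) * e / (k - 1)
    f <- f / sum(f)
    dmultinom(counts, prob = f, log = TRUE)
  })
  as.integer(grid[which.max(ll), ])
}

# --- bootstrap support of a given tip clade (or its complement) --------
clade_support <- function(tree, tips) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  all_tips <- tree$tip.label
  for (i in seq_along(pp)) {
    set <- labs[pp[[i]]]
    if (setequal(set, tips) || setequal(set, setdiff(all_tips, tips))) {
      return(as.numeric(tree$node.label[i]))
    }
  }
  NA_real_
}
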