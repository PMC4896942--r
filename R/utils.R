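# internal helpers shared across modules

# let data.table's [ dispatch work from this namespace
.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

# reverse complement of a plain character scalar (ACGT only)
revcomp <- function(x) {
  stopifnot(length(x) == 1L)
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

# Watson-Crick complement test for single bases (vectorized)
is_complement <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

# universal genetic code, standard table
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (any(is.na(aa))) stop("cannot translate codon(s): ",
                           paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)

# split a CDS string into codons
split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3: ", n)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

# random DNA string(s)
random_dna <- function(n, length, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# check sequences contain only ACGT; error lists offending positions
check_acgt <- function(seq, what = "sequence") {
  bad <- gregexpr("[^ACGT]", seq)[[1]]
  if (bad[1] != -1L) {
    stop(what, " contains ambiguous/non-ACGT bases at position(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# deterministic child seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}
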