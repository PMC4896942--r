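#' Variant tables (VCF subset dialect)
#'
#' A `variant_table` is a `data.table` with one row per variant site and
#' columns `chrom`, `pos` (1-based, as in VCF), `id`, `ref`, `alt` (list
#' column, 1--3 alternate alleles), `qual`, `mq` (mapping quality), `bq`
#' (base quality), `caller`, `unfilterable` (logical; required annotation
#' missing), `reason`, and `ad` (list column: integer matrix of per-allele
#' read counts, alleles in rows with REF first, accessions in columns; a
#' column of `NA` marks a missing genotype).  Accession names are kept in
#' the `samples` attribute.
#'
#' The dialect requires per-sample `AD`; site-level `MQ` plus either `BQ`
#' or `BaseQRankSum` (configurable, see `bq_key`).  Records with missing
#' required keys are retained and tagged `unfilterable`, never silently
#' dropped.
#'
#' @name variant_table
NULL

new_variant_table <- function(dt, samples) {
  data.table::setDT(dt)
  data.table::setattr(dt, "samples", samples)
  data.table::setattr(dt, "class",
                      c("variant_table", "data.table", "data.frame"))
  dt
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d site(s), %d accession(s): %s\n",
              nrow(x), length(attr(x, "samples")),
              paste(utils::head(attr(x, "samples"), 4), collapse = ", ")))
  NextMethod()
}

#' Read a VCF (subset dialect) into a variant table
#'
#' @param path path to an uncompressed VCF 4.x file
#' @param bq_key INFO key(s) accepted for per-site base quality, tried in
#'   order; defaults to `c("BQ", "BaseQRankSum")`
#' @param caller label stored in the `caller` column (default: file stem)
#' @return a [variant_table]
#' @export
read_vcf_subset <- function(path, bq_key = c("BQ", "BaseQRankSum"),
                            caller = NULL) {
  stopifnot(file.exists(path))
  caller <- caller %||% sub("\\.vcf$", "", basename(path))
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in ", path)
  cols <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) > 9) cols[10:length(cols)] else character()
  body <- lines[seq_along(lines) > hdr[1] & !startsWith(lines, "#")]
  body <- body[nzchar(body)]
  n <- length(body)
  out <- list(chrom = character(n), pos = integer(n), id = character(n),
              ref = character(n), alt = vector("list", n), qual = numeric(n),
              mq = numeric(n), bq = numeric(n),
              unfilterable = logical(n), reason = character(n),
              ad = vector("list", n))
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) stop("malformed VCF data line ", hdr[1] + i)
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1L) {
      stop("out-of-range POS in VCF at data line ", i, ": ", f[2])
    }
    out$chrom[i] <- f[1]; out$pos[i] <- pos; out$id[i] <- f[3]
    out$ref[i] <- f[4]
    alt <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    out$alt[[i]] <- alt
    out$qual[i] <- suppressWarnings(as.numeric(f[6]))
    info <- parse_vcf_info(f[8])
    out$mq[i] <- suppressWarnings(as.numeric(info[["MQ"]] %||% NA))
    bqv <- NA_real_
    for (k in bq_key) {
      if (!is.null(info[[k]])) { bqv <- suppressWarnings(as.numeric(info[[k]])); break }
    }
    out$bq[i] <- bqv
    nal <- 1L + length(alt)
    ad <- matrix(NA_integer_, nrow = nal, ncol = length(samples))
    has_ad <- FALSE
    if (length(samples) && length(f) >= 10L) {
      fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
      ad_ix <- match("AD", fmt)
      has_ad <- !is.na(ad_ix)
      if (has_ad) {
        for (s in seq_along(samples)) {
          sv <- strsplit(f[9L + s], ":", fixed = TRUE)[[1]]
          gt <- if (!is.na(match("GT", fmt)) && length(sv) >= match("GT", fmt))
            sv[match("GT", fmt)] else "."
          if (grepl("^\\.([/|]\\.)*$", gt) && (length(sv) < ad_ix || sv[ad_ix] == ".")) {
            next  # missing genotype, depths stay NA
          }
          if (length(sv) >= ad_ix && sv[ad_ix] != ".") {
            cnt <- suppressWarnings(as.integer(
              strsplit(sv[ad_ix], ",", fixed = TRUE)[[1]]))
            ad[seq_len(min(nal, length(cnt))), s] <- cnt[seq_len(min(nal, length(cnt)))]
          }
        }
      }
    }
    out$ad[[i]] <- ad
    missing_keys <- c(if (is.na(out$mq[i])) "MQ",
                      if (is.na(bqv)) paste(bq_key, collapse = "/"),
                      if (is.na(out$qual[i])) "QUAL",
                      if (!has_ad && length(samples)) "AD")
    if (length(missing_keys)) {
      out$unfilterable[i] <- TRUE
      out$reason[i] <- paste("missing", paste(missing_keys, collapse = ","))
    }
  }
  dt <- data.table::as.data.table(out)
  dt[, "caller" := caller]
  new_variant_table(dt, samples)
}

parse_vcf_info <- function(x) {
  if (x == "." || !nzchar(x)) return(list())
  kv <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) > 1) p[2] else TRUE)
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1L))
}

#' Write a variant table as VCF
#'
#' @param variants a [variant_table]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(variants, path) {
  samples <- attr(variants, "samples")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=polycap",
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
    '##INFO=<ID=BQ,Number=1,Type=Float,Description="Base quality">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  ), con)
  for (i in seq_len(nrow(variants))) {
    ad <- variants$ad[[i]]
    dp <- sum(ad, na.rm = TRUE)
    info <- c(
      if (!is.na(variants$mq[i])) sprintf("MQ=%g", variants$mq[i]),
      if (!is.na(variants$bq[i])) sprintf("BQ=%g", variants$bq[i]),
      sprintf("DP=%d", dp))
    info <- if (length(info)) paste(info, collapse = ";") else "."
    fields <- c(variants$chrom[i], variants$pos[i], variants$id[i],
                variants$ref[i], paste(variants$alt[[i]], collapse = ","),
                if (is.na(variants$qual[i])) "." else
                  format(variants$qual[i], trim = TRUE),
                "PASS", info)
    if (length(samples)) {
      sf <- vapply(seq_along(samples), function(s) {
        if (all(is.na(ad[, s]))) "./.:." else
          paste0("./.", ":", paste(ad[, s], collapse = ","))
      }, character(1))
      fields <- c(fields, "GT:AD", sf)
    }
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}
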