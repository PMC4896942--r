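#' Fit the linear capture-efficiency model
#'
#' Ordinary least squares of uniquely mapped reads on probe features,
#' with backward elimination of features that do not contribute
#' significantly (partial F test via `drop1`, threshold `alpha`), and a
#' relative-importance decomposition of R^2 obtained by averaging
#' sequential R^2 contributions over all feature orderings (the LMG
#' decomposition; computed exactly from all-subset fits, practical for
#' <= 6 features).  The importances are non-negative and sum to the
#' model R^2.
#'
#' @param features data.frame of numeric feature columns (e.g. `gc`,
#'   `pmfe`, `dimer`, `hairpin`)
#' @param reads numeric response: uniquely mapped reads per probe
#' @param alpha significance threshold for keeping a feature (default
#'   0.001)
#' @return object of class `capture_model`: list with `coefficients`
#'   (named, incl. `(Intercept)`), `selected`, `dropped`, `r_squared`,
#'   `importance` (named, sums to `r_squared`), `fit` (the `lm` object),
#'   `n`
#' @export
fit_capture_model <- function(features, reads, alpha = 0.001) {
  x <- as.data.frame(features)
  x <- x[vapply(x, is.numeric, logical(1))]
  stopifnot(nrow(x) == length(reads))
  if (nrow(x) < 10 * ncol(x)) {
    stop("need >= 10 observations per feature: ", nrow(x), " rows for ",
         ncol(x), " features")
  }
  qrX <- qr(cbind(1, as.matrix(x)))
  if (qrX$rank < ncol(x) + 1L) {
    dropped_cols <- colnames(x)[qrX$pivot[seq(qrX$rank + 1L,
                                              ncol(x) + 1L)] - 1L]
    stop("rank-deficient design; collinear feature set includes: ",
         paste(dropped_cols, collapse = ", "))
  }
  dat <- cbind(x, .reads = reads)
  vars <- colnames(x)
  dropped <- character()
  repeat {
    if (!length(vars)) break
    fml <- stats::as.formula(paste(".reads ~", paste(vars, collapse = " + ")))
    fit <- stats::lm(fml, data = dat)
    dr <- stats::drop1(fit, test = "F")
    pv <- dr[["Pr(>F)"]][-1L]
    names(pv) <- rownames(dr)[-1L]
    worst <- which.max(pv)
    if (length(pv) && !is.na(pv[worst]) && pv[worst] > alpha) {
      dropped <- c(dropped, names(pv)[worst])
      vars <- setdiff(vars, names(pv)[worst])
    } else break
  }
  if (!length(vars)) {
    fit <- stats::lm(.reads ~ 1, data = dat)
    return(structure(list(coefficients = stats::coef(fit),
                          selected = character(), dropped = dropped,
                          r_squared = 0,
                          importance = stats::setNames(numeric(0),
                                                       character(0)),
                          fit = fit, n = nrow(dat)),
                     class = "capture_model"))
  }
  r2 <- summary(fit)$r.squared
  importance <- lmg_importance(x[vars], reads)
  structure(list(coefficients = stats::coef(fit), selected = vars,
                 dropped = dropped, r_squared = r2,
                 importance = importance, fit = fit, n = nrow(dat)),
            class = "capture_model")
}

# LMG decomposition: imp_j = sum over subsets S not containing j of
# w(|S|) * (R2(S + j) - R2(S)), w(s) = s! (p-1-s)! / p!
lmg_importance <- function(x, y) {
  p <- ncol(x)
  nm <- colnames(x)
  X <- as.matrix(x)
  r2_of <- numeric(2^p)  # subset bitmask -> R^2
  tss <- sum((y - mean(y))^2)
  for (mask in seq_len(2^p - 1L)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    fit <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    r2_of[mask + 1L] <- 1 - sum(fit$residuals^2) / tss
  }
  w <- function(s) factorial(s) * factorial(p - 1 - s) / factorial(p)
  imp <- stats::setNames(numeric(p), nm)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(2^p - 1L)) {
      if (bitwAnd(mask, bit) != 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      imp[j] <- imp[j] + w(s) * (r2_of[bitwOr(mask, bit) + 1L] -
                                   r2_of[mask + 1L])
    }
  }
  imp
}

#' @export
print.capture_model <- function(x, ...) {
  cat("<capture_model> n =", x$n, "\n")
  if (!length(x$selected)) {
    cat("  intercept-only model (no significant features)\n")
  } else {
    eq <- paste(sprintf("%+.4g*%s", x$coefficients[x$selected], x$selected),
                collapse = " ")
    cat(sprintf("  reads = %.4g %s\n", x$coefficients[["(Intercept)"]], eq))
    cat(sprintf("  R^2 = %.4f; importance: %s\n", x$r_squared,
                paste(sprintf("%s %.3f", names(x$importance), x$importance),
                      collapse = ", ")))
  }
  if (length(x$dropped)) cat("  dropped:", paste(x$dropped, collapse = ", "),
                             "\n")
  invisible(x)
}
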