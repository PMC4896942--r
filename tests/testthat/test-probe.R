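test_that("GC, hairpin and dimer of fixed strings", {
  f <- compute_features(c(p = strrep("ATGC", 30)))
  expect_equal(f$gc, 50)
  expect_equal(f$length, 120L)

  fa <- compute_features(c(p = strrep("A", 30)))
  expect_equal(fa$gc, 0)
  expect_equal(fa$hairpin, 0L)
  expect_equal(fa$dimer, 0L)
  expect_equal(fa$pmfe, 0)

  expect_error(compute_features(c(p = paste0(strrep("A", 25), "N"))),
               "position")
  expect_error(compute_features(c(p = "ACGT")), ">= 20")
})

test_that("features are pure functions of the sequence", {
  set.seed(61)
  s <- stats::setNames(vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
    character(1)), c("a", "b", "c"))
  expect_identical(compute_features(s), compute_features(s))
})

test_that("PMFE, hairpin, dimer equal brute-force enumeration (short)", {
  set.seed(62)
  for (i in 1:40) {
    n <- sample(20:26, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    expect_equal(polycap:::pmfe_dp_cpp(s), polycap:::pmfe_enum_cpp(s),
                 info = s)
    expect_equal(polycap:::hairpin_score_cpp(s), oracle_hairpin(s), info = s)
    expect_equal(polycap:::dimer_score_cpp(s), oracle_dimer(s), info = s)
  }
  # cross-check the C++ enumeration oracle against a pure-R recursion
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 14, TRUE), collapse = "")
    expect_equal(polycap:::pmfe_enum_cpp(s), oracle_pmfe_r(s), info = s)
  }
})

test_that("planted stems give hairpin >= stem length", {
  set.seed(63)
  for (i in 1:10) {
    stem <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", stem), "")[[1]]),
                collapse = "")
    probe <- paste0(strrep("A", 5), stem, "TTTT", rc, strrep("A", 5))
    expect_gte(polycap:::hairpin_score_cpp(probe), 10L)
  }
})

test_that("successful-probe window matches the brute-force predicate", {
  # degenerate constant counts: everything excluded (strict bounds)
  feats <- data.frame(probe_id = letters[1:5], reads = rep(100, 5))
  expect_warning(sel <- select_successful_probes(feats), "window")
  expect_equal(nrow(sel), 0L)
  expect_equal(attr(sel, "lower"), 10)
  expect_equal(attr(sel, "upper"), 100)

  # mean 260 reproduces the classic lower bound of 26
  feats260 <- data.frame(reads = c(rep(260, 99), 260))
  expect_warning(sel260 <- select_successful_probes(feats260), "window")
  expect_equal(attr(sel260, "lower"), 26)

  set.seed(64)
  counts <- rpois(10000, 260)
  tab <- data.frame(probe_id = seq_along(counts), reads = counts)
  sel2 <- select_successful_probes(tab)
  lower <- 0.1 * mean(counts)
  upper <- stats::quantile(counts, 0.99, names = FALSE)
  expect_setequal(sel2$probe_id,
                  tab$probe_id[counts > lower & counts < upper])

  expect_error(select_successful_probes(tab[0, ]), "empty")
})

test_that("correlation pruning keeps one representative per group", {
  set.seed(65)
  n <- 300
  gc <- runif(n, 20, 80)
  tm <- 40 + 0.5 * gc                      # perfectly collinear with GC
  phfe <- -50 - 0.4 * gc + rnorm(n, 0, 0.01)
  hairpin <- sample(0:12, n, TRUE)
  dimer <- sample(0:12, n, TRUE)
  x <- data.frame(gc = gc, tm = tm, phfe = phfe, hairpin = hairpin,
                  dimer = dimer)
  pr <- prune_correlated(x)
  expect_true("gc" %in% pr$keep)           # priority representative
  expect_false(any(c("tm", "phfe") %in% pr$keep))
  # representatives are mutually below threshold
  cm <- pr$cor[pr$keep, pr$keep]
  expect_true(all(abs(cm[upper.tri(cm)]) <= 0.95))

  indep <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_setequal(prune_correlated(indep)$keep, c("a", "b", "c"))

  with_const <- cbind(indep, k = 1)
  expect_warning(pc <- prune_correlated(with_const), "constant")
  expect_false("k" %in% pc$keep)
})

test_that("capture model: noise-free recovery and pure-noise collapse", {
  set.seed(66)
  n <- 500
  X <- data.frame(gc = runif(n, 20, 80), pmfe = runif(n, -16, 0),
                  dimer = sample(0:20, n, TRUE),
                  hairpin = sample(0:15, n, TRUE))
  beta <- c(164.46, 5.08, 13.3, -2.11, -10.67)
  mu <- beta[1] + beta[2] * X$gc + beta[3] * X$pmfe + beta[4] * X$dimer +
    beta[5] * X$hairpin
  fit0 <- suppressWarnings(fit_capture_model(X, mu))
  expect_equal(unname(fit0$coefficients[c("(Intercept)", "gc", "pmfe",
                                          "dimer", "hairpin")]),
               beta, tolerance = 1e-10)

  noise <- rnorm(n)
  fitn <- fit_capture_model(X, noise)
  expect_length(fitn$selected, 0L)
  expect_equal(fitn$r_squared, 0)

  # rank-deficient design errors, naming a collinear column
  X2 <- X; X2$gc2 <- 2 * X$gc
  expect_error(fit_capture_model(X2, mu), "collinear")
})

test_that("relative importances are the exact LMG shares", {
  set.seed(67)
  n <- 400
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 2 * X$a - X$b + 0.5 * X$c + rnorm(n)
  fit <- fit_capture_model(X, y, alpha = 0.5)
  expect_equal(sum(fit$importance), fit$r_squared, tolerance = 1e-10)
  expect_true(all(fit$importance >= 0))
  # orthogonal-ish predictors: importance ranks follow coefficient size
  expect_equal(names(sort(fit$importance, decreasing = TRUE)),
               c("a", "b", "c"))
})

test_that("coverage summary: uniform depth, flank geometry, merging", {
  depth <- data.frame(chrom = "chr1", pos = 0:999, depth = 50)
  probes <- data.frame(chrom = "chr1", start = c(200L, 600L),
                       end = c(320L, 720L))
  cov <- coverage_summary(depth, probes, flank = 100)
  expect_equal(cov$targets$msd, c(50, 50))
  expect_equal(cov$cumulative$fraction_at_least[cov$cumulative$depth == 50],
               1.0)

  cov0 <- coverage_summary(depth, probes, flank = 0)
  expect_equal(cov0$targets$start, probes$start)
  expect_equal(cov0$targets$end, probes$end)

  # overlapping probes merge into one target
  probes2 <- data.frame(chrom = "chr1", start = c(200L, 250L),
                        end = c(320L, 400L))
  cov2 <- coverage_summary(depth, probes2, flank = 100)
  expect_equal(nrow(cov2$targets), 1L)
  expect_equal(cov2$targets$start, 100)
  expect_equal(cov2$targets$end, 500)

  # outside the table -> zero depth with warning
  far <- data.frame(chrom = "chr1", start = 5000L, end = 5100L)
  expect_warning(cov3 <- coverage_summary(depth, far, flank = 0), "zero")
  expect_equal(cov3$targets$msd, 0)
})
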