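test_that("coverage is the percentage of bases under the feature union", {
  pr <- GRanges("c", IRanges(1, 1000))           # [0,1000)
  genes <- GRanges("c", IRanges(501, 1500))      # [500,1500)
  expect_equal(computeCoverage(pr, genes), 50)
  ## overlapping features merged: [100,400) + [300,600) -> [100,600)
  genes2 <- GRanges("c", IRanges(c(101, 301), c(400, 600)))
  expect_equal(computeCoverage(pr, genes2), 50)
  expect_equal(computeCoverage(pr, GRanges("c", IRanges(5001, 6000))), 0)
  expect_error(computeCoverage(GRanges("c", IRanges(5, 4)), genes))
})

test_that("coverage equals per-base counting on random nested/abutting fixtures", {
  set.seed(40)
  for (rep in 1:60) {
    s <- sort(sample(0:480, 6)); e <- s + sample(5:120, 6, replace = TRUE)
    feats <- GRanges("c", IRanges(s + 1, e))
    is <- sample(0:400, 1); ie <- is + sample(20:200, 1)
    interval <- GRanges("c", IRanges(is + 1, ie))
    got <- computeCoverage(interval, feats)
    expect_equal(got, coverageOracle(is, ie, s, e))
    expect_gte(got, 0); expect_lte(got, 100)
  }
  ## coverage of a union of disjoint intervals is the length-weighted mean
  i1 <- GRanges("c", IRanges(1, 100)); i2 <- GRanges("c", IRanges(201, 500))
  f <- GRanges("c", IRanges(51, 260))
  both <- computeCoverage(c(i1, i2), f)
  expect_equal(computeCoverage(GenomicRanges::reduce(c(i1, i2)), f),
               both, tolerance = 1)  # disjoint parts stay separate intervals
  expect_equal(weighted.mean(both, c(100, 300)),
               (50 + 60) / 400 * 100)
})

test_that("top-quartile flags use the linear-interpolation 75th percentile", {
  f <- topQuartileFlags(1:100)
  expect_equal(sum(f), 25)
  expect_true(all(which(f) == 76:100))   # threshold 75.25
  expect_true(all(topQuartileFlags(rep(2, 10))))
  set.seed(41)
  v <- runif(10000)
  expect_true(mean(topQuartileFlags(v)) >= 0.25 &&
              mean(topQuartileFlags(v)) <= 0.26)
})

test_that("exact binomial and Clopper-Pearson match brute-force computations", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(5:200, 1)
    x <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(binomTestTwoSided(x, n, p0), binomOracle(x, n, p0),
                 tolerance = 1e-10)
    ci <- clopperPearsonCI(x, n)
    ref <- stats::binom.test(x, n)$conf.int
    expect_equal(unname(ci), as.numeric(ref), tolerance = 1e-10)
  }
  expect_equal(binomTestTwoSided(30, 50, 0.4), binomOracle(30, 50, 0.4),
               tolerance = 1e-12)
})

test_that("hypergeometric tests match direct combinatorial sums", {
  expect_equal(hypergeomTests(3, 30, 10, 100)["over"],
               hyperOverOracle(3, 30, 10, 100), tolerance = 1e-12,
               ignore_attr = TRUE)
  set.seed(43)
  for (rep in 1:50) {
    N <- sample(20:150, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    x <- sample(max(0, K + n - N):min(K, n), 1)
    ht <- hypergeomTests(x, K, n, N)
    expect_equal(unname(ht["over"]), hyperOverOracle(x, K, n, N),
                 tolerance = 1e-10)
    expect_equal(unname(ht["under"]), hyperUnderOracle(x, K, n, N),
                 tolerance = 1e-10)
  }
})

test_that("probe-level class tests use one-sample t and doubled-tail binomial", {
  set.seed(44)
  n <- 200
  pd <- data.frame(cls = rep(c("EM", "L"), each = n / 2),
                   gc = rnorm(n, 36, 2),
                   k9 = runif(n) < 0.3)
  res <- probeClassTests(pd, continuous = "gc", binary = "k9")
  ## t statistic against the region mean, recomputed directly
  emGc <- pd$gc[pd$cls == "EM"]
  tt <- (mean(emGc) - mean(pd$gc)) / (sd(emGc) / sqrt(length(emGc)))
  row <- res[res$cls == "EM" & res$feature == "gc", ]
  expect_equal(row$statistic, tt, tolerance = 1e-10)
  expect_equal(row$p_value, 2 * pt(-abs(tt), length(emGc) - 1),
               tolerance = 1e-10)
  brow <- res[res$cls == "L" & res$feature == "k9", ]
  x <- sum(pd$k9[pd$cls == "L"])
  expect_equal(brow$p_value, binomOracle(x, n / 2, mean(pd$k9)),
               tolerance = 1e-12)
  ## a class matching the region mean scores p ~ 1
  pd2 <- data.frame(cls = rep(c("EM", "L"), each = 60),
                    gc = rep(c(1, 2, 3, 4), 30))
  res2 <- probeClassTests(pd2, continuous = "gc")
  expect_gt(res2$p_value[res2$cls == "EM"], 0.9)
  ## classes under the n threshold are omitted
  pd3 <- rbind(pd, data.frame(cls = "E", gc = rnorm(5), k9 = FALSE))
  res3 <- probeClassTests(pd3, continuous = "gc", nMin = 20)
  expect_false("E" %in% res3$cls)
  ## zero-variance class reports NA with the row retained
  pd4 <- data.frame(cls = rep(c("EM", "L"), each = 25),
                    gc = c(rep(5, 25), rnorm(25)))
  res4 <- probeClassTests(pd4, continuous = "gc", nMin = 10)
  expect_true(is.na(res4$p_value[res4$cls == "EM"]))
})

test_that("the EM/L replicon comparison is a Welch t-test with fractional df", {
  rf <- data.frame(cls = rep(c("EM", "L"), each = 3),
                   gc = c(36, 37, 38, 34, 35, 36))
  out <- repliconCompare(rf, features = "gc")
  x <- c(36, 37, 38); y <- c(34, 35, 36)
  se2 <- var(x) / 3 + var(y) / 3
  tW <- (mean(x) - mean(y)) / sqrt(se2)
  dfW <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(out$t, tW, tolerance = 1e-10)
  expect_equal(out$df, dfW, tolerance = 1e-10)
  expect_equal(out$p_value, 2 * pt(-abs(tW), dfW), tolerance = 1e-10)
  ## identical groups: zero difference, p = 1
  rf2 <- data.frame(cls = rep(c("EM", "L"), each = 3), gc = rep(c(1, 2, 3), 2))
  out2 <- repliconCompare(rf2, features = "gc")
  expect_equal(out2$t, 0); expect_equal(out2$p_value, 1)
  expect_error(repliconCompare(rf[-(1:2), ], features = "gc"),
               ">= 2 replicons")
})

test_that("gene TSS anchors are strand-aware and boundary genes count rightward", {
  reps <- GRanges("c", IRanges(c(1, 100001), c(100000, 200000)),
                  replicon_id = c("rep001", "rep002"),
                  cls = factor(c("EM", "L"), levels = timingClasses()))
  pr <- makeProbes(200)
  ## + gene starting exactly at the second replicon's first base
  feats <- GRanges("c", IRanges(c(100001, 50001), c(101000, 51000)),
                   strand = c("+", "-"),
                   feature_id = c("g1", "g2"), kind = "gene")
  tab <- repliconFeatureTable(reps, pr, feats)
  expect_equal(tab$gene_content * width(reps) / 1e6, c(1, 1))
  ## flip the boundary gene to - strand: TSS moves to its end
  GenomicRanges::strand(feats)[1] <- "-"
  tab2 <- repliconFeatureTable(reps, pr, feats)
  expect_equal(tab2$gene_content * width(reps) / 1e6, c(1, 1))
})

test_that("bin geometry folds ten intervals into five symmetric bins", {
  reps <- GRanges("c", IRanges(1, 100000),
                  replicon_id = "rep001",
                  cls = factor("EM", levels = timingClasses()),
                  n_probes = 100L)
  pr <- makeProbes(100)
  ## probe at relative position 0.03 -> interval 1 -> bin 5
  flags <- rep(FALSE, 100); flags[4] <- TRUE     # center 3500, rel 0.035
  bp <- binProfile(reps, pr, flags)
  expect_equal(bp$bins$positive[bp$bins$bin == 5], 1)
  ## innermost intervals {5,6} -> bin 1
  flags2 <- rep(FALSE, 100); flags2[c(45, 56)] <- TRUE
  bp2 <- binProfile(reps, pr, flags2)
  expect_equal(bp2$bins$positive[bp2$bins$bin == 1], 2)
  ## bins partition the probes
  expect_equal(sum(bp$bins$n), 100)
  expect_equal(bp$bins$n, rep(20L, 5))
  ## reflection invariance: mirrored flags give identical bin counts
  set.seed(45)
  flags3 <- runif(100) < 0.3
  b1 <- binProfile(reps, pr, flags3)$bins
  b2 <- binProfile(reps, pr, rev(flags3))$bins
  expect_equal(b1$positive, b2$positive)
  ## proportions match a direct tabulation oracle
  rel <- (probeCenters(pr) - 0) / 100000
  interval <- pmin(10, floor(rel * 10) + 1)
  bin <- 6 - pmin(interval, 11 - interval)
  for (b in 1:5)
    expect_equal(b1$proportion[b], mean(flags3[bin == b]))
})

test_that("binomial CIs in bin profiles cover a uniform null rate", {
  set.seed(46)
  n <- 200
  reps <- GRanges("c", IRanges((seq_len(n) - 1) * 1e5 + 1, seq_len(n) * 1e5),
                  replicon_id = sprintf("rep%03d", seq_len(n)),
                  cls = factor(rep("EM", n), levels = timingClasses()),
                  n_probes = 100L)
  pr <- makeProbes(n * 100)
  flags <- runif(n * 100) < 0.4
  bp <- binProfile(reps, pr, flags)
  ## joint statement over 5 bins: use 99% per-bin intervals so the null
  ## check is not a coin flip on the multiple-comparison level
  ci99 <- t(mapply(clopperPearsonCI, bp$bins$positive, bp$bins$n, 0.99))
  expect_true(all(ci99[, 1] <= 0.4 & ci99[, 2] >= 0.4))
  expect_equal(bp$overall, mean(flags))
  ## per-replicon averaging mode stays close to the pooled estimate here
  bpR <- binProfile(reps, pr, flags, mode = "perReplicon")
  expect_equal(bpR$bins$proportion, bp$bins$proportion, tolerance = 0.02)
})
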