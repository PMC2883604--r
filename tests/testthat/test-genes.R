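mkGenes <- function(starts, ends, strand = "+", ids = NULL) {
  gr <- GRanges("c", IRanges(starts + 1, ends), strand = strand)
  mcols(gr)$feature_id <- if (is.null(ids)) sprintf("g%03d", seq_along(gr))
                          else ids
  mcols(gr)$kind <- "gene"
  gr
}

test_that("the pattern map is the fixed activity-ranked bijection", {
  expect_equal(patternOf(TRUE, FALSE, TRUE, TRUE), 1L)
  expect_equal(patternOf(FALSE, FALSE, FALSE, FALSE), 13L)
  expect_equal(patternOf(FALSE, TRUE, FALSE, FALSE), 16L)
  expect_equal(patternOf(FALSE, FALSE, TRUE, FALSE), 3L)
  expect_equal(patternOf(TRUE, TRUE, TRUE, TRUE), 7L)
  ## bijection over all 16 vectors
  grid <- expand.grid(k4 = c(TRUE, FALSE), k9 = c(TRUE, FALSE),
                      k56 = c(TRUE, FALSE), mc = c(TRUE, FALSE))
  pats <- patternOf(grid$k4, grid$k9, grid$k56, grid$mc)
  expect_setequal(pats, 1:16)
})

test_that("gene marks are any-positive over overlapping probes", {
  pr <- makeProbes(30)
  marks <- data.frame(probe_id = mcols(pr)$probe_id,
                      k4 = FALSE, k9 = FALSE,
                      k56 = c(TRUE, rep(FALSE, 29)),
                      mc = FALSE)
  g <- mkGenes(c(500, 20000), c(2500, 25000))   # g1 over probes 1-3
  gm <- assignGeneMarks(g, pr, marks)
  expect_true(gm$k56[gm$gene_id == "g001"])
  expect_false(gm$k56[gm$gene_id == "g002"])
  expect_equal(gm$pattern[gm$gene_id == "g002"], 13L)  # all-negative
  ## majority rule flips the call when positives are a minority
  gmMaj <- assignGeneMarks(g, pr, marks, rule = "majority")
  expect_false(gmMaj$k56[gmMaj$gene_id == "g001"])
  ## genes with no probe overlap are excluded and counted
  g2 <- mkGenes(c(500, 900000), c(2500, 901000))
  gm2 <- assignGeneMarks(g2, pr, marks)
  expect_equal(nrow(gm2), 1)
  expect_equal(attr(gm2, "n_excluded"), 1L)
})

test_that("gene mark assignment matches a per-base overlap oracle", {
  set.seed(50)
  pr <- makeProbes(50)
  for (rep in 1:20) {
    marks <- data.frame(probe_id = mcols(pr)$probe_id,
                        k4 = runif(50) < 0.4, k9 = runif(50) < 0.2,
                        k56 = runif(50) < 0.4, mc = runif(50) < 0.3)
    s <- sample(0:45000, 5); e <- s + sample(800:6000, 5, replace = TRUE)
    g <- mkGenes(s, pmin(e, 50000))
    gm <- assignGeneMarks(g, pr, marks)
    for (i in seq_len(nrow(gm))) {
      gi <- which(mcols(g)$feature_id == gm$gene_id[i])
      ovProbes <- which(start(pr) <= end(g)[gi] & end(pr) >= start(g)[gi])
      for (mk in c("k4", "k9", "k56", "mc"))
        expect_equal(gm[[mk]][i], any(marks[[mk]][ovProbes]))
    }
  }
})

test_that("gene timing is the overlap-length plurality over segments", {
  segs <- GRanges("c", IRanges(c(1, 10001), c(10000, 30000)),
                  cls = factor(c("EM", "L"), levels = timingClasses()))
  g <- mkGenes(c(2000, 7001, 40000), c(5000, 17000, 41000))
  gt <- assignGeneTiming(g, segs)
  expect_equal(as.character(gt$cls), c("EM", "L"))   # g3 has no overlap
  expect_equal(attr(gt, "n_excluded"), 1L)
  ## 70/30 split goes to the dominant class
  g2 <- mkGenes(7001, 17000)  # 3 kb EM, 7 kb L
  expect_equal(as.character(assignGeneTiming(g2, segs)$cls), "L")
  ## exact tie resolved by the fixed order
  g3 <- mkGenes(5000, 15000)  # 5 kb each
  expect_equal(as.character(assignGeneTiming(g3, segs)$cls), "EM")
})

test_that("pattern activity table reproduces exact binomial enrichment", {
  ## constructed margins: 2844 genes, 60.6% active overall; one 818-gene
  ## pattern at 75.8% active must test far beyond the 0.001 level
  nAll <- 2844; nGrp <- 818
  xGrp <- round(0.758 * nGrp)
  xRest <- round(0.606 * nAll) - xGrp
  genes <- data.frame(
    gene_id = sprintf("g%04d", 1:nAll),
    pattern = rep(c(1L, 13L), c(nGrp, nAll - nGrp)),
    present = c(rep(c(TRUE, FALSE), c(xGrp, nGrp - xGrp)),
                rep(c(TRUE, FALSE), c(xRest, nAll - nGrp - xRest))),
    level = 5, cls = "EM")
  tab <- patternActivityTable(genes)
  p0 <- mean(genes$present)
  row1 <- tab[!is.na(tab$pattern) & tab$pattern == 1, ]
  expect_equal(row1$p_value, binomOracle(xGrp, nGrp, p0), tolerance = 1e-12)
  expect_lt(row1$p_value, 0.001)
  expect_equal(row1$code, "***")
  ## ordered by decreasing activity, overall row first
  expect_true(is.na(tab$pattern[1]))
  expect_equal(tab$pct_active[1], 100 * p0)
  expect_true(all(diff(tab$pct_active[-1]) <= 0))
  ## a single-pattern gene set matches the overall rate exactly: p = 1
  one <- genes; one$pattern <- 2L
  tabOne <- patternActivityTable(one)
  expect_equal(tabOne$p_value[!is.na(tabOne$pattern)], 1)
})

test_that("timing enrichment is one-sided hypergeometric in both directions", {
  set.seed(51)
  genes <- data.frame(
    gene_id = sprintf("g%03d", 1:100),
    pattern = rep(c(1L, 2L), c(10, 90)),
    present = TRUE, level = 5,
    cls = factor(rep(c("EM", "L"), c(30, 70)), levels = timingClasses()))
  genes$cls[1:3] <- "EM"; genes$cls[4:10] <- "L"
  tab <- timingEnrichmentTable(genes)
  row <- tab[tab$pattern == 1 & tab$cls == "EM", ]
  x <- sum(genes$pattern == 1 & genes$cls == "EM")
  expect_equal(row$p_over, hyperOverOracle(x, sum(genes$cls == "EM"), 10, 100),
               tolerance = 1e-12)
  ## the whole gene set as one pattern is never enriched anywhere
  all1 <- genes; all1$pattern <- 1L
  tabAll <- timingEnrichmentTable(all1)
  expect_true(all(tabAll$p_over == 1))
  ## maximal overlap: over-representation p is the tail point mass
  genes2 <- genes; genes2$cls <- factor(rep("L", 100),
                                        levels = timingClasses())
  genes2$cls[genes2$pattern == 1] <- "EM"
  tab2 <- timingEnrichmentTable(genes2)
  r2 <- tab2[tab2$pattern == 1 & tab2$cls == "EM", ]
  expect_equal(r2$p_over, hyperOverOracle(10, 10, 10, 100), tolerance = 1e-12)
})

test_that("activity by timing reproduces the unconditional rate and omits empty classes", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:60),
                      pattern = 1L, present = rep(c(TRUE, FALSE), c(36, 24)),
                      level = rnorm(60, 5),
                      cls = factor(rep(c("EM", "L"), each = 30),
                                   levels = timingClasses()))
  tab <- activityByTiming(genes)
  expect_equal(tab$pct_active[tab$cls == "All"], 60)
  expect_setequal(tab$cls, c("All", "EM", "L"))
  expect_equal(tab$n[tab$cls == "EM"], 30)
})

test_that("element distributions use midpoint bins with exact CIs", {
  n <- 50
  reps <- GRanges("c", IRanges((seq_len(n) - 1) * 1e5 + 1, seq_len(n) * 1e5),
                  replicon_id = sprintf("rep%03d", seq_len(n)),
                  cls = factor(rep("EM", n), levels = timingClasses()),
                  n_probes = 100L)
  set.seed(52)
  mids <- runif(2000, 0, n * 1e5)
  el <- GRanges("c", IRanges(floor(mids) + 1, width = 200))
  dist <- elementDistributionInReplicons(el, reps)
  expect_equal(sum(dist$bins$count), dist$nAssigned)
  ## uniform placement: every bin CI covers the uniform share 0.2
  expect_true(all(dist$bins$ci_lower <= 0.2 & dist$bins$ci_upper >= 0.2))
  ## intergenic complement of an everything-tiling gene set is empty
  extent <- GRanges("c", IRanges(1, 1e5))
  tiling <- GRanges("c", IRanges(c(1, 40001), c(40000, 1e5)))
  expect_length(intergenicRegions(tiling, extent), 0)
  gaps <- intergenicRegions(GRanges("c", IRanges(2001, 3000)), extent)
  expect_equal(sum(width(gaps)), 1e5 - 1000)
})

test_that("gene records join marks, timing and expression on complete cases", {
  gm <- data.frame(gene_id = c("g1", "g2", "g3"), k4 = TRUE, k9 = FALSE,
                   k56 = TRUE, mc = FALSE, pattern = 4L)
  gt <- data.frame(gene_id = c("g1", "g3"),
                   cls = factor(c("EM", "L"), levels = timingClasses()))
  ex <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   present = TRUE, level = 5)
  gr <- geneRecords(gm, gt, ex)
  expect_equal(gr$gene_id, c("g1", "g3"))
  expect_equal(as.character(gr$cls), c("EM", "L"))
})
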