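
test_that("profile extrema follow the neighbour rule with plateau midpoints", {
  expect_equal(findExtrema(c(0, 1, 2, 1, 0))$maxima, 3L)
  expect_equal(findExtrema(c(0, 1, 2, 1, 0))$minima, integer(0))
  ## two-probe plateau collapses to the left-of-center probe
  expect_equal(findExtrema(c(0, 1, 1, 0))$maxima, 2L)
  expect_equal(findExtrema(c(2, 1, 1, 2))$minima, 2L)
  expect_equal(findExtrema(c(0, 1, 1, 1, 0))$maxima, 3L)
  ## chromosome-end probes excluded; short profiles empty
  expect_equal(findExtrema(c(3, 1, 2))$maxima, integer(0))
  expect_equal(findExtrema(c(1, 2))$maxima, integer(0))
  set.seed(30)
  for (rep in 1:100) {
    v <- cumsum(sample(c(-1, 0, 1), 300, replace = TRUE))
    expect_equal(findExtrema(v), extremaOracle(v))
  }
})

test_that("zone roles flip between early/mid and late profiles", {
  pr <- makeProbes(60)
  v <- sin(2 * pi * probeCenters(pr) / 30000)
  sm <- cbind(early = v, mid = v, late = v)
  prof <- new("RepliProfiles", probes = pr, smoothed = sm, window = 10000)
  zE <- makeZones(prof, "early")
  zL <- makeZones(prof, "late")
  maxAnchors <- sort(mcols(zE)$anchor[mcols(zE)$kind == "initiation"])
  expect_equal(sort(mcols(zL)$anchor[mcols(zL)$kind == "termination"]),
               maxAnchors)  # same extrema, flipped role
})

test_that("zones are 10-kb, merged when overlapping, clipped at chromosome ends", {
  pr <- makeProbes(100)
  v <- rep(0, 100)
  v[c(30, 36)] <- 1          # two maxima 6 kb apart -> merged 16-kb zone
  v[c(33)] <- -1
  v[3] <- 2                   # maximum 2.5 kb from the start -> clipped
  v[1] <- 1.5
  prof <- new("RepliProfiles", probes = pr,
              smoothed = cbind(early = v, mid = v, late = v),
              window = 10000)
  z <- makeZones(prof, "early")
  init <- z[mcols(z)$kind == "initiation"]
  w <- width(init)
  expect_true(any(abs(w - 16000) <= 1))      # merged pair
  clipped <- init[start(init) == 1]
  expect_length(clipped, 1)
  expect_lt(width(clipped), 10000)           # clipped at the chromosome end
  ## unclipped zones are at least the nominal width; same-kind zones disjoint
  expect_true(all(w[start(init) > 1] >= 10000))
  expect_length(findOverlaps(init, drop.self = TRUE, drop.redundant = TRUE), 0)
})

test_that("zone timing is the overlap-length plurality with the fixed tie order", {
  segs <- GRanges("c", IRanges(c(1, 61, 101), c(60, 100, 200)),
                  cls = factor(c("EM", "ML", "L"), levels = timingClasses()))
  z <- GRanges("c", IRanges(c(1, 101, 41), c(100, 150, 140)))
  zt <- assignZoneTiming(z, segs)
  expect_equal(as.character(mcols(zt)$cls), c("EM", "L", "ML"))
  ## 50/50 tie resolved by fixed order (EM before L)
  segs2 <- GRanges("c", IRanges(c(1, 51), c(50, 100)),
                   cls = factor(c("L", "EM"), levels = timingClasses()))
  zt2 <- assignZoneTiming(GRanges("c", IRanges(1, 100)), segs2)
  expect_equal(as.character(mcols(zt2)$cls), "EM")
  ## zone with no probes -> I with QC flag
  zt3 <- assignZoneTiming(GRanges("c", IRanges(500, 600)), segs)
  expect_equal(as.character(mcols(zt3)$cls), "I")
  expect_true(mcols(zt3)$qc_no_probes)
})

test_that("zone matching is greedy nearest-center within tolerance", {
  mkZ <- function(centers) GRanges("c", IRanges(centers - 5000 + 1, centers + 5000),
                                   anchor = centers)
  a <- mkZ(c(100000, 300000))
  expect_equal(matchZones(a, a)$matchedFraction, 1)
  b <- mkZ(125000)
  expect_equal(matchZones(mkZ(100000), b)$matchedFraction, 0)  # 25 kb > tol
  expect_equal(matchZones(mkZ(100000), b, tol = 30000)$matchedFraction, 1)
  ## well-separated jittered copies match the obvious optimal assignment
  set.seed(31)
  centers <- sort(sample(seq(5e4, 5e6, by = 1e5), 50))
  jit <- centers + rnorm(50, 0, 5000)
  m <- matchZones(mkZ(centers), mkZ(sort(jit)), tol = 20000)
  expect_equal(m$matchedFraction, 1)
  expect_equal(order(m$pairs$a), order(m$pairs$b))  # order-preserving
})

test_that("boundary selection honours the three-tier precedence", {
  mkTerm <- function(centers, cls = "L") {
    if (length(centers) == 0) {
      gr <- GRanges()
      mcols(gr)$cls <- factor(character(0), levels = timingClasses())
      return(gr)
    }
    GRanges("c", IRanges(centers - 5000 + 1, centers + 5000),
            anchor = centers,
            cls = factor(cls, levels = timingClasses()))
  }
  segs <- GRanges("c", IRanges(c(1, 200001), c(200000, 400000)),
                  cls = factor(c("EM", "L"), levels = timingClasses()))
  ## one zone at the same site in all three fractions -> single Tier-1
  bd <- selectBoundaries(mkTerm(100000, "EM"), mkTerm(100000, "EM"),
                         mkTerm(100000, "EM"), segs)
  expect_equal(nrow(bd), 1)
  expect_equal(bd$tier, 1L)
  expect_equal(bd$position, 100000)
  ## late-only zone in late territory -> Tier 2
  bd2 <- selectBoundaries(mkTerm(numeric(0)), mkTerm(numeric(0)),
                          mkTerm(300000, "L"), segs)
  expect_equal(bd2$tier, 2L)
  ## early/mid minima in early/mid-enriched territory -> Tier 3
  bd3 <- selectBoundaries(mkTerm(150000, "EM"), mkTerm(numeric(0)),
                          mkTerm(numeric(0)), segs)
  expect_equal(bd3$tier, 3L)
  ## an early zone in L territory qualifies for no tier
  bd4 <- suppressWarnings(selectBoundaries(
    mkTerm(300000, "L"), mkTerm(numeric(0)), mkTerm(numeric(0)), segs))
  expect_equal(nrow(bd4), 0)
  expect_warning(selectBoundaries(mkTerm(numeric(0)), mkTerm(numeric(0)),
                                  mkTerm(numeric(0)), segs),
                 "no termination zones")
  ## dropping Tier-3 input does not move a Tier-1 boundary
  bd5 <- selectBoundaries(mkTerm(c(100000, 150000), "EM"),
                          mkTerm(100000, "EM"), mkTerm(100000, "EM"), segs)
  expect_equal(bd5$position[bd5$tier == 1], bd$position[bd$tier == 1])
  ## boundaries closer than minSep merge to their midpoint
  bd6 <- selectBoundaries(mkTerm(c(100000, 110000), "EM"),
                          mkTerm(numeric(0)), mkTerm(numeric(0)), segs)
  expect_equal(nrow(bd6), 1)
  expect_equal(bd6$position, 105000)
  ## initiation-zone veto: both other fractions calling initiation blocks a
  ## lone termination call
  init <- list(early = GRanges("c", IRanges(145001, 155000)),
               mid = GRanges(), late = GRanges("c", IRanges(145001, 155000)))
  expect_warning(bd7 <- selectBoundaries(
    mkTerm(numeric(0)), mkTerm(150000, "EM"), mkTerm(numeric(0)), segs,
    initZones = init))
  expect_equal(nrow(bd7), 0)
})

test_that("replicons fill between boundaries and take the plurality class", {
  pr <- makeProbes(100)
  ## composition 45% EM / 40% L / 15% M inside one replicon -> EM
  segs <- GRanges("c", IRanges(c(1, 45001, 85001), c(45000, 85000, 100000)),
                  cls = factor(c("EM", "L", "M"), levels = timingClasses()))
  reps <- buildReplicons(numeric(0), pr, segs, chromLength = 100000)
  expect_length(reps, 1)
  expect_equal(as.character(mcols(reps)$cls), "EM")
  comp <- mcols(reps)$composition
  expect_equal(unname(comp[1, c("EM", "L", "M")]), c(0.45, 0.40, 0.15))
  ## k internal boundaries -> k+1 replicons tiling the chromosome
  bds <- c(20000, 50000, 80000)
  reps3 <- buildReplicons(bds, pr, segs, chromLength = 100000)
  expect_length(reps3, 4)
  expect_equal(sum(width(reps3)), 100000)
  expect_equal(buildReplicons(bds, pr, segs, chromLength = 100000,
                              ends = "boundary") |> length(), 2)
})

test_that("domains are maximal runs of like-classed replicons", {
  mkReps <- function(cls) {
    n <- length(cls)
    GRanges("c", IRanges((seq_len(n) - 1) * 1e5 + 1, seq_len(n) * 1e5),
            replicon_id = sprintf("rep%03d", seq_len(n)),
            cls = factor(cls, levels = timingClasses()))
  }
  expect_length(clusterDomains(mkReps(c("EM", "EM", "EM", "L", "L"))), 2)
  expect_length(clusterDomains(mkReps(rep(c("EM", "L"), 5))), 10)
  set.seed(32)
  for (rep in 1:20) {
    cls <- sample(c("EM", "L", "M"), 30, replace = TRUE)
    expect_length(clusterDomains(mkReps(cls)), length(rle(cls)$lengths))
  }
})
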