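## Shared fixtures: small builders plus a cache so expensive simulations are
## generated once per test run.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

.simCache <- new.env(parent = emptyenv())

## simulated chromosome (+ optional annotation layer), cached by arguments
cachedSim <- function(seed, noiseSd = 0.3, chromLength = 3e6,
                      withAnnotation = FALSE, ...) {
  key <- paste("sim", seed, noiseSd, chromLength, withAnnotation, ...,
               sep = "_")
  if (is.null(.simCache[[key]])) {
    cfg <- simConfig(chromLength = chromLength, seed = seed,
                     noiseSd = noiseSd, ...)
    sim <- simulateChromosome(cfg)
    sim$config <- cfg
    if (withAnnotation)
      sim$ann <- simulateMarksGenes(cfg, sim$truth, sim$repliSet)
    .simCache[[key]] <- sim
  }
  .simCache[[key]]
}

## full replicon map for a simulated chromosome, cached
cachedMap <- function(seed, noiseSd = 0.3, chromLength = 3e6) {
  key <- paste("map", seed, noiseSd, chromLength, sep = "_")
  if (is.null(.simCache[[key]])) {
    sim <- cachedSim(seed, noiseSd, chromLength)
    fr <- setNames(c("early", "mid", "late"), c("early", "mid", "late"))
    prof <- smoothProfiles(sim$repliSet)
    profZone <- smoothProfiles(sim$repliSet, window = 50000)
    segs <- lapply(fr, function(f) callSegments(prof, f))
    seg <- reconcileSegments(segs$early, segs$mid, segs$late,
                             probes(sim$repliSet))
    zl <- lapply(fr, function(f)
      assignZoneTiming(makeZones(profZone, f), seg))
    term <- lapply(zl, function(z) z[mcols(z)$kind == "termination"])
    init <- lapply(zl, function(z) z[mcols(z)$kind == "initiation"])
    bd <- selectBoundaries(term$early, term$mid, term$late, seg,
                           initZones = init)
    reps <- buildReplicons(bd, probes(sim$repliSet), seg,
                           initZones = reduce(do.call(c, unname(init))))
    .simCache[[key]] <- list(sim = sim, profiles = prof,
                             zoneProfiles = profZone, segments = seg,
                             zones = zl, boundaries = bd, replicons = reps)
  }
  .simCache[[key]]
}

## uniform 1-kb probe grid
makeProbes <- function(n, len = 1000, chrom = "c") {
  gr <- GRanges(chrom, IRanges(start = (seq_len(n) - 1) * len + 1,
                               width = len))
  mcols(gr)$probe_id <- sprintf("p%04d", seq_len(n))
  mcols(gr)$gc <- rep(0.36, n)
  gr
}

## origin family of the replicon containing each position, from ground truth
familyAt <- function(x, truth, forkSpeed = 3e5) {
  org <- truth@origins
  vapply(x, function(xi) {
    tt <- org$meanFiringTime + abs(xi - org$position) / forkSpeed
    org$family[which.min(tt)]
  }, character(1))
}

## independent per-base coverage oracle (counts bases, no interval algebra)
coverageOracle <- function(intervalStart, intervalEnd, featStart, featEnd) {
  bases <- intervalStart:(intervalEnd - 1)
  cov <- vapply(bases, function(b)
    any(b >= featStart & b < featEnd), logical(1))
  100 * sum(cov) / length(bases)
}

## exact doubled-tail binomial oracle by direct summation
binomOracle <- function(x, n, p0) {
  probs <- dbinom(0:n, n, p0)
  lower <- sum(probs[0:x + 1])
  upper <- sum(probs[(x:n) + 1])
  min(1, 2 * min(lower, upper))
}

## hypergeometric tail oracles by direct combinatorial sums (no complements,
## so tiny tails keep full precision)
hyperOverOracle <- function(x, K, n, N) {
  if (x > min(K, n)) return(0)
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
hyperUnderOracle <- function(x, K, n, N) {
  lo <- max(0, K + n - N)
  if (x < lo) return(0)
  ks <- lo:min(x, K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

## boundary recovery and family-class consistency for one simulated
## chromosome, via the full analysis path
recoveryStats <- function(seed, noiseSd, tol = 20000) {
  m <- cachedMap(seed, noiseSd)
  truth <- m$sim$truth
  bd <- m$boundaries$position
  hit <- vapply(truth@boundaries,
                function(b) any(abs(bd - b) <= tol), logical(1))
  reps <- m$replicons
  mids <- (start(reps) - 1 + end(reps)) / 2
  fam <- familyAt(mids, truth)
  cls <- as.character(mcols(reps)$cls)
  consistent <- mapply(function(f, cl)
    cl %in% familyConsistentClasses(f), fam, cls)
  list(recovered = mean(hit), consistent = mean(consistent),
       nBoundaries = length(bd), nTrue = length(truth@boundaries),
       medianRepliconKb = median(width(reps)) / 1000)
}

## independent run-scan oracle: maximal >0 runs, keep spans >= minLen
runScanOracle <- function(probes, values, minLen) {
  pos <- values > 0
  segs <- list()
  i <- 1
  while (i <= length(pos)) {
    if (pos[i]) {
      j <- i
      while (j < length(pos) && pos[j + 1]) j <- j + 1
      span <- end(probes)[j] - start(probes)[i] + 1
      if (span >= minLen)
        segs[[length(segs) + 1]] <- c(start(probes)[i], end(probes)[j])
      i <- j + 1
    } else i <- i + 1
  }
  if (length(segs) == 0) return(matrix(numeric(0), 0, 2))
  do.call(rbind, segs)
}

## exhaustive neighbour-comparison extrema oracle with the plateau rule
extremaOracle <- function(v) {
  n <- length(v)
  maxima <- integer(0); minima <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && v[j + 1] == v[i]) j <- j + 1
    if (i > 1 && j < n) {              # interior plateau
      left <- v[i - 1]; right <- v[j + 1]
      mid <- floor((i + j) / 2)
      if (v[i] > left && v[i] > right) maxima <- c(maxima, mid)
      if (v[i] < left && v[i] < right) minima <- c(minima, mid)
    }
    i <- j + 1
  }
  list(maxima = maxima, minima = minima)
}
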