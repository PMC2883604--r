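## Simulated chromatin marks, gene/TE annotation and expression, correlated
## with the replication-timing ground truth.

## scaled distance d in [0,1] from the claiming origin, relative to the
## half-length of the containing true replicon, plus the replicon family
.originDistance <- function(x, truth, forkSpeed) {
  org <- truth@origins
  rt <- .repTime(x, org$position, org$meanFiringTime, forkSpeed)
  bnd <- sort(truth@boundaries)
  breaks <- c(0, bnd, truth@chromLength)
  repIdx <- findInterval(x, breaks, rightmost.closed = TRUE)
  repIdx[repIdx < 1] <- 1L
  repIdx[repIdx > length(breaks) - 1] <- length(breaks) - 1L
  half <- (breaks[repIdx + 1] - breaks[repIdx]) / 2
  d <- pmin(1, abs(x - org$position[rt$claim]) / pmax(half, 1))
  list(d = d, family = org$family[rt$claim])
}

.markProb <- function(d, family, par) {
  p <- numeric(length(d))
  for (fam in c("early", "late")) {
    sel <- family == fam
    p[sel] <- par[[fam]]["base"] + par[[fam]]["slope"] * d[sel]
  }
  p
}

.checkMarkParams <- function(markParams) {
  for (mk in names(markParams)) {
    for (fam in c("early", "late")) {
      pr <- markParams[[mk]][[fam]]
      ends <- pr["base"] + pr["slope"] * c(0, 1)
      if (any(ends < 0 | ends > 1))
        stop(sprintf("mark probability for %s (%s family) leaves [0,1] over d in [0,1]",
                     mk, fam))
    }
  }
  invisible(TRUE)
}

## sequential non-overlapping placement: exponential gaps whose local mean
## depends on position (through the supplied function), lognormal lengths
.placeElements <- function(L, gapMeanAt, lenMeanlog, lenSdlog, lenMin) {
  starts <- numeric(0); ends <- numeric(0)
  x <- 0
  repeat {
    gap <- rexp(1, rate = 1 / gapMeanAt(x))
    s <- x + gap
    len <- max(lenMin, rlnorm(1, lenMeanlog, lenSdlog))
    if (s + len >= L) break
    starts <- c(starts, s); ends <- c(ends, s + len)
    x <- s + len
  }
  data.frame(start = floor(starts), end = ceiling(ends))
}

#' Simulate annotation, epigenetic mark calls and gene expression
#'
#' Layers genes, transposable elements, binary epigenetic-mark calls and
#' expression measurements on a simulated chromosome, with the spatial
#' structure the downstream statistics are designed to detect:
#' \itemize{
#'   \item per-probe mark probabilities are linear in the scaled distance
#'     `d` in \[0,1\] from the claiming origin (relative to the containing
#'     true replicon's half-length) with family-specific base and slope --
#'     by default H3K56ac decreases away from origins, H3K9me2 and 5mC are
#'     elevated in late-family replicons, and 5mC/H3K4me1/2 increase toward
#'     termination zones of early-family replicons;
#'   \item genes are placed by an inhomogeneous point process whose
#'     intensity increases with `d` in early-family replicons; TEs with
#'     intensity elevated in late-family replicons;
#'   \item a gene's presence (active transcription) probability is logistic
#'     in the fraction of its overlapping probes positive for H3K56ac
#'     (activating) and H3K9me2 (repressive), tuned to ~60% active overall;
#'     expression levels are Normal(6, 1.5) for present genes and
#'     Normal(3.5, 1) otherwise.
#' }
#'
#' @param config a [SimConfig-class] (mark/gene parameters are taken from
#'   `config@markParams` and `config@geneParams`).
#' @param truth the [GroundTruth-class] from [simulateChromosome()].
#' @param probes the probe GRanges (or a [RepliSet-class]).
#' @return A list with:
#' \describe{
#'   \item{features}{GRanges of genes and TEs (`feature_id`, `kind`, strand).}
#'   \item{marks}{data.frame `probe_id`, `k4`, `k9`, `k56`, `mc` (logical).}
#'   \item{expression}{data.frame `gene_id`, `present` (logical), `level`.}
#'   \item{probeInfo}{data.frame with the per-probe `d` and `family` used
#'     by the generator (truth channel for tests).}
#' }
#' @export
#' @examples
#' sim <- simulateChromosome(simConfig(chromLength = 1e6, seed = 1))
#' ann <- simulateMarksGenes(simConfig(chromLength = 1e6, seed = 1),
#'                           sim$truth, sim$repliSet)
#' table(ann$marks$k9, ann$probeInfo$family)
simulateMarksGenes <- function(config, truth, probes) {
  stopifnot(is(config, "SimConfig"), is(truth, "GroundTruth"))
  if (is(probes, "RepliSet")) probes <- probes(probes)
  .checkMarkParams(config@markParams)
  set.seed(config@seed + 7919L)   # independent stream, still seed-determined

  centers <- probeCenters(probes)
  od <- .originDistance(centers, truth, config@forkSpeed)
  n <- length(centers)

  mp <- config@markParams
  marks <- data.frame(probe_id = mcols(probes)$probe_id)
  for (mk in c("k4", "k9", "k56", "mc")) {
    pr <- .markProb(od$d, od$family, mp[[mk]])
    marks[[mk]] <- runif(n) < pr
  }

  gp <- config@geneParams
  famAt <- function(x) .originDistance(x, truth, config@forkSpeed)
  geneGapAt <- function(x) {
    f <- famAt(x)
    if (f$family == "early") gp$geneGapBaseEarly / (0.5 + f$d) else gp$geneGapLate
  }
  teGapAt <- function(x) {
    f <- famAt(x)
    if (f$family == "early") gp$teGapEarly else gp$teGapLate
  }
  L <- truth@chromLength
  g <- .placeElements(L, geneGapAt, gp$geneLenMeanlog, gp$geneLenSdlog,
                      gp$geneLenMin)
  te <- .placeElements(L, teGapAt, gp$teLenMeanlog, gp$teLenSdlog, gp$teLenMin)

  chrom <- as.character(seqnames(probes))[1]
  mk <- function(df, kind, prefix) {
    if (nrow(df) == 0)
      return(GRanges(character(0), IRanges(), feature_id = character(0),
                     kind = character(0)))
    gr <- GRanges(chrom, IRanges(start = df$start + 1, end = df$end),
                  strand = sample(c("+", "-"), nrow(df), replace = TRUE))
    mcols(gr)$feature_id <- sprintf("%s%04d", prefix, seq_len(nrow(df)))
    mcols(gr)$kind <- kind
    gr
  }
  genes <- mk(g, "gene", "g")
  tes <- mk(te, "TE", "te")
  features <- c(genes, tes)

  ## presence logistic in overlapping-probe k56/k9 fractions
  ov <- findOverlaps(genes, probes)
  f56 <- rep(0, length(genes)); f9 <- rep(0, length(genes))
  if (length(ov)) {
    nOv <- tabulate(queryHits(ov), length(genes))
    s56 <- rowsum(as.numeric(marks$k56[subjectHits(ov)]), queryHits(ov))
    s9 <- rowsum(as.numeric(marks$k9[subjectHits(ov)]), queryHits(ov))
    idx <- as.integer(rownames(s56))
    f56[idx] <- s56[, 1] / nOv[idx]
    f9[idx] <- s9[, 1] / nOv[idx]
  }
  pPresent <- plogis(gp$presentIntercept + gp$presentK56 * f56 +
                     gp$presentK9 * f9)
  present <- runif(length(genes)) < pPresent
  level <- ifelse(present,
                  rnorm(length(genes), gp$levelPresentMean, gp$levelPresentSd),
                  rnorm(length(genes), gp$levelAbsentMean, gp$levelAbsentSd))
  expression <- data.frame(gene_id = mcols(genes)$feature_id,
                           present = present, level = level)

  list(features = features, marks = marks, expression = expression,
       probeInfo = data.frame(probe_id = mcols(probes)$probe_id,
                              d = od$d, family = od$family))
}

#' Mark-call probability at a scaled origin distance
#'
#' The generator's per-probe probability that a mark call is positive, as a
#' function of the scaled distance `d` from the claiming origin and the
#' replicon family, under a configuration's `markParams`
#' (`base + slope * d` per family).
#'
#' @param mark one of `"k4"`, `"k9"`, `"k56"`, `"mc"`.
#' @param d scaled origin distance(s) in \[0,1\].
#' @param family `"early"` or `"late"` (recycled).
#' @param config a [SimConfig-class].
#' @return Numeric probabilities.
#' @export
#' @examples
#' markProbability("k56", 0, "early", simConfig())   # 0.50
markProbability <- function(mark, d, family, config = simConfig()) {
  mark <- match.arg(mark, c("k4", "k9", "k56", "mc"))
  n <- max(length(d), length(family))
  d <- rep_len(d, n); family <- rep_len(family, n)
  .markProb(d, family, config@markParams[[mark]])
}
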