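## S4 classes: SimConfig, GroundTruth, RepliSet, RepliProfiles.
## Segments, zones, replicons and domains are plain GRanges with metadata
## columns, mirroring how range-centric Bioconductor packages expose results.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' SimConfig: parameters of the synthetic-chromosome simulator
#'
#' Holds every knob of the stochastic origin-firing model used by
#' [simulateChromosome()] and [simulateMarksGenes()].  Use the
#' [simConfig()] constructor rather than `new()`.
#'
#' @slot chromLength chromosome length in bp.
#' @slot probeLength tiling-probe length in bp (probes tile the chromosome).
#' @slot originSpacingMean mean inter-origin spacing in bp (gamma renewal).
#' @slot originSpacingShape gamma shape of the inter-origin spacing.
#' @slot pEarlyFamily probability that an origin belongs to the early-firing
#'   family.
#' @slot firingWindowEarly,firingWindowLate numeric(2); interval of S-phase
#'   (units of \[0,1\]) from which an origin's mean firing time is drawn,
#'   per family.
#' @slot firingJitterSd cell-to-cell SD of an origin's firing time (S units).
#' @slot forkSpeed replication fork speed in bp per S-phase unit.
#' @slot fractionWindows numeric(4) breakpoints partitioning \[0,1\] into the
#'   early, mid and late sorting windows (half-open, last window closed).
#' @slot signalGain log2 gain applied to the enrichment signal.
#' @slot noiseSd per-replicate additive Gaussian noise SD (log2 units).
#' @slot nReplicates number of replicate arrays per fraction.
#' @slot gcMean,gcSd mean/SD of the per-probe GC fraction (drawn from a Beta).
#' @slot markParams per-mark, per-family `base`/`slope` of the positive-call
#'   probability as a function of scaled origin distance d in \[0,1\].
#' @slot geneParams gene/TE placement and expression parameters; see
#'   [simulateMarksGenes()].
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig", slots = c(
  chromLength       = "numeric",
  probeLength       = "numeric",
  originSpacingMean = "numeric",
  originSpacingShape = "numeric",
  pEarlyFamily      = "numeric",
  firingWindowEarly = "numeric",
  firingWindowLate  = "numeric",
  firingJitterSd    = "numeric",
  forkSpeed         = "numeric",
  fractionWindows   = "numeric",
  signalGain        = "numeric",
  noiseSd           = "numeric",
  nReplicates       = "integer",
  gcMean            = "numeric",
  gcSd              = "numeric",
  markParams        = "list",
  geneParams        = "list",
  seed              = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  fw <- object@fractionWindows
  if (length(fw) != 4L || fw[1] != 0 || fw[4] != 1 || any(diff(fw) <= 0))
    msg <- c(msg, "fractionWindows must be 4 increasing breakpoints from 0 to 1 (exact partition)")
  for (nm in c("firingWindowEarly", "firingWindowLate")) {
    w <- slot(object, nm)
    if (length(w) != 2L || w[1] >= w[2] || w[1] < 0 || w[2] > 1)
      msg <- c(msg, sprintf("%s must be an increasing interval within [0,1]", nm))
  }
  if (object@forkSpeed <= 0) msg <- c(msg, "forkSpeed must be > 0")
  if (object@probeLength <= 0 || object@chromLength <= 0)
    msg <- c(msg, "chromLength and probeLength must be positive")
  if (object@firingJitterSd < 0) msg <- c(msg, "firingJitterSd must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@pEarlyFamily < 0 || object@pEarlyFamily > 1)
    msg <- c(msg, "pEarlyFamily must be in [0,1]")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

.defaultMarkParams <- function() list(
  k4  = list(early = c(base = 0.30, slope = 0.12),
             late  = c(base = 0.38, slope = 0.00)),
  k9  = list(early = c(base = 0.05, slope = 0.00),
             late  = c(base = 0.30, slope = 0.00)),
  k56 = list(early = c(base = 0.50, slope = -0.20),
             late  = c(base = 0.40, slope = -0.15)),
  mc  = list(early = c(base = 0.20, slope = 0.15),
             late  = c(base = 0.42, slope = 0.00))
)

.defaultGeneParams <- function() list(
  geneLenMeanlog = log(1800), geneLenSdlog = 0.4, geneLenMin = 300,
  geneGapBaseEarly = 1600,   # mean intergenic gap in early replicons = base/(0.5+d)
  geneGapLate = 2700,        # flat mean gap in late replicons
  teLenMeanlog = log(350), teLenSdlog = 0.5, teLenMin = 80,
  teGapEarly = 8400, teGapLate = 2500,
  presentIntercept = 0.2, presentK56 = 1.2, presentK9 = -2.5,
  levelPresentMean = 6, levelPresentSd = 1.5,
  levelAbsentMean = 3.5, levelAbsentSd = 1
)

#' Construct a simulator configuration
#'
#' Defaults encode the study conditions the pipeline is validated against:
#' a ~1-kb tiling grid, gamma-renewal origins with ~107-kb mean spacing, two
#' origin-firing families (early and late), Gaussian firing jitter, constant
#' fork speed, three equal S-phase sorting windows, and enrichment ratios of
#' the form `signalGain * log2((p + 1e-6) / (1/3))` plus Gaussian noise.
#'
#' @param chromLength chromosome length in bp (default 3e6).
#' @param probeLength probe length in bp (default 1000).
#' @param originSpacingMean mean inter-origin spacing in bp (default 107000).
#' @param originSpacingShape gamma shape parameter (default 4).
#' @param pEarlyFamily probability an origin is early-firing (default 0.5).
#' @param firingWindowEarly,firingWindowLate mean-firing-time windows for the
#'   two families, in S-phase units (defaults `c(0, 0.40)` and
#'   `c(0.55, 0.90)`).
#' @param firingJitterSd SD of the per-cell firing-time jitter (default
#'   0.20, a dispersion spanning roughly half of S phase at 2 SD: origin
#'   activation order within each family is stochastic from cell to cell,
#'   which is what makes the early and mid fraction profiles similar).
#' @param forkSpeed fork speed in bp per S-phase unit (default 3e5).
#' @param fractionWindows numeric(4) breakpoints of the early/mid/late
#'   sorting windows (default `c(0, 0.33, 0.66, 1)`).
#' @param signalGain log2 signal gain (default 1.5).
#' @param noiseSd replicate noise SD in log2 units (default 0.3).
#' @param nReplicates replicate arrays per fraction (default 3).
#' @param gcMean,gcSd GC fraction distribution (defaults 0.36, 0.03).
#' @param markParams,geneParams optional overrides merged over the defaults;
#'   see [simulateMarksGenes()].
#' @param seed integer RNG seed (default 1).
#' @return A validated [SimConfig-class] object.
#' @export
#' @examples
#' cfg <- simConfig(chromLength = 1e6, seed = 7)
#' cfg
simConfig <- function(chromLength = 3e6,
                      probeLength = 1000,
                      originSpacingMean = 107000,
                      originSpacingShape = 4,
                      pEarlyFamily = 0.5,
                      firingWindowEarly = c(0, 0.40),
                      firingWindowLate = c(0.55, 0.90),
                      firingJitterSd = 0.20,
                      forkSpeed = 3e5,
                      fractionWindows = c(0, 0.33, 0.66, 1),
                      signalGain = 1.5,
                      noiseSd = 0.3,
                      nReplicates = 3L,
                      gcMean = 0.36,
                      gcSd = 0.03,
                      markParams = list(),
                      geneParams = list(),
                      seed = 1L) {
  mp <- utils::modifyList(.defaultMarkParams(), markParams)
  gp <- utils::modifyList(.defaultGeneParams(), geneParams)
  new("SimConfig",
      chromLength = as.numeric(chromLength),
      probeLength = as.numeric(probeLength),
      originSpacingMean = as.numeric(originSpacingMean),
      originSpacingShape = as.numeric(originSpacingShape),
      pEarlyFamily = as.numeric(pEarlyFamily),
      firingWindowEarly = as.numeric(firingWindowEarly),
      firingWindowLate = as.numeric(firingWindowLate),
      firingJitterSd = as.numeric(firingJitterSd),
      forkSpeed = as.numeric(forkSpeed),
      fractionWindows = as.numeric(fractionWindows),
      signalGain = as.numeric(signalGain),
      noiseSd = as.numeric(noiseSd),
      nReplicates = as.integer(nReplicates),
      gcMean = as.numeric(gcMean), gcSd = as.numeric(gcSd),
      markParams = mp, geneParams = gp,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  chromosome: %.0f bp, %.0f-bp probes\n",
              object@chromLength, object@probeLength))
  cat(sprintf("  origins: gamma(shape=%g) spacing, mean %.0f bp; P(early family)=%g\n",
              object@originSpacingShape, object@originSpacingMean,
              object@pEarlyFamily))
  cat(sprintf("  firing: early [%g,%g], late [%g,%g], jitter sd %g; fork %g bp/S\n",
              object@firingWindowEarly[1], object@firingWindowEarly[2],
              object@firingWindowLate[1], object@firingWindowLate[2],
              object@firingJitterSd, object@forkSpeed))
  cat(sprintf("  fractions: [%s); signal gain %g, noise sd %g, %d replicates; seed %d\n",
              paste(object@fractionWindows, collapse = ", "),
              object@signalGain, object@noiseSd, object@nReplicates,
              object@seed))
})

#' GroundTruth: simulator record for recovery tests
#'
#' @slot origins data.frame with columns `position` (bp), `family`
#'   (`"early"`/`"late"`), `meanFiringTime` (S units) and `active` (whether
#'   the origin fires before a fork from a neighbour arrives anywhere in its
#'   vicinity, i.e. it owns territory).
#' @slot boundaries bp positions of the local maxima of the expected
#'   replication-time curve t(x): the true replicon boundaries.
#' @slot trueProbeClass per-probe timing class implied by the labeling
#'   probabilities (fractions with p > 1/3), e.g. `"EM"`; `"I"` if none.
#' @slot trueRepTime per-probe expected replication time t(x) in \[0,1\].
#' @slot labelingProb n x 3 matrix of closed-form per-fraction labeling
#'   probabilities (columns early, mid, late; rows sum to 1).
#' @slot chromLength chromosome length in bp.
#' @export
setClass("GroundTruth", slots = c(
  origins = "data.frame",
  boundaries = "numeric",
  trueProbeClass = "character",
  trueRepTime = "numeric",
  labelingProb = "matrix",
  chromLength = "numeric"
))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  if (!all(c("position", "family", "meanFiringTime") %in% names(object@origins)))
    msg <- c(msg, "origins needs columns position, family, meanFiringTime")
  if (any(object@trueRepTime < 0 | object@trueRepTime > 1))
    msg <- c(msg, "trueRepTime must lie in [0,1]")
  if (nrow(object@labelingProb) != length(object@trueProbeClass))
    msg <- c(msg, "labelingProb rows must match trueProbeClass length")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d origins (%d active), %d boundaries, %d probes, chrom %.0f bp\n",
              nrow(object@origins), sum(object@origins$active),
              length(object@boundaries), length(object@trueProbeClass),
              object@chromLength))
})

#' RepliSet: probes with per-fraction, per-replicate enrichment ratios
#'
#' The container for raw input data: a sorted, non-overlapping tiling-probe
#' grid ([GenomicRanges::GRanges] with `probe_id` and `gc` metadata columns)
#' plus a probes x arrays matrix of log2(BrdU-IP/input) ratios, each array
#' column annotated with its S-phase fraction and replicate number.
#'
#' @slot probes GRanges of probes, sorted, non-overlapping, with metadata
#'   columns `probe_id` and `gc`.
#' @slot ratios numeric matrix, `length(probes)` rows, one column per array.
#' @slot fraction factor (`early`/`mid`/`late`), one per array column.
#' @slot replicate integer replicate index, one per array column.
#' @export
setClass("RepliSet", slots = c(
  probes = "GRanges",
  ratios = "matrix",
  fraction = "factor",
  replicate = "integer"
))

setValidity("RepliSet", function(object) {
  msg <- character(0)
  n <- length(object@probes)
  if (nrow(object@ratios) != n)
    msg <- c(msg, "ratios must have one row per probe")
  if (ncol(object@ratios) != length(object@fraction) ||
      ncol(object@ratios) != length(object@replicate))
    msg <- c(msg, "fraction and replicate must annotate every ratio column")
  if (!all(levels(object@fraction) %in% .FRACTIONS))
    msg <- c(msg, "fraction levels must be early/mid/late")
  if (!all(c("probe_id", "gc") %in% names(mcols(object@probes))))
    msg <- c(msg, "probes need metadata columns probe_id and gc")
  if (n > 1) {
    if (is.unsorted(start(object@probes)))
      msg <- c(msg, "probes must be sorted by start")
    ov <- findOverlaps(object@probes, drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov) > 0)
      msg <- c(msg, "probes must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RepliSet
#'
#' @param probes GRanges with `probe_id` and `gc` metadata columns.
#' @param ratios numeric matrix of log2 ratios (probes x arrays).
#' @param fraction character/factor of `"early"`, `"mid"`, `"late"` per
#'   array column.
#' @param replicate integer replicate index per array column.
#' @return A [RepliSet-class].
#' @export
RepliSet <- function(probes, ratios, fraction, replicate) {
  new("RepliSet", probes = probes, ratios = as.matrix(ratios),
      fraction = factor(as.character(fraction), levels = .FRACTIONS),
      replicate = as.integer(replicate))
}

setMethod("show", "RepliSet", function(object) {
  cat(sprintf("RepliSet: %d probes on %s, %d arrays (%s)\n",
              length(object@probes),
              paste(unique(as.character(seqnames(object@probes))), collapse = ","),
              ncol(object@ratios),
              paste(sprintf("%s x%d", .FRACTIONS,
                            tabulate(object@fraction, 3L)), collapse = ", ")))
})

#' RepliProfiles: loess-smoothed per-fraction replication profiles
#'
#' @slot probes the probe GRanges the profiles are aligned to (1:1).
#' @slot smoothed numeric matrix with columns `early`, `mid`, `late`.
#' @slot window genomic smoothing window in bp.
#' @export
setClass("RepliProfiles", slots = c(
  probes = "GRanges",
  smoothed = "matrix",
  window = "numeric"
))

setValidity("RepliProfiles", function(object) {
  msg <- character(0)
  if (nrow(object@smoothed) != length(object@probes))
    msg <- c(msg, "smoothed values must align 1:1 with probes")
  if (!identical(colnames(object@smoothed), .FRACTIONS))
    msg <- c(msg, "smoothed columns must be early, mid, late")
  if (any(!is.finite(object@smoothed)))
    msg <- c(msg, "smoothed values must all be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RepliProfiles", function(object) {
  cat(sprintf("RepliProfiles: %d probes, %.0f-bp window\n",
              length(object@probes), object@window))
})

## ---- accessors -----------------------------------------------------------

#' @rdname probes
#' @export
setGeneric("probes", function(object) standardGeneric("probes"))

#' Probe ranges of a container
#'
#' @param object a [RepliSet-class] or [RepliProfiles-class].
#' @return The probe [GenomicRanges::GRanges].
#' @export
#' @rdname probes
setMethod("probes", "RepliSet", function(object) object@probes)

#' @rdname probes
#' @export
setMethod("probes", "RepliProfiles", function(object) object@probes)

#' @rdname ratioMatrix
#' @export
setGeneric("ratioMatrix", function(object) standardGeneric("ratioMatrix"))

#' Raw ratio matrix of a RepliSet
#'
#' @param object a [RepliSet-class].
#' @return Numeric matrix (probes x arrays) with the per-column fraction and
#'   replicate available via [arrayFractions()] and [arrayReplicates()].
#' @export
#' @rdname ratioMatrix
setMethod("ratioMatrix", "RepliSet", function(object) object@ratios)

#' Per-array fraction and replicate annotations
#'
#' @param object a [RepliSet-class].
#' @return `arrayFractions`: factor of fractions; `arrayReplicates`: integer
#'   replicate indices (one per ratio column).
#' @export
arrayFractions <- function(object) object@fraction

#' @rdname arrayFractions
#' @export
arrayReplicates <- function(object) object@replicate

#' @rdname smoothedValues
#' @export
setGeneric("smoothedValues", function(object, fraction = NULL)
  standardGeneric("smoothedValues"))

#' Smoothed profile values
#'
#' @param object a [RepliProfiles-class].
#' @param fraction optional fraction name (`"early"`, `"mid"`, `"late"`);
#'   when `NULL` the full matrix is returned.
#' @return Numeric matrix or vector of smoothed log2 enrichment values.
#' @export
#' @rdname smoothedValues
setMethod("smoothedValues", "RepliProfiles", function(object, fraction = NULL) {
  if (is.null(fraction)) return(object@smoothed)
  fraction <- match.arg(fraction, .FRACTIONS)
  object@smoothed[, fraction]
})

#' Probe center coordinates
#'
#' Midpoint of each probe, the coordinate at which profiles are evaluated.
#'
#' @param x a GRanges (or RepliSet/RepliProfiles via [probes()]).
#' @return Numeric vector of centers in bp.
#' @export
probeCenters <- function(x) {
  if (is(x, "RepliSet") || is(x, "RepliProfiles")) x <- probes(x)
  ## midpoint on the continuous axis (GRanges are 1-based closed, so the
  ## interval covers [start-1, end) of the continuous coordinate line)
  (start(x) - 1 + end(x)) / 2
}
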