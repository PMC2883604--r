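## Synthetic-chromosome simulator: stochastic origin firing with constant-speed
## bidirectional forks (biphasic, two firing families), closed-form fraction
## labeling probabilities, and additive log2 array noise.

.EPS_LOG <- 1e-6   # floor inside log2 so p = 0 maps to a finite ratio

## Expected replication time at positions x for given origins:
## t(x) = min over origins o of clip(f_o + |x - o| / forkSpeed, 0, 1).
## Returns t and the index of the claiming (minimizing) origin.
.repTime <- function(x, originPos, firing, forkSpeed) {
  t <- rep(Inf, length(x))
  claim <- integer(length(x))
  for (k in seq_along(originPos)) {
    tk <- firing[k] + abs(x - originPos[k]) / forkSpeed
    upd <- tk < t
    t[upd] <- tk[upd]
    claim[upd] <- k
  }
  list(t = pmin(pmax(t, 0), 1), claim = claim)
}

## Closed-form labeling probabilities: t = clip(mu + jitter, 0, 1) with
## Gaussian jitter on the claiming origin's firing time; mass clipped at 0/1
## falls into the first/last fraction window.
.labelingProb <- function(mu, jitterSd, breaks) {
  n <- length(mu)
  p <- matrix(0, n, 3, dimnames = list(NULL, .FRACTIONS))
  if (jitterSd > 0) {
    p[, 1] <- pnorm((breaks[2] - mu) / jitterSd)
    p[, 3] <- pnorm((breaks[3] - mu) / jitterSd, lower.tail = FALSE)
    p[, 2] <- pmax(0, 1 - p[, 1] - p[, 3])
  } else {
    t <- pmin(pmax(mu, 0), 1)
    idx <- findInterval(t, breaks, rightmost.closed = TRUE)
    p[cbind(seq_len(n), idx)] <- 1
  }
  p
}

.classFromProb <- function(p, threshold = 1 / 3) {
  bits <- p > threshold
  key <- paste0(bits[, 1] + 0L, bits[, 2] + 0L, bits[, 3] + 0L)
  unname(.BITS_TO_CLASS[key])
}

## True replicon boundaries: local maxima of t(x) on a fine grid, plateau
## midpoints, grid ends excluded.  Origins passively replicated by a
## neighbour's fork produce no maximum and hence no boundary.
.trueBoundaries <- function(originPos, firing, forkSpeed, chromLength,
                            step = 100) {
  grid <- seq(0, chromLength, by = step)
  t <- .repTime(grid, originPos, firing, forkSpeed)$t
  r <- rle(t)
  K <- length(r$values)
  if (K < 3) return(numeric(0))
  idxEnd <- cumsum(r$lengths)
  idxStart <- idxEnd - r$lengths + 1L
  isMax <- c(FALSE, r$values[2:(K - 1)] > r$values[1:(K - 2)] &
                    r$values[2:(K - 1)] > r$values[3:K], FALSE)
  mid <- floor((idxStart + idxEnd) / 2)
  grid[mid[isMax]]
}

#' Simulate a synthetic chromosome with known replication-timing ground truth
#'
#' Origins are placed by a gamma renewal process, assigned to an early- or
#' late-firing family, and given a mean firing time uniform in the family
#' window.  The expected replication time of a locus is
#' `t(x) = min over origins o of clip(f_o + |x - o|/forkSpeed, 0, 1)`.
#' Per-probe labeling probabilities for the three S-phase sorting windows are
#' the closed-form Normal-CDF probabilities of `t(x)` falling in each window
#' under Gaussian jitter of the claiming origin's firing time (mass clipped
#' at 0 or 1 counts toward the first or last window, so the three
#' probabilities sum to exactly 1).  Each replicate array measures
#' `signalGain * log2((p + 1e-6)/(1/3))` plus Gaussian noise.
#'
#' @param config a [SimConfig-class]; `config@seed` makes the run fully
#'   reproducible.
#' @return A list with elements:
#' \describe{
#'   \item{repliSet}{a [RepliSet-class] of probes and replicate ratios.}
#'   \item{truth}{a [GroundTruth-class]: origins (with activity status),
#'     true boundaries (local maxima of t(x)), per-probe labeling
#'     probabilities, true timing classes and true replication times.}
#' }
#' @export
#' @examples
#' sim <- simulateChromosome(simConfig(chromLength = 1e6, seed = 1))
#' sim$repliSet
#' sim$truth
simulateChromosome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@chromLength < 3 * config@originSpacingMean)
    stop("chromLength must be at least 3 * originSpacingMean (too few replicons to analyze)")
  set.seed(config@seed)

  L <- config@chromLength
  ## renewal process: cumulative gamma spacings from the left end
  nDraw <- ceiling(L / config@originSpacingMean * 3) + 20
  scale <- config@originSpacingMean / config@originSpacingShape
  sp <- rgamma(nDraw, shape = config@originSpacingShape, scale = scale)
  pos <- cumsum(sp)
  pos <- pos[pos < L]
  if (length(pos) < 2)
    stop("fewer than two origins drawn; increase chromLength")
  family <- ifelse(rbinom(length(pos), 1, config@pEarlyFamily) == 1,
                   "early", "late")
  firing <- numeric(length(pos))
  fe <- config@firingWindowEarly; fl <- config@firingWindowLate
  firing[family == "early"] <- runif(sum(family == "early"), fe[1], fe[2])
  firing[family == "late"]  <- runif(sum(family == "late"), fl[1], fl[2])

  ## probe grid (continuous coords [s, s+len) -> GRanges 1-based closed)
  nProbes <- floor(L / config@probeLength)
  s0 <- (seq_len(nProbes) - 1) * config@probeLength
  centers <- s0 + config@probeLength / 2
  gcK <- config@gcMean * (1 - config@gcMean) / config@gcSd^2 - 1
  gc <- rbeta(nProbes, config@gcMean * gcK, (1 - config@gcMean) * gcK)

  rt <- .repTime(centers, pos, firing, config@forkSpeed)
  mu <- firing[rt$claim] + abs(centers - pos[rt$claim]) / config@forkSpeed
  p <- .labelingProb(mu, config@firingJitterSd, config@fractionWindows)

  nArr <- 3L * config@nReplicates
  base <- config@signalGain * log2((p + .EPS_LOG) / (1 / 3))
  ratios <- matrix(NA_real_, nProbes, nArr)
  fraction <- rep(.FRACTIONS, each = config@nReplicates)
  replicate <- rep(seq_len(config@nReplicates), times = 3L)
  for (j in seq_len(nArr)) {
    f <- match(fraction[j], .FRACTIONS)
    noise <- if (config@noiseSd > 0) rnorm(nProbes, 0, config@noiseSd) else 0
    ratios[, j] <- base[, f] + noise
  }
  colnames(ratios) <- paste(fraction, replicate, sep = "_")

  gr <- GRanges("chrS", IRanges(start = s0 + 1, end = s0 + config@probeLength))
  mcols(gr)$probe_id <- sprintf("p%05d", seq_len(nProbes))
  mcols(gr)$gc <- gc
  rs <- RepliSet(gr, ratios, fraction, replicate)

  boundaries <- .trueBoundaries(pos, firing, config@forkSpeed, L)
  ## an origin is active if it claims at least one grid point at its own site
  grid <- seq(0, L, by = 100)
  claim <- .repTime(grid, pos, firing, config@forkSpeed)$claim
  active <- seq_along(pos) %in% unique(claim)

  truth <- new("GroundTruth",
               origins = data.frame(position = pos, family = family,
                                    meanFiringTime = firing, active = active),
               boundaries = boundaries,
               trueProbeClass = .classFromProb(p),
               trueRepTime = pmin(pmax(mu, 0), 1),
               labelingProb = p,
               chromLength = L)
  list(repliSet = rs, truth = truth)
}
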