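## Per-fraction enriched-segment calling and cross-fraction reconciliation
## into the eight replication-timing classes.

#' Call enriched segments from a smoothed fraction profile
#'
#' Maximal runs of consecutive probes with smoothed log2 ratio > 0 become
#' segments spanning from the first probe's start to the last probe's end;
#' positive runs whose genomic span is shorter than `minLen` are discarded
#' (treated as not enriched).  Sub-threshold negative gaps are never
#' bridged.
#'
#' @param x a [RepliProfiles-class] (with `fraction` naming the profile) or
#'   a probe GRanges (with `values` supplied).
#' @param fraction which fraction profile to segment (`"early"`, `"mid"`,
#'   `"late"`).
#' @param minLen minimum genomic span in bp (default 10000).
#' @param values numeric per-probe smoothed values when `x` is a GRanges.
#' @return GRanges of enriched segments with metadata column `n_probes`.
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("c", IRanges::IRanges(0:19 * 1000 + 1, width = 1000))
#' v <- c(rep(-1, 3), rep(1, 12), rep(-1, 5))
#' callSegments(gr, values = v)
callSegments <- function(x, fraction = NULL, minLen = 10000, values = NULL) {
  if (is(x, "RepliProfiles")) {
    stopifnot(!is.null(fraction))
    values <- smoothedValues(x, fraction)
    x <- probes(x)
  }
  stopifnot(is(x, "GRanges"), length(values) == length(x))
  if (is.unsorted(start(x))) stop("probes must be sorted")
  r <- rle(as.vector(values > 0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0)
    return(GRanges(seqnames = character(0), ranges = IRanges(),
                   n_probes = integer(0)))
  segStart <- start(x)[starts[keep]]
  segEnd <- end(x)[ends[keep]]
  span <- segEnd - segStart + 1
  ok <- span >= minLen
  gr <- GRanges(rep(as.character(seqnames(x))[1], sum(ok)),
                IRanges(segStart[ok], segEnd[ok]))
  mcols(gr)$n_probes <- (ends[keep] - starts[keep] + 1L)[ok]
  gr
}

#' Per-probe timing class from three per-fraction segmentations
#'
#' Each probe receives a 3-bit membership vector (overlaps an early
#' segment?, a mid segment?, a late segment?) mapped to a class:
#' `100 -> E, 110 -> EM, 010 -> M, 011 -> ML, 001 -> L, 101 -> EL,
#' 111 -> EML, 000 -> I`.
#'
#' @param probes probe GRanges.
#' @param earlySegs,midSegs,lateSegs GRanges from [callSegments()].
#' @return Factor of classes (levels [timingClasses()]) aligned to probes.
#' @export
probeTimingClass <- function(probes, earlySegs, midSegs, lateSegs) {
  bits <- cbind(overlapsAny(probes, earlySegs),
                overlapsAny(probes, midSegs),
                overlapsAny(probes, lateSegs))
  key <- paste0(bits[, 1] + 0L, bits[, 2] + 0L, bits[, 3] + 0L)
  factor(unname(.BITS_TO_CLASS[key]), levels = .CLASS_LEVELS)
}

#' Reconcile per-fraction segmentations into timing-class segments
#'
#' Maximal runs of probes with equal class (from [probeTimingClass()])
#' become segments with no minimum-length filter; the result tiles the
#' probe-covered extent.
#'
#' @param earlySegs,midSegs,lateSegs per-fraction GRanges from
#'   [callSegments()] on a shared probe grid.
#' @param probes the shared probe GRanges.
#' @return GRanges of timing segments with metadata columns `cls` (factor)
#'   and `n_probes`, sorted and non-overlapping.
#' @export
reconcileSegments <- function(earlySegs, midSegs, lateSegs, probes) {
  ext <- range(probes)
  for (segs in list(earlySegs, midSegs, lateSegs)) {
    if (length(segs) && (min(start(segs)) < start(ext) ||
                         max(end(segs)) > end(ext)))
      stop("fraction segment outside the probe extent")
  }
  cls <- probeTimingClass(probes, earlySegs, midSegs, lateSegs)
  r <- rle(as.character(cls))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gr <- GRanges(as.character(seqnames(probes))[1],
                IRanges(start(probes)[starts], end(probes)[ends]))
  mcols(gr)$cls <- factor(r$values, levels = .CLASS_LEVELS)
  mcols(gr)$n_probes <- r$lengths
  gr
}

#' Length-weighted timing-class composition of named regions
#'
#' For each region, the fraction of probe-covered bases assigned to each
#' timing class; rows sum to 1 for regions with any covered base.
#'
#' @param segments reconciled timing segments from [reconcileSegments()].
#' @param regions GRanges of disjoint regions (e.g. chromosome arms), with
#'   an optional `name` metadata column used for row names.
#' @return Matrix (regions x 8 classes) of base fractions.
#' @export
classComposition <- function(segments, regions) {
  if (length(regions) > 1) {
    ov <- findOverlaps(regions, drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov)) stop("regions must not overlap")
  }
  out <- matrix(0, length(regions), length(.CLASS_LEVELS),
                dimnames = list(mcols(regions)$name, .CLASS_LEVELS))
  hits <- findOverlaps(regions, segments)
  if (length(hits)) {
    inter <- pintersect(regions[queryHits(hits)], segments[subjectHits(hits)])
    w <- width(inter)
    cls <- as.character(mcols(segments)$cls[subjectHits(hits)])
    for (h in seq_along(hits))
      out[queryHits(hits)[h], cls[h]] <- out[queryHits(hits)[h], cls[h]] + w[h]
    tot <- rowSums(out)
    out[tot > 0, ] <- out[tot > 0, , drop = FALSE] / tot[tot > 0]
  }
  out
}
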