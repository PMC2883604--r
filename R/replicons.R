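## Profile extrema, initiation/termination zones, precedence-based replicon
## boundary selection, replicon assembly and replication-domain clustering.

## plurality vote over per-class weights with the fixed tie-break order
## (earliest class in .CLASS_LEVELS wins ties)
.pluralityClass <- function(weights) {
  w <- setNames(numeric(length(.CLASS_LEVELS)), .CLASS_LEVELS)
  w[names(weights)] <- weights
  .CLASS_LEVELS[which.max(w)]   # which.max takes the first maximum
}

#' Find local extrema of a smoothed profile
#'
#' Probe index `i` is a maximum iff its value exceeds the value of the
#' nearest differing neighbour on each side; plateaus of equal values
#' collapse to their midpoint index (left of center for even-length
#' plateaus).  Minima are symmetric.  Extrema in the first or last run of
#' the profile (chromosome ends) are excluded.
#'
#' @param values numeric profile values at sorted probes.
#' @return List with integer vectors `maxima` and `minima` (probe indices).
#' @export
#' @examples
#' findExtrema(c(0, 1, 2, 1, 0, 1, 1, 0))
findExtrema <- function(values) {
  n <- length(values)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  r <- rle(as.vector(values))
  K <- length(r$values)
  if (K < 3) return(list(maxima = integer(0), minima = integer(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- as.integer(floor((starts + ends) / 2))
  k <- 2:(K - 1)
  isMax <- r$values[k] > r$values[k - 1] & r$values[k] > r$values[k + 1]
  isMin <- r$values[k] < r$values[k - 1] & r$values[k] < r$values[k + 1]
  list(maxima = mids[k][isMax], minima = mids[k][isMin])
}

#' Build initiation/termination zones from profile extrema
#'
#' In the early and mid S-phase profiles, local maxima mark initiation
#' zones and local minima mark termination zones; in the late profile the
#' roles flip (maxima are termination zones, minima initiation zones).
#' Each extremum becomes a `width`-bp interval centered on the probe,
#' clipped at the chromosome ends; overlapping zones of the same kind are
#' merged to their union.
#'
#' @param profiles a [RepliProfiles-class].
#' @param fraction `"early"`, `"mid"` or `"late"`.
#' @param width zone width in bp (default 10000).
#' @param chromLength chromosome length used for clipping (default: end of
#'   the last probe).
#' @return GRanges of zones with metadata columns `kind`
#'   (`"initiation"`/`"termination"`), `fraction` and `anchor` (center bp).
#' @export
makeZones <- function(profiles, fraction, width = 10000, chromLength = NULL) {
  stopifnot(is(profiles, "RepliProfiles"))
  fraction <- match.arg(fraction, .FRACTIONS)
  pr <- probes(profiles)
  if (is.null(chromLength)) chromLength <- max(end(pr))
  ex <- findExtrema(smoothedValues(profiles, fraction))
  if (fraction == "late") {
    initIdx <- ex$minima; termIdx <- ex$maxima
  } else {
    initIdx <- ex$maxima; termIdx <- ex$minima
  }
  centers <- probeCenters(pr)
  chrom <- as.character(seqnames(pr))[1]
  mkKind <- function(idx, kind) {
    if (length(idx) == 0)
      return(GRanges(character(0), IRanges(), kind = character(0),
                     fraction = character(0), anchor = numeric(0)))
    s <- pmax(0, centers[idx] - width / 2)
    e <- pmin(chromLength, centers[idx] + width / 2)
    gr <- reduce(GRanges(chrom, IRanges(floor(s) + 1, ceiling(e))))
    mcols(gr)$kind <- kind
    mcols(gr)$fraction <- fraction
    mcols(gr)$anchor <- (start(gr) - 1 + end(gr)) / 2
    gr
  }
  z <- c(mkKind(initIdx, "initiation"), mkKind(termIdx, "termination"))
  sort(z)
}

#' Assign a timing class to zones from the reconciled segmentation
#'
#' Class of a zone = plurality of overlap length among the timing classes
#' of the segments it intersects, ties broken by the fixed class order
#' `E, EM, M, ML, L, EL, EML, I` (earliest wins).  Zones overlapping no
#' segment are classed `I` and flagged.
#'
#' @param zones GRanges of zones.
#' @param segments reconciled timing segments ([reconcileSegments()]).
#' @return `zones` with added metadata columns `cls` and `qc_no_probes`.
#' @export
assignZoneTiming <- function(zones, segments) {
  cls <- rep("I", length(zones))
  noProbes <- rep(TRUE, length(zones))
  hits <- findOverlaps(zones, segments)
  if (length(hits)) {
    w <- width(pintersect(zones[queryHits(hits)], segments[subjectHits(hits)]))
    segCls <- as.character(mcols(segments)$cls)[subjectHits(hits)]
    for (q in unique(queryHits(hits))) {
      sel <- queryHits(hits) == q
      ws <- tapply(w[sel], segCls[sel], sum)
      cls[q] <- .pluralityClass(ws)
      noProbes[q] <- FALSE
    }
  }
  mcols(zones)$cls <- factor(cls, levels = .CLASS_LEVELS)
  mcols(zones)$qc_no_probes <- noProbes
  zones
}

#' Greedily match two same-kind zone lists by center proximity
#'
#' Pairs are formed greedily by increasing center distance, each zone used
#' at most once, only pairs within `tol` allowed.  The matched fraction of
#' `zonesA` is the headline reproducibility statistic (e.g. the share of
#' early-fraction initiation zones within 20 kb of a mid-fraction one).
#'
#' @param zonesA,zonesB GRanges of zones (with `anchor` metadata, else
#'   centers are computed).
#' @param tol maximum center distance in bp (default 20000).
#' @return List with `pairs` (data.frame `a`, `b`, `distance`) and
#'   `matchedFraction` (share of `zonesA` matched).
#' @export
matchZones <- function(zonesA, zonesB, tol = 20000) {
  ca <- .zoneCenters(zonesA); cb <- .zoneCenters(zonesB)
  if (length(ca) == 0 || length(cb) == 0)
    return(list(pairs = data.frame(a = integer(0), b = integer(0),
                                   distance = numeric(0)),
                matchedFraction = if (length(ca)) 0 else NaN))
  d <- abs(outer(ca, cb, "-"))
  cand <- which(d <= tol, arr.ind = TRUE)
  ord <- order(d[cand])
  cand <- cand[ord, , drop = FALSE]
  usedA <- logical(length(ca)); usedB <- logical(length(cb))
  a <- integer(0); b <- integer(0); dd <- numeric(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <- TRUE; usedB[j] <- TRUE
      a <- c(a, i); b <- c(b, j); dd <- c(dd, d[i, j])
    }
  }
  list(pairs = data.frame(a = a, b = b, distance = dd),
       matchedFraction = length(a) / length(ca))
}

.zoneCenters <- function(z) {
  if (is(z, "GRanges")) {
    if (!is.null(mcols(z)$anchor)) mcols(z)$anchor
    else (start(z) - 1 + end(z)) / 2
  } else as.numeric(z)
}

#' Select replicon boundaries from termination zones by precedence
#'
#' Boundaries are chosen from the three per-fraction termination-zone sets
#' in three tiers:
#' \enumerate{
#'   \item late-fraction termination zones with a matching zone (centers
#'     within `tol`) in \emph{both} the early and mid lists; the boundary
#'     sits at the center of the merged union of the three zones;
#'   \item remaining late-fraction termination zones (optionally required
#'     to carry a timing class containing L);
#'   \item remaining early/mid termination zones that sit in territory
#'     enriched in early and/or mid S phase, i.e. whose timing class (from
#'     [assignZoneTiming()] against the reconciled segmentation) is one of
#'     `tier3Classes`.
#' }
#' Boundaries closer than `minSep` are merged to their midpoint (the
#' surviving tier is the best of the merged ones).
#'
#' @param termEarly,termMid,termLate per-fraction termination-zone GRanges,
#'   classed via [assignZoneTiming()].
#' @param segments reconciled timing segments; used to class Tier-3 zones
#'   when they carry no `cls` metadata.
#' @param tol matching tolerance in bp (default 20000).
#' @param minSep minimum boundary separation in bp (default 20000).
#' @param requireLClass if TRUE, Tier 2 additionally requires the zone's
#'   timing class to contain L (default FALSE: late-profile provenance
#'   suffices).
#' @param tier3Classes timing classes counting as "enriched in early and/or
#'   mid S phase" for Tier 3 (default: every class containing an E or M
#'   component).
#' @param initZones optional list with elements `early`, `mid`, `late` of
#'   initiation-zone GRanges.  When given, a termination-zone candidate is
#'   vetoed if \emph{both} other fractions identify an initiation zone
#'   overlapping its center: a location two profiles flag as an origin
#'   region is not accepted as a fork-convergence site on the word of the
#'   third.
#' @return data.frame with columns `position` (bp) and `tier` (1-3),
#'   sorted; zero rows (with a warning) if every tier is empty.
#' @export
selectBoundaries <- function(termEarly, termMid, termLate, segments,
                             tol = 20000, minSep = 20000,
                             requireLClass = FALSE,
                             tier3Classes = c("E", "EM", "M", "ML", "EL", "EML"),
                             initZones = NULL) {
  if (!is.null(initZones)) {
    veto <- function(z, own) {
      if (length(z) == 0) return(z)
      centers <- .zoneCenters(z)
      others <- setdiff(.FRACTIONS, own)
      inInit <- vapply(others, function(f) {
        iz <- initZones[[f]]
        if (is.null(iz) || length(iz) == 0) return(rep(FALSE, length(z)))
        pts <- GRanges(as.character(seqnames(z))[1],
                       IRanges(floor(centers) + 1, width = 1))
        overlapsAny(pts, iz)
      }, logical(length(z)))
      if (length(z) == 1) inInit <- matrix(inInit, nrow = 1)
      z[rowSums(inInit) < 2]
    }
    termEarly <- veto(termEarly, "early")
    termMid <- veto(termMid, "mid")
    termLate <- veto(termLate, "late")
  }
  cE <- .zoneCenters(termEarly); cM <- .zoneCenters(termMid)
  cL <- .zoneCenters(termLate)
  usedE <- logical(length(cE)); usedM <- logical(length(cM))
  pos <- numeric(0); tier <- integer(0)

  ## Tier 1: late zones corroborated in both early and mid
  tier2Pool <- logical(length(cL))
  for (i in seq_along(cL)) {
    dE <- if (length(cE)) abs(cE - cL[i]) else numeric(0)
    dM <- if (length(cM)) abs(cM - cL[i]) else numeric(0)
    okE <- which(!usedE & dE <= tol)
    okM <- which(!usedM & dM <= tol)
    if (length(okE) && length(okM)) {
      jE <- okE[which.min(dE[okE])]
      jM <- okM[which.min(dM[okM])]
      usedE[jE] <- TRUE; usedM[jM] <- TRUE
      lo <- min(start(termLate)[i] - 1, start(termEarly)[jE] - 1,
                start(termMid)[jM] - 1)
      hi <- max(end(termLate)[i], end(termEarly)[jE], end(termMid)[jM])
      pos <- c(pos, (lo + hi) / 2); tier <- c(tier, 1L)
    } else tier2Pool[i] <- TRUE
  }

  ## Tier 2: remaining late-fraction termination zones
  t2 <- which(tier2Pool)
  if (requireLClass && length(t2)) {
    zc <- as.character(mcols(termLate)$cls)
    if (is.null(zc)) stop("requireLClass needs zones classed via assignZoneTiming()")
    t2 <- t2[grepl("L", zc[t2])]
  }
  pos <- c(pos, cL[t2]); tier <- c(tier, rep(2L, length(t2)))

  ## Tier 3: remaining early/mid zones in early/mid-enriched territory
  zoneCls <- function(z) {
    cls <- mcols(z)$cls
    if (is.null(cls)) cls <- mcols(assignZoneTiming(z, segments))$cls
    as.character(cls)
  }
  remE <- which(!usedE); remM <- which(!usedM)
  t3 <- c(cE[remE][zoneCls(termEarly)[remE] %in% tier3Classes],
          cM[remM][zoneCls(termMid)[remM] %in% tier3Classes])
  pos <- c(pos, t3); tier <- c(tier, rep(3L, length(t3)))

  if (length(pos) == 0) {
    warning("no termination zones in any tier: single whole-chromosome replicon")
    return(data.frame(position = numeric(0), tier = integer(0)))
  }
  ord <- order(pos)
  pos <- pos[ord]; tier <- tier[ord]

  ## merge boundaries closer than minSep to their midpoint
  grp <- cumsum(c(1, diff(pos) >= minSep))
  mpos <- tapply(pos, grp, function(p) (min(p) + max(p)) / 2)
  mtier <- tapply(tier, grp, min)
  data.frame(position = as.numeric(mpos), tier = as.integer(mtier))
}

#' Assemble replicons between consecutive boundaries
#'
#' Replicons are the intervals between consecutive boundary positions; the
#' chromosome ends close the first and last replicon (`ends =
#' "chromosome"`, default) or replicons exist only between boundaries
#' (`ends = "boundary"`).  Each replicon gets a per-class composition
#' (probe-base length fractions), a dominant class (plurality, fixed
#' tie-break order), and its contained initiation zones (center
#' containment).
#'
#' @param boundaries numeric positions or the data.frame from
#'   [selectBoundaries()].
#' @param probes probe GRanges.
#' @param segments reconciled timing segments.
#' @param initZones optional merged initiation-zone GRanges.
#' @param chromLength chromosome length (default: end of last probe).
#' @param ends end convention, `"chromosome"` or `"boundary"`.
#' @return GRanges of replicons with metadata columns `replicon_id`, `cls`,
#'   `n_probes`, `composition` (matrix column, one column per class),
#'   `n_init_zones` and `qc_no_probes`.
#' @export
buildReplicons <- function(boundaries, probes, segments, initZones = NULL,
                           chromLength = NULL,
                           ends = c("chromosome", "boundary")) {
  ends <- match.arg(ends)
  if (is.data.frame(boundaries)) boundaries <- boundaries$position
  boundaries <- sort(as.numeric(boundaries))
  if (is.null(chromLength)) chromLength <- max(end(probes))
  brk <- if (ends == "chromosome") unique(c(0, boundaries, chromLength))
         else boundaries
  if (length(brk) < 2)
    stop("need at least two breakpoints to form a replicon")
  chrom <- as.character(seqnames(probes))[1]
  reps <- GRanges(chrom, IRanges(floor(head(brk, -1)) + 1,
                                 floor(tail(brk, -1))))
  mcols(reps)$replicon_id <- sprintf("rep%03d", seq_along(reps))

  comp <- matrix(0, length(reps), length(.CLASS_LEVELS),
                 dimnames = list(NULL, .CLASS_LEVELS))
  nProbes <- integer(length(reps))
  probeCls <- .probeClassFromSegments(probes, segments)
  hits <- findOverlaps(reps, probes)
  if (length(hits)) {
    w <- width(pintersect(reps[queryHits(hits)], probes[subjectHits(hits)]))
    cls <- as.character(probeCls)[subjectHits(hits)]
    for (h in seq_along(hits))
      comp[queryHits(hits)[h], cls[h]] <- comp[queryHits(hits)[h], cls[h]] + w[h]
    nProbes <- tabulate(queryHits(hits), length(reps))
  }
  tot <- rowSums(comp)
  dominant <- rep(NA_character_, length(reps))
  for (i in seq_along(reps)) {
    if (tot[i] > 0) {
      comp[i, ] <- comp[i, ] / tot[i]
      dominant[i] <- .pluralityClass(comp[i, comp[i, ] > 0])
    }
  }
  mcols(reps)$cls <- factor(dominant, levels = .CLASS_LEVELS)
  mcols(reps)$n_probes <- nProbes
  mcols(reps)$composition <- comp
  mcols(reps)$qc_no_probes <- nProbes == 0
  nInit <- integer(length(reps))
  if (!is.null(initZones) && length(initZones)) {
    zc <- .zoneCenters(initZones)
    zidx <- findInterval(zc, c(start(reps) - 1, chromLength))
    zidx <- zidx[zidx >= 1 & zidx <= length(reps)]
    nInit <- tabulate(zidx, length(reps))
  }
  mcols(reps)$n_init_zones <- nInit
  reps
}

## per-probe class via the reconciled segmentation (largest-overlap segment)
.probeClassFromSegments <- function(probes, segments) {
  cls <- rep("I", length(probes))
  hits <- findOverlaps(probes, segments)
  if (length(hits)) {
    w <- width(pintersect(probes[queryHits(hits)], segments[subjectHits(hits)]))
    ord <- order(queryHits(hits), -w)
    first <- !duplicated(queryHits(hits)[ord])
    cls[queryHits(hits)[ord][first]] <-
      as.character(mcols(segments)$cls)[subjectHits(hits)[ord][first]]
  }
  factor(cls, levels = .CLASS_LEVELS)
}

#' Cluster adjacent like-classed replicons into replication domains
#'
#' Maximal runs of adjacent replicons sharing a dominant timing class are
#' merged into domains.
#'
#' @param replicons GRanges from [buildReplicons()].
#' @return GRanges of domains with `cls`, `n_replicons` and `member_ids`;
#'   `metadata`-free summary `meanLength` is attached as an attribute.
#' @export
clusterDomains <- function(replicons) {
  if (length(replicons) == 0) return(replicons)
  cls <- as.character(mcols(replicons)$cls)
  cls[is.na(cls)] <- "I"
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dom <- GRanges(as.character(seqnames(replicons))[1],
                 IRanges(start(replicons)[starts], end(replicons)[ends]))
  mcols(dom)$cls <- factor(r$values, levels = .CLASS_LEVELS)
  mcols(dom)$n_replicons <- r$lengths
  mcols(dom)$member_ids <- vapply(seq_along(starts), function(i)
    paste(mcols(replicons)$replicon_id[starts[i]:ends[i]], collapse = ","),
    character(1))
  attr(dom, "meanLength") <- mean(width(dom))
  dom
}

#' Timing classes consistent with an origin-firing family
#'
#' A replicon descended from an early-family origin replicates in the first
#' half of S phase, so its dominant class should carry only early/mid
#' enrichment (`E`, `EM` or `M`); a late-family replicon should carry late
#' enrichment (`L` or `ML`).  Used by the parameter-recovery tests to score
#' whether a called replicon class is consistent with the simulated family.
#'
#' @param family `"early"` or `"late"` (vectorised).
#' @return A list of allowed class sets (or a single set for scalar input).
#' @export
#' @examples
#' familyConsistentClasses("early")
familyConsistentClasses <- function(family) {
  map <- list(early = c("E", "EM", "M"), late = c("L", "ML"))
  if (length(family) == 1) map[[match.arg(family, names(map))]]
  else map[family]
}
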