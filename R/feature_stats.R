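## Coverage/GC features and the probe-level, replicon-level and
## within-replicon statistical analyses.

#' Percent coverage of intervals by a feature set
#'
#' Percentage of bases of each interval overlapped by the union of the
#' features (overlapping features are merged first, so coverage never
#' exceeds 100).
#'
#' @param intervals GRanges of query intervals (probes, replicons, ...).
#' @param features GRanges of features of one kind (genes or TEs); if a
#'   `kind` metadata column is present, `kind` selects the subset.
#' @param kind optional feature kind to filter on (`"gene"` or `"TE"`).
#' @return Numeric vector of percentages in \[0,100\] aligned to
#'   `intervals`.
#' @export
computeCoverage <- function(intervals, features, kind = NULL) {
  if (any(width(intervals) <= 0)) stop("zero-length interval")
  if (!is.null(kind) && !is.null(mcols(features)$kind))
    features <- features[mcols(features)$kind == kind]
  red <- reduce(features)
  covered <- numeric(length(intervals))
  hits <- findOverlaps(intervals, red)
  if (length(hits)) {
    w <- width(pintersect(intervals[queryHits(hits)], red[subjectHits(hits)]))
    agg <- rowsum(w, queryHits(hits))
    covered[as.integer(rownames(agg))] <- agg[, 1]
  }
  100 * covered / width(intervals)
}

#' Flag the top quartile of a per-probe value
#'
#' TRUE where the value is at or above the array-wide 75th percentile
#' (linear-interpolation quantile).  AT-rich probes are the top quartile of
#' `1 - gc`; gene-rich probes the top quartile of gene coverage.
#'
#' @param values numeric per-probe values over the whole array.
#' @param quartile quantile threshold (default 0.75).
#' @return Logical vector aligned to `values`.
#' @export
topQuartileFlags <- function(values, quartile = 0.75) {
  values >= quantile(values, quartile, type = 7, names = FALSE)
}

#' Probe-level enrichment tests per timing class within a region
#'
#' For each timing class with at least `nMin` probes in the region:
#' continuous features (GC%, gene coverage %, TE coverage %) are compared
#' to the region-wide mean by a two-sided one-sample t-test; binary
#' features (mark calls, AT-rich/gene-rich flags) by an exact two-sided
#' binomial test ([binomTestTwoSided()]) against the region-wide positive
#' fraction.
#'
#' @param probeData data.frame with one row per probe in the region: a
#'   `cls` column (timing class) plus feature columns.
#' @param continuous character vector naming continuous feature columns.
#' @param binary character vector naming logical feature columns.
#' @param region label copied to the output (default `""`).
#' @param nMin minimum class size (default 20); smaller classes omitted.
#' @return data.frame with one row per (class x feature): `region`, `cls`,
#'   `feature`, `type`, `n`, `estimate` (class mean or positive %),
#'   `reference` (region mean / %), `statistic`, `df`, `p_value`, `code`,
#'   plus an `all` row per feature, and a Benjamini-Hochberg `p_adj`
#'   column (informational; codes use raw p).
#' @export
probeClassTests <- function(probeData, continuous = character(0),
                            binary = character(0), region = "", nMin = 20) {
  stopifnot("cls" %in% names(probeData))
  cls <- as.character(probeData$cls)
  keep <- names(which(table(cls) >= nMin))
  keep <- .CLASS_LEVELS[.CLASS_LEVELS %in% keep]
  rows <- list()
  addRow <- function(...) rows[[length(rows) + 1]] <<- data.frame(...)
  for (feat in continuous) {
    v <- probeData[[feat]]
    mu0 <- mean(v)
    addRow(region = region, cls = "All", feature = feat, type = "continuous",
           n = length(v), estimate = mu0, reference = mu0,
           statistic = NA_real_, df = NA_real_, p_value = NA_real_)
    for (cl in keep) {
      x <- v[cls == cl]
      if (sd(x) == 0) {
        addRow(region = region, cls = cl, feature = feat,
               type = "continuous", n = length(x), estimate = mean(x),
               reference = mu0, statistic = NA_real_, df = NA_real_,
               p_value = NA_real_)
      } else {
        tt <- t.test(x, mu = mu0)
        addRow(region = region, cls = cl, feature = feat,
               type = "continuous", n = length(x), estimate = mean(x),
               reference = mu0, statistic = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value)
      }
    }
  }
  for (feat in binary) {
    v <- as.logical(probeData[[feat]])
    p0 <- mean(v)
    addRow(region = region, cls = "All", feature = feat, type = "binary",
           n = length(v), estimate = 100 * p0, reference = 100 * p0,
           statistic = NA_real_, df = NA_real_, p_value = NA_real_)
    for (cl in keep) {
      x <- v[cls == cl]
      addRow(region = region, cls = cl, feature = feat, type = "binary",
             n = length(x), estimate = 100 * mean(x), reference = 100 * p0,
             statistic = sum(x), df = NA_real_,
             p_value = binomTestTwoSided(sum(x), length(x), p0))
    }
  }
  out <- do.call(rbind, rows)
  out$code <- signifCode(out$p_value)
  out$p_adj <- NA_real_
  tested <- !is.na(out$p_value)
  out$p_adj[tested] <- p.adjust(out$p_value[tested], method = "BH")
  out
}

#' Per-replicon feature table
#'
#' Computes, for each replicon: GC% (probe-length-weighted mean), gene and
#' TE coverage %, gene content (TSS per Mb, strand-aware: `+` genes anchor
#' at their start, `-` genes at their end), TE content (low coordinate per
#' Mb), and the positive-probe percentage of each mark.
#'
#' @param replicons GRanges from [buildReplicons()].
#' @param probes probe GRanges with `gc` metadata.
#' @param features GRanges with `kind` (`"gene"`/`"TE"`).
#' @param marks data.frame of per-probe mark calls (`probe_id`, `k4`,
#'   `k9`, `k56`, `mc`) aligned to `probes` by `probe_id`.
#' @return data.frame with one row per replicon.
#' @export
repliconFeatureTable <- function(replicons, probes, features, marks = NULL) {
  genes <- features[mcols(features)$kind == "gene"]
  tes <- features[mcols(features)$kind == "TE"]
  centers <- probeCenters(probes)
  ## anchor points: TSS for genes (strand-aware), low coordinate for TEs
  tss <- ifelse(as.character(strand(genes)) == "-",
                end(genes) - 1, start(genes) - 1)
  teLow <- start(tes) - 1
  brk <- c(start(replicons) - 1, max(end(replicons)))
  countAnchors <- function(a) {
    idx <- findInterval(a, brk)
    tabulate(idx[idx >= 1 & idx <= length(replicons)], length(replicons))
  }
  out <- data.frame(
    replicon_id = mcols(replicons)$replicon_id,
    cls = as.character(mcols(replicons)$cls),
    length = width(replicons),
    gc = NA_real_,
    gene_coverage = computeCoverage(replicons, genes),
    te_coverage = computeCoverage(replicons, tes),
    gene_content = countAnchors(tss) / width(replicons) * 1e6,
    te_content = countAnchors(teLow) / width(replicons) * 1e6
  )
  pidx <- findInterval(centers, brk)
  inRep <- pidx >= 1 & pidx <= length(replicons)
  gcSum <- rowsum(mcols(probes)$gc[inRep], pidx[inRep])
  nP <- tabulate(pidx[inRep], length(replicons))
  out$gc[as.integer(rownames(gcSum))] <- 100 * gcSum[, 1] /
    nP[as.integer(rownames(gcSum))]
  if (!is.null(marks)) {
    mm <- marks[match(mcols(probes)$probe_id, marks$probe_id), ]
    for (mk in c("k4", "k9", "k56", "mc")) {
      s <- rowsum(as.numeric(mm[[mk]][inRep]), pidx[inRep])
      v <- rep(NA_real_, length(replicons))
      v[as.integer(rownames(s))] <- 100 * s[, 1] /
        nP[as.integer(rownames(s))]
      out[[paste0(mk, "_pct")]] <- v
    }
  }
  out$n_probes <- nP
  out
}

#' Welch comparison of EM and L replicons
#'
#' Compares every feature column between EM- and L-classed replicons with
#' an unequal-variance (Welch) two-sample t-test, two-sided.
#'
#' @param repliconFeatures data.frame from [repliconFeatureTable()].
#' @param classes the two classes to compare (default `c("EM", "L")`).
#' @param features feature columns to test (default: all numeric columns
#'   except identifiers and probe counts).
#' @return data.frame with `feature`, group means, `t`, `df`, `p_value`,
#'   `code`.
#' @export
repliconCompare <- function(repliconFeatures, classes = c("EM", "L"),
                            features = NULL) {
  stopifnot(length(classes) == 2)
  a <- repliconFeatures[repliconFeatures$cls %in% classes[1], , drop = FALSE]
  b <- repliconFeatures[repliconFeatures$cls %in% classes[2], , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2)
    stop(sprintf("need >= 2 replicons per class (%s: %d, %s: %d)",
                 classes[1], nrow(a), classes[2], nrow(b)))
  if (is.null(features)) {
    features <- setdiff(names(repliconFeatures)[vapply(repliconFeatures,
                                                       is.numeric, TRUE)],
                        c("length", "n_probes"))
  }
  rows <- lapply(features, function(feat) {
    x <- a[[feat]]; y <- b[[feat]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    tt <- t.test(x, y, var.equal = FALSE)
    data.frame(feature = feat,
               mean_a = mean(x), mean_b = mean(y),
               n_a = length(x), n_b = length(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", classes[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", classes[2])
  out$code <- signifCode(out$p_value)
  out
}

## interval 1..10 by relative position, then the symmetric 5-bin fold:
## intervals {5,6} -> bin 1 (innermost, near initiation zones),
## {1,10} -> bin 5 (outermost, near termination zones)
.binOfRelPos <- function(rel) {
  interval <- pmin(10L, as.integer(floor(rel * 10)) + 1L)
  interval[interval < 1L] <- 1L
  bin <- 6L - pmin(interval, 11L - interval)
  list(interval = interval, bin = bin)
}

#' Within-replicon distribution of a binary probe feature
#'
#' Each replicon is divided into 10 equal intervals of its length; probes
#' are assigned by center position, and the 10 intervals are folded into 5
#' symmetric bins (the two innermost intervals are bin 1, nearest the
#' initiation zone; the two outermost are bin 5, nearest the termination
#' zones).  The per-bin proportion of feature-positive probes is reported
#' with an exact Clopper-Pearson 95% CI, alongside the class-wide mean
#' proportion.
#'
#' @param replicons GRanges from [buildReplicons()]; only replicons with at
#'   least `minProbes` probes are used.
#' @param probes probe GRanges.
#' @param flags logical per-probe feature vector aligned to `probes`.
#' @param cls restrict to replicons of this dominant class (default NULL:
#'   all).
#' @param minProbes minimum probes per replicon (default 10).
#' @param mode `"pooled"` (default) pools probes across replicons;
#'   `"perReplicon"` averages per-replicon proportions (CIs still from the
#'   pooled counts).
#' @return List with `bins` (data.frame `bin`, `n`, `positive`,
#'   `proportion`, `ci_lower`, `ci_upper`) and `overall` (class-wide mean
#'   proportion).
#' @export
binProfile <- function(replicons, probes, flags, cls = NULL, minProbes = 10,
                       mode = c("pooled", "perReplicon")) {
  mode <- match.arg(mode)
  stopifnot(length(flags) == length(probes))
  if (!is.null(cls))
    replicons <- replicons[as.character(mcols(replicons)$cls) %in% cls]
  replicons <- replicons[mcols(replicons)$n_probes >= minProbes]
  centers <- probeCenters(probes)
  brk <- c(start(replicons) - 1, max(end(replicons)))
  assign <- .assignProbesToReplicons(centers, replicons)
  ok <- !is.na(assign$repIdx)
  rel <- (centers[ok] - (start(replicons) - 1)[assign$repIdx[ok]]) /
    width(replicons)[assign$repIdx[ok]]
  bin <- .binOfRelPos(rel)$bin
  f <- as.logical(flags)[ok]
  bins <- data.frame(bin = 1:5, n = 0L, positive = 0L, proportion = NA_real_,
                     ci_lower = NA_real_, ci_upper = NA_real_)
  for (b in 1:5) {
    sel <- bin == b
    n <- sum(sel); x <- sum(f[sel])
    bins$n[b] <- n; bins$positive[b] <- x
    if (n > 0) {
      ci <- clopperPearsonCI(x, n)
      if (mode == "pooled") {
        bins$proportion[b] <- x / n
      } else {
        ri <- assign$repIdx[ok][sel]
        perRep <- tapply(f[sel], ri, mean)
        bins$proportion[b] <- mean(perRep)
      }
      bins$ci_lower[b] <- ci["lower"]; bins$ci_upper[b] <- ci["upper"]
    }
  }
  list(bins = bins, overall = mean(f))
}

## replicon index of each probe center (NA outside every replicon); the
## replicon set may be a filtered, non-tiling subset, so containment is
## tested per replicon rather than via breakpoints
.assignProbesToReplicons <- function(centers, replicons) {
  repIdx <- rep(NA_integer_, length(centers))
  if (length(replicons)) {
    s <- start(replicons) - 1; e <- end(replicons)
    idx <- findInterval(centers, sort(s))
    ## replicons are sorted and disjoint, so interval test per candidate
    ord <- order(s)
    cand <- ord[pmax(idx, 1)]
    inside <- idx >= 1 & centers >= s[cand] & centers < e[cand]
    repIdx[inside] <- cand[inside]
  }
  list(repIdx = repIdx)
}
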