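## Replicate averaging, quantile normalization, fixed-genomic-window loess
## smoothing, profile correlations and decile ranking.

#' Average replicate arrays within each S-phase fraction
#'
#' Per-probe mean of the replicate log2 ratios of each fraction, ignoring
#' missing replicate values.  A probe with no value at all in a fraction is
#' flagged missing and filled by linear interpolation in genomic coordinate
#' from the flanking probes (constant extrapolation at chromosome ends) so
#' that downstream smoothing sees a complete profile.
#'
#' @param rs a [RepliSet-class].  Dye-swap arrays are assumed already
#'   sign-oriented (the probe-table reader flips `_swap` columns).
#' @param maxMissing abort if more than this proportion of probes in any
#'   fraction has no replicate value at all (default 0.05).
#' @return List with `values` (probes x 3 matrix, columns early/mid/late)
#'   and `missing` (logical matrix flagging interpolated entries).
#' @export
averageReplicates <- function(rs, maxMissing = 0.05) {
  stopifnot(is(rs, "RepliSet"))
  m <- ratioMatrix(rs)
  frac <- arrayFractions(rs)
  centers <- probeCenters(rs)
  values <- matrix(NA_real_, nrow(m), 3, dimnames = list(NULL, .FRACTIONS))
  missing <- matrix(FALSE, nrow(m), 3, dimnames = list(NULL, .FRACTIONS))
  for (f in .FRACTIONS) {
    cols <- which(frac == f)
    if (length(cols) == 0)
      stop(sprintf("no replicate arrays for fraction '%s'", f))
    sub <- m[, cols, drop = FALSE]
    v <- rowMeans(sub, na.rm = TRUE)
    miss <- !is.finite(v)            # all replicates missing
    if (mean(miss) > maxMissing)
      stop(sprintf(
        "fraction '%s': %.1f%% of probes have no replicate value (limit %.1f%%)",
        f, 100 * mean(miss), 100 * maxMissing))
    if (any(miss)) {
      v[miss] <- approx(centers[!miss], v[!miss], xout = centers[miss],
                        rule = 2)$y
    }
    values[, f] <- v
    missing[, f] <- miss
  }
  list(values = values, missing = missing)
}

#' Quantile-normalize arrays to a common distribution
#'
#' Forces every column of a probes x arrays matrix onto the reference
#' distribution formed by the row-wise mean of the sorted columns; ties
#' within a column receive the mean of the reference values they span.
#' Delegates to [limma::normalizeQuantiles()] (ties averaged), the
#' implementation classically used for two-colour enrichment arrays.
#'
#' @param mat numeric matrix with at least two columns; all values finite.
#' @return Matrix of the same dimensions with identical sorted columns.
#' @export
quantileNormalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("quantile normalization needs at least 2 columns")
  if (any(!is.finite(mat))) stop("non-finite values in input matrix")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

## Core smoother: locally weighted quadratic fit in a fixed genomic window
## (tricube weights on |x - x0| / (window/2)), evaluated at each probe
## center.  Windows with fewer than minProbes positively weighted probes
## fall back to the tricube-weighted mean.
.loessSmoothVector <- function(pos, y, window, minProbes = 8L, degree = 2L) {
  n <- length(pos)
  stopifnot(length(y) == n)
  if (is.unsorted(pos)) stop("probe positions must be sorted")
  half <- window / 2
  lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
  hi <- findInterval(pos + half, pos)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- lo[i]:hi[i]
    dx <- pos[idx] - pos[i]
    u <- abs(dx) / half
    w <- (1 - pmin(u, 1)^3)^3
    pw <- w > 0
    if (sum(pw) < minProbes || degree == 0L) {
      out[i] <- if (any(pw)) sum(w * y[idx]) / sum(w) else y[i]
      next
    }
    xs <- dx / half             # scale to [-1,1] to keep X'WX well-conditioned
    X <- cbind(1, xs, if (degree >= 2L) xs^2)
    XtW <- t(X * w)
    beta <- tryCatch(solve(XtW %*% X, XtW %*% y[idx]),
                     error = function(e) NULL)
    out[i] <- if (is.null(beta)) sum(w * y[idx]) / sum(w) else beta[1]
  }
  out
}

#' Loess-smooth a genomic profile in a fixed genomic window
#'
#' At each probe center `x0`, fits a locally weighted quadratic to the
#' probes whose centers fall in `[x0 - window/2, x0 + window/2]`, with
#' tricube weights on `|x - x0| / (window/2)`, and returns the fitted value
#' at `x0`.  Windows holding fewer than `minProbes` probes fall back to the
#' tricube-weighted mean.  The window is a genomic span, not a probe count,
#' so the smoother is robust to gaps in the tiling grid.
#'
#' @param pos sorted numeric positions (probe centers, bp).
#' @param values numeric profile values aligned to `pos`.
#' @param window genomic window in bp; must be at least 10x the median
#'   probe spacing implied by `pos` when `checkWindow` is TRUE.
#' @param minProbes minimum probes for a quadratic fit (default 8).
#' @param degree local polynomial degree, 0, 1 or 2 (default 2).
#' @param checkWindow verify the window/probe-length precondition.
#' @return Numeric vector of smoothed values aligned to `pos`.
#' @export
loessSmooth <- function(pos, values, window, minProbes = 8L, degree = 2L,
                        checkWindow = TRUE) {
  if (checkWindow && length(pos) > 1) {
    medLen <- median(diff(pos))
    if (window < 10 * medLen)
      stop("window must be at least 10 x the median probe spacing")
  }
  .loessSmoothVector(pos, values, window, minProbes, degree)
}

#' Smooth all three fraction profiles of a RepliSet
#'
#' Runs [averageReplicates()] (optionally after [quantileNormalize()] within
#' each fraction) and loess-smooths each fraction profile in a fixed
#' genomic window.
#'
#' @param rs a [RepliSet-class].
#' @param window smoothing window in bp (default 150000).
#' @param normalize `"quantile"` (within-fraction quantile normalization of
#'   the replicate arrays, the default) or `"none"`.
#' @param minProbes,degree passed to [loessSmooth()].
#' @return A [RepliProfiles-class].
#' @export
#' @examples
#' sim <- simulateChromosome(simConfig(chromLength = 1e6, seed = 1))
#' prof <- smoothProfiles(sim$repliSet)
#' head(smoothedValues(prof))
smoothProfiles <- function(rs, window = 150000,
                           normalize = c("quantile", "none"),
                           minProbes = 8L, degree = 2L) {
  stopifnot(is(rs, "RepliSet"))
  normalize <- match.arg(normalize)
  if (normalize == "quantile") {
    m <- ratioMatrix(rs)
    frac <- arrayFractions(rs)
    for (f in .FRACTIONS) {
      cols <- which(frac == f)
      if (length(cols) >= 2 && all(is.finite(m[, cols])))
        m[, cols] <- quantileNormalize(m[, cols])
    }
    rs <- RepliSet(probes(rs), m, frac, arrayReplicates(rs))
  }
  avg <- averageReplicates(rs)
  centers <- probeCenters(rs)
  sm <- vapply(.FRACTIONS, function(f)
    loessSmooth(centers, avg$values[, f], window, minProbes, degree),
    numeric(length(centers)))
  colnames(sm) <- .FRACTIONS
  new("RepliProfiles", probes = probes(rs), smoothed = sm, window = window)
}

#' Pearson correlation between two aligned profiles
#'
#' @param a,b equal-length numeric vectors, or a [RepliProfiles-class] as
#'   `a` with two fraction names in `b` (e.g. `c("early", "late")`).
#' @return Pearson r, or `NA` (with a warning) if either profile has zero
#'   variance.
#' @export
profileCorrelation <- function(a, b) {
  if (is(a, "RepliProfiles")) {
    stopifnot(length(b) == 2)
    sm <- smoothedValues(a)
    b2 <- sm[, match.arg(b[2], .FRACTIONS)]
    a <- sm[, match.arg(b[1], .FRACTIONS)]
    b <- b2
  }
  stopifnot(length(a) == length(b))
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Decile ranks of a profile
#'
#' Partitions probes into 10 equal-count groups by value (group 1 lowest);
#' ties are broken by genomic position, leftmost first.  This is the
#' tabular representation behind decile heat maps.
#'
#' @param values numeric per-probe values (smoothed ratios, expression, ...).
#' @param pos genomic positions used for deterministic tie-breaking.
#' @return Integer vector of decile ranks 1-10 aligned to the input.
#' @export
decileRank <- function(values, pos = seq_along(values)) {
  n <- length(values)
  if (n < 10) stop("decile ranking needs at least 10 probes")
  stopifnot(length(pos) == n)
  ord <- order(values, pos)
  dec <- integer(n)
  dec[ord] <- as.integer(ceiling(seq_len(n) * 10 / n))
  dec
}
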