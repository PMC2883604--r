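## Gene-level analysis: epigenetic patterns, timing classes, and the
## expression/timing association tables.

## The fixed 16-pattern map: 4-bit mark vector (K4, K9, K56, 5mC) -> pattern
## number ranked by gene activity (pattern 1 most likely expressed).
.PATTERN_TABLE <- data.frame(
  k4  = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
          TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
  k9  = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
          TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
  k56 = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
          FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
  mc  = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
          FALSE, TRUE, FALSE, TRUE, TRUE, FALSE),
  pattern = 1:16
)

#' Epigenetic pattern number of a 4-bit mark vector
#'
#' Total bijective lookup from the (K4, K9, K56, 5mC) mark vector to the
#' fixed pattern number 1-16 ranked by gene activity: e.g.
#' `(+,-,+,+) -> 1`, `(-,-,-,-) -> 13`, `(-,+,-,-) -> 16`.
#'
#' @param k4,k9,k56,mc logical vectors (recycled to a common length).
#' @return Integer pattern numbers in 1-16.
#' @export
#' @examples
#' patternOf(TRUE, FALSE, TRUE, TRUE)   # 1
#' patternOf(FALSE, FALSE, FALSE, FALSE) # 13
patternOf <- function(k4, k9, k56, mc) {
  key <- paste(as.logical(k4), as.logical(k9), as.logical(k56),
               as.logical(mc))
  ref <- paste(.PATTERN_TABLE$k4, .PATTERN_TABLE$k9, .PATTERN_TABLE$k56,
               .PATTERN_TABLE$mc)
  .PATTERN_TABLE$pattern[match(key, ref)]
}

#' Assign mark calls to genes from overlapping probes
#'
#' A gene is positive for a mark iff at least one overlapping probe is
#' positive (`rule = "any"`, the default, matching the enrichment-call
#' semantics of the probe data) or iff more than half are
#' (`rule = "majority"`).  Genes overlapping no probe are excluded and
#' counted in the attached QC report.
#'
#' @param genes GRanges of genes (with `feature_id`).
#' @param probes probe GRanges.
#' @param marks data.frame of per-probe calls (`probe_id`, `k4`, `k9`,
#'   `k56`, `mc`).
#' @param rule `"any"` or `"majority"`.
#' @return data.frame `gene_id`, `k4`, `k9`, `k56`, `mc`, `pattern`, with
#'   attribute `n_excluded` (genes without probe overlap).
#' @export
assignGeneMarks <- function(genes, probes, marks, rule = c("any", "majority")) {
  rule <- match.arg(rule)
  mm <- marks[match(mcols(probes)$probe_id, marks$probe_id), ]
  hits <- findOverlaps(genes, probes)
  hasProbe <- seq_along(genes) %in% queryHits(hits)
  out <- data.frame(gene_id = mcols(genes)$feature_id[hasProbe])
  for (mk in c("k4", "k9", "k56", "mc")) {
    v <- as.numeric(mm[[mk]])[subjectHits(hits)]
    agg <- if (rule == "any") rowsum(v, queryHits(hits)) > 0
           else rowsum(v, queryHits(hits)) / rowsum(rep(1, length(v)),
                                                    queryHits(hits)) > 0.5
    flags <- setNames(as.logical(agg[, 1]), rownames(agg))
    out[[mk]] <- unname(flags[as.character(which(hasProbe))])
  }
  out$pattern <- patternOf(out$k4, out$k9, out$k56, out$mc)
  attr(out, "n_excluded") <- sum(!hasProbe)
  out
}

#' Assign timing classes to genes from the reconciled segmentation
#'
#' Class with the greatest total overlap length with the gene; ties broken
#' by the fixed class order.  Genes overlapping no segment are excluded.
#'
#' @param genes GRanges of genes (with `feature_id`).
#' @param segments reconciled timing segments.
#' @return data.frame `gene_id`, `cls`, with attribute `n_excluded`.
#' @export
assignGeneTiming <- function(genes, segments) {
  hits <- findOverlaps(genes, segments)
  ids <- mcols(genes)$feature_id
  cls <- rep(NA_character_, length(genes))
  if (length(hits)) {
    w <- width(pintersect(genes[queryHits(hits)], segments[subjectHits(hits)]))
    segCls <- as.character(mcols(segments)$cls)[subjectHits(hits)]
    for (q in unique(queryHits(hits))) {
      sel <- queryHits(hits) == q
      cls[q] <- .pluralityClass(tapply(w[sel], segCls[sel], sum))
    }
  }
  keep <- !is.na(cls)
  out <- data.frame(gene_id = ids[keep],
                    cls = factor(cls[keep], levels = .CLASS_LEVELS))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Combine marks, timing and expression into gene records
#'
#' Inner-joins the outputs of [assignGeneMarks()], [assignGeneTiming()] and
#' the expression table on `gene_id`; genes missing from any source are
#' dropped (incomplete data).
#'
#' @param geneMarks data.frame from [assignGeneMarks()].
#' @param geneTiming data.frame from [assignGeneTiming()].
#' @param expression data.frame `gene_id`, `present`, `level`.
#' @return data.frame of complete gene records.
#' @export
geneRecords <- function(geneMarks, geneTiming, expression) {
  out <- merge(geneMarks, geneTiming, by = "gene_id")
  out <- merge(out, expression, by = "gene_id")
  out[order(out$gene_id), , drop = FALSE]
}

#' Gene activity by epigenetic pattern
#'
#' Per pattern: gene count, mean expression level (over all genes in the
#' pattern), percent active (presence calls), and an exact two-sided
#' binomial test of the pattern's activity rate against the overall rate.
#' Rows are ordered by decreasing activity; patterns with no genes are
#' omitted.
#'
#' @param genes data.frame from [geneRecords()].
#' @return data.frame `pattern`, `n`, `mean_level`, `pct_active`,
#'   `p_value`, `code`, preceded by an `all` summary row.
#' @export
patternActivityTable <- function(genes) {
  p0 <- mean(genes$present)
  rows <- lapply(sort(unique(genes$pattern)), function(pt) {
    g <- genes[genes$pattern == pt, ]
    data.frame(pattern = pt, n = nrow(g), mean_level = mean(g$level),
               pct_active = 100 * mean(g$present),
               p_value = binomTestTwoSided(sum(g$present), nrow(g), p0))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$pct_active, out$pattern), ]
  out <- rbind(data.frame(pattern = NA_integer_, n = nrow(genes),
                          mean_level = mean(genes$level),
                          pct_active = 100 * p0, p_value = NA_real_),
               out)
  out$code <- signifCode(out$p_value)
  rownames(out) <- NULL
  out
}

#' Pattern x timing-class enrichment (hypergeometric)
#'
#' For every (pattern, class) cell: the overlap count is tested against a
#' hypergeometric null (sampling the pattern's genes from all genes);
#' one-sided over- and under-representation p-values are both reported,
#' the significance code uses the smaller with its direction.
#'
#' @param genes data.frame from [geneRecords()].
#' @return data.frame `pattern`, `cls`, `n_pattern`, `n_class`, `overlap`,
#'   `pct`, `p_over`, `p_under`, `direction`, `code`.
#' @export
timingEnrichmentTable <- function(genes) {
  N <- nrow(genes)
  rows <- list()
  for (pt in sort(unique(genes$pattern))) {
    g <- genes$pattern == pt
    for (cl in .CLASS_LEVELS) {
      c0 <- as.character(genes$cls) == cl
      K <- sum(c0)
      if (K == 0) next
      x <- sum(g & c0)
      ht <- hypergeomTests(x, K, sum(g), N)
      rows[[length(rows) + 1]] <- data.frame(
        pattern = pt, cls = cl, n_pattern = sum(g), n_class = K,
        overlap = x, pct = 100 * x / sum(g),
        p_over = ht["over"], p_under = ht["under"],
        direction = if (ht["over"] <= ht["under"]) "over" else "under")
    }
  }
  out <- do.call(rbind, rows)
  out$code <- signifCode(pmin(out$p_over, out$p_under))
  rownames(out) <- NULL
  out
}

#' Gene activity by timing class
#'
#' Per timing class: gene count, percent active, mean expression level, and
#' an exact two-sided binomial test against the overall activity rate.
#'
#' @param genes data.frame from [geneRecords()].
#' @return data.frame with an `All` row followed by one row per non-empty
#'   class.
#' @export
activityByTiming <- function(genes) {
  p0 <- mean(genes$present)
  rows <- list(data.frame(cls = "All", n = nrow(genes),
                          pct_active = 100 * p0,
                          mean_level = mean(genes$level),
                          p_value = NA_real_))
  for (cl in .CLASS_LEVELS) {
    g <- genes[as.character(genes$cls) == cl, ]
    if (nrow(g) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      cls = cl, n = nrow(g), pct_active = 100 * mean(g$present),
      mean_level = mean(g$level),
      p_value = binomTestTwoSided(sum(g$present), nrow(g), p0))
  }
  out <- do.call(rbind, rows)
  out$code <- signifCode(out$p_value)
  rownames(out) <- NULL
  out
}

#' Intergenic regions within an extent
#'
#' The complement of the gene union inside `extent` (regions overlapping no
#' annotated gene).
#'
#' @param genes GRanges of genes.
#' @param extent GRanges of the probed extent (single range).
#' @return GRanges of intergenic regions.
#' @export
intergenicRegions <- function(genes, extent) {
  GenomicRanges::setdiff(extent, reduce(genes, ignore.strand = TRUE),
                         ignore.strand = TRUE)
}

#' Within-replicon distribution of elements (genes or intergenic regions)
#'
#' Elements are assigned to replicons and 5-fold symmetric bins by their
#' midpoint ([binProfile()] geometry); the per-bin share of elements is
#' reported with exact binomial CIs.  Elements spanning a replicon boundary
#' are assigned by midpoint and flagged in the returned count.
#'
#' @param elements GRanges (e.g. genes with a given epigenetic pattern, or
#'   intergenic regions).
#' @param replicons GRanges from [buildReplicons()]; only replicons of
#'   class `cls` (when given) with at least `minProbes` probes are used.
#' @param cls optional dominant-class filter.
#' @param minProbes minimum probes per replicon (default 10).
#' @return List with `bins` (data.frame `bin`, `count`, `proportion`,
#'   `ci_lower`, `ci_upper`), `nAssigned` and `nSpanning` (midpoint-assigned
#'   boundary spanners).
#' @export
elementDistributionInReplicons <- function(elements, replicons, cls = NULL,
                                           minProbes = 10) {
  if (!is.null(cls))
    replicons <- replicons[as.character(mcols(replicons)$cls) %in% cls]
  replicons <- replicons[mcols(replicons)$n_probes >= minProbes]
  mid <- (start(elements) - 1 + end(elements)) / 2
  assign <- .assignProbesToReplicons(mid, replicons)
  ok <- !is.na(assign$repIdx)
  spanning <- sum(ok & !(start(elements) - 1 >=
                           (start(replicons) - 1)[pmax(assign$repIdx, 1)] &
                         end(elements) <=
                           end(replicons)[pmax(assign$repIdx, 1)]))
  rel <- (mid[ok] - (start(replicons) - 1)[assign$repIdx[ok]]) /
    width(replicons)[assign$repIdx[ok]]
  bin <- .binOfRelPos(rel)$bin
  total <- length(bin)
  bins <- data.frame(bin = 1:5, count = tabulate(bin, 5L))
  bins$proportion <- if (total > 0) bins$count / total else NA_real_
  ci <- t(vapply(bins$count, function(x)
    if (total > 0) clopperPearsonCI(x, total) else c(NA_real_, NA_real_),
    numeric(2)))
  bins$ci_lower <- ci[, 1]; bins$ci_upper <- ci[, 2]
  list(bins = bins, nAssigned = total, nSpanning = spanning)
}
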