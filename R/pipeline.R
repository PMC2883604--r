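## End-to-end pipeline driver and its configuration.

#' Pipeline configuration
#'
#' Collects input paths and every numeric knob of the pipeline; values
#' round-trip losslessly through YAML ([writePipelineConfig()] /
#' [readPipelineConfig()]).
#'
#' @param probesPath probe-table TSV (required by [runPipeline()]).
#' @param featuresPath optional gene/TE annotation (BED or GFF3).
#' @param marksPath optional per-probe mark-call TSV.
#' @param expressionPath optional per-gene expression TSV.
#' @param regions optional data.frame (`name`, `chrom`, `start`, `end`;
#'   0-based half-open) of named analysis regions; default: one region
#'   spanning the probed extent.
#' @param window loess window for replication profiles, bp (default
#'   150000).
#' @param zoneWindow loess window for extremum detection
#'   (zones/boundaries), bp (default 50000): fine enough to resolve
#'   extrema at the ~100-kb replicon scale.
#' @param minLen minimum enriched-segment span, bp (default 10000).
#' @param zoneWidth zone width, bp (default 10000).
#' @param tol zone matching tolerance, bp (default 20000).
#' @param minSep minimum boundary separation, bp (default 20000).
#' @param nMin minimum class size for probe-level tests (default 20).
#' @param quartile top-quartile threshold (default 0.75).
#' @param binMode `"pooled"` or `"perReplicon"` for [binProfile()].
#' @param endRule replicon end convention, `"chromosome"` or `"boundary"`.
#' @param geneMarkRule `"any"` or `"majority"` for [assignGeneMarks()].
#' @param normalize `"quantile"` or `"none"`.
#' @param requireLClass Tier-2 class requirement in [selectBoundaries()].
#' @param seed integer seed recorded in the manifest.
#' @return A validated list of class `replitime_config`.
#' @export
pipelineConfig <- function(probesPath = NULL, featuresPath = NULL,
                           marksPath = NULL, expressionPath = NULL,
                           regions = NULL,
                           window = 150000, zoneWindow = 50000,
                           minLen = 10000,
                           zoneWidth = 10000, tol = 20000, minSep = 20000,
                           nMin = 20, quartile = 0.75,
                           binMode = "pooled", endRule = "chromosome",
                           geneMarkRule = "any", normalize = "quantile",
                           requireLClass = FALSE, seed = 1L) {
  cfg <- list(probesPath = probesPath, featuresPath = featuresPath,
              marksPath = marksPath, expressionPath = expressionPath,
              regions = regions, window = window, zoneWindow = zoneWindow,
              minLen = minLen,
              zoneWidth = zoneWidth, tol = tol, minSep = minSep,
              nMin = nMin, quartile = quartile, binMode = binMode,
              endRule = endRule, geneMarkRule = geneMarkRule,
              normalize = normalize, requireLClass = requireLClass,
              seed = as.integer(seed))
  for (nm in c("window", "zoneWindow", "minLen", "zoneWidth", "tol", "minSep"))
    if (cfg[[nm]] <= 0) stop(nm, " must be positive")
  if (cfg$tol < cfg$zoneWidth / 2)
    stop("tol must be at least zoneWidth/2")
  stopifnot(binMode %in% c("pooled", "perReplicon"),
            endRule %in% c("chromosome", "boundary"),
            geneMarkRule %in% c("any", "majority"),
            normalize %in% c("quantile", "none"))
  class(cfg) <- "replitime_config"
  cfg
}

#' Read/write a pipeline configuration as YAML
#'
#' @param config a `replitime_config` from [pipelineConfig()].
#' @param path YAML file path.
#' @return The configuration (read) or `path` invisibly (write).
#' @export
writePipelineConfig <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$regions)) x$regions <- as.list(as.data.frame(x$regions))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$regions)) x$regions <- as.data.frame(x$regions)
  do.call(pipelineConfig, x)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full replication-timing pipeline
#'
#' Executes normalize -> smooth -> segment -> zones/boundaries ->
#' replicons/domains -> feature statistics -> gene analyses, writing every
#' result table plus a run manifest to `outdir`.  Stages whose inputs are
#' absent (no annotation, marks or expression) are skipped with a message;
#' the replicon map is always produced.  Output bytes are a deterministic
#' function of the inputs and configuration.
#'
#' @param config a `replitime_config` from [pipelineConfig()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results
#'   (`profiles`, `segments`, `zones`, `boundaries`, `replicons`,
#'   `domains`, and when computed `probeStats`, `repliconStats`, `bins`,
#'   `genes`, `manifest`).
#' @export
runPipeline <- function(config, outdir) {
  stopifnot(inherits(config, "replitime_config"))
  if (is.null(config$probesPath)) stop("config$probesPath is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  rs <- .stage("read_probes", readProbeTable(config$probesPath))
  counts$probes <- length(probes(rs))

  prof <- .stage("smooth", smoothProfiles(rs, window = config$window,
                                          normalize = config$normalize))
  smoothedDf <- data.frame(probe_id = mcols(probes(rs))$probe_id,
                           as.data.frame(smoothedValues(prof)))
  .writeTSV(smoothedDf, file.path(outdir, "smoothed.tsv"))
  counts$smoothed <- nrow(smoothedDf)

  segsByFrac <- .stage("segment", lapply(setNames(.FRACTIONS, .FRACTIONS),
    function(f) callSegments(prof, f, minLen = config$minLen)))
  segments <- .stage("reconcile",
    reconcileSegments(segsByFrac$early, segsByFrac$mid, segsByFrac$late,
                      probes(rs)))
  writeClassedBED(segments, file.path(outdir, "segments.bed"))
  counts$segments <- length(segments)

  zones <- .stage("zones", {
    profZone <- smoothProfiles(rs, window = config$zoneWindow,
                               normalize = config$normalize)
    zl <- lapply(setNames(.FRACTIONS, .FRACTIONS), function(f)
      assignZoneTiming(makeZones(profZone, f, width = config$zoneWidth),
                       segments))
    do.call(c, unname(zl))
  })
  writeClassedBED(zones, file.path(outdir, "zones.bed"))
  counts$zones <- length(zones)

  term <- lapply(setNames(.FRACTIONS, .FRACTIONS), function(f)
    zones[mcols(zones)$fraction == f & mcols(zones)$kind == "termination"])
  init <- lapply(setNames(.FRACTIONS, .FRACTIONS), function(f)
    zones[mcols(zones)$fraction == f & mcols(zones)$kind == "initiation"])
  initAll <- reduce(zones[mcols(zones)$kind == "initiation"])
  boundaries <- .stage("boundaries",
    selectBoundaries(term$early, term$mid, term$late, segments,
                     tol = config$tol, minSep = config$minSep,
                     requireLClass = config$requireLClass,
                     initZones = init))
  .writeTSV(boundaries, file.path(outdir, "boundaries.tsv"))

  replicons <- .stage("replicons",
    buildReplicons(boundaries, probes(rs), segments, initZones = initAll,
                   ends = config$endRule))
  writeClassedBED(replicons, file.path(outdir, "replicons.bed"))
  repDf <- data.frame(replicon_id = mcols(replicons)$replicon_id,
                      chrom = as.character(seqnames(replicons)),
                      start = start(replicons) - 1, end = end(replicons),
                      cls = as.character(mcols(replicons)$cls),
                      n_probes = mcols(replicons)$n_probes,
                      n_init_zones = mcols(replicons)$n_init_zones)
  .writeTSV(cbind(repDf, as.data.frame(mcols(replicons)$composition)),
            file.path(outdir, "replicons.tsv"))
  domains <- .stage("domains", clusterDomains(replicons))
  writeClassedBED(domains, file.path(outdir, "domains.bed"))
  counts$replicons <- length(replicons)
  counts$domains <- length(domains)

  out <- list(profiles = prof, segments = segments, zones = zones,
              boundaries = boundaries, replicons = replicons,
              domains = domains)

  features <- NULL
  if (!is.null(config$featuresPath)) {
    features <- .stage("read_features", readFeatures(config$featuresPath))
    counts$features <- length(features)
  } else message("no annotation input: feature statistics skipped")
  marks <- NULL
  if (!is.null(config$marksPath)) {
    marks <- .stage("read_marks", readMarkCalls(config$marksPath))
  } else message("no mark input: mark statistics skipped")

  if (!is.null(features)) {
    pd <- .stage("probe_features", {
      pr <- probes(rs)
      df <- data.frame(
        probe_id = mcols(pr)$probe_id,
        cls = .probeClassFromSegments(pr, segments),
        gc = 100 * mcols(pr)$gc,
        gene_coverage = computeCoverage(pr, features, "gene"),
        te_coverage = computeCoverage(pr, features, "TE"))
      df$at_rich <- topQuartileFlags(100 - df$gc, config$quartile)
      df$gene_rich <- topQuartileFlags(df$gene_coverage, config$quartile)
      if (!is.null(marks)) {
        mm <- marks[match(df$probe_id, marks$probe_id), ]
        df[c("k4", "k9", "k56", "mc")] <- mm[c("k4", "k9", "k56", "mc")]
      }
      df
    })
    regions <- config$regions
    if (is.null(regions)) {
      ext <- range(probes(rs))
      regions <- data.frame(name = "chromosome",
                            chrom = as.character(seqnames(ext)),
                            start = start(ext) - 1, end = end(ext))
    }
    probeStats <- .stage("probe_stats", {
      res <- lapply(seq_len(nrow(regions)), function(i) {
        rgr <- GRanges(regions$chrom[i],
                       IRanges(regions$start[i] + 1, regions$end[i]))
        sel <- overlapsAny(probes(rs), rgr)
        bin <- c("at_rich", "gene_rich",
                 intersect(c("k4", "k9", "k56", "mc"), names(pd)))
        probeClassTests(pd[sel, ], region = regions$name[i],
                        continuous = c("gc", "gene_coverage", "te_coverage"),
                        binary = bin, nMin = config$nMin)
      })
      do.call(rbind, res)
    })
    .writeTSV(probeStats, file.path(outdir, "probe_stats.tsv"))
    out$probeStats <- probeStats

    repFeat <- .stage("replicon_features",
      repliconFeatureTable(replicons, probes(rs), features, marks))
    .writeTSV(repFeat, file.path(outdir, "replicon_features.tsv"))
    out$repliconFeatures <- repFeat
    cmp <- tryCatch(repliconCompare(repFeat), error = function(e) NULL)
    if (!is.null(cmp)) {
      .writeTSV(cmp, file.path(outdir, "replicon_compare.tsv"))
      out$repliconStats <- cmp
    } else message("EM/L replicon comparison skipped (too few replicons)")

    if (!is.null(marks)) {
      binsTab <- .stage("bins", {
        rows <- list()
        mm <- marks[match(mcols(probes(rs))$probe_id, marks$probe_id), ]
        featFlags <- c(list(at_rich = pd$at_rich, gene_rich = pd$gene_rich),
                       lapply(mm[c("k4", "k9", "k56", "mc")], as.logical))
        for (cl in c("EM", "L")) {
          for (fn in names(featFlags)) {
            bp <- binProfile(replicons, probes(rs), featFlags[[fn]],
                             cls = cl, mode = config$binMode)
            b <- bp$bins
            b$cls <- cl; b$feature <- fn; b$overall <- bp$overall
            rows[[length(rows) + 1]] <- b
          }
        }
        do.call(rbind, rows)
      })
      .writeTSV(binsTab, file.path(outdir, "bins.tsv"))
      out$bins <- binsTab
    }

    if (!is.null(marks) && !is.null(config$expressionPath)) {
      genesTab <- .stage("genes", {
        expr <- readExpression(config$expressionPath)
        genesGr <- features[mcols(features)$kind == "gene"]
        gm <- assignGeneMarks(genesGr, probes(rs), marks,
                              rule = config$geneMarkRule)
        gt <- assignGeneTiming(genesGr, segments)
        geneRecords(gm, gt, expr)
      })
      .writeTSV(genesTab, file.path(outdir, "genes.tsv"))
      .writeTSV(patternActivityTable(genesTab),
                file.path(outdir, "pattern_activity.tsv"))
      .writeTSV(timingEnrichmentTable(genesTab),
                file.path(outdir, "timing_enrichment.tsv"))
      .writeTSV(activityByTiming(genesTab),
                file.path(outdir, "activity_by_timing.tsv"))
      out$genes <- genesTab
    } else if (is.null(config$expressionPath)) {
      message("no expression input: gene analyses skipped")
    }
  }

  manifest <- list(
    package = "replitime",
    version = as.character(utils::packageVersion("replitime")),
    seed = config$seed,
    config = .manifestConfig(config),
    config_md5 = .configHash(config),
    counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}

.manifestConfig <- function(config) {
  x <- unclass(config)
  if (!is.null(x$regions)) x$regions <- as.list(as.data.frame(x$regions))
  x
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writePipelineConfig(config, tmp)
  unname(tools::md5sum(tmp))
}
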