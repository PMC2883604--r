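## Readers and writers.  On-disk conventions: probe TSV and BED use 0-based
## half-open coordinates, GFF3 is 1-based closed; internally everything is a
## GRanges (1-based closed).  GFF3/BED parsing is delegated to rtracklayer.

.fmtNum <- function(x) formatC(x, digits = 6, format = "g")

.writeTSV <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], .fmtNum)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a probe table
#'
#' TSV with columns `probe_id`, `chrom`, `start`, `end` (0-based
#' half-open), `gc`, then one log2-ratio column per array named
#' `<fraction>_<replicate>`; dye-swap arrays carry a `_swap` suffix and are
#' stored sign-flipped (the reader flips them back).
#'
#' @param rs a [RepliSet-class].
#' @param path output file.
#' @param swap optional logical per array column: write that column
#'   negated with a `_swap` suffix.
#' @return `path`, invisibly.
#' @export
writeProbeTable <- function(rs, path, swap = NULL) {
  pr <- probes(rs)
  m <- ratioMatrix(rs)
  cn <- paste(as.character(arrayFractions(rs)), arrayReplicates(rs),
              sep = "_")
  if (!is.null(swap)) {
    stopifnot(length(swap) == ncol(m))
    m[, swap] <- -m[, swap]
    cn[swap] <- paste0(cn[swap], "_swap")
  }
  colnames(m) <- cn
  df <- data.frame(probe_id = mcols(pr)$probe_id,
                   chrom = as.character(seqnames(pr)),
                   start = start(pr) - 1, end = end(pr),
                   gc = mcols(pr)$gc, check.names = FALSE)
  .writeTSV(cbind(df, as.data.frame(m, check.names = FALSE)), path)
}

#' Read a probe table
#'
#' Parses the TSV written by [writeProbeTable()]: ratio columns are
#' recognised by the `<fraction>_<replicate>[_swap]` naming convention and
#' `_swap` columns are sign-flipped on read (dye-swap orientation).
#' Validation failures report the offending line number.
#'
#' @param path probe TSV file.
#' @return A [RepliSet-class].
#' @export
readProbeTable <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("probe_id", "chrom", "start", "end", "gc")
  if (!all(need %in% names(df)))
    stop("probe table must have columns ", paste(need, collapse = ", "))
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop(sprintf("probe end <= start at line %d", bad[1] + 1L))
  ratioCols <- grep("^(early|mid|late)_[0-9]+(_swap)?$", names(df),
                    value = TRUE)
  if (length(ratioCols) == 0) stop("no ratio columns found")
  m <- as.matrix(df[ratioCols])
  if (!is.numeric(m)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(as.matrix(df[ratioCols])))))
    stop(sprintf("non-numeric ratio value at line %d",
                 ((bad[1] - 1) %% nrow(df)) + 2L))
  }
  swap <- grepl("_swap$", ratioCols)
  m[, swap] <- -m[, swap]
  fraction <- sub("_.*$", "", ratioCols)
  replicate <- as.integer(sub("^(early|mid|late)_([0-9]+).*$", "\\2",
                              ratioCols))
  ord <- order(df$chrom, df$start)
  df <- df[ord, ]; m <- m[ord, , drop = FALSE]
  gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end))
  mcols(gr)$probe_id <- df$probe_id
  mcols(gr)$gc <- df$gc
  if (length(gr) > 1) {
    ov <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    if (length(ov))
      stop(sprintf("overlapping probes at line %d",
                   min(queryHits(ov), subjectHits(ov)) + 1L))
  }
  colnames(m) <- sub("_swap$", "", ratioCols)
  RepliSet(gr, m, fraction, replicate)
}

#' Write features (genes/TEs) to BED or GFF3
#'
#' BED uses 0-based half-open coordinates with `kind:feature_id` in the
#' name field; GFF3 is 1-based closed with the kind as the feature type
#' (`gene` or `transposable_element`) and the id in `ID`.
#'
#' @param features GRanges with `feature_id` and `kind` metadata.
#' @param path output file; format chosen by extension (`.bed`, `.gff3`,
#'   `.gff`).
#' @return `path`, invisibly.
#' @export
writeFeatures <- function(features, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- granges(features)
    mcols(gr)$name <- paste(mcols(features)$kind,
                            mcols(features)$feature_id, sep = ":")
    rtracklayer::export(gr, path, format = "BED")
  } else if (ext %in% c("gff3", "gff")) {
    gr <- granges(features)
    mcols(gr)$type <- ifelse(mcols(features)$kind == "TE",
                             "transposable_element", "gene")
    mcols(gr)$ID <- mcols(features)$feature_id
    rtracklayer::export(gr, path, format = "GFF3")
  } else stop("unsupported feature format: ", ext)
  invisible(path)
}

#' Read features (genes/TEs) from BED or GFF3
#'
#' Auto-detects the dialect by extension (BED 0-based half-open, GFF3
#' 1-based closed) and returns unified internal coordinates.
#'
#' @param path input file.
#' @return GRanges with `feature_id` and `kind` metadata columns.
#' @export
readFeatures <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- mcols(gr)$name
    kind <- sub(":.*$", "", nm)
    id <- sub("^[^:]*:", "", nm)
    if (!all(kind %in% c("gene", "TE")))
      stop("BED name field must be 'gene:<id>' or 'TE:<id>'")
  } else if (ext %in% c("gff3", "gff")) {
    gr <- rtracklayer::import(path, format = "GFF3")
    type <- as.character(mcols(gr)$type)
    kind <- ifelse(type == "gene", "gene", "TE")
    id <- as.character(mcols(gr)$ID)
  } else stop("unsupported feature format: ", ext)
  out <- granges(gr)
  mcols(out) <- NULL
  mcols(out)$feature_id <- id
  mcols(out)$kind <- kind
  sort(out, ignore.strand = TRUE)
}

#' Write/read per-probe mark calls
#'
#' TSV with `probe_id` and logical `k4`, `k9`, `k56`, `mc` columns.
#'
#' @param marks data.frame of mark calls.
#' @param path file path.
#' @return The data.frame (read) or `path` invisibly (write).
#' @export
writeMarkCalls <- function(marks, path) .writeTSV(marks, path)

#' @rdname writeMarkCalls
#' @export
readMarkCalls <- function(path) {
  df <- read.delim(path)
  for (mk in c("k4", "k9", "k56", "mc")) df[[mk]] <- as.logical(df[[mk]])
  df
}

#' Write/read gene expression calls
#'
#' TSV with `gene_id`, logical `present`, numeric `level`.
#'
#' @param expression data.frame of expression records.
#' @param path file path.
#' @return The data.frame (read) or `path` invisibly (write).
#' @export
writeExpression <- function(expression, path) .writeTSV(expression, path)

#' @rdname writeExpression
#' @export
readExpression <- function(path) {
  df <- read.delim(path)
  df$present <- as.logical(df$present)
  df
}

#' Write/read simulator ground truth
#'
#' A TSV pair: `<stem>_origins.tsv` (position, family, mean firing time,
#' active) and `<stem>_boundaries.tsv` (position).
#'
#' @param truth a [GroundTruth-class].
#' @param stem path stem for the two files.
#' @return For the reader: a list with `origins` and `boundaries`.
#' @export
writeGroundTruth <- function(truth, stem) {
  .writeTSV(truth@origins, paste0(stem, "_origins.tsv"))
  .writeTSV(data.frame(position = truth@boundaries),
            paste0(stem, "_boundaries.tsv"))
  invisible(stem)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(stem) {
  list(origins = read.delim(paste0(stem, "_origins.tsv")),
       boundaries = read.delim(paste0(stem, "_boundaries.tsv"))$position)
}

#' Write classed intervals as BED4
#'
#' BED (0-based half-open) with the timing class in the name field;
#' used for timing segments, zones, replicons and domains.
#'
#' @param gr GRanges with a `cls` metadata column (and optionally `kind`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClassedBED <- function(gr, path) {
  nm <- as.character(mcols(gr)$cls)
  if (!is.null(mcols(gr)$kind))
    nm <- paste(mcols(gr)$kind, nm, sep = ":")
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1, end = end(gr), name = nm)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
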