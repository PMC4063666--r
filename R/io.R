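#' @importFrom rtracklayer import export
#' @importFrom jsonlite write_json
NULL

#' Construct a probe table
#'
#' @param chrom,pos,cy3,cy5 per-probe chromosome, 1-based position and
#'   channel intensities.
#' @param masked logical per-probe mask (default all unmasked).
#' @return A [ProbeTable-class], sorted by chromosome then position.
#' @export
probeTable <- function(chrom, pos, cy3, cy5, masked = FALSE) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   cy3 = as.numeric(cy3), cy5 = as.numeric(cy5),
                   masked = rep_len(as.logical(masked), length(pos)))
  df <- df[order(df$chrom, df$pos), ]
  rownames(df) <- NULL
  new("ProbeTable", probes = df)
}

#' Read a probe table from TSV
#'
#' Tab-separated file with header \code{chrom, pos, cy3, cy5} (an optional
#' \code{masked} column is honored); \code{#} comment lines are skipped.
#' Rows are validated (positive intensities, no duplicate positions) and
#' sorted.
#'
#' @param path file path.
#' @return A [ProbeTable-class].
#' @export
readProbeTable <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse probe table ", path, ": ",
                             conditionMessage(e)))
  need <- c("chrom", "pos", "cy3", "cy5")
  if (!all(need %in% names(df)))
    stop("probe TSV needs columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$pos) | !is.finite(df$cy3) | !is.finite(df$cy5))
  if (length(bad))
    stop("malformed probe row (data line ", bad[1L], ") in ", path)
  if (any(df$cy3 <= 0) || any(df$cy5 <= 0)) {
    bad <- which(df$cy3 <= 0 | df$cy5 <= 0)[1L]
    stop("nonpositive intensity at data line ", bad, " in ", path)
  }
  if (anyDuplicated(df[, c("chrom", "pos")]))
    stop("duplicated (chrom, pos) probe in ", path)
  masked <- if ("masked" %in% names(df)) as.logical(df$masked) else FALSE
  probeTable(df$chrom, df$pos, df$cy3, df$cy5, masked)
}

#' Write a probe table to TSV
#'
#' Writes the standard probe format (header \code{chrom, pos, cy3, cy5,
#' masked}); optional \code{#} comment lines (e.g. the simulation seed)
#' precede the header so [readProbeTable()] round-trips the file.
#'
#' @param pt a [ProbeTable-class].
#' @param path output path.
#' @param comments character vector of comment lines (without \code{#}).
#' @return Invisibly, \code{path}.
#' @export
writeProbeTable <- function(pt, path, comments = character()) {
  stopifnot(is(pt, "ProbeTable"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  utils::write.table(pt@probes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read masked intervals from BED3
#'
#' Reads a BED file (0-based half-open), merges overlapping or touching
#' intervals, and returns 1-based inclusive \code{GRanges} as used by
#' [applyMasks()]. An empty file yields an empty \code{GRanges}.
#'
#' @param path BED file path.
#' @return \code{GRanges} of merged masked intervals.
#' @export
readBedMask <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("cannot parse BED ", path, ": ",
                                          conditionMessage(e)))
  GenomicRanges::reduce(GenomicRanges::granges(gr))
}

#' Write masked intervals to BED3
#'
#' @param gr 1-based inclusive \code{GRanges}.
#' @param path output path (0-based half-open on disk).
#' @return Invisibly, \code{path}.
#' @export
writeBedMask <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr))
  writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), path)
  invisible(path)
}

#' Write composite-profile tracks as bedGraph
#'
#' Writes the per-bin mean (and optionally SD) of a composite profile as
#' bedGraph (chrom, 0-based start, end, value); \code{NA} (masked) bins
#' are skipped.
#'
#' @param profile a [CompositeProfile-class].
#' @param path output path for the mean track.
#' @param what \code{"mean"} or \code{"sd"}.
#' @return Invisibly, \code{path}.
#' @export
writeBedGraph <- function(profile, path, what = c("mean", "sd")) {
  stopifnot(is(profile, "CompositeProfile"))
  what <- match.arg(what)
  vals <- if (what == "mean") profile@mean else profile@sd
  starts <- binStarts(profile)
  ends <- pmin(starts + profile@binSize, profile@chromLength)
  keep <- !is.na(vals)
  gr <- GenomicRanges::GRanges(
    profile@chrom, IRanges::IRanges(starts[keep] + 1, ends[keep]),
    score = vals[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path bedGraph path (0-based half-open).
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{value}.
#' @export
readBedGraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             value = gr$score)
}

#' Write a run-metadata sidecar
#'
#' Records the parameters, seed and input checksums of a run next to its
#' outputs, as JSON.
#'
#' @param params named list of parameters (seed included by convention).
#' @param path output JSON path.
#' @param inputs optional character vector of input file paths; their md5
#'   checksums are recorded.
#' @return Invisibly, \code{path}.
#' @export
writeRunMetadata <- function(params, path, inputs = character()) {
  meta <- list(parameters = params,
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (length(inputs))
    meta$inputChecksums <- as.list(tools::md5sum(inputs))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
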