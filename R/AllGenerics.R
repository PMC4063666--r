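#' @rdname accessors
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname accessors
#' @export
setGeneric("chromLength", function(x) standardGeneric("chromLength"))

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname accessors
#' @export
setGeneric("binStarts", function(x) standardGeneric("binStarts"))

#' @rdname accessors
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname accessors
#' @export
setGeneric("trackPositions", function(x) standardGeneric("trackPositions"))

#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname accessors
#' @export
setGeneric("trackMask", function(x) standardGeneric("trackMask"))

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname accessors
#' @export
setGeneric("profileMean", function(x) standardGeneric("profileMean"))

#' @rdname accessors
#' @export
setGeneric("profileSD", function(x) standardGeneric("profileSD"))

#' @rdname accessors
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname accessors
#' @export
setGeneric("probes", function(x) standardGeneric("probes"))

#' @rdname accessors
#' @export
setGeneric("origins", function(x) standardGeneric("origins"))

#' @rdname accessors
#' @export
setGeneric("maskedIntervals", function(x) standardGeneric("maskedIntervals"))

#' Accessors for rerepCGH data classes
#'
#' Small read-only accessors exposing the slots of the package's S4
#' containers: chromosome identity and length, probe data, grid geometry,
#' track/profile values and masks, replicate counts, and the origins and
#' masked intervals of a [GenomeSpec-class].
#'
#' @param x a rerepCGH S4 object.
#' @return The corresponding slot value; see each class's documentation.
#' @name accessors
#' @examples
#' gs <- genomeSpec(c(chrS = 2e5),
#'                  origins = originSpec("chrS", 1e5, efficiency = 0.5))
#' origins(gs)
NULL

#' @rdname accessors
setMethod("chromName", "RatioTrack", function(x) x@chrom)
#' @rdname accessors
setMethod("chromName", "SmoothProfile", function(x) x@chrom)
#' @rdname accessors
setMethod("chromName", "CompositeProfile", function(x) x@chrom)

#' @rdname accessors
setMethod("chromLength", "RatioTrack", function(x) x@chromLength)
#' @rdname accessors
setMethod("chromLength", "SmoothProfile", function(x) x@chromLength)
#' @rdname accessors
setMethod("chromLength", "CompositeProfile", function(x) x@chromLength)

#' @rdname accessors
setMethod("binSize", "SmoothProfile", function(x) x@binSize)
#' @rdname accessors
setMethod("binSize", "CompositeProfile", function(x) x@binSize)

#' @rdname accessors
setMethod("binStarts", "SmoothProfile",
          function(x) (seq_along(x@values) - 1) * x@binSize)
#' @rdname accessors
setMethod("binStarts", "CompositeProfile",
          function(x) (seq_along(x@mean) - 1) * x@binSize)

#' @rdname accessors
setMethod("binCenters", "SmoothProfile",
          function(x) (seq_along(x@values) - 0.5) * x@binSize)
#' @rdname accessors
setMethod("binCenters", "CompositeProfile",
          function(x) (seq_along(x@mean) - 0.5) * x@binSize)

#' @rdname accessors
setMethod("trackPositions", "RatioTrack", function(x) x@positions)
#' @rdname accessors
setMethod("trackValues", "RatioTrack", function(x) x@values)
#' @rdname accessors
setMethod("trackMask", "RatioTrack", function(x) x@mask)

#' @rdname accessors
setMethod("profileValues", "SmoothProfile", function(x) x@values)
#' @rdname accessors
setMethod("profileMean", "CompositeProfile", function(x) x@mean)
#' @rdname accessors
setMethod("profileSD", "CompositeProfile", function(x) x@sd)
#' @rdname accessors
setMethod("nReplicates", "CompositeProfile", function(x) x@n)
#' @rdname accessors
setMethod("nReplicates", "SimConfig", function(x) x@nReplicates)

#' @rdname accessors
setMethod("probes", "ProbeTable", function(x) x@probes)
#' @rdname accessors
setMethod("origins", "GenomeSpec", function(x) x@origins)
#' @rdname accessors
setMethod("maskedIntervals", "GenomeSpec", function(x) x@masked)

setMethod("show", "Segment", function(object) {
  cat(sprintf("%s(%+d..%+d): %d bp origin-relative segment\n",
              if (nzchar(object@originName)) object@originName else "segment",
              object@hi, object@lo, segmentLength(object)))
})

setMethod("show", "MutationSpec", function(object) {
  detail <- switch(object@kind,
    linker_substitution = sprintf("%d bp linker %s", nchar(object@payload),
                                  object@payload),
    insertion = sprintf("%d nt insert", nchar(object@payload)),
    deletion = sprintf("%d nt removed", object@deletionLength))
  at <- if (is.na(object@at)) "" else sprintf(" at position %d", object@at)
  cat(sprintf("MutationSpec: %s (%s)%s\n", object@kind, detail, at))
})

setMethod("show", "ProbeTable", function(object) {
  p <- object@probes
  cat(sprintf("ProbeTable: %d probes on %d chromosome(s); %d masked\n",
              nrow(p), length(unique(p$chrom)), sum(p$masked)))
  if (nrow(p)) {
    utils::head(p, 3L) |> print()
    if (nrow(p) > 3L) cat(sprintf("... and %d more rows\n", nrow(p) - 3L))
  }
})

setMethod("show", "RatioTrack", function(object) {
  cat(sprintf(
    "RatioTrack on %s (%.0f bp): %d probes (%d masked), mean %.4g C\n",
    object@chrom, object@chromLength, length(object@positions),
    sum(object@mask), mean(object@values[!object@mask], na.rm = TRUE)))
})

setMethod("show", "SmoothProfile", function(object) {
  cat(sprintf(
    "SmoothProfile on %s: %d bins of %.0f bp, kernel %.4g kb, mean %.4g C\n",
    object@chrom, length(object@values), object@binSize, object@kernel,
    mean(object@values, na.rm = TRUE)))
})

setMethod("show", "CompositeProfile", function(object) {
  cat(sprintf(
    "CompositeProfile on %s: %d bins of %.0f bp, n = %d replicates, mean %.4g C\n",
    object@chrom, length(object@mean), object@binSize, object@n,
    mean(object@mean, na.rm = TRUE)))
})

setMethod("show", "GenomeSpec", function(object) {
  cat(sprintf("GenomeSpec: %d chromosome(s), %.3g Mb total, %d origin(s), %d masked interval(s)\n",
              length(object@chromosomes), sum(object@chromosomes) / 1e6,
              nrow(object@origins), length(object@masked)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: fork %.4g bp/min x %.4g min (peak half-width %.4g kb), ",
    "probes every %.0f bp,\n  sigma = %.3g, %d replicate(s), target %.2gC, ",
    "seed %d\n"),
    object@forkSpeed, object@inductionMinutes,
    object@forkSpeed * object@inductionMinutes / 1000, object@probeSpacing,
    object@noiseSigma, object@nReplicates, object@targetContent, object@seed))
})
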