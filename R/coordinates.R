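#' Linear index of an origin-relative coordinate
#'
#' The origin-relative numbering has no position zero: +1 follows -1
#' directly. Mapping a coordinate c to the linear index idx(c) = c for
#' c > 0 and c + 1 for c < 0 restores ordinary integer arithmetic, so that
#' lengths and gaps can be computed by subtraction. Under this convention
#' the fragment (+300..-106) is 300 + 106 = 406 bp, exactly as fragment
#' sizes are quoted in the field.
#'
#' @param coord integer vector of nonzero origin-relative coordinates.
#' @return Integer vector of linear indices.
#' @examples
#' coordIndex(c(-2L, -1L, 1L, 2L))  # -1, 0, 1, 2
#' @export
coordIndex <- function(coord) {
  coord <- checkCoord(coord)
  ifelse(coord > 0L, coord, coord + 1L)
}

checkCoord <- function(coord) {
  if (!length(coord)) stop("empty coordinate")
  if (any(is.na(coord)) || any(coord != as.integer(coord)))
    stop("origin-relative coordinates must be integers")
  coord <- as.integer(coord)
  if (any(coord == 0L))
    stop("invalid coordinate: the origin-relative numbering has no position 0")
  coord
}

#' Construct an origin-relative segment
#'
#' Builds a [Segment-class] from its two bounding coordinates, written in
#' the field's \code{(hi..lo)} orientation (e.g. \code{317(+300..-106)}).
#' The coordinates are orientation-normalized on construction: whichever
#' bound has the larger linear index is stored as \code{hi}.
#'
#' @param hi,lo nonzero integer origin-relative coordinates.
#' @param originName optional name of the anchoring origin (e.g. "317").
#' @return A [Segment-class].
#' @examples
#' segment(300, -106, "317")   # the 406 bp fragment 317(+300..-106)
#' segmentLength(segment(33, 1))  # the 33 bp ORC binding site
#' @export
segment <- function(hi, lo, originName = "") {
  hi <- checkCoord(hi); lo <- checkCoord(lo)
  if (coordIndex(hi) < coordIndex(lo)) { tmp <- hi; hi <- lo; lo <- tmp }
  new("Segment", originName = as.character(originName), hi = hi, lo = lo)
}

#' Length of an origin-relative segment
#'
#' Number of nucleotides spanned by a segment, inclusive of both bounds,
#' computed on the zero-free linear index: idx(hi) - idx(lo) + 1.
#'
#' @param seg a [Segment-class].
#' @return Integer length in bp.
#' @examples
#' segmentLength(segment(300, -106))  # 406
#' segmentLength(segment(153, 87))    # 67 (the RIP317 element)
#' @export
segmentLength <- function(seg) {
  stopifnot(is(seg, "Segment"))
  coordIndex(seg@hi) - coordIndex(seg@lo) + 1L
}

#' Gap between two non-overlapping segments
#'
#' Number of nucleotides strictly between two segments, e.g. the spacing
#' separating a re-initiation promoter (RIP) from the ORC binding site of
#' its origin. \code{upstream} must lie entirely at higher linear index
#' than \code{downstream}; the segments may touch (gap 0) but not overlap.
#'
#' @param upstream [Segment-class] at higher coordinates (the RIP side).
#' @param downstream [Segment-class] at lower coordinates (the OBS side).
#' @return Integer gap in bp (>= 0).
#' @examples
#' rip <- segment(153, 87, "RIP317")
#' obs <- segment(33, 1, "OBS317")
#' gapBetween(rip, obs)  # 53 bp RIP-OBS spacing
#' @export
gapBetween <- function(upstream, downstream) {
  stopifnot(is(upstream, "Segment"), is(downstream, "Segment"))
  gap <- coordIndex(upstream@lo) - coordIndex(downstream@hi) - 1L
  if (gap < 0L)
    stop("segments overlap: upstream must lie entirely above downstream")
  gap
}

#' Construct a mutation specification
#'
#' One of the three edits used to dissect origin-adjacent sequence:
#' \describe{
#'   \item{linker_substitution}{replace \code{nchar(payload)} bases in
#'     place with the linker; total length unchanged.}
#'   \item{insertion}{insert \code{payload} after position \code{at}.}
#'   \item{deletion}{remove \code{payload} (an integer count) bases
#'     starting at position \code{at}.}
#' }
#'
#' @param kind \code{"linker_substitution"}, \code{"insertion"} or
#'   \code{"deletion"}.
#' @param payload DNA string for substitutions/insertions; integer number
#'   of deleted nucleotides for deletions.
#' @param at 1-based position in the target sequence (see
#'   [MutationSpec-class]); may be \code{NA} for pure spacing arithmetic.
#' @return A [MutationSpec-class].
#' @examples
#' mutationSpec("linker_substitution", "GGGATCCG", at = 1)
#' mutationSpec("deletion", 16)   # the L21-L27 ligation deletion
#' @export
mutationSpec <- function(kind, payload, at = NA_integer_) {
  kind <- match.arg(kind, c("linker_substitution", "insertion", "deletion"))
  if (kind == "deletion") {
    if (!is.numeric(payload) || length(payload) != 1L || payload < 0 ||
        payload != as.integer(payload))
      stop("deletion payload must be a single nonnegative integer length")
    new("MutationSpec", kind = kind, payload = "",
        deletionLength = as.integer(payload), at = as.integer(at))
  } else {
    payload <- foldDNA(payload)
    new("MutationSpec", kind = kind, payload = payload,
        deletionLength = 0L, at = as.integer(at))
  }
}

#' Net length change of an edit
#'
#' @param edit a [MutationSpec-class].
#' @return Integer: +insert length, -deletion length, or 0 for a linker
#'   substitution.
#' @export
editDelta <- function(edit) {
  stopifnot(is(edit, "MutationSpec"))
  switch(edit@kind,
         linker_substitution = 0L,
         insertion = nchar(edit@payload),
         deletion = -edit@deletionLength)
}

#' RIP-OBS spacing after an insertion or deletion
#'
#' Spacing mutants move a re-initiation promoter relative to its origin's
#' ORC binding site by inserting synthetic DNA into, or deleting DNA from,
#' the wild-type spacer. The resulting spacing is the wild-type spacing
#' plus the edit's net length change and must remain nonnegative.
#'
#' @param wtSpacing integer wild-type spacing in bp (e.g. 53 for the
#'   RIP317-OBS spacer, 36 for RIP1238).
#' @param edit a [MutationSpec-class] insertion or deletion placed in the
#'   spacer (a linker substitution leaves spacing unchanged).
#' @return Integer spacing in bp.
#' @examples
#' ins100 <- mutationSpec("insertion", strrep("A", 100))
#' editedSpacing(53, ins100)                     # 153
#' editedSpacing(53, mutationSpec("deletion", 16))  # 37
#' @export
editedSpacing <- function(wtSpacing, edit) {
  stopifnot(is.numeric(wtSpacing), length(wtSpacing) == 1L, wtSpacing >= 0)
  out <- as.integer(wtSpacing) + editDelta(edit)
  if (out < 0L)
    stop(sprintf("deletion of %d nt exceeds the %d bp spacer",
                 edit@deletionLength, as.integer(wtSpacing)))
  out
}

#' Read origin-relative segment definitions from TSV
#'
#' Expects tab-separated columns \code{origin_name}, \code{hi}, \code{lo}
#' (a header line; \code{#} comments ignored).
#'
#' @param path file path.
#' @return A list of [Segment-class] objects, named by \code{origin_name}.
#' @export
readSegmentsTsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("origin_name", "hi", "lo")
  if (!all(need %in% names(df)))
    stop("segment TSV needs columns: ", paste(need, collapse = ", "))
  segs <- lapply(seq_len(nrow(df)), function(i)
    segment(df$hi[i], df$lo[i], df$origin_name[i]))
  names(segs) <- df$origin_name
  segs
}

#' Write segment definitions to TSV
#'
#' @param segments list of [Segment-class] objects.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeSegmentsTsv <- function(segments, path) {
  df <- data.frame(
    origin_name = vapply(segments, function(s) s@originName, character(1)),
    hi = vapply(segments, function(s) s@hi, integer(1)),
    lo = vapply(segments, function(s) s@lo, integer(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
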