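#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   letterFrequency
NULL

# Case-fold and validate a DNA string over {A,C,G,T}.
foldDNA <- function(x) {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop("expected a single DNA string")
  x <- unname(toupper(x))
  if (!nzchar(x)) stop("empty sequence")
  if (grepl("[^ACGT]", x))
    stop("sequence contains characters outside {A, C, G, T}")
  x
}

#' AT content of a DNA sequence
#'
#' Fraction of A and T bases. Re-initiation promoter elements are strongly
#' AT-rich (RIP317 and RIP1238 are 92\% and 84\% AT), so composition is a
#' routine check on constructed and synthetic spacer sequences.
#'
#' @param seq DNA string (character, \code{DNAString} or single-element
#'   \code{DNAStringSet}); case-folded on input, alphabet restricted to
#'   A/C/G/T.
#' @return Fraction in [0, 1].
#' @examples
#' atContent("ATAT")  # 1
#' atContent("GCGC")  # 0
#' @export
atContent <- function(seq) {
  seq <- foldDNA(seq)
  dna <- DNAStringSet(seq)
  at <- sum(letterFrequency(dna, c("A", "T")))
  at / nchar(seq)
}

#' Linker-scan mutant series
#'
#' Systematic linker substitution across a sequence: for each start offset
#' the fixed linker replaces the corresponding bases in place, preserving
#' total length. Mutants are labeled L1..Ln in offset order, the field's
#' convention for linker scans (8 bp GGGATCCG linker in the origin
#' literature).
#'
#' @param seq DNA string to scan.
#' @param linker DNA string substituted at each offset.
#' @param startOffsets integer vector of 0-based offsets of the linker's
#'   first base; each offset + linker length must not exceed the sequence
#'   length.
#' @return A \code{DNAStringSet} of mutants named L1..Ln.
#' @examples
#' muts <- linkerScan("ACGTACGTACGT", "GGGA", startOffsets = c(0, 4, 8))
#' names(muts)
#' @export
linkerScan <- function(seq, linker = "GGGATCCG", startOffsets) {
  seq <- foldDNA(seq); linker <- foldDNA(linker)
  n <- nchar(seq); k <- nchar(linker)
  startOffsets <- as.integer(startOffsets)
  if (any(startOffsets < 0L) || any(startOffsets + k > n))
    stop("linker offset out of range for this sequence")
  muts <- vapply(startOffsets, function(off) {
    paste0(substr(seq, 1L, off), linker, substr(seq, off + k + 1L, n))
  }, character(1))
  out <- DNAStringSet(muts)
  names(out) <- paste0("L", seq_along(muts))
  out
}

#' Apply a single edit to a sequence
#'
#' Applies a [MutationSpec-class] at its stored position: a linker
#' substitution replaces bases in place (length preserved); an insertion
#' places the payload after position \code{at} (0 prepends); a deletion
#' removes \code{deletionLength} bases starting at \code{at}.
#'
#' @param seq DNA string to edit.
#' @param edit a [MutationSpec-class] with a non-\code{NA} position.
#' @return The edited sequence as a character string.
#' @examples
#' applyEdit("AAAATTTT", mutationSpec("linker_substitution", "GG", at = 3))
#' applyEdit("AAAATTTT", mutationSpec("insertion", "CC", at = 4))
#' applyEdit("AAAATTTT", mutationSpec("deletion", 2, at = 5))
#' @export
applyEdit <- function(seq, edit) {
  seq <- foldDNA(seq)
  stopifnot(is(edit, "MutationSpec"))
  n <- nchar(seq); at <- edit@at
  if (is.na(at)) stop("edit has no position; supply 'at' in mutationSpec()")
  switch(edit@kind,
    linker_substitution = {
      k <- nchar(edit@payload)
      if (at < 1L || at + k - 1L > n) stop("substitution site outside sequence")
      paste0(substr(seq, 1L, at - 1L), edit@payload,
             substr(seq, at + k, n))
    },
    insertion = {
      if (at < 0L || at > n) stop("insertion site outside sequence")
      paste0(substr(seq, 1L, at), edit@payload, substr(seq, at + 1L, n))
    },
    deletion = {
      k <- edit@deletionLength
      if (k == 0L) return(seq)
      if (at < 1L || at + k - 1L > n) stop("deletion extends outside sequence")
      paste0(substr(seq, 1L, at - 1L), substr(seq, at + k, n))
    })
}

#' Read sequences from FASTA
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} that case-folds to
#' uppercase and validates the A/C/G/T alphabet.
#'
#' @param path FASTA file path.
#' @return A \code{DNAStringSet}.
#' @export
readSequences <- function(path) {
  x <- readDNAStringSet(path)
  chars <- toupper(as.character(x))
  if (any(grepl("[^ACGT]", chars)))
    stop("FASTA contains characters outside {A, C, G, T}")
  out <- DNAStringSet(chars)
  names(out) <- names(x)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or \code{DNAStringSet}.
#' @param path output FASTA path.
#' @return Invisibly, \code{path}.
#' @export
writeSequences <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(toupper(seqs))
  writeXStringSet(seqs, path)
  invisible(path)
}
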