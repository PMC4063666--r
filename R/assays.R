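#' ChIP-qPCR fold enrichment by the 2^-ddCt method
#'
#' Computes, per culture, fold enrichment of a target locus in the
#' immunoprecipitate (IP) over the whole-cell extract (WCE), normalized to
#' non-origin control loci: technical-replicate Ct values are averaged
#' within each (fraction, target) well group, \eqn{\Delta Ct(x) =
#' \bar{Ct}_{IP}(x) - \bar{Ct}_{WCE}(x)}, \eqn{\Delta\Delta Ct} subtracts
#' the mean \eqn{\Delta Ct} of the controls, and fold
#' \eqn{= 2^{-\Delta\Delta Ct}}. Averaging the controls' \eqn{\Delta Ct}
#' values (the default) equals taking the geometric mean of their folds;
#' set \code{controlAggregation = "fold"} for the arithmetic mean of folds
#' instead.
#'
#' @param ct long-format data.frame with columns \code{sample},
#'   \code{fraction} ("IP"/"WCE"), \code{target}, \code{replicate},
#'   \code{ct}.
#' @param target locus to quantify.
#' @param controls non-origin control loci (default ADH1 and SLH1).
#' @param controlAggregation \code{"delta_ct"} (default) or \code{"fold"}.
#' @return Named numeric vector: fold enrichment per sample (culture).
#' @examples
#' ct <- expand.grid(sample = "c1", fraction = c("IP", "WCE"),
#'                   target = c("ARS317", "ADH1", "SLH1"), replicate = 1:3)
#' ct$ct <- ifelse(ct$fraction == "IP" & ct$target == "ARS317", 24, 25)
#' foldEnrichment(ct, "ARS317")  # one cycle below controls: fold 2
#' @export
foldEnrichment <- function(ct, target, controls = c("ADH1", "SLH1"),
                           controlAggregation = c("delta_ct", "fold")) {
  controlAggregation <- match.arg(controlAggregation)
  need <- c("sample", "fraction", "target", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and > 0")
  loci <- unique(c(target, controls))
  out <- vapply(unique(as.character(ct$sample)), function(smp) {
    sub <- ct[ct$sample == smp, , drop = FALSE]
    dCt <- vapply(loci, function(loc) {
      ip <- sub$ct[sub$fraction == "IP" & sub$target == loc]
      wce <- sub$ct[sub$fraction == "WCE" & sub$target == loc]
      if (!length(ip) || !length(wce))
        stop(sprintf("sample %s: missing IP or WCE wells for %s", smp, loc))
      mean(ip) - mean(wce)
    }, numeric(1))
    if (controlAggregation == "delta_ct") {
      ddCt <- dCt[[target]] - mean(dCt[controls])
      2^(-ddCt)
    } else {
      mean(2^(-(dCt[[target]] - dCt[controls])))
    }
  }, numeric(1))
  out
}

#' Summarize per-culture fold enrichments
#'
#' Arithmetic mean and sample SD of fold enrichments over independent
#' cultures (reported as mean +/- SD, typically n = 3).
#'
#' @param folds numeric fold enrichments, one per culture (n >= 2).
#' @param target optional locus label carried into the result.
#' @return A data.frame with \code{target}, \code{meanFold},
#'   \code{sdFold}, \code{n}.
#' @export
enrichmentSummary <- function(folds, target = NA_character_) {
  if (length(folds) < 2L)
    stop("need at least 2 cultures to summarize enrichment")
  if (any(folds <= 0)) stop("fold enrichments must be > 0")
  data.frame(target = target, meanFold = mean(folds),
             sdFold = stats::sd(folds), n = length(folds))
}

#' Plasmid mitotic stability
#'
#' Fraction of cells retaining a CEN-ARS plasmid, a proxy for origin
#' activity: for each transformant, colonies on its selective plates are
#' pooled and divided by the pooled count on its non-selective plates;
#' the assay reports mean +/- sample SD over the (typically 3) independent
#' transformants of each construct. Fractions above 1 (counting noise)
#' are reported and flagged, not truncated.
#'
#' @param counts data.frame with columns \code{construct},
#'   \code{transformant}, \code{plate}, \code{selective_cfu},
#'   \code{nonselective_cfu}.
#' @return A data.frame per construct: \code{construct}, \code{meanStability},
#'   \code{sdStability}, \code{n} (transformants), \code{anyOverOne};
#'   per-transformant pooled fractions in attribute
#'   \code{"perTransformant"}.
#' @examples
#' cc <- data.frame(construct = "p1", transformant = rep(1:3, each = 2),
#'                  plate = rep(1:2, 3),
#'                  selective_cfu = c(450, 450, 225, 225, 300, 300),
#'                  nonselective_cfu = 500)
#' mitoticStability(cc)
#' @export
mitoticStability <- function(counts) {
  need <- c("construct", "transformant", "plate", "selective_cfu",
            "nonselective_cfu")
  if (!all(need %in% names(counts)))
    stop("counts table needs columns: ", paste(need, collapse = ", "))
  if (any(counts$selective_cfu < 0) || any(counts$nonselective_cfu < 0))
    stop("colony counts must be >= 0")
  pooled <- stats::aggregate(
    cbind(selective_cfu, nonselective_cfu) ~ construct + transformant,
    data = counts, FUN = sum)
  if (any(pooled$nonselective_cfu == 0))
    stop("a transformant has zero total non-selective colonies")
  per <- data.frame(construct = pooled$construct,
                    transformant = pooled$transformant,
                    fraction = pooled$selective_cfu / pooled$nonselective_cfu)
  out <- do.call(rbind, lapply(split(per, per$construct), function(g) {
    data.frame(construct = g$construct[1L],
               meanStability = mean(g$fraction),
               sdStability = if (nrow(g) > 1L) stats::sd(g$fraction) else 0,
               n = nrow(g),
               anyOverOne = any(g$fraction > 1))
  }))
  rownames(out) <- NULL
  attr(out, "perTransformant") <- per
  out
}

#' Read a long-format qPCR Ct table
#'
#' TSV with header \code{sample, fraction, target, replicate, ct};
#' \code{#} comment lines ignored.
#'
#' @param path file path.
#' @return data.frame for [foldEnrichment()].
#' @export
readQpcrTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample", "fraction", "target", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("qPCR TSV needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$ct)) || any(df$ct <= 0))
    stop("Ct values must be finite and > 0")
  df
}

#' Read a colony-count table for mitotic stability
#'
#' TSV with header \code{construct, transformant, plate, selective_cfu,
#' nonselective_cfu}; \code{#} comment lines ignored.
#'
#' @param path file path.
#' @return data.frame for [mitoticStability()].
#' @export
readStabilityTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("construct", "transformant", "plate", "selective_cfu",
            "nonselective_cfu")
  if (!all(need %in% names(df)))
    stop("stability TSV needs columns: ", paste(need, collapse = ", "))
  df
}
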