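#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
NULL

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Pair of gapless coding sequences partitioned into codons
#'
#' Holds two equal-length, gapless coding sequences analysed codon-by-codon.
#' Both sequences must be over the ACGT alphabet, have length divisible by
#' three and contain no internal stop codons (standard genetic code).
#'
#' @slot codonsA,codonsB character vectors of 3-mers, equal length.
#'
#' @seealso [readCodonAlignment()], [simulateCodonPair()], [ng86()]
#' @export
setClass("CodonPairAlignment",
  representation(codonsA = "character", codonsB = "character"))

setValidity("CodonPairAlignment", function(object) {
  a <- object@codonsA
  b <- object@codonsB
  if (length(a) != length(b))
    return("codonsA and codonsB must have equal length")
  if (length(a) == 0L)
    return("alignment is empty")
  if (!all(nchar(c(a, b)) == 3L))
    return("all codons must be 3-mers")
  if (any(grepl("[^ACGT]", c(a, b))))
    return("alphabet must be ACGT (gapless, unambiguous)")
  if (any(a %in% .STOP_CODONS) || any(b %in% .STOP_CODONS))
    return("internal stop codon present")
  TRUE
})

#' Construct a CodonPairAlignment from two coding sequences
#'
#' @param seqA,seqB character scalars (nucleotide strings) or character
#'   vectors of codons.
#' @return A [CodonPairAlignment-class] object.
#' @examples
#' CodonPairAlignment("TTTGGGGGG", "TTCGGGGGG")
#' @export
CodonPairAlignment <- function(seqA, seqB) {
  toCodons <- function(x) {
    if (length(x) == 1L && nchar(x) != 3L) {
      x <- toupper(x)
      if (nchar(x) %% 3L != 0L)
        stop("sequence length is not codon-multiple (", nchar(x), " nt)",
             call. = FALSE)
      substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
    } else toupper(x)
  }
  new("CodonPairAlignment", codonsA = toCodons(seqA), codonsB = toCodons(seqB))
}

#' @describeIn CodonPairAlignment-class number of codons
#' @param x a CodonPairAlignment
#' @export
setMethod("length", "CodonPairAlignment", function(x) length(x@codonsA))

#' @export
setMethod("show", "CodonPairAlignment", function(object) {
  cat("CodonPairAlignment with", length(object), "codons\n")
  n <- min(5L, length(object))
  cat("  A:", paste(object@codonsA[seq_len(n)], collapse = " "),
      if (length(object) > n) "...\n" else "\n")
  cat("  B:", paste(object@codonsB[seq_len(n)], collapse = " "),
      if (length(object) > n) "...\n" else "\n")
})

#' @describeIn CodonPairAlignment-class codons of the first sequence
#' @export
codonsA <- function(x) x@codonsA

#' @describeIn CodonPairAlignment-class codons of the second sequence
#' @export
codonsB <- function(x) x@codonsB

#' LTR retrotransposon element: the two aligned terminal repeats
#'
#' An element's 5' and 3' long terminal repeats, pre-aligned with gap
#' columns dropped. Their divergence dates the insertion through the
#' molecular clock T = D / (2 mu), because the two repeats are identical
#' at insertion time.
#'
#' @slot elementId single element identifier.
#' @slot ltr5,ltr3 equal-length aligned sequences (ACGTN; N excluded
#'   pairwise from distance computation).
#' @slot source optional origin annotation (e.g. "chr9:1000").
#'
#' @seealso [k2pDistance()], [insertionTime()], [simulateLtrPair()]
#' @export
setClass("LTRElement",
  representation(elementId = "character", ltr5 = "character",
                 ltr3 = "character", source = "character"),
  prototype(source = NA_character_))

setValidity("LTRElement", function(object) {
  if (length(object@ltr5) != 1L || length(object@ltr3) != 1L)
    return("ltr5 and ltr3 must be single sequences")
  if (nchar(object@ltr5) != nchar(object@ltr3))
    return("ltr5 and ltr3 must have equal aligned length")
  if (nchar(object@ltr5) < 100L)
    return("aligned LTR length must be >= 100 bp")
  if (grepl("[^ACGTN]", object@ltr5) || grepl("[^ACGTN]", object@ltr3))
    return("alphabet must be ACGT (N allowed, excluded pairwise)")
  TRUE
})

#' Construct an LTRElement
#' @param elementId element identifier.
#' @param ltr5,ltr3 aligned 5' and 3' terminal repeat sequences.
#' @param source optional chrom/pos annotation.
#' @return An [LTRElement-class] object.
#' @export
LTRElement <- function(elementId, ltr5, ltr3, source = NA_character_) {
  new("LTRElement", elementId = as.character(elementId),
      ltr5 = toupper(ltr5), ltr3 = toupper(ltr3),
      source = as.character(source))
}

#' @export
setMethod("show", "LTRElement", function(object) {
  cat("LTRElement", object@elementId, "(", nchar(object@ltr5), "bp aligned )\n")
})

#' @describeIn LTRElement-class 5' terminal repeat
#' @param x an LTRElement
#' @export
ltr5 <- function(x) x@ltr5

#' @describeIn LTRElement-class 3' terminal repeat
#' @export
ltr3 <- function(x) x@ltr3

#' Expression study: counts, gene lengths and sample design
#'
#' A \linkS4class{SummarizedExperiment} subclass holding a genes x samples
#' non-negative integer count matrix (assay \code{"counts"}), per-gene
#' transcript lengths in bp (\code{rowData(x)$gene_length}) and the sample
#' design (\code{colData} columns \code{tissue}, \code{line},
#' \code{treatment}, \code{time_h}, \code{replicate}).
#'
#' @seealso [ExpressionStudy()], [simulateExpression()], [rpkmMatrix()]
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0) || any(cts != round(cts)))
    return("counts must be non-negative integers")
  if (!"gene_length" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData column 'gene_length' is required")
  gl <- SummarizedExperiment::rowData(object)$gene_length
  if (any(!is.finite(gl)) || any(gl <= 0))
    return("gene_length must be positive for every gene")
  need <- c("tissue", "line", "treatment", "time_h", "replicate")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    return(paste("colData columns missing:", paste(miss, collapse = ", ")))
  TRUE
})

#' Construct an ExpressionStudy
#'
#' @param counts genes x samples matrix of non-negative integer counts with
#'   row and column names.
#' @param geneLengths numeric vector of transcript lengths (bp), one per
#'   counts row (recycled by name when named).
#' @param samples data.frame of per-sample records with columns
#'   \code{tissue} (root/leaf/bark/strobilus or NA for cell lines),
#'   \code{line} (HC/LC/none), \code{treatment} (MeJA/control),
#'   \code{time_h} (0/2/4/8/24 or NA) and \code{replicate}.
#' @return An [ExpressionStudy-class] object.
#' @export
ExpressionStudy <- function(counts, geneLengths, samples) {
  counts <- as.matrix(counts)
  if (!is.null(names(geneLengths)) && !is.null(rownames(counts)))
    geneLengths <- geneLengths[rownames(counts)]
  if (length(geneLengths) != nrow(counts))
    stop("every counts row needs a gene_length", call. = FALSE)
  if (nrow(samples) != ncol(counts))
    stop("every counts column needs a sample record", call. = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_length = as.numeric(geneLengths)),
    colData = S4Vectors::DataFrame(samples))
  new("ExpressionStudy", se)
}

#' @describeIn ExpressionStudy-class per-gene transcript lengths (bp)
#' @param x an ExpressionStudy
#' @export
geneLengths <- function(x) {
  gl <- SummarizedExperiment::rowData(x)$gene_length
  names(gl) <- rownames(x)
  gl
}

#' @describeIn ExpressionStudy-class sample design table
#' @export
sampleInfo <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' Density-peak report for a divergence distribution
#'
#' Result of Gaussian-KDE peak detection on a vector of Ks or 4DTv values:
#' peaks are local maxima of the density estimate, reported in descending
#' density order.
#'
#' @slot values finite values entering the KDE.
#' @slot bandwidth Silverman rule-of-thumb bandwidth used.
#' @slot peaks data.frame with columns \code{location} and \code{density}.
#' @slot binWidth display histogram bin width.
#' @slot nSaturated number of saturated/undefined values excluded.
#'
#' @seealso [findDensityPeaks()], [ksDistribution()]
#' @export
setClass("PeakReport",
  representation(values = "numeric", bandwidth = "numeric",
                 peaks = "data.frame", binWidth = "numeric",
                 nSaturated = "integer"))

setValidity("PeakReport", function(object) {
  if (nrow(object@peaks) &&
      (any(object@peaks$location < min(object@values) - object@bandwidth) ||
       any(object@peaks$location > max(object@values) + object@bandwidth)))
    return("peak locations must lie within the data range")
  TRUE
})

#' @export
setMethod("show", "PeakReport", function(object) {
  cat("PeakReport:", length(object@values), "values, bandwidth",
      signif(object@bandwidth, 4), "\n")
  if (object@nSaturated > 0L)
    cat("  saturated/undefined excluded:", object@nSaturated, "\n")
  if (nrow(object@peaks)) {
    cat("  peaks (density-ordered):\n")
    print(format(object@peaks, digits = 4), row.names = FALSE)
  } else cat("  no peaks detected\n")
})

#' @describeIn PeakReport-class detected peaks, descending density
#' @param x a PeakReport
#' @export
peaks <- function(x) x@peaks

#' @describeIn PeakReport-class finite values used
#' @export
peakValues <- function(x) x@values

#' Michaelis-Menten fit result
#'
#' @slot km Michaelis constant (same units as the substrate grid, uM).
#' @slot vmax limiting rate (velocity units).
#' @slot kcat turnover number Vmax / [E] (per second), NA when the enzyme
#'   concentration was not supplied.
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag.
#' @slot fitted fitted velocities at the input substrate grid.
#'
#' @seealso [fitMichaelisMenten()], [kineticRatios()]
#' @export
setClass("MMFit",
  representation(km = "numeric", vmax = "numeric", kcat = "numeric",
                 rss = "numeric", converged = "logical", fitted = "numeric"))

setValidity("MMFit", function(object) {
  if (object@converged && (!is.finite(object@km) || object@km <= 0 ||
                           !is.finite(object@vmax) || object@vmax <= 0))
    return("converged fit must have positive Km and Vmax")
  TRUE
})

#' @export
setMethod("show", "MMFit", function(object) {
  cat("Michaelis-Menten fit:",
      if (object@converged) "converged" else "NOT converged", "\n")
  cat(sprintf("  Km = %.6g, Vmax = %.6g, RSS = %.3g\n",
              object@km, object@vmax, object@rss))
  if (is.finite(object@kcat)) cat(sprintf("  kcat = %.6g s^-1\n", object@kcat))
})

#' @describeIn MMFit-class Michaelis constant
#' @param x an MMFit
#' @export
km <- function(x) x@km

#' @describeIn MMFit-class limiting rate
#' @export
vmax <- function(x) x@vmax

#' @describeIn MMFit-class turnover number
#' @export
kcat <- function(x) x@kcat
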