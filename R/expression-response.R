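# RPKM, per-gene up/down calls, the +-1 group response score, group
# expression sums, and qPCR 2^-ddCt fold change.

#' Reads per kilobase per million mapped reads
#'
#' RPKM = 1e9 * count / (length_bp * library_size). For a matrix the
#' library size defaults to the column sums.
#'
#' @param counts numeric vector (one sample) or genes x samples matrix.
#' @param geneLengths transcript lengths in bp, one per gene.
#' @param librarySize total mapped reads per sample; defaults to
#'   \code{sum(counts)} / column sums.
#' @return RPKM values with the shape of \code{counts}.
#' @examples
#' rpkm(100, 2000, 1e7)  # 5
#' @export
rpkm <- function(counts, geneLengths, librarySize = NULL) {
  if (any(geneLengths <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (is.matrix(counts)) {
    if (is.null(librarySize)) librarySize <- colSums(counts)
    if (any(librarySize <= 0)) stop("library size must be > 0",
                                    call. = FALSE)
    return(1e9 * sweep(counts / geneLengths, 2L, librarySize, "/"))
  }
  if (is.null(librarySize)) librarySize <- sum(counts)
  if (librarySize <= 0) stop("library size must be > 0", call. = FALSE)
  1e9 * counts / (geneLengths * librarySize)
}

#' RPKM matrix of an ExpressionStudy
#'
#' @param study an [ExpressionStudy-class].
#' @return genes x samples RPKM matrix (library size = column sums of the
#'   count matrix).
#' @export
rpkmMatrix <- function(study) {
  stopifnot(is(study, "ExpressionStudy"))
  rpkm(SummarizedExperiment::assay(study, "counts"), geneLengths(study))
}

#' Per-gene up/down direction calls from RPKM
#'
#' log2 fold change is computed on pseudocounted RPKM; the call is +1 when
#' log2fc exceeds log2(fcThreshold), -1 below -log2(fcThreshold), else 0.
#' Replicates should be averaged before calling.
#'
#' @param rpkmTreated,rpkmControl named numeric vectors of mean RPKM.
#' @param fcThreshold fold-change threshold (> 1).
#' @param pseudocount added to both RPKM values before the ratio.
#' @return data.frame with columns \code{gene_id, log2fc, call}.
#' @export
callDirection <- function(rpkmTreated, rpkmControl, fcThreshold = 1.5,
                          pseudocount = 0.1) {
  stopifnot(fcThreshold > 1, pseudocount > 0,
            length(rpkmTreated) == length(rpkmControl))
  lfc <- log2((rpkmTreated + pseudocount) / (rpkmControl + pseudocount))
  thr <- log2(fcThreshold)
  call <- ifelse(lfc > thr, 1L, ifelse(lfc < -thr, -1L, 0L))
  data.frame(gene_id = names(rpkmTreated) %||%
               paste0("gene", seq_along(lfc)),
             log2fc = unname(lfc), call = unname(call))
}

#' Group expression profile: response score and expression sum
#'
#' The response score sums the +-1 member calls (an integer in [-n, +n]);
#' the group expression is the sum of member RPKM.
#'
#' @param group a single group (one-element GRanges from [detectGroups()]).
#' @param calls data.frame from [callDirection()] (or a named +-1/0
#'   vector).
#' @param rpkmValues named per-gene RPKM vector.
#' @return one-row data.frame with columns \code{label, n_members,
#'   sum_expression, response_score}.
#' @export
groupProfile <- function(group, calls, rpkmValues) {
  stopifnot(length(group) == 1L)
  members <- unlist(group$member_ids)
  if (is.data.frame(calls))
    calls <- stats::setNames(calls$call, calls$gene_id)
  missing <- setdiff(members, intersect(names(calls), names(rpkmValues)))
  if (length(missing))
    stop("group members missing from expression tables: ",
         paste(missing, collapse = ", "), call. = FALSE)
  data.frame(label = group$label, n_members = length(members),
             sum_expression = sum(rpkmValues[members]),
             response_score = as.integer(sum(calls[members])))
}

#' Profiles for every detected group
#'
#' @param groups GRanges from [detectGroups()].
#' @inheritParams groupProfile
#' @return data.frame with one row per group.
#' @export
groupProfiles <- function(groups, calls, rpkmValues) {
  do.call(rbind, lapply(seq_along(groups), function(i)
    groupProfile(groups[i], calls, rpkmValues)))
}

#' qPCR relative fold change, 2^(-ddCt)
#'
#' @param deltaDeltaCt finite ddCt value(s).
#' @return fold change(s).
#' @examples
#' ddctFoldChange(-2)  # 4
#' @export
ddctFoldChange <- function(deltaDeltaCt) {
  stopifnot(all(is.finite(deltaDeltaCt)))
  2^(-deltaDeltaCt)
}
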