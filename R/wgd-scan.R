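# Paralogue pair construction with reciprocal-best-hit and c-score filters,
# and Ks / 4DTv distributions with KDE peak detection for WGD signatures.

#' Reciprocal-best-hit paralogue pairs with c-score filtering
#'
#' Self-hits are removed; the best non-self hit of each query is chosen by
#' bitscore (ties broken by lower e-value, then lexicographic subject id);
#' the c-score of a hit is its bitscore divided by the query's best
#' non-self bitscore. An unordered pair is kept iff each gene is the
#' other's best hit and both directed rows pass all three filters:
#' e-value <= \code{evalueMax}, c-score >= \code{cMin}, alignment length >=
#' \code{alnMin}.
#'
#' @param hits data.frame with columns \code{query, subject, bitscore,
#'   evalue, aln_length} (see [readSimilarityHits()]).
#' @param evalueMax e-value threshold.
#' @param cMin c-score threshold.
#' @param alnMin alignment length threshold (amino acids).
#' @return data.frame of pairs with columns \code{gene_a, gene_b, bitscore,
#'   evalue, aln_length, c_score, source}; \code{gene_a < gene_b}. The
#'   recorded bitscore is the larger, the e-value the larger (worse), the
#'   alignment length and c-score the smaller of the two directed rows.
#' @export
rbhPairs <- function(hits, evalueMax = 1e-5, cMin = 0.3, alnMin = 100) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      bitscore = numeric(), evalue = numeric(),
                      aln_length = numeric(), c_score = numeric(),
                      source = character())
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  # deterministic best hit per query: bitscore desc, evalue asc, subject asc
  ord <- order(hits$query, -hits$bitscore, hits$evalue, hits$subject)
  h <- hits[ord, , drop = FALSE]
  bestIdx <- !duplicated(h$query)
  best <- h[bestIdx, , drop = FALSE]
  bestScore <- stats::setNames(best$bitscore, best$query)
  bestSubject <- stats::setNames(best$subject, best$query)
  best$c_score <- best$bitscore / bestScore[best$query]
  keep <- character(0)
  rows <- list()
  for (q in best$query) {
    s <- bestSubject[[q]]
    if (q >= s) next                       # handle each unordered pair once
    if (is.na(bestSubject[s]) || bestSubject[[s]] != q) next
    rq <- best[best$query == q, ]
    rs <- best[best$query == s, ]
    okFilters <- all(c(rq$evalue, rs$evalue) <= evalueMax) &&
      all(c(rq$c_score, rs$c_score) >= cMin) &&
      all(c(rq$aln_length, rs$aln_length) >= alnMin)
    if (!okFilters) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = q, gene_b = s,
      bitscore = max(rq$bitscore, rs$bitscore),
      evalue = max(rq$evalue, rs$evalue),
      aln_length = min(rq$aln_length, rs$aln_length),
      c_score = min(rq$c_score, rs$c_score),
      source = "rbh")
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Detect density peaks in a divergence distribution
#'
#' Gaussian KDE with the Silverman rule-of-thumb bandwidth on a 512-point
#' grid; peaks are sign changes of the density derivative, returned in
#' descending density order.
#'
#' @param values numeric vector; non-finite values are excluded and
#'   counted as saturated.
#' @param binWidth display histogram bin width recorded in the report.
#' @param minValues minimum number of finite values required.
#' @return a [PeakReport-class].
#' @export
findDensityPeaks <- function(values, binWidth = 0.05, minValues = 10L) {
  finite <- values[is.finite(values)]
  nSat <- length(values) - length(finite)
  if (length(finite) < minValues)
    .tmError(paste0("peak detection refused: only ", length(finite),
                    " finite values (need >= ", minValues, ")"),
             "tm_insufficient_data_error")
  if (stats::sd(finite) == 0) {
    # degenerate distribution: single peak at the common value
    return(new("PeakReport", values = finite, bandwidth = 0,
               peaks = data.frame(location = finite[1L],
                                  density = Inf),
               binWidth = binWidth, nSaturated = as.integer(nSat)))
  }
  d <- stats::density(finite, bw = "nrd0", n = 512L)
  dy <- diff(d$y)
  loc <- which(diff(sign(dy)) == -2) + 1L
  pk <- data.frame(location = d$x[loc], density = d$y[loc])
  pk <- pk[order(-pk$density), , drop = FALSE]
  rownames(pk) <- NULL
  new("PeakReport", values = finite, bandwidth = d$bw, peaks = pk,
      binWidth = binWidth, nSaturated = as.integer(nSat))
}

# resolve the (pairs, alignments) calling conventions and apply a per-pair
# statistic; `pairs` may be NULL/omitted when a cohort list is given
.pairValues <- function(pairs, alignments, statFun) {
  if (is.null(alignments)) {
    alignments <- pairs
    pairs <- NULL
  }
  if (is.data.frame(pairs)) {
    if (nrow(pairs) == 0L)
      .tmError("empty pair set", "tm_insufficient_data_error")
    key <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
    if (!all(key %in% names(alignments)))
      .tmError("every pair needs a codon alignment named '<a>|<b>'",
               "tm_parse_error")
    alignments <- alignments[key]
  }
  if (length(alignments) == 0L)
    .tmError("empty pair set", "tm_insufficient_data_error")
  vapply(alignments, statFun, numeric(1))
}

#' Ks distribution of a paralogue cohort with peak detection
#'
#' Per-pair Ks via NG86 ([ng86()]); saturated pairs are excluded and
#' counted in the report.
#'
#' @param pairs data.frame from [rbhPairs()] (or a syntenic pair table with
#'   columns \code{gene_a}, \code{gene_b}); may be omitted by passing the
#'   alignments as an unnamed cohort list.
#' @param alignments named list of [CodonPairAlignment-class] objects keyed
#'   \code{"<gene_a>|<gene_b>"}, or an arbitrary list when \code{pairs} is
#'   a list cohort.
#' @param binWidth display histogram bin width.
#' @return a [PeakReport-class].
#' @export
ksDistribution <- function(pairs, alignments = NULL, binWidth = 0.05) {
  ks <- .pairValues(pairs, alignments,
                    function(a) suppressWarnings(ng86(a)$Ks))
  findDensityPeaks(ks, binWidth = binWidth)
}

#' 4DTv distribution of a paralogue cohort with peak detection
#'
#' As [ksDistribution()] but using the fourfold-degenerate transversion
#' rate ([fourDTv()]).
#'
#' @inheritParams ksDistribution
#' @return a [PeakReport-class].
#' @export
fourDTvDistribution <- function(pairs, alignments = NULL, binWidth = 0.05) {
  vals <- .pairValues(pairs, alignments,
                      function(a) fourDTv(a)[["fourDTv"]])
  findDensityPeaks(vals, binWidth = binWidth)
}
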