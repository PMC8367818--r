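# Dating LTR retrotransposon insertions from the divergence of their two
# terminal repeats, which are identical at insertion time.

#' Kimura two-parameter distance between two aligned sequences
#'
#' P and Q are the transition and transversion proportions over comparable
#' sites (positions where either sequence has N are skipped from numerator
#' and denominator); D = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q).
#'
#' @param ltr5,ltr3 equal-length aligned sequences (ACGTN), or pass a
#'   single [LTRElement-class] as \code{ltr5}.
#' @return named numeric vector \code{c(P =, Q =, D =, sites =)}.
#' @examples
#' el <- simulateLtrPair(1000, 5e6, seed = 7)
#' k2pDistance(el)
#' @export
k2pDistance <- function(ltr5, ltr3 = NULL) {
  if (is(ltr5, "LTRElement")) {
    ltr3 <- ltr5@ltr3
    ltr5 <- ltr5@ltr5
  }
  a <- .chars(toupper(ltr5))
  b <- .chars(toupper(ltr3))
  if (length(a) != length(b))
    .tmError("aligned sequences must have equal length", "tm_length_error")
  keep <- a %in% .BASES & b %in% .BASES
  n <- sum(keep)
  if (n < 100L)
    .tmError("fewer than 100 comparable sites", "tm_length_error")
  a <- a[keep]; b <- b[keep]
  ts <- .isTransitionVec(a, b)
  P <- sum(ts) / n
  Q <- sum(a != b & !ts) / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    .tmError("K2P distance saturated (log argument <= 0)",
             "tm_saturation_error")
  D <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  c(P = P, Q = Q, D = D, sites = n)
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' Single-rate fallback: D = -(3/4) log(1 - (4/3) p) with p the proportion
#' of differing comparable sites.
#'
#' @inheritParams k2pDistance
#' @return named numeric vector \code{c(p =, D =, sites =)}.
#' @export
jcDistance <- function(ltr5, ltr3 = NULL) {
  if (is(ltr5, "LTRElement")) {
    ltr3 <- ltr5@ltr3
    ltr5 <- ltr5@ltr5
  }
  a <- .chars(toupper(ltr5))
  b <- .chars(toupper(ltr3))
  if (length(a) != length(b))
    .tmError("aligned sequences must have equal length", "tm_length_error")
  keep <- a %in% .BASES & b %in% .BASES
  n <- sum(keep)
  if (n < 100L)
    .tmError("fewer than 100 comparable sites", "tm_length_error")
  p <- sum(a[keep] != b[keep]) / n
  if (p >= 3 / 4)
    .tmError("JC distance saturated", "tm_saturation_error")
  c(p = p, D = -3 / 4 * log(1 - 4 / 3 * p), sites = n)
}

#' Estimate the insertion age of an LTR element
#'
#' Applies the molecular clock T = D / (2 mu) to the divergence of the two
#' terminal repeats.
#'
#' @param element an [LTRElement-class].
#' @param mu neutral mutation rate per site per year (override per species,
#'   e.g. \code{RICE_MU}).
#' @param model distance correction, \code{"k2p"} (default) or \code{"jc"}.
#' @return one-row data.frame with columns \code{element_id, P, Q, D, T}
#'   (P and Q are NA under the JC model).
#' @export
insertionTime <- function(element, mu = TAXUS_MU, model = c("k2p", "jc")) {
  stopifnot(is(element, "LTRElement"), mu > 0)
  model <- match.arg(model)
  if (model == "k2p") {
    d <- k2pDistance(element)
    data.frame(element_id = element@elementId, P = d[["P"]], Q = d[["Q"]],
               D = d[["D"]], T = d[["D"]] / (2 * mu))
  } else {
    d <- jcDistance(element)
    data.frame(element_id = element@elementId, P = NA_real_, Q = NA_real_,
               D = d[["D"]], T = d[["D"]] / (2 * mu))
  }
}

#' Insertion ages for a cohort of LTR elements
#'
#' @param elements list of [LTRElement-class] objects.
#' @inheritParams insertionTime
#' @return data.frame with one row per dateable element plus an attribute
#'   \code{saturated} listing element ids whose distance saturated.
#' @export
insertionTimes <- function(elements, mu = TAXUS_MU, model = c("k2p", "jc")) {
  model <- match.arg(model)
  rows <- list()
  sat <- character()
  for (el in elements) {
    r <- tryCatch(insertionTime(el, mu, model), tm_saturation_error =
                    function(e) NULL)
    if (is.null(r)) sat <- c(sat, el@elementId)
    else rows[[length(rows) + 1L]] <- r
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(element_id = character(), P = numeric(),
                         Q = numeric(), D = numeric(), T = numeric())
  attr(out, "saturated") <- sat
  out
}

#' Histogram of LTR insertion ages
#'
#' Bins ages into \code{[0, binWidth)}, \code{[binWidth, 2 binWidth)}, ...
#' up to \code{maxAge}; ages beyond \code{maxAge} and saturated elements
#' are reported separately. Fractions are relative to all elements
#' (dateable plus saturated), so they sum to 1 with the overflow and
#' saturated classes.
#'
#' @param elements list of [LTRElement-class] objects, or a data.frame from
#'   [insertionTimes()].
#' @param binWidth bin width in years.
#' @param maxAge upper age bound in years.
#' @inheritParams insertionTime
#' @return list with \code{breaks}, \code{counts}, \code{fraction},
#'   \code{nOverflow}, \code{nSaturated}, \code{ages}.
#' @export
ageHistogram <- function(elements, binWidth, maxAge, mu = TAXUS_MU,
                         model = c("k2p", "jc")) {
  stopifnot(binWidth > 0, maxAge > binWidth)
  ages <- if (is.data.frame(elements)) elements
          else insertionTimes(elements, mu, match.arg(model))
  if (nrow(ages) == 0L)
    .tmError("no dateable elements", "tm_saturation_error")
  nSat <- length(attr(ages, "saturated") %||% character())
  breaks <- seq(0, maxAge, by = binWidth)
  if (breaks[length(breaks)] < maxAge) breaks <- c(breaks, maxAge)
  inRange <- ages$T <= maxAge
  counts <- as.vector(table(cut(ages$T[inRange], breaks, right = FALSE,
                                include.lowest = TRUE)))
  total <- nrow(ages) + nSat
  list(breaks = breaks, counts = counts, fraction = counts / total,
       nOverflow = sum(!inRange), nSaturated = nSat, ages = ages$T)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of insertions within an age window
#'
#' @param ages numeric ages in years (e.g. \code{ageHistogram(...)$ages}).
#' @param lo,hi window bounds in years (inclusive).
#' @return fraction of ages with \code{lo <= age <= hi}.
#' @examples
#' ageWindowFraction(c(1e6, 9e6, 12e6), 8e6, 24e6)
#' @export
ageWindowFraction <- function(ages, lo, hi) {
  stopifnot(hi >= lo, length(ages) > 0)
  mean(ages >= lo & ages <= hi)
}
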