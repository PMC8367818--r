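#' @importFrom Biostrings GENETIC_CODE
NULL

# ---- genetic-code machinery (standard code, cached lookup tables) ----------

.tmCache <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")

.senseCodons <- function() {
  cods <- names(Biostrings::GENETIC_CODE)
  cods[!cods %in% .STOP_CODONS]
}

.translate1 <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# Per-codon synonymous site count: at each position, the fraction of
# single-base changes that are synonymous, with changes to stop codons
# removed from the denominator (standard NG86 practice).
.codonSynSites <- function(codon) {
  ch <- .chars(codon)
  aa <- .translate1(codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0L
    den <- 0L
    for (b in setdiff(.BASES, ch[pos])) {
      mut <- ch
      mut[pos] <- b
      mutc <- paste(mut, collapse = "")
      if (mutc %in% .STOP_CODONS) next
      den <- den + 1L
      if (.translate1(mutc) == aa) syn <- syn + 1L
    }
    if (den > 0L) s <- s + syn / den
  }
  s
}

# Equal-weight pathway averaging of synonymous/nonsynonymous differences
# between two codons. Pathways passing through a stop codon are excluded;
# if no pathway avoids stops the average falls back to all pathways and the
# pair is flagged.
.codonPairDiffs <- function(c1, c2) {
  ch1 <- .chars(c1)
  ch2 <- .chars(c2)
  pos <- which(ch1 != ch2)
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0, flagged = 0))
  perms <- switch(k,
    `1` = list(pos),
    `2` = list(pos, rev(pos)),
    `3` = {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  walk <- function(order) {
    cur <- ch1
    syn <- 0L; non <- 0L
    for (p in order) {
      nxt <- cur
      nxt[p] <- ch2[p]
      curc <- paste(cur, collapse = "")
      nxtc <- paste(nxt, collapse = "")
      if (nxtc %in% .STOP_CODONS) return(NULL)   # stop-crossing pathway
      if (.translate1(curc) == .translate1(nxtc)) syn <- syn + 1L
      else non <- non + 1L
      cur <- nxt
    }
    c(syn, non)
  }
  res <- lapply(perms, walk)
  ok <- !vapply(res, is.null, logical(1))
  flagged <- 0
  if (!any(ok)) {
    # endpoints are sense codons, so this needs every ordering to cross a
    # stop; average over all orderings counting the stop step as observed
    walkAll <- function(order) {
      cur <- ch1
      syn <- 0L; non <- 0L
      for (p in order) {
        nxt <- cur
        nxt[p] <- ch2[p]
        if (.translate1(paste(cur, collapse = "")) ==
            .translate1(paste(nxt, collapse = ""))) syn <- syn + 1L
        else non <- non + 1L
        cur <- nxt
      }
      c(syn, non)
    }
    res <- lapply(perms, walkAll)
    ok <- rep(TRUE, length(res))
    flagged <- 1
  }
  m <- do.call(rbind, res[ok])
  c(sd = mean(m[, 1]), nd = mean(m[, 2]), flagged = flagged)
}

# lazily built lookup tables over the 61 sense codons
.ngTables <- function() {
  if (!is.null(.tmCache$sites)) return(.tmCache)
  sense <- .senseCodons()
  sites <- vapply(sense, .codonSynSites, numeric(1))
  n <- length(sense)
  sd <- matrix(0, n, n, dimnames = list(sense, sense))
  nd <- matrix(0, n, n, dimnames = list(sense, sense))
  fl <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- .codonPairDiffs(sense[i], sense[j])
      sd[i, j] <- d[["sd"]]
      nd[i, j] <- d[["nd"]]
      fl[i, j] <- d[["flagged"]]
    }
  }
  .tmCache$sites <- sites
  .tmCache$sd <- sd
  .tmCache$nd <- nd
  .tmCache$flagged <- fl
  .tmCache
}

# ---- exported operations ---------------------------------------------------

#' Count synonymous and nonsynonymous sites (NG86)
#'
#' Fractional site counting following Nei & Gojobori (1986): at each codon
#' position the synonymous site fraction is the proportion of single-base
#' changes that preserve the amino acid, with changes to stop codons
#' excluded from the denominator. S is averaged over the two sequences and
#' N = 3L - S, so S + N always equals three times the codon count.
#'
#' @param pair a [CodonPairAlignment-class].
#' @return named numeric vector \code{c(S =, N =)}.
#' @examples
#' countSites(CodonPairAlignment("TTTGGGGGG", "TTTGGGGGG"))  # S = 7/3
#' @export
countSites <- function(pair) {
  stopifnot(is(pair, "CodonPairAlignment"))
  tab <- .ngTables()
  sA <- sum(tab$sites[pair@codonsA])
  sB <- sum(tab$sites[pair@codonsB])
  S <- (sA + sB) / 2
  c(S = S, N = 3 * length(pair) - S)
}

#' Count synonymous and nonsynonymous differences (NG86)
#'
#' Codons differing at k positions are scored by averaging the
#' synonymous/nonsynonymous step assignments over all k! orderings of
#' single-base steps; orderings that pass through a stop codon are excluded
#' from the average. Sd + Nd equals the number of differing positions.
#'
#' @param pair a [CodonPairAlignment-class].
#' @return named numeric vector \code{c(Sd =, Nd =)}.
#' @export
countDifferences <- function(pair) {
  stopifnot(is(pair, "CodonPairAlignment"))
  tab <- .ngTables()
  idx <- cbind(pair@codonsA, pair@codonsB)
  sd <- sum(tab$sd[idx])
  nd <- sum(tab$nd[idx])
  nflag <- sum(tab$flagged[idx])
  if (nflag > 0)
    warning(nflag, " codon(s) had only stop-crossing pathways; ",
            "averaged over all orderings")
  c(Sd = sd, Nd = nd)
}

#' NG86 Ka/Ks estimate with Jukes-Cantor correction
#'
#' Computes S, N, Sd, Nd, the proportions pS = Sd/S and pN = Nd/N, and the
#' Jukes-Cantor corrected rates Ks = -(3/4) log(1 - (4/3) pS) (Ka
#' analogously). A proportion at or beyond the JC saturation bound 3/4
#' yields an NA rate with the corresponding \code{*Saturated} flag set;
#' S = 0 or N = 0 yields an NA proportion (flag NA), never a silent zero.
#' The 4DTv transversion rate at fourfold-degenerate sites is included.
#'
#' @param pair a [CodonPairAlignment-class].
#' @return one-row data.frame with columns \code{S, N, Sd, Nd, pS, pN, Ks,
#'   Ka, ksSaturated, kaSaturated, fourDTv, n4dSites}.
#' @examples
#' ng86(CodonPairAlignment("TTTGGGGGG", "TTCGGGGGG"))  # Ks = -0.75 log(3/7)
#' @export
ng86 <- function(pair) {
  sn <- countSites(pair)
  dd <- countDifferences(pair)
  jc <- function(p) {
    if (!is.finite(p)) return(list(k = NA_real_, sat = NA))
    if (p >= 3 / 4) return(list(k = NA_real_, sat = TRUE))
    list(k = -3 / 4 * log(1 - 4 / 3 * p), sat = FALSE)
  }
  pS <- if (sn[["S"]] > 0) dd[["Sd"]] / sn[["S"]] else NA_real_
  pN <- if (sn[["N"]] > 0) dd[["Nd"]] / sn[["N"]] else NA_real_
  ks <- jc(pS)
  ka <- jc(pN)
  ft <- fourDTv(pair)
  data.frame(S = sn[["S"]], N = sn[["N"]], Sd = dd[["Sd"]], Nd = dd[["Nd"]],
             pS = pS, pN = pN, Ks = ks$k, Ka = ka$k,
             ksSaturated = ks$sat, kaSaturated = ka$sat,
             fourDTv = ft[["fourDTv"]], n4dSites = ft[["n4dSites"]])
}

# prefixes whose four third-position codons encode one amino acid
.fourfoldPrefixes <- function() {
  if (!is.null(.tmCache$ffpref)) return(.tmCache$ffpref)
  prefs <- apply(expand.grid(.BASES, .BASES), 1L, paste, collapse = "")
  ff <- prefs[vapply(prefs, function(p) {
    aas <- .translate1(paste0(p, .BASES))
    !any(paste0(p, .BASES) %in% .STOP_CODONS) && length(unique(aas)) == 1L
  }, logical(1))]
  .tmCache$ffpref <- ff
  ff
}

#' Transversion rate at fourfold-degenerate third positions (4DTv)
#'
#' A third-codon position qualifies when both codons share identical first
#' two bases and that prefix is fourfold degenerate. 4DTv is the fraction
#' of qualifying sites whose third bases differ by a transversion
#' (purine vs pyrimidine); the proportion is reported uncorrected.
#'
#' @param pair a [CodonPairAlignment-class].
#' @return named numeric vector \code{c(fourDTv =, n4dSites =)};
#'   \code{fourDTv} is NA when no site qualifies.
#' @export
fourDTv <- function(pair) {
  stopifnot(is(pair, "CodonPairAlignment"))
  prefA <- substr(pair@codonsA, 1L, 2L)
  prefB <- substr(pair@codonsB, 1L, 2L)
  qual <- prefA == prefB & prefA %in% .fourfoldPrefixes()
  n4d <- sum(qual)
  if (n4d == 0L)
    return(c(fourDTv = NA_real_, n4dSites = 0))
  tA <- substr(pair@codonsA[qual], 3L, 3L)
  tB <- substr(pair@codonsB[qual], 3L, 3L)
  ntv <- sum(.isTransitionVec(tA, tB) == FALSE & tA != tB)
  c(fourDTv = ntv / n4d, n4dSites = n4d)
}

#' Neutral mutation rate used for the molecular clock (per site per year)
#'
#' Default slow gymnosperm rate used throughout; the rice rate
#' \code{RICE_MU} illustrates how strongly the clock rescales ages.
#' @export
TAXUS_MU <- 7.34573e-10

#' @rdname TAXUS_MU
#' @export
RICE_MU <- 1.8e-8

#' Convert a synonymous divergence to an age
#'
#' Molecular-clock conversion T = Ks / (2 mu): the divergence accumulated
#' along both lineages since duplication, divided by twice the per-lineage
#' neutral rate.
#'
#' @param ks synonymous substitutions per synonymous site (finite, >= 0).
#' @param mu neutral mutation rate per site per year.
#' @return age in years.
#' @examples
#' ksToAge(0.00300677) / 1e6  # about 2.05 Ma
#' @export
ksToAge <- function(ks, mu = TAXUS_MU) {
  if (any(!is.finite(ks)) || any(ks < 0))
    stop("ks must be finite and non-negative (saturated estimates cannot ",
         "be dated)", call. = FALSE)
  stopifnot(mu > 0)
  ks / (2 * mu)
}
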