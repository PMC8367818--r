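# Three-round subtraction screening for candidate pathway genes:
# (1) tissue filter (root/bark over leaf), (2) HC vs LC differential
# expression with an NB exact conditional count test, (3) anchor-gene
# Pearson correlation over the jasmonate time course.

#' Round 1: tissue subtraction filter
#'
#' Keeps genes whose mean RPKM is higher in root or in bark than in leaf,
#' subject to a minimum-expression floor on the maximal tissue mean.
#'
#' @param study an [ExpressionStudy-class] containing root, leaf and bark
#'   samples.
#' @param floor minimum maximal-tissue mean RPKM for a gene to be
#'   considered expressed.
#' @return character vector of surviving gene ids.
#' @export
round1TissueFilter <- function(study, floor = 1) {
  cd <- sampleInfo(study)
  rk <- rpkmMatrix(study)
  tiss <- c("root", "bark", "leaf")
  idx <- lapply(tiss, function(t)
    which(!is.na(cd$tissue) & cd$tissue == t))
  names(idx) <- tiss
  missing <- tiss[lengths(idx) == 0L]
  if (length(missing))
    stop("missing tissue samples: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- vapply(idx, function(i) rowMeans(rk[, i, drop = FALSE]),
              numeric(nrow(rk)))
  keep <- (m[, "root"] > m[, "leaf"] | m[, "bark"] > m[, "leaf"]) &
    apply(m, 1L, max) >= floor
  rownames(rk)[keep]
}

# Exact conditional two-sample count test for equal-library-size groups.
# Under a common NB(mu, phi) model, the group sums are NB(n_i mu, phi/n_i);
# conditioning on the total gives an exact double-tail p-value (the
# classic exact NB test). phi ~ 0 reduces to the conditional binomial.
.nbExactTest <- function(t1, t2, n1, n2, phi) {
  tt <- t1 + t2
  if (tt == 0L) return(NA_real_)
  if (phi < 1e-8) {
    pr <- stats::dbinom(0:tt, tt, n1 / (n1 + n2))
  } else {
    muH0 <- tt / (n1 + n2)
    p1 <- stats::dnbinom(0:tt, size = n1 / phi, mu = n1 * muH0)
    p2 <- stats::dnbinom(tt:0, size = n2 / phi, mu = n2 * muH0)
    pr <- p1 * p2
    s <- sum(pr)
    if (s <= 0) return(NA_real_)
    pr <- pr / s
  }
  sum(pr[pr <= pr[t1 + 1L] * (1 + 1e-7)])
}

#' Round 2: HC vs LC differential expression
#'
#' Per-gene two-sample test on library-size-adjusted counts under a
#' negative-binomial model with a method-of-moments common dispersion,
#' using an exact conditional double-tail test on the group sums (an exact
#' conditional binomial test when the dispersion estimate is ~0). P-values
#' are Benjamini-Hochberg adjusted across tested genes; survivors satisfy
#' log2fc > \code{logfcMin} (HC over LC, CPM with pseudocount) and
#' fdr < \code{fdrMax}. All-zero genes are excluded from testing and
#' reported.
#'
#' @param study an [ExpressionStudy-class] with HC and LC control samples
#'   (>= 2 replicates each).
#' @param logfcMin signed log2 fold-change threshold (HC over LC).
#' @param fdrMax BH-adjusted p-value threshold.
#' @param pseudocount CPM pseudocount for the fold change.
#' @return list with \code{results} (data.frame \code{gene_id, log2fc,
#'   pvalue, fdr}), \code{survivors} (gene ids), \code{excluded} (all-zero
#'   gene ids) and \code{dispersion} (the common MoM estimate).
#' @export
round2HcLcDe <- function(study, logfcMin = 1, fdrMax = 0.05,
                         pseudocount = 0.5) {
  cd <- sampleInfo(study)
  hc <- which(!is.na(cd$line) & cd$line == "HC" & cd$treatment == "control")
  lc <- which(!is.na(cd$line) & cd$line == "LC" & cd$treatment == "control")
  if (length(hc) < 2L || length(lc) < 2L)
    stop("need >= 2 replicates per cell line", call. = FALSE)
  counts <- SummarizedExperiment::assay(study, "counts")[, c(hc, lc),
                                                         drop = FALSE]
  grp <- rep(c("HC", "LC"), c(length(hc), length(lc)))
  libs <- colSums(counts)
  excluded <- rownames(counts)[rowSums(counts) == 0L]
  counts <- counts[rowSums(counts) > 0L, , drop = FALSE]
  gm <- exp(mean(log(libs)))
  adj <- round(sweep(counts, 2L, gm / libs, "*"))
  iH <- grp == "HC"
  m1 <- rowMeans(adj[, iH, drop = FALSE])
  m2 <- rowMeans(adj[, !iH, drop = FALSE])
  v1 <- apply(adj[, iH, drop = FALSE], 1L, stats::var)
  v2 <- apply(adj[, !iH, drop = FALSE], 1L, stats::var)
  mbar <- (m1 + m2) / 2
  s2w <- (v1 + v2) / 2
  # pooled method-of-moments common dispersion: least-squares fit of the
  # quadratic mean-variance relation v = m + phi m^2 across genes
  usable <- is.finite(s2w) & mbar >= 1
  phi <- max(0, sum(s2w[usable] - mbar[usable]) / sum(mbar[usable]^2))
  t1 <- rowSums(adj[, iH, drop = FALSE])
  t2 <- rowSums(adj[, !iH, drop = FALSE])
  pval <- vapply(seq_len(nrow(adj)), function(g)
    .nbExactTest(t1[g], t2[g], sum(iH), sum(!iH), phi), numeric(1))
  cpm <- sweep(counts, 2L, libs, "/") * 1e6
  lfc <- log2((rowMeans(cpm[, iH, drop = FALSE]) + pseudocount) /
              (rowMeans(cpm[, !iH, drop = FALSE]) + pseudocount))
  fdr <- stats::p.adjust(pval, method = "BH")
  res <- data.frame(gene_id = rownames(counts), log2fc = unname(lfc),
                    pvalue = unname(pval), fdr = unname(fdr))
  surv <- res$gene_id[!is.na(res$pvalue) & res$log2fc > logfcMin &
                      res$fdr < fdrMax]
  list(results = res, survivors = surv, excluded = excluded,
       dispersion = phi)
}

#' Round 3: anchor-gene Pearson correlation over the jasmonate course
#'
#' Replicates are averaged per time point (0, 2, 4, 8, 24 h, n = 5
#' values); for each anchor-candidate pair the Pearson correlation and its
#' two-sided t-test p-value (t = r sqrt(n-2)/sqrt(1-r^2), df = n - 2) are
#' computed and pairs with p < \code{pMax} are kept. Zero-variance series
#' are skipped and recorded.
#'
#' @param study an [ExpressionStudy-class] with MeJA time-course samples.
#' @param anchors anchor gene ids (known pathway genes).
#' @param candidates candidate gene ids (e.g. survivors of rounds 1 and
#'   2); anchors themselves are not tested against each other.
#' @param pMax p-value threshold.
#' @return data.frame of surviving edges with columns \code{anchor_id,
#'   candidate_id, r, pvalue}; attribute \code{skipped} lists
#'   zero-variance genes.
#' @export
round3AnchorCorrelation <- function(study, anchors, candidates,
                                    pMax = 0.05) {
  cd <- sampleInfo(study)
  mj <- which(cd$treatment == "MeJA" & !is.na(cd$time_h))
  if (length(mj) == 0L) stop("no MeJA time-course samples", call. = FALSE)
  tps <- sort(unique(cd$time_h[mj]))
  rk <- rpkmMatrix(study)[, mj, drop = FALSE]
  series <- vapply(tps, function(t)
    rowMeans(rk[, cd$time_h[mj] == t, drop = FALSE]),
    numeric(nrow(rk)))
  colnames(series) <- tps
  n <- length(tps)
  stopifnot(n >= 3L)
  candidates <- setdiff(candidates, anchors)
  ok <- rownames(series)
  anchors <- intersect(anchors, ok)
  candidates <- intersect(candidates, ok)
  novar <- rownames(series)[apply(series, 1L, stats::sd) == 0]
  skipA <- intersect(novar, c(anchors, candidates))
  anchors <- setdiff(anchors, novar)
  candidates <- setdiff(candidates, novar)
  rows <- list()
  for (a in anchors) {
    for (cand in candidates) {
      ct <- stats::cor.test(series[a, ], series[cand, ],
                            method = "pearson",
                            alternative = "two.sided")
      if (is.finite(ct$p.value) && ct$p.value < pMax)
        rows[[length(rows) + 1L]] <- data.frame(
          anchor_id = a, candidate_id = cand,
          r = unname(ct$estimate), pvalue = ct$p.value)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(anchor_id = character(),
                         candidate_id = character(), r = numeric(),
                         pvalue = numeric())
  attr(out, "skipped") <- skipA
  out
}

#' Assemble the coregulation network from screened edges
#'
#' Nodes are the anchors plus surviving candidates; a candidate correlated
#' with several anchors contributes one node and several edges.
#'
#' @param edges data.frame from [round3AnchorCorrelation()].
#' @param annotations optional named character vector mapping gene id to
#'   family label (e.g. "CYP725A").
#' @param tfIds,transferaseIds optional id sets flagged on the nodes.
#' @return list with \code{nodes} (data.frame \code{id, role, family,
#'   is_tf, is_transferase}) and \code{edges}.
#' @export
buildNetwork <- function(edges, annotations = NULL, tfIds = character(),
                         transferaseIds = character()) {
  anchors <- unique(edges$anchor_id)
  cands <- setdiff(unique(edges$candidate_id), anchors)
  ids <- c(anchors, cands)
  nodes <- data.frame(
    id = ids,
    role = rep(c("anchor", "candidate"), c(length(anchors), length(cands))),
    family = if (is.null(annotations)) rep(NA_character_, length(ids))
             else unname(annotations[ids]),
    is_tf = ids %in% tfIds,
    is_transferase = ids %in% transferaseIds)
  list(nodes = nodes, edges = edges)
}
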