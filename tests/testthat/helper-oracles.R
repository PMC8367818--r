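# Independent brute-force oracles, coded from first principles and kept
# separate from the package implementations they check.

.oStops <- c("TAA", "TAG", "TGA")
.oCode <- Biostrings::GENETIC_CODE
.oAA <- function(codon) unname(.oCode[codon])
.oBases <- c("A", "C", "G", "T")

# fractional synonymous sites of one codon, stop mutations dropped from
# the per-position denominator
oracleCodonS <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0; den <- 0
    for (b in .oBases) {
      if (b == ch[pos]) next
      mut <- ch; mut[pos] <- b
      mc <- paste(mut, collapse = "")
      if (mc %in% .oStops) next
      den <- den + 1
      if (.oAA(mc) == .oAA(codon)) syn <- syn + 1
    }
    if (den > 0) total <- total + syn / den
  }
  total
}

# recursive enumeration of substitution pathways between two codons,
# excluding stop-crossing pathways (falling back to all pathways when none
# survive, mirroring the documented degenerate-case behaviour)
oracleCodonDiffs <- function(c1, c2, allowStops = FALSE) {
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  acc <- list()
  recur <- function(cur, remaining, syn, non) {
    if (!length(remaining)) {
      acc[[length(acc) + 1]] <<- c(syn, non)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur; nxt[p] <- ch2[p]
      nc <- paste(nxt, collapse = "")
      if (!allowStops && nc %in% .oStops) next
      same <- .oAA(paste(cur, collapse = "")) == .oAA(nc)
      recur(nxt, setdiff(remaining, p), syn + same, non + !same)
    }
  }
  recur(ch1, which(ch1 != ch2), 0, 0)
  if (!length(acc)) return(oracleCodonDiffs(c1, c2, allowStops = TRUE))
  m <- do.call(rbind, acc)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

oracleNG86 <- function(codonsA, codonsB) {
  S <- (sum(vapply(codonsA, oracleCodonS, 0)) +
        sum(vapply(codonsB, oracleCodonS, 0))) / 2
  N <- 3 * length(codonsA) - S
  d <- rowSums(vapply(seq_along(codonsA), function(i)
    oracleCodonDiffs(codonsA[i], codonsB[i]), numeric(2)))
  pS <- if (S > 0) d[["sd"]] / S else NA_real_
  pN <- if (N > 0) d[["nd"]] / N else NA_real_
  jc <- function(p) if (!is.finite(p) || p >= 0.75) NA_real_
                    else -0.75 * log(1 - 4 / 3 * p)
  list(S = S, N = N, Sd = d[["sd"]], Nd = d[["nd"]],
       Ks = jc(pS), Ka = jc(pN))
}

# exhaustive reciprocal-best-hit oracle over a directed hit table
oracleRBH <- function(hits, evalueMax = 1e-5, cMin = 0.3, alnMin = 100) {
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  bestRow <- function(q) {
    h <- hits[hits$query == q, , drop = FALSE]
    if (!nrow(h)) return(NULL)
    h <- h[order(-h$bitscore, h$evalue, h$subject), , drop = FALSE]
    h[1, , drop = FALSE]
  }
  out <- list()
  for (q in sort(unique(hits$query))) {
    rq <- bestRow(q)
    s <- rq$subject
    if (q >= s) next
    rs <- bestRow(s)
    if (is.null(rs) || rs$subject != q) next
    cq <- 1; cs <- 1  # best hit of its query by construction
    if (all(c(rq$evalue, rs$evalue) <= evalueMax) &&
        all(c(cq, cs) >= cMin) &&
        all(c(rq$aln_length, rs$aln_length) >= alnMin))
      out[[length(out) + 1]] <- c(q, s)
  }
  out
}

# enumerate all maximal same-chromosome runs satisfying both group criteria
oracleGroups <- function(df, maxGap, minSize) {
  out <- list()
  for (chr in unique(df$chrom)) {
    g <- df[df$chrom == chr, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    n <- nrow(g)
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (j - i + 1 < minSize) next
        gapsOk <- TRUE
        if (j > i)
          for (k in i:(j - 1))
            if (max(0, g$start[k + 1] - g$end[k]) > maxGap) gapsOk <- FALSE
        if (!gapsOk) next
        leftOk <- i == 1 || max(0, g$start[i] - g$end[i - 1]) > maxGap
        rightOk <- j == n || max(0, g$start[j + 1] - g$end[j]) > maxGap
        if (leftOk && rightOk)
          out[[length(out) + 1]] <- g$gene_id[i:j]
      }
    }
  }
  out
}

# step-up Benjamini-Hochberg, computed literally from the definition
oracleBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[ord[j]] / j, 0)
    adj[ord[i]] <- min(1, min(vals))
  }
  adj
}

# random binary tree with branch lengths; returns tree + additive matrix
makeAdditiveCase <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  list(tree = ape::unroot(tr), d = stats::cophenetic(tr))
}

# small hand-built ExpressionStudy: one sample per named column spec
makeStudy <- function(counts, tissue = NA, line = NA, treatment = "control",
                      time_h = NA, replicate = 1, lengths = NULL) {
  ns <- ncol(counts)
  rec <- function(x) rep_len(x, ns)
  samples <- data.frame(tissue = rec(tissue), line = rec(line),
                        treatment = rec(treatment), time_h = rec(time_h),
                        replicate = rec(replicate))
  rownames(samples) <- colnames(counts)
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  ExpressionStudy(counts, stats::setNames(lengths, rownames(counts)),
                  samples)
}
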