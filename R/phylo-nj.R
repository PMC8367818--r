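# p-distance matrices and Saitou-Nei neighbour-joining trees with Newick
# round-trip, as used for protein-family phylogenies.

.alnToMatrix <- function(aln) {
  if (is(aln, "XStringSet")) {
    nm <- names(aln)
    aln <- as.character(aln)
    names(aln) <- nm
  }
  stopifnot(is.character(aln), length(aln) >= 2L)
  if (length(unique(nchar(aln))) != 1L)
    .tmError("aligned sequences must have equal length", "tm_length_error")
  if (is.null(names(aln)))
    names(aln) <- paste0("seq", seq_along(aln))
  m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

# characters treated as missing for pairwise deletion; N/X only for the
# matching alphabet (N is asparagine in protein alignments)
.missingChars <- function(m) {
  isDnaish <- mean(m %in% c("A", "C", "G", "T", "U", "N", "-", ".", "?")) >
    0.95
  if (isDnaish) c("-", ".", "?", "N") else c("-", ".", "?", "X")
}

#' Pairwise p-distance matrix from an alignment
#'
#' d = mismatches / compared sites with pairwise deletion of gap and
#' ambiguity columns; identical formula for nucleotide and protein
#' alignments.
#'
#' @param aln named character vector of equal-length aligned sequences, or
#'   a Biostrings \code{XStringSet}.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pDistance <- function(aln) {
  m <- .alnToMatrix(aln)
  miss <- .missingChars(m)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !(m[i, ] %in% miss) & !(m[j, ] %in% miss)
      if (!any(ok))
        .tmError(paste0("no comparable sites between ", rownames(m)[i],
                        " and ", rownames(m)[j]), "tm_length_error")
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimising
#' Q(i,j) = (r-2) d(i,j) - R(i) - R(j) is joined, with ties broken by the
#' lexicographically smallest pair of cluster labels; branch lengths use
#' the standard NJ formulas and the final three clusters are resolved by
#' the three-point formulas into the central trifurcation of the unrooted
#' tree. Negative branch-length estimates are clamped to zero and counted
#' in the \code{negativeClamped} attribute.
#'
#' @param d symmetric distance matrix with labelled rows/columns (or a
#'   \code{dist}); >= 3 taxa.
#' @return an unrooted \code{ape::phylo} tree.
#' @export
neighborJoining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L)
    .tmError("neighbour joining needs >= 3 taxa", "tm_length_error")
  if (!isSymmetric(unname(d)) || any(!is.finite(d)) ||
      any(abs(diag(d)) > 1e-12))
    .tmError("distance matrix must be symmetric, finite, zero-diagonal",
             "tm_parse_error")
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  nClamped <- 0L
  fmt <- function(v) {
    if (v < 0) nClamped <<- nClamped + 1L
    sprintf("%.10g", max(0, v))
  }
  # each active cluster: newick fragment + label used for tie-breaking;
  # placeholder tip tokens avoid Newick metacharacter issues, original
  # labels are restored after parsing
  origLabels <- rownames(d)
  frag <- as.list(sprintf("tmTip%d", seq_len(nrow(d))))
  lab <- rownames(d)
  while (length(lab) > 3L) {
    r <- length(lab)
    R <- rowSums(d)
    best <- NULL
    bestQ <- Inf
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        q <- (r - 2) * d[i, j] - R[i] - R[j]
        pair <- sort(c(lab[i], lab[j]))
        if (q < bestQ - 1e-12 ||
            (abs(q - bestQ) <= 1e-12 && !is.null(best) &&
             (pair[1L] < best$pair[1L] ||
              (pair[1L] == best$pair[1L] && pair[2L] < best$pair[2L])))) {
          best <- list(i = i, j = j, pair = pair)
          bestQ <- min(bestQ, q)
        }
      }
    }
    i <- best$i; j <- best$j
    vi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- d[i, j] - vi
    newFrag <- paste0("(", frag[[i]], ":", fmt(vi), ",",
                      frag[[j]], ":", fmt(vj), ")")
    newLab <- min(lab[i], lab[j])
    dNew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dNew[keep]),
                c(dNew[keep], 0))
    rownames(d2) <- colnames(d2) <- c(lab[keep], newLab)
    d <- d2
    frag <- c(frag[keep], list(newFrag))
    lab <- c(lab[keep], newLab)
  }
  # three-point resolution of the central node
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", frag[[1L]], ":", fmt(v1), ",", frag[[2L]], ":",
                fmt(v2), ",", frag[[3L]], ":", fmt(v3), ");")
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- origLabels[as.integer(sub("tmTip", "",
                                              tree$tip.label))]
  attr(tree, "negativeClamped") <- nClamped
  tree
}

#' Write / read Newick trees
#'
#' Thin wrappers around the ape Newick codec; labels containing spaces or
#' Newick metacharacters are single-quoted on output.
#'
#' @param tree an \code{ape::phylo}.
#' @param path file path.
#' @return \code{writeNewick} returns \code{path} invisibly;
#'   \code{readNewick} returns an \code{ape::phylo}.
#' @export
writeNewick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  # labels with Newick metacharacters go through placeholder tokens so the
  # ape serialiser cannot munge them, then come back single-quoted
  needQuote <- grepl("[ ,():;']", tree$tip.label)
  orig <- tree$tip.label
  tree$tip.label[needQuote] <- sprintf("tmQuoted%d", which(needQuote))
  txt <- ape::write.tree(tree)
  for (k in which(needQuote))
    txt <- sub(sprintf("tmQuoted%d", k),
               paste0("'", gsub("'", "''", orig[k]), "'"), txt,
               fixed = TRUE)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L)
    .tmError("empty or missing Newick file", "tm_parse_error")
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  # substitute single-quoted labels with placeholder tokens (the ape
  # parser does not support Newick quoting), restore after parsing
  qre <- "'((?:[^']|'')*)'"
  mm <- gregexpr(qre, txt)[[1L]]
  labels <- character(0)
  if (mm[1L] != -1L) {
    raw <- regmatches(txt, gregexpr(qre, txt))[[1L]]
    labels <- gsub("''", "'", substr(raw, 2L, nchar(raw) - 1L))
    for (k in seq_along(raw))
      txt <- sub(raw[k], sprintf("tmQuoted%d", k), txt, fixed = TRUE)
  }
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e)
    .tmError(paste("malformed Newick:", conditionMessage(e)),
             "tm_parse_error"))
  if (is.null(tree))
    .tmError("malformed Newick file", "tm_parse_error")
  if (length(labels)) {
    hit <- grepl("^tmQuoted[0-9]+$", tree$tip.label)
    idx <- as.integer(sub("tmQuoted", "", tree$tip.label[hit]))
    tree$tip.label[hit] <- labels[idx]
  }
  tree
}
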