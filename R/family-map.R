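# CYP450-style family classification by identity cutoffs, chromosome
# distribution statistics and physical gene-group detection.

#' Identity cutoffs for CYP450-style classification
#'
#' The conventional nomenclature thresholds: >= 97\% identity to a named
#' reference marks an allelic variant, >= 55\% the same subfamily,
#' >= 40\% the same family; below 40\% the query is unclassified (a
#' candidate new family).
#'
#' @param alleleMin,subfamilyMin,familyMin percent-identity cutoffs,
#'   strictly decreasing.
#' @return a \code{ClassificationRule} list.
#' @export
classificationRule <- function(alleleMin = 97, subfamilyMin = 55,
                               familyMin = 40) {
  stopifnot(alleleMin > subfamilyMin, subfamilyMin > familyMin)
  structure(list(alleleMin = alleleMin, subfamilyMin = subfamilyMin,
                 familyMin = familyMin), class = "ClassificationRule")
}

#' Classify a gene against named references by percent identity
#'
#' Takes the best-identity reference (ties broken by identity then
#' reference name) and assigns the query at the deepest level its identity
#' supports.
#'
#' @param queryId query gene id.
#' @param identities data.frame with columns \code{reference},
#'   \code{identity} (percent) and optionally \code{family},
#'   \code{subfamily} naming each reference's membership.
#' @param rule a [classificationRule()].
#' @return one-row data.frame with columns \code{query, level} (one of
#'   \code{allele-of, subfamily-of, family-of, unclassified}),
#'   \code{reference, identity, family, subfamily}.
#' @export
classifyByIdentity <- function(queryId, identities,
                               rule = classificationRule()) {
  blank <- data.frame(query = queryId, level = "unclassified",
                      reference = NA_character_, identity = NA_real_,
                      family = NA_character_, subfamily = NA_character_)
  if (is.null(identities) || nrow(identities) == 0L) {
    warning("empty identity table for ", queryId, "; unclassified")
    return(blank)
  }
  ord <- order(-identities$identity, identities$reference)
  best <- identities[ord[1L], , drop = FALSE]
  fam <- if ("family" %in% colnames(best)) best$family else NA_character_
  subfam <- if ("subfamily" %in% colnames(best)) best$subfamily
            else NA_character_
  level <-
    if (best$identity >= rule$alleleMin) "allele-of"
    else if (best$identity >= rule$subfamilyMin) "subfamily-of"
    else if (best$identity >= rule$familyMin) "family-of"
    else "unclassified"
  data.frame(query = queryId, level = level,
             reference = if (level == "unclassified") NA_character_
                         else best$reference,
             identity = best$identity,
             family = if (level == "unclassified") NA_character_ else fam,
             subfamily = if (level %in% c("allele-of", "subfamily-of"))
                           subfam else NA_character_)
}

#' Detect physical gene groups by single-linkage gap chaining
#'
#' Per chromosome, genes of the target families are sorted by start and
#' chained while the intergenic gap (next start minus previous end, floored
#' at 0 for overlapping genes) is at most \code{maxGap}; chains with at
#' least \code{minSize} members become groups, labelled
#' \code{"<chrom>.<k>"} in coordinate order. Strand is ignored.
#'
#' @param loci GRanges of gene loci (from [readAnnotation()] or
#'   [simulateLayout()]) with \code{gene_id} and \code{family} columns.
#' @param familyFilter character vector of family labels to include, or
#'   NULL for all loci.
#' @param maxGap maximal intergenic gap in bp (comparison is \code{<=}).
#' @param minSize minimal number of member genes.
#' @return GRanges of groups spanning min start to max end, with metadata
#'   columns \code{label}, \code{n_members}, \code{member_ids}
#'   (CharacterList), \code{n_families}.
#' @export
detectGroups <- function(loci, familyFilter = NULL, maxGap = 5.26e6,
                         minSize = 7L) {
  empty <- GenomicRanges::GRanges()
  GenomicRanges::mcols(empty) <- S4Vectors::DataFrame(
    label = character(), n_members = integer(),
    member_ids = IRanges::CharacterList(), n_families = integer())
  if (length(loci) == 0L) return(empty)
  if (!is.null(familyFilter))
    loci <- loci[loci$family %in% familyFilter]
  if (length(loci) == 0L) return(empty)
  ord <- order(as.character(GenomicRanges::seqnames(loci)),
               GenomicRanges::start(loci), GenomicRanges::end(loci),
               loci$gene_id)
  loci <- loci[ord]
  out <- list()
  for (chr in unique(as.character(GenomicRanges::seqnames(loci)))) {
    g <- loci[as.character(GenomicRanges::seqnames(loci)) == chr]
    st <- GenomicRanges::start(g)
    en <- GenomicRanges::end(g)
    gaps <- if (length(g) > 1L) pmax(0, st[-1L] - en[-length(g)]) else
            numeric(0)
    chainId <- cumsum(c(0, gaps > maxGap))
    k <- 0L
    for (cid in unique(chainId)) {
      idx <- which(chainId == cid)
      if (length(idx) < minSize) next
      k <- k + 1L
      mem <- g[idx]
      gr <- GenomicRanges::GRanges(
        chr, IRanges::IRanges(min(st[idx]), max(en[idx])))
      GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
        label = paste0(chr, ".", k),
        n_members = length(idx),
        member_ids = IRanges::CharacterList(list(mem$gene_id)),
        n_families = length(unique(mem$family)))
      out[[length(out) + 1L]] <- gr
    }
  }
  if (!length(out)) return(empty)
  res <- suppressWarnings(do.call(c, out))
  names(res) <- res$label
  res
}

#' Per-chromosome distribution of a gene family
#'
#' @param loci GRanges of gene loci with \code{family}.
#' @param family family label to tabulate.
#' @return data.frame with columns \code{chrom}, \code{count},
#'   \code{percent} (100 * count / family total, rounded to 2 decimals);
#'   empty when the family is absent.
#' @export
chromosomeDistribution <- function(loci, family) {
  sel <- loci[loci$family == family]
  if (length(sel) == 0L)
    return(data.frame(chrom = character(), count = integer(),
                      percent = numeric()))
  tab <- table(as.character(GenomicRanges::seqnames(sel)))
  data.frame(chrom = names(tab), count = as.integer(tab),
             percent = round(100 * as.integer(tab) / length(sel), 2),
             row.names = NULL)
}

#' Family aggregation summary over detected groups
#'
#' @param groups GRanges from [detectGroups()].
#' @return list with \code{perGroup} (data.frame label, n_families) and
#'   \code{summary} (counts of groups with exactly one family and with at
#'   most three families).
#' @export
familyAggregation <- function(groups) {
  perGroup <- data.frame(label = character(), n_families = integer())
  if (length(groups))
    perGroup <- data.frame(label = groups$label,
                           n_families = groups$n_families)
  list(perGroup = perGroup,
       summary = c(oneFamily = sum(perGroup$n_families == 1L),
                   atMostThreeFamilies = sum(perGroup$n_families <= 3L)))
}
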