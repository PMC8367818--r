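# Generators producing inputs with the statistical structure the analysis
# stages assume: gene layouts with planted physical groups, codon pairs at
# a specified expected synonymous divergence, LTR pairs of known insertion
# age, and negative-binomial expression studies with planted tissue,
# cell-line and jasmonate time-course signal.

#' Specification for a synthetic gene layout
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param nBackgroundGenes number of background (non-target-family) genes
#'   placed uniformly without overlap.
#' @param plantedGroups list of planted physical groups, each a list with
#'   \code{chrom}, \code{n} (members, >= 1), \code{maxGap} (bp, maximal
#'   internal intergenic gap) and \code{family}.
#' @param geneLength fixed gene length (bp).
#' @param backgroundFamily family label given to background genes.
#' @param seed integer seed; layouts are deterministic given the seed.
#' @return a \code{LayoutSpec} list.
#' @export
layoutSpec <- function(chromLengths, nBackgroundGenes = 100L,
                       plantedGroups = list(), geneLength = 2000L,
                       backgroundFamily = "other", seed = 1L) {
  stopifnot(length(chromLengths) >= 1L, all(chromLengths > 0),
            nBackgroundGenes >= 0L)
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  for (g in plantedGroups) {
    stopifnot(g$n >= 1L, g$maxGap >= 0, g$chrom %in% names(chromLengths))
    span <- g$n * geneLength + (g$n - 1L) * g$maxGap
    if (span > chromLengths[[g$chrom]])
      stop("planted group span exceeds chromosome ", g$chrom, call. = FALSE)
  }
  structure(list(chromLengths = chromLengths,
                 nBackgroundGenes = as.integer(nBackgroundGenes),
                 plantedGroups = plantedGroups,
                 geneLength = as.integer(geneLength),
                 backgroundFamily = backgroundFamily,
                 seed = as.integer(seed)),
            class = "LayoutSpec")
}

#' Simulate a chromosome gene layout with planted physical groups
#'
#' Planted groups are placed with internal intergenic gaps drawn uniformly
#' in \code{[0, maxGap]}; background genes are placed uniformly without
#' overlapping any other gene. Deterministic given the spec seed.
#'
#' @param spec a [layoutSpec()].
#' @return GRanges of gene loci with \code{gene_id}, \code{family},
#'   \code{subfamily} metadata columns.
#' @export
simulateLayout <- function(spec) {
  stopifnot(inherits(spec, "LayoutSpec"))
  withSeed(spec$seed, {
    len <- spec$geneLength
    chrom <- character(); start <- numeric(); fam <- character()
    for (g in spec$plantedGroups) {
      gaps <- if (g$n > 1L) floor(stats::runif(g$n - 1L, 0, g$maxGap + 1))
              else numeric(0)
      offs <- cumsum(c(0, gaps + len))
      span <- offs[g$n] + len
      maxStart <- spec$chromLengths[[g$chrom]] - span + 1
      if (maxStart < 1) stop("infeasible packing for planted group on ",
                             g$chrom, call. = FALSE)
      s0 <- floor(stats::runif(1L, 1, maxStart + 1))
      chrom <- c(chrom, rep(g$chrom, g$n))
      start <- c(start, s0 + offs)
      fam <- c(fam, rep(g$family, g$n))
    }
    placed <- data.frame(chrom = chrom, start = start, end = start + len - 1)
    nb <- spec$nBackgroundGenes
    if (nb > 0L) {
      pChrom <- spec$chromLengths / sum(spec$chromLengths)
      tries <- 0L
      while (nb > 0L) {
        tries <- tries + 1L
        if (tries > 200L)
          stop("infeasible packing: could not place background genes",
               call. = FALSE)
        cands <- sample(names(spec$chromLengths), nb, replace = TRUE,
                        prob = pChrom)
        s <- floor(stats::runif(nb, 1,
                                spec$chromLengths[cands] - len + 2))
        for (i in seq_len(nb)) {
          ov <- placed$chrom == cands[i] &
                placed$start <= s[i] + len - 1 & placed$end >= s[i]
          if (!any(ov)) {
            placed <- rbind(placed, data.frame(chrom = cands[i],
                                               start = s[i],
                                               end = s[i] + len - 1))
            chrom <- c(chrom, cands[i])
            start <- c(start, s[i])
            fam <- c(fam, spec$backgroundFamily)
            nb <- nb - 1L
          }
        }
      }
    }
    ord <- order(chrom, start)
    gr <- GenomicRanges::GRanges(
      seqnames = chrom[ord],
      ranges = IRanges::IRanges(start[ord], width = len),
      strand = sample(c("+", "-"), length(ord), replace = TRUE))
    ids <- sprintf("g%05d", seq_along(gr))
    GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
      gene_id = ids, family = fam[ord],
      subfamily = rep(NA_character_, length(ord)))
    names(gr) <- ids
    gr
  })
}

# ---- codon-pair generator --------------------------------------------------

# Codons whose synonymous variation is purely third-position with regular
# NG86 site fractions: no synonymous change at positions 1-2 for any class
# member and third-position site fraction exactly (m-1)/3. Restricting the
# ancestor to these codons makes the class-calibrated mutation scheme give
# E[pS | ancestor] equal to the Jukes-Cantor forward proportion exactly.
.cleanCodonClasses <- function() {
  if (!is.null(.tmCache$classes)) return(.tmCache$classes)
  sense <- .senseCodons()
  posFractions <- function(codon) {
    ch <- .chars(codon)
    aa <- .translate1(codon)
    vapply(1:3, function(pos) {
      syn <- 0L; den <- 0L
      for (b in setdiff(.BASES, ch[pos])) {
        mut <- ch; mut[pos] <- b
        mutc <- paste(mut, collapse = "")
        if (mutc %in% .STOP_CODONS) next
        den <- den + 1L
        if (.translate1(mutc) == aa) syn <- syn + 1L
      }
      if (den > 0L) syn / den else 0
    }, numeric(1))
  }
  classes <- list()
  for (cod in sense) {
    pref <- substr(cod, 1L, 2L)
    aa <- .translate1(cod)
    members <- paste0(pref, .BASES)
    members <- members[!members %in% .STOP_CODONS &
                       .translate1(members) == aa]
    m <- length(members)
    ok <- all(vapply(members, function(cm) {
      f <- posFractions(cm)
      f[1] == 0 && f[2] == 0 && abs(f[3] - (m - 1) / 3) < 1e-9
    }, logical(1)))
    if (ok)
      classes[[cod]] <- list(third = substr(members, 3L, 3L), m = m)
  }
  .tmCache$classes <- classes
  classes
}

#' Simulate a codon pair with a specified expected synonymous divergence
#'
#' Draws an ancestral coding sequence and mutates only synonymous third
#' positions, using per-degeneracy-class substitution probabilities
#' calibrated so that the expected NG86 proportion of synonymous
#' differences equals the Jukes-Cantor forward transform of
#' \code{targetKs}; the JC-corrected Ks estimate is therefore unbiased for
#' \code{targetKs} at any divergence below saturation, and Ka is exactly 0
#' by construction.
#'
#' @param nCodons number of codons (>= 50).
#' @param targetKs expected synonymous substitutions per synonymous site
#'   (>= 0, finite).
#' @param seed integer seed.
#' @return a [CodonPairAlignment-class].
#' @export
simulateCodonPair <- function(nCodons, targetKs, seed = 1L) {
  stopifnot(nCodons >= 50L)
  if (!is.finite(targetKs) || targetKs < 0)
    stop("targetKs must be finite and >= 0 (corrected distance undefined ",
         "beyond Jukes-Cantor saturation)", call. = FALSE)
  pstar <- 3 / 4 * (1 - exp(-4 * targetKs / 3))
  if (pstar >= 3 / 4)
    stop("targetKs beyond Jukes-Cantor saturation", call. = FALSE)
  classes <- .cleanCodonClasses()
  cods <- names(classes)
  mvec <- vapply(classes, `[[`, numeric(1), "m")
  withSeed(seed, {
    anc <- sample(cods, nCodons, replace = TRUE)
    m <- mvec[anc]
    pm <- (m - 1) / 3 * pstar
    flip <- stats::runif(nCodons) < pm
    b <- anc
    if (any(flip)) {
      b[flip] <- vapply(which(flip), function(i) {
        cl <- classes[[anc[i]]]
        cur3 <- substr(anc[i], 3L, 3L)
        alt <- cl$third[cl$third != cur3]
        paste0(substr(anc[i], 1L, 2L),
               if (length(alt) == 1L) alt else sample(alt, 1L))
      }, character(1))
    }
    CodonPairAlignment(anc, b)
  })
}

# ---- LTR generator ---------------------------------------------------------

.K2P_TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.K2P_TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                           C = c("A", "G"), T = c("A", "G"))

# evolve sequence for `time` years under K2P with total rate mu and
# transition:transversion rate ratio kappa
.evolveK2P <- function(bases, time, mu, kappa) {
  beta <- mu / (kappa + 2)
  alpha <- kappa * beta
  pTs <- 0.25 + 0.25 * exp(-4 * beta * time) -
         0.5 * exp(-2 * (alpha + beta) * time)
  pTvEach <- 0.25 - 0.25 * exp(-4 * beta * time)
  u <- stats::runif(length(bases))
  out <- bases
  ts <- u < pTs
  tv1 <- !ts & u < pTs + pTvEach
  tv2 <- !ts & !tv1 & u < pTs + 2 * pTvEach
  out[ts] <- .K2P_TRANSITION[bases[ts]]
  out[tv1] <- vapply(bases[tv1], function(b) .K2P_TRANSVERSIONS[[b]][1L],
                     character(1))
  out[tv2] <- vapply(bases[tv2], function(b) .K2P_TRANSVERSIONS[[b]][2L],
                     character(1))
  out
}

#' Simulate an LTR element of known insertion age
#'
#' Two copies of a random ancestral repeat evolve independently for
#' \code{age} years under the Kimura two-parameter model with total rate
#' \code{mu} per site per year, so the expected pairwise divergence is
#' D = 2 mu age and the clock estimate T = D/(2 mu) recovers the age.
#'
#' @param length repeat length in bp (>= 100).
#' @param age insertion age in years (>= 0).
#' @param mu neutral mutation rate per site per year.
#' @param kappa transition:transversion rate ratio (default 2, a typical
#'   plant value).
#' @param seed integer seed.
#' @param elementId element identifier.
#' @return an [LTRElement-class].
#' @export
simulateLtrPair <- function(length, age, mu = TAXUS_MU, kappa = 2,
                            seed = 1L, elementId = "ltr1") {
  stopifnot(length >= 100L, age >= 0, mu > 0, kappa > 0)
  withSeed(seed, {
    anc <- sample(.BASES, length, replace = TRUE)
    l5 <- .evolveK2P(anc, age, mu, kappa)
    l3 <- .evolveK2P(anc, age, mu, kappa)
    LTRElement(elementId, paste(l5, collapse = ""),
               paste(l3, collapse = ""))
  })
}

# ---- expression generator --------------------------------------------------

#' Design for a synthetic expression study
#'
#' Defaults emulate the study design the screens assume: three tissues
#' (root, leaf, bark), two half-sib cell lines (HC, LC) and a jasmonate
#' induction time course at 0, 2, 4, 8 and 24 h, each with 3 biological
#' replicates, with pathway genes (anchors and their true partners) more
#' highly expressed in root/bark, up in HC, and sharing a latent jasmonate
#' trajectory.
#'
#' @param nGenes total genes.
#' @param librarySize expected reads per sample.
#' @param dispersion negative-binomial dispersion (>= 0; 0 gives Poisson).
#' @param tissueLog2Effects named log2 effects applied to pathway genes in
#'   the named tissues, relative to leaf.
#' @param hcLcLog2Effect log2 effect for pathway genes in HC vs LC.
#' @param anchorIds planted pathway anchor genes (subset of gene ids
#'   \code{sprintf("g\%05d", 1:nGenes)}).
#' @param partnerIds designated true partners sharing the jasmonate
#'   trajectory with the anchors.
#' @param mejaProfile named log2 latent trajectory over hours 0,2,4,8,24
#'   shared by anchors and partners.
#' @param profileNoiseSd sd of independent per-gene-per-time log2 noise
#'   added to the shared trajectory.
#' @param nReps biological replicates per condition.
#' @param seed integer seed.
#' @return an \code{ExprDesign} list.
#' @export
exprDesign <- function(nGenes = 2000L, librarySize = 1e6,
                       dispersion = 0.1,
                       tissueLog2Effects = c(root = 2, bark = 1.5),
                       hcLcLog2Effect = 2,
                       anchorIds = character(),
                       partnerIds = character(),
                       mejaProfile = c(`0` = 0, `2` = 2, `4` = 3,
                                       `8` = 2, `24` = 1),
                       profileNoiseSd = 0.25, nReps = 3L, seed = 1L) {
  stopifnot(nGenes >= 1L, librarySize > 0, dispersion >= 0,
            all(is.finite(tissueLog2Effects)), is.finite(hcLcLog2Effect),
            nReps >= 2L)
  ids <- sprintf("g%05d", seq_len(nGenes))
  stopifnot(all(anchorIds %in% ids), all(partnerIds %in% ids))
  structure(list(nGenes = as.integer(nGenes), librarySize = librarySize,
                 dispersion = dispersion,
                 tissueLog2Effects = tissueLog2Effects,
                 hcLcLog2Effect = hcLcLog2Effect,
                 anchorIds = anchorIds, partnerIds = partnerIds,
                 mejaProfile = mejaProfile,
                 profileNoiseSd = profileNoiseSd,
                 nReps = as.integer(nReps), seed = as.integer(seed)),
            class = "ExprDesign")
}

#' Simulate an expression study from a design
#'
#' Counts are negative-binomial around
#' \code{librarySize * relative abundance * 2^(applicable effects)};
#' anchors and partners additionally follow the shared jasmonate
#' trajectory plus independent log2 noise during the time course.
#'
#' @param design an [exprDesign()].
#' @return an [ExpressionStudy-class].
#' @export
simulateExpression <- function(design) {
  stopifnot(inherits(design, "ExprDesign"))
  withSeed(design$seed, {
    n <- design$nGenes
    ids <- sprintf("g%05d", seq_len(n))
    lens <- floor(stats::runif(n, 1000, 4001))
    rel <- stats::rlnorm(n, 0, 1)
    rel <- rel / sum(rel)
    pathway <- union(design$anchorIds, design$partnerIds)
    isPath <- ids %in% pathway
    reps <- seq_len(design$nReps)
    samples <- rbind(
      expand.grid(tissue = c("root", "leaf", "bark"), line = "none",
                  treatment = "control", time_h = NA_real_,
                  replicate = reps, stringsAsFactors = FALSE),
      expand.grid(tissue = NA_character_, line = c("HC", "LC"),
                  treatment = "control", time_h = NA_real_,
                  replicate = reps, stringsAsFactors = FALSE),
      expand.grid(tissue = NA_character_, line = "LC",
                  treatment = "MeJA", time_h = c(0, 2, 4, 8, 24),
                  replicate = reps, stringsAsFactors = FALSE))
    rownames(samples) <- sprintf(
      "s%02d_%s", seq_len(nrow(samples)),
      ifelse(!is.na(samples$tissue), samples$tissue,
             ifelse(samples$treatment == "MeJA",
                    paste0("MeJA", samples$time_h, "h"), samples$line)))
    # latent jasmonate deviation per pathway gene x time (shared trajectory
    # plus independent noise), identical across replicates of a time point
    tpts <- as.character(c(0, 2, 4, 8, 24))
    dev <- matrix(0, n, length(tpts), dimnames = list(ids, tpts))
    if (any(isPath))
      dev[isPath, ] <- matrix(rep(design$mejaProfile[tpts],
                                  each = sum(isPath)),
                              ncol = length(tpts)) +
        stats::rnorm(sum(isPath) * length(tpts), 0, design$profileNoiseSd)
    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(ids, rownames(samples)))
    for (j in seq_len(nrow(samples))) {
      lf <- rep(0, n)
      sm <- samples[j, ]
      if (!is.na(sm$tissue) && sm$tissue %in% names(design$tissueLog2Effects))
        lf[isPath] <- lf[isPath] + design$tissueLog2Effects[[sm$tissue]]
      if (!is.na(sm$line) && sm$line == "HC")
        lf[isPath] <- lf[isPath] + design$hcLcLog2Effect
      if (sm$treatment == "MeJA")
        lf <- lf + dev[, as.character(sm$time_h)]
      mu <- design$librarySize * rel * 2^lf
      counts[, j] <- if (design$dispersion > 0)
        stats::rnbinom(n, mu = mu, size = 1 / design$dispersion)
      else stats::rpois(n, mu)
    }
    ExpressionStudy(counts, stats::setNames(lens, ids), samples)
  })
}
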