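test_that("identity classification applies the 97/55/40 cutoffs", {
  refs <- data.frame(reference = c("CYP725A4", "CYP725B1"),
                     identity = c(98.2, 45),
                     family = c("CYP725", "CYP725"),
                     subfamily = c("CYP725A", "CYP725B"))
  a <- classifyByIdentity("q1", refs)
  expect_equal(a$level, "allele-of")
  expect_equal(a$reference, "CYP725A4")
  expect_equal(a$subfamily, "CYP725A")

  sub <- classifyByIdentity("q2", transform(refs, identity = c(60, 45)))
  expect_equal(sub$level, "subfamily-of")
  expect_equal(sub$subfamily, "CYP725A")

  fam <- classifyByIdentity("q3", transform(refs, identity = c(42, 30)))
  expect_equal(fam$level, "family-of")
  expect_equal(fam$family, "CYP725")
  expect_true(is.na(fam$subfamily))

  un <- classifyByIdentity("q4", transform(refs, identity = c(35, 30)))
  expect_equal(un$level, "unclassified")
  expect_true(is.na(un$reference))

  # ties resolve by identity then reference name
  tie <- classifyByIdentity("q5", data.frame(
    reference = c("CYP725A9", "CYP725A1"), identity = c(70, 70),
    family = "CYP725", subfamily = "CYP725A"))
  expect_equal(tie$reference, "CYP725A1")

  expect_warning(none <- classifyByIdentity("q6", refs[0, ]), "empty")
  expect_equal(none$level, "unclassified")

  expect_error(classificationRule(50, 55, 40))
})

.mkLoci <- function(chrom, start, end, family,
                    ids = sprintf("g%03d", seq_along(start))) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start, end))
  GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = ids, family = family,
    subfamily = rep(NA_character_, length(gr)))
  names(gr) <- ids
  gr
}

test_that("group detection chains genes by intergenic gap", {
  # 7 genes, all gaps 1 Mb -> one group of 7
  st <- seq(1e6, by = 1.01e6, length.out = 7)
  loci <- .mkLoci("chr9", st, st + 1e4, rep("CYP450", 7))
  g <- detectGroups(loci, "CYP450", maxGap = 5.26e6, minSize = 7)
  expect_equal(length(g), 1L)
  expect_equal(g$label, "chr9.1")
  expect_equal(GenomicRanges::start(g), as.integer(st[1]))
  expect_equal(GenomicRanges::end(g), as.integer(st[7] + 1e4))

  # a single 6-Mb gap after gene 7 splits 14 genes into two groups of 7
  st2 <- c(st, st[7] + 6.3e6 + cumsum(rep(1.01e6, 7)))
  loci2 <- .mkLoci("chr9", st2, st2 + 1e4, rep("CYP450", 14))
  g2 <- detectGroups(loci2, "CYP450", maxGap = 5.26e6, minSize = 7)
  expect_equal(length(g2), 2L)
  expect_equal(g2$label, c("chr9.1", "chr9.2"))
  expect_equal(g2$n_members, c(7L, 7L))

  # six genes never qualify at minSize 7
  expect_equal(length(detectGroups(loci[1:6], "CYP450", minSize = 7)), 0L)

  # overlapping genes count as gap 0
  ov <- .mkLoci("chr1", c(100, 150, 160, 200, 220, 230, 240),
                c(155, 170, 210, 215, 228, 238, 260), rep("F", 7))
  expect_equal(length(detectGroups(ov, "F", maxGap = 10, minSize = 7)), 1L)

  expect_equal(length(detectGroups(GenomicRanges::GRanges())), 0L)
})

test_that("group detection is invariant to input order and strand", {
  set.seed(12)
  st <- sort(sample.int(50e6, 20))
  loci <- .mkLoci("chr3", st, st + 2000, rep("CYP450", 20))
  base <- detectGroups(loci, "CYP450", maxGap = 3e6, minSize = 4)
  perm <- sample(seq_along(loci))
  shuffled <- loci[perm]
  GenomicRanges::strand(shuffled) <- sample(c("+", "-"), 20, TRUE)
  again <- detectGroups(shuffled, "CYP450", maxGap = 3e6, minSize = 4)
  expect_identical(as.data.frame(base), as.data.frame(again))
})

test_that("group detection equals the maximal-run oracle on random layouts", {
  set.seed(99)
  for (trial in 1:120) {
    n <- sample(3:50, 1)
    chrom <- sample(paste0("chr", 1:3), n, TRUE)
    start <- sample.int(30e6, n)
    len <- sample(500:5000, n, TRUE)
    df <- data.frame(chrom = chrom, start = start, end = start + len,
                     gene_id = sprintf("g%03d", 1:n))
    maxGap <- sample(c(1e5, 1e6, 5e6), 1)
    minSize <- sample(2:7, 1)
    loci <- .mkLoci(df$chrom, df$start, df$end, rep("X", n), df$gene_id)
    got <- detectGroups(loci, "X", maxGap = maxGap, minSize = minSize)
    want <- oracleGroups(df, maxGap, minSize)
    expect_equal(length(got), length(want))
    if (length(want)) {
      gotMembers <- lapply(seq_along(got), function(i)
        sort(unlist(got$member_ids[i])))
      wantMembers <- lapply(want, sort)
      expect_true(all(vapply(wantMembers, function(w)
        any(vapply(gotMembers, identical, TRUE, w)), TRUE)))
    }
    # every reported group obeys the gap criterion and is maximal
    for (i in seq_along(got)) {
      mem <- df[match(unlist(got$member_ids[i]), df$gene_id), ]
      mem <- mem[order(mem$start), ]
      if (nrow(mem) > 1)
        expect_true(all(pmax(0, mem$start[-1] -
                               mem$end[-nrow(mem)]) <= maxGap))
    }
  }
})

test_that("chromosome distribution reports rounded percentages", {
  loci <- .mkLoci(c(rep("chr9", 59), rep("chr2", 20)),
                  seq_len(79) * 1e5, seq_len(79) * 1e5 + 100,
                  rep("CYP725A", 79))
  cd <- chromosomeDistribution(loci, "CYP725A")
  expect_equal(cd$percent[cd$chrom == "chr9"], 74.68)
  expect_equal(sum(cd$count), 79)

  one <- chromosomeDistribution(.mkLoci("chr1", 1:4 * 100, 1:4 * 100 + 10,
                                        rep("F", 4))[1], "F")
  expect_equal(one$percent, 100)
  quarter <- chromosomeDistribution(
    .mkLoci(c("chr1", "chr2", "chr2", "chr2"), 1:4 * 100, 1:4 * 100 + 10,
            rep("F", 4)), "F")
  expect_equal(quarter$percent[quarter$chrom == "chr1"], 25.00)

  expect_equal(nrow(chromosomeDistribution(loci, "nope")), 0L)
})

test_that("family aggregation counts distinct families per group", {
  st <- seq(1e6, by = 2e5, length.out = 8)
  mixed <- .mkLoci("chr5", st, st + 1000,
                   c(rep("CYP725A", 3), rep("CYP750", 3), "CYP720",
                     "CYP725A"))
  g <- detectGroups(mixed, unique(mixed$family), maxGap = 1e6, minSize = 7)
  expect_equal(g$n_families, 3L)
  agg <- familyAggregation(g)
  expect_equal(unname(agg$summary["oneFamily"]), 0L)
  expect_equal(unname(agg$summary["atMostThreeFamilies"]), 1L)

  pure <- .mkLoci("chr5", st[1:7], st[1:7] + 1000, rep("CYP725A", 7))
  gp <- detectGroups(pure, "CYP725A", maxGap = 1e6, minSize = 7)
  expect_equal(familyAggregation(gp)$perGroup$n_families, 1L)
})
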