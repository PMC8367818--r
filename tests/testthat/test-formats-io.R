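writeToyGff <- function(path, lines = NULL) {
  if (is.null(lines))
    lines <- c(
      "##gff-version 3",
      "chr1\ttoy\tgene\t100\t250\t.\t+\t.\tID=geneA",
      "chr1\ttoy\tgene\t500\t900\t.\t-\t.\tID=geneB",
      "chr2\ttoy\tgene\t1000\t2200\t.\t+\t.\tID=geneC")
  writeLines(lines, path)
  path
}

test_that("annotation reader preserves coordinates and attaches families", {
  gff <- writeToyGff(withr::local_tempfile(fileext = ".gff3"))
  fam <- data.frame(gene_id = c("geneA", "geneB", "geneC"),
                    family = c("CYP725A", "CYP725B", "other"))
  loci <- readAnnotation(gff, fam)
  expect_equal(length(loci), 3L)
  expect_equal(GenomicRanges::start(loci["geneA"]), 100L)
  expect_equal(GenomicRanges::end(loci["geneA"]), 250L)
  expect_equal(loci$family, c("CYP725A", "CYP725B", "other"))

  # missing map entry -> family "unassigned" with a warning
  expect_warning(loci2 <- readAnnotation(gff, fam[1:2, ]), "unassigned")
  expect_equal(sum(loci2$family == "unassigned"), 1L)
})

test_that("annotation reader rejects malformed input with line numbers", {
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttoy\tgene\t100\t250\t.\t+\t.\tID=geneA",
               "chr1\ttoy\tgene\t500"), bad)
  err <- tryCatch(readAnnotation(bad), error = function(e) e)
  expect_s3_class(err, "tm_parse_error")
  expect_match(conditionMessage(err), "line 3")

  dup <- writeToyGff(withr::local_tempfile(fileext = ".gff3"),
                     c("##gff-version 3",
                       "chr1\ttoy\tgene\t1\t10\t.\t+\t.\tID=geneA",
                       "chr1\ttoy\tgene\t20\t30\t.\t+\t.\tID=geneA"))
  expect_error(readAnnotation(dup), class = "tm_parse_error")
})

test_that("annotation write/read round-trips coordinates and families", {
  spec <- layoutSpec(c(chr1 = 2e6, chr2 = 3e6), 10,
                     list(list(chrom = "chr2", n = 4, maxGap = 5e4,
                               family = "CYP725A")), seed = 8)
  loci <- simulateLayout(spec)
  gff <- withr::local_tempfile(fileext = ".gff3")
  famTsv <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotation(loci, gff, famTsv)
  back <- readAnnotation(gff, famTsv)
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(loci))
  expect_identical(GenomicRanges::end(back), GenomicRanges::end(loci))
  expect_identical(back$family, loci$family)
  expect_identical(back$gene_id, loci$gene_id)
})

test_that("codon alignment reader enforces its preconditions", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "TTTGGGGGG", ">b", "TTCGGGGGG"), fa)
  pair <- readCodonAlignment(fa)
  expect_equal(length(pair), 3L)

  writeLines(c(">a", "TTTGGGGGGA", ">b", "TTCGGGGGGA"), fa)
  expect_error(readCodonAlignment(fa), class = "tm_length_error")

  writeLines(c(">a", "TTTTAAGGG", ">b", "TTCTACGGG"), fa)
  expect_error(readCodonAlignment(fa), class = "tm_stop_codon_error")

  writeLines(c(">a", "TTTGGGNNN", ">b", "TTCGGGAAA"), fa)
  expect_error(readCodonAlignment(fa), class = "tm_parse_error")
  expect_equal(length(readCodonAlignment(fa, dropAmbiguous = TRUE)), 2L)

  writeLines(c(">a", "TTT"), fa)
  expect_error(readCodonAlignment(fa), class = "tm_parse_error")
})

test_that("LTR FASTA pairing follows the 5LTR/3LTR suffix convention", {
  els <- list(simulateLtrPair(150, 1e6, seed = 1, elementId = "rt1"),
              simulateLtrPair(200, 2e6, seed = 2, elementId = "rt2"))
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLtrPairs(els, fa)
  back <- readLtrPairs(fa)
  expect_named(back, c("rt1", "rt2"))
  expect_identical(ltr3(back$rt2), ltr3(els[[2]]))

  writeLines(c(">x_5LTR", strrep("A", 120)), fa)
  expect_error(readLtrPairs(fa), class = "tm_parse_error")
})

test_that("similarity-hit reader validates its columns", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("query\tsubject\tbitscore\tevalue\taln_length",
               "A\tB\t500\t1e-50\t150"), tsv)
  hits <- readSimilarityHits(tsv)
  expect_equal(hits$bitscore, 500)
  writeLines(c("query\tsubject\tbitscore", "A\tB\t500"), tsv)
  expect_error(readSimilarityHits(tsv), class = "tm_parse_error")
})

test_that("group output is 0-based half-open, labelled, and length-preserving", {
  spec <- layoutSpec(c(chr9 = 60e6), 0,
                     list(list(chrom = "chr9", n = 7, maxGap = 2e6,
                               family = "CYP450"),
                          list(chrom = "chr9", n = 8, maxGap = 2e6,
                               family = "CYP450")), seed = 31)
  loci <- simulateLayout(spec)
  groups <- detectGroups(loci, "CYP450", maxGap = 2.1e6, minSize = 7)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeGroups(groups, bed)
  df <- utils::read.delim(bed)
  expect_equal(nrow(df), length(groups))
  expect_true(all(diff(df$start) > 0) || nrow(df) < 2)
  if (nrow(df) == 2) expect_equal(df$label, c("chr9.1", "chr9.2"))
  # 1-based inclusive -> 0-based half-open keeps the span length
  expect_equal(df$end - df$start, GenomicRanges::width(groups))

  empty <- detectGroups(loci, "absent-family")
  writeGroups(empty, bed)
  expect_equal(nrow(utils::read.delim(bed)), 0L)
})

test_that("run config round-trips and the logger formats levels", {
  cfg <- list(mu = TAXUS_MU, maxGap = 5.26e6, seed = 11L)
  js <- withr::local_tempfile(fileext = ".json")
  writeRunConfig(cfg, js)
  back <- readRunConfig(js)
  expect_equal(back$mu, TAXUS_MU)
  expect_equal(back$seed, 11L)
  expect_match(tmLog("WARN", "low coverage", file = nullfile()),
               "^\\[WARN\\]")
})
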