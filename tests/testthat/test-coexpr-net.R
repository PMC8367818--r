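test_that("round 1 keeps genes higher in root or bark than leaf", {
  counts <- matrix(
    c(5000, 1000, 2000,    # gA: root > leaf -> kept
      1000, 1000, 2000,    # gB: neither root nor bark beats leaf
      400,  3000, 100,     # gC: bark > leaf -> kept
      3,    1,    2),      # gD: root > leaf but below the floor
    nrow = 4, byrow = TRUE,
    dimnames = list(c("gA", "gB", "gC", "gD"),
                    c("root1", "bark1", "leaf1")))
  st <- makeStudy(counts, tissue = c("root", "bark", "leaf"), line = "none")
  kept <- round1TissueFilter(st, floor = 1)
  expect_setequal(kept, c("gA", "gC"))

  noLeaf <- makeStudy(counts[, 1:2], tissue = c("root", "bark"),
                      line = "none")
  expect_error(round1TissueFilter(noLeaf), "leaf")
})

test_that("round 2 finds no survivors without signal and flags all-zero genes", {
  set.seed(21)
  base <- matrix(stats::rnbinom(50 * 6, mu = 60, size = 10), 50,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
  counts <- cbind(base[, 1:3], base[, 1:3])  # identical HC and LC blocks
  counts["g50", ] <- 0L
  colnames(counts) <- c(paste0("HC", 1:3), paste0("LC", 1:3))
  st <- makeStudy(counts, line = rep(c("HC", "LC"), each = 3),
                  replicate = rep(1:3, 2))
  r2 <- round2HcLcDe(st)
  expect_equal(length(r2$survivors), 0L)
  expect_equal(r2$excluded, "g50")
  expect_false("g50" %in% r2$results$gene_id)
  expect_error(round2HcLcDe(makeStudy(counts[, c(1, 4)],
                                      line = c("HC", "LC"))),
               "replicates")
})

test_that("round 2 recovers planted HC-upregulated genes", {
  d <- exprDesign(nGenes = 400, hcLcLog2Effect = 2,
                  tissueLog2Effects = c(root = 0, bark = 0),
                  anchorIds = sprintf("g%05d", 1:25),
                  partnerIds = sprintf("g%05d", 26:50), seed = 61)
  r2 <- round2HcLcDe(simulateExpression(d))
  planted <- sprintf("g%05d", 1:50)
  # planted genes dominate the survivor set; recovery of individual genes
  # is curbed by composition bias (planting 50/400 genes at 4x inflates
  # the HC library, shrinking measured fold changes toward the cutoff)
  expect_gte(sum(planted %in% r2$survivors), 30)
  expect_lte(length(setdiff(r2$survivors, planted)), 2)
  # fold changes of survivors point the HC way
  expect_true(all(r2$results$log2fc[r2$results$gene_id %in%
                                      r2$survivors] > 1))
})

test_that("round 3 keeps pairs beyond the n=5 critical correlation", {
  tcrit <- stats::qt(0.975, df = 3)
  rcrit <- tcrit / sqrt(tcrit^2 + 3)
  expect_equal(rcrit, 0.878, tolerance = 5e-4)

  # controlled five-point series; a filler gene keeps library sizes equal
  anchor <- c(10, 20, 30, 40, 50)
  hi <- c(12, 18, 32, 41, 48)       # r ~ 0.997 -> kept
  lo <- c(30, 10, 40, 20, 35)       # weak correlation -> dropped
  filler <- 200 - anchor - hi - lo
  counts <- rbind(anchor = anchor, hi = hi, lo = lo, filler = filler)
  counts <- counts[, rep(1:5, each = 3)]
  colnames(counts) <- paste0("mj", seq_len(15))
  st <- makeStudy(counts, line = "LC", treatment = "MeJA",
                  time_h = rep(c(0, 2, 4, 8, 24), each = 3),
                  replicate = rep(1:3, 5))
  expect_lt(abs(stats::cor(anchor, lo)), rcrit)
  edges <- round3AnchorCorrelation(st, "anchor", c("hi", "lo", "filler"))
  expect_true("hi" %in% edges$candidate_id)
  expect_false("lo" %in% edges$candidate_id)
  expect_true(all(abs(edges$r) > 0.878))

  # candidate identical to the anchor: r = 1, kept
  counts2 <- rbind(anchor = anchor, twin = anchor, filler = 100 - 2 * anchor)
  counts2 <- counts2[, rep(1:5, each = 3)]
  colnames(counts2) <- paste0("mj", seq_len(15))
  st2 <- makeStudy(counts2, line = "LC", treatment = "MeJA",
                   time_h = rep(c(0, 2, 4, 8, 24), each = 3),
                   replicate = rep(1:3, 5))
  e2 <- round3AnchorCorrelation(st2, "anchor", c("twin", "filler"))
  expect_true("twin" %in% e2$candidate_id)
  expect_equal(e2$r[e2$candidate_id == "twin"], 1, tolerance = 1e-9)

  # zero-variance series are skipped, not kept
  counts3 <- rbind(anchor = anchor, flat = rep(20, 5),
                   filler = 100 - anchor - 20)
  counts3 <- counts3[, rep(1:5, each = 3)]
  colnames(counts3) <- paste0("mj", seq_len(15))
  st3 <- makeStudy(counts3, line = "LC", treatment = "MeJA",
                   time_h = rep(c(0, 2, 4, 8, 24), each = 3),
                   replicate = rep(1:3, 5))
  e3 <- round3AnchorCorrelation(st3, "anchor", c("flat", "filler"))
  expect_false("flat" %in% e3$candidate_id)
  expect_true("flat" %in% attr(e3, "skipped"))
})

test_that("round 2 agrees with an independent exact-test implementation", {
  d <- exprDesign(nGenes = 400, hcLcLog2Effect = 2,
                  tissueLog2Effects = c(root = 0, bark = 0),
                  anchorIds = sprintf("g%05d", 1:25),
                  partnerIds = sprintf("g%05d", 26:50), seed = 62)
  st <- simulateExpression(d)
  mine <- round2HcLcDe(st)$survivors
  cd <- sampleInfo(st)
  sel <- which(cd$line %in% c("HC", "LC") & cd$treatment == "control")
  cts <- SummarizedExperiment::assay(st, "counts")[, sel]
  y <- edgeR::DGEList(cts[rowSums(cts) > 0, ],
                      group = factor(cd$line[sel],
                                     levels = c("LC", "HC")))
  y <- edgeR::estimateDisp(y)
  tab <- edgeR::topTags(edgeR::exactTest(y), n = Inf)$table
  ref <- rownames(tab)[tab$logFC > 1 & tab$FDR < 0.05]
  jac <- length(intersect(ref, mine)) / length(union(ref, mine))
  expect_gte(jac, 0.8)
})

test_that("screening rounds nest: the network draws on earlier survivors", {
  d <- exprDesign(nGenes = 300, anchorIds = sprintf("g%05d", 1:5),
                  partnerIds = sprintf("g%05d", 6:15), seed = 71)
  st <- simulateExpression(d)
  r1 <- round1TissueFilter(st)
  r2 <- round2HcLcDe(st)
  pool <- intersect(r1, r2$survivors)
  edges <- round3AnchorCorrelation(st, sprintf("g%05d", 1:5), pool)
  expect_true(all(edges$candidate_id %in% pool))

  net <- buildNetwork(edges,
                      annotations = stats::setNames(
                        rep("CYP725A", 15), sprintf("g%05d", 1:15)),
                      tfIds = "g00006")
  expect_true(all(net$edges$candidate_id %in% net$nodes$id))
  expect_setequal(unique(net$nodes$role), c("anchor", "candidate"))
  # a candidate linked to several anchors is a single node
  multi <- table(net$edges$candidate_id)
  if (any(multi > 1)) {
    cid <- names(multi)[multi > 1][1]
    expect_equal(sum(net$nodes$id == cid), 1L)
  }
  expect_true(net$nodes$is_tf[net$nodes$id == "g00006"] ||
                !"g00006" %in% net$nodes$id)

  empty <- buildNetwork(edges[0, ])
  expect_equal(nrow(empty$nodes), 0L)
})
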