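test_that("expression ratios apply the nTPM > 1 filter and ratio rule", {
  expr <- rbind(
    makeExpressionFixture("RAMP1", c("ctx1", "ctx2"), c(5, 0.9)),
    makeExpressionFixture(c("g_yes", "g_no"), c("ctx1", "ctx2"),
      c(10, 8, 6, 4)))
  ann <- data.frame(gpcr_id = c("g_yes", "g_no"), ramp_id = "RAMP1",
    label = c("yes", "no"), stringsAsFactors = FALSE)
  out <- expressionRatioTest(expr, ann)
  # ctx2 excluded: RAMP1 at 0.9 nTPM fails the strict > 1 filter
  expect_equal(unique(out$ratios$context_id), "ctx1")
  expect_equal(out$ratios$ratio[out$ratios$gpcr_id == "g_yes"], 10 / 5)
  expect_equal(out$ratios$ratio[out$ratios$gpcr_id == "g_no"], 6 / 5)
  expect_equal(out$tests$n_yes, 1L)

  # only one label available -> skipped with a warning
  annOne <- ann[ann$label == "yes", ]
  expect_warning(one <- expressionRatioTest(expr, annOne), "one label")
  expect_null(one$tests)
})

test_that("interactors show higher ratios when constructed to do so", {
  set.seed(31)
  nG <- 120L
  gy <- sprintf("yes%03d", seq_len(nG))
  gn <- sprintf("no%03d", seq_len(nG))
  contexts <- sprintf("ctx%d", 1:2)
  expr <- rbind(
    makeExpressionFixture("RAMP2", contexts, c(4, 4)),
    makeExpressionFixture(gy, contexts, exp(rnorm(2 * nG, log(40), 0.5))),
    makeExpressionFixture(gn, contexts, exp(rnorm(2 * nG, log(10), 0.5))))
  ann <- data.frame(gpcr_id = c(gy, gn), ramp_id = "RAMP2",
    label = rep(c("yes", "no"), each = nG), stringsAsFactors = FALSE)
  out <- expressionRatioTest(expr, ann)
  expect_gte(out$tests$n_yes, 200L)
  expect_lt(out$tests$p_value, 0.005)
})

test_that("the ratio test holds its nominal type-I error under identical
  distributions", {
  set.seed(77)
  gpcrs <- sprintf("g%02d", 1:40)
  ann <- data.frame(gpcr_id = gpcrs, ramp_id = "RAMP1",
    label = rep(c("yes", "no"), each = 20), stringsAsFactors = FALSE)
  nRej <- 0L
  nRep <- 300L
  for (i in seq_len(nRep)) {
    expr <- rbind(
      makeExpressionFixture("RAMP1", "ctx", 4),
      makeExpressionFixture(gpcrs, "ctx", exp(rnorm(40, 2, 0.6))))
    out <- expressionRatioTest(expr, ann)
    if (out$tests$p_value < 0.05) nRej <- nRej + 1L
  }
  expect_gte(nRej / nRep, 0.02)
  expect_lte(nRej / nRep, 0.09)
})

test_that("binarization is strict at 1 nTPM and clustering pairs identical
  profiles", {
  expr <- rbind(
    makeExpressionFixture("gA", c("c1", "c2", "c3"), c(1.0, 1.01, 8)),
    makeExpressionFixture("gB", c("c1", "c2", "c3"), c(1.0, 1.01, 8)),
    makeExpressionFixture("gC", c("c1", "c2", "c3"), c(200, 300, 0.2)))
  out <- binarizeAndCluster(expr)
  expect_false(out$binary["gA", "c1"])   # exactly 1 is not expressed
  expect_true(out$binary["gA", "c2"])
  expect_equal(out$log2["gA", "c3"], log2(8))
  expect_equal(out$log2["gA", "c1"], 0)

  coph <- as.matrix(stats::cophenetic(out$dendrogram))
  expect_equal(coph["gA", "gB"], 0)
  # the identical pair is adjacent in leaf order
  pos <- match(c("gA", "gB"), out$order)
  expect_equal(abs(diff(pos)), 1L)

  zero <- makeExpressionFixture(c("g1", "g2"), c("c1", "c2"),
    rep(0.5, 4))
  expect_error(binarizeAndCluster(zero), class = "sba_clustering_error")
  expect_error(binarizeAndCluster(expr[expr$gene_id == "gA", ]),
    class = "sba_validation_error")
})

test_that("clustering distances are invariant to input row permutation", {
  set.seed(41)
  genes <- sprintf("g%d", 1:6)
  expr <- makeExpressionFixture(genes, sprintf("c%d", 1:5),
    exp(rnorm(30, 1, 1)))
  a <- binarizeAndCluster(expr)
  b <- binarizeAndCluster(expr[sample(nrow(expr)), ])
  ca <- as.matrix(stats::cophenetic(a$dendrogram))
  cb <- as.matrix(stats::cophenetic(b$dendrogram))
  expect_equal(ca[genes, genes], cb[genes, genes])
})

test_that("per-context interacting percentages follow the expression
  gates", {
  expr <- rbind(
    makeExpressionFixture("RAMP1", c("ctxA", "ctxB"), c(3, 0.5)),
    makeExpressionFixture(c("g1", "g2", "g3"), c("ctxA", "ctxB"),
      c(5, 5, 5, 5, 5, 5)))
  ann <- data.frame(gpcr_id = c("g1", "g2", "g3"), ramp_id = "RAMP1",
    label = c("yes", "yes", "no"), stringsAsFactors = FALSE)
  out <- pctInteractingPerContext(expr, ann)
  expect_equal(out$context_id, "ctxA")  # RAMP1 not expressed in ctxB
  expect_equal(out$n_gpcrs_expressed, 3L)
  expect_equal(out$pct_yes, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(out$pct_no, 100 / 3, tolerance = 1e-9)
  expect_equal(out$pct_yes + out$pct_no, 100)
})

test_that("expressed-receptor counts per context track the fixture design", {
  set.seed(13)
  nG <- 100L
  gpcrs <- sprintf("g%03d", seq_len(nG))
  contexts <- sprintf("ctx%02d", 1:12)
  rows <- list(makeExpressionFixture("RAMP3", contexts, rep(4, 12)))
  planned <- round(seq(18, 71, length.out = 12))
  for (i in seq_along(contexts)) {
    expressed <- sample(gpcrs, planned[i])
    rows[[i + 1L]] <- data.frame(gene_id = gpcrs, context_id = contexts[i],
      ntpm = ifelse(gpcrs %in% expressed, 5, 0.2),
      stringsAsFactors = FALSE)
  }
  expr <- do.call(rbind, rows)
  ann <- data.frame(gpcr_id = gpcrs, ramp_id = "RAMP3",
    label = sample(c("yes", "no"), nG, replace = TRUE),
    stringsAsFactors = FALSE)
  out <- pctInteractingPerContext(expr, ann)
  expect_equal(sort(out$n_gpcrs_expressed), sort(planned))
  expect_true(all(out$n_gpcrs_expressed >= 18 &
    out$n_gpcrs_expressed <= 71))
})

test_that("coupling enrichment reproduces exact Fisher results", {
  # balanced 2x2 -> odds ratio 1, p = 1
  gpcrs <- sprintf("g%02d", 1:40)
  ann <- data.frame(gpcr_id = gpcrs, ramp_id = "RAMP1",
    label = rep(c("yes", "no"), each = 20), stringsAsFactors = FALSE)
  coupling <- data.frame(gpcr_id = c(gpcrs[1:10], gpcrs[21:30]),
    transducer = "Gs", tier = "primary", log_emax_over_ec50 = NA_real_,
    stringsAsFactors = FALSE)
  out <- couplingEnrichment(coupling, ann)
  gs <- out[out$comparison == "Gs", ]
  expect_equal(gs$odds_ratio, 1, tolerance = 1e-9)
  expect_equal(gs$p_value, 1)

  # [[8,2],[1,5]] laid out as interacting/non x coupled/not
  g2 <- sprintf("h%02d", 1:16)
  ann2 <- data.frame(gpcr_id = g2, ramp_id = "RAMP1",
    label = rep(c("yes", "no"), c(9, 7)), stringsAsFactors = FALSE)
  coupling2 <- data.frame(gpcr_id = c(g2[1:8], g2[10:11]),
    transducer = "Gi", tier = "primary", log_emax_over_ec50 = NA_real_,
    stringsAsFactors = FALSE)
  out2 <- couplingEnrichment(coupling2, ann2)
  gi <- out2[out2$comparison == "Gi", ]
  expect_equal(gi$p_value, oracleFisherP(8, 1, 2, 5), tolerance = 1e-9)
  expect_equal(gi$p_value, 0.034965, tolerance = 1e-4)

  # beta-arrestin binarization: 0 is no coupling, > 0 couples
  coupling3 <- data.frame(gpcr_id = c(gpcrs[1:12], gpcrs[21:24]),
    transducer = "Barr2", tier = "primary",
    log_emax_over_ec50 = c(rep(0.1, 10), 0, 0, rep(0.1, 2), 0, 0),
    stringsAsFactors = FALSE)
  out3 <- couplingEnrichment(coupling3, ann)
  b <- out3[out3$comparison == "Barr2", ]
  expect_equal(b$n_interacting, 10L)
  expect_equal(b$n_non_interacting, 2L)
})

test_that("MolBoolean summaries implement the net-RCP arithmetic", {
  rcp <- data.frame(
    image_id = c("i1", "i2", "blank1"),
    stain_condition = c("pair", "pair", "blank"),
    nuclei = c(30L, 10L, 10L),
    rcp_gpcr = c(300L, 400L, 20L),
    rcp_ramp = c(300L, 300L, 20L),
    rcp_overlap = c(300L, 200L, 20L), stringsAsFactors = FALSE)
  out <- molbooleanSummarize(rcp)
  # 300/30 = 10 RCPs per cell, minus 2 blank RCPs per cell
  expect_equal(out$net_rcp_gpcr[1L], 8)
  expect_equal(out$pct_overlap[1L], 100 * 8 / 24)

  # overlap 20 out of a net total of 100
  rcp2 <- data.frame(image_id = c("a", "blank1"),
    stain_condition = c("pair", "blank"), nuclei = c(10L, 10L),
    rcp_gpcr = c(500L, 0L), rcp_ramp = c(300L, 0L),
    rcp_overlap = c(200L, 0L), stringsAsFactors = FALSE)
  expect_equal(molbooleanSummarize(rcp2)$pct_overlap, 20)

  # blank larger than signal clamps at zero
  rcp3 <- rcp
  rcp3$rcp_gpcr[1:2] <- c(10L, 5L)
  expect_message(out3 <- molbooleanSummarize(rcp3), "clamped")
  expect_equal(out3$net_rcp_gpcr, c(0, 0))

  expect_error(molbooleanSummarize(rcp[1:2, ]),
    class = "sba_validation_error")
})

test_that("MolBoolean comparisons flag reduced complex formation", {
  counts <- simulateRcpCounts(30, meanRcpPerCell = list(
    positive = c(8, 8, 5), reduced = c(8, 8, 2.5)),
    blankRate = 0.5, seed = 19)
  summ <- molbooleanSummarize(counts)
  cmp <- molbooleanCompare(summ, positiveControl = "positive")
  red <- cmp$comparisons[cmp$comparisons$group == "reduced", ]
  expect_true(red$significant)
  expect_lt(red$estimate, 0)

  # control against itself: difference 0, adjusted p ~ 1
  summSelf <- summ
  summSelf$stain_condition[summSelf$stain_condition == "reduced"] <-
    "positive2"
  summSelf$pct_overlap[summSelf$stain_condition == "positive2"] <-
    summSelf$pct_overlap[summSelf$stain_condition == "positive"]
  cmp2 <- molbooleanCompare(summSelf, positiveControl = "positive")
  expect_gte(cmp2$comparisons$p_adjusted, 0.99)

  expect_error(molbooleanCompare(summ, positiveControl = "nope"),
    class = "sba_validation_error")
})
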