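test_that("sensitivity/specificity curves count the confusion correctly", {
  score <- c(5, 6, 7, 0, 1, 2)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  at3 <- sensSpecCurves(score, lab, thresholds = 3)
  expect_equal(at3$tp, 3)
  expect_equal(at3$fn, 0)
  expect_equal(at3$tn, 3)
  expect_equal(at3$fp, 0)
  expect_equal(at3$sensitivity, 1)
  expect_equal(at3$specificity, 1)

  below <- sensSpecCurves(score, lab, thresholds = -1)
  expect_equal(c(below$sensitivity, below$specificity), c(1, 0))
  above <- sensSpecCurves(score, lab, thresholds = 10)
  expect_equal(c(above$sensitivity, above$specificity), c(0, 1))

  set.seed(21)
  cv <- sensSpecCurves(rnorm(40), rep(c(TRUE, FALSE), 20))
  expect_true(all(diff(cv$sensitivity) <= 0))
  expect_true(all(diff(cv$specificity) >= 0))

  expect_error(sensSpecCurves(1:3, c(TRUE, TRUE, TRUE)),
    class = "sba_calibration_error")
})

test_that("intersection threshold matches brute-force enumeration", {
  # perfectly separated toy: intersection inside the gap, sens = spec = 1
  score <- c(5, 6, 7, 0, 1, 2)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  # with a strict ">" call rule, t = 2 already separates perfectly and the
  # smallest-threshold tie-break selects it
  t1 <- selectIntersectionThreshold(sensSpecCurves(score, lab))
  expect_gte(t1, 2)
  expect_lt(t1, 5)
  at <- sensSpecCurves(score, lab, thresholds = t1)
  expect_equal(c(at$sensitivity, at$specificity), c(1, 1))

  # interleaved toy: best balance is sens = spec = 0.5
  score2 <- c(1, 3, 0, 2)
  lab2 <- c(TRUE, TRUE, FALSE, FALSE)
  t2 <- selectIntersectionThreshold(sensSpecCurves(score2, lab2))
  expect_equal(t2, oracleIntersection(score2, lab2))
  at2 <- sensSpecCurves(score2, lab2, thresholds = t2)
  expect_equal(at2$sensitivity, 0.5)
  expect_equal(at2$specificity, 0.5)

  # anti-calibration: flipped labels cannot beat chance
  t3 <- selectIntersectionThreshold(sensSpecCurves(score, !lab))
  at3 <- sensSpecCurves(score, !lab, thresholds = t3)
  expect_lte(at3$sensitivity + at3$specificity, 1)

  set.seed(17)
  for (i in 1:200) {
    n <- sample(4:50, 1L)
    sc <- round(rnorm(n, sd = 2), sample(0:2, 1L))  # force occasional ties
    lb <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lb) || all(lb)) next
    expect_equal(
      selectIntersectionThreshold(sensSpecCurves(sc, lb)),
      oracleIntersection(sc, lb))
  }
})

test_that("density + MAD threshold follows mode + 6 scaled MADs", {
  set.seed(12)
  x <- rnorm(1e4)
  th <- densityMadThreshold(x)
  expect_gt(th, 5.4)
  expect_lt(th, 6.6)
  expect_equal(densityMadThreshold(x + 7), th + 7, tolerance = 1e-9)

  y <- c(0, 1, 2, 3, 4, 100)
  expect_equal(densityMadThreshold(y),
    oracleKdeMode(y) + 6 * 1.4826 * 1.5, tolerance = 1e-6)

  # zero MAD falls back to the sample SD
  z <- c(rep(1, 9), 4)
  expect_equal(densityMadThreshold(z),
    oracleKdeMode(z) + 6 * sd(z), tolerance = 1e-6)
  expect_error(densityMadThreshold(rep(2, 10)),
    class = "sba_degenerate_error")
})

test_that("threshold application uses a strict inequality and is
  monotone", {
  sc <- new("ScoreMatrix", scores = data.frame(
    gpcr_id = c("g1", "g2", "g3"), ramp_id = "RAMP1", unit_id = "s",
    capture_family = "epitope_based", score = c(3.6, 3.5, 3.4),
    stringsAsFactors = FALSE), scoreKind = "robust_z")
  th <- data.frame(unit_id = "s", ramp_id = "RAMP1",
    capture_family = "epitope_based", threshold = 3.5,
    stringsAsFactors = FALSE)
  cm <- applyThresholds(sc, th)
  expect_equal(calls(cm)$hit, c(TRUE, FALSE, FALSE))

  higher <- th; higher$threshold <- 3.55
  expect_lte(sum(calls(applyThresholds(sc, higher))$hit),
    sum(calls(cm)$hit))

  empty <- new("ScoreMatrix", scores = calls(cm)[0, 1:5],
    scoreKind = "robust_z")
  expect_equal(nrow(calls(applyThresholds(empty, th))), 0L)

  bad <- th; bad$unit_id <- "other"
  expect_error(applyThresholds(sc, bad), class = "sba_validation_error")
})

test_that("calibrated thresholds separate a strong-effect screen", {
  scr <- simulateScreen(simulationConfig(nGpcrs = 30, seed = 14,
    nProteinAbsRange = c(0L, 0L)))
  sm <- scoreScreen(scr)
  ts <- simulateTruthSet(scr, seed = 15)
  th <- calibrateThresholds(sm$epitope, ts)
  expect_equal(nrow(thresholds(th)), 15L)  # 5 schemes x 3 RAMPs
  cm <- calls(applyThresholds(sm$epitope, th))
  tr <- groundTruth(scr)
  truthOf <- setNames(tr$interacting, paste(tr$gpcr_id, tr$ramp_id))
  isInt <- truthOf[paste(cm$gpcr_id, cm$ramp_id)]
  expect_gt(mean(cm$hit[isInt]), 0.9)
  expect_gt(mean(!cm$hit[!isInt]), 0.9)
})

test_that("endogenous calling averages replicate robust Z-scores and obeys
  the 3.5 rule", {
  cfg <- simulationConfig(nGpcrs = 30, logEffect = 3, seed = 22)
  scr <- simulateEndogenous(cfg, nCellLines = 1)
  cm <- calls(endogenousCall(scr))

  # oracle recomputation for one detection antibody
  det <- "det-RAMP1-PE"
  m <- merge(mfiTable(scr), sampleSheet(scr), by = "sample_id")
  sig <- m[!m$is_buffer & m$detection_antibody_id == det, ]
  buf <- m[m$is_buffer & m$detection_antibody_id == det, ]
  bufMed <- tapply(buf$mfi, buf$capture_antibody_id, median)
  sig$snr <- sig$mfi / as.numeric(bufMed[sig$capture_antibody_id])
  sig$rep <- paste0(sig$bio_replicate, ".", sig$tech_replicate)
  wide <- tapply(sig$snr, list(sig$capture_antibody_id, sig$rep), mean)
  wide <- quantileNormalize(wide)
  rz <- apply(wide, 2L, robustZ)
  expected <- rowMeans(rz)
  got <- cm[cm$ramp_id == "RAMP1", ]
  expect_equal(setNames(got$score, got$unit_id),
    expected[got$unit_id])
  expect_equal(got$hit, unname(expected[got$unit_id] > 3.5))

  # buffer-only input yields zero calls
  bufOnly <- scr
  keep <- sampleSheet(scr)$sample_id[sampleSheet(scr)$is_buffer]
  bufScreen <- new("SBAScreen",
    mfi = mfiTable(scr)[mfiTable(scr)$sample_id %in% keep, ],
    panel = antibodyPanel(scr),
    samples = sampleSheet(scr)[sampleSheet(scr)$is_buffer, ],
    schemes = schemeTable(scr), truth = groundTruth(scr),
    metadata = list())
  expect_equal(nrow(calls(endogenousCall(bufScreen))), 0L)
})
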