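test_that("evidence classes follow the thirds rule with medium at exact
  boundaries", {
  expect_equal(evidenceClass(4, 5), "strong")
  expect_equal(evidenceClass(2, 5), "medium")
  expect_equal(evidenceClass(1, 5), "weak")
  expect_equal(evidenceClass(4, 6), "medium")  # exactly 2/3
  expect_equal(evidenceClass(2, 6), "medium")  # exactly 1/3
  expect_equal(evidenceClass(0, 0), "absent")
  expect_equal(evidenceClass(c(5, 0), c(5, 4)), c("strong", "weak"))
  expect_error(evidenceClass(3, 2), class = "sba_validation_error")
  expect_error(evidenceClass(-1, 2), class = "sba_validation_error")
})

test_that("adding a passing scheme never demotes the evidence class", {
  rank <- c(weak = 1L, medium = 2L, strong = 3L)
  for (n in 1:8) {
    for (p in 0:n) {
      expect_gte(rank[evidenceClass(p + 1L, n + 1L)],
        rank[evidenceClass(p, n)])
    }
  }
})

test_that("yes/no/inconclusive integration matches the full truth table", {
  combos <- expand.grid(
    epitope = c("strong", "medium", "weak"),
    protein = c("strong", "medium", "weak", "absent"),
    stringsAsFactors = FALSE)
  expected <- c(
    "strong+strong" = "yes", "medium+strong" = "yes",
    "weak+strong" = "inconclusive",
    "strong+medium" = "yes", "medium+medium" = "inconclusive",
    "weak+medium" = "no",
    "strong+weak" = "inconclusive", "medium+weak" = "no",
    "weak+weak" = "no",
    "strong+absent" = "yes", "medium+absent" = "inconclusive",
    "weak+absent" = "no")
  got <- integrateYesNo(combos$epitope, combos$protein)
  expect_equal(got,
    unname(expected[paste(combos$epitope, combos$protein, sep = "+")]))
  expect_error(integrateYesNo("absent", "strong"),
    class = "sba_validation_error")
})

test_that("evidence table counts schemes and annotation spreads families", {
  cm <- new("CallMatrix", calls = data.frame(
    gpcr_id = rep("g1", 7),
    ramp_id = "RAMP1",
    unit_id = c("s1", "s2", "s3", "s4", "s5", "ab1", "ab2"),
    capture_family = c(rep("epitope_based", 5), rep("protein_based", 2)),
    score = 1, threshold = 0,
    hit = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE))
  ev <- evidenceTable(cm)
  expect_equal(nrow(ev), 2L)
  ep <- ev[ev$capture_family == "epitope_based", ]
  expect_equal(ep$n_schemes, 5L)
  expect_equal(ep$n_passing, 4L)
  expect_equal(ep$class, "strong")
  pr <- ev[ev$capture_family == "protein_based", ]
  expect_equal(pr$class, "medium")  # 1 of 2 passing
  ann <- annotateInteractome(ev)
  expect_equal(ann$label, "yes")

  # a pair with no protein data integrates from epitope evidence alone
  ev2 <- ev[ev$capture_family == "epitope_based", ]
  expect_equal(annotateInteractome(ev2)$protein_class, "absent")
  expect_equal(annotateInteractome(ev2)$label, "yes")
})

test_that("overlap patterns partition the receptor universe", {
  sets <- list(RAMP1 = c("g1", "g2"), RAMP2 = "g1", RAMP3 = "g1")
  oc <- overlapCounts(sets, universe = c("g1", "g2", "g3"))
  counts <- setNames(oc$count, oc$pattern)
  expect_equal(unname(counts["RAMP1&RAMP2&RAMP3"]), 1L)
  expect_equal(unname(counts["RAMP1"]), 1L)
  expect_equal(unname(counts["none"]), 1L)
  expect_equal(sum(oc$count), 3L)
  expect_equal(sum(counts[!names(counts) %in%
    c("RAMP1", "RAMP1&RAMP2&RAMP3", "none")]), 0L)

  same <- overlapCounts(list(A = c("x", "y"), B = c("x", "y")))
  sc <- setNames(same$count, same$pattern)
  expect_equal(unname(sc["A&B"]), 2L)
  expect_equal(sum(sc[names(sc) != "A&B"]), 0L)

  set.seed(9)
  uni <- sprintf("g%02d", 1:30)
  rnd <- list(a = sample(uni, 10), b = sample(uni, 15), c = sample(uni, 5))
  expect_equal(sum(overlapCounts(rnd, uni)$count), 30L)
})

test_that("expression-quartile bias proportions match hand counts", {
  expr <- setNames(1:8, sprintf("g%d", 1:8))
  ev <- data.frame(
    gpcr_id = sprintf("g%d", 1:8), ramp_id = "RAMP1",
    capture_family = "epitope_based", n_schemes = 5L,
    n_passing = c(5L, 5L, 2L, 2L, 1L, 1L, 5L, 5L),
    stringsAsFactors = FALSE)
  ev$class <- evidenceClass(ev$n_passing, ev$n_schemes)
  qb <- expressionQuartileBias(ev, expr)
  q1 <- qb[qb$quartile == "Q1", ]
  expect_equal(setNames(q1$proportion, q1$class)[c("strong", "medium")],
    c(strong = 1, medium = 0))
  q4 <- qb[qb$quartile == "Q4", ]
  expect_equal(unname(setNames(q4$proportion, q4$class)["strong"]), 1)
  q2 <- qb[qb$quartile == "Q2", ]
  expect_equal(unname(setNames(q2$proportion, q2$class)["medium"]), 1)
  for (q in c("Q1", "Q2", "Q3", "Q4")) {
    expect_equal(sum(qb$n[qb$quartile == q]), 2L)
    expect_equal(sum(qb$proportion[qb$quartile == q]), 1)
  }
  expect_error(expressionQuartileBias(ev, expr[1:3]),
    class = "sba_validation_error")
})

test_that("screen summaries are internally consistent", {
  empty <- new("CallMatrix", calls = data.frame(
    gpcr_id = character(), ramp_id = character(), unit_id = character(),
    capture_family = character(), score = numeric(),
    threshold = numeric(), hit = logical(), stringsAsFactors = FALSE))
  s0 <- summarizeScreen(epitopeCalls = empty)
  expect_equal(sum(s0$schemeHits$n_hits), 0)

  # 215 x 3 annotation: per-RAMP label counts sum to the receptor count
  ann <- expand.grid(gpcr_id = sprintf("G%03d", 1:215),
    ramp_id = c("RAMP1", "RAMP2", "RAMP3"), stringsAsFactors = FALSE)
  set.seed(2)
  ann$label <- sample(c("yes", "no", "inconclusive"), nrow(ann),
    replace = TRUE)
  lab <- summarizeScreen(annotation = ann)$labels
  expect_equal(nrow(ann), 645L)
  expect_equal(lab$yes + lab$no + lab$inconclusive, rep(215L, 3L))
})
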