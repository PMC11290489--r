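# Post-interactome analyses: expression ratios, RAMP expression binarization
# and clustering, per-context interacting percentages, transducer-coupling
# enrichment, and MolBoolean RCP summaries/comparisons.

#' GPCR:RAMP expression-ratio comparison between interactors and
#' non-interactors
#'
#' For each RAMP, the GPCR/RAMP nTPM ratio is computed in every context
#' (cell type or tissue) where both genes exceed 1 nTPM; one observation per
#' (GPCR, context). Ratios of annotated interactors ("yes") are compared
#' with non-interactors ("no") by a two-sided Wilcoxon rank-sum test;
#' inconclusive receptors are excluded.
#'
#' @param expr data.frame (schema \code{"expression"}).
#' @param annotation data.frame from [annotateInteractome()] (or any table
#'   with \code{gpcr_id}, \code{ramp_id}, \code{label}).
#' @param minNtpm expression floor, strict (default 1).
#' @return list: \code{ratios} (data.frame \code{gpcr_id}, \code{ramp_id},
#'   \code{context_id}, \code{ratio}, \code{label}) and \code{tests}
#'   (data.frame per RAMP: group sizes and two-sided p). RAMPs with only one
#'   label available are skipped with a warning.
#' @export
expressionRatioTest <- function(expr, annotation, minNtpm = 1) {
  ann <- annotation[annotation$label %in% c("yes", "no"), , drop = FALSE]
  ramps <- sort(unique(ann$ramp_id))
  ratioList <- list()
  testList <- list()
  for (r in ramps) {
    re <- expr[expr$gene_id == r & expr$ntpm > minNtpm, , drop = FALSE]
    if (!nrow(re)) next
    rampNtpm <- setNames(re$ntpm, re$context_id)
    annR <- ann[ann$ramp_id == r, ]
    ge <- expr[expr$gene_id %in% annR$gpcr_id & expr$ntpm > minNtpm &
      expr$context_id %in% names(rampNtpm), , drop = FALSE]
    if (!nrow(ge)) next
    lab <- setNames(annR$label, annR$gpcr_id)
    rr <- data.frame(gpcr_id = ge$gene_id, ramp_id = r,
      context_id = ge$context_id,
      ratio = ge$ntpm / as.numeric(rampNtpm[ge$context_id]),
      label = as.character(lab[ge$gene_id]), stringsAsFactors = FALSE)
    ratioList[[r]] <- rr
    nYes <- sum(rr$label == "yes")
    nNo <- sum(rr$label == "no")
    if (nYes < 1L || nNo < 1L) {
      warning(sprintf(
        "RAMP %s skipped: ratios available for one label only", r))
      next
    }
    p <- wilcox.test(rr$ratio[rr$label == "yes"],
      rr$ratio[rr$label == "no"], alternative = "two.sided")$p.value
    testList[[r]] <- data.frame(ramp_id = r, n_yes = nYes, n_no = nNo,
      p_value = p, stringsAsFactors = FALSE)
  }
  list(
    ratios = if (length(ratioList)) do.call(rbind, c(ratioList,
      make.row.names = FALSE)) else NULL,
    tests = if (length(testList)) do.call(rbind, c(testList,
      make.row.names = FALSE)) else NULL)
}

#' Binarize expression at 1 nTPM and cluster genes
#'
#' Expression strictly above 1 nTPM counts as expressed. Heat values are 0
#' where not expressed and log2(nTPM) where expressed. Genes are clustered
#' hierarchically (Euclidean distance, complete linkage by default) over
#' contexts.
#'
#' @param expr data.frame (schema \code{"expression"}) covering >= 2 genes
#'   and >= 2 contexts.
#' @param method linkage for [stats::hclust()] (default "complete").
#' @return list: \code{binary} (logical genes x contexts), \code{log2}
#'   (numeric matrix), \code{dendrogram} (hclust object), \code{order}
#'   (gene labels in leaf order).
#' @export
binarizeAndCluster <- function(expr, method = "complete") {
  genes <- sort(unique(expr$gene_id))
  contexts <- sort(unique(expr$context_id))
  if (length(genes) < 2L || length(contexts) < 2L) {
    .validationError("need >= 2 genes and >= 2 contexts")
  }
  m <- matrix(0, length(genes), length(contexts),
    dimnames = list(genes, contexts))
  m[cbind(match(expr$gene_id, genes), match(expr$context_id, contexts))] <-
    expr$ntpm
  binary <- m > 1
  logm <- ifelse(binary, log2(pmax(m, 1)), 0)
  if (all(!binary)) {
    .sbaStop("no gene is expressed anywhere: nothing to cluster",
      "sba_clustering_error")
  }
  hc <- hclust(dist(logm, method = "euclidean"), method = method)
  list(binary = binary, log2 = logm, dendrogram = hc,
    order = rownames(logm)[hc$order])
}

#' Percentage of interacting receptors per context
#'
#' For every context where the RAMP exceeds 1 nTPM, the percentage of
#' "yes"- and "no"-annotated receptors among the receptors expressed
#' (> 1 nTPM) in that context; contexts with no labeled expressed receptor
#' are omitted. Percentages sum to 100.
#'
#' @inheritParams expressionRatioTest
#' @return data.frame: \code{context_id}, \code{ramp_id},
#'   \code{n_gpcrs_expressed}, \code{pct_yes}, \code{pct_no}.
#' @export
pctInteractingPerContext <- function(expr, annotation, minNtpm = 1) {
  ann <- annotation[annotation$label %in% c("yes", "no"), , drop = FALSE]
  out <- list()
  for (r in sort(unique(ann$ramp_id))) {
    rampCtx <- expr$context_id[expr$gene_id == r & expr$ntpm > minNtpm]
    annR <- ann[ann$ramp_id == r, ]
    lab <- setNames(annR$label, annR$gpcr_id)
    for (ctx in rampCtx) {
      g <- expr$gene_id[expr$context_id == ctx & expr$ntpm > minNtpm &
        expr$gene_id %in% annR$gpcr_id]
      if (!length(g)) next
      labs <- lab[g]
      out[[length(out) + 1L]] <- data.frame(
        context_id = ctx, ramp_id = r, n_gpcrs_expressed = length(g),
        pct_yes = 100 * mean(labs == "yes"),
        pct_no = 100 * mean(labs == "no"), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Transducer-coupling enrichment in RAMP interactors
#'
#' Compares G-protein and beta-arrestin couplings between receptors that
#' interact with any RAMP ("yes" for at least one) and receptors that do not
#' ("no" for every RAMP with a decidable label, none "yes"). Beta-arrestin
#' couplings are binarized at log(Emax/EC50) > 0. For each (transducer,
#' tier) a 2x2 Fisher exact test (conditional-MLE odds ratio) is computed;
#' the number of primary couplings per receptor is compared by an r x c
#' Fisher test (p only).
#'
#' @param coupling data.frame (schema \code{"coupling"}).
#' @param annotation data.frame from [annotateInteractome()].
#' @return data.frame: \code{comparison}, \code{tier}, \code{odds_ratio}
#'   (NA for r x c), \code{p_value}, group counts. Comparisons with an empty
#'   margin are skipped with a warning.
#' @export
couplingEnrichment <- function(coupling, annotation) {
  byG <- split(annotation$label, annotation$gpcr_id)
  status <- vapply(byG, function(l) {
    if (any(l == "yes")) "interacting"
    else if (any(l == "no")) "non_interacting"
    else NA_character_
  }, character(1L))
  status <- status[!is.na(status)]
  # the coupling table is assumed restricted to receptors with transducer
  # data; a receptor absent from it has no annotated couplings
  gpcrs <- names(status)
  if (length(unique(status[gpcrs])) < 2L) {
    .calibrationError("need both interacting and non-interacting receptors")
  }
  isInt <- status[gpcrs] == "interacting"
  cp <- coupling[coupling$gpcr_id %in% gpcrs, , drop = FALSE]
  # binarize beta-arrestin rows on log(Emax/EC50): 0 means no coupling
  isArr <- grepl("arr", cp$transducer, ignore.case = TRUE)
  coupled <- rep(TRUE, nrow(cp))
  coupled[isArr] <- !is.na(cp$log_emax_over_ec50[isArr]) &
    cp$log_emax_over_ec50[isArr] > 0
  cp <- cp[coupled, , drop = FALSE]

  out <- list()
  for (tier in unique(cp$tier)) {
    sub <- cp[cp$tier == tier, ]
    for (tr in sort(unique(sub$transducer))) {
      has <- gpcrs %in% sub$gpcr_id[sub$transducer == tr]
      tab <- table(factor(has, levels = c(TRUE, FALSE)),
        factor(isInt, levels = c(TRUE, FALSE)))
      if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
        warning(sprintf("skipping %s (%s): empty margin", tr, tier))
        next
      }
      ft <- fisher.test(tab)
      out[[length(out) + 1L]] <- data.frame(
        comparison = tr, tier = tier,
        n_interacting = sum(has & isInt),
        n_non_interacting = sum(has & !isInt),
        odds_ratio = unname(ft$estimate), p_value = ft$p.value,
        stringsAsFactors = FALSE)
    }
  }
  prim <- cp[cp$tier == "primary" & !grepl("arr", cp$transducer,
    ignore.case = TRUE), ]
  nPrim <- vapply(gpcrs, function(g) sum(prim$gpcr_id == g), integer(1L))
  tab <- table(nPrim, factor(isInt, levels = c(TRUE, FALSE)))
  if (nrow(tab) >= 2L && all(colSums(tab) > 0L)) {
    ft <- fisher.test(tab, workspace = 2e6)
    out[[length(out) + 1L]] <- data.frame(
      comparison = "n_primary_couplings", tier = "primary",
      n_interacting = sum(isInt), n_non_interacting = sum(!isInt),
      odds_ratio = NA_real_, p_value = ft$p.value, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Net RCPs per cell and percent complexed signal
#'
#' Per image and channel, total rolling-circle products divided by the
#' nuclei count; the mean per-cell blank signal (unstained cells) is then
#' subtracted and negative nets are clamped at 0 (with a message counting
#' clamped values). The percent overlap is the net complexed signal over
#' the total net signal of the three channels.
#'
#' @param rcp data.frame (schema \code{"rcp"}) including the blank rows.
#' @param blankCondition \code{stain_condition} value of the blank series.
#' @return data.frame: \code{image_id}, \code{stain_condition}, per-channel
#'   \code{net_rcp_*} (RCPs/cell) and \code{pct_overlap} in [0, 100]
#'   (NA when all three nets are 0).
#' @export
molbooleanSummarize <- function(rcp, blankCondition = "blank") {
  rcp <- validateSbaTable(rcp, "rcp")
  blanks <- rcp[rcp$stain_condition == blankCondition, , drop = FALSE]
  if (!nrow(blanks)) {
    .validationError(sprintf("blank condition '%s' not present",
      blankCondition))
  }
  stained <- rcp[rcp$stain_condition != blankCondition, , drop = FALSE]
  chans <- c("rcp_gpcr", "rcp_ramp", "rcp_overlap")
  blankMean <- vapply(chans, function(ch) mean(blanks[[ch]] / blanks$nuclei),
    numeric(1L))
  nets <- vapply(chans, function(ch) {
    net <- stained[[ch]] / stained$nuclei - blankMean[[ch]]
    pmax(net, 0)
  }, numeric(nrow(stained)))
  if (nrow(stained) == 1L) nets <- matrix(nets, nrow = 1L,
    dimnames = list(NULL, chans))
  nClamped <- sum(vapply(chans, function(ch)
    sum(stained[[ch]] / stained$nuclei < blankMean[[ch]]), integer(1L)))
  if (nClamped > 0L) {
    message(sprintf("%d net value(s) below 0 clamped", nClamped))
  }
  total <- rowSums(nets)
  data.frame(
    image_id = stained$image_id, stain_condition = stained$stain_condition,
    net_rcp_gpcr = nets[, "rcp_gpcr"], net_rcp_ramp = nets[, "rcp_ramp"],
    net_rcp_overlap = nets[, "rcp_overlap"],
    pct_overlap = ifelse(total > 0, 100 * nets[, "rcp_overlap"] / total,
      NA_real_),
    stringsAsFactors = FALSE)
}

#' Compare percent complexed signal across stain conditions
#'
#' One-way ANOVA of per-image percent overlap across stain conditions,
#' followed by Dunnett's comparisons against the positive control; a
#' condition is flagged significant at adjusted p < 0.05.
#'
#' @param summaries data.frame from [molbooleanSummarize()].
#' @param positiveControl \code{stain_condition} used as the Dunnett
#'   reference.
#' @param alpha significance level for the flag (default 0.05).
#' @return list as in [rampExpressionQc()], with a \code{significant}
#'   column.
#' @export
molbooleanCompare <- function(summaries, positiveControl, alpha = 0.05) {
  if (!positiveControl %in% summaries$stain_condition) {
    .validationError(sprintf("positive control '%s' not present",
      positiveControl))
  }
  ok <- !is.na(summaries$pct_overlap)
  res <- rampExpressionQc(summaries$pct_overlap[ok],
    summaries$stain_condition[ok], reference = positiveControl)
  res$comparisons$significant <- res$comparisons$p_adjusted < alpha
  res
}
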