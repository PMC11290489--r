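# Evidence classes, yes/no/inconclusive integration and screen summaries.

#' Evidence class from the fraction of passing schemes
#'
#' strong when more than two-thirds of the capture-detection schemes passed,
#' weak when less than one-third passed, medium otherwise (a fraction of
#' exactly 1/3 or 2/3 is medium), and absent when no scheme produced data.
#'
#' @param nPassing integer vector, schemes calling the pair.
#' @param nSchemes integer vector, schemes with data for the pair.
#' @return character vector in \code{c("strong", "medium", "weak", "absent")}.
#' @examples
#' evidenceClass(c(4, 2, 1, 4, 0), c(5, 5, 5, 6, 0))
#' @export
evidenceClass <- function(nPassing, nSchemes) {
  nPassing <- as.integer(nPassing)
  nSchemes <- as.integer(nSchemes)
  if (any(nSchemes < 0L, na.rm = TRUE)) {
    .validationError("nSchemes must be non-negative")
  }
  if (any(nPassing < 0L | nPassing > nSchemes, na.rm = TRUE)) {
    .validationError("need 0 <= nPassing <= nSchemes")
  }
  out <- rep("medium", length(nPassing))
  f <- nPassing / nSchemes
  out[nSchemes == 0L] <- "absent"
  out[nSchemes > 0L & f * 3 > 2] <- "strong"
  out[nSchemes > 0L & f * 3 < 1] <- "weak"
  out
}

#' Evidence table per (GPCR, RAMP, capture family)
#'
#' Counts, per pair and capture family, the schemes with data and the
#' schemes calling a hit, and assigns the strong/medium/weak/absent class.
#' For the protein-based family each capture antibody of the receptor counts
#' as one scheme.
#'
#' @param callMatrix a [CallMatrix-class] (epitope and/or protein calls).
#' @param universe optional data.frame (\code{gpcr_id}, \code{ramp_id}) of
#'   pairs to report even if a family has no data (class \code{"absent"}).
#' @return data.frame: \code{gpcr_id}, \code{ramp_id},
#'   \code{capture_family}, \code{n_schemes}, \code{n_passing},
#'   \code{class}.
#' @export
evidenceTable <- function(callMatrix, universe = NULL) {
  cm <- calls(callMatrix)
  if (!nrow(cm)) {
    return(data.frame(gpcr_id = character(), ramp_id = character(),
      capture_family = character(), n_schemes = integer(),
      n_passing = integer(), class = character(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(hit ~ gpcr_id + ramp_id + capture_family,
    data = cm, FUN = length)
  names(agg)[4L] <- "n_schemes"
  pass <- stats::aggregate(hit ~ gpcr_id + ramp_id + capture_family,
    data = cm, FUN = sum)
  agg$n_passing <- pass$hit[match(
    paste(agg$gpcr_id, agg$ramp_id, agg$capture_family),
    paste(pass$gpcr_id, pass$ramp_id, pass$capture_family))]
  if (!is.null(universe)) {
    for (fam in unique(cm$capture_family)) {
      have <- paste(agg$gpcr_id[agg$capture_family == fam],
        agg$ramp_id[agg$capture_family == fam])
      missing <- universe[!paste(universe$gpcr_id, universe$ramp_id) %in%
        have, , drop = FALSE]
      if (nrow(missing)) {
        agg <- rbind(agg, data.frame(gpcr_id = missing$gpcr_id,
          ramp_id = missing$ramp_id, capture_family = fam,
          n_schemes = 0L, n_passing = 0L, stringsAsFactors = FALSE))
      }
    }
  }
  agg$class <- evidenceClass(agg$n_passing, agg$n_schemes)
  agg <- agg[order(agg$capture_family, agg$gpcr_id, agg$ramp_id), ]
  rownames(agg) <- NULL
  agg
}

#' Integrate epitope- and protein-based evidence into yes/no/inconclusive
#'
#' strong+strong, strong+medium and medium+strong give "yes"; weak+weak,
#' weak+medium and medium+weak give "no"; a receptor lacking protein capture
#' data is assigned from its epitope evidence alone (strong: yes, weak: no,
#' medium: inconclusive); every remaining combination (strong+weak,
#' weak+strong, medium+medium) is "inconclusive".
#'
#' @param epitopeClass character vector in strong/medium/weak (epitope
#'   evidence is never absent: every receptor has the five tag schemes).
#' @param proteinClass character vector in strong/medium/weak/absent.
#' @return character vector of labels "yes", "no", "inconclusive".
#' @export
integrateYesNo <- function(epitopeClass, proteinClass) {
  ok <- c("strong", "medium", "weak")
  if (any(!epitopeClass %in% ok)) {
    .validationError(
      "epitopeClass must be strong/medium/weak (absent not allowed)")
  }
  if (any(!proteinClass %in% c(ok, "absent"))) {
    .validationError("proteinClass must be strong/medium/weak/absent")
  }
  key <- paste(epitopeClass, proteinClass, sep = "+")
  map <- c(
    "strong+strong" = "yes", "strong+medium" = "yes",
    "medium+strong" = "yes",
    "weak+weak" = "no", "weak+medium" = "no", "medium+weak" = "no",
    "strong+absent" = "yes", "weak+absent" = "no",
    "medium+absent" = "inconclusive",
    "strong+weak" = "inconclusive", "weak+strong" = "inconclusive",
    "medium+medium" = "inconclusive")
  unname(map[key])
}

#' Annotate the interactome from an evidence table
#'
#' Spreads the per-family evidence classes of [evidenceTable()] into one row
#' per (GPCR, RAMP) and applies [integrateYesNo()].
#'
#' @param evidence data.frame from [evidenceTable()].
#' @return data.frame: \code{gpcr_id}, \code{ramp_id},
#'   \code{epitope_class}, \code{protein_class}, \code{label}.
#' @export
annotateInteractome <- function(evidence) {
  ep <- evidence[evidence$capture_family == "epitope_based", ]
  pr <- evidence[evidence$capture_family == "protein_based", ]
  if (!nrow(ep)) .validationError("no epitope-based evidence present")
  out <- data.frame(gpcr_id = ep$gpcr_id, ramp_id = ep$ramp_id,
    epitope_class = ep$class, stringsAsFactors = FALSE)
  idx <- match(paste(out$gpcr_id, out$ramp_id),
    paste(pr$gpcr_id, pr$ramp_id))
  out$protein_class <- ifelse(is.na(idx), "absent", pr$class[idx])
  out$label <- integrateYesNo(out$epitope_class, out$protein_class)
  out <- out[order(out$gpcr_id, out$ramp_id), ]
  rownames(out) <- NULL
  out
}

#' Set-overlap pattern counts (UpSet-style)
#'
#' Counts, over a universe of receptors, every non-empty membership pattern
#' across the given per-RAMP sets plus the none-of-them pattern; the counts
#' partition the universe.
#'
#' @param sets named list of character vectors (e.g. RAMP1/2/3 interactor
#'   sets).
#' @param universe character vector of all receptors considered; defaults to
#'   the union of the sets.
#' @return data.frame: \code{pattern} (set names joined by \code{"&"}, or
#'   \code{"none"}), \code{count}.
#' @export
overlapCounts <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(universe)) universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
    logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
    dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1L, function(row) {
    if (!any(row)) "none" else paste(names(sets)[row], collapse = "&")
  })
  k <- length(sets)
  combos <- unlist(lapply(seq_len(k), function(i) {
    apply(utils::combn(names(sets), i), 2L, paste, collapse = "&")
  }))
  counts <- table(factor(pattern, levels = c(combos, "none")))
  data.frame(pattern = names(counts), count = as.integer(counts),
    stringsAsFactors = FALSE)
}

#' Evidence-class proportions per expression quartile
#'
#' Splits receptors (or RAMPs) at the three sample quartiles of their
#' expression score (type-7 quantiles; values equal to a boundary fall in
#' the lower bin) and tabulates the strong/medium/weak proportions within
#' each quartile.
#'
#' @param evidence data.frame from [evidenceTable()], one capture family.
#' @param expression named numeric vector of expression scores per entity
#'   appearing in \code{evidence$gpcr_id} (or \code{$ramp_id} when
#'   \code{by = "ramp_id"}).
#' @param by entity column, \code{"gpcr_id"} (default) or \code{"ramp_id"}.
#' @return data.frame: \code{quartile} (Q1..Q4), \code{class}, \code{n},
#'   \code{proportion}; proportions sum to 1 within each quartile with data.
#' @export
expressionQuartileBias <- function(evidence, expression, by = "gpcr_id") {
  if (length(expression) < 4L) {
    .validationError("need expression scores for >= 4 entities")
  }
  qs <- quantile(expression, probs = c(0.25, 0.5, 0.75), type = 7)
  bin <- cut(expression, breaks = c(-Inf, qs, Inf),
    labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  names(bin) <- names(expression)
  ev <- evidence[evidence[[by]] %in% names(expression), , drop = FALSE]
  ev$quartile <- bin[ev[[by]]]
  tab <- table(ev$quartile, factor(ev$class,
    levels = c("strong", "medium", "weak")))
  prop <- prop.table(tab, margin = 1L)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("quartile", "class", "n")
  out$proportion <- as.data.frame(prop)$Freq
  out$proportion[is.nan(out$proportion)] <- NA_real_
  out[order(out$quartile, out$class), ]
}

#' Screen summary tables
#'
#' The headline count tables of a screen: hits per (RAMP, epitope scheme)
#' (column sums of the call matrix), positive protein-capture antibodies per
#' RAMP with their percentage of the antibody panel, and yes/no/inconclusive
#' pair counts per RAMP.
#'
#' @param epitopeCalls [CallMatrix-class] of epitope-scheme calls, or NULL.
#' @param proteinCalls [CallMatrix-class] of per-antibody calls, or NULL.
#' @param annotation data.frame from [annotateInteractome()], or NULL.
#' @param nPanelAntibodies denominator for the protein-capture percentage;
#'   defaults to the number of distinct antibodies in \code{proteinCalls}.
#' @return list of data.frames \code{schemeHits}, \code{proteinCapture},
#'   \code{labels} (NULL where the input was NULL).
#' @export
summarizeScreen <- function(epitopeCalls = NULL, proteinCalls = NULL,
                            annotation = NULL, nPanelAntibodies = NULL) {
  schemeHits <- NULL
  if (!is.null(epitopeCalls)) {
    cm <- calls(epitopeCalls)
    schemeHits <- if (!nrow(cm)) {
      data.frame(ramp_id = character(), unit_id = character(),
        n_hits = integer(), stringsAsFactors = FALSE)
    } else {
      stats::aggregate(hit ~ ramp_id + unit_id, data = cm, FUN = sum)
    }
    names(schemeHits)[3L] <- "n_hits"
    schemeHits <- schemeHits[order(schemeHits$ramp_id,
      schemeHits$unit_id), ]
    rownames(schemeHits) <- NULL
  }
  proteinCapture <- NULL
  if (!is.null(proteinCalls)) {
    cm <- calls(proteinCalls)
    if (is.null(nPanelAntibodies)) {
      nPanelAntibodies <- length(unique(cm$unit_id))
    }
    ramps <- sort(unique(cm$ramp_id))
    proteinCapture <- do.call(rbind, lapply(ramps, function(r) {
      sub <- cm[cm$ramp_id == r, ]
      pos <- unique(sub$unit_id[sub$hit])
      data.frame(ramp_id = r, n_antibodies = nPanelAntibodies,
        n_positive = length(pos),
        pct_positive = 100 * length(pos) / nPanelAntibodies,
        n_gpcrs = length(unique(sub$gpcr_id[sub$hit])),
        stringsAsFactors = FALSE)
    }))
    rownames(proteinCapture) <- NULL
  }
  labels <- NULL
  if (!is.null(annotation)) {
    tab <- table(annotation$ramp_id, factor(annotation$label,
      levels = c("yes", "no", "inconclusive")))
    labels <- data.frame(ramp_id = rownames(tab),
      yes = as.integer(tab[, "yes"]), no = as.integer(tab[, "no"]),
      inconclusive = as.integer(tab[, "inconclusive"]),
      stringsAsFactors = FALSE)
    rownames(labels) <- NULL
  }
  list(schemeHits = schemeHits, proteinCapture = proteinCapture,
    labels = labels)
}
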