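# Threshold selection and binary hit calling: literature-calibrated
# sensitivity/specificity intersection for epitope-based schemes, kernel
# density peak + 6 scaled MADs per protein-capture antibody, and the fixed
# 3.5 cutoff for endogenous screens.

#' Robust-Z score matrices of a simulated or imported screen
#'
#' Epitope-based schemes are scored per (RAMP, scheme): the MFI of each
#' (GPCR, RAMP) well under that scheme, transformed to robust Z-scores
#' across receptors. Protein-based capture is scored per antibody: robust
#' Z-scores across all lysate wells measured on that bead, from which the
#' (target GPCR, RAMP) entries are the pair scores (the remaining wells form
#' the antibody's negative population, used for thresholding).
#'
#' @param screen an [SBAScreen-class].
#' @return list with \code{epitope} ([ScoreMatrix-class], robust Z) and
#'   \code{protein} ([ScoreMatrix-class] or NULL when the panel has no
#'   protein-capture antibodies).
#' @export
scoreScreen <- function(screen) {
  stopifnot(is(screen, "SBAScreen"))
  si <- buildScoreInput(screen)
  pairs <- si$pairs[si$pairs$capture_family == "epitope_based" &
    si$pairs$ramp_id != "mock" & !is.na(si$pairs$mfi), , drop = FALSE]
  # average any replicates to one measurement per (pair, scheme)
  agg <- stats::aggregate(mfi ~ gpcr_id + ramp_id + scheme_id, data = pairs,
    FUN = mean)
  parts <- split(agg, list(agg$scheme_id, agg$ramp_id), drop = TRUE)
  ep <- do.call(rbind, lapply(parts, function(d) {
    d$score <- robustZ(d$mfi)
    d
  }))
  epScores <- data.frame(gpcr_id = ep$gpcr_id, ramp_id = ep$ramp_id,
    unit_id = ep$scheme_id, capture_family = "epitope_based",
    score = ep$score, stringsAsFactors = FALSE)
  epScores <- epScores[order(epScores$unit_id, epScores$ramp_id,
    epScores$gpcr_id), ]
  rownames(epScores) <- NULL

  pr <- .proteinRz(screen)
  protein <- NULL
  if (!is.null(pr)) {
    protein <- new("ScoreMatrix", scores = pr$pairScores,
      scoreKind = "robust_z")
  }
  list(
    epitope = new("ScoreMatrix", scores = epScores, scoreKind = "robust_z"),
    protein = protein
  )
}

# robust Z per protein-capture antibody across all lysate wells; returns the
# pair-level scores and the full per-antibody distributions
.proteinRz <- function(screen) {
  panel <- screen@panel
  hpa <- panel[panel$role == "capture" & panel$target_class == "gpcr", ]
  if (!nrow(hpa)) return(NULL)
  samples <- screen@samples
  m <- merge(screen@mfi, samples[, c("sample_id", "gpcr_id", "ramp_id",
    "is_buffer")], by = "sample_id")
  m <- m[!m$is_buffer & m$capture_antibody_id %in% hpa$antibody_id, ,
    drop = FALSE]
  target <- setNames(hpa$target_id, hpa$antibody_id)
  dists <- split(m, m$capture_antibody_id)
  pairScores <- vector("list", length(dists))
  distributions <- vector("list", length(dists))
  names(distributions) <- names(dists)
  for (i in seq_along(dists)) {
    d <- dists[[i]]
    rz <- robustZ(d$mfi)
    distributions[[i]] <- rz
    ab <- names(dists)[i]
    sel <- d$gpcr_id == target[[ab]] & d$ramp_id != "mock"
    if (any(sel)) {
      pairScores[[i]] <- data.frame(gpcr_id = d$gpcr_id[sel],
        ramp_id = d$ramp_id[sel], unit_id = ab,
        capture_family = "protein_based", score = rz[sel],
        stringsAsFactors = FALSE)
    }
  }
  pairScores <- do.call(rbind, pairScores[!vapply(pairScores, is.null,
    logical(1L))])
  if (is.null(pairScores)) return(NULL)
  pairScores <- pairScores[order(pairScores$unit_id, pairScores$ramp_id), ]
  rownames(pairScores) <- NULL
  list(pairScores = pairScores, distributions = distributions)
}

#' Sensitivity and specificity as a function of the threshold
#'
#' A pair is called a hit when its score strictly exceeds the threshold.
#' Sensitivity is the fraction of literature-interacting pairs correctly
#' detected; specificity the fraction of literature non-interacting pairs
#' correctly not detected. Sensitivity is non-increasing and specificity
#' non-decreasing in the threshold.
#'
#' @param score numeric pair scores.
#' @param interacting logical truth labels (same length), or character
#'   \code{"interacting"} / \code{"non_interacting"}.
#' @param thresholds candidate thresholds; by default the sorted unique
#'   scores plus midpoints between consecutive unique scores.
#' @return data.frame: \code{threshold}, \code{tp}, \code{fn}, \code{tn},
#'   \code{fp}, \code{sensitivity}, \code{specificity}.
#' @export
sensSpecCurves <- function(score, interacting, thresholds = NULL) {
  if (is.character(interacting) || is.factor(interacting)) {
    interacting <- as.character(interacting) == "interacting"
  }
  if (length(score) != length(interacting) || anyNA(score) ||
      anyNA(interacting)) {
    .validationError("score and labels must align with no missing values")
  }
  nPos <- sum(interacting)
  nNeg <- sum(!interacting)
  if (nPos < 1L || nNeg < 1L) {
    .calibrationError(
      "truth set must contain both interacting and non-interacting pairs")
  }
  if (is.null(thresholds)) {
    u <- sort(unique(score))
    thresholds <- sort(unique(c(u, (head(u, -1L) + tail(u, -1L)) / 2)))
  }
  tp <- vapply(thresholds, function(t) sum(score > t & interacting),
    numeric(1L))
  fp <- vapply(thresholds, function(t) sum(score > t & !interacting),
    numeric(1L))
  data.frame(threshold = thresholds, tp = tp, fn = nPos - tp,
    tn = nNeg - fp, fp = fp, sensitivity = tp / nPos,
    specificity = (nNeg - fp) / nNeg)
}

#' Threshold at the sensitivity-specificity intersection
#'
#' Selects the candidate threshold minimizing |sensitivity - specificity|;
#' ties are broken by maximal sensitivity + specificity, then by the
#' smallest threshold. On a grid containing a geometric crossing point this
#' returns that crossing.
#'
#' @param curves data.frame from [sensSpecCurves()].
#' @return the selected threshold (single numeric).
#' @export
selectIntersectionThreshold <- function(curves) {
  stopifnot(all(c("threshold", "sensitivity", "specificity") %in%
    names(curves)))
  if (!nrow(curves)) .calibrationError("empty candidate grid")
  if (all(c("tp", "fn", "tn", "fp") %in% names(curves))) {
    # exact integer arithmetic on a common denominator, immune to
    # floating-point ties: sens - spec = (tp*nNeg - tn*nPos)/(nPos*nNeg)
    nPos <- curves$tp + curves$fn
    nNeg <- curves$tn + curves$fp
    gap <- abs(curves$tp * nNeg - curves$tn * nPos)
    total <- curves$tp * nNeg + curves$tn * nPos
  } else {
    gap <- round(abs(curves$sensitivity - curves$specificity), 12L)
    total <- round(curves$sensitivity + curves$specificity, 12L)
  }
  ord <- order(gap, -total, curves$threshold)
  curves$threshold[ord[1L]]
}

#' Density-peak + MAD threshold for one antibody
#'
#' Threshold = KDE mode + multiplier x 1.4826 x MAD, where the mode is the
#' argmax of a Gaussian kernel density estimate (Silverman's rule-of-thumb
#' bandwidth) evaluated on a 512-point grid spanning the observed range, and
#' MAD is the raw median absolute deviation of the scores. With most wells
#' negative for any one antibody, the mode and MAD describe the expected
#' negative population. A zero MAD falls back to the sample SD; if that is
#' also zero the scale is degenerate.
#'
#' @param score numeric robust-Z scores of one antibody (>= 2 values;
#'   >= 8 recommended for a stable density peak).
#' @param madMultiplier number of scaled MADs above the peak (default 6).
#' @return the threshold (single numeric).
#' @export
densityMadThreshold <- function(score, madMultiplier = 6) {
  if (length(score) < 2L || anyNA(score)) {
    .validationError("densityMadThreshold needs >= 2 non-missing scores")
  }
  scale <- 1.4826 * median(abs(score - median(score)))
  if (scale == 0) {
    scale <- sd(score)
    if (scale == 0) {
      .degenerateError("both MAD and SD are zero: threshold undefined")
    }
  }
  bw <- stats::bw.nrd0(score)
  grid <- seq(min(score), max(score), length.out = 512L)
  dens <- colMeans(stats::dnorm(outer(score, grid, "-") / bw)) / bw
  mode <- grid[which.max(dens)]
  mode + madMultiplier * scale
}

#' Calibrate epitope-scheme thresholds against a literature truth set
#'
#' For each (RAMP, epitope scheme), joins the pair scores with the truth-set
#' labels, computes the sensitivity and specificity curves over the
#' candidate grid and selects the intersection threshold.
#'
#' @param epitopeScores [ScoreMatrix-class] of epitope-based robust Z scores
#'   (from [scoreScreen()]).
#' @param truthSet data.frame (\code{gpcr_id}, \code{ramp_id}, \code{label}).
#' @return [ThresholdSet-class] with one row per (RAMP, scheme).
#' @export
calibrateThresholds <- function(epitopeScores, truthSet) {
  stopifnot(is(epitopeScores, "ScoreMatrix"))
  sc <- scores(epitopeScores)
  sc <- merge(sc, truthSet, by = c("gpcr_id", "ramp_id"))
  if (!nrow(sc)) .calibrationError("no scored pair has a truth label")
  parts <- split(sc, list(sc$unit_id, sc$ramp_id), drop = TRUE)
  rows <- lapply(parts, function(d) {
    t <- selectIntersectionThreshold(
      sensSpecCurves(d$score, d$label))
    data.frame(unit_id = d$unit_id[1L], ramp_id = d$ramp_id[1L],
      capture_family = "epitope_based", threshold = t,
      stringsAsFactors = FALSE)
  })
  th <- do.call(rbind, rows)
  rownames(th) <- NULL
  new("ThresholdSet", thresholds = th, endogenous = 3.5)
}

#' Per-antibody density + MAD thresholds for protein-based capture
#'
#' @param screen an [SBAScreen-class] containing protein-capture antibodies.
#' @param madMultiplier scaled-MAD multiplier (default 6).
#' @param minScores minimum wells per antibody (default 8); antibodies with
#'   fewer are rejected.
#' @return [ThresholdSet-class] with one row per antibody
#'   (\code{ramp_id = NA}: the threshold applies across RAMPs).
#' @export
proteinThresholds <- function(screen, madMultiplier = 6, minScores = 8L) {
  pr <- .proteinRz(screen)
  if (is.null(pr)) {
    .validationError("screen has no protein-capture antibodies")
  }
  small <- names(pr$distributions)[vapply(pr$distributions, length,
    integer(1L)) < minScores]
  if (length(small)) {
    .validationError(sprintf("antibody(ies) with < %d scores: %s",
      minScores, paste(head(small, 5L), collapse = ", ")))
  }
  th <- data.frame(
    unit_id = names(pr$distributions),
    ramp_id = NA_character_,
    capture_family = "protein_based",
    threshold = vapply(pr$distributions, densityMadThreshold, numeric(1L),
      madMultiplier = madMultiplier),
    stringsAsFactors = FALSE)
  rownames(th) <- NULL
  new("ThresholdSet", thresholds = th, endogenous = 3.5)
}

#' Apply thresholds to a score matrix
#'
#' A hit requires the score to strictly exceed its threshold. Epitope-scheme
#' scores match thresholds on (unit, RAMP); per-antibody thresholds carry
#' \code{ramp_id = NA} and match on the unit alone.
#'
#' @param scoreMatrix a [ScoreMatrix-class].
#' @param thresholdSet a [ThresholdSet-class] (or a data.frame shaped like
#'   its \code{thresholds} slot).
#' @return [CallMatrix-class].
#' @export
applyThresholds <- function(scoreMatrix, thresholdSet) {
  stopifnot(is(scoreMatrix, "ScoreMatrix"))
  th <- if (is(thresholdSet, "ThresholdSet")) thresholds(thresholdSet) else
    thresholdSet
  sc <- scores(scoreMatrix)
  if (!nrow(sc)) {
    return(new("CallMatrix", calls = cbind(sc,
      data.frame(threshold = numeric(0), hit = logical(0)))))
  }
  exact <- setNames(th$threshold, paste(th$unit_id, th$ramp_id))
  unitOnly <- th[is.na(th$ramp_id), ]
  byUnit <- setNames(unitOnly$threshold, unitOnly$unit_id)
  t <- exact[paste(sc$unit_id, sc$ramp_id)]
  t[is.na(t)] <- byUnit[sc$unit_id[is.na(t)]]
  if (anyNA(t)) {
    miss <- unique(paste(sc$unit_id, sc$ramp_id)[is.na(t)])
    .validationError(sprintf("no threshold for: %s",
      paste(head(miss, 5L), collapse = "; ")))
  }
  sc$threshold <- as.numeric(t)
  sc$hit <- sc$score > sc$threshold
  new("CallMatrix", calls = sc)
}

#' Endogenous interactome calling at a fixed cutoff
#'
#' The native-lysate pipeline: MFI to signal-to-noise ratios against the
#' cell line's buffer wells, quantile normalization of the replicate columns
#' (per cell line and detection antibody), robust Z-scores across capture
#' antibodies within each replicate, and a hit when the replicate-mean
#' robust Z strictly exceeds the cutoff (default 3.5).
#'
#' @param screen an [SBAScreen-class] from [simulateEndogenous()] or
#'   equivalent imported tables.
#' @param threshold fixed cutoff on the mean robust Z (default 3.5).
#' @return [CallMatrix-class] with a \code{cell_line} column; \code{score}
#'   is the replicate-mean robust Z.
#' @export
endogenousCall <- function(screen, threshold = 3.5) {
  stopifnot(is(screen, "SBAScreen"))
  samples <- screen@samples
  panel <- screen@panel
  detTarget <- setNames(panel$target_id, panel$antibody_id)
  capTarget <- setNames(panel$target_id, panel$antibody_id)
  m <- merge(screen@mfi, samples, by = "sample_id")
  out <- list()
  for (cl in unique(samples$cell_line[!samples$is_buffer])) {
    mc <- m[m$cell_line == cl, , drop = FALSE]
    buffer <- mc[mc$is_buffer, c("capture_antibody_id",
      "detection_antibody_id", "mfi")]
    signal <- mc[!mc$is_buffer, , drop = FALSE]
    if (!nrow(signal)) next
    signal <- snrTransform(signal, buffer)
    signal$replicate <- paste0("b", signal$bio_replicate, "t",
      signal$tech_replicate)
    for (det in unique(signal$detection_antibody_id)) {
      sd_ <- signal[signal$detection_antibody_id == det, , drop = FALSE]
      wide <- tapply(sd_$snr, list(sd_$capture_antibody_id, sd_$replicate),
        mean)
      if (anyNA(wide)) {
        .validationError(sprintf(
          "incomplete replicate design for detection '%s' in %s", det, cl))
      }
      wide <- if (ncol(wide) >= 2L) quantileNormalize(wide) else wide
      if (nrow(wide) < 2L) {
        .validationError("need >= 2 capture antibodies per detection")
      }
      rz <- apply(wide, 2L, robustZ)
      meanRz <- rowMeans(rz)
      out[[length(out) + 1L]] <- data.frame(
        gpcr_id = as.character(capTarget[rownames(wide)]),
        ramp_id = as.character(detTarget[[det]]),
        unit_id = rownames(wide),
        capture_family = "protein_based",
        score = as.numeric(meanRz),
        threshold = threshold,
        hit = as.numeric(meanRz) > threshold,
        cell_line = cl,
        stringsAsFactors = FALSE)
    }
  }
  callsDf <- if (length(out)) do.call(rbind, out) else
    data.frame(gpcr_id = character(), ramp_id = character(),
      unit_id = character(), capture_family = character(),
      score = numeric(), threshold = numeric(), hit = logical(),
      cell_line = character(), stringsAsFactors = FALSE)
  rownames(callsDf) <- NULL
  new("CallMatrix", calls = callsDf)
}
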