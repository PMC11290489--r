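# Synthetic SBA screen generator. The design mirrors the real screen: every
# GPCR is expressed alone (mock) and co-expressed with each RAMP, all lysates
# are measured on one multiplexed bead panel, and five epitope-based plus
# 0..k protein-based capture-detection schemes probe each pair.

.TAG_SCHEMES <- data.frame(
  scheme_id = c("1D4-OLLAS", "FLAG-OLLAS", "HA-1D4", "OLLAS-1D4"),
  capture_family = "epitope_based",
  capture_kind = c("gpcr_tag_1d4", "gpcr_tag_flag", "ramp_tag_ha",
    "ramp_tag_ollas"),
  detection_kind = c("anti_ollas_pe", "anti_ollas_pe", "anti_1d4_pe",
    "anti_1d4_pe"),
  capture_antibody_id = c("anti-1D4", "anti-FLAG", "anti-HA", "anti-OLLAS"),
  detection_antibody_id = c("det-OLLAS-PE", "det-OLLAS-PE", "det-1D4-PE",
    "det-1D4-PE"),
  stringsAsFactors = FALSE
)

#' Capture-detection schemes of the epitope-tagged screen
#'
#' The five epitope-based schemes (two GPCR-tag captures with RAMP-tag
#' detection, two RAMP-tag captures with GPCR-tag detection, and RAMP-specific
#' polyclonal capture with GPCR-tag detection, which counts as epitope-based
#' because it generalizes to every receptor) plus the protein-based family of
#' anti-GPCR capture antibodies with RAMP-tag detection.
#'
#' @return data.frame with one row per scheme; \code{capture_antibody_id} is
#'   NA where the capture antibody depends on the RAMP (RAMP-specific
#'   capture) or on the GPCR (protein-based capture).
#' @export
sbaSchemes <- function() {
  rbind(
    .TAG_SCHEMES,
    data.frame(
      scheme_id = c("RAMP-1D4", "GPCR-OLLAS"),
      capture_family = c("epitope_based", "protein_based"),
      capture_kind = c("ramp_specific", "gpcr_specific"),
      detection_kind = c("anti_1d4_pe", "anti_ollas_pe"),
      capture_antibody_id = NA_character_,
      detection_antibody_id = c("det-1D4-PE", "det-OLLAS-PE"),
      stringsAsFactors = FALSE
    )
  )
}

#' Build the sample sheet of a synthetic screen
#'
#' Each receptor contributes one sample per transfection condition: alone
#' (mock co-transfection) and co-expressed with each RAMP. One mock-only
#' sample and the configured number of buffer wells are appended.
#'
#' @param config a [SimulationConfig-class].
#' @return data.frame sample sheet (schema \code{"samples"}).
#' @examples
#' sheet <- buildSampleSheet(simulationConfig(nGpcrs = 215))
#' sum(sheet$gpcr_id != "mock" & !sheet$is_buffer)  # 860
#' @export
buildSampleSheet <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  gpcrs <- sprintf("GPCR%03d", seq_len(config@nGpcrs))
  conds <- c("mock", config@ramps)
  grid <- expand.grid(ramp_id = conds, gpcr_id = gpcrs,
    stringsAsFactors = FALSE)[, c("gpcr_id", "ramp_id")]
  sheet <- data.frame(
    sample_id = sprintf("S-%s-%s", grid$gpcr_id, grid$ramp_id),
    cell_line = "Expi293F",
    gpcr_id = grid$gpcr_id,
    ramp_id = grid$ramp_id,
    bio_replicate = 1L,
    tech_replicate = 1L,
    total_protein = 50,
    is_buffer = FALSE,
    stringsAsFactors = FALSE
  )
  extra <- data.frame(
    sample_id = c("S-mock", sprintf("BUFFER-%02d",
      seq_len(config@nBufferWells))),
    cell_line = "Expi293F",
    gpcr_id = "mock",
    ramp_id = "mock",
    bio_replicate = 1L,
    tech_replicate = 1L,
    total_protein = c(50, rep(0, config@nBufferWells)),
    is_buffer = c(FALSE, rep(TRUE, config@nBufferWells)),
    stringsAsFactors = FALSE
  )
  rbind(sheet, extra)
}

.buildPanel <- function(config) {
  gpcrs <- sprintf("GPCR%03d", seq_len(config@nGpcrs))
  lo <- config@nProteinAbsRange[1L]
  hi <- config@nProteinAbsRange[2L]
  nAbs <- if (lo == hi) rep(lo, length(gpcrs)) else
    sample(seq(lo, hi), length(gpcrs), replace = TRUE)
  hpaIds <- unlist(mapply(function(g, k) {
    if (k > 0) sprintf("HPA-%s-%d", g, seq_len(k)) else character()
  }, gpcrs, nAbs, SIMPLIFY = FALSE), use.names = FALSE)
  hpa <- if (length(hpaIds)) {
    data.frame(antibody_id = hpaIds, target_id = rep(gpcrs, nAbs),
      target_class = "gpcr", role = "capture", host = "rabbit_pab",
      stringsAsFactors = FALSE)
  } else {
    NULL
  }
  core <- data.frame(
    antibody_id = c("anti-1D4", "anti-FLAG", "anti-HA", "anti-OLLAS",
      paste0("anti-", config@ramps)),
    target_id = c("1D4", "FLAG", "HA", "OLLAS", config@ramps),
    target_class = c(rep("epitope_tag", 4L), rep("ramp",
      length(config@ramps))),
    role = "capture",
    host = c(rep("mouse_mab", 4L), rep("rabbit_pab", length(config@ramps))),
    stringsAsFactors = FALSE
  )
  det <- data.frame(
    antibody_id = c("det-1D4-PE", "det-OLLAS-PE"),
    target_id = c("1D4", "OLLAS"),
    target_class = "epitope_tag",
    role = "detection",
    host = "mouse_mab",
    stringsAsFactors = FALSE
  )
  panel <- rbind(core, hpa, det)
  panel$bead_id <- ifelse(panel$role == "capture",
    sprintf("BEAD-%03d", cumsum(panel$role == "capture")), NA_character_)
  panel[, c("antibody_id", "bead_id", "target_id", "target_class", "role",
    "host")]
}

# measurement combinations (capture bead x detection antibody) of the screen;
# includes the RAMP-expression QC readouts (RAMP-tag capture + RAMP-tag
# detection) that are not interaction schemes
.screenCombos <- function(panel, config) {
  cap <- panel[panel$role == "capture", ]
  tags <- .TAG_SCHEMES
  rampAbs <- cap$antibody_id[cap$target_class == "ramp"]
  hpaAbs <- cap$antibody_id[cap$target_class == "gpcr"]
  rbind(
    data.frame(capture_antibody_id = tags$capture_antibody_id,
      detection_antibody_id = tags$detection_antibody_id,
      purpose = "scheme", stringsAsFactors = FALSE),
    data.frame(capture_antibody_id = rampAbs,
      detection_antibody_id = "det-1D4-PE", purpose = "scheme",
      stringsAsFactors = FALSE),
    if (length(hpaAbs)) data.frame(capture_antibody_id = hpaAbs,
      detection_antibody_id = "det-OLLAS-PE", purpose = "scheme",
      stringsAsFactors = FALSE),
    data.frame(capture_antibody_id = c("anti-HA", rampAbs),
      detection_antibody_id = "det-OLLAS-PE", purpose = "qc",
      stringsAsFactors = FALSE)
  )
}

#' Simulate an epitope-tagged GPCR-RAMP interaction screen
#'
#' Generates a seed-reproducible synthetic screen with known ground truth.
#' On the natural-log scale, each MFI record is bead baseline +
#' capture-antibody offset + detection-antibody offset + \code{logEffect}
#' when the probed complex (or, for the expression-QC readouts, the probed
#' RAMP) is present in the well, plus Gaussian noise; MFI is the exponential
#' and therefore strictly positive. Buffer wells are baseline-only.
#'
#' @param config a [SimulationConfig-class].
#' @return An [SBAScreen-class]; `groundTruth()` returns the sampled truth.
#' @examples
#' scr <- simulateScreen(simulationConfig(nGpcrs = 6, seed = 3))
#' scr
#' @export
simulateScreen <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .withSeed(config@seed, {
    gpcrs <- sprintf("GPCR%03d", seq_len(config@nGpcrs))
    truth <- expand.grid(ramp_id = config@ramps, gpcr_id = gpcrs,
      stringsAsFactors = FALSE)[, c("gpcr_id", "ramp_id")]
    truth$interacting <- rbinom(nrow(truth), 1L, config@interactProb) == 1L
    samples <- buildSampleSheet(config)
    panel <- .buildPanel(config)
    combos <- .screenCombos(panel, config)

    beads <- panel$antibody_id[panel$role == "capture"]
    baseline <- setNames(log(100) + rnorm(length(beads), 0, 0.2), beads)
    affinity <- setNames(rnorm(nrow(panel), 0, config@abAffinitySd),
      panel$antibody_id)

    rec <- merge(combos, samples[, c("sample_id", "gpcr_id", "ramp_id",
      "is_buffer")], by = NULL)  # cross join
    capTarget <- setNames(panel$target_id, panel$antibody_id)
    capClass <- setNames(panel$target_class, panel$antibody_id)
    ct <- capTarget[rec$capture_antibody_id]
    cc <- capClass[rec$capture_antibody_id]
    isRampDet <- rec$detection_antibody_id == "det-OLLAS-PE"
    complex <- !rec$is_buffer & rec$gpcr_id != "mock" &
      rec$ramp_id != "mock" &
      .truthLookup(truth, rec$gpcr_id, rec$ramp_id)
    present <- logical(nrow(rec))
    schemeRow <- rec$purpose == "scheme"
    # interaction schemes require the complex, and the capture antibody must
    # bind a constituent actually present in the well
    tagCapture <- schemeRow & cc == "epitope_tag"
    present[tagCapture] <- complex[tagCapture]
    rampCapture <- schemeRow & cc == "ramp"
    present[rampCapture] <- complex[rampCapture] &
      ct[rampCapture] == rec$ramp_id[rampCapture]
    gpcrCapture <- schemeRow & cc == "gpcr"
    present[gpcrCapture] <- complex[gpcrCapture] &
      ct[gpcrCapture] == rec$gpcr_id[gpcrCapture]
    # QC readouts see the free RAMP irrespective of complex formation
    qcHA <- rec$purpose == "qc" & cc == "epitope_tag"
    present[qcHA] <- !rec$is_buffer[qcHA] & rec$ramp_id[qcHA] != "mock"
    qcRamp <- rec$purpose == "qc" & cc == "ramp"
    present[qcRamp] <- !rec$is_buffer[qcRamp] &
      ct[qcRamp] == rec$ramp_id[qcRamp]

    logmfi <- baseline[rec$capture_antibody_id] +
      affinity[rec$capture_antibody_id] +
      affinity[rec$detection_antibody_id] +
      config@logEffect * present +
      rnorm(nrow(rec), 0, config@noiseSd)
    mfi <- data.frame(
      sample_id = rec$sample_id,
      capture_antibody_id = rec$capture_antibody_id,
      detection_antibody_id = rec$detection_antibody_id,
      mfi = exp(logmfi),
      stringsAsFactors = FALSE
    )
    mfi <- mfi[order(mfi$sample_id, mfi$capture_antibody_id,
      mfi$detection_antibody_id), ]
    rownames(mfi) <- NULL
    new("SBAScreen", mfi = mfi, panel = panel, samples = samples,
      schemes = sbaSchemes(), truth = truth,
      metadata = list(config = .configAsList(config), kind = "duet_screen"))
  })
}

.truthLookup <- function(truth, gpcr, ramp) {
  key <- paste(truth$gpcr_id, truth$ramp_id)
  flag <- setNames(truth$interacting, key)
  out <- flag[paste(gpcr, ramp)]
  out[is.na(out)] <- FALSE
  unname(out)
}

.configAsList <- function(config) {
  list(nGpcrs = config@nGpcrs, ramps = config@ramps,
    interactProb = config@interactProb, logEffect = config@logEffect,
    noiseSd = config@noiseSd, abAffinitySd = config@abAffinitySd,
    nProteinAbsRange = config@nProteinAbsRange,
    nBufferWells = config@nBufferWells,
    truthLabelNoise = config@truthLabelNoise, seed = config@seed)
}

#' Sample a literature-style truth set from a ground truth
#'
#' Stands in for the set of previously published interaction /
#' non-interaction reports used to calibrate thresholds: a fraction of all
#' pairs is sampled without replacement and each sampled label is flipped
#' with probability \code{labelNoise}.
#'
#' @param truth ground-truth data.frame (\code{gpcr_id}, \code{ramp_id},
#'   \code{interacting}) or an [SBAScreen-class].
#' @param coverage fraction of pairs retained, in (0, 1].
#' @param labelNoise flip probability in [0, 1).
#' @param seed integer seed.
#' @return data.frame with columns \code{gpcr_id}, \code{ramp_id},
#'   \code{label} (\code{"interacting"} / \code{"non_interacting"}).
#' @export
simulateTruthSet <- function(truth, coverage = 1, labelNoise = 0, seed = 1L) {
  if (is(truth, "SBAScreen")) truth <- groundTruth(truth)
  .assertScalarNumber(coverage, "coverage", lower = 0, upper = 1,
    strict_lower = TRUE)
  .assertScalarNumber(labelNoise, "labelNoise", lower = 0, upper = 1)
  if (labelNoise >= 1) .validationError("labelNoise must be < 1")
  .withSeed(seed, {
    n <- round(coverage * nrow(truth))
    if (n < 1L) .calibrationError("coverage selects no pairs")
    keep <- sort(sample.int(nrow(truth), n))
    out <- truth[keep, c("gpcr_id", "ramp_id"), drop = FALSE]
    lab <- truth$interacting[keep]
    if (labelNoise > 0) {
      flip <- runif(n) < labelNoise
      lab <- xor(lab, flip)
    }
    out$label <- ifelse(lab, "interacting", "non_interacting")
    rownames(out) <- NULL
    out
  })
}

#' Simulate an endogenous (wild-type cell line) SBA screen
#'
#' Per cell line, biological triplicates measured in technical duplicate on
#' anti-GPCR capture beads (one antibody per receptor) with RAMP-specific
#' detection, plus buffer wells. A minority of (GPCR, RAMP) pairs carry the
#' interaction effect; the same truth applies to all cell lines.
#'
#' @param config a [SimulationConfig-class]; \code{nGpcrs} sets the number of
#'   anti-GPCR capture antibodies.
#' @param nCellLines number of cell lines (>= 1).
#' @param interactFraction probability that a pair carries the effect
#'   (kept small so the negative bulk dominates each detection channel).
#' @param nBioReplicates,nTechReplicates replicate design per cell line.
#' @return An [SBAScreen-class] with \code{metadata$kind == "endogenous"}.
#' @export
simulateEndogenous <- function(config, nCellLines = 3L,
                               interactFraction = 0.05,
                               nBioReplicates = 3L, nTechReplicates = 2L) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (nCellLines < 1L) .validationError("nCellLines must be >= 1")
  .assertScalarNumber(interactFraction, "interactFraction", 0, 1)
  .withSeed(config@seed, {
    gpcrs <- sprintf("GPCR%03d", seq_len(config@nGpcrs))
    cells <- sprintf("CELL%d", seq_len(nCellLines))
    truth <- expand.grid(ramp_id = config@ramps, gpcr_id = gpcrs,
      stringsAsFactors = FALSE)[, c("gpcr_id", "ramp_id")]
    truth$interacting <- rbinom(nrow(truth), 1L, interactFraction) == 1L

    cap <- data.frame(
      antibody_id = paste0("AB-", gpcrs),
      bead_id = sprintf("BEAD-%03d", seq_along(gpcrs)),
      target_id = gpcrs, target_class = "gpcr", role = "capture",
      host = "rabbit_pab", stringsAsFactors = FALSE)
    det <- data.frame(
      antibody_id = paste0("det-", config@ramps, "-PE"),
      bead_id = NA_character_, target_id = config@ramps,
      target_class = "ramp", role = "detection", host = "rabbit_pab",
      stringsAsFactors = FALSE)
    panel <- rbind(cap, det)

    reps <- expand.grid(tech_replicate = seq_len(nTechReplicates),
      bio_replicate = seq_len(nBioReplicates), cell_line = cells,
      stringsAsFactors = FALSE)
    lysates <- data.frame(
      sample_id = sprintf("L-%s-b%d-t%d", reps$cell_line,
        reps$bio_replicate, reps$tech_replicate),
      cell_line = reps$cell_line, gpcr_id = "endogenous",
      ramp_id = "endogenous", bio_replicate = reps$bio_replicate,
      tech_replicate = reps$tech_replicate, total_protein = 50,
      is_buffer = FALSE, stringsAsFactors = FALSE)
    bufs <- expand.grid(well = seq_len(config@nBufferWells),
      cell_line = cells, stringsAsFactors = FALSE)
    buffers <- data.frame(
      sample_id = sprintf("BUF-%s-%02d", bufs$cell_line, bufs$well),
      cell_line = bufs$cell_line, gpcr_id = "mock", ramp_id = "mock",
      bio_replicate = 1L, tech_replicate = 1L, total_protein = 0,
      is_buffer = TRUE, stringsAsFactors = FALSE)
    samples <- rbind(lysates, buffers)

    baseline <- setNames(log(100) + rnorm(nrow(cap), 0, 0.2),
      cap$antibody_id)
    affinity <- setNames(rnorm(nrow(panel), 0, config@abAffinitySd),
      panel$antibody_id)

    rec <- merge(
      expand.grid(capture_antibody_id = cap$antibody_id,
        detection_antibody_id = det$antibody_id, stringsAsFactors = FALSE),
      samples[, c("sample_id", "is_buffer")], by = NULL)
    g <- sub("^AB-", "", rec$capture_antibody_id)
    r <- sub("-PE$", "", sub("^det-", "", rec$detection_antibody_id))
    present <- !rec$is_buffer & .truthLookup(truth, g, r)
    logmfi <- baseline[rec$capture_antibody_id] +
      affinity[rec$capture_antibody_id] +
      affinity[rec$detection_antibody_id] +
      config@logEffect * present + rnorm(nrow(rec), 0, config@noiseSd)
    mfi <- data.frame(
      sample_id = rec$sample_id,
      capture_antibody_id = rec$capture_antibody_id,
      detection_antibody_id = rec$detection_antibody_id,
      mfi = exp(logmfi), stringsAsFactors = FALSE)
    mfi <- mfi[order(mfi$sample_id, mfi$capture_antibody_id,
      mfi$detection_antibody_id), ]
    rownames(mfi) <- NULL

    schemes <- data.frame(scheme_id = "GPCRcapt-RAMPdet",
      capture_family = "protein_based", capture_kind = "gpcr_specific",
      detection_kind = "anti_ramp_pe", capture_antibody_id = NA_character_,
      detection_antibody_id = NA_character_, stringsAsFactors = FALSE)
    new("SBAScreen", mfi = mfi, panel = panel, samples = samples,
      schemes = schemes, truth = truth,
      metadata = list(config = .configAsList(config), kind = "endogenous",
        nCellLines = nCellLines, interactFraction = interactFraction))
  })
}

#' Simulate MolBoolean rolling-circle-product count tables
#'
#' Per image: a nuclei count drawn uniformly from \code{cellsPerImage} and
#' Poisson-distributed RCP counts per channel with per-cell rates given by
#' \code{meanRcpPerCell}, plus a blank (unstained) series whose per-cell rate
#' is \code{blankRate} in every channel.
#'
#' @param nImages images per stain condition.
#' @param meanRcpPerCell numeric of length 3 (per-cell rates for the
#'   GPCR-only, RAMP-only and complexed channels) or a named list of such
#'   vectors, one per stain condition.
#' @param blankRate per-cell RCP rate of the blank series (>= 0).
#' @param cellsPerImage length-2 integer range of cells per image; the lower
#'   bound must be >= 1.
#' @param seed integer seed.
#' @param condition stain-condition name when \code{meanRcpPerCell} is a
#'   single vector.
#' @return data.frame (schema \code{"rcp"}) including the blank rows.
#' @export
simulateRcpCounts <- function(nImages, meanRcpPerCell = c(8, 8, 5),
                              blankRate = 0.5, cellsPerImage = c(20L, 60L),
                              seed = 1L, condition = "stain") {
  if (nImages < 1L) .validationError("nImages must be >= 1")
  .assertScalarNumber(blankRate, "blankRate", lower = 0)
  if (length(cellsPerImage) != 2L || cellsPerImage[1L] < 1L ||
      cellsPerImage[1L] > cellsPerImage[2L]) {
    .validationError("cellsPerImage must be a range (lo, hi) with lo >= 1")
  }
  if (!is.list(meanRcpPerCell)) {
    meanRcpPerCell <- setNames(list(meanRcpPerCell), condition)
  }
  for (rates in meanRcpPerCell) {
    if (length(rates) != 3L || any(!is.finite(rates)) || any(rates < 0)) {
      .validationError("each rate vector must be 3 non-negative numbers")
    }
  }
  .withSeed(seed, {
    one <- function(cond, rates) {
      nuclei <- sample(seq(cellsPerImage[1L], cellsPerImage[2L]), nImages,
        replace = TRUE)
      data.frame(
        image_id = sprintf("%s-img%03d", cond, seq_len(nImages)),
        stain_condition = cond,
        nuclei = nuclei,
        rcp_gpcr = rpois(nImages, nuclei * rates[1L]),
        rcp_ramp = rpois(nImages, nuclei * rates[2L]),
        rcp_overlap = rpois(nImages, nuclei * rates[3L]),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(
      mapply(one, names(meanRcpPerCell), meanRcpPerCell, SIMPLIFY = FALSE),
      list(one("blank", rep(blankRate, 3L)))))
    rownames(out) <- NULL
    out
  })
}
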