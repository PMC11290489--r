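#' Configuration of a synthetic SBA screen
#'
#' Parameters of the synthetic suspension-bead-array (SBA) screen generator.
#' The generator emulates a screen in which every GPCR is expressed alone
#' (mock) and co-expressed with each RAMP, the lysates are measured on a
#' multiplexed bead panel over five epitope-based capture-detection schemes
#' and a variable number of protein-based (anti-GPCR antibody) schemes, and
#' buffer wells provide the background for signal-to-noise ratios.
#'
#' Intensities follow a lognormal noise model: on the natural-log scale a
#' measurement is bead baseline + capture-antibody offset + detection-antibody
#' offset + \code{logEffect} when the probed complex is present, plus
#' Gaussian noise with standard deviation \code{noiseSd}. Exponentiation
#' guarantees strictly positive MFI and gives the heavy-tailed bulk typical
#' of Luminex data.
#'
#' @slot nGpcrs number of receptors in the library.
#' @slot ramps character vector of RAMP identifiers.
#' @slot interactProb probability that a (GPCR, RAMP) pair truly interacts.
#' @slot logEffect mean natural-log MFI shift added when a true complex is
#'   measured by a scheme that requires it.
#' @slot noiseSd standard deviation of the log-scale measurement noise.
#' @slot abAffinitySd spread of per-antibody log-scale affinity offsets.
#' @slot nProteinAbsRange integer interval (lo, hi): anti-GPCR capture
#'   antibodies available per receptor (0 allowed).
#' @slot nBufferWells number of buffer-only wells.
#' @slot truthLabelNoise probability that a literature truth label is flipped.
#' @slot seed integer seed for the random generator.
#'
#' @seealso [simulationConfig()], [simulateScreen()]
#' @export
setClass("SimulationConfig",
  representation(
    nGpcrs = "integer",
    ramps = "character",
    interactProb = "numeric",
    logEffect = "numeric",
    noiseSd = "numeric",
    abAffinitySd = "numeric",
    nProteinAbsRange = "integer",
    nBufferWells = "integer",
    truthLabelNoise = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@nGpcrs) != 1L || is.na(object@nGpcrs) ||
      object@nGpcrs < 1L) {
    msg <- c(msg, "nGpcrs must be a positive integer")
  }
  if (length(object@ramps) < 1L || anyDuplicated(object@ramps) ||
      any(!nzchar(object@ramps))) {
    msg <- c(msg, "ramps must be a non-empty set of unique identifiers")
  }
  if (object@interactProb < 0 || object@interactProb > 1) {
    msg <- c(msg, "interactProb must lie in [0, 1]")
  }
  if (!is.finite(object@noiseSd) || object@noiseSd <= 0) {
    msg <- c(msg, "noiseSd must be > 0")
  }
  if (object@abAffinitySd < 0) {
    msg <- c(msg, "abAffinitySd must be >= 0")
  }
  if (length(object@nProteinAbsRange) != 2L ||
      any(object@nProteinAbsRange < 0L) ||
      object@nProteinAbsRange[1L] > object@nProteinAbsRange[2L]) {
    msg <- c(msg, "nProteinAbsRange must be an integer interval lo <= hi, lo >= 0")
  }
  if (object@nBufferWells < 1L) {
    msg <- c(msg, "nBufferWells must be a positive integer")
  }
  if (object@truthLabelNoise < 0 || object@truthLabelNoise >= 1) {
    msg <- c(msg, "truthLabelNoise must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-screen configuration
#'
#' @param nGpcrs positive integer, number of receptors.
#' @param ramps character vector of RAMP identifiers.
#' @param interactProb per-RAMP probability of a true interaction, in [0, 1].
#' @param logEffect log-scale MFI shift of a true complex (default 2.0, i.e.
#'   about a 7.4-fold intensity increase).
#' @param noiseSd log-scale noise standard deviation (> 0).
#' @param abAffinitySd per-antibody log-scale affinity spread (>= 0).
#' @param nProteinAbsRange length-2 integer interval, antibodies per GPCR for
#'   protein-based capture; 0 is allowed and yields receptors without protein
#'   capture data.
#' @param nBufferWells number of buffer-only wells.
#' @param truthLabelNoise probability in [0, 1) of flipping a truth label.
#' @param seed integer seed.
#'
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nGpcrs = 4, seed = 7)
#' @export
simulationConfig <- function(nGpcrs,
                             ramps = c("RAMP1", "RAMP2", "RAMP3"),
                             interactProb = 0.5,
                             logEffect = 2.0,
                             noiseSd = 0.5,
                             abAffinitySd = 0.3,
                             nProteinAbsRange = c(0L, 6L),
                             nBufferWells = 8L,
                             truthLabelNoise = 0,
                             seed = 1L) {
  new("SimulationConfig",
    nGpcrs = as.integer(nGpcrs),
    ramps = as.character(ramps),
    interactProb = as.numeric(interactProb),
    logEffect = as.numeric(logEffect),
    noiseSd = as.numeric(noiseSd),
    abAffinitySd = as.numeric(abAffinitySd),
    nProteinAbsRange = as.integer(nProteinAbsRange),
    nBufferWells = as.integer(nBufferWells),
    truthLabelNoise = as.numeric(truthLabelNoise),
    seed = as.integer(seed)
  )
}

#' A multiplexed SBA screen
#'
#' Container for one suspension-bead-array screen: the long-format MFI table,
#' the antibody panel, the sample sheet, the capture-detection scheme table
#' and, for synthetic screens, the generating ground truth and configuration.
#'
#' @slot mfi data.frame with columns \code{sample_id},
#'   \code{capture_antibody_id}, \code{detection_antibody_id}, \code{mfi}.
#' @slot panel data.frame describing antibodies (see [readSbaTable()] schema
#'   \code{"panel"}).
#' @slot samples data.frame sample sheet (schema \code{"samples"}).
#' @slot schemes data.frame of capture-detection schemes.
#' @slot truth data.frame with columns \code{gpcr_id}, \code{ramp_id},
#'   \code{interacting} (logical), or a zero-row data.frame for real screens.
#' @slot metadata list of provenance information (configuration values, seed).
#'
#' @export
setClass("SBAScreen",
  representation(
    mfi = "data.frame",
    panel = "data.frame",
    samples = "data.frame",
    schemes = "data.frame",
    truth = "data.frame",
    metadata = "list"
  )
)

setValidity("SBAScreen", function(object) {
  msg <- character()
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
    } else {
      character()
    }
  }
  msg <- c(msg, need(object@mfi,
    c("sample_id", "capture_antibody_id", "detection_antibody_id", "mfi"),
    "mfi"))
  msg <- c(msg, need(object@panel,
    c("antibody_id", "bead_id", "target_id", "target_class", "role", "host"),
    "panel"))
  msg <- c(msg, need(object@samples,
    c("sample_id", "cell_line", "gpcr_id", "ramp_id", "bio_replicate",
      "tech_replicate", "total_protein", "is_buffer"),
    "samples"))
  if (!length(msg)) {
    if (any(object@mfi$mfi < 0, na.rm = TRUE)) {
      msg <- c(msg, "mfi values must be non-negative")
    }
    if (anyDuplicated(object@samples$sample_id)) {
      msg <- c(msg, "sample_id must be unique in the sample sheet")
    }
    key <- paste(object@mfi$sample_id, object@mfi$capture_antibody_id,
      object@mfi$detection_antibody_id)
    if (anyDuplicated(key)) {
      msg <- c(msg, "(sample, capture, detection) keys must be unique in mfi")
    }
    unknown <- setdiff(object@mfi$sample_id, object@samples$sample_id)
    if (length(unknown)) {
      msg <- c(msg, sprintf("mfi references unknown sample(s): %s",
        paste(head(unknown, 3L), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Normalized score matrix
#'
#' Long-format scores per (GPCR, RAMP, scoring unit), where the unit is an
#' epitope-based capture-detection scheme or a protein-based capture
#' antibody. Exactly one score kind is stored per object.
#'
#' @slot scores data.frame with columns \code{gpcr_id}, \code{ramp_id},
#'   \code{unit_id}, \code{capture_family}, \code{score}, plus optional
#'   grouping columns (e.g. \code{cell_line}).
#' @slot scoreKind one of \code{"raw_mfi"}, \code{"snr"}, \code{"z"},
#'   \code{"robust_z"}.
#' @export
setClass("ScoreMatrix",
  representation(scores = "data.frame", scoreKind = "character")
)

setValidity("ScoreMatrix", function(object) {
  msg <- character()
  cols <- c("gpcr_id", "ramp_id", "unit_id", "capture_family", "score")
  miss <- setdiff(cols, names(object@scores))
  if (length(miss)) {
    msg <- c(msg, sprintf("scores is missing column(s): %s",
      paste(miss, collapse = ", ")))
  }
  if (length(object@scoreKind) != 1L ||
      !object@scoreKind %in% c("raw_mfi", "snr", "z", "robust_z")) {
    msg <- c(msg, "scoreKind must be one of raw_mfi, snr, z, robust_z")
  }
  if (!length(msg) && nrow(object@scores) &&
      !all(is.finite(object@scores$score))) {
    msg <- c(msg, "scores must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Interaction-calling thresholds
#'
#' Thresholds on the robust-Z scale: literature-calibrated thresholds per
#' (RAMP, epitope scheme), density + MAD thresholds per protein-capture
#' antibody, and the fixed endogenous cutoff (default 3.5).
#'
#' @slot thresholds data.frame with columns \code{unit_id}, \code{ramp_id}
#'   (NA for per-antibody thresholds that apply across RAMPs),
#'   \code{capture_family}, \code{threshold}.
#' @slot endogenous single numeric, cutoff for endogenous screens.
#' @export
setClass("ThresholdSet",
  representation(thresholds = "data.frame", endogenous = "numeric")
)

setValidity("ThresholdSet", function(object) {
  msg <- character()
  cols <- c("unit_id", "ramp_id", "capture_family", "threshold")
  miss <- setdiff(cols, names(object@thresholds))
  if (length(miss)) {
    msg <- c(msg, sprintf("thresholds is missing column(s): %s",
      paste(miss, collapse = ", ")))
  }
  if (!length(msg) && nrow(object@thresholds) &&
      !all(is.finite(object@thresholds$threshold))) {
    msg <- c(msg, "thresholds must be finite")
  }
  if (length(object@endogenous) != 1L || !is.finite(object@endogenous)) {
    msg <- c(msg, "endogenous cutoff must be a single finite number")
  }
  if (length(msg)) msg else TRUE
})

#' Binary call matrix
#'
#' One row per scored (GPCR, RAMP, unit): the score, the threshold applied
#' and the resulting hit flag (strict \code{score > threshold}).
#'
#' @slot calls data.frame with columns \code{gpcr_id}, \code{ramp_id},
#'   \code{unit_id}, \code{capture_family}, \code{score}, \code{threshold},
#'   \code{hit}, plus optional grouping columns.
#' @export
setClass("CallMatrix", representation(calls = "data.frame"))

setValidity("CallMatrix", function(object) {
  cols <- c("gpcr_id", "ramp_id", "unit_id", "capture_family", "score",
    "threshold", "hit")
  miss <- setdiff(cols, names(object@calls))
  if (length(miss)) {
    sprintf("calls is missing column(s): %s", paste(miss, collapse = ", "))
  } else if (nrow(object@calls) && !is.logical(object@calls$hit)) {
    "hit must be logical"
  } else {
    TRUE
  }
})
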