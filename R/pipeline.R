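# End-to-end orchestration: simulate -> score -> calibrate -> call ->
# integrate -> summarize, with every stage artifact written to disk so each
# stage is independently inspectable and reruns are byte-identical.

#' Run the screen pipeline end to end
#'
#' Simulates a screen from \code{config} (or scores supplied tables),
#' computes robust-Z score matrices, calibrates the epitope-scheme
#' thresholds on a truth set sampled from the ground truth, derives the
#' per-antibody density + MAD thresholds, produces call matrices, evidence
#' classes, the yes/no/inconclusive annotation and the summary count tables.
#' All intermediate tables are written as TSV with JSON metadata sidecars;
#' rerunning with the same configuration reproduces identical files.
#'
#' @param config a [SimulationConfig-class].
#' @param outDir output directory, created if needed; NULL skips writing.
#' @param truthCoverage fraction of ground-truth pairs in the calibration
#'   truth set.
#' @param truthLabelNoise label-flip probability of the truth set; defaults
#'   to the configuration value.
#' @param madMultiplier scaled-MAD multiplier for protein thresholds.
#' @return (invisibly) list with the screen, score matrices, threshold
#'   sets, call matrices, evidence table, annotation and summaries.
#' @export
runPipeline <- function(config, outDir = NULL, truthCoverage = 1,
                        truthLabelNoise = NULL, madMultiplier = 6) {
  stopifnot(is(config, "SimulationConfig"))
  if (is.null(truthLabelNoise)) truthLabelNoise <- config@truthLabelNoise
  meta <- c(.configAsList(config), list(truthCoverage = truthCoverage,
    truthLabelNoise = truthLabelNoise, madMultiplier = madMultiplier))
  emit <- function(df, name, schema = NULL) {
    if (!is.null(outDir)) {
      writeSbaTable(df, file.path(outDir, paste0(name, ".tsv")),
        schema = schema, metadata = meta)
    }
    message(sprintf("[%s] %d rows", name, nrow(df)))
  }
  if (!is.null(outDir) && !dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }

  screen <- simulateScreen(config)
  emit(mfiTable(screen), "mfi", "mfi")
  emit(antibodyPanel(screen), "panel", "panel")
  emit(sampleSheet(screen), "samples", "samples")

  truthSet <- simulateTruthSet(screen, coverage = truthCoverage,
    labelNoise = truthLabelNoise, seed = config@seed + 1L)
  emit(truthSet, "truth_set", "truth")

  sm <- scoreScreen(screen)
  emit(scores(sm$epitope), "scores_epitope")

  thEp <- calibrateThresholds(sm$epitope, truthSet)
  emit(thresholds(thEp), "thresholds_epitope")
  epCalls <- applyThresholds(sm$epitope, thEp)
  emit(calls(epCalls), "calls_epitope")

  prCalls <- NULL
  if (!is.null(sm$protein)) {
    thPr <- proteinThresholds(screen, madMultiplier = madMultiplier)
    emit(thresholds(thPr), "thresholds_protein")
    prCalls <- applyThresholds(sm$protein, thPr)
    emit(calls(prCalls), "calls_protein")
  }

  allCalls <- rbind(calls(epCalls),
    if (!is.null(prCalls)) calls(prCalls))
  evidence <- evidenceTable(new("CallMatrix", calls = allCalls))
  emit(evidence, "evidence")
  annotation <- annotateInteractome(evidence)
  emit(annotation, "annotation")

  summaries <- summarizeScreen(epitopeCalls = epCalls,
    proteinCalls = prCalls, annotation = annotation)
  if (!is.null(outDir)) {
    for (nm in names(summaries)) {
      if (!is.null(summaries[[nm]])) {
        writeSbaTable(summaries[[nm]],
          file.path(outDir, paste0("summary_", nm, ".tsv")),
          metadata = meta)
      }
    }
  }
  invisible(list(screen = screen, truthSet = truthSet, scoreMatrices = sm,
    epitopeThresholds = thEp, epitopeCalls = epCalls,
    proteinCalls = prCalls, evidence = evidence, annotation = annotation,
    summaries = summaries))
}
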