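# Tabular data model: schema registry, validated readers/writers, and the
# join that assembles scoring input from MFI + panel + sample sheet.

.SCHEMAS <- list(
  mfi = list(
    columns = c(sample_id = "character", capture_antibody_id = "character",
      detection_antibody_id = "character", mfi = "numeric"),
    key = c("sample_id", "capture_antibody_id", "detection_antibody_id")
  ),
  panel = list(
    columns = c(antibody_id = "character", bead_id = "character",
      target_id = "character", target_class = "character",
      role = "character", host = "character"),
    key = "antibody_id"
  ),
  samples = list(
    columns = c(sample_id = "character", cell_line = "character",
      gpcr_id = "character", ramp_id = "character",
      bio_replicate = "integer", tech_replicate = "integer",
      total_protein = "numeric", is_buffer = "logical"),
    key = "sample_id"
  ),
  truth = list(
    columns = c(gpcr_id = "character", ramp_id = "character",
      label = "character"),
    key = c("gpcr_id", "ramp_id")
  ),
  expression = list(
    columns = c(gene_id = "character", context_id = "character",
      ntpm = "numeric"),
    key = c("gene_id", "context_id")
  ),
  coupling = list(
    columns = c(gpcr_id = "character", transducer = "character",
      tier = "character", log_emax_over_ec50 = "numeric"),
    key = c("gpcr_id", "transducer", "tier")
  ),
  rcp = list(
    columns = c(image_id = "character", stain_condition = "character",
      nuclei = "integer", rcp_gpcr = "integer", rcp_ramp = "integer",
      rcp_overlap = "integer"),
    key = c("image_id", "stain_condition")
  )
)

.coerceColumn <- function(x, type, name) {
  raw <- trimws(as.character(x))
  missing <- is.na(x) | raw %in% c("", "NA", "NaN")
  out <- switch(type,
    character = as.character(x),
    logical = as.logical(raw),
    integer = suppressWarnings(as.integer(raw)),
    numeric = suppressWarnings(as.numeric(raw))
  )
  bad <- which(!missing & is.na(out))
  if (length(bad)) {
    .validationError(sprintf(
      "column '%s': unparsable %s value(s) at row(s) %s", name, type,
      paste(head(bad, 5L), collapse = ", ")))
  }
  out
}

#' Validate a data.frame against a table schema
#'
#' Header matching is case-insensitive and order-free; numeric columns are
#' coerced with an error naming unparsable rows; duplicate keys raise a
#' validation error listing the offending keys. Rows with a missing value in
#' the table's measurement column (\code{mfi}, \code{ntpm}) are dropped with
#' a message; missing values elsewhere are not allowed.
#'
#' @param df a data.frame.
#' @param schema one of \code{"mfi"}, \code{"panel"}, \code{"samples"},
#'   \code{"truth"}, \code{"expression"}, \code{"coupling"}, \code{"rcp"}.
#' @return the validated, coerced data.frame (row order preserved).
#' @export
validateSbaTable <- function(df, schema) {
  spec <- .SCHEMAS[[match.arg(schema, names(.SCHEMAS))]]
  names(df) <- tolower(names(df))
  miss <- setdiff(names(spec$columns), names(df))
  if (length(miss)) {
    .validationError(sprintf("missing required column(s): %s",
      paste(miss, collapse = ", ")))
  }
  df <- df[, names(spec$columns), drop = FALSE]
  for (nm in names(spec$columns)) {
    df[[nm]] <- .coerceColumn(df[[nm]], spec$columns[[nm]], nm)
  }
  valueCol <- intersect(c("mfi", "ntpm"), names(df))
  if (length(valueCol)) {
    drop <- is.na(df[[valueCol]])
    if (any(drop)) {
      message(sprintf("dropping %d row(s) with missing %s", sum(drop),
        valueCol))
      df <- df[!drop, , drop = FALSE]
    }
  }
  isMissing <- vapply(df, function(x) anyNA(x), logical(1L))
  allowedNA <- c("bead_id", "log_emax_over_ec50")
  badNA <- setdiff(names(df)[isMissing], allowedNA)
  if (length(badNA)) {
    .validationError(sprintf("missing values not allowed in column(s): %s",
      paste(badNA, collapse = ", ")))
  }
  key <- do.call(paste, c(df[spec$key], sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    shown <- gsub("\r", " / ", unique(key[dup]))
    .validationError(sprintf("duplicate key(s) for (%s): %s",
      paste(spec$key, collapse = ", "),
      paste(head(shown, 5L), collapse = "; ")))
  }
  if ("mfi" %in% names(df) && any(df$mfi < 0)) {
    .validationError("mfi values must be non-negative")
  }
  if ("ntpm" %in% names(df) && any(df$ntpm < 0)) {
    .validationError("ntpm values must be non-negative")
  }
  if ("nuclei" %in% names(df) && any(df$nuclei < 1L)) {
    .validationError("nuclei must be >= 1")
  }
  rownames(df) <- NULL
  df
}

.inferDelim <- function(path, delim) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read and validate a typed table
#'
#' @param path CSV or TSV file; the delimiter is inferred from the extension
#'   unless \code{delim} is given.
#' @param schema table kind; see [validateSbaTable()].
#' @param delim optional field delimiter override.
#' @return validated data.frame.
#' @export
readSbaTable <- function(path, schema, delim = NULL) {
  if (!file.exists(path)) .validationError(sprintf("no such file: %s", path))
  df <- read.csv(path, sep = .inferDelim(path, delim),
    stringsAsFactors = FALSE, check.names = FALSE)
  validateSbaTable(df, schema)
}

#' Write a table with a JSON metadata sidecar
#'
#' Writes CSV or TSV (by extension) plus \code{<path>.meta.json} recording
#' the schema, package version and any caller-supplied metadata (seed,
#' configuration). No timestamps are written, so identical inputs produce
#' byte-identical outputs.
#'
#' @param df data.frame to write.
#' @param path output file ending in .csv or .tsv.
#' @param schema optional schema name; when given the table is validated
#'   before writing.
#' @param metadata named list stored in the sidecar.
#' @return \code{path}, invisibly.
#' @export
writeSbaTable <- function(df, path, schema = NULL, metadata = list()) {
  if (!is.null(schema)) df <- validateSbaTable(df, schema)
  sep <- .inferDelim(path, NULL)
  write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  side <- c(list(schema = if (is.null(schema)) NA else schema,
    package = "RAMPscreen",
    version = as.character(utils::packageVersion("RAMPscreen")),
    n_rows = nrow(df)), metadata)
  jsonlite::write_json(side, paste0(path, ".meta.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  invisible(path)
}

#' Assemble scoring input from a screen
#'
#' Joins the MFI table with the antibody panel, sample sheet and scheme
#' table into one row per measured (GPCR, RAMP-condition, scheme, capture
#' antibody, replicate). Mock co-transfection rows are retained (with
#' \code{ramp_id == "mock"}); for the RAMP-specific capture scheme a mock
#' well has no matching capture bead, so its row carries NA measurement.
#' Buffer wells are returned separately for SNR normalization.
#'
#' @param screen an [SBAScreen-class] (or the corresponding \code{mfi},
#'   \code{panel}, \code{samples}, \code{schemes} tables).
#' @param mfi,panel,samples,schemes individual tables, used when
#'   \code{screen} is missing.
#' @return list with elements \code{pairs} (data.frame: \code{gpcr_id},
#'   \code{ramp_id}, \code{scheme_id}, \code{capture_family},
#'   \code{capture_antibody_id}, \code{detection_antibody_id},
#'   \code{replicate}, \code{mfi}) and \code{buffer} (buffer-well records).
#' @export
buildScoreInput <- function(screen, mfi = NULL, panel = NULL, samples = NULL,
                            schemes = NULL) {
  if (!missing(screen)) {
    stopifnot(is(screen, "SBAScreen"))
    mfi <- screen@mfi; panel <- screen@panel
    samples <- screen@samples; schemes <- screen@schemes
  }
  unknownAb <- setdiff(
    unique(c(mfi$capture_antibody_id, mfi$detection_antibody_id)),
    panel$antibody_id)
  if (length(unknownAb)) {
    .joinError(sprintf("MFI references unknown antibody id(s): %s",
      paste(head(unknownAb, 5L), collapse = ", ")))
  }
  unknownS <- setdiff(mfi$sample_id, samples$sample_id)
  if (length(unknownS)) {
    .joinError(sprintf("MFI references unknown sample id(s): %s",
      paste(head(unknownS, 5L), collapse = ", ")))
  }
  m <- merge(mfi, samples, by = "sample_id")
  buffer <- m[m$is_buffer, c("capture_antibody_id", "detection_antibody_id",
    "mfi")]
  m <- m[!m$is_buffer & m$gpcr_id != "mock", , drop = FALSE]
  capInfo <- panel[panel$role == "capture", ]
  m <- merge(m, setNames(capInfo[, c("antibody_id", "target_id",
    "target_class")], c("capture_antibody_id", "capture_target",
    "capture_target_class")), by = "capture_antibody_id")

  ep <- schemes[schemes$capture_family == "epitope_based", , drop = FALSE]
  out <- vector("list", nrow(ep) + 1L)
  for (i in seq_len(nrow(ep))) {
    s <- ep[i, ]
    if (!is.na(s$capture_antibody_id)) {
      sel <- m[m$capture_antibody_id == s$capture_antibody_id &
        m$detection_antibody_id == s$detection_antibody_id, , drop = FALSE]
    } else {
      # RAMP-specific capture: bead must match the sample's RAMP; mock wells
      # have no matching bead and contribute an NA row per sample
      sel <- m[m$capture_target_class == "ramp" &
        m$capture_target == m$ramp_id &
        m$detection_antibody_id == s$detection_antibody_id, , drop = FALSE]
      mockWells <- unique(m[m$ramp_id == "mock",
        c("sample_id", "gpcr_id", "ramp_id", "bio_replicate",
          "tech_replicate")])
      if (nrow(mockWells)) {
        sel <- rbind(
          sel[, c("sample_id", "gpcr_id", "ramp_id", "bio_replicate",
            "tech_replicate", "capture_antibody_id",
            "detection_antibody_id", "mfi")],
          cbind(mockWells, capture_antibody_id = NA_character_,
            detection_antibody_id = s$detection_antibody_id,
            mfi = NA_real_))
      }
    }
    if (nrow(sel)) {
      out[[i]] <- data.frame(
        gpcr_id = sel$gpcr_id, ramp_id = sel$ramp_id,
        scheme_id = s$scheme_id, capture_family = "epitope_based",
        capture_antibody_id = sel$capture_antibody_id,
        detection_antibody_id = sel$detection_antibody_id,
        replicate = paste0("b", sel$bio_replicate, "t", sel$tech_replicate),
        mfi = sel$mfi, stringsAsFactors = FALSE)
    }
  }
  pr <- schemes[schemes$capture_family == "protein_based", , drop = FALSE]
  if (nrow(pr)) {
    sel <- m[m$capture_target_class == "gpcr" &
      m$capture_target == m$gpcr_id, , drop = FALSE]
    if (nrow(pr) == 1L && !is.na(pr$detection_antibody_id[1L])) {
      sel <- sel[sel$detection_antibody_id == pr$detection_antibody_id[1L], ,
        drop = FALSE]
    }
    if (nrow(sel)) {
      out[[nrow(ep) + 1L]] <- data.frame(
        gpcr_id = sel$gpcr_id, ramp_id = sel$ramp_id,
        scheme_id = pr$scheme_id[1L], capture_family = "protein_based",
        capture_antibody_id = sel$capture_antibody_id,
        detection_antibody_id = sel$detection_antibody_id,
        replicate = paste0("b", sel$bio_replicate, "t", sel$tech_replicate),
        mfi = sel$mfi, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  pairs <- pairs[order(pairs$scheme_id, pairs$capture_antibody_id,
    pairs$gpcr_id, pairs$ramp_id), ]
  rownames(pairs) <- NULL
  rownames(buffer) <- NULL
  list(pairs = pairs, buffer = buffer)
}
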