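# Score transformations and QC statistics: robust Z, Z, SNR, quantile
# normalization, RAMP-expression ANOVA/Dunnett QC, replicate reproducibility.

#' Robust Z-score
#'
#' \code{(x - median(x)) / (1.4826 * MAD(x))}, where MAD is the raw median
#' absolute deviation and 1.4826 the normal-consistency constant. Values at
#' the median map to 0 and the transform is invariant under positive affine
#' transformations of the input.
#'
#' @param x numeric vector, length >= 2.
#' @return numeric vector of robust Z-scores.
#' @examples
#' robustZ(1:5)[5]  # 2 / 1.4826 = 1.3490
#' @export
robustZ <- function(x) {
  if (length(x) < 2L || anyNA(x)) {
    .validationError("robustZ needs >= 2 non-missing values")
  }
  med <- median(x)
  madRaw <- median(abs(x - med))
  if (madRaw == 0) {
    .degenerateError("MAD is zero: robust Z-score undefined")
  }
  (x - med) / (1.4826 * madRaw)
}

#' Z-score (mean/SD standardization)
#'
#' Centers at the mean and scales by the population (maximum-likelihood)
#' standard deviation, so the output has mean 0 and SD 1 in the population
#' sense; e.g. \code{c(0, 0, 2, 2)} maps to \code{c(-1, -1, 1, 1)}.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return numeric vector with mean 0 and SD 1.
#' @export
zScore <- function(x) {
  if (length(x) < 2L || anyNA(x)) {
    .validationError("zScore needs >= 2 non-missing values")
  }
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) .degenerateError("SD is zero: Z-score undefined")
  (x - m) / s
}

#' Signal-to-noise ratios against buffer wells
#'
#' Divides each MFI by the median buffer-well MFI of the same (capture,
#' detection) antibody combination, so a buffer median itself maps to
#' SNR = 1.
#'
#' @param mfi data.frame (schema \code{"mfi"}) of signal records.
#' @param buffer data.frame with columns \code{capture_antibody_id},
#'   \code{detection_antibody_id}, \code{mfi}: the buffer-well records.
#' @return \code{mfi} with an added \code{snr} column.
#' @export
snrTransform <- function(mfi, buffer) {
  keyOf <- function(d) paste(d$capture_antibody_id, d$detection_antibody_id,
    sep = "\r")
  med <- tapply(buffer$mfi, keyOf(buffer), median)
  k <- keyOf(mfi)
  missing <- setdiff(unique(k), names(med))
  if (length(missing)) {
    .validationError(sprintf(
      "no buffer records for %d (capture, detection) combination(s): %s",
      length(missing),
      paste(gsub("\r", " / ", head(missing, 5L)), collapse = "; ")))
  }
  mfi$snr <- mfi$mfi / as.numeric(med[k])
  mfi
}

#' Quantile normalization
#'
#' Forces every column of a numeric matrix onto the identical empirical
#' distribution (the row-wise mean of the column-sorted values), preserving
#' within-column rank order; ties share the mean of the reference values at
#' the tied ranks. Delegates to \code{limma::normalizeBetweenArrays}, the
#' standard implementation for array-style intensity data. The operation is
#' idempotent.
#'
#' @param m numeric matrix with >= 2 columns (e.g. replicates).
#' @return matrix of the same dimensions.
#' @export
quantileNormalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    .validationError("quantileNormalize expects a numeric matrix")
  }
  if (ncol(m) < 2L) .validationError("need >= 2 columns")
  out <- limma::normalizeBetweenArrays(m, method = "quantile")
  dimnames(out) <- dimnames(m)
  out
}

#' RAMP-expression QC: ANOVA with Dunnett comparisons against mock
#'
#' One-way ANOVA of expression-readout scores across transfection groups,
#' followed by Dunnett's many-to-one comparisons of each RAMP group against
#' the mock reference (single-step multivariate-t adjustment, via
#' \pkg{multcomp}).
#'
#' @param values numeric readouts (e.g. log MFI of RAMP-tag capture/detect).
#' @param groups factor or character of transfection groups.
#' @param reference reference (mock) group label.
#' @return list with \code{anova} (data.frame: F statistic and p) and
#'   \code{comparisons} (data.frame: group, mean difference vs reference,
#'   Dunnett-adjusted p).
#' @export
rampExpressionQc <- function(values, groups, reference = "mock") {
  groups <- as.character(groups)
  if (!reference %in% groups) {
    .validationError(sprintf("reference group '%s' absent", reference))
  }
  counts <- table(groups)
  if (length(counts) < 2L) .validationError("need >= 2 groups")
  if (any(counts < 2L)) {
    .validationError(sprintf("group(s) with < 2 observations: %s",
      paste(names(counts)[counts < 2L], collapse = ", ")))
  }
  g <- stats::relevel(factor(groups), ref = reference)
  fit <- aov(values ~ g, data = data.frame(values = values, g = g))
  an <- summary(fit)[[1L]]
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  ts <- summary(glt)$test
  comparisons <- data.frame(
    group = sub(sprintf(" - %s$", reference), "", names(ts$coefficients)),
    estimate = as.numeric(ts$coefficients),
    p_adjusted = as.numeric(ts$pvalues),
    stringsAsFactors = FALSE)
  rownames(comparisons) <- NULL
  list(
    anova = data.frame(statistic = an[["F value"]][1L],
      p_value = an[["Pr(>F)"]][1L]),
    comparisons = comparisons)
}

#' Replicate reproducibility by one-sided rank test
#'
#' One-sided (greater) unpaired Wilcoxon rank-sum test that co-expression
#' scores exceed the GPCR-alone (mock) scores; exact when sample sizes
#' permit and there are no ties.
#'
#' @param coexpressed numeric scores from GPCR + RAMP samples.
#' @param alone numeric scores from GPCR-alone samples.
#' @return the one-sided p-value.
#' @export
replicateReproducibility <- function(coexpressed, alone) {
  if (!length(coexpressed) || !length(alone)) {
    .validationError("both score vectors must be non-empty")
  }
  wilcox.test(coexpressed, alone, alternative = "greater")$p.value
}
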