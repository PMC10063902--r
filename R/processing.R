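#' Processing parameters for the site-level cleanup chain
#'
#' The chain mirrors standard label-free phosphoproteomics practice:
#' class-I confidence filtering (localization probability >= 0.75 and delta
#' score >= 8, thresholds inclusive), a valid-value filter keeping sites
#' quantified in at least `minValidFraction` of the samples of at least one
#' group, log2 transformation, median normalization, and group-mean
#' imputation of cells whose group retains at least `minValidFraction`
#' observed values.
#'
#' `stageOrder` controls the order in which enabled stages run; the default
#' imputes last, on the normalized log2 scale, where a group mean is a
#' sensible central value (on the raw scale means are dominated by the
#' highest replicate).  The literal published order (impute on the raw
#' scale before filtering) is available by reordering.
#'
#' @param minLocProb class-I localization probability threshold.
#' @param minDeltaScore class-I delta-score threshold.
#' @param minValidFraction valid-value / imputation-eligibility fraction.
#' @param impute `"group_mean"` or `"none"`.
#' @param normalize `"median"` or `"none"`.
#' @param log2 apply log2 transformation?
#' @param stageOrder permutation of the enabled stage names among
#'   `c("classI", "valid", "log2", "median", "impute")`.
#' @return classed list (`ProcessingParams`).
#' @export
processingParams <- function(minLocProb = 0.75, minDeltaScore = 8,
                             minValidFraction = 0.5,
                             impute = c("group_mean", "none"),
                             normalize = c("median", "none"),
                             log2 = TRUE, stageOrder = NULL) {
  impute <- match.arg(impute)
  normalize <- match.arg(normalize)
  enabled <- c("classI", "valid",
               if (log2) "log2",
               if (normalize == "median") "median",
               if (impute == "group_mean") "impute")
  stageOrder <- stageOrder %||% enabled
  if (!setequal(stageOrder, enabled))
    .stopf("stageOrder must be a permutation of the enabled stages: %s",
           paste(enabled, collapse = ", "))
  if (minValidFraction < 0 || minValidFraction > 1)
    .stopf("minValidFraction must lie in [0, 1]")
  structure(list(minLocProb = minLocProb, minDeltaScore = minDeltaScore,
                 minValidFraction = minValidFraction, impute = impute,
                 normalize = normalize, log2 = log2,
                 stageOrder = stageOrder),
            class = "ProcessingParams")
}

#' Class-I confidence filter
#'
#' Keeps records with localization probability and delta score at or above
#' the thresholds (both comparisons inclusive).
#'
#' @param x a [PhosphoExperiment-class].
#' @param minLocProb,minDeltaScore inclusive thresholds.
#' @return filtered [PhosphoExperiment-class] with a provenance record of
#'   kept/dropped counts.
#' @export
filterClassOne <- function(x, minLocProb = 0.75, minDeltaScore = 8) {
  sd <- siteData(x)
  keep <- sd$localizationProb >= minLocProb & sd$deltaScore >= minDeltaScore
  out <- x[keep, ]
  if (!any(keep)) .warnf("class-I filter removed every record")
  .appendStep(out, "filter_class_one", min_loc_prob = minLocProb,
              min_delta_score = minDeltaScore,
              kept = sum(keep), dropped = sum(!keep))
}

# fraction of observed values per record within each design group
.groupValidFractions <- function(x, design) {
  mat <- intensities(x)
  g <- designGroups(design)
  absent <- setdiff(unlist(g), colnames(mat))
  if (length(absent))
    .stopf("design sample(s) not in table: %s", paste(absent, collapse = ", "))
  vapply(g, function(s) rowMeans(!is.na(mat[, s, drop = FALSE])),
         numeric(nrow(mat)))
}

#' Valid-value filter
#'
#' Keeps records quantified in at least `minValidFraction` of the samples
#' of at least one design group.
#'
#' @param x a [PhosphoExperiment-class].
#' @param design a [StudyDesign-class].
#' @param minValidFraction required observed fraction (inclusive).
#' @return filtered [PhosphoExperiment-class].
#' @export
filterValidValues <- function(x, design, minValidFraction = 0.5) {
  if (any(lengths(designGroups(design)) == 0))
    .stopf("design error: group with zero samples")
  fr <- .groupValidFractions(x, design)
  keep <- apply(fr, 1L, max) >= minValidFraction
  out <- x[keep, ]
  .appendStep(out, "filter_valid_values",
              min_valid_fraction = minValidFraction,
              kept = sum(keep), dropped = sum(!keep))
}

#' Group-mean imputation
#'
#' Replaces each missing cell whose group retains at least
#' `minValidFraction` observed values with the arithmetic mean of that
#' group's observed values (on the current intensity scale).  Groups below
#' the fraction are left missing; observed cells are untouched.
#'
#' @inheritParams filterValidValues
#' @return imputed [PhosphoExperiment-class].
#' @export
imputeGroupMean <- function(x, design, minValidFraction = 0.5) {
  mat <- intensities(x)
  nImputed <- 0L
  for (s in designGroups(design)) {
    sub <- mat[, s, drop = FALSE]
    nObs <- rowSums(!is.na(sub))
    eligible <- nObs / length(s) >= minValidFraction & nObs < length(s)
    if (!any(eligible)) next
    gm <- rowMeans(sub, na.rm = TRUE)
    for (j in seq_along(s)) {
      fill <- eligible & is.na(sub[, j])
      mat[fill, s[j]] <- gm[fill]
      nImputed <- nImputed + sum(fill)
    }
  }
  SummarizedExperiment::assay(x, "intensity") <- mat
  .appendStep(x, "impute_group_mean", min_valid_fraction = minValidFraction,
              n_imputed = nImputed)
}

#' Log2 transformation
#'
#' @param x a [PhosphoExperiment-class] on the raw scale; zeros were
#'   already read as missing, so all observed values must be positive.
#' @return the experiment on the log2 scale.
#' @export
log2Transform <- function(x) {
  if (identical(intensityScale(x), "log2"))
    .stopf("table is already on the log2 scale")
  mat <- intensities(x)
  if (any(mat <= 0, na.rm = TRUE))
    .stopf("data error: non-positive intensity cannot be log2-transformed")
  SummarizedExperiment::assay(x, "intensity") <- log2(mat)
  x <- .setScale(x, "log2")
  .appendStep(x, "log2_transform")
}

#' Median normalization
#'
#' Per sample, subtracts that sample's median over observed values and adds
#' back the grand median of the pre-normalization sample medians, so the
#' overall location is preserved and all sample medians coincide.
#'
#' @param x a [PhosphoExperiment-class] on the log2 scale.
#' @return normalized experiment; all sample medians equal within 1e-9.
#' @export
medianNormalize <- function(x) {
  if (!identical(intensityScale(x), "log2"))
    .stopf("median normalization expects the log2 scale")
  mat <- intensities(x)
  med <- apply(mat, 2L, median, na.rm = TRUE)
  if (any(is.na(med)))
    .stopf("sample(s) with zero observed values: %s",
           paste(colnames(mat)[is.na(med)], collapse = ", "))
  grand <- median(med)
  mat <- sweep(mat, 2L, med - grand)
  SummarizedExperiment::assay(x, "intensity") <- mat
  .appendStep(x, "median_normalize", grand_median = grand)
}

#' Identification summary statistics
#'
#' Tabulates the table the way identification overviews report it: record
#' counts by multiplicity class, distinct (protein, position) site count,
#' protein count, and S/T/Y residue counts and fractions.
#'
#' @param x a [PhosphoExperiment-class].
#' @return list with `n_records`, `n_by_multiplicity`, `n_sites`,
#'   `n_proteins`, `residue_counts`, `residue_fractions`.
#' @export
summarizeSites <- function(x) {
  sd <- siteData(x)
  siteKey <- paste(sd$protein, sd$position)
  firstOfSite <- !duplicated(siteKey)
  resCounts <- vapply(c("S", "T", "Y"),
                      function(r) sum(sd$residue[firstOfSite] == r),
                      integer(1))
  nSites <- sum(firstOfSite)
  list(
    n_records = nrow(sd),
    n_by_multiplicity = vapply(.MULT_LEVELS,
                               function(m) sum(sd$multiplicity == m),
                               integer(1)),
    n_sites = nSites,
    n_proteins = length(unique(sd$protein)),
    residue_counts = resCounts,
    residue_fractions = if (nSites > 0) resCounts / nSites else
      setNames(rep(NA_real_, 3), c("S", "T", "Y"))
  )
}

#' Residue composition from counts
#'
#' Convenience for reporting serine/threonine/tyrosine percentages from
#' site counts (e.g. 17,577 S, 3,424 T, 238 Y of 21,239 sites gives
#' 82.76/16.12/1.12%).
#'
#' @param counts named numeric vector of per-residue site counts.
#' @return list with `counts`, `total`, `fractions`, `percent`.
#' @export
residueComposition <- function(counts) {
  total <- sum(counts)
  fr <- counts / total
  list(counts = counts, total = total, fractions = fr, percent = 100 * fr)
}

#' Run the full processing chain
#'
#' Applies the enabled stages in `stageOrder` and reports identification
#' summaries before and after.
#'
#' @param x a [PhosphoExperiment-class] on the raw scale.
#' @param design a [StudyDesign-class].
#' @param params a [processingParams()] object.
#' @return list with `experiment` (processed), `summaryBefore`,
#'   `summaryAfter`.
#' @export
runProcessing <- function(x, design, params = processingParams()) {
  stopifnot(inherits(params, "ProcessingParams"))
  before <- summarizeSites(x)
  for (stage in params$stageOrder) {
    x <- switch(stage,
      classI = filterClassOne(x, params$minLocProb, params$minDeltaScore),
      valid = filterValidValues(x, design, params$minValidFraction),
      log2 = log2Transform(x),
      median = medianNormalize(x),
      impute = imputeGroupMean(x, design, params$minValidFraction),
      .stopf("unknown stage: %s", stage))
  }
  list(experiment = x, summaryBefore = before, summaryAfter = summarizeSites(x))
}
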