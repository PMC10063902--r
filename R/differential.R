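#' Differential-calling parameters
#'
#' A site is called regulated in a contrast when its |log2 fold change|
#' meets `minAbsLog2FC` and its (adjusted, if `pAdjust != "none"`) t-test
#' p-value is below `maxP`.  The default criteria are fold change >= 1.5
#' and raw p < 0.05, the field-standard pairing for a fold-change plus
#' t-test screen.  `test = "student"` is the default: with three replicates
#' per group the pooled-variance t-test holds its nominal type-I level,
#' whereas the Welch-Satterthwaite approximation is noticeably conservative
#' at n = 3 (kept as an option for unequal-variance designs).
#'
#' @param minAbsLog2FC minimum |log2 fold change| (inclusive).
#' @param maxP significance threshold (exclusive, p < maxP).
#' @param test `"student"` (pooled variance) or `"welch"`.
#' @param pAdjust `"none"` or `"BH"`.
#' @return classed list (`DifferentialParams`).
#' @export
differentialParams <- function(minAbsLog2FC = log2(1.5), maxP = 0.05,
                               test = c("student", "welch"),
                               pAdjust = c("none", "BH")) {
  test <- match.arg(test)
  pAdjust <- match.arg(pAdjust)
  if (maxP <= 0 || maxP >= 1) .stopf("maxP must lie in (0, 1)")
  if (minAbsLog2FC < 0) .stopf("minAbsLog2FC must be >= 0")
  structure(list(minAbsLog2FC = minAbsLog2FC, maxP = maxP, test = test,
                 pAdjust = pAdjust),
            class = "DifferentialParams")
}

# vectorised two-sample t statistics over the rows of two matrices
.rowTTest <- function(a, b, test) {
  n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  v1 <- rowSums((a - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((b - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  testable <- n1 >= 2 & n2 >= 2
  if (test == "welch") {
    se2 <- v1 / n1 + v2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  p <- 2 * pt(-abs(t), df)
  t[!testable] <- NA_real_
  p[!testable] <- NA_real_
  list(log2fc = m1 - m2, t = t, df = df, p = p,
       n1 = n1, n2 = n2, testable = testable)
}

#' Differential site calling for one contrast
#'
#' Computes, per site, the log2 fold change (numerator-group mean minus
#' denominator-group mean on the log2 scale) and a two-sided two-sample
#' t-test p-value, then classifies each site as `up`, `down` or `ns`
#' against the thresholds.  Sites without at least two observed values in
#' both groups are reported with `p = NA` and `call = "ns"`, never dropped.
#'
#' @param x a [PhosphoExperiment-class] on the log2 scale.
#' @param design a [StudyDesign-class].
#' @param contrast a contrast name present in the design (e.g. `"H/C"`) or
#'   a length-2 character vector `c(numerator, denominator)`.
#' @param params a [differentialParams()] object.
#' @return data.frame (one row per site) with columns `site_id`, `protein`,
#'   `gene`, `position`, `residue`, `multiplicity`, `log2fc`, `t`, `p`,
#'   optionally `padj`, and `call`; attributes `contrast`, `params`,
#'   `provenance`.
#' @export
computeContrast <- function(x, design, contrast,
                            params = differentialParams()) {
  stopifnot(inherits(params, "DifferentialParams"))
  if (!identical(intensityScale(x), "log2"))
    .stopf("differential testing expects the log2 scale; run log2Transform first")
  ct <- designContrasts(design)
  if (length(contrast) == 1L) {
    hit <- match(contrast, ct$name)
    if (is.na(hit)) .stopf("unknown contrast: %s", contrast)
    num <- ct$numerator[hit]; den <- ct$denominator[hit]
    cname <- ct$name[hit]
  } else {
    num <- contrast[1]; den <- contrast[2]
    if (!all(c(num, den) %in% names(designGroups(design))))
      .stopf("contrast groups not in design: %s/%s", num, den)
    cname <- paste0(num, "/", den)
  }
  g <- designGroups(design)
  mat <- intensities(x)
  res <- .rowTTest(mat[, g[[num]], drop = FALSE],
                   mat[, g[[den]], drop = FALSE], params$test)
  pcrit <- res$p
  out <- data.frame(siteData(x)[c("protein", "gene", "position", "residue",
                                  "multiplicity")],
                    site_id = rownames(x),
                    log2fc = res$log2fc, t = res$t, p = res$p,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (params$pAdjust == "BH") {
    out$padj <- p.adjust(out$p, method = "BH")
    pcrit <- out$padj
  }
  sig <- !is.na(pcrit) & pcrit < params$maxP &
    abs(out$log2fc) >= params$minAbsLog2FC
  out$call <- ifelse(sig & out$log2fc > 0, "up",
                     ifelse(sig & out$log2fc < 0, "down", "ns"))
  attr(out, "contrast") <- cname
  attr(out, "params") <- params
  attr(out, "provenance") <- .provenanceToken(provenance(x))
  out
}

#' Volcano-plot table
#'
#' One row per tested site with the volcano coordinates log2 fold change
#' and -log10 p; untested (`p = NA`) sites are excluded.  Counts by call
#' are attached as the `"counts"` attribute.
#'
#' @param dt a differential table from [computeContrast()].
#' @return data.frame with `site_id`, `gene`, `log2fc`, `neg_log10_p`,
#'   `call`.
#' @export
volcanoTable <- function(dt) {
  keep <- !is.na(dt$p)
  out <- data.frame(site_id = dt$site_id[keep], gene = dt$gene[keep],
                    log2fc = dt$log2fc[keep],
                    neg_log10_p = -log10(dt$p[keep]),
                    call = dt$call[keep], stringsAsFactors = FALSE)
  attr(out, "counts") <- c(up = sum(out$call == "up"),
                           down = sum(out$call == "down"),
                           ns = sum(out$call == "ns"))
  attr(out, "contrast") <- attr(dt, "contrast")
  out
}

#' Per-contrast significant-site counts
#'
#' @param tables list of differential tables (optionally named; unnamed
#'   entries take their `"contrast"` attribute).
#' @return data.frame with `contrast`, `n_significant`, `n_up`, `n_down`;
#'   `n_up + n_down == n_significant` by construction.
#' @export
summarizeContrasts <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  rows <- lapply(seq_along(tables), function(i) {
    dt <- tables[[i]]
    nm <- names(tables)[i] %||% NA_character_
    if (is.na(nm) || nm == "") nm <- attr(dt, "contrast") %||% sprintf("contrast_%d", i)
    up <- sum(dt$call == "up"); down <- sum(dt$call == "down")
    data.frame(contrast = nm, n_significant = up + down,
               n_up = up, n_down = down, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
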