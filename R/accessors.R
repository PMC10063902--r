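#' Accessors for pipeline classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x a [PhosphoExperiment-class], [StudyDesign-class] or
#'   [GeneSetCollection-class] object.
#' @name accessors
NULL

#' @describeIn accessors site metadata as a plain data.frame.
#' @export
siteData <- function(x) {
  stopifnot(is(x, "PhosphoExperiment"))
  as.data.frame(SummarizedExperiment::rowData(x))
}

#' @describeIn accessors the intensity matrix (NA = missing).
#' @export
intensities <- function(x) {
  stopifnot(is(x, "PhosphoExperiment"))
  SummarizedExperiment::assay(x, "intensity")
}

#' @describeIn accessors unique `protein_position_multiplicity` keys.
#' @export
siteKeys <- function(x) rownames(x)

#' @describeIn accessors current intensity scale, `"raw"` or `"log2"`.
#' @export
intensityScale <- function(x) S4Vectors::metadata(x)$scale %||% "raw"

#' @describeIn accessors ordered list of processing-step descriptors.
#' @export
provenance <- function(x) S4Vectors::metadata(x)$provenance %||% list()

# internal: record a processing step on the object
.appendStep <- function(x, step, ...) {
  p <- provenance(x)
  p[[length(p) + 1L]] <- c(list(step = step), list(...))
  S4Vectors::metadata(x)$provenance <- p
  x
}

.setScale <- function(x, scale) {
  S4Vectors::metadata(x)$scale <- scale
  x
}

#' @describeIn accessors named list group -> sample ids.
#' @export
designGroups <- function(x) {
  stopifnot(is(x, "StudyDesign"))
  x@groups
}

#' @describeIn accessors all sample ids in design order.
#' @export
designSamples <- function(x) unlist(designGroups(x), use.names = FALSE)

#' @describeIn accessors named character vector sample id -> group label.
#' @export
sampleGroups <- function(x) {
  g <- designGroups(x)
  setNames(rep(names(g), lengths(g)), unlist(g, use.names = FALSE))
}

#' @describeIn accessors contrast table (name, numerator, denominator).
#' @export
designContrasts <- function(x) {
  stopifnot(is(x, "StudyDesign"))
  x@contrasts
}

#' @describeIn accessors named list of member vectors.
#' @export
geneSets <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  x@sets
}

#' @describeIn accessors per-set info table (set_id, set_name, category).
#' @export
setInfo <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  x@info
}

#' @export
setMethod("show", "PhosphoExperiment", function(object) {
  cat(sprintf("PhosphoExperiment: %d site records x %d samples [%s scale]\n",
              nrow(object), ncol(object), intensityScale(object)))
  rd <- SummarizedExperiment::rowData(object)
  if (nrow(rd)) {
    cat(sprintf("  proteins: %d | residues: %s\n",
                length(unique(rd$protein)),
                paste(sprintf("%s=%d", names(table(rd$residue)),
                              as.integer(table(rd$residue))),
                      collapse = " ")))
  }
  p <- provenance(object)
  if (length(p))
    cat("  provenance:", .provenanceToken(p), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "StudyDesign", function(object) {
  g <- designGroups(object)
  cat(sprintf("StudyDesign: %d groups, %d samples\n", length(g),
              length(designSamples(object))))
  for (nm in names(g))
    cat(sprintf("  %s: %s\n", nm, paste(g[[nm]], collapse = ", ")))
  ct <- designContrasts(object)
  cat("  contrasts:", paste(ct$name, collapse = ", "), "\n")
  invisible(NULL)
})

#' @export
setMethod("show", "GeneSetCollection", function(object) {
  info <- setInfo(object)
  cat(sprintf("GeneSetCollection: %d sets (%s)\n", nrow(info),
              paste(sprintf("%s=%d", names(table(info$category)),
                            as.integer(table(info$category))),
                    collapse = ", ")))
  invisible(NULL)
})

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))
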