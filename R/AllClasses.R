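#' PhosphoExperiment: phosphosite quantifications with site metadata
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one row per phosphosite x multiplicity state and one column per sample.
#' The single assay, `"intensity"`, stores quantified intensities with `NA`
#' for unquantified (missing) cells; a zero in an input file is read as
#' missing.  Row metadata carries the site annotation used throughout the
#' pipeline: `protein`, `gene`, `position` (1-based residue index),
#' `residue` (one of S/T/Y), `localizationProb`, `deltaScore` and
#' `multiplicity` (one of `"1"`, `"2"`, `"3+"`).
#'
#' `metadata(x)$scale` records the current intensity scale (`"raw"` or
#' `"log2"`) and `metadata(x)$provenance` the ordered list of processing
#' steps applied so far; every stage appends to it.
#'
#' @aliases PhosphoExperiment-class
#' @export
setClass("PhosphoExperiment",
  contains = "SummarizedExperiment"
)

.REQUIRED_SITE_COLS <- c("protein", "gene", "position", "residue",
                         "localizationProb", "deltaScore", "multiplicity")

setValidity("PhosphoExperiment", function(object) {
  msg <- character(0)
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  rd <- SummarizedExperiment::rowData(object)
  missingCols <- setdiff(.REQUIRED_SITE_COLS, colnames(rd))
  if (length(missingCols))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(missingCols, collapse = ", ")))
  if (length(msg)) return(msg)
  if (nrow(rd) > 0) {
    if (!all(rd$residue %in% c("S", "T", "Y")))
      msg <- c(msg, "residue must be one of S, T, Y")
    if (!all(rd$position >= 1))
      msg <- c(msg, "position must be >= 1")
    lp <- rd$localizationProb
    if (any(lp < 0 | lp > 1))
      msg <- c(msg, "localizationProb must lie in [0, 1]")
    if (any(rd$deltaScore < 0))
      msg <- c(msg, "deltaScore must be >= 0")
    if (!all(rd$multiplicity %in% .MULT_LEVELS))
      msg <- c(msg, "multiplicity must be one of '1', '2', '3+'")
    key <- paste(rd$protein, rd$position, rd$multiplicity, sep = "|")
    if (anyDuplicated(key))
      msg <- c(msg, paste0("duplicate (protein, position, multiplicity): ",
                           paste(head(unique(key[duplicated(key)]), 5),
                                 collapse = "; ")))
    a <- SummarizedExperiment::assay(object, "intensity")
    if (any(is.infinite(a)))
      msg <- c(msg, "intensities must be finite or NA")
    sc <- S4Vectors::metadata(object)$scale %||% "raw"
    if (identical(sc, "raw") && any(a < 0, na.rm = TRUE))
      msg <- c(msg, "raw-scale intensities must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PhosphoExperiment
#'
#' @param intensity numeric matrix, sites x samples, `NA` for missing.
#' @param siteData data.frame with columns `protein`, `gene`, `position`,
#'   `residue`, `localizationProb`, `deltaScore`, `multiplicity`.
#' @param scale `"raw"` or `"log2"`; the scale of `intensity`.
#' @param provenance optional list of prior processing-step descriptors.
#' @return A [PhosphoExperiment-class] object.
#' @examples
#' m <- matrix(2^rnorm(6, 20), 2, 3,
#'             dimnames = list(NULL, c("C1", "C2", "C3")))
#' sd <- data.frame(protein = c("P1", "P2"), gene = c("GNAI1", "GSK3A"),
#'                  position = c(10L, 21L), residue = c("S", "T"),
#'                  localizationProb = c(0.99, 0.80), deltaScore = c(40, 12),
#'                  multiplicity = c("1", "1"))
#' pe <- PhosphoExperiment(m, sd)
#' pe
#' @export
PhosphoExperiment <- function(intensity, siteData, scale = "raw",
                              provenance = list()) {
  if (!is.matrix(intensity)) intensity <- as.matrix(intensity)
  stopifnot(is.data.frame(siteData) || is(siteData, "DataFrame"))
  siteData <- as.data.frame(siteData)
  siteData$position <- as.integer(siteData$position)
  siteData$multiplicity <- as.character(siteData$multiplicity)
  rn <- paste0(siteData$protein, "_", siteData$position, "_",
               siteData$multiplicity)
  rownames(intensity) <- rn
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = S4Vectors::DataFrame(siteData, row.names = rn)
  )
  S4Vectors::metadata(se)$scale <- scale
  S4Vectors::metadata(se)$provenance <- provenance
  new("PhosphoExperiment", se)
}

#' StudyDesign: sample-to-group assignment and ordered contrasts
#'
#' Encodes the experimental layout: named groups of sample identifiers
#' (e.g. the four-arm design C = control diet, H = high-fat diet,
#' S = semaglutide-treated, E = empagliflozin-treated) and an ordered list
#' of contrasts, each a numerator/denominator group pair such as H/C.
#'
#' @aliases StudyDesign-class
#' @export
setClass("StudyDesign",
  representation(groups = "list", contrasts = "data.frame")
)

setValidity("StudyDesign", function(object) {
  msg <- character(0)
  g <- object@groups
  if (is.null(names(g)) || any(names(g) == ""))
    msg <- c(msg, "groups must be a named list")
  samples <- unlist(g, use.names = FALSE)
  if (anyDuplicated(samples))
    msg <- c(msg, paste0("sample(s) in more than one group: ",
                         paste(unique(samples[duplicated(samples)]),
                               collapse = ", ")))
  if (any(lengths(g) < 2))
    msg <- c(msg, "every group needs >= 2 samples")
  ct <- object@contrasts
  need <- c("name", "numerator", "denominator")
  if (!all(need %in% colnames(ct))) {
    msg <- c(msg, "contrasts needs columns name, numerator, denominator")
  } else if (nrow(ct) > 0) {
    unknown <- setdiff(c(ct$numerator, ct$denominator), names(g))
    if (length(unknown))
      msg <- c(msg, paste0("contrast references unknown group(s): ",
                           paste(unknown, collapse = ", ")))
    if (anyDuplicated(ct$name))
      msg <- c(msg, "contrast names must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StudyDesign
#'
#' When `contrasts` is omitted and the groups are exactly C, H, S, E (in any
#' order) the default contrast set H/C, S/H, E/H is installed.
#'
#' @param groups named list, group label -> character vector of sample ids.
#' @param contrasts optional; either a data.frame with columns `name`,
#'   `numerator`, `denominator`, or a character vector of `"NUM/DEN"` strings.
#' @return A [StudyDesign-class] object.
#' @examples
#' d <- StudyDesign(list(C = c("C1", "C2", "C3"), H = c("H1", "H2", "H3"),
#'                       S = c("S1", "S2", "S3"), E = c("E1", "E2", "E3")))
#' designContrasts(d)
#' @export
StudyDesign <- function(groups, contrasts = NULL) {
  if (is.null(contrasts)) {
    if (all(c("C", "H", "S", "E") %in% names(groups))) {
      contrasts <- c("H/C", "S/H", "E/H")
    } else {
      .stopf("no contrasts given and groups are not the default C/H/S/E set")
    }
  }
  if (is.character(contrasts)) {
    parts <- strsplit(contrasts, "/", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad))
      .stopf("malformed contrast string(s): %s",
             paste(contrasts[bad], collapse = ", "))
    contrasts <- data.frame(
      name = contrasts,
      numerator = vapply(parts, `[`, character(1), 1L),
      denominator = vapply(parts, `[`, character(1), 2L),
      stringsAsFactors = FALSE
    )
  }
  groups <- lapply(groups, as.character)
  new("StudyDesign", groups = groups,
      contrasts = as.data.frame(contrasts, stringsAsFactors = FALSE))
}

#' GeneSetCollection: flat annotation sets for enrichment
#'
#' Named gene/protein sets, each tagged with a category (`KEGG`, `GO_BP`,
#' `GO_CC`, `GO_MF` or `SUBCELL`).  Members are uppercased symbols; matching
#' throughout the package is by uppercase symbol.
#'
#' @aliases GeneSetCollection-class
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", info = "data.frame")
)

.GS_CATEGORIES <- c("KEGG", "GO_BP", "GO_CC", "GO_MF", "SUBCELL")

setValidity("GeneSetCollection", function(object) {
  msg <- character(0)
  s <- object@sets
  info <- object@info
  if (!all(c("set_id", "set_name", "category") %in% colnames(info)))
    msg <- c(msg, "info needs columns set_id, set_name, category")
  else {
    if (!identical(names(s), info$set_id))
      msg <- c(msg, "set names and info$set_id out of step")
    if (!all(info$category %in% .GS_CATEGORIES))
      msg <- c(msg, paste0("category must be one of ",
                           paste(.GS_CATEGORIES, collapse = ", ")))
  }
  if (any(lengths(s) == 0))
    msg <- c(msg, "gene sets must be non-empty")
  if (any(vapply(s, anyDuplicated, integer(1)) > 0))
    msg <- c(msg, "gene-set members must be deduplicated")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors (members; uppercased on
#'   construction and deduplicated).
#' @param category single category label for all sets, or a vector along
#'   `sets`.
#' @param setNames optional human-readable names (defaults to the ids).
#' @return A [GeneSetCollection-class] object.
#' @export
GeneSetCollection <- function(sets, category = "KEGG", setNames = NULL) {
  sets <- lapply(sets, function(m) unique(toupper(as.character(m))))
  ids <- names(sets)
  if (is.null(ids)) .stopf("sets must be a named list")
  info <- data.frame(
    set_id = ids,
    set_name = setNames %||% ids,
    category = rep_len(category, length(sets)),
    stringsAsFactors = FALSE
  )
  new("GeneSetCollection", sets = sets, info = info)
}
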