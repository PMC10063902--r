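#' Column-name dialect for phosphosite tables
#'
#' MaxQuant "Phospho (STY)Sites"-style exports vary in column naming; the
#' dialect maps logical fields to the column names found in the file.
#' Intensity columns are recognised as
#' `<intensityPrefix><sample><multiplicitySep><m>` with `m` in 1..3
#' (MaxQuant's `___1/___2/___3` multiplicity states; state 3 means three or
#' more phosphates and is stored as multiplicity `"3+"`).
#'
#' @param protein,gene,position,aminoAcid,locProb,deltaScore column names.
#' @param intensityPrefix prefix of intensity columns.
#' @param multiplicitySep separator before the multiplicity state.
#' @return a named list usable as `dialect` in [readPhosphoSites()].
#' @export
phosphoDialect <- function(protein = "Protein", gene = "Gene names",
                           position = "Position", aminoAcid = "Amino acid",
                           locProb = "Localization prob",
                           deltaScore = "Delta score",
                           intensityPrefix = "Intensity ",
                           multiplicitySep = "___") {
  list(protein = protein, gene = gene, position = position,
       aminoAcid = aminoAcid, locProb = locProb, deltaScore = deltaScore,
       intensityPrefix = intensityPrefix, multiplicitySep = multiplicitySep)
}

#' Read a phosphosite quantification table
#'
#' Parses a tab-delimited site table in the MaxQuant Phospho(STY)Sites
#' dialect into a [PhosphoExperiment-class].  Each file row is expanded into
#' one record per multiplicity state carrying at least one quantified
#' intensity; zero and empty intensity cells are read as missing (`NA`),
#' the MaxQuant convention for unquantified values.  No row is silently
#' dropped: the provenance step records `rows_in`, expanded record counts
#' and the number of all-missing states set aside.
#'
#' @param path file path.
#' @param dialect column-name mapping, see [phosphoDialect()].
#' @return A [PhosphoExperiment-class] on the raw intensity scale.
#' @export
readPhosphoSites <- function(path, dialect = phosphoDialect()) {
  raw <- read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "", na.strings = c("", "NA", "NaN"))
  mandatory <- c(dialect$protein, dialect$gene, dialect$position,
                 dialect$aminoAcid, dialect$locProb, dialect$deltaScore)
  absent <- setdiff(mandatory, colnames(raw))
  if (length(absent))
    .stopf("configuration error: mandatory column(s) not in file: %s",
           paste(absent, collapse = ", "))

  pref <- dialect$intensityPrefix
  sep <- dialect$multiplicitySep
  intCols <- colnames(raw)[startsWith(colnames(raw), pref) &
                             grepl(sep, colnames(raw), fixed = TRUE)]
  if (length(intCols) == 0)
    .stopf("configuration error: no intensity columns matching '%s<sample>%s<m>'",
           pref, sep)
  body <- substring(intCols, nchar(pref) + 1L)
  pieces <- strsplit(body, sep, fixed = TRUE)
  sampleOf <- vapply(pieces, `[`, character(1), 1L)
  multOf <- vapply(pieces, `[`, character(1), 2L)
  if (!all(multOf %in% c("1", "2", "3")))
    .stopf("unrecognised multiplicity suffix in intensity column(s): %s",
           paste(intCols[!multOf %in% c("1", "2", "3")], collapse = ", "))
  samples <- unique(sampleOf)
  mults <- sort(unique(multOf))

  residue <- toupper(trimws(as.character(raw[[dialect$aminoAcid]])))
  badRes <- which(!residue %in% c("S", "T", "Y"))
  if (length(badRes))
    .stopf("data error: non-S/T/Y residue at file row(s) %s",
           paste(head(badRes, 10), collapse = ", "))

  pos <- suppressWarnings(as.integer(raw[[dialect$position]]))
  lp <- suppressWarnings(as.numeric(raw[[dialect$locProb]]))
  ds <- suppressWarnings(as.numeric(raw[[dialect$deltaScore]]))
  badRow <- which(is.na(pos) | pos < 1 | is.na(lp) | lp < 0 | lp > 1 |
                    is.na(ds) | ds < 0)
  if (length(badRow)) {
    .warnf("rejected %d row(s) failing type validation (file rows: %s)",
           length(badRow), paste(head(badRow, 20), collapse = ", "))
  }
  keep <- setdiff(seq_len(nrow(raw)), badRow)

  recs <- list()
  mats <- list()
  for (m in mults) {
    cols <- intCols[multOf == m]
    colSample <- sampleOf[multOf == m]
    if (!setequal(colSample, samples))
      .stopf("configuration error: multiplicity state %s lacks columns for sample(s): %s",
             m, paste(setdiff(samples, colSample), collapse = ", "))
    mat <- as.matrix(raw[keep, cols[match(samples, colSample)], drop = FALSE])
    mode(mat) <- "numeric"
    mat[!is.na(mat) & mat == 0] <- NA  # zero means unquantified
    colnames(mat) <- samples
    mlab <- if (m == "3") "3+" else m
    recs[[m]] <- data.frame(
      protein = as.character(raw[[dialect$protein]])[keep],
      gene = toupper(as.character(raw[[dialect$gene]])[keep]),
      position = pos[keep],
      residue = residue[keep],
      localizationProb = lp[keep],
      deltaScore = ds[keep],
      multiplicity = mlab,
      stringsAsFactors = FALSE
    )
    mats[[m]] <- mat
  }
  site <- do.call(rbind, recs)
  mat <- do.call(rbind, mats)
  observed <- rowSums(!is.na(mat)) > 0
  nAllMissing <- sum(!observed)
  site <- site[observed, , drop = FALSE]
  mat <- mat[observed, , drop = FALSE]

  key <- paste(site$protein, site$position, site$multiplicity, sep = "|")
  if (anyDuplicated(key))
    .stopf("data error: duplicate (protein, position, multiplicity): %s",
           paste(head(unique(key[duplicated(key)]), 5), collapse = "; "))

  pe <- PhosphoExperiment(mat, site)
  pe <- .appendStep(pe, "read_phosphosite_table",
                    path = path, rows_in = nrow(raw),
                    rows_rejected = length(badRow),
                    records_expanded = nrow(raw) * length(mults) -
                      length(badRow) * length(mults),
                    records_all_missing = nAllMissing,
                    records_kept = nrow(site))
  validObject(pe)
  pe
}

#' Write a PhosphoExperiment as a dialect-conformant site table
#'
#' Inverse of [readPhosphoSites()]: one file row per record, intensity
#' columns `<prefix><sample>___<m>` with the record's own multiplicity
#' state filled and the others left empty.  Missing intensities are written
#' as empty cells.
#'
#' @param x a [PhosphoExperiment-class].
#' @param path output file.
#' @param dialect see [phosphoDialect()].
#' @return `path`, invisibly.
#' @export
writePhosphoSites <- function(x, path, dialect = phosphoDialect()) {
  sd <- siteData(x)
  mat <- intensities(x)
  samples <- colnames(mat)
  mstates <- c("1", "2", "3")
  out <- data.frame(a = sd$protein, b = sd$gene, c = sd$position,
                    d = sd$residue, e = sd$localizationProb,
                    f = sd$deltaScore, stringsAsFactors = FALSE,
                    check.names = FALSE)
  colnames(out) <- c(dialect$protein, dialect$gene, dialect$position,
                     dialect$aminoAcid, dialect$locProb, dialect$deltaScore)
  recState <- ifelse(sd$multiplicity == "3+", "3", sd$multiplicity)
  for (m in mstates) {
    for (s in samples) {
      col <- paste0(dialect$intensityPrefix, s, dialect$multiplicitySep, m)
      v <- rep("", nrow(out))
      sel <- recState == m
      v[sel] <- .fmtNum(mat[sel, s])
      v[sel][is.na(mat[sel, s])] <- ""
      out[[col]] <- v
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a study design from YAML
#'
#' The file declares `groups:` (group label -> list of sample ids) and
#' optionally `contrasts:` as `"NUM/DEN"` strings or mappings with
#' `name`/`numerator`/`denominator`.  Without a `contrasts:` entry the
#' default H/C, S/H, E/H set is used (requires groups C, H, S, E).
#'
#' @param path YAML file.
#' @return A [StudyDesign-class].
#' @export
readStudyDesign <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups)) .stopf("design file lacks a 'groups' section")
  groups <- lapply(cfg$groups, as.character)
  contrasts <- cfg$contrasts
  if (!is.null(contrasts) && is.list(contrasts) &&
      all(vapply(contrasts, is.list, logical(1)))) {
    contrasts <- data.frame(
      name = vapply(contrasts, function(x)
        x$name %||% paste0(x$numerator, "/", x$denominator), character(1)),
      numerator = vapply(contrasts, function(x) x$numerator, character(1)),
      denominator = vapply(contrasts, function(x) x$denominator, character(1)),
      stringsAsFactors = FALSE
    )
  } else if (!is.null(contrasts)) {
    contrasts <- as.character(unlist(contrasts))
  }
  StudyDesign(groups, contrasts)
}

#' Read gene sets from a GMT file
#'
#' Standard Broad GMT: `set_id TAB description TAB member TAB member ...`.
#' Members are uppercased and deduplicated; sets left with zero members are
#' dropped with a warning.
#'
#' @param path GMT file.
#' @param category category label applied to all sets in the file (one of
#'   KEGG, GO_BP, GO_CC, GO_MF, SUBCELL).
#' @return A [GeneSetCollection-class].
#' @export
readGeneSets <- function(path, category = "KEGG") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    .warnf("empty gene-set file: %s", path)
    return(new("GeneSetCollection", sets = setNames(list(), character(0)),
               info = data.frame(set_id = character(0),
                                 set_name = character(0),
                                 category = character(0),
                                 stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad))
    .stopf("malformed GMT line(s) (need id, description, members): %s",
           paste(head(bad, 10), collapse = ", "))
  ids <- vapply(fields, `[`, character(1), 1L)
  descs <- vapply(fields, `[`, character(1), 2L)
  members <- lapply(fields, function(f) {
    m <- f[-(1:2)]
    unique(toupper(m[nzchar(m)]))
  })
  empty <- lengths(members) == 0
  if (any(empty)) {
    .warnf("dropping %d gene set(s) with zero members: %s", sum(empty),
           paste(head(ids[empty], 10), collapse = ", "))
    ids <- ids[!empty]; descs <- descs[!empty]; members <- members[!empty]
  }
  if (anyDuplicated(ids))
    .stopf("duplicate set id(s) in GMT: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(members) <- ids
  GeneSetCollection(members, category = category, setNames = descs)
}

#' Read a protein-protein interaction edge list
#'
#' Three-column TSV (protein A, protein B, confidence).  STRING flat files
#' store the combined score times 1000; `scoreScale = "milli"` divides by
#' 1000 so confidences land in \[0, 1\].  Edges are canonicalised: symbols
#' uppercased, self-loops dropped with a warning, undirected pairs stored
#' with A < B, duplicates collapsed keeping the maximum confidence.
#'
#' @param path TSV file.
#' @param scoreScale `"unit"` (scores already in \[0,1\]) or `"milli"`.
#' @param header does the file carry a header row?
#' @return data.frame with columns `protein_a`, `protein_b`, `confidence`.
#' @export
readPPIEdges <- function(path, scoreScale = c("unit", "milli"),
                         header = TRUE) {
  scoreScale <- match.arg(scoreScale)
  df <- read.delim(path, sep = "\t", header = header,
                   stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 3)
    .stopf("PPI edge file needs 3 columns (a, b, confidence); found %d",
           ncol(df))
  edges <- data.frame(a = toupper(as.character(df[[1]])),
                      b = toupper(as.character(df[[2]])),
                      confidence = as.numeric(df[[3]]),
                      stringsAsFactors = FALSE)
  if (scoreScale == "milli") edges$confidence <- edges$confidence / 1000
  if (any(is.na(edges$confidence)))
    .stopf("non-numeric confidence value(s) in %s", path)
  if (any(edges$confidence < 0 | edges$confidence > 1))
    .stopf("confidence outside [0, 1] after scaling (scoreScale = '%s')",
           scoreScale)
  canonicalizeEdges(edges)
}

#' Canonicalise an undirected edge list
#'
#' @param edges data.frame with columns `a`/`protein_a`, `b`/`protein_b`,
#'   `confidence`.
#' @return canonical data.frame (`protein_a < protein_b`, self-loops
#'   removed, duplicates collapsed to the maximum confidence), sorted.
#' @export
canonicalizeEdges <- function(edges) {
  a <- edges[[intersect(c("a", "protein_a"), colnames(edges))[1]]]
  b <- edges[[intersect(c("b", "protein_b"), colnames(edges))[1]]]
  conf <- edges$confidence
  self <- a == b
  if (any(self)) {
    .warnf("dropping %d self-loop edge(s)", sum(self))
    a <- a[!self]; b <- b[!self]; conf <- conf[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- tapply(conf, key, max)
  parts <- strsplit(names(keep), "\r", fixed = TRUE)
  out <- data.frame(protein_a = vapply(parts, `[`, character(1), 1L),
                    protein_b = vapply(parts, `[`, character(1), 2L),
                    confidence = as.numeric(keep),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a result table as TSV with a provenance header
#'
#' Writes any tabular result with `#`-prefixed header lines recording the
#' package version and caller-supplied parameters, followed by a plain TSV
#' body.  Numeric columns survive a write/read round trip to at least 12
#' significant digits.
#'
#' @param df data.frame.
#' @param path output path.
#' @param params named list recorded in the header.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("phosphoScreen"))
  writeLines(sprintf("#phosphoScreen\t%s", ver), con)
  for (nm in names(params))
    writeLines(sprintf("#%s\t%s", nm, paste(params[[nm]], collapse = ",")),
               con)
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- .fmtNum(out[[j]])
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "NA"))
  invisible(path)
}

#' Read a table written by [writeResultTable()]
#'
#' @param path file path.
#' @return data.frame (header comment lines skipped).
#' @export
readResultTable <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", quote = "",
             stringsAsFactors = FALSE)
}
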