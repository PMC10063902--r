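#' Site-level reversal pairs between a disease and a treatment contrast
#'
#' Finds evidence that a phosphorylation change seen in the disease
#' contrast (e.g. H/C) is opposed under treatment (e.g. S/H): a significant
#' `down` call in one table paired with a significant `up` call in the
#' other.  Two matching modes:
#'
#' * `"protein"` (default): any significant site of a protein in the
#'   disease table pairs with any opposite-direction significant site of
#'   the same protein in the treatment table.  Disease and treatment need
#'   not act on the same residue — regulated positions typically differ
#'   (a channel subunit may lose phosphorylation at one serine with disease
#'   while treatment adds it at another).
#' * `"site"`: the stricter same-record match on identical
#'   (protein, position, multiplicity).
#'
#' Both tables must descend from the same processed experiment; their
#' provenance tokens are compared and a mismatch is an error.
#'
#' @param disease,treatment differential tables from [computeContrast()].
#' @param mode `"protein"` or `"site"`.
#' @return data.frame of site pairs: `protein`, `gene`, `pattern`
#'   (`down_up` = down in disease, up in treatment; `up_down` symmetric),
#'   disease site columns (`disease_position`, `disease_residue`,
#'   `disease_call`, `disease_p`) and the treatment counterparts.
#' @export
findReversedSites <- function(disease, treatment,
                              mode = c("protein", "site")) {
  mode <- match.arg(mode)
  pd <- attr(disease, "provenance"); pt <- attr(treatment, "provenance")
  if (!is.null(pd) && !is.null(pt) && !identical(pd, pt))
    .stopf("differential tables come from different processing runs (provenance mismatch)")
  dSig <- disease[disease$call != "ns", , drop = FALSE]
  tSig <- treatment[treatment$call != "ns", , drop = FALSE]
  key <- if (mode == "site") "site_id" else "protein"
  tcols <- if (mode == "site")
    c("site_id", "position", "residue", "call", "p") else
    c("protein", "position", "residue", "call", "p", "site_id")
  merged <- merge(
    dSig[c("protein", "gene", "position", "residue", "call", "p", "site_id")],
    tSig[tcols],
    by = key,
    suffixes = c("_d", "_t")
  )
  if (nrow(merged) == 0) return(.emptyReversalPairs())
  opposite <- (merged$call_d == "down" & merged$call_t == "up") |
    (merged$call_d == "up" & merged$call_t == "down")
  merged <- merged[opposite, , drop = FALSE]
  if (nrow(merged) == 0) return(.emptyReversalPairs())
  out <- data.frame(
    protein = merged$protein,
    gene = merged$gene,
    pattern = ifelse(merged$call_d == "down", "down_up", "up_down"),
    disease_position = merged$position_d,
    disease_residue = merged$residue_d,
    disease_call = merged$call_d,
    disease_p = merged$p_d,
    treatment_position = merged$position_t,
    treatment_residue = merged$residue_t,
    treatment_call = merged$call_t,
    treatment_p = merged$p_t,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene, out$disease_position, out$treatment_position), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyReversalPairs <- function() {
  data.frame(protein = character(0), gene = character(0),
             pattern = character(0), disease_position = integer(0),
             disease_residue = character(0), disease_call = character(0),
             disease_p = numeric(0), treatment_position = integer(0),
             treatment_residue = character(0), treatment_call = character(0),
             treatment_p = numeric(0), stringsAsFactors = FALSE)
}

#' Protein-level reversal classification
#'
#' Collapses site-level reversal pairs to one row per protein:
#' `down_up` when only down-in-disease / up-in-treatment evidence exists,
#' `up_down` for the opposite-only pattern, and `mixed` when distinct site
#' pairs support both patterns (a single pair can never be mixed).
#'
#' @param pairs output of [findReversedSites()].
#' @return data.frame with `protein`, `gene`, `class`,
#'   `disease_direction` / `treatment_direction` labels in the Down / Up /
#'   "Up/down" table style, and `n_pairs`.
#' @export
classifyReversalProteins <- function(pairs) {
  if (nrow(pairs) == 0)
    return(data.frame(protein = character(0), gene = character(0),
                      class = character(0), disease_direction = character(0),
                      treatment_direction = character(0),
                      n_pairs = integer(0), stringsAsFactors = FALSE))
  sp <- split(pairs, pairs$protein)
  rows <- lapply(sp, function(df) {
    pats <- unique(df$pattern)
    cls <- if (length(pats) == 2) "mixed" else pats
    dirs <- switch(cls,
      down_up = c("Down", "Up"),
      up_down = c("Up", "Down"),
      mixed = c("Up/down", "Down/up"))
    data.frame(protein = df$protein[1], gene = df$gene[1], class = cls,
               disease_direction = dirs[1], treatment_direction = dirs[2],
               n_pairs = nrow(df), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$class, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict reversal hits to the top-ranked pathways
#'
#' Keeps proteins belonging to at least one of the given pathway sets and
#' attaches the matching pathway ids; hits outside every set are dropped.
#'
#' @param hits protein-level hits from [classifyReversalProteins()].
#' @param topSets enrichment rows (e.g. from [topPathways()]) whose
#'   `set_id` column names the pathways to restrict to; may also be a
#'   character vector of set ids.
#' @param gsc the [GeneSetCollection-class] the set ids refer to.
#' @return `hits` filtered, with a `pathways` column (semicolon-separated),
#'   sorted by class then gene.
#' @export
restrictToPathways <- function(hits, topSets, gsc) {
  ids <- if (is.character(topSets)) topSets else topSets$set_id
  sets <- geneSets(gsc)[intersect(ids, names(geneSets(gsc)))]
  if (nrow(hits) == 0 || length(sets) == 0) {
    hits$pathways <- character(nrow(hits))
    return(hits[integer(0), , drop = FALSE])
  }
  up <- toupper(hits$gene)
  memberOf <- lapply(up, function(g)
    names(sets)[vapply(sets, function(m) g %in% m, logical(1))])
  keep <- lengths(memberOf) > 0
  out <- hits[keep, , drop = FALSE]
  out$pathways <- vapply(memberOf[keep], paste, character(1),
                         collapse = ";")
  out <- out[order(out$class, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end reversal screen
#'
#' Composition of [findReversedSites()], [classifyReversalProteins()] and
#' [restrictToPathways()].
#'
#' @inheritParams findReversedSites
#' @inheritParams restrictToPathways
#' @return the restricted protein-level hit table.
#' @export
reversalScreen <- function(disease, treatment, topSets, gsc,
                           mode = c("protein", "site")) {
  pairs <- findReversedSites(disease, treatment, mode = match.arg(mode))
  restrictToPathways(classifyReversalProteins(pairs), topSets, gsc)
}

#' Build differential tables from a published direction fixture
#'
#' Turns a table of per-protein direction calls (columns: gene, disease
#' direction, treatment direction, with values `Down`, `Up` or `Up/down` /
#' `Down/up`) into a matched pair of synthetic differential tables: each
#' plain direction becomes one significant site, each mixed direction two
#' sites, with treatment sites placed at different positions than disease
#' sites (regulated positions differ across contrasts).  Useful for
#' re-running the screen on direction columns transcribed from published
#' reversal tables.
#'
#' @param df data.frame whose first three columns are gene, disease
#'   direction, treatment direction.
#' @return list with `disease` and `treatment` differential tables sharing
#'   a provenance token.
#' @export
directionFixtureTables <- function(df) {
  gene <- as.character(df[[1]])
  ddir <- as.character(df[[2]])
  tdir <- as.character(df[[3]])
  mk <- function(dirs, offset) {
    rows <- lapply(seq_along(gene), function(i) {
      d <- tolower(dirs[i])
      calls <- if (grepl("/", d)) strsplit(d, "/", fixed = TRUE)[[1]] else d
      data.frame(protein = toupper(gene[i]), gene = toupper(gene[i]),
                 position = offset + seq_along(calls),
                 residue = "S", multiplicity = "1",
                 site_id = paste0(toupper(gene[i]), "_",
                                  offset + seq_along(calls), "_1"),
                 log2fc = ifelse(calls == "up", 1, -1),
                 t = ifelse(calls == "up", 8, -8), p = 1e-4,
                 call = calls, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "provenance") <- "direction_fixture"
    out
  }
  list(disease = mk(ddir, 0L), treatment = mk(tdir, 100L))
}
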