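#' Fisher's exact over-representation test across gene sets
#'
#' For each set, members are first intersected with the background
#' universe; the one-sided (upper-tail) hypergeometric p-value of the
#' foreground overlap is then computed, i.e. the probability of drawing at
#' least `k` set members when sampling `n` proteins from a universe of `N`
#' containing `K` members.  The enrichment score is the fold
#' over-representation `(k/n) / (K/N)`.  Sets with no foreground overlap
#' are reported with p = 1 (the upper tail includes zero).
#'
#' @param foreground character vector of protein/gene symbols (subset of
#'   `background`); case-insensitive.
#' @param background universe of symbols (e.g. all proteins quantified
#'   after processing).
#' @param gsc a [GeneSetCollection-class].
#' @param categories optional categories to test (default: all).
#' @param alpha significance level recorded in the `significant` column.
#' @return data.frame sorted by (p ascending, enrichment score descending,
#'   set_id): `set_id`, `set_name`, `category`, `k`, `K`, `n`, `N`,
#'   `fisher_p`, `enrichment_score`, `significant`, `rank`.
#' @export
fisherEnrichment <- function(foreground, background, gsc,
                             categories = NULL, alpha = 0.05) {
  foreground <- unique(toupper(foreground))
  background <- unique(toupper(background))
  if (length(background) == 0) .stopf("empty background universe")
  outside <- setdiff(foreground, background)
  if (length(outside))
    .stopf("foreground not a subset of background (e.g. %s)",
           paste(head(outside, 5), collapse = ", "))
  info <- setInfo(gsc)
  sets <- geneSets(gsc)
  if (!is.null(categories)) {
    keep <- info$category %in% categories
    info <- info[keep, , drop = FALSE]
    sets <- sets[keep]
  }
  N <- length(background)
  n <- length(foreground)
  rows <- lapply(seq_along(sets), function(i) {
    members <- intersect(sets[[i]], background)
    K <- length(members)
    k <- length(intersect(members, foreground))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    score <- if (K > 0 && n > 0) (k / n) / (K / N) else NA_real_
    data.frame(set_id = info$set_id[i], set_name = info$set_name[i],
               category = info$category[i], k = k, K = K, n = n, N = N,
               fisher_p = p, enrichment_score = score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_id = character(0), set_name = character(0),
                      category = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), fisher_p = numeric(0),
                      enrichment_score = numeric(0),
                      significant = logical(0), rank = integer(0)))
  out$significant <- out$fisher_p < alpha
  ord <- order(out$fisher_p, -out$enrichment_score, out$set_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Top-ranked pathways
#'
#' Deterministic head of the enrichment ranking within one category:
#' ordered by p ascending, enrichment score descending, then set id.
#'
#' @param results output of [fisherEnrichment()].
#' @param n number of sets to keep (default 20, the usual bubble-plot
#'   depth).
#' @param category category to rank within (default `"KEGG"`).
#' @return the first `n` rows, re-ranked 1..n.
#' @export
topPathways <- function(results, n = 20, category = "KEGG") {
  sub <- results[results$category == category, , drop = FALSE]
  ord <- order(sub$fisher_p, -sub$enrichment_score, sub$set_id)
  out <- head(sub[ord, , drop = FALSE], n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Subcellular compartment tabulation
#'
#' Counts proteins per compartment using the `SUBCELL` sets of the
#' collection.  Multi-compartment proteins contribute to every compartment
#' they belong to (so compartment fractions can exceed 1 when summed); the
#' numbers of multi-compartment and unassigned proteins are reported
#' alongside.
#'
#' @param proteins character vector of symbols.
#' @param gsc a [GeneSetCollection-class] containing `SUBCELL` sets.
#' @return list with `counts` (data.frame compartment/count/fraction),
#'   `n_proteins`, `n_multi`, `n_unassigned`.
#' @export
subcellularClassify <- function(proteins, gsc) {
  proteins <- unique(toupper(proteins))
  info <- setInfo(gsc)
  sets <- geneSets(gsc)[info$category == "SUBCELL"]
  hits <- vapply(sets, function(m) sum(proteins %in% m), integer(1))
  nCompPerProt <- if (length(sets)) {
    member <- matrix(unlist(lapply(sets, function(m) proteins %in% m)),
                     nrow = length(proteins))
    rowSums(member)
  } else rep(0L, length(proteins))
  counts <- data.frame(
    compartment = names(sets) %||% character(0),
    count = as.integer(hits),
    fraction = if (length(proteins)) hits / length(proteins) else numeric(0),
    stringsAsFactors = FALSE
  )
  counts <- counts[order(-counts$count, counts$compartment), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, n_proteins = length(proteins),
       n_multi = sum(nCompPerProt > 1),
       n_unassigned = sum(nCompPerProt == 0))
}
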