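# builders shared across test files; everything is generated in code

# a random PhosphoExperiment with given sample names
makeExperiment <- function(nSites = 20, samples = c("C1", "C2", "C3",
                                                    "H1", "H2", "H3"),
                           seed = 1, missing = 0.15, scale = "raw",
                           nProteins = max(2L, nSites %/% 3L)) {
  set.seed(seed)
  prot <- sprintf("P%03d", sample.int(nProteins, nSites, replace = TRUE))
  pos <- integer(nSites)
  for (p in unique(prot)) {
    idx <- which(prot == p)
    pos[idx] <- sample.int(5000L, length(idx))
  }
  mat <- matrix(2^rnorm(nSites * length(samples), 20, 2), nSites,
                dimnames = list(NULL, samples))
  if (missing > 0) mat[runif(length(mat)) < missing] <- NA
  sd <- data.frame(
    protein = prot,
    gene = toupper(prot),
    position = pos,
    residue = sample(c("S", "T", "Y"), nSites, replace = TRUE,
                     prob = c(0.8, 0.15, 0.05)),
    localizationProb = runif(nSites),
    deltaScore = rgamma(nSites, 2, scale = 10),
    multiplicity = sample(c("1", "2", "3+"), nSites, replace = TRUE,
                          prob = c(0.8, 0.15, 0.05)),
    stringsAsFactors = FALSE
  )
  pe <- PhosphoExperiment(if (scale == "log2") log2(mat) else mat, sd,
                          scale = scale)
  pe
}

twoGroupDesign <- function(contrast = "H/C") {
  StudyDesign(list(C = c("C1", "C2", "C3"), H = c("H1", "H2", "H3")),
              contrasts = contrast)
}

fourGroupDesign <- function() {
  StudyDesign(list(C = paste0("C", 1:3), H = paste0("H", 1:3),
                   S = paste0("S", 1:3), E = paste0("E", 1:3)))
}

# experiment with exactly specified intensity matrix (log2 scale)
matExperiment <- function(mat, scale = "log2") {
  n <- nrow(mat)
  sd <- data.frame(protein = sprintf("P%03d", seq_len(n)),
                   gene = sprintf("G%03d", seq_len(n)),
                   position = seq_len(n), residue = "S",
                   localizationProb = 0.99, deltaScore = 50,
                   multiplicity = "1", stringsAsFactors = FALSE)
  PhosphoExperiment(mat, sd, scale = scale)
}

# write a MaxQuant-style site table; intensities is a list:
# intensities[[sample]][[multiplicity]] = numeric vector over rows
writeToySiteFile <- function(path, site, intensities,
                             dialect = phosphoDialect()) {
  df <- data.frame(a = site$protein, b = site$gene, c = site$position,
                   d = site$residue, e = site$localizationProb,
                   f = site$deltaScore, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(dialect$protein, dialect$gene, dialect$position,
                    dialect$aminoAcid, dialect$locProb, dialect$deltaScore)
  for (s in names(intensities))
    for (m in names(intensities[[s]]))
      df[[paste0(dialect$intensityPrefix, s, dialect$multiplicitySep, m)]] <-
        intensities[[s]][[m]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a tiny differential table written by hand
handDiffTable <- function(protein, position, call, p = 1e-3,
                          provenance = "toy") {
  n <- length(protein)
  if (n == 0) {
    out <- data.frame(protein = character(0), gene = character(0),
                      position = integer(0), residue = character(0),
                      multiplicity = character(0), site_id = character(0),
                      log2fc = numeric(0), t = numeric(0), p = numeric(0),
                      call = character(0), stringsAsFactors = FALSE)
    attr(out, "provenance") <- provenance
    return(out)
  }
  lfc <- ifelse(call == "up", 1.5, ifelse(call == "down", -1.5, 0.05))
  out <- data.frame(protein = protein, gene = toupper(protein),
                    position = position, residue = "S", multiplicity = "1",
                    site_id = paste0(protein, "_", position, "_1"),
                    log2fc = lfc, t = lfc * 5,
                    p = ifelse(call == "ns", 0.9, p),
                    call = call, stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  out
}

# independent oracles ---------------------------------------------------

# upper-tail hypergeometric by exhaustive enumeration over achievable k
hyperOracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  js <- seq(k, min(K, n))
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# protein-level reversal by brute-force double loop over all site pairs
bruteReversalPairs <- function(disease, treatment) {
  out <- list()
  for (i in seq_len(nrow(disease))) {
    for (j in seq_len(nrow(treatment))) {
      if (disease$protein[i] != treatment$protein[j]) next
      cd <- disease$call[i]; ct <- treatment$call[j]
      if (cd == "ns" || ct == "ns" || cd == ct) next
      out[[length(out) + 1L]] <- data.frame(
        protein = disease$protein[i],
        pattern = if (cd == "down") "down_up" else "up_down",
        disease_position = disease$position[i],
        treatment_position = treatment$position[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(protein = character(0),
                                      pattern = character(0),
                                      disease_position = integer(0),
                                      treatment_position = integer(0)))
  do.call(rbind, out)
}

# connected components by flood fill over an edge list
floodComponents <- function(nodes, edges) {
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  adj <- lapply(setNames(nodes, nodes), function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[i]; b <- edges$protein_b[i]
    if (a %in% nodes && b %in% nodes) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  cid <- 0L
  for (v in nodes) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, adj[[u]][is.na(comp[adj[[u]]])])
    }
  }
  comp
}
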