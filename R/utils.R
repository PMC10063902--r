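#' @importFrom methods new validObject is slot
#' @importFrom stats median p.adjust phyper pt rbeta rbinom rgamma rnorm runif
#'   setNames var
#' @importFrom utils head read.delim write.table combn packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.MULT_LEVELS <- c("1", "2", "3+")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic token summarising a processing history; used to detect
# cross-stage mixing of tables that did not come from the same run.
.provenanceToken <- function(steps) {
  if (length(steps) == 0L) return("unprocessed")
  paste(vapply(steps, function(s) s$step, character(1)), collapse = ">")
}

.checkProbs <- function(p, what) {
  if (any(p < 0)) .stopf("%s must be non-negative", what)
  if (abs(sum(p) - 1) > 1e-9) .stopf("%s must sum to 1 (within 1e-9)", what)
  invisible(p)
}

# format numerics so a write/read cycle preserves 12 significant digits
.fmtNum <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}
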