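#' Normalize condition labels
#'
#' Tissue / cell-type labels from independently produced expression tables are
#' matched by name. The matching key is the trimmed, case-folded label, so
#' \code{" Lung "} and \code{"lung"} refer to the same condition.
#'
#' @param x character vector of condition labels.
#' @return character vector of normalized labels.
#' @examples
#' normalizeConditionLabels(c(" Lung ", "BRAIN"))
#' @export
normalizeConditionLabels <- function(x) {
  tolower(trimws(as.character(x)))
}

# INFO-level log line to stderr; every filter/dedup count goes through here so
# a run leaves a complete count trail.
.logInfo <- function(fmt, ...) {
  message(sprintf(fmt, ...))
}

# Run `expr` with the RNG seeded to `seed`, restoring global RNG state after.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.isCount <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pair key used wherever (lncRNA, disease) pairs index into each other.
.pairKey <- function(a, b) paste(a, b, sep = "\r")
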