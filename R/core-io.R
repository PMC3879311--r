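#' Read an expression table
#'
#' Reads a tab-separated expression table into an
#' \linkS4class{ExpressionMatrix}. Two layouts are supported:
#' \describe{
#'   \item{\code{plain}}{first column = entity ID, remaining columns = one
#'     score per condition; the header names the conditions.}
#'   \item{\code{bedlike}}{UCSC-style: columns \code{chrom}, \code{start},
#'     \code{end}, \code{name}, then one score column per condition. The
#'     matrix is keyed by \code{name}; chrom/start/end are carried as opaque
#'     annotation in \code{rowData} (start/end are 0-based half-open if ever
#'     interpreted, per the UCSC convention).}
#' }
#' Condition labels are trimmed and case-folded so that two independently
#' produced tables can be matched by name. Row and column counts are logged.
#'
#' @param path path to a TSV file with a header row.
#' @param layout \code{"plain"} or \code{"bedlike"}.
#' @param saturationValue optional saturation score (e.g. 1000 for UCSC
#'   tracks), recorded in the object's metadata for downstream degenerate
#'   filtering.
#' @return an \linkS4class{ExpressionMatrix}.
#' @details Hard errors: duplicate entity ID (named in the message);
#'   negative or non-numeric value (row/column named); empty matrix.
#' @seealso [writeExpressionTable()] for the inverse operation.
#' @examples
#' f <- system.file("extdata", "lnc_example.tsv", package = "lncDA")
#' readExpressionTable(f, layout = "bedlike", saturationValue = 1000)
#' @export
readExpressionTable <- function(path, layout = c("plain", "bedlike"),
                                saturationValue = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (nrow(tab) == 0L) stop("empty expression table: ", path)
  rowData <- NULL
  if (layout == "bedlike") {
    need <- c("chrom", "start", "end", "name")
    if (ncol(tab) < 5L || !all(need %in% tolower(colnames(tab)[1:4])))
      stop("bedlike layout requires leading columns chrom, start, end, name")
    colnames(tab)[1:4] <- tolower(colnames(tab)[1:4])
    ids <- as.character(tab$name)
    rowData <- tab[, need[need != "name"], drop = FALSE]
    scores <- tab[, -(1:4), drop = FALSE]
  } else {
    ids <- as.character(tab[[1L]])
    scores <- tab[, -1L, drop = FALSE]
  }
  if (ncol(scores) < 2L)
    stop("expression table needs at least 2 condition columns: ", path)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate entity ID '%s' in %s",
                 ids[duplicated(ids)][1L], path))
  m <- matrix(NA_real_, nrow(scores), ncol(scores),
              dimnames = list(ids, colnames(scores)))
  for (j in seq_len(ncol(scores))) {
    v <- suppressWarnings(as.numeric(scores[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric expression value at row '%s', column '%s'",
                   ids[bad[1L]], colnames(scores)[j]))
    if (any(v < 0)) {
      bad <- which(v < 0)[1L]
      stop(sprintf("negative expression value at row '%s', column '%s'",
                   ids[bad], colnames(scores)[j]))
    }
    m[, j] <- v
  }
  .logInfo("readExpressionTable: %d entities x %d conditions from %s",
           nrow(m), ncol(m), path)
  ExpressionMatrix(m, rowData = rowData, saturationValue = saturationValue)
}

#' Write an expression table
#'
#' Inverse of [readExpressionTable()]: writes the plain layout (entity ID
#' column named \code{entity_id}, one column per condition), or the bedlike
#' layout when the object carries chrom/start/end annotation and
#' \code{layout = "bedlike"}. Writing then reading reproduces the matrix
#' content exactly (order and labels preserved).
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path output TSV path.
#' @param layout \code{"plain"} or \code{"bedlike"}.
#' @return invisibly, \code{path}.
#' @export
writeExpressionTable <- function(x, path, layout = c("plain", "bedlike")) {
  layout <- match.arg(layout)
  v <- expressionValues(x)
  if (layout == "bedlike") {
    rd <- as.data.frame(SummarizedExperiment::rowData(x))
    if (!all(c("chrom", "start", "end") %in% colnames(rd)))
      stop("bedlike output requires chrom/start/end rowData")
    out <- data.frame(chrom = rd$chrom, start = rd$start, end = rd$end,
                      name = rownames(v), v, check.names = FALSE,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(entity_id = rownames(v), v, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared two-column TSV reader with header auto-detection: the first line is
# taken as a header when neither field looks like data already seen in known
# header vocabularies (gene/lncrna/disease variants).
.readPairTable <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty association table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short))
    stop(sprintf("line %d of %s has fewer than 2 columns", short[1L], path))
  first <- tolower(trimws(fields[[1L]][1:2]))
  headerWords <- c("gene", "gene_id", "geneid", "lncrna", "lncrna_id",
                   "lincrna", "disease", "disease_id", "diseaseid")
  if (all(first %in% headerWords)) {
    fields <- fields[-1L]
    if (!length(fields)) stop("association table has a header but no data: ",
                              path)
  }
  a <- trimws(vapply(fields, `[[`, "", 1L))
  b <- trimws(vapply(fields, `[[`, "", 2L))
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

#' Read a gene-disease association table
#'
#' Reads a two-column TSV (gene ID, disease ID; header optional and
#' auto-detected) in the shape of a DisGeNET extract. Duplicate lines are
#' deduplicated with a logged count.
#'
#' @param path path to the TSV file.
#' @return a \linkS4class{GeneDiseaseMap}.
#' @examples
#' f <- system.file("extdata", "gene_disease_example.tsv", package = "lncDA")
#' readGeneDiseaseTable(f)
#' @export
readGeneDiseaseTable <- function(path) {
  p <- .readPairTable(path, "gene-disease")
  .logInfo("readGeneDiseaseTable: %d lines from %s", nrow(p), path)
  GeneDiseaseMap(p)
}

#' Read a known lncRNA-disease association table
#'
#' Same format and rules as [readGeneDiseaseTable()], but typed as
#' lncRNA-disease pairs (the validation standard for [loocv()] and
#' [overlapAccuracy()]).
#'
#' @param path path to the two-column TSV (lncRNA ID, disease ID).
#' @return an \linkS4class{AssociationSet}.
#' @export
readAssociationSet <- function(path) {
  p <- .readPairTable(path, "lncRNA-disease")
  .logInfo("readAssociationSet: %d lines from %s", nrow(p), path)
  AssociationSet(p)
}

#' Write an association set
#'
#' @param x an \linkS4class{AssociationSet}.
#' @param path output TSV path; columns \code{lncrna_id}, \code{disease_id}.
#' @return invisibly, \code{path}.
#' @export
writeAssociationSet <- function(x, path) {
  utils::write.table(associationPairs(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.predictionCols <- c("lncrna_id", "disease_id", "n", "x", "y",
                     "p_raw", "p_bonferroni", "q_fdr")
.predictionHeader <- c("lncRNA", "disease", "n", "x", "y",
                       "p_raw", "p_bonferroni", "q_fdr")

# Empty prediction table with the canonical schema.
.emptyPredictions <- function() {
  data.frame(lncrna_id = character(0), disease_id = character(0),
             n = integer(0), x = integer(0), y = integer(0),
             p_raw = numeric(0), p_bonferroni = numeric(0),
             q_fdr = numeric(0), stringsAsFactors = FALSE)
}

#' Write enrichment predictions
#'
#' Writes the prediction table produced by [enrichDiseases()] as a TSV with
#' columns \code{lncRNA}, \code{disease}, \code{n} (co-expressed gene-set
#' size), \code{x} (disease gene-set size within the universe), \code{y}
#' (overlap size), \code{p_raw}, \code{p_bonferroni}, \code{q_fdr}, in input
#' order (the enrichment contract sorts ascending by FDR).
#'
#' @param results data.frame of enrichment results.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @seealso [readPredictions()]
#' @export
writePredictions <- function(results, path) {
  stopifnot(all(.predictionCols %in% colnames(results)))
  out <- results[, .predictionCols, drop = FALSE]
  colnames(out) <- .predictionHeader
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read enrichment predictions
#'
#' Reads a TSV written by [writePredictions()] back into the canonical
#' prediction data.frame (round-trip identity on content and order).
#'
#' @param path path to the prediction TSV.
#' @return data.frame with columns \code{lncrna_id}, \code{disease_id},
#'   \code{n}, \code{x}, \code{y}, \code{p_raw}, \code{p_bonferroni},
#'   \code{q_fdr}.
#' @export
readPredictions <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(.predictionHeader %in% colnames(tab)))
    stop("not a prediction table (missing expected columns): ", path)
  tab <- tab[, .predictionHeader, drop = FALSE]
  colnames(tab) <- .predictionCols
  tab$lncrna_id <- as.character(tab$lncrna_id)
  tab$disease_id <- as.character(tab$disease_id)
  for (cc in c("n", "x", "y")) tab[[cc]] <- as.integer(tab[[cc]])
  rownames(tab) <- NULL
  tab
}
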