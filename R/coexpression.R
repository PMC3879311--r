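#' Remove degenerate expression profiles
#'
#' Drops rows whose scores are constant at 0 (never expressed) or constant
#' at the saturation score (saturated in every condition; 1000 on UCSC score
#' tracks). Both carry no ranking information and would make tau and Spearman
#' correlation undefined or meaningless. Removal counts are logged and
#' returned so a run's count trail can be checked exactly.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param saturationValue the saturation score; default 1000. \code{NULL}
#'   disables the saturation rule (only all-zero rows are removed).
#' @return list with components \code{kept} (an ExpressionMatrix, or
#'   \code{NULL} if every row was removed), \code{removedIds},
#'   \code{removedZeroIds}, \code{removedSaturatedIds}.
#' @examples
#' m <- ExpressionMatrix(matrix(c(0, 0, 0, 5, 2, 0, 1000, 1000, 1000),
#'        3, 3, byrow = TRUE,
#'        dimnames = list(c("z", "ok", "sat"), c("a", "b", "c"))))
#' filterDegenerate(m)$removedIds
#' @export
filterDegenerate <- function(x, saturationValue = 1000) {
  stopifnot(methods::is(x, "ExpressionMatrix"))
  v <- expressionValues(x)
  allZero <- rowSums(v != 0) == 0L
  if (is.null(saturationValue)) {
    allSat <- rep(FALSE, nrow(v))
  } else {
    allSat <- rowSums(v != saturationValue) == 0L
  }
  drop <- allZero | allSat
  .logInfo("filterDegenerate: removed %d row(s) (%d all-zero, %d all-saturation)",
           sum(drop), sum(allZero), sum(allSat))
  kept <- if (all(drop)) NULL else x[!drop, ]
  list(kept = kept,
       removedIds = rownames(v)[drop],
       removedZeroIds = rownames(v)[allZero],
       removedSaturatedIds = rownames(v)[allSat])
}

#' Conditions shared by two expression matrices
#'
#' Intersects the (normalized) condition labels of two matrices, in the
#' first matrix's column order. Correlating over too few shared conditions
#' is meaningless, so fewer than \code{minCommon} shared labels is a hard
#' error.
#'
#' @param a,b \linkS4class{ExpressionMatrix} objects.
#' @param minCommon minimum number of shared conditions; default 5.
#' @return character vector of shared condition labels, in \code{a}'s order.
#' @export
commonConditions <- function(a, b, minCommon = 5) {
  shared <- intersect(conditionLabels(a), conditionLabels(b))
  if (length(shared) < minCommon)
    stop(sprintf("only %d condition(s) shared between the matrices (need >= %d)",
                 length(shared), minCommon))
  shared
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of the average-rank (fractional-rank) transforms of
#' the two vectors — the standard tie-aware Spearman definition. Invariant
#' under strictly increasing transforms of either input; symmetric; always
#' in [-1, 1].
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return rho in [-1, 1], or \code{NA_real_} when either vector is constant
#'   (the correlation is undefined; [buildCoexpressionNetwork()] skips and
#'   counts such pairs).
#' @examples
#' spearmanRho(c(1, 2, 3), c(10, 20, 30))   #  1
#' spearmanRho(c(1, 2, 3), c(3, 2, 1))      # -1
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# Two-sided p-value for a Spearman coefficient via the t approximation
# t = rho * sqrt((n-2)/(1-rho^2)) with n-2 df. Reported only; the network
# filter uses rho itself. Clamped into (0, 1].
.spearmanPValue <- function(rho, n) {
  p <- ifelse(abs(rho) >= 1, 0,
              2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Build the lncRNA-gene co-expression network
#'
#' Computes the Spearman rank correlation between every lncRNA and every
#' gene over their shared conditions and keeps pairs with rho >= cutoff
#' (inclusive: a pair at exactly the cutoff is co-expressed). Each retained
#' edge carries rho and a two-sided p-value from the t approximation
#' (reported only; the filter uses rho alone). Pairs involving a profile
#' constant over the shared conditions have undefined correlation and are
#' skipped with a logged count. Output order is deterministic: lncRNA ID,
#' then gene ID.
#'
#' @param lnc \linkS4class{ExpressionMatrix} of lncRNAs, already passed
#'   through [filterDegenerate()].
#' @param genes \linkS4class{ExpressionMatrix} of genes.
#' @param cutoff Spearman rho cutoff in [-1, 1]; default 0.7.
#' @param minCommon minimum shared conditions (see [commonConditions()]).
#' @return data.frame with columns \code{lncrna_id}, \code{gene_id},
#'   \code{rho}, \code{p_value}; zero rows if no pair reaches the cutoff.
#' @export
buildCoexpressionNetwork <- function(lnc, genes, cutoff = 0.7, minCommon = 5) {
  if (cutoff < -1 || cutoff > 1) stop("cutoff must be in [-1, 1]")
  shared <- commonConditions(lnc, genes, minCommon = minCommon)
  L <- expressionValues(lnc)[, shared, drop = FALSE]
  G <- expressionValues(genes)[, shared, drop = FALSE]
  # rank rows (average ranks for ties); Pearson on ranks == Spearman
  rankRows <- function(m) t(apply(m, 1L, rank))
  Lr <- rankRows(L)
  Gr <- rankRows(G)
  constL <- apply(Lr, 1L, function(r) all(r == r[1L]))
  constG <- apply(Gr, 1L, function(r) all(r == r[1L]))
  nSkipped <- sum(constL) * nrow(G) + sum(constG) * nrow(L) -
    sum(constL) * sum(constG)
  if (nSkipped > 0)
    .logInfo("buildCoexpressionNetwork: skipped %d pair(s) with constant profiles over the %d shared conditions",
             nSkipped, length(shared))
  rho <- suppressWarnings(stats::cor(t(Lr), t(Gr)))
  rho[constL, ] <- NA_real_
  rho[, constG] <- NA_real_
  # inclusive boundary, robust to floating-point representation of exact
  # rational coefficients (e.g. rho = 7/10 on 5 ranks)
  hit <- which(!is.na(rho) & rho >= cutoff - 1e-12, arr.ind = TRUE)
  edges <- data.frame(
    lncrna_id = rownames(L)[hit[, 1L]],
    gene_id = rownames(G)[hit[, 2L]],
    rho = rho[hit],
    p_value = .spearmanPValue(rho[hit], length(shared)),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$lncrna_id, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  .logInfo("buildCoexpressionNetwork: %d co-expressed pair(s) between %d lncRNA(s) and %d gene(s) at rho >= %.3g over %d shared conditions",
           nrow(edges), length(unique(edges$lncrna_id)),
           length(unique(edges$gene_id)), cutoff, length(shared))
  edges
}
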