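#' Hypergeometric upper-tail probability
#'
#' P(Y >= y) where Y is the number of disease genes in a uniform draw of n
#' genes from a universe of M genes containing x disease genes:
#' \deqn{P(Y \ge y) = \sum_{k=y}^{\min(n,x)} \binom{x}{k}\binom{M-x}{n-k} / \binom{M}{n}.}
#' Evaluated through the hypergeometric survival function
#' (\code{stats::phyper}), which works in a numerically stable way for large
#' M; the result is clamped into (0, 1]. Vectorized over its arguments.
#'
#' @param M universe size (number of genes with expression profiles).
#' @param x number of disease genes within the universe, 0 <= x <= M.
#' @param n co-expressed gene-set size, 0 <= n <= M.
#' @param y observed overlap, 0 <= y <= min(n, x).
#' @return upper-tail probability in (0, 1].
#' @examples
#' hypergeomTail(10, 5, 4, 0)   # 1: P(Y >= 0)
#' hypergeomTail(10, 5, 4, 4)   # 5/210
#' hypergeomTail(6, 3, 3, 2)    # 0.5
#' @export
hypergeomTail <- function(M, x, n, y) {
  if (!all(vapply(list(M, x, n, y), function(v)
    is.numeric(v) && !anyNA(v) && all(is.finite(v)) && all(v == round(v)),
    TRUE)))
    stop("M, x, n, y must be finite integers")
  k <- max(length(M), length(x), length(n), length(y))
  M <- rep_len(M, k); x <- rep_len(x, k)
  n <- rep_len(n, k); y <- rep_len(y, k)
  if (any(x < 0 | x > M) || any(n < 0 | n > M))
    stop("require 0 <= x <= M and 0 <= n <= M")
  if (any(y < 0 | y > pmin(n, x)))
    stop("require 0 <= y <= min(n, x)")
  p <- stats::phyper(y - 1, m = x, n = M - x, k = n, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Bonferroni correction
#'
#' \code{min(1, p * m)} for a family of m tests.
#'
#' @param p raw p-value(s) in (0, 1].
#' @param m family size, >= 1.
#' @return corrected p-value(s) in (0, 1].
#' @export
bonferroni <- function(p, m) {
  stopifnot(.isCount(m), m >= 1, all(p > 0), all(p <= 1))
  pmin(1, p * m)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjusted values: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1 and mapped back
#' to input order. \code{m} may exceed the vector length: the extra,
#' implicit tests are treated as p = 1 (used by [enrichDiseases()] when
#' zero-overlap tests belong to the family but are not reported).
#'
#' @param pvals vector of raw p-values in (0, 1]; may be empty.
#' @param m family size; defaults to \code{length(pvals)}.
#' @return adjusted q-values, same order as input.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03))   # 0.03 0.03 0.03
#' @export
bhFdr <- function(pvals, m = length(pvals)) {
  if (!length(pvals)) return(numeric(0))
  stopifnot(all(pvals > 0), all(pvals <= 1), .isCount(m),
            m >= length(pvals))
  stats::p.adjust(pvals, method = "BH", n = m)
}

#' Disease enrichment of co-expressed gene sets
#'
#' Scores each (lncRNA, disease) pair by the hypergeometric upper-tail
#' probability that the lncRNA's co-expressed gene set contains at least the
#' observed number of the disease's genes, corrects for multiple testing
#' (Bonferroni and BH-FDR as separate columns from the raw p-values), keeps
#' pairs with FDR <= cutoff, and sorts ascending by FDR.
#'
#' Disease gene sets are intersected with the expression universe before x
#' is counted; diseases left with no gene in the universe are dropped with a
#' logged count. Pairs with zero overlap (y = 0, p = 1 always) are not
#' reported but still count toward the correction family. The family is
#' per-lncRNA by default (all eligible diseases tested against one lncRNA's
#' gene set), since many disease gene sets are tested against the same
#' co-expressed set; \code{family = "global"} pools every test instead.
#'
#' @param network co-expression edge data.frame from
#'   [buildCoexpressionNetwork()] (columns \code{lncrna_id},
#'   \code{gene_id}); must be nonempty.
#' @param gd a \linkS4class{GeneDiseaseMap}.
#' @param universe character vector of gene IDs defining the universe —
#'   normally \code{entityIds()} of the gene expression matrix.
#' @param universeSize optional override of M (otherwise
#'   \code{length(universe)}), for replication against a stated universe.
#' @param fdrCutoff FDR significance cutoff in [0, 1]; default 0.05.
#' @param family \code{"per_lncrna"} (default) or \code{"global"}.
#' @return data.frame with columns \code{lncrna_id}, \code{disease_id},
#'   \code{n}, \code{x}, \code{y}, \code{p_raw}, \code{p_bonferroni},
#'   \code{q_fdr}, sorted ascending by \code{q_fdr}, ties broken by
#'   \code{p_raw} then (lncRNA ID, disease ID). Attributes \code{n_tests}
#'   (reported tests, y >= 1), \code{family_size} and \code{universe_size}
#'   record the run.
#' @export
enrichDiseases <- function(network, gd, universe, universeSize = NULL,
                           fdrCutoff = 0.05,
                           family = c("per_lncrna", "global")) {
  family <- match.arg(family)
  stopifnot(methods::is(gd, "GeneDiseaseMap"))
  if (fdrCutoff < 0 || fdrCutoff > 1) stop("fdrCutoff must be in [0, 1]")
  if (is.null(network) || nrow(network) == 0L)
    stop("co-expression network is empty")
  universe <- unique(as.character(universe))
  M <- universeSize %||% length(universe)
  if (!.isCount(M) || M < length(universe))
    stop("universeSize must be an integer >= the number of universe genes")

  coexpr <- lapply(split(network$gene_id, network$lncrna_id),
                   function(g) intersect(unique(g), universe))
  coexpr <- coexpr[lengths(coexpr) > 0L]
  dsets <- lapply(diseaseGenes(gd), function(g) intersect(g, universe))
  nDropped <- sum(lengths(dsets) == 0L)
  if (nDropped > 0)
    .logInfo("enrichDiseases: dropped %d disease(s) with no gene in the universe",
             nDropped)
  dsets <- dsets[lengths(dsets) > 0L]
  if (!length(coexpr) || !length(dsets))
    stop("no lncRNA gene set or no disease gene set overlaps the universe")
  nDis <- length(dsets)
  xs <- lengths(dsets)
  if (any(xs > M) || any(lengths(coexpr) > M))
    stop("universe smaller than a gene set; check universeSize")

  rows <- vector("list", length(coexpr))
  for (i in seq_along(coexpr)) {
    gset <- coexpr[[i]]
    n <- length(gset)
    ys <- vapply(dsets, function(dg) length(intersect(gset, dg)), 0L)
    hit <- which(ys >= 1L)
    if (!length(hit)) next
    rows[[i]] <- data.frame(
      lncrna_id = names(coexpr)[i],
      disease_id = names(dsets)[hit],
      n = n, x = unname(xs[hit]), y = unname(ys[hit]),
      p_raw = hypergeomTail(M, unname(xs[hit]), n, unname(ys[hit])),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) {
    .logInfo("enrichDiseases: no (lncRNA, disease) pair with overlap >= 1")
    return(.emptyPredictions())
  }
  nTests <- nrow(res)
  if (family == "per_lncrna") {
    famSize <- nDis
    res$p_bonferroni <- bonferroni(res$p_raw, famSize)
    qs <- lapply(split(res$p_raw, res$lncrna_id), bhFdr, m = famSize)
    res$q_fdr <- unsplit(qs, res$lncrna_id)
  } else {
    famSize <- length(coexpr) * nDis
    res$p_bonferroni <- bonferroni(res$p_raw, famSize)
    res$q_fdr <- bhFdr(res$p_raw, m = famSize)
  }
  res <- res[res$q_fdr <= fdrCutoff, , drop = FALSE]
  res <- res[order(res$q_fdr, res$p_raw, res$lncrna_id, res$disease_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  .logInfo("enrichDiseases: %d test(s) with overlap >= 1, %d prediction(s) at FDR <= %.3g (family %s, M = %d)",
           nTests, nrow(res), fdrCutoff, family, M)
  attr(res, "n_tests") <- nTests
  attr(res, "family_size") <- famSize
  attr(res, "universe_size") <- M
  res
}
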