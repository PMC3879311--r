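#' Tissue specificity score (tau)
#'
#' The tau index of a nonnegative expression profile over N >= 2 conditions:
#' \deqn{\tau = \sum_{i=1}^{N} (1 - \hat x_i) / (N - 1),}
#' where \eqn{\hat x_i} is the expression in condition i divided by the
#' maximal expression of the profile. tau = 0 for a constant nonzero profile
#' (ubiquitous expression) and tau = 1 when exactly one condition is
#' expressed (perfect tissue specificity); tau is invariant to positive
#' rescaling of the profile.
#'
#' @param profile numeric vector of finite, nonnegative expression values
#'   over N >= 2 conditions with \code{max(profile) > 0}. All-zero
#'   (degenerate) profiles are a caller error: filter them first with
#'   [filterDegenerate()].
#' @return tau, a single value in [0, 1].
#' @examples
#' tauScore(c(5, 5, 5, 5))   # 0: uniform
#' tauScore(c(7, 0, 0))      # 1: single expressed tissue
#' tauScore(c(10, 5, 0))     # 0.75
#' @export
tauScore <- function(profile) {
  if (!is.numeric(profile) || length(profile) < 2L)
    stop("tau requires a numeric profile over at least 2 conditions")
  if (anyNA(profile) || any(!is.finite(profile)) || any(profile < 0))
    stop("tau requires finite nonnegative expression values")
  mx <- max(profile)
  if (mx <= 0)
    stop("tau is undefined for an all-zero profile; filter degenerate rows first")
  sum(1 - profile / mx) / (length(profile) - 1L)
}

#' Conditions attaining the maximal expression of a profile
#'
#' Returns every condition label whose expression equals the profile maximum,
#' in matrix column order. Ties are meaningful: an lncRNA peaking in two or
#' more tissues simultaneously is linked to each of them downstream. Peak
#' detection uses exact equality of the stored values by default (source
#' scores are integers on UCSC 0-1000 tracks); \code{tol} adds a relative
#' tolerance for floating-point inputs.
#'
#' @param profile numeric vector with \code{max(profile) > 0}.
#' @param labels condition labels, same length as \code{profile}.
#' @param tol relative tolerance: values >= max * (1 - tol) count as peaks.
#'   Default 0 (exact equality).
#' @return nonempty character vector of peak condition labels.
#' @examples
#' peakTissues(c(3, 9, 9, 1), c("A", "B", "C", "D"))  # "B" "C"
#' @export
peakTissues <- function(profile, labels, tol = 0) {
  stopifnot(length(profile) == length(labels))
  mx <- max(profile)
  if (mx <= 0)
    stop("peak tissues are undefined for an all-zero profile")
  labels[profile >= mx * (1 - tol)]
}

#' Partition lncRNAs into tissue-specific and non-tissue-specific sets
#'
#' Scores every row of an expression matrix with [tauScore()] and splits at
#' a cutoff. The boundary is inclusive: tau >= cutoff is tissue-specific
#' (so the documented score 0.8 itself counts as specific). Tissue-specific
#' records carry their peak tissues ([peakTissues()]); the two outputs
#' partition the input rows exactly.
#'
#' @param x an \linkS4class{ExpressionMatrix} with degenerate (all-zero)
#'   rows already removed (see [filterDegenerate()]).
#' @param cutoff tau cutoff in [0, 1]; default 0.8.
#' @param tol relative peak-detection tolerance passed to [peakTissues()].
#' @return list with components \code{specific} and \code{nonspecific}, each
#'   an \link[S4Vectors]{DataFrame} with columns \code{lncrna_id},
#'   \code{tau}, \code{is_tissue_specific} and \code{peak_tissues} (a
#'   \link[IRanges]{CharacterList}; populated only for specific records).
#' @examples
#' m <- ExpressionMatrix(matrix(c(9, 1, 0, 5, 0, 5), 2, 3, byrow = TRUE,
#'        dimnames = list(c("a", "b"), c("t1", "t2", "t3"))))
#' partitionBySpecificity(m)
#' @export
partitionBySpecificity <- function(x, cutoff = 0.8, tol = 0) {
  stopifnot(methods::is(x, "ExpressionMatrix"))
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]")
  v <- expressionValues(x)
  taus <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) {
    taus[i] <- tryCatch(tauScore(v[i, ]), error = function(e)
      stop(sprintf("lncRNA '%s': %s", rownames(v)[i], conditionMessage(e)),
           call. = FALSE))
  }
  specific <- taus >= cutoff
  peaks <- vector("list", nrow(v))
  peaks[specific] <- lapply(which(specific), function(i)
    peakTissues(v[i, ], colnames(v), tol = tol))
  peaks[!specific] <- list(character(0))
  rec <- S4Vectors::DataFrame(
    lncrna_id = rownames(v),
    tau = taus,
    is_tissue_specific = specific,
    peak_tissues = IRanges::CharacterList(peaks))
  .logInfo("partitionBySpecificity: %d tissue-specific, %d non-tissue-specific (cutoff %.3g)",
           sum(specific), sum(!specific), cutoff)
  list(specific = rec[specific, ], nonspecific = rec[!specific, ])
}

#' Map tissue-specific lncRNAs to tissue-related disease classes
#'
#' For each tissue-specific lncRNA, the tissue(s) of maximal expression name
#' the disease class it is linked to: one prediction per (lncRNA, peak
#' tissue), so an lncRNA peaking in k tissues yields k predictions. The
#' default class label is \code{"<tissue>-related diseases"}; a user-supplied
#' two-column mapping table (tissue, disease_class) overrides it. A peak
#' tissue absent from a supplied mapping falls back to the default label
#' with a warning.
#'
#' @param specific \link[S4Vectors]{DataFrame} of tissue-specific records
#'   from [partitionBySpecificity()] (must carry \code{peak_tissues}).
#' @param tissueDiseaseMap optional data.frame whose first two columns are
#'   tissue label and disease-class label.
#' @return data.frame with columns \code{lncrna_id}, \code{peak_tissue},
#'   \code{disease_class}.
#' @examples
#' m <- ExpressionMatrix(matrix(c(9, 1, 0, 0, 0, 8), 2, 3, byrow = TRUE,
#'        dimnames = list(c("a", "b"), c("lung", "brain", "ovary"))))
#' part <- partitionBySpecificity(m)
#' mapTissueDiseases(part$specific)
#' @export
mapTissueDiseases <- function(specific, tissueDiseaseMap = NULL) {
  stopifnot(!is.null(specific$peak_tissues))
  lut <- NULL
  if (!is.null(tissueDiseaseMap)) {
    lut <- stats::setNames(as.character(tissueDiseaseMap[[2L]]),
                           normalizeConditionLabels(tissueDiseaseMap[[1L]]))
  }
  npeaks <- lengths(specific$peak_tissues)
  if (any(npeaks == 0L))
    stop("every tissue-specific record must have at least one peak tissue")
  ids <- rep(specific$lncrna_id, npeaks)
  tissues <- unlist(as.list(specific$peak_tissues), use.names = FALSE)
  classes <- sprintf("%s-related diseases", tissues)
  if (!is.null(lut)) {
    hit <- tissues %in% names(lut)
    classes[hit] <- unname(lut[tissues[hit]])
    if (any(!hit))
      warning(sprintf("tissue(s) absent from the mapping table, using default labels: %s",
                      paste(unique(tissues[!hit]), collapse = ", ")))
  }
  data.frame(lncrna_id = ids, peak_tissue = tissues,
             disease_class = classes, stringsAsFactors = FALSE)
}
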