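#' Harmonize predicted and known association spaces
#'
#' Restricts a prediction table and a known association set to the lncRNAs
#' and diseases present in both, so that ranks, positives and negatives are
#' all drawn from one candidate space. Prediction order is preserved.
#'
#' @param predictions enrichment prediction data.frame (sorted per the
#'   [enrichDiseases()] contract).
#' @param known an \linkS4class{AssociationSet} of known (experimentally
#'   verified) lncRNA-disease pairs, or an equivalent two-column data.frame.
#' @return list with components \code{predictions} (restricted, order
#'   preserved), \code{known} (restricted data.frame), \code{lncIds},
#'   \code{diseaseIds} (the common ID sets).
#' @details Hard error when no lncRNA or no disease is shared, with
#'   diagnostic counts for both sides.
#' @export
harmonize <- function(predictions, known) {
  kp <- if (methods::is(known, "AssociationSet")) associationPairs(known)
        else data.frame(lncrna_id = as.character(known[[1L]]),
                        disease_id = as.character(known[[2L]]),
                        stringsAsFactors = FALSE)
  if (nrow(predictions) == 0L || nrow(kp) == 0L)
    stop("harmonize needs nonempty predictions and known associations")
  lncIds <- intersect(unique(predictions$lncrna_id), unique(kp$lncrna_id))
  disIds <- intersect(unique(predictions$disease_id), unique(kp$disease_id))
  if (!length(lncIds) || !length(disIds))
    stop(sprintf(paste0("no common association space: %d/%d shared lncRNAs, ",
                        "%d/%d shared diseases (predicted/known sides: ",
                        "%d and %d lncRNAs, %d and %d diseases)"),
                 length(lncIds), length(lncIds),
                 length(disIds), length(disIds),
                 length(unique(predictions$lncrna_id)),
                 length(unique(kp$lncrna_id)),
                 length(unique(predictions$disease_id)),
                 length(unique(kp$disease_id))))
  predKeep <- predictions$lncrna_id %in% lncIds &
    predictions$disease_id %in% disIds
  knownKeep <- kp$lncrna_id %in% lncIds & kp$disease_id %in% disIds
  pred <- predictions[predKeep, , drop = FALSE]
  kp <- kp[knownKeep, , drop = FALSE]
  rownames(pred) <- rownames(kp) <- NULL
  .logInfo("harmonize: %d lncRNA(s), %d disease(s); %d prediction(s), %d known pair(s) in the common space",
           length(lncIds), length(disIds), nrow(pred), nrow(kp))
  list(predictions = pred, known = kp, lncIds = lncIds, diseaseIds = disIds)
}

#' Rank candidate pairs against an ordered prediction list
#'
#' Rank 1 is the most significant prediction. Candidate pairs absent from
#' the prediction list all share the worst rank, one past the list length
#' (excluding them would leave the false positive rate undefined beyond the
#' list). With an empty prediction list every candidate gets the degenerate
#' rank 1 (logged).
#'
#' @param predictions prediction data.frame sorted ascending by q_fdr per
#'   the [enrichDiseases()] contract (its deterministic tie-break order is
#'   the rank order for tied FDR values).
#' @param candidates data.frame of candidate pairs with columns
#'   \code{lncrna_id}, \code{disease_id}.
#' @return the \code{candidates} data.frame with an integer \code{rank}
#'   column appended.
#' @export
rankTable <- function(predictions, candidates) {
  stopifnot(all(c("lncrna_id", "disease_id") %in% colnames(candidates)))
  if (nrow(predictions) == 0L) {
    .logInfo("rankTable: empty prediction list; all candidates share rank 1")
    candidates$rank <- 1L
    return(candidates)
  }
  pos <- match(.pairKey(candidates$lncrna_id, candidates$disease_id),
               .pairKey(predictions$lncrna_id, predictions$disease_id))
  candidates$rank <- ifelse(is.na(pos), nrow(predictions) + 1L, pos)
  candidates
}

#' ROC curve and AUC from a rank-threshold sweep
#'
#' Sweeps the rank threshold t over all distinct ranks; at each t a pair is
#' called positive when its rank <= t (smaller rank = stronger prediction),
#' giving TPR over the known (positive) pairs and FPR over the remaining
#' candidate (negative) pairs. AUC is the trapezoidal area, which equals the
#' tie-corrected Mann-Whitney statistic: a positive tied with a negative
#' counts 1/2.
#'
#' @param positiveRanks integer ranks of the known pairs; nonempty.
#' @param negativeRanks integer ranks of all other candidate pairs; nonempty.
#' @return a \linkS4class{RocCurve}.
#' @examples
#' rocAuc(c(1, 3), c(2, 4))   # AUC 0.75
#' @export
rocAuc <- function(positiveRanks, negativeRanks) {
  if (!length(positiveRanks) || !length(negativeRanks))
    stop("ROC needs at least one positive and one negative rank")
  th <- sort(unique(c(positiveRanks, negativeRanks)))
  tpr <- vapply(th, function(t) mean(positiveRanks <= t), 0)
  fpr <- vapply(th, function(t) mean(negativeRanks <= t), 0)
  pts <- data.frame(threshold = c(0, th), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1L) +
                                utils::tail(pts$tpr, -1L)) / 2)
  methods::new("RocCurve", points = pts, auc = auc)
}

#' Leave-one-out rank validation of predictions against known associations
#'
#' Each known lncRNA-disease association is held out and scored by its rank
#' in the prediction list; sweeping a rank threshold yields an ROC curve
#' whose area summarizes recovery of the known associations. Because the
#' method never uses known lncRNA-disease pairs to make predictions, the
#' prediction list is identical in every fold, and LOOCV reduces to ranking
#' each known pair once in the fixed list; \code{literal = TRUE} runs the
#' explicit one-fold-per-pair loop anyway (identical output, kept for
#' fidelity). Negatives are all harmonized candidate pairs (the full lncRNA
#' x disease grid over the common ID sets) not in the known set.
#'
#' @param predictions enrichment prediction data.frame.
#' @param known an \linkS4class{AssociationSet} (or two-column data.frame)
#'   of known associations.
#' @param literal run the explicit leave-one-out loop instead of the
#'   single-pass reduction; default \code{FALSE}.
#' @return a \linkS4class{RocCurve}.
#' @export
loocv <- function(predictions, known, literal = FALSE) {
  h <- harmonize(predictions, known)
  candidates <- expand.grid(lncrna_id = h$lncIds, disease_id = h$diseaseIds,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ranked <- rankTable(h$predictions, candidates)
  isPos <- .pairKey(ranked$lncrna_id, ranked$disease_id) %in%
    .pairKey(h$known$lncrna_id, h$known$disease_id)
  if (literal) {
    # one fold per known pair: rank the held-out pair in the (fixed) list
    posRanks <- vapply(seq_len(nrow(h$known)), function(i) {
      rankTable(h$predictions, h$known[i, , drop = FALSE])$rank
    }, 0L)
  } else {
    posRanks <- ranked$rank[isPos]
  }
  rocAuc(posRanks, ranked$rank[!isPos])
}

#' Overlap accuracy of predictions against known associations
#'
#' Counts the predicted pairs that can be checked against the known set —
#' those whose lncRNA has at least one known association — and the fraction
#' of them that are themselves known pairs.
#'
#' @param predictions enrichment prediction data.frame.
#' @param known an \linkS4class{AssociationSet} (or two-column data.frame).
#' @return list with components \code{verified} (predicted pairs found in
#'   the known set), \code{verifiable} (predicted pairs whose lncRNA occurs
#'   in the known set) and \code{fraction} (verified/verifiable;
#'   \code{NA} with a warning when nothing is verifiable).
#' @export
overlapAccuracy <- function(predictions, known) {
  kp <- if (methods::is(known, "AssociationSet")) associationPairs(known)
        else data.frame(lncrna_id = as.character(known[[1L]]),
                        disease_id = as.character(known[[2L]]),
                        stringsAsFactors = FALSE)
  verifiable <- predictions$lncrna_id %in% unique(kp$lncrna_id)
  verified <- verifiable &
    .pairKey(predictions$lncrna_id, predictions$disease_id) %in%
    .pairKey(kp$lncrna_id, kp$disease_id)
  nVerifiable <- sum(verifiable)
  nVerified <- sum(verified)
  frac <- if (nVerifiable == 0L) {
    warning("no predicted pair is verifiable against the known set")
    NA_real_
  } else nVerified / nVerifiable
  list(verified = nVerified, verifiable = nVerifiable, fraction = frac)
}
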