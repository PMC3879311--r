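#' Configuration for the synthetic benchmark generator
#'
#' Collects and validates the parameters of [generateSynthetic()]. The
#' defaults define the package's standing benchmark: a desk-scale analogue
#' of the real data shapes (an lncRNA score matrix and a larger gene atlas
#' sharing a subset of condition labels) with block-structured co-expression
#' and disease gene sets concentrated in blocks, so the planted
#' lncRNA-disease truth is recoverable by the pipeline.
#'
#' @param n_lnc,n_genes entity counts (default 50 lncRNAs, 300 genes).
#' @param n_cond_lnc,n_cond_genes,n_common condition counts for the lncRNA
#'   matrix, the gene matrix, and their shared subset (defaults 12, 20, 8;
#'   \code{n_common} must be >= 5 and <= both totals).
#' @param n_blocks number of co-expression blocks (default 5).
#' @param n_diseases number of diseases (default 10; assigned to blocks
#'   round-robin).
#' @param frac_specific fraction of lncRNAs made tissue-specific
#'   (single-peak) rather than block-correlated; default 0.2 — a minority,
#'   as in real lncRNA catalogues restricted to informative profiles.
#' @param block_noise_sd standard deviation of the log-scale noise around
#'   each block's latent signal; default 0.2 (moderate: same-block pairs
#'   usually, not always, exceed the 0.7 rho cutoff on 8 conditions).
#' @param bg_genes_per_disease,block_genes_per_disease composition of each
#'   disease gene set: genes drawn uniformly from all genes vs from the
#'   disease's block (defaults 5 and 15). \code{block_genes_per_disease = 0}
#'   gives the null world with no planted signal.
#' @param n_degenerate_zero,n_degenerate_saturated all-zero / all-saturation
#'   lncRNA rows injected to exercise [filterDegenerate()] (defaults 2, 2).
#' @param saturation_value saturation score; rows are scaled to
#'   [0, saturation_value] and rounded to integers, mimicking UCSC score
#'   tracks (default 1000).
#' @param seed integer seed; all randomness flows from it.
#' @return a validated list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(n_lnc = 50, n_genes = 300,
                            n_cond_lnc = 12, n_cond_genes = 20,
                            n_common = 8, n_blocks = 5, n_diseases = 10,
                            frac_specific = 0.2, block_noise_sd = 0.2,
                            bg_genes_per_disease = 5,
                            block_genes_per_disease = 15,
                            n_degenerate_zero = 2,
                            n_degenerate_saturated = 2,
                            saturation_value = 1000, seed = 1) {
  cfg <- list(n_lnc = n_lnc, n_genes = n_genes, n_cond_lnc = n_cond_lnc,
              n_cond_genes = n_cond_genes, n_common = n_common,
              n_blocks = n_blocks, n_diseases = n_diseases,
              frac_specific = frac_specific,
              block_noise_sd = block_noise_sd,
              bg_genes_per_disease = bg_genes_per_disease,
              block_genes_per_disease = block_genes_per_disease,
              n_degenerate_zero = n_degenerate_zero,
              n_degenerate_saturated = n_degenerate_saturated,
              saturation_value = saturation_value, seed = seed)
  counts <- c("n_lnc", "n_genes", "n_cond_lnc", "n_cond_genes", "n_common",
              "n_blocks", "n_diseases", "bg_genes_per_disease",
              "block_genes_per_disease", "n_degenerate_zero",
              "n_degenerate_saturated")
  for (nm in counts)
    if (!.isCount(cfg[[nm]]))
      stop(sprintf("%s must be a nonnegative integer", nm))
  if (n_lnc < 1 || n_genes < 1 || n_blocks < 1 || n_diseases < 1)
    stop("n_lnc, n_genes, n_blocks, n_diseases must be positive")
  if (n_common < 5)
    stop("n_common must be >= 5 (rank correlation needs enough conditions)")
  if (n_common > n_cond_lnc || n_common > n_cond_genes)
    stop("n_common cannot exceed either matrix's condition count")
  if (frac_specific < 0 || frac_specific > 1)
    stop("frac_specific must be in [0, 1]")
  if (block_noise_sd < 0) stop("block_noise_sd must be >= 0")
  if (bg_genes_per_disease + block_genes_per_disease < 1)
    stop("each disease needs at least one gene")
  if (saturation_value <= 0) stop("saturation_value must be positive")
  if (!.isCount(abs(seed))) stop("seed must be an integer")
  structure(cfg, class = "SyntheticConfig")
}

# Scale a positive row to [0, saturation] and round to integers (UCSC-style
# scores); the transform is monotone, so within-row ranks are preserved up
# to rounding ties.
.scaleToScore <- function(v, saturation) {
  round(v / max(v) * saturation)
}

#' Generate a seeded synthetic benchmark with planted truth
#'
#' Builds the inputs the pipeline consumes — an lncRNA expression matrix, a
#' gene expression matrix sharing a subset of condition labels, and a
#' gene-disease map — plus the planted ground truth, deterministically from
#' the config seed. Construction:
#' \enumerate{
#'   \item a latent positive signal is drawn per (block, shared condition);
#'   \item non-tissue-specific lncRNAs and all genes take a random monotone
#'     transform (power and scale) of their block's latent signal times
#'     log-normal noise on the shared conditions, and independent noise on
#'     their private conditions — so Spearman, not Pearson, is the right
#'     detector;
#'   \item a \code{frac_specific} subset of lncRNAs instead get near-zero
#'     expression except one peak condition (tau close to 1);
#'   \item each disease draws \code{block_genes_per_disease} genes from one
#'     block and \code{bg_genes_per_disease} uniformly;
#'   \item the truth pairs each non-specific lncRNA with the diseases of its
#'     block; all-zero and all-saturation rows are appended to exercise the
#'     degenerate filter (their IDs are reported for exact-count tests).
#' }
#' Rows are scaled to [0, saturation] and rounded to integers.
#'
#' @param config a \code{SyntheticConfig} from [syntheticConfig()].
#' @return list with components \code{lnc}, \code{genes}
#'   (\linkS4class{ExpressionMatrix}), \code{geneDisease}
#'   (\linkS4class{GeneDiseaseMap}) and \code{truth}, itself a list:
#'   \code{trueLncDisease} (\linkS4class{AssociationSet}),
#'   \code{trueSpecific} (named vector lncRNA -> peak condition),
#'   \code{blockAssignment} (named vector entity -> block),
#'   \code{degenerateZeroIds}, \code{degenerateSaturatedIds}.
#' @examples
#' sim <- generateSynthetic(syntheticConfig(seed = 7))
#' dim(sim$lnc)
#' sim$truth$trueLncDisease
#' @export
generateSynthetic <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  .withSeed(config$seed, {
    sat <- config$saturation_value
    condCommon <- sprintf("shared%02d", seq_len(config$n_common))
    condLnc <- c(condCommon,
                 sprintf("lnconly%02d",
                         seq_len(config$n_cond_lnc - config$n_common)))
    condGene <- c(condCommon,
                  sprintf("geneonly%02d",
                          seq_len(config$n_cond_genes - config$n_common)))
    # Latent block signal with bounded dynamic range (log-sd 0.6): block
    # entities must look ubiquitously expressed (tau < 0.8), since they
    # model the non-tissue-specific population.
    latent <- matrix(exp(stats::rnorm(config$n_blocks * config$n_common,
                                      sd = 0.6)),
                     config$n_blocks, config$n_common)

    blockRow <- function(block, nPrivate) {
      pw <- stats::runif(1, 1.0, 1.4)
      sc <- stats::runif(1, 0.5, 2)
      common <- sc * latent[block, ]^pw *
        exp(stats::rnorm(config$n_common, sd = config$block_noise_sd))
      c(common, exp(stats::rnorm(nPrivate, sd = 0.6)))
    }

    nSpec <- round(config$frac_specific * config$n_lnc)
    nNonspec <- config$n_lnc - nSpec
    lncIds <- sprintf("lnc%03d", seq_len(config$n_lnc))
    specIds <- if (nSpec) lncIds[seq_len(nSpec)] else character(0)
    nonspecIds <- lncIds[setdiff(seq_len(config$n_lnc), seq_len(nSpec))]
    lncBlocks <- stats::setNames(rep_len(seq_len(config$n_blocks),
                                         max(nNonspec, 1L))[seq_len(nNonspec)],
                                 nonspecIds)

    nPrivLnc <- config$n_cond_lnc - config$n_common
    L <- matrix(0, config$n_lnc, config$n_cond_lnc,
                dimnames = list(lncIds, condLnc))
    specPeaks <- stats::setNames(sample(condLnc, nSpec, replace = TRUE),
                                 specIds)
    for (id in specIds) {
      # near-zero background, saturated peak: tau close to 1 by construction
      row <- sample(0:round(0.02 * sat), config$n_cond_lnc, replace = TRUE)
      row[match(specPeaks[[id]], condLnc)] <- sat
      L[id, ] <- row
    }
    for (id in nonspecIds)
      L[id, ] <- .scaleToScore(blockRow(lncBlocks[[id]], nPrivLnc), sat)

    geneIds <- sprintf("gene%04d", seq_len(config$n_genes))
    geneBlocks <- stats::setNames(rep_len(seq_len(config$n_blocks),
                                          config$n_genes), geneIds)
    nPrivGene <- config$n_cond_genes - config$n_common
    G <- matrix(0, config$n_genes, config$n_cond_genes,
                dimnames = list(geneIds, condGene))
    for (id in geneIds)
      G[id, ] <- .scaleToScore(blockRow(geneBlocks[[id]], nPrivGene), sat)

    degZero <- degSat <- character(0)
    if (config$n_degenerate_zero > 0) {
      degZero <- sprintf("lnc_deg_zero%02d",
                         seq_len(config$n_degenerate_zero))
      L <- rbind(L, matrix(0, config$n_degenerate_zero, config$n_cond_lnc,
                           dimnames = list(degZero, condLnc)))
    }
    if (config$n_degenerate_saturated > 0) {
      degSat <- sprintf("lnc_deg_sat%02d",
                        seq_len(config$n_degenerate_saturated))
      L <- rbind(L, matrix(sat, config$n_degenerate_saturated,
                           config$n_cond_lnc,
                           dimnames = list(degSat, condLnc)))
    }

    disIds <- sprintf("D%02d", seq_len(config$n_diseases))
    disBlocks <- stats::setNames(rep_len(seq_len(config$n_blocks),
                                         config$n_diseases), disIds)
    gdRows <- list()
    for (d in disIds) {
      blockGenes <- geneIds[geneBlocks == disBlocks[[d]]]
      gset <- character(0)
      if (config$block_genes_per_disease > 0)
        gset <- sample(blockGenes,
                       min(config$block_genes_per_disease,
                           length(blockGenes)))
      if (config$bg_genes_per_disease > 0)
        gset <- union(gset, sample(geneIds, config$bg_genes_per_disease))
      gdRows[[d]] <- data.frame(gene_id = gset, disease_id = d,
                                stringsAsFactors = FALSE)
    }
    gd <- GeneDiseaseMap(do.call(rbind, gdRows))

    truthPairs <- do.call(rbind, lapply(nonspecIds, function(id) {
      ds <- disIds[disBlocks == lncBlocks[[id]]]
      if (!length(ds)) return(NULL)
      data.frame(lncrna_id = id, disease_id = ds, stringsAsFactors = FALSE)
    }))
    if (is.null(truthPairs))
      truthPairs <- data.frame(lncrna_id = character(0),
                               disease_id = character(0))

    list(lnc = ExpressionMatrix(L, saturationValue = sat),
         genes = ExpressionMatrix(G, saturationValue = sat),
         geneDisease = gd,
         truth = list(
           trueLncDisease = AssociationSet(truthPairs),
           trueSpecific = specPeaks,
           blockAssignment = c(lncBlocks, geneBlocks),
           degenerateZeroIds = degZero,
           degenerateSaturatedIds = degSat))
  })
}
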