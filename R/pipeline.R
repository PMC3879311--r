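#' Pipeline configuration
#'
#' Validates and collects everything [runPipeline()] needs: the three input
#' tables (as file paths or in-memory objects) and the framework's cutoffs —
#' tau 0.8 for the tissue-specificity partition, Spearman rho 0.7 for
#' co-expression, FDR 0.05 for enrichment significance.
#'
#' @param lnc lncRNA expression input: a TSV path or an
#'   \linkS4class{ExpressionMatrix}.
#' @param genes gene expression input: a TSV path or an
#'   \linkS4class{ExpressionMatrix}.
#' @param geneDisease gene-disease input: a two-column TSV path or a
#'   \linkS4class{GeneDiseaseMap}.
#' @param tissueDiseaseMap optional tissue -> disease-class mapping: a
#'   two-column TSV path or data.frame.
#' @param lncLayout layout of the lncRNA TSV (\code{"plain"} or
#'   \code{"bedlike"}); ignored for in-memory input.
#' @param tauCutoff tau partition cutoff in [0, 1]; default 0.8.
#' @param rhoCutoff Spearman cutoff in [-1, 1]; default 0.7.
#' @param fdrCutoff FDR significance cutoff in [0, 1]; default 0.05.
#' @param saturationValue saturation score for the degenerate filter;
#'   default 1000.
#' @param minCommon minimum shared conditions for correlation; default 5.
#' @param family multiple-testing family, \code{"per_lncrna"} or
#'   \code{"global"}.
#' @param universeSize optional override of the enrichment universe size
#'   (otherwise the gene matrix's row count).
#' @param outDir optional output directory; when set, [runPipeline()] writes
#'   \code{tissue_predictions.tsv}, \code{predictions.tsv} and
#'   \code{report.txt} there.
#' @return a validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(lnc, genes, geneDisease, tissueDiseaseMap = NULL,
                           lncLayout = c("plain", "bedlike"),
                           tauCutoff = 0.8, rhoCutoff = 0.7,
                           fdrCutoff = 0.05, saturationValue = 1000,
                           minCommon = 5,
                           family = c("per_lncrna", "global"),
                           universeSize = NULL, outDir = NULL) {
  if (tauCutoff < 0 || tauCutoff > 1) stop("tauCutoff must be in [0, 1]")
  if (rhoCutoff < -1 || rhoCutoff > 1) stop("rhoCutoff must be in [-1, 1]")
  if (fdrCutoff < 0 || fdrCutoff > 1) stop("fdrCutoff must be in [0, 1]")
  if (!is.null(saturationValue) && saturationValue <= 0)
    stop("saturationValue must be positive")
  if (!.isCount(minCommon) || minCommon < 2)
    stop("minCommon must be an integer >= 2")
  structure(list(lnc = lnc, genes = genes, geneDisease = geneDisease,
                 tissueDiseaseMap = tissueDiseaseMap,
                 lncLayout = match.arg(lncLayout),
                 tauCutoff = tauCutoff, rhoCutoff = rhoCutoff,
                 fdrCutoff = fdrCutoff, saturationValue = saturationValue,
                 minCommon = minCommon, family = match.arg(family),
                 universeSize = universeSize, outDir = outDir),
            class = "PipelineConfig")
}

# Run a pipeline stage, prefixing any error with the stage name.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full lncRNA-disease inference pipeline
#'
#' Executes the four-step framework end to end: (1) degenerate-profile
#' filtering and tau scoring partition the lncRNAs at the tau cutoff;
#' (2) tissue-specific lncRNAs are mapped to tissue-related disease classes
#' via their peak tissues; (3) non-tissue-specific lncRNAs get a
#' co-expressed gene set by Spearman correlation against the gene matrix
#' over their shared conditions; (4) each co-expressed set is tested for
#' disease gene-set enrichment by the hypergeometric upper tail, corrected
#' (Bonferroni, BH-FDR), filtered at the FDR cutoff and sorted ascending by
#' FDR. Every filter count is logged and returned in the report; the run is
#' fully deterministic (no randomness), so identical inputs and config give
#' byte-identical outputs.
#'
#' @param config a \code{PipelineConfig} from [pipelineConfig()].
#' @return list with components \code{tissuePredictions} (data.frame:
#'   \code{lncrna_id}, \code{peak_tissue}, \code{disease_class}),
#'   \code{predictions} (enrichment data.frame per [enrichDiseases()]),
#'   \code{network} (co-expression edges) and \code{report} (named list of
#'   run counts: lncRNAs read, degenerate rows removed, specific /
#'   non-specific counts, edge count, tests performed, predictions at the
#'   FDR cutoff, universe size).
#' @examples
#' sim <- generateSynthetic(syntheticConfig(seed = 1))
#' res <- runPipeline(pipelineConfig(sim$lnc, sim$genes, sim$geneDisease))
#' res$report
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  lnc <- .stage("read_lnc", {
    if (methods::is(config$lnc, "ExpressionMatrix")) config$lnc
    else readExpressionTable(config$lnc, layout = config$lncLayout,
                             saturationValue = config$saturationValue)
  })
  genes <- .stage("read_genes", {
    if (methods::is(config$genes, "ExpressionMatrix")) config$genes
    else readExpressionTable(config$genes)
  })
  gd <- .stage("read_gene_disease", {
    if (methods::is(config$geneDisease, "GeneDiseaseMap")) config$geneDisease
    else readGeneDiseaseTable(config$geneDisease)
  })
  tdMap <- .stage("read_tissue_disease_map", {
    if (is.null(config$tissueDiseaseMap) ||
        is.data.frame(config$tissueDiseaseMap)) config$tissueDiseaseMap
    else utils::read.delim(config$tissueDiseaseMap, header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  })

  nRead <- nrow(lnc)
  filt <- .stage("filter_degenerate",
                 filterDegenerate(lnc, config$saturationValue))
  if (is.null(filt$kept))
    stop("pipeline stage 'filter_degenerate' failed: every lncRNA row is degenerate")

  part <- .stage("partition",
                 partitionBySpecificity(filt$kept, config$tauCutoff))
  tissuePred <- .stage("map_tissue_diseases", {
    if (nrow(part$specific))
      mapTissueDiseases(part$specific, tdMap)
    else data.frame(lncrna_id = character(0), peak_tissue = character(0),
                    disease_class = character(0), stringsAsFactors = FALSE)
  })

  if (nrow(part$nonspecific)) {
    nonspec <- filt$kept[part$nonspecific$lncrna_id, ]
    network <- .stage("build_network",
                      buildCoexpressionNetwork(nonspec, genes,
                                               cutoff = config$rhoCutoff,
                                               minCommon = config$minCommon))
  } else {
    network <- data.frame(lncrna_id = character(0), gene_id = character(0),
                          rho = numeric(0), p_value = numeric(0),
                          stringsAsFactors = FALSE)
  }
  if (nrow(network)) {
    predictions <- .stage("enrich",
                          enrichDiseases(network, gd,
                                         universe = entityIds(genes),
                                         universeSize = config$universeSize,
                                         fdrCutoff = config$fdrCutoff,
                                         family = config$family))
  } else {
    predictions <- .emptyPredictions()
  }

  report <- list(
    lncrnas_read = nRead,
    degenerate_removed = length(filt$removedIds),
    degenerate_zero = length(filt$removedZeroIds),
    degenerate_saturated = length(filt$removedSaturatedIds),
    tissue_specific = nrow(part$specific),
    non_tissue_specific = nrow(part$nonspecific),
    tissue_predictions = nrow(tissuePred),
    coexpression_edges = nrow(network),
    enrichment_tests = attr(predictions, "n_tests") %||% 0L,
    predictions_at_fdr = nrow(predictions),
    universe_size = attr(predictions, "universe_size") %||% nrow(genes),
    tau_cutoff = config$tauCutoff,
    rho_cutoff = config$rhoCutoff,
    fdr_cutoff = config$fdrCutoff)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tissuePred,
                       file.path(config$outDir, "tissue_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writePredictions(predictions,
                     file.path(config$outDir, "predictions.tsv"))
    writeLines(sprintf("%s: %s", names(report),
                       vapply(report, format, "")),
               file.path(config$outDir, "report.txt"))
  }
  list(tissuePredictions = tissuePred, predictions = predictions,
       network = network, report = report)
}

#' Read a flat key:value configuration file
#'
#' Parses a minimal \code{key: value} file (one pair per line; blank lines
#' and \code{#} comments ignored) — a YAML subset sufficient for pipeline
#' and simulation configs. Values that parse as numbers are returned
#' numeric.
#'
#' @param path path to the config file.
#' @return named list of values.
#' @export
readConfigFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    key <- trimws(m[2L])
    val <- trimws(m[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
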