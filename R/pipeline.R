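#' End-to-end network inference
#'
#' Runs the full pipeline: optional methylation-probe filtering, candidate
#' edge enumeration, prior-matrix construction, two-phase MCMC, edge-weight
#' summarisation, thresholding and CPDAG labelling. When `outDir` is given,
#' also writes the weighted network (TSV/GraphML/SIF), the completed prior
#' matrix, the convergence report, diagnostic plots and a reproducibility
#' manifest.
#'
#' @param ds an [OmicsDataset-class].
#' @param pk optional curated prior-knowledge table
#'   (see [readPriorKnowledge()]).
#' @param tfTargets optional TF->target table or incidence matrix.
#' @param settings an [McmcSettings-class].
#' @param layers a [LayerDefinition-class] (default [layerDefinition()]).
#' @param lmMeth filter methylation probes by regression first?
#' @param rSquaredThres,pValThres probe-filter thresholds.
#' @param betaMax upper bound of the sampled inverse temperature.
#' @param edgeFreqMode,edgeFreqThres thresholding rule for the reported
#'   network (see [thresholdEdges()]).
#' @param minseglen convergence-check minimum segment length (iterations).
#' @param initMode initial structure mode.
#' @param outDir optional output directory.
#' @return a list with elements `network` ([WeightedNetwork-class]),
#'   `weights`, `run` ([McmcRun-class]), `convergence`
#'   ([ConvergenceReport-class]), `methFilter` (or NULL), `candidates`.
#' @export
inferNetwork <- function(ds, pk = NULL, tfTargets = NULL, settings,
                         layers = layerDefinition(ds), lmMeth = TRUE,
                         rSquaredThres = 0.3, pValThres = 0.05,
                         betaMax = 10, edgeFreqMode = "quantile",
                         edgeFreqThres = 0.75, minseglen = NULL,
                         initMode = "pk_seeded", outDir = NULL) {
  mf <- NULL
  if (!is.null(ds@meth) && lmMeth) {
    mf <- filterMethProbes(ds, rSquaredThres, pValThres)
    ds <- mf@dataset
    layers <- layerDefinition(ds, fanInGE = layers@fanInMax[["GE"]])
  }
  if (!is.null(outDir))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cands <- candidateEdges(ds, layers)
  b <- buildPriorMatrix(cands, pk = pk, tfTargets = tfTargets)
  pm <- priorModel(b, beta = settings@betaInit, betaMax = betaMax,
                   sampleBeta = settings@sampleBeta)
  run <- runMcmc(ds, layers, pm, settings, initMode = initMode,
                 candidates = cands,
                 checkpointPath = if (!is.null(outDir))
                   file.path(outDir, "checkpoint.json"))
  w <- edgeWeights(run@trace)
  net <- weightedNetwork(w, cands, layers, mode = edgeFreqMode,
                         value = edgeFreqThres, pk = pk,
                         geneSymbols = ds@geneSymbols)
  if (is.null(minseglen))
    minseglen <- max(1L, (settings@totalIterations - settings@burnIn) %/% 4L)
  conv <- tryCatch(convergenceCheck(run@trace, minseglen),
                   error = function(e) NULL)
  out <- list(network = net, weights = w, run = run, convergence = conv,
              methFilter = mf, candidates = cands)
  if (!is.null(outDir)) .writeRunOutputs(out, ds, layers, settings, outDir)
  out
}

.writeRunOutputs <- function(out, ds, layers, settings, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  exportNetwork(out$network, file.path(outDir, "network.tsv"), "tsv")
  exportNetwork(out$network, file.path(outDir, "network.graphml"), "graphml")
  exportNetwork(out$network, file.path(outDir, "network.sif"), "sif")
  writePriorMatrix(out$run@prior, file.path(outDir, "prior_completed.tsv"))
  utils::write.table(
    data.frame(edge = names(out$weights), weight = unname(out$weights)),
    file.path(outDir, "edge_weights.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(out$convergence))
    writeConvergenceReport(out$convergence,
                           file.path(outDir, "convergence.json"))
  if (!is.null(out$methFilter))
    writeFilterReport(out$methFilter,
                      file.path(outDir, "meth_filter_report.tsv"))
  tracePlot(out$run@trace, file.path(outDir, "trace.png"),
            report = out$convergence)
  networkPlot(out$network, file.path(outDir, "network.png"))
  manifest <- list(
    package = "OmicsBN",
    package_version = as.character(utils::packageVersion("OmicsBN")),
    r_version = R.version.string,
    seed = settings@seed,
    layers = layers@layers,
    fan_in_max = as.list(layers@fanInMax),
    n_samples = nrow(ds@ge),
    n_genes = ncol(ds@ge),
    settings = list(total_iterations = settings@totalIterations,
                    burn_in = settings@burnIn, thin = settings@thin,
                    phase1_fraction = settings@phase1Fraction,
                    sample_beta = settings@sampleBeta,
                    beta_init = settings@betaInit))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Compare an inferred weighted network against a ground truth
#'
#' Precision and recall of the thresholded edge set against the true edges
#' (restricted to the candidate universe the weights were computed over),
#' plus ranking quality: the area under the ROC curve over all candidate
#' edges scored by their posterior weight. When the thresholded network is
#' empty, precision is reported as 1 by convention (stated in the output).
#'
#' @param gt a [GroundTruth-class].
#' @param weights named numeric edge weights (keys "parent->child").
#' @param retained character vector of retained edge keys (e.g. from
#'   [thresholdEdges()]); default: edges with weight > 0.5.
#' @return a list with `precision`, `recall`, `auroc`, `n_candidates`,
#'   `n_true_in_candidates`, `precision_convention`.
#' @export
evaluateNetwork <- function(gt, weights,
                            retained = names(weights)[weights > 0.5]) {
  trueKeys <- .edgeKey(gt@edges$parent, gt@edges$child)
  candKeys <- names(weights)
  labels <- candKeys %in% trueKeys
  if (!any(labels))
    stop("no true edge lies inside the candidate space; feature sets ",
         "probably mismatch", call. = FALSE)
  tp <- sum(retained %in% trueKeys)
  precision <- if (length(retained)) tp / length(retained) else 1
  recall <- tp / sum(labels)
  auroc <- if (all(labels) || !any(labels)) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(response = labels,
                                   predictor = unname(weights),
                                   direction = "<", quiet = TRUE)))
  list(precision = precision, recall = recall, auroc = auroc,
       n_candidates = length(candKeys), n_true_in_candidates = sum(labels),
       precision_convention = if (length(retained)) "observed"
         else "empty network: precision = 1 by convention")
}
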