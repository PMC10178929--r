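#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' Multi-omics dataset
#'
#' Container for sample-aligned continuous omics matrices: gene expression
#' (always present), and optionally copy-number and methylation. All matrices
#' share the same samples in rows, in identical order; features are columns.
#' Methylation probes are tied to genes through the probe annotation.
#'
#' @slot ge numeric matrix, samples x genes.
#' @slot cnv numeric matrix (samples x genes) or `NULL`. Column names must be
#'   a subset of the gene-expression column names.
#' @slot meth numeric matrix (samples x probes) or `NULL`.
#' @slot probeMap data.frame with columns `probe_id`, `gene_id` mapping each
#'   methylation probe to exactly one gene, or `NULL` when `meth` is absent.
#' @slot geneSymbols named character vector mapping gene ids to display
#'   symbols (may be empty).
#' @export
setClass("OmicsDataset",
  representation(
    ge = "matrix",
    cnv = "matrixOrNULL",
    meth = "matrixOrNULL",
    probeMap = "dfOrNULL",
    geneSymbols = "character"
  ),
  prototype(cnv = NULL, meth = NULL, probeMap = NULL,
            geneSymbols = character(0))
)

setValidity("OmicsDataset", function(object) {
  msgs <- character(0)
  ge <- object@ge
  if (!is.numeric(ge)) msgs <- c(msgs, "ge must be a numeric matrix")
  if (is.null(rownames(ge)) || is.null(colnames(ge)))
    msgs <- c(msgs, "ge must have sample rownames and gene colnames")
  if (anyNA(ge)) msgs <- c(msgs, "ge contains missing values")
  if (anyDuplicated(colnames(ge)))
    msgs <- c(msgs, "duplicated gene ids in ge")
  for (mod in c("cnv", "meth")) {
    m <- slot(object, mod)
    if (is.null(m)) next
    if (!is.numeric(m)) msgs <- c(msgs, paste(mod, "must be numeric"))
    if (anyNA(m)) msgs <- c(msgs, paste(mod, "contains missing values"))
    if (!identical(rownames(m), rownames(ge)))
      msgs <- c(msgs, paste(mod, "samples differ from ge samples"))
  }
  if (!is.null(object@cnv) &&
      !all(colnames(object@cnv) %in% colnames(ge)))
    msgs <- c(msgs, "cnv columns must match ge gene ids")
  if (!is.null(object@meth)) {
    if (is.null(object@probeMap))
      msgs <- c(msgs, "meth requires a probe annotation (probeMap)")
    else {
      pm <- object@probeMap
      if (!all(c("probe_id", "gene_id") %in% names(pm)))
        msgs <- c(msgs, "probeMap needs columns probe_id, gene_id")
      else {
        if (anyDuplicated(pm$probe_id))
          msgs <- c(msgs, "probes mapped to more than one gene")
        if (!all(colnames(object@meth) %in% pm$probe_id))
          msgs <- c(msgs, "meth columns missing from probe annotation")
        if (!all(pm$gene_id[match(colnames(object@meth), pm$probe_id)] %in%
                 colnames(ge)))
          msgs <- c(msgs, "probe maps to a gene absent from ge")
      }
    }
    if (any(colnames(object@meth) %in% colnames(ge)))
      msgs <- c(msgs, "probe ids collide with gene ids")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ordered omics layer definition
#'
#' Layers are ordered GE, CNV, METH; each carries a per-layer fan-in limit
#' (maximum number of parents a child may take from that layer). The GE layer
#' is always present; CNV/METH layers only when the matching matrix exists.
#'
#' @slot layers character vector, subset of c("GE","CNV","METH"), GE first.
#' @slot fanInMax named integer vector of per-layer parent limits (>= 1).
#' @export
setClass("LayerDefinition",
  representation(layers = "character", fanInMax = "integer"))

setValidity("LayerDefinition", function(object) {
  msgs <- character(0)
  if (!length(object@layers) || object@layers[1] != "GE")
    msgs <- c(msgs, "GE layer must be present and first")
  if (!all(object@layers %in% c("GE", "CNV", "METH")))
    msgs <- c(msgs, "layers must be among GE, CNV, METH")
  if (!identical(sort(names(object@fanInMax)), sort(object@layers)))
    msgs <- c(msgs, "fanInMax must be named by the layers")
  if (any(object@fanInMax < 1L))
    msgs <- c(msgs, "fan-in limits must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Candidate edge universe
#'
#' The set of directed edges the sampler may ever propose. GE nodes may
#' regulate other GE nodes; a CNV or METH node may only point at the GE node
#' of its own gene (cis effect), never the reverse, and cross-layer nodes
#' take no parents.
#'
#' @slot nodes data.frame with columns `id`, `layer`, `gene` (the owning gene;
#'   equal to `id` for GE nodes).
#' @slot edges data.frame with columns `parent`, `child`, `parentLayer`,
#'   `childLayer`.
#' @export
setClass("CandidateEdgeSet",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("CandidateEdgeSet", function(object) {
  e <- object@edges
  msgs <- character(0)
  if (nrow(e)) {
    if (any(e$parentLayer == "GE" & e$childLayer != "GE"))
      msgs <- c(msgs, "GE -> CNV/METH edges are excluded")
    if (any(e$childLayer != "GE"))
      msgs <- c(msgs, "CNV/METH nodes cannot be children")
    if (any(e$parent == e$child)) msgs <- c(msgs, "self-loops forbidden")
  }
  if (length(msgs)) msgs else TRUE
})

#' Methylation probe filter result
#'
#' Per-probe regression report plus a copy of the dataset with non-retained
#' probes removed. A probe is retained iff its coefficient of determination
#' passes `r_squared >= rSquaredThres` and its slope p-value passes
#' `p_value <= pValThres`.
#'
#' @slot report data.frame: probe_id, gene_id, r_squared, p_value, retained.
#' @slot dataset the filtered [OmicsDataset-class].
#' @slot thresholds numeric, c(r_squared, p_value) thresholds applied.
#' @export
setClass("MethFilterResult",
  representation(report = "data.frame", dataset = "OmicsDataset",
                 thresholds = "numeric"))

#' Biological prior matrix
#'
#' A belief value in \[0,1\] for every candidate edge, with per-edge
#' provenance: `curated` (database-derived present/absent), `tf_target`
#' (transcription-factor/target evidence), `empirical` (estimated from the
#' phase-1 posterior edge frequency) or `default` (no knowledge, 0.5).
#'
#' @slot values named numeric vector keyed "parent->child".
#' @slot provenance named character vector over the same keys.
#' @export
setClass("PriorMatrix",
  representation(values = "numeric", provenance = "character"))

setValidity("PriorMatrix", function(object) {
  msgs <- character(0)
  if (!identical(names(object@values), names(object@provenance)))
    msgs <- c(msgs, "values and provenance must share keys")
  if (any(object@values < 0 | object@values > 1))
    msgs <- c(msgs, "prior beliefs must lie in [0,1]")
  bad <- setdiff(unique(object@provenance),
                 c("curated", "tf_target", "empirical", "default"))
  if (length(bad)) msgs <- c(msgs, paste("unknown provenance:", bad[1]))
  if (length(msgs)) msgs else TRUE
})

#' Energy-based structure prior
#'
#' P(G) is proportional to exp(-beta * E(G)) where the energy E(G) sums, over
#' candidate edges, the absolute mismatch between the prior belief and edge
#' presence. `beta` is the inverse temperature, optionally sampled on
#' \[0, betaMax\].
#'
#' @slot b the [PriorMatrix-class].
#' @slot beta nonnegative inverse temperature.
#' @slot betaMax upper bound for sampled beta.
#' @slot sampleBeta logical; sample beta by Metropolis-Hastings?
#' @export
setClass("PriorModel",
  representation(b = "PriorMatrix", beta = "numeric", betaMax = "numeric",
                 sampleBeta = "logical"))

setValidity("PriorModel", function(object) {
  msgs <- character(0)
  if (object@beta < 0 || object@beta > object@betaMax)
    msgs <- c(msgs, "beta must lie in [0, betaMax]")
  if (object@betaMax <= 0) msgs <- c(msgs, "betaMax must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Layered network structure
#'
#' A DAG over typed nodes, stored as indices into the candidate edge table of
#' its [CandidateEdgeSet-class]. Validity enforces acyclicity and the
#' per-layer fan-in limits.
#'
#' @slot candidates the candidate edge universe.
#' @slot edgeIdx integer indices of present edges (rows of
#'   `candidateEdges(candidates)`).
#' @slot fanInMax named integer vector of per-layer fan-in limits.
#' @export
setClass("NetworkStructure",
  representation(candidates = "CandidateEdgeSet", edgeIdx = "integer",
                 fanInMax = "integer"))

setValidity("NetworkStructure", function(object) {
  e <- object@candidates@edges
  idx <- object@edgeIdx
  msgs <- character(0)
  if (length(idx)) {
    if (any(idx < 1L | idx > nrow(e)))
      return("edge indices outside the candidate table")
    if (anyDuplicated(idx)) msgs <- c(msgs, "duplicated edges")
    sub <- e[idx, , drop = FALSE]
    # acyclicity only involves GE->GE edges; cross-layer parents are roots
    gesub <- sub[sub$parentLayer == "GE", , drop = FALSE]
    if (nrow(gesub) && .hasCycle(gesub$parent, gesub$child))
      msgs <- c(msgs, "structure contains a directed cycle")
    for (ly in names(object@fanInMax)) {
      cnt <- table(sub$child[sub$parentLayer == ly])
      if (length(cnt) && max(cnt) > object@fanInMax[[ly]])
        msgs <- c(msgs, paste("fan-in limit exceeded in layer", ly))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' MCMC sampler settings
#'
#' @slot totalIterations iterations of the final (phase-2) sampling run.
#' @slot burnIn iterations discarded before snapshots are recorded.
#' @slot thin snapshot interval in iterations.
#' @slot seed integer RNG seed driving the whole run.
#' @slot phase1Fraction fraction of `totalIterations` spent in the
#'   empirical-prior adaptation phase (phase 1) before the final run.
#' @slot sampleBeta logical, sample the prior inverse temperature?
#' @slot betaInit initial beta.
#' @export
setClass("McmcSettings",
  representation(totalIterations = "integer", burnIn = "integer",
                 thin = "integer", seed = "integer",
                 phase1Fraction = "numeric", sampleBeta = "logical",
                 betaInit = "numeric"))

setValidity("McmcSettings", function(object) {
  msgs <- character(0)
  if (object@burnIn >= object@totalIterations)
    msgs <- c(msgs, "burnIn must be smaller than totalIterations")
  if (object@thin < 1L) msgs <- c(msgs, "thin must be >= 1")
  if (object@phase1Fraction < 0 || object@phase1Fraction > 1)
    msgs <- c(msgs, "phase1Fraction must lie in [0,1]")
  if (object@betaInit < 0) msgs <- c(msgs, "betaInit must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Posterior trace of sampled structures
#'
#' @slot candidates candidate edge universe the snapshots refer to.
#' @slot snapshots list of integer vectors (candidate-edge indices), one per
#'   retained sample.
#' @slot snapshotIter iteration index of each snapshot.
#' @slot logScore per-iteration total BGe log score.
#' @slot logPrior per-iteration log structure prior (incl. beta term).
#' @slot beta per-iteration inverse temperature.
#' @slot accepted named integer, accepted proposals by move type.
#' @slot proposed named integer, proposals by move type.
#' @slot burnIn,thin,seed the settings used for recording.
#' @export
setClass("PosteriorTrace",
  representation(candidates = "CandidateEdgeSet", snapshots = "list",
                 snapshotIter = "integer", logScore = "numeric",
                 logPrior = "numeric", beta = "numeric",
                 accepted = "integer", proposed = "integer",
                 burnIn = "integer", thin = "integer", seed = "integer"))

#' Result of a two-phase MCMC run
#'
#' @slot trace the phase-2 (final) [PosteriorTrace-class].
#' @slot phase1 the phase-1 (adaptation) trace, or NULL-like empty trace.
#' @slot prior the completed [PriorMatrix-class] used in phase 2.
#' @slot priorInput the prior matrix before empirical completion.
#' @slot settings the [McmcSettings-class] used.
#' @export
setClass("McmcRun",
  representation(trace = "PosteriorTrace", phase1 = "PosteriorTrace",
                 prior = "PriorMatrix", priorInput = "PriorMatrix",
                 settings = "McmcSettings"))

#' Thresholded weighted network
#'
#' @slot nodes data.frame: id, layer, gene, symbol.
#' @slot edges data.frame: parent, parent_layer, child, child_layer, weight,
#'   directed, in_pk. Undirected (CPDAG-reversible) edges carry the skeleton
#'   weight (frequency of either direction).
#' @export
setClass("WeightedNetwork",
  representation(nodes = "data.frame", edges = "data.frame"))

#' MCMC convergence report
#'
#' Mean-shift changepoint scan of the post-burn-in log-posterior series; the
#' chain is flagged converged when no changepoint is detected.
#'
#' @slot changepoints integer snapshot positions of detected mean shifts.
#' @slot converged logical.
#' @slot stats named numeric trace summary.
#' @slot minseglen minimum segment length in iterations.
#' @export
setClass("ConvergenceReport",
  representation(changepoints = "integer", converged = "logical",
                 stats = "numeric", minseglen = "integer"))

#' Ground-truth network for simulation
#'
#' @slot nodes data.frame: id, layer, gene.
#' @slot edges data.frame: parent, child, coef.
#' @slot noiseSd named numeric per-node residual standard deviations.
#' @slot seed generation seed.
#' @export
setClass("GroundTruth",
  representation(nodes = "data.frame", edges = "data.frame",
                 noiseSd = "numeric", seed = "integer"))

setValidity("GroundTruth", function(object) {
  if (nrow(object@edges) && any(abs(object@edges$coef) < 0.2))
    "edge coefficients must be bounded away from zero (|coef| >= 0.2)"
  else TRUE
})
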