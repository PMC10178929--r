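#' Sample a ground-truth layered network
#'
#' Draws a random GE regulatory DAG (uniform random topological order, then
#' independent edge coin-flips at `edgeProb`, with flips suppressed once a
#' child reaches `fanInMax` GE parents), attaches a cis CNV parent to each
#' gene with probability `pCnv`, and `probesPerGene` causally linked
#' methylation parents per gene plus `noiseProbesPerGene` annotated but
#' causally unconnected probes. Edge coefficients are drawn uniformly from
#' +/- \[0.5, 1.5\] and node noise standard deviations from \[0.5, 1\].
#'
#' @param nGenes number of GE genes.
#' @param edgeProb GE->GE edge probability.
#' @param pCnv probability a gene has a CNV parent.
#' @param probesPerGene linked methylation probes per gene.
#' @param fanInMax maximum GE parents per gene.
#' @param seed integer seed.
#' @param noiseProbesPerGene unlinked (pure-noise) probes per gene.
#' @return a [GroundTruth-class].
#' @export
generateTrueNetwork <- function(nGenes, edgeProb = 0.2, pCnv = 0,
                                probesPerGene = 0L, fanInMax = 3L,
                                seed = 1L, noiseProbesPerGene = 0L) {
  stopifnot(nGenes >= 1, edgeProb >= 0, edgeProb <= 1, pCnv >= 0, pCnv <= 1,
            probesPerGene >= 0, fanInMax >= 1)
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(nGenes))
  ord <- sample(genes)
  par <- chl <- character(0)
  for (j in seq_along(ord)[-1]) {
    nPar <- 0L
    for (i in sample(seq_len(j - 1))) {
      if (nPar >= fanInMax) break
      if (stats::runif(1) < edgeProb) {
        par <- c(par, ord[i]); chl <- c(chl, ord[j])
        nPar <- nPar + 1L
      }
    }
  }
  nodes <- data.frame(id = genes, layer = "GE", gene = genes,
                      stringsAsFactors = FALSE)
  hasCnv <- stats::runif(nGenes) < pCnv
  if (any(hasCnv)) {
    cg <- genes[hasCnv]
    nodes <- rbind(nodes, data.frame(id = paste0("cnv_", cg), layer = "CNV",
                                     gene = cg, stringsAsFactors = FALSE))
    par <- c(par, paste0("cnv_", cg)); chl <- c(chl, cg)
  }
  if (probesPerGene > 0) {
    for (k in seq_len(probesPerGene)) {
      pr <- sprintf("cg%s_%d", sub("G", "", genes), k)
      nodes <- rbind(nodes, data.frame(id = pr, layer = "METH", gene = genes,
                                       stringsAsFactors = FALSE))
      par <- c(par, pr); chl <- c(chl, genes)
    }
  }
  if (noiseProbesPerGene > 0) {
    for (k in seq_len(noiseProbesPerGene)) {
      pr <- sprintf("cg%s_n%d", sub("G", "", genes), k)
      nodes <- rbind(nodes, data.frame(id = pr, layer = "METH", gene = genes,
                                       stringsAsFactors = FALSE))
    }
  }
  coef <- stats::runif(length(par), 0.5, 1.5) *
    sample(c(-1, 1), length(par), replace = TRUE)
  edges <- data.frame(parent = par, child = chl, coef = coef,
                      stringsAsFactors = FALSE)
  noiseSd <- setNames(stats::runif(nrow(nodes), 0.5, 1), nodes$id)
  gt <- new("GroundTruth", nodes = nodes, edges = edges, noiseSd = noiseSd,
            seed = as.integer(seed))
  methods::validObject(gt)
  gt
}

#' @describeIn generateTrueNetwork true edge table accessor
#' @param gt a [GroundTruth-class].
#' @export
trueEdges <- function(gt) gt@edges

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@nodes), "nodes,", nrow(object@edges),
      "edges (seed", object@seed, ")\n")
})

#' Simulate a multi-omics dataset from a ground truth
#'
#' Linear-Gaussian structural equations: root nodes (CNV, METH and
#' parentless GE) are standard normal; every other GE node is the
#' coefficient-weighted sum of its parents plus Gaussian noise with the
#' node's standard deviation, evaluated in topological order.
#'
#' @param gt a [GroundTruth-class].
#' @param nSamples number of samples (>= 3).
#' @param seed integer seed.
#' @return an [OmicsDataset-class] in the package's matrix conventions.
#' @export
simulateDataset <- function(gt, nSamples, seed = 1L) {
  stopifnot(nSamples >= 3)
  set.seed(seed)
  nodes <- gt@nodes
  ids <- nodes$id
  n <- as.integer(nSamples)
  vals <- matrix(0, n, length(ids), dimnames =
                   list(sprintf("s%04d", seq_len(n)), ids))
  parentsOf <- split(seq_len(nrow(gt@edges)),
                     factor(gt@edges$child, levels = ids))
  done <- setNames(logical(length(ids)), ids)
  pending <- ids
  while (length(pending)) {
    progressed <- FALSE
    for (id in pending) {
      eIdx <- parentsOf[[id]]
      pars <- gt@edges$parent[eIdx]
      if (all(done[pars])) {
        mu <- if (length(pars))
          vals[, pars, drop = FALSE] %*% gt@edges$coef[eIdx] else 0
        sd <- if (length(pars)) gt@noiseSd[[id]] else 1
        vals[, id] <- mu + stats::rnorm(n, 0, sd)
        done[id] <- TRUE
        progressed <- TRUE
      }
    }
    pending <- ids[!done]
    if (!progressed) stop("ground truth contains a cycle", call. = FALSE)
  }
  ge <- vals[, nodes$id[nodes$layer == "GE"], drop = FALSE]
  cnv <- meth <- NULL; pm <- NULL
  if (any(nodes$layer == "CNV")) {
    cnv <- vals[, nodes$id[nodes$layer == "CNV"], drop = FALSE]
    colnames(cnv) <- sub("^cnv_", "", colnames(cnv))
  }
  if (any(nodes$layer == "METH")) {
    probes <- nodes$id[nodes$layer == "METH"]
    meth <- vals[, probes, drop = FALSE]
    pm <- data.frame(probe_id = probes,
                     gene_id = nodes$gene[match(probes, nodes$id)],
                     stringsAsFactors = FALSE)
  }
  omicsDataset(ge = ge, cnv = cnv, meth = meth, probeMap = pm)
}

#' Emit a (possibly corrupted) prior-knowledge table from a ground truth
#'
#' Samples `floor(trueFrac * T)` of the T true GE->GE edges as `present`
#' rows, plus `floor(falseFrac * T)` GE->GE non-edges as `present`
#' misinformation, for prior-robustness experiments.
#'
#' @param gt a [GroundTruth-class].
#' @param trueFrac fraction of true GE->GE edges to include.
#' @param falseFrac misinformation rows as a fraction of the true edge count.
#' @param seed integer seed.
#' @return data.frame with columns src_gene, dst_gene, edge_type.
#' @export
corruptPrior <- function(gt, trueFrac, falseFrac, seed = 1L) {
  stopifnot(trueFrac >= 0, trueFrac <= 1, falseFrac >= 0)
  set.seed(seed)
  genes <- gt@nodes$id[gt@nodes$layer == "GE"]
  isGE <- gt@edges$parent %in% genes
  te <- gt@edges[isGE, , drop = FALSE]
  nTrue <- floor(trueFrac * nrow(te))
  pick <- if (nTrue > 0) sample(nrow(te), nTrue) else integer(0)
  out <- data.frame(src_gene = te$parent[pick], dst_gene = te$child[pick],
                    edge_type = rep("present", nTrue),
                    stringsAsFactors = FALSE)
  nFalse <- floor(falseFrac * nrow(te))
  if (nFalse > 0) {
    grid <- expand.grid(src = genes, dst = genes, stringsAsFactors = FALSE)
    grid <- grid[grid$src != grid$dst, ]
    keys <- .edgeKey(grid$src, grid$dst)
    nonEdges <- grid[!keys %in% .edgeKey(te$parent, te$child), ]
    pick2 <- sample(nrow(nonEdges), min(nFalse, nrow(nonEdges)))
    out <- rbind(out, data.frame(src_gene = nonEdges$src[pick2],
                                 dst_gene = nonEdges$dst[pick2],
                                 edge_type = "present",
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Simulate a dataset and write all inputs to disk
#'
#' Writes the omics matrices and probe annotation in the TSV conventions of
#' [readOmicsData()], plus the ground-truth edge list (TSV) and generation
#' metadata (JSON).
#'
#' @param gt a [GroundTruth-class].
#' @param nSamples samples to simulate.
#' @param dir output directory.
#' @param seed simulation seed.
#' @return invisibly, named character vector of files written.
#' @export
simulateToFiles <- function(gt, nSamples, dir, seed = 1L) {
  ds <- simulateDataset(gt, nSamples, seed)
  files <- writeOmicsData(ds, dir)
  files["truth_edges"] <- file.path(dir, "truth_edges.tsv")
  utils::write.table(gt@edges, files["truth_edges"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files["truth_meta"] <- file.path(dir, "truth_meta.json")
  jsonlite::write_json(list(
    nodes = gt@nodes, noise_sd = as.list(gt@noiseSd),
    generation_seed = gt@seed, simulation_seed = seed,
    n_samples = nSamples), files["truth_meta"], auto_unbox = TRUE,
    digits = NA)
  invisible(files)
}
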