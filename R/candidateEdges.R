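#' Define the ordered omics layers and their fan-in limits
#'
#' @param ds an [OmicsDataset-class]; layers are derived from the modalities
#'   present.
#' @param fanInGE maximum number of GE parents per GE node.
#' @param fanInCNV,fanInMETH per-layer parent limits for the cross-layer
#'   parents of a GE node (CNV contributes at most one candidate parent per
#'   gene anyway; METH one per retained probe).
#' @return a [LayerDefinition-class].
#' @export
layerDefinition <- function(ds, fanInGE = 3L, fanInCNV = 1L, fanInMETH = 2L) {
  layers <- "GE"
  fan <- c(GE = as.integer(fanInGE))
  if (!is.null(ds@cnv)) { layers <- c(layers, "CNV")
                          fan["CNV"] <- as.integer(fanInCNV) }
  if (!is.null(ds@meth)) { layers <- c(layers, "METH")
                           fan["METH"] <- as.integer(fanInMETH) }
  new("LayerDefinition", layers = layers, fanInMax = fan)
}

#' Enumerate the candidate edge universe
#'
#' Builds every edge the sampler may propose: all ordered GE->GE pairs
#' (no self-loops), the cis copy-number edge cnv_g -> g for each gene with
#' CNV data, and probe -> gene(probe) for each methylation probe present in
#' the (already filtered) dataset. Edges from the GE layer into the CNV or
#' METH layers are excluded, and CNV/METH nodes take no parents.
#'
#' CNV node ids are prefixed `cnv_` to keep them distinct from the gene ids.
#'
#' @param ds an [OmicsDataset-class] (apply [filterMethProbes()] first when
#'   methylation is present).
#' @param layers a [LayerDefinition-class] consistent with `ds`.
#' @return a [CandidateEdgeSet-class].
#' @export
candidateEdges <- function(ds, layers = layerDefinition(ds)) {
  genes <- colnames(ds@ge)
  nodes <- data.frame(id = genes, layer = "GE", gene = genes,
                      stringsAsFactors = FALSE)
  p <- c <- pl <- character(0)
  if (length(genes) > 1) {
    grid <- expand.grid(parent = genes, child = genes,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$parent != grid$child, ]
    p <- grid$parent; c <- grid$child; pl <- rep("GE", nrow(grid))
  }
  if (!is.null(ds@cnv) && "CNV" %in% layers@layers) {
    cg <- colnames(ds@cnv)
    nodes <- rbind(nodes, data.frame(id = paste0("cnv_", cg), layer = "CNV",
                                     gene = cg, stringsAsFactors = FALSE))
    p <- c(p, paste0("cnv_", cg)); c <- c(c, cg)
    pl <- c(pl, rep("CNV", length(cg)))
  }
  if (!is.null(ds@meth) && "METH" %in% layers@layers) {
    pr <- colnames(ds@meth)
    pg <- ds@probeMap$gene_id[match(pr, ds@probeMap$probe_id)]
    nodes <- rbind(nodes, data.frame(id = pr, layer = "METH", gene = pg,
                                     stringsAsFactors = FALSE))
    p <- c(p, pr); c <- c(c, pg); pl <- c(pl, rep("METH", length(pr)))
  }
  edges <- data.frame(parent = p, child = c, parentLayer = pl,
                      childLayer = rep("GE", length(p)),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  new("CandidateEdgeSet", nodes = nodes, edges = edges)
}

#' @describeIn candidateEdges the candidate edge table
#' @param x a [CandidateEdgeSet-class].
#' @export
edgeTable <- function(x) x@edges

#' @describeIn candidateEdges the typed node table
#' @export
nodeTable <- function(x) x@nodes

setMethod("show", "CandidateEdgeSet", function(object) {
  cat("CandidateEdgeSet:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "candidate edges\n")
  print(table(object@edges$parentLayer))
})

#' Enumerate all legal parent-set configurations of a node
#'
#' For a GE node, every subset of its candidate parents whose per-layer
#' counts respect the layer fan-in limits; parents from different layers are
#' combined freely (the GE fan-in only counts GE parents). CNV and METH nodes
#' are roots: their only parent set is the empty set.
#'
#' @param node node id.
#' @param candidates a [CandidateEdgeSet-class].
#' @param layers a [LayerDefinition-class].
#' @return a list of character vectors (possibly empty vectors), one per
#'   configuration.
#' @export
parentSets <- function(node, candidates, layers) {
  nd <- candidates@nodes
  if (!node %in% nd$id) stop("unknown node: ", node, call. = FALSE)
  if (nd$layer[nd$id == node] != "GE") return(list(character(0)))
  e <- candidates@edges
  perLayer <- lapply(layers@layers, function(ly) {
    pars <- e$parent[e$child == node & e$parentLayer == ly]
    k <- min(layers@fanInMax[[ly]], length(pars))
    subs <- list(character(0))
    if (length(pars) && k >= 1)
      for (sz in seq_len(k))
        subs <- c(subs, utils::combn(pars, sz, simplify = FALSE))
    subs
  })
  out <- perLayer[[1]]
  for (i in seq_along(perLayer)[-1]) {
    out <- unlist(lapply(out, function(a)
      lapply(perLayer[[i]], function(b) c(a, b))), recursive = FALSE)
  }
  out
}

#' Construct a layered network structure over a candidate edge set
#'
#' @param candidates a [CandidateEdgeSet-class].
#' @param edges either integer row indices into `edgeTable(candidates)` or a
#'   data.frame with columns `parent`, `child`.
#' @param layers a [LayerDefinition-class] providing fan-in limits.
#' @return a validated [NetworkStructure-class].
#' @export
networkStructure <- function(candidates, edges = integer(0), layers) {
  if (is.data.frame(edges)) {
    key <- .edgeKey(candidates@edges$parent, candidates@edges$child)
    idx <- match(.edgeKey(edges$parent, edges$child), key)
    if (anyNA(idx))
      stop("edge outside the candidate set: ",
           .edgeKey(edges$parent, edges$child)[which(is.na(idx))[1]],
           call. = FALSE)
    edges <- idx
  }
  g <- new("NetworkStructure", candidates = candidates,
           edgeIdx = as.integer(edges), fanInMax = layers@fanInMax)
  methods::validObject(g)
  g
}

#' @describeIn networkStructure edge table of a structure
#' @param g a [NetworkStructure-class].
#' @export
structureEdges <- function(g) {
  e <- g@candidates@edges[g@edgeIdx, , drop = FALSE]
  rownames(e) <- NULL
  e
}

setMethod("show", "NetworkStructure", function(object) {
  cat("NetworkStructure:", nrow(object@candidates@nodes), "nodes,",
      length(object@edgeIdx), "edges\n")
})
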