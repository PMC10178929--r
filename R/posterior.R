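#' Posterior edge weights from a trace
#'
#' The weight of a candidate edge is its empirical frequency over the
#' retained structure snapshots: those recorded after `burnIn` iterations,
#' subsampled so that consecutive retained snapshots are at least `thin`
#' iterations apart. Weights are direction-specific.
#'
#' @param trace a [PosteriorTrace-class].
#' @param burnIn iterations to discard (default: the trace's own burn-in).
#' @param thin minimal spacing in iterations between retained snapshots
#'   (default: the trace's own thinning; must be a use of the recorded
#'   snapshot grid).
#' @return named numeric vector over all candidate edges (keys
#'   "parent->child"), values in \[0,1\].
#' @export
edgeWeights <- function(trace, burnIn = trace@burnIn, thin = trace@thin) {
  e <- trace@candidates@edges
  keys <- .edgeKey(e$parent, e$child)
  w <- setNames(numeric(nrow(e)), keys)
  if (burnIn >= max(trace@snapshotIter, length(trace@logScore)))
    stop("burnIn exceeds the trace span", call. = FALSE)
  keep <- trace@snapshotIter > burnIn
  idx <- which(keep)
  if (length(idx) && thin > trace@thin) {
    step <- max(1L, as.integer(ceiling(thin / trace@thin)))
    idx <- idx[seq(1L, length(idx), by = step)]
  }
  if (!length(idx)) return(w)
  counts <- numeric(nrow(e))
  for (i in idx) {
    s <- trace@snapshots[[i]]
    counts[s] <- counts[s] + 1
  }
  w[] <- counts / length(idx)
  w
}

#' Threshold posterior edge weights
#'
#' In `quantile` mode an edge is retained when its weight reaches the
#' `value`-quantile of all nonzero edge weights (linear-interpolation
#' "type 7" quantiles); in `absolute` mode when its weight reaches `value`.
#' Ties at the threshold are retained.
#'
#' @param weights named numeric vector from [edgeWeights()].
#' @param mode `"quantile"` or `"absolute"`.
#' @param value quantile level or absolute cutoff, in \[0,1\].
#' @return character vector of retained edge keys.
#' @export
thresholdEdges <- function(weights, mode = c("quantile", "absolute"),
                           value = 0.75) {
  mode <- match.arg(mode)
  if (!length(weights)) stop("empty weight vector", call. = FALSE)
  if (value < 0 || value > 1)
    stop("threshold value must lie in [0,1]", call. = FALSE)
  cut <- if (mode == "quantile") {
    nz <- weights[weights > 0]
    if (!length(nz)) return(character(0))
    unname(stats::quantile(nz, value, type = 7))
  } else value
  names(weights)[weights >= cut & weights > 0]
}

# ---- CPDAG -----------------------------------------------------------------

#' Compelled and reversible edges of a DAG (CPDAG labelling)
#'
#' Labels each edge of a DAG as compelled (directed in every member of its
#' Markov equivalence class) or reversible, by orienting the v-structures of
#' the skeleton and closing under the Meek orientation rules. Cross-layer
#' (CNV/METH -> GE) edges are always compelled: their reversal lies outside
#' the candidate edge space.
#'
#' @param g a [NetworkStructure-class].
#' @return data.frame with columns `parent`, `child`, `compelled` (logical);
#'   one row per edge of `g`, parent/child as in `g` (reversible edges keep
#'   the input orientation but are flagged `compelled = FALSE`).
#' @export
toCpdag <- function(g) {
  e <- structureEdges(g)
  if (nrow(e) == 0L)
    return(data.frame(parent = character(0), child = character(0),
                      compelled = logical(0)))
  ids <- g@candidates@nodes$id
  n <- length(ids)
  pI <- match(e$parent, ids); cI <- match(e$child, ids)
  adj <- matrix(FALSE, n, n)
  adj[cbind(pI, cI)] <- TRUE
  if (.hasCycle(e$parent, e$child))
    stop("input graph is cyclic; CPDAG is defined for DAGs only",
         call. = FALSE)
  lab <- .cpdagLabel(adj)
  compelled <- lab[cbind(pI, cI)] == 2L
  # cross-layer edges cannot be reversed inside the candidate space
  compelled[e$parentLayer != "GE"] <- TRUE
  data.frame(parent = e$parent, child = e$child, compelled = compelled,
             stringsAsFactors = FALSE)
}

# label matrix: 0 absent, 1 undirected skeleton edge, 2 oriented u->v
.cpdagLabel <- function(adj) {
  n <- nrow(adj)
  skel <- adj | t(adj)
  lab <- matrix(0L, n, n)
  lab[skel] <- 1L
  orient <- function(u, v) { lab[u, v] <<- 2L; lab[v, u] <<- 0L }
  # v-structures of the DAG: u -> w <- v with u, v non-adjacent
  for (w in seq_len(n)) {
    pars <- which(adj[, w])
    if (length(pars) < 2) next
    for (a in seq_along(pars)) for (b in seq_along(pars)) {
      if (a >= b) next
      u <- pars[a]; v <- pars[b]
      if (!skel[u, v]) { orient(u, w); orient(v, w) }
    }
  }
  # Meek rules until fixpoint
  repeat {
    changed <- FALSE
    und <- which(lab == 1L & upper.tri(matrix(TRUE, n, n)) |
                   lab == 1L & lower.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    for (r in seq_len(nrow(und))) {
      a <- und[r, 1]; b <- und[r, 2]
      if (lab[a, b] != 1L) next
      # R1: c -> a, a - b, c and b non-adjacent  =>  a -> b
      if (any(lab[, a] == 2L & !skel[, b])) {
        orient(a, b); changed <- TRUE; next
      }
      # R2: a -> c -> b and a - b  =>  a -> b
      if (any(lab[a, ] == 2L & lab[, b] == 2L)) {
        orient(a, b); changed <- TRUE; next
      }
      # R3: a - c -> b, a - d -> b, c and d non-adjacent  =>  a -> b
      cand <- which(lab[a, ] == 1L & lab[, b] == 2L)
      if (length(cand) >= 2) {
        done <- FALSE
        for (i in seq_along(cand)) {
          for (j in seq_along(cand)) {
            if (i < j && !skel[cand[i], cand[j]]) {
              orient(a, b); changed <- TRUE; done <- TRUE; break
            }
          }
          if (done) break
        }
        if (done) next
      }
    }
    if (!changed) break
  }
  lab
}

#' Build a thresholded weighted network from posterior edge weights
#'
#' Retains edges by [thresholdEdges()], collapses pairs retained in both
#' directions into a single undirected edge carrying the skeleton weight
#' (sum of the two direction frequencies), and, when the retained directed
#' graph is acyclic, flags CPDAG-reversible edges as undirected (these also
#' carry the skeleton weight). Cross-layer edges are always directed.
#'
#' @param weights named numeric vector from [edgeWeights()].
#' @param candidates the [CandidateEdgeSet-class] the weights refer to.
#' @param layers a [LayerDefinition-class] (for fan-in metadata on the CPDAG
#'   step).
#' @param mode,value thresholding rule, see [thresholdEdges()].
#' @param pk optional curated prior table; marks retained edges found there.
#' @param geneSymbols optional named vector of display symbols.
#' @return a [WeightedNetwork-class].
#' @export
weightedNetwork <- function(weights, candidates, layers,
                            mode = c("quantile", "absolute"), value = 0.75,
                            pk = NULL, geneSymbols = character(0)) {
  mode <- match.arg(mode)
  kept <- thresholdEdges(weights, mode, value)
  e <- candidates@edges
  keys <- .edgeKey(e$parent, e$child)
  sub <- e[keys %in% kept, , drop = FALSE]
  w <- unname(weights[.edgeKey(sub$parent, sub$child)])
  revKey <- .edgeKey(sub$child, sub$parent)
  wRev <- weights[revKey]; wRev[is.na(wRev)] <- 0
  directed <- rep(TRUE, nrow(sub))
  weightOut <- w
  # both directions retained -> one undirected edge with skeleton weight
  dup <- revKey %in% .edgeKey(sub$parent, sub$child)
  if (any(dup)) {
    first <- !duplicated(pmin(.edgeKey(sub$parent, sub$child), revKey)) & dup
    drop <- dup & !first
    directed[first] <- FALSE
    weightOut[first] <- w[first] + unname(wRev[first])
    sub <- sub[!drop, , drop = FALSE]
    directed <- directed[!drop]; weightOut <- weightOut[!drop]
    w <- w[!drop]; wRev <- wRev[!drop]
  }
  # CPDAG labelling of the retained directed part
  dir <- sub[directed, , drop = FALSE]
  if (nrow(dir) && !.hasCycle(dir$parent, dir$child)) {
    gsub <- networkStructure(candidates, dir, layers)
    lab <- toCpdag(gsub)
    rev <- !lab$compelled
    if (any(rev)) {
      pos <- which(directed)[rev]
      directed[pos] <- FALSE
      weightOut[pos] <- w[pos] + unname(wRev[pos])
    }
  } else if (nrow(dir) && .hasCycle(dir$parent, dir$child)) {
    warning("retained directed edges contain a cycle; ",
            "CPDAG labelling skipped", call. = FALSE)
  }
  inPK <- rep(FALSE, nrow(sub))
  if (!is.null(pk) && nrow(pk)) {
    pkKeys <- .edgeKey(pk$src_gene[pk$edge_type == "present"],
                       pk$dst_gene[pk$edge_type == "present"])
    k1 <- .edgeKey(sub$parent, sub$child)
    k2 <- .edgeKey(sub$child, sub$parent)
    inPK <- k1 %in% pkKeys | (!directed & k2 %in% pkKeys)
  }
  nodes <- candidates@nodes
  nodes$symbol <- ifelse(nodes$gene %in% names(geneSymbols),
                         unname(geneSymbols[nodes$gene]), nodes$id)
  used <- nodes$id %in% c(sub$parent, sub$child)
  edges <- data.frame(parent = sub$parent, parent_layer = sub$parentLayer,
                      child = sub$child, child_layer = sub$childLayer,
                      weight = weightOut, directed = directed, in_pk = inPK,
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  new("WeightedNetwork", nodes = nodes[used, , drop = FALSE], edges = edges)
}

#' @describeIn weightedNetwork the weighted edge table
#' @param net a [WeightedNetwork-class].
#' @export
networkEdges <- function(net) net@edges

setMethod("show", "WeightedNetwork", function(object) {
  cat("WeightedNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges (",
      sum(!object@edges$directed), "undirected )\n")
})

# ---- convergence -----------------------------------------------------------

# binary segmentation for mean shifts; penalty 2 * log(n) * sigma2 with
# sigma2 from first differences (robust to the mean shifts themselves)
.binseg <- function(x, minseg, penalty) {
  n <- length(x)
  cps <- integer(0)
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L * minseg) return(invisible(NULL))
    seg <- x[lo:hi]
    cs <- cumsum(seg); tot <- cs[len]
    k <- minseg:(len - minseg)
    rss0 <- sum(seg^2) - tot^2 / len
    rss1 <- (sum(seg^2)) -
      (cs[k]^2 / k + (tot - cs[k])^2 / (len - k))
    gain <- rss0 - rss1
    best <- which.max(gain)
    if (gain[best] > penalty) {
      cp <- lo + k[best] - 1L
      cps <<- c(cps, cp)
      recurse(lo, cp)
      recurse(cp + 1L, hi)
    }
    invisible(NULL)
  }
  recurse(1L, n)
  sort(cps)
}

#' Changepoint-based convergence check of an MCMC trace
#'
#' Applies mean-shift binary segmentation to the post-burn-in log-posterior
#' series at snapshot resolution, with penalty `2 * log(n) * sigma2`
#' (`sigma2` estimated from first differences) and minimum segment length
#' `minseglen / thin` snapshots. The chain is flagged converged when no
#' changepoint is detected.
#'
#' @param trace a [PosteriorTrace-class].
#' @param minseglen minimum segment length in iterations (default 50000).
#' @return a [ConvergenceReport-class].
#' @export
convergenceCheck <- function(trace, minseglen = 50000L) {
  minseglen <- as.integer(minseglen)
  if (minseglen < 1L) stop("minseglen must be positive", call. = FALSE)
  series <- .snapshotLogPosterior(trace)
  minseg <- max(2L, as.integer(ceiling(minseglen / trace@thin)))
  if (length(series) < 2L * minseg)
    stop("trace too short: need more than 2 * minseglen iterations after ",
         "burn-in", call. = FALSE)
  sigma2 <- mean(diff(series)^2) / 2
  cps <- if (sigma2 == 0) integer(0)
    else .binseg(series, minseg, 2 * log(length(series)) * sigma2)
  new("ConvergenceReport", changepoints = cps,
      converged = length(cps) == 0L,
      stats = c(n_snapshots = length(series), mean = mean(series),
                sd = stats::sd(series), sigma2_hat = sigma2),
      minseglen = minseglen)
}

.snapshotLogPosterior <- function(trace) {
  if (!length(trace@snapshotIter))
    stop("trace has no recorded snapshots", call. = FALSE)
  trace@logScore[trace@snapshotIter] + trace@logPrior[trace@snapshotIter]
}

#' Write a convergence report as JSON
#'
#' @param report a [ConvergenceReport-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeConvergenceReport <- function(report, path) {
  jsonlite::write_json(list(
    converged = report@converged,
    changepoints = report@changepoints,
    minseglen = report@minseglen,
    stats = as.list(report@stats)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

setMethod("show", "ConvergenceReport", function(object) {
  cat("ConvergenceReport:",
      if (object@converged) "converged" else
        paste("NOT converged;", length(object@changepoints),
              "changepoint(s) at", paste(object@changepoints,
                                         collapse = ", ")), "\n")
})

# ---- export ----------------------------------------------------------------

#' Export a weighted network
#'
#' `tsv` writes the edge table (columns parent, parent_layer, child,
#' child_layer, weight, directed, in_pk) and round-trips losslessly through
#' [importNetwork()]. `graphml` and `sif` go through igraph / plain text for
#' downstream tools (SIF relation = "parentlayer-childlayer").
#'
#' @param net a [WeightedNetwork-class].
#' @param path output file path.
#' @param format one of `"tsv"`, `"graphml"`, `"sif"`.
#' @return invisibly, the path.
#' @export
exportNetwork <- function(net, path, format = c("tsv", "graphml", "sif")) {
  format <- match.arg(format)
  e <- net@edges
  if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    lines <- if (nrow(e))
      paste(e$parent, paste0(e$parent_layer, "-", e$child_layer), e$child,
            sep = "\t") else character(0)
    writeLines(lines, path)
  } else {
    gdf <- if (nrow(e)) e[, c("parent", "child")] else
      data.frame(parent = character(0), child = character(0))
    g <- igraph::graph_from_data_frame(gdf, directed = TRUE,
                                       vertices = net@nodes)
    if (nrow(e)) {
      igraph::E(g)$weight <- e$weight
      igraph::E(g)$directed <- e$directed
      igraph::E(g)$in_pk <- e$in_pk
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @describeIn exportNetwork read back a TSV network export
#' @param nodes optional node table to restore (default: reconstructed from
#'   the edge table).
#' @export
importNetwork <- function(path, nodes = NULL) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(nodes)) {
    ids <- unique(c(e$parent, e$child))
    ly <- character(length(ids))
    ly[ids %in% e$parent] <- e$parent_layer[match(ids[ids %in% e$parent],
                                                  e$parent)]
    ly[ids %in% e$child] <- ifelse(ly[ids %in% e$child] == "",
                                   e$child_layer[match(ids[ids %in% e$child],
                                                       e$child)],
                                   ly[ids %in% e$child])
    nodes <- data.frame(id = ids, layer = ly, gene = ids, symbol = ids,
                        stringsAsFactors = FALSE)
  }
  if (!nrow(e))
    e <- data.frame(parent = character(0), parent_layer = character(0),
                    child = character(0), child_layer = character(0),
                    weight = numeric(0), directed = logical(0),
                    in_pk = logical(0))
  new("WeightedNetwork", nodes = nodes, edges = e)
}

# ---- plots -----------------------------------------------------------------

#' Diagnostic trace plot
#'
#' Log-posterior trace with the burn-in boundary and any detected
#' changepoints marked. Plotting never alters numeric results.
#'
#' @param trace a [PosteriorTrace-class].
#' @param path optional PNG path; when `NULL`, plots to the active device.
#' @param report optional [ConvergenceReport-class] whose changepoints are
#'   marked.
#' @return invisibly, `path`.
#' @export
tracePlot <- function(trace, path = NULL, report = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 450)
    on.exit(grDevices::dev.off())
  }
  lp <- trace@logScore + trace@logPrior
  graphics::plot(seq_along(lp), lp, type = "l", col = "grey30",
                 xlab = "iteration", ylab = "log posterior",
                 main = "MCMC trace")
  graphics::abline(v = trace@burnIn, col = "steelblue", lty = 2)
  if (!is.null(report) && length(report@changepoints)) {
    cpIter <- trace@snapshotIter[report@changepoints]
    graphics::abline(v = cpIter, col = "firebrick", lty = 3)
  }
  invisible(path)
}

#' Layered network plot
#'
#' Renders the weighted network with node colour/shape by layer and edge
#' width by weight; the layout is seeded so repeated calls give identical
#' coordinates.
#'
#' @param net a [WeightedNetwork-class].
#' @param path optional PNG path.
#' @param layoutSeed seed for the layout (default 1).
#' @return invisibly, `path`.
#' @export
networkPlot <- function(net, path = NULL, layoutSeed = 1L) {
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 800)
    on.exit(grDevices::dev.off())
  }
  e <- net@edges
  gdf <- if (nrow(e)) e[, c("parent", "child")] else
    data.frame(parent = character(0), child = character(0))
  g <- igraph::graph_from_data_frame(gdf, directed = TRUE,
                                     vertices = net@nodes)
  cols <- c(GE = "lightsteelblue", CNV = "palegreen3", METH = "lightsalmon")
  shp <- c(GE = "circle", CNV = "square", METH = "circle")
  vl <- net@nodes$layer
  lay <- .withPreservedRNG({
    set.seed(layoutSeed)
    igraph::layout_with_fr(g)
  })
  igraph::plot.igraph(g, layout = lay,
    vertex.color = cols[vl], vertex.shape = shp[vl],
    vertex.label = net@nodes$symbol, vertex.label.cex = 0.8,
    edge.width = if (nrow(e)) 1 + 3 * e$weight else 1,
    edge.arrow.size = if (nrow(e)) ifelse(e$directed, 0.5, 0) else 0.5)
  graphics::legend("topleft", legend = unique(vl), pt.bg = cols[unique(vl)],
                   pch = 21, bty = "n")
  invisible(path)
}
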