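#' BGe score hyperparameters
#'
#' Parameters of the Gaussian-inverse-Wishart prior behind the Bayesian
#' Gaussian equivalent (BGe) marginal-likelihood score: prior mean `nu`,
#' prior precision on the mean `alphaMu`, Wishart degrees of freedom
#' `alphaW`, and the parametric matrix `tMatrix` of the Wishart prior.
#'
#' @slot nu numeric prior mean vector (one entry per node).
#' @slot alphaMu positive scalar.
#' @slot alphaW scalar, must exceed `length(nu) - 1`.
#' @slot tMatrix symmetric positive-definite matrix.
#' @export
setClass("BGeHyperparameters",
  representation(nu = "numeric", alphaMu = "numeric", alphaW = "numeric",
                 tMatrix = "matrix"))

setValidity("BGeHyperparameters", function(object) {
  d <- length(object@nu)
  msgs <- character(0)
  if (object@alphaMu <= 0) msgs <- c(msgs, "alphaMu must be positive")
  if (object@alphaW <= d - 1)
    msgs <- c(msgs, "alphaW must exceed dim - 1")
  if (!isTRUE(all.equal(object@tMatrix, t(object@tMatrix))))
    msgs <- c(msgs, "tMatrix must be symmetric")
  if (length(msgs)) msgs else TRUE
})

# node ordering shared by the scorer and the candidate edge universe:
# GE genes, then cnv_<gene> columns, then methylation probes
.nodeDataMatrix <- function(ds) {
  X <- ds@ge
  if (!is.null(ds@cnv)) {
    cnv <- ds@cnv
    colnames(cnv) <- paste0("cnv_", colnames(cnv))
    X <- cbind(X, cnv)
  }
  if (!is.null(ds@meth)) X <- cbind(X, ds@meth)
  X
}

#' Default score-equivalent BGe hyperparameters for a dataset
#'
#' `nu` is the per-feature sample mean, `alphaMu = 1`, `alphaW = d + 2` and
#' `tMatrix = alphaMu * (alphaW - d - 1) / (alphaMu + 1) * I`, the standard
#' score-equivalent default for d features.
#'
#' @param ds an [OmicsDataset-class].
#' @param alphaMu prior precision on the mean (default 1).
#' @return a [BGeHyperparameters-class].
#' @export
bgeHyperparameters <- function(ds, alphaMu = 1) {
  X <- .nodeDataMatrix(ds)
  if (nrow(X) < 2L)
    stop("at least 2 samples are required to score networks", call. = FALSE)
  d <- ncol(X)
  alphaW <- d + 2
  tScale <- alphaMu * (alphaW - d - 1) / (alphaMu + 1)
  tm <- diag(tScale, d)
  dimnames(tm) <- list(colnames(X), colnames(X))
  hp <- new("BGeHyperparameters", nu = colMeans(X), alphaMu = alphaMu,
            alphaW = alphaW, tMatrix = tm)
  methods::validObject(hp)
  hp
}

#' Create a BGe score cache for a dataset
#'
#' Precomputes the posterior parametric matrix and memoises local scores so
#' the sampler can revisit parent sets cheaply. A cache hit returns the
#' bit-identical value of a fresh computation; the cache is tied to one
#' dataset/hyperparameter pair.
#'
#' @param ds an [OmicsDataset-class].
#' @param hp a [BGeHyperparameters-class] (defaults to
#'   [bgeHyperparameters()]).
#' @return an environment of class `BGeScoreCache`.
#' @export
newScoreCache <- function(ds, hp = bgeHyperparameters(ds)) {
  X <- .nodeDataMatrix(ds)
  N <- nrow(X); d <- ncol(X)
  if (length(hp@nu) != d)
    stop("hyperparameter dimension does not match the dataset",
         call. = FALSE)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  S <- crossprod(Xc)
  dev <- hp@nu - xbar
  R <- hp@tMatrix + S +
    (N * hp@alphaMu / (N + hp@alphaMu)) * tcrossprod(dev)
  env <- new.env(parent = emptyenv())
  env$X <- X; env$N <- N; env$d <- d
  env$alphaMu <- hp@alphaMu; env$alphaW <- hp@alphaW
  env$Tm <- hp@tMatrix; env$R <- R
  env$nodeIndex <- setNames(seq_len(d), colnames(X))
  env$store <- new.env(parent = emptyenv())
  class(env) <- "BGeScoreCache"
  env
}

# log-determinant of a principal submatrix via Cholesky, one jitter retry
.logdetSub <- function(M, idx) {
  A <- M[idx, idx, drop = FALSE]
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(A + diag(1e-8, nrow(A))), error = function(e) NULL)
    if (is.null(ch))
      stop("numerically degenerate posterior matrix over columns: ",
           paste(colnames(M)[idx], collapse = ", "), call. = FALSE)
  }
  2 * sum(log(diag(ch)))
}

# log marginal likelihood of the data restricted to node subset A (indices);
# the subset model inherits degrees of freedom alphaW - d + |A|
.logmlSubset <- function(env, idx) {
  l <- length(idx)
  if (l == 0L) return(0)
  N <- env$N
  aw <- env$alphaW - env$d + l
  j <- seq_len(l)
  lgr <- sum(lgamma((N + aw + 1 - j) / 2) - lgamma((aw + 1 - j) / 2))
  -(l * N / 2) * log(pi) +
    (l / 2) * (log(env$alphaMu) - log(env$alphaMu + N)) +
    lgr +
    (aw / 2) * .logdetSub(env$Tm, idx) -
    ((N + aw) / 2) * .logdetSub(env$R, idx)
}

.localScoreIdx <- function(env, i, pidx) {
  key <- if (length(pidx)) paste(i, paste(sort(pidx), collapse = ","),
                                 sep = "|") else as.character(i)
  hit <- env$store[[key]]
  if (!is.null(hit)) return(hit)
  val <- .logmlSubset(env, c(pidx, i)) - .logmlSubset(env, pidx)
  env$store[[key]] <- val
  val
}

#' Local BGe score of a node given a parent set
#'
#' Log marginal likelihood of the node's data column given the parent
#' columns, computed as the ratio of two subset marginal likelihoods under
#' the Gaussian-inverse-Wishart model, in log space via Cholesky
#' factorizations and log-gamma functions. The score is equal for all DAGs in
#' a Markov equivalence class when summed over nodes.
#'
#' @param node node id (a data column name).
#' @param parents character vector of parent node ids (may be empty).
#' @param cache a `BGeScoreCache` from [newScoreCache()].
#' @return the log score (scalar).
#' @export
bgeLocalScore <- function(node, parents, cache) {
  stopifnot(inherits(cache, "BGeScoreCache"))
  if (node %in% parents)
    stop("a node cannot be its own parent: ", node, call. = FALSE)
  i <- cache$nodeIndex[[node]]
  if (is.null(i)) stop("unknown node: ", node, call. = FALSE)
  pidx <- cache$nodeIndex[parents]
  if (anyNA(pidx))
    stop("unknown parent node(s): ",
         paste(parents[is.na(pidx)], collapse = ", "), call. = FALSE)
  .localScoreIdx(cache, i, as.integer(pidx))
}

#' Total BGe score of a network structure
#'
#' Sum of [bgeLocalScore()] over all nodes with their parent sets in `g`.
#' The score is decomposable: a single-edge change only alters the affected
#' child's local term.
#'
#' @param g a [NetworkStructure-class].
#' @param cache a `BGeScoreCache` over the same dataset.
#' @return the total log score.
#' @export
bgeNetworkScore <- function(g, cache) {
  stopifnot(inherits(cache, "BGeScoreCache"))
  e <- structureEdges(g)
  total <- 0
  for (node in g@candidates@nodes$id) {
    pars <- e$parent[e$child == node]
    total <- total + bgeLocalScore(node, pars, cache)
  }
  total
}

#' Dump the memoised local scores (debugging aid)
#'
#' @param cache a `BGeScoreCache`.
#' @param path optional TSV output path with columns node, parents,
#'   log_score; when NULL the table is only returned.
#' @return the data.frame of cached scores (invisibly when written to file).
#' @export
dumpScoreCache <- function(cache, path = NULL) {
  keys <- ls(cache$store)
  nodeNames <- names(cache$nodeIndex)
  rows <- lapply(keys, function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    pidx <- if (length(parts) > 1)
      as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]]) else integer(0)
    data.frame(node = nodeNames[as.integer(parts[1])],
               parents = paste(nodeNames[pidx], collapse = ","),
               log_score = cache$store[[k]], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(data.frame(node = character(0),
    parents = character(0), log_score = numeric(0)))))
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
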