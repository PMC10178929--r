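#' MCMC settings constructor
#'
#' @param totalIterations iterations of the final sampling phase.
#' @param burnIn iterations discarded before recording snapshots.
#' @param thin snapshot interval in iterations.
#' @param seed integer seed; drives move choice, acceptance and beta
#'   proposals through one RNG stream.
#' @param phase1Fraction fraction of `totalIterations` run as the
#'   empirical-prior adaptation phase before the final run (default 0.5).
#' @param sampleBeta sample the prior inverse temperature?
#' @param betaInit initial inverse temperature.
#' @return an [McmcSettings-class].
#' @export
mcmcSettings <- function(totalIterations, burnIn, thin = 1L, seed = 42L,
                         phase1Fraction = 0.5, sampleBeta = TRUE,
                         betaInit = 1) {
  s <- new("McmcSettings", totalIterations = as.integer(totalIterations),
           burnIn = as.integer(burnIn), thin = as.integer(thin),
           seed = as.integer(seed), phase1Fraction = phase1Fraction,
           sampleBeta = sampleBeta, betaInit = betaInit)
  methods::validObject(s)
  s
}

# ---- small R-side structure bookkeeping (used by initialStructure) ---------

.newSamplerState <- function(candidates, fanInMax, edgeIdx = integer(0)) {
  nodes <- candidates@nodes
  d <- nrow(nodes)
  ids <- nodes$id
  eng <- new.env(parent = emptyenv())
  eng$d <- d
  eng$ids <- ids
  eng$layerOf <- nodes$layer
  eng$geIdx <- which(nodes$layer == "GE")
  eng$nGE <- length(eng$geIdx)
  eng$mapGE <- integer(d); eng$mapGE[eng$geIdx] <- seq_len(eng$nGE)
  eng$fanIn <- fanInMax
  e <- candidates@edges
  pI <- match(e$parent, ids); cI <- match(e$child, ids)
  eng$edgeRow <- matrix(0L, d, d)
  eng$edgeRow[cbind(pI, cI)] <- seq_len(nrow(e))
  eng$edgeLin <- (cI - 1L) * d + pI
  eng$adj <- matrix(FALSE, d, d)
  eng$geAdj <- matrix(0, eng$nGE, eng$nGE)
  eng$indegGE <- integer(d)
  eng$indegCNV <- integer(d)
  eng$indegMETH <- integer(d)
  for (r in edgeIdx) .applyEdge(eng, pI[r], cI[r], TRUE)
  eng
}

.applyEdge <- function(eng, u, v, add) {
  eng$adj[u, v] <- add
  step <- if (add) 1L else -1L
  ly <- eng$layerOf[u]
  if (ly == "GE") {
    eng$indegGE[v] <- eng$indegGE[v] + step
    eng$geAdj[eng$mapGE[u], eng$mapGE[v]] <- as.numeric(add)
  } else if (ly == "CNV") eng$indegCNV[v] <- eng$indegCNV[v] + step
  else eng$indegMETH[v] <- eng$indegMETH[v] + step
  invisible(NULL)
}

# strict reachability (paths of length >= 1) over the GE subgraph
.geReach <- function(geAdj) {
  R <- geAdj
  repeat {
    Rn <- ((R + R %*% geAdj) > 0) * 1
    if (identical(Rn, R)) break
    R <- Rn
  }
  R
}

# matrices handed to the C++ core
.candMatrices <- function(candidates, fanInMax) {
  nodes <- candidates@nodes
  ids <- nodes$id
  d <- length(ids)
  e <- candidates@edges
  candRow <- matrix(0L, d, d)
  candRow[cbind(match(e$parent, ids), match(e$child, ids))] <-
    seq_len(nrow(e))
  layerCode <- c(GE = 0L, CNV = 1L, METH = 2L)[nodes$layer]
  fan3 <- c(GE = 1L, CNV = 1L, METH = 1L)
  fan3[names(fanInMax)] <- as.integer(fanInMax)
  list(candRow = candRow, layerCode = unname(layerCode),
       fanIn = unname(fan3), ids = ids, d = d)
}

.adjFromEdgeIdx <- function(cm, candidates, edgeIdx) {
  e <- candidates@edges
  adj <- matrix(0L, cm$d, cm$d)
  if (length(edgeIdx))
    adj[cbind(match(e$parent[edgeIdx], cm$ids),
              match(e$child[edgeIdx], cm$ids))] <- 1L
  adj
}

#' All legal single-edge moves from a structure
#'
#' Lists the sampler's move neighborhood: deletion of any present edge,
#' addition of any absent candidate edge that keeps the graph acyclic and
#' within the per-layer fan-in limits, and reversal of any GE->GE edge whose
#' reversal is itself legal (cross-layer edges are never reversible because
#' GE -> CNV/METH edges are excluded from the candidate set).
#'
#' @param g a [NetworkStructure-class].
#' @return data.frame with columns `type` ("add", "delete", "reverse"),
#'   `parent`, `child`.
#' @export
legalMoves <- function(g) {
  cm <- .candMatrices(g@candidates, g@fanInMax)
  adj <- .adjFromEdgeIdx(cm, g@candidates, g@edgeIdx)
  mv <- .cppEnumMoves(adj, cm$candRow, cm$layerCode, cm$fanIn)
  out <- data.frame(type = c("add", "delete", "reverse")[mv$type],
                    parent = cm$ids[mv$u + 1L], child = cm$ids[mv$v + 1L],
                    stringsAsFactors = FALSE)
  out[order(match(out$type, c("delete", "add", "reverse"))), , drop = FALSE]
}

#' Initial structure for the sampler
#'
#' `empty` returns the edgeless DAG. `pk_seeded` greedily adds
#' curated-present edges (belief > 0.5 with provenance `curated` or
#' `tf_target`) in random order, skipping any edge that would create a cycle
#' or exceed a fan-in limit.
#'
#' @param candidates a [CandidateEdgeSet-class].
#' @param layers a [LayerDefinition-class].
#' @param mode `"empty"` or `"pk_seeded"`.
#' @param b a [PriorMatrix-class]; required for `pk_seeded`.
#' @param seed optional seed for the insertion order.
#' @return a [NetworkStructure-class].
#' @export
initialStructure <- function(candidates, layers,
                             mode = c("pk_seeded", "empty"), b = NULL,
                             seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "empty")
    return(networkStructure(candidates, integer(0), layers))
  if (is.null(b)) stop("pk_seeded mode requires a prior matrix",
                       call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cur <- which(b@provenance %in% c("curated", "tf_target") & b@values > 0.5)
  eng <- .newSamplerState(candidates, layers@fanInMax)
  if (length(cur)) {
    ord <- if (length(cur) > 1) sample(cur) else cur
    d <- eng$d
    for (r in ord) {
      lin <- eng$edgeLin[r]
      u <- ((lin - 1L) %% d) + 1L; v <- ((lin - 1L) %/% d) + 1L
      ly <- eng$layerOf[u]
      okFan <- switch(ly,
        GE = eng$indegGE[v] < eng$fanIn[["GE"]],
        CNV = eng$indegCNV[v] < eng$fanIn[["CNV"]],
        METH = eng$indegMETH[v] < eng$fanIn[["METH"]])
      if (!okFan) next
      if (ly == "GE") {
        reach <- .geReach(eng$geAdj)
        if (reach[eng$mapGE[v], eng$mapGE[u]] > 0) next
      }
      .applyEdge(eng, u, v, TRUE)
    }
  }
  networkStructure(candidates, sort(eng$edgeRow[which(eng$adj)]), layers)
}

# ---- two-phase driver ------------------------------------------------------

#' Two-phase MCMC over layered network structures
#'
#' Phase 1 (adaptation, `phase1Fraction * totalIterations` iterations) runs
#' with the curated/default prior matrix; its posterior edge frequencies
#' (own burn-in = half of phase 1, same thinning) complete the missing prior
#' entries via [empiricalPriorUpdate()]. Phase 2 restarts from the phase-1
#' final structure with the completed prior and runs `totalIterations`
#' iterations; its trace is returned. One structure proposal per iteration;
#' when beta is sampled, a beta proposal is interleaved once per structure
#' sweep (every `n` nodes iterations). Fully reproducible given the seed.
#'
#' When `checkpointPath` is given, a resumable JSON checkpoint is written
#' every `checkpointEvery` iterations and an existing checkpoint is resumed
#' from automatically; a resumed run reproduces the uninterrupted one.
#'
#' @param ds an [OmicsDataset-class] (methylation already filtered).
#' @param layers a [LayerDefinition-class].
#' @param pm a [PriorModel-class] over the candidate edges of `ds`.
#' @param settings an [McmcSettings-class].
#' @param initMode initial structure mode, see [initialStructure()].
#' @param hp BGe hyperparameters (default [bgeHyperparameters()]); the
#'   sampler requires the scalar-diagonal `tMatrix` that constructor builds.
#' @param candidates candidate edge set (default [candidateEdges()]).
#' @param checkpointPath optional path for a resumable JSON checkpoint.
#' @param checkpointEvery checkpoint interval in iterations.
#' @param stopAfter testing hook: abort after this many global iterations,
#'   writing a checkpoint (requires `checkpointPath`); the call then returns
#'   an object of class `McmcInterrupt`.
#' @return an [McmcRun-class].
#' @export
runMcmc <- function(ds, layers = layerDefinition(ds), pm, settings,
                    initMode = c("pk_seeded", "empty"),
                    hp = bgeHyperparameters(ds),
                    candidates = candidateEdges(ds, layers),
                    checkpointPath = NULL, checkpointEvery = 10000L,
                    stopAfter = NULL) {
  initMode <- match.arg(initMode)
  if (!identical(names(pm@b@values),
                 .edgeKey(candidates@edges$parent, candidates@edges$child)))
    stop("prior matrix does not cover the candidate edge set", call. = FALSE)
  if (!is.null(stopAfter) && is.null(checkpointPath))
    stop("stopAfter requires checkpointPath", call. = FALSE)

  sc <- newScoreCache(ds, hp)
  if (!identical(names(sc$nodeIndex), candidates@nodes$id))
    stop("candidate set does not match the dataset's node order",
         call. = FALSE)
  tdiag <- hp@tMatrix[1, 1]
  if (any(hp@tMatrix != diag(tdiag, nrow(hp@tMatrix))))
    stop("the sampler requires a scalar-diagonal tMatrix ",
         "(as built by bgeHyperparameters)", call. = FALSE)
  cm <- .candMatrices(candidates, layers@fanInMax)

  p1Iters <- as.integer(round(settings@phase1Fraction *
                                settings@totalIterations))
  mkPhase <- function(iters, burnIn, thin) {
    list(iters = iters, burnIn = burnIn, thin = thin,
         logScore = numeric(iters), logPrior = numeric(iters),
         beta = numeric(iters), snapshots = list(),
         snapshotIter = integer(0),
         accepted = setNames(integer(4),
                             c("add", "delete", "reverse", "beta")),
         proposed = setNames(integer(4),
                             c("add", "delete", "reverse", "beta")))
  }
  ph <- list(mkPhase(p1Iters, p1Iters %/% 2L, settings@thin),
             mkPhase(settings@totalIterations, settings@burnIn,
                     settings@thin))

  state <- new.env(parent = emptyenv())
  resume <- !is.null(checkpointPath) && file.exists(checkpointPath)
  bvals1 <- unname(pm@b@values)
  if (resume) {
    .loadCheckpoint(checkpointPath, state, ph, settings)
    ph <- state$ph
    adj <- .adjFromEdgeIdx(cm, candidates, state$edgeIdx)
    assign(".Random.seed", state$randomSeed, envir = globalenv())
  } else {
    set.seed(settings@seed)
    g0 <- initialStructure(candidates, layers, mode = initMode, b = pm@b)
    adj <- .adjFromEdgeIdx(cm, candidates, g0@edgeIdx)
    state$phase <- 1L
    state$iterDone <- 0L
    state$globalIter <- 0L
    state$beta <- settings@betaInit
    state$prior2 <- NULL
    state$localSc <- as.numeric(.cppLocalScores(adj, cm$candRow,
      cm$layerCode, cm$fanIn, bvals1, sc$R, tdiag, hp@alphaMu, hp@alphaW,
      sc$N))
    state$total <- sum(state$localSc)
    a <- numeric(length(bvals1)); a[g0@edgeIdx] <- 1
    state$E <- sum(abs(bvals1 - a))
  }

  while (state$phase <= 2L) {
    p <- state$phase
    cur <- ph[[p]]
    bcur <- if (p == 1L) bvals1 else unname(state$prior2@values)
    while (state$iterDone < cur$iters) {
      n <- cur$iters - state$iterDone
      if (!is.null(checkpointPath))
        n <- min(n, checkpointEvery -
                   state$globalIter %% checkpointEvery)
      if (!is.null(stopAfter))
        n <- min(n, stopAfter - state$globalIter)
      res <- .cppSampleChunk(adj, cm$candRow, cm$layerCode, cm$fanIn, bcur,
        sc$R, tdiag, hp@alphaMu, hp@alphaW, sc$N, state$localSc,
        state$total, state$E, state$beta, as.integer(n), state$iterDone,
        cur$burnIn, cur$thin, settings@sampleBeta, pm@betaMax, 0.5)
      sl <- (state$iterDone + 1L):(state$iterDone + n)
      cur$logScore[sl] <- res$logScore
      cur$logPrior[sl] <- res$logPrior
      cur$beta[sl] <- res$betaSeries
      if (length(res$snapshots)) {
        cur$snapshots <- c(cur$snapshots, lapply(res$snapshots, as.integer))
        cur$snapshotIter <- c(cur$snapshotIter,
                              as.integer(res$snapshotIter))
      }
      cur$accepted <- cur$accepted + as.integer(res$accepted)
      cur$proposed <- cur$proposed + as.integer(res$proposed)
      adj <- res$adj
      state$localSc <- res$localSc
      state$total <- res$total
      state$E <- res$E
      state$beta <- res$beta
      state$iterDone <- state$iterDone + as.integer(n)
      state$globalIter <- state$globalIter + as.integer(n)
      state$edgeIdx <- sort(cm$candRow[adj > 0L])
      if (!is.null(checkpointPath)) {
        ph[[p]] <- cur
        .saveCheckpoint(checkpointPath, state, ph, settings)
      }
      if (!is.null(stopAfter) && state$globalIter >= stopAfter)
        return(structure(list(interrupted = TRUE,
                              checkpoint = checkpointPath),
                         class = "McmcInterrupt"))
    }
    ph[[p]] <- cur
    if (p == 1L) {
      if (is.null(state$prior2)) {
        # no adaptation phase -> keep the input prior untouched
        state$prior2 <- if (p1Iters > 0L) {
          tr1 <- .phaseToTrace(ph[[1]], candidates, settings,
                               p1Iters %/% 2L)
          w1 <- if (length(tr1@snapshots)) edgeWeights(tr1)
            else setNames(numeric(nrow(candidates@edges)),
                          names(pm@b@values))
          empiricalPriorUpdate(pm@b, w1)
        } else pm@b
      }
      bnew <- unname(state$prior2@values)
      a <- numeric(length(bnew)); a[state$edgeIdx] <- 1
      state$E <- sum(abs(bnew - a))
      state$phase <- 2L
      state$iterDone <- 0L
    } else state$phase <- 3L
  }
  if (!is.null(checkpointPath) && file.exists(checkpointPath))
    unlink(checkpointPath)

  tr1 <- .phaseToTrace(ph[[1]], candidates, settings, p1Iters %/% 2L)
  tr2 <- .phaseToTrace(ph[[2]], candidates, settings, settings@burnIn)
  new("McmcRun", trace = tr2, phase1 = tr1, prior = state$prior2,
      priorInput = pm@b, settings = settings)
}

.phaseToTrace <- function(p, candidates, settings, burnIn) {
  new("PosteriorTrace", candidates = candidates, snapshots = p$snapshots,
      snapshotIter = p$snapshotIter, logScore = p$logScore,
      logPrior = p$logPrior, beta = p$beta, accepted = p$accepted,
      proposed = p$proposed, burnIn = as.integer(burnIn),
      thin = settings@thin, seed = settings@seed)
}

setMethod("show", "McmcRun", function(object) {
  cat("McmcRun:", length(object@trace@snapshots), "phase-2 snapshots over",
      length(object@trace@logScore), "iterations\n")
  acc <- object@trace@accepted / pmax(object@trace@proposed, 1L)
  cat("  acceptance:", paste(names(acc), sprintf("%.2f", acc),
                             collapse = ", "), "\n")
})

setMethod("show", "PosteriorTrace", function(object) {
  cat("PosteriorTrace:", length(object@snapshots), "snapshots,",
      length(object@logScore), "iterations, burn-in", object@burnIn,
      ", thin", object@thin, "\n")
})

# ---- checkpointing ---------------------------------------------------------

.saveCheckpoint <- function(path, state, ph, settings) {
  phSer <- lapply(ph, function(p) list(
    iters = p$iters, burnIn = p$burnIn, thin = p$thin,
    logScore = .num2chr(p$logScore), logPrior = .num2chr(p$logPrior),
    beta = .num2chr(p$beta), snapshots = p$snapshots,
    snapshotIter = p$snapshotIter, accepted = p$accepted,
    proposed = p$proposed))
  obj <- list(
    format = "OmicsBN-checkpoint-1",
    settingsKey = .settingsKey(settings),
    phase = state$phase, iterDone = state$iterDone,
    globalIter = state$globalIter,
    beta = .num2chr(state$beta),
    edgeIdx = state$edgeIdx,
    total = .num2chr(state$total), E = .num2chr(state$E),
    localSc = .num2chr(state$localSc),
    randomSeed = get(".Random.seed", envir = globalenv()),
    ph = phSer,
    prior2 = if (!is.null(state$prior2))
      list(values = .num2chr(state$prior2@values),
           keys = names(state$prior2@values),
           provenance = unname(state$prior2@provenance))
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, null = "null")
  file.rename(tmp, path)
  invisible(path)
}

.loadCheckpoint <- function(path, state, phTemplate, settings) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr <- function(x) vapply(x, as.character, character(1))
  num <- function(x) .chr2num(chr(x))
  int <- function(x) vapply(x, as.integer, integer(1))
  if (!identical(obj$format, "OmicsBN-checkpoint-1"))
    stop("unrecognized checkpoint format in ", path, call. = FALSE)
  if (!identical(obj$settingsKey, .settingsKey(settings)))
    stop("checkpoint in ", path, " was written with different settings",
         call. = FALSE)
  state$phase <- as.integer(obj$phase)
  state$iterDone <- as.integer(obj$iterDone)
  state$globalIter <- as.integer(obj$globalIter)
  state$beta <- .chr2num(obj$beta)
  state$edgeIdx <- int(obj$edgeIdx)
  state$total <- .chr2num(obj$total)
  state$E <- .chr2num(obj$E)
  state$localSc <- num(obj$localSc)
  state$randomSeed <- int(obj$randomSeed)
  ph <- phTemplate
  for (i in 1:2) {
    src <- obj$ph[[i]]
    done <- if (state$phase > i) ph[[i]]$iters
            else if (state$phase == i) state$iterDone else 0L
    if (done > 0) {
      ph[[i]]$logScore[1:done] <- num(src$logScore)[1:done]
      ph[[i]]$logPrior[1:done] <- num(src$logPrior)[1:done]
      ph[[i]]$beta[1:done] <- num(src$beta)[1:done]
    }
    ph[[i]]$snapshots <- lapply(src$snapshots, int)
    ph[[i]]$snapshotIter <- int(src$snapshotIter)
    ph[[i]]$accepted <- setNames(int(src$accepted),
                                 names(phTemplate[[i]]$accepted))
    ph[[i]]$proposed <- setNames(int(src$proposed),
                                 names(phTemplate[[i]]$proposed))
  }
  if (!is.null(obj$prior2) && length(obj$prior2)) {
    keys <- chr(obj$prior2$keys)
    state$prior2 <- new("PriorMatrix",
      values = setNames(num(obj$prior2$values), keys),
      provenance = setNames(chr(obj$prior2$provenance), keys))
  }
  state$ph <- ph
  invisible(state)
}

.settingsKey <- function(s) {
  paste(s@totalIterations, s@burnIn, s@thin, s@seed, s@phase1Fraction,
        s@sampleBeta, s@betaInit, sep = "/")
}
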