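makeMcmcFixture <- function(seed = 31) {
  gt <- generateTrueNetwork(5, edgeProb = 0.3, pCnv = 0.6,
                            probesPerGene = 1, seed = seed)
  ds <- simulateDataset(gt, 60, seed = seed + 1)
  layers <- layerDefinition(ds)
  cands <- candidateEdges(ds, layers)
  b <- buildPriorMatrix(cands)
  list(gt = gt, ds = ds, layers = layers, cands = cands,
       pm = priorModel(b, beta = 1, betaMax = 10, sampleBeta = TRUE))
}

test_that("the move enumeration matches a brute-force legality check", {
  fx <- makeMcmcFixture()
  set.seed(1)
  g <- initialStructure(fx$cands, fx$layers, mode = "empty")
  # walk a few random legal moves to land on a nontrivial structure
  for (k in 1:15) {
    mv <- legalMoves(g)
    m <- mv[sample(nrow(mv), 1), ]
    e <- structureEdges(g)[, c("parent", "child")]
    e2 <- switch(m$type,
      add = rbind(e, data.frame(parent = m$parent, child = m$child)),
      delete = e[!(e$parent == m$parent & e$child == m$child), ],
      reverse = rbind(e[!(e$parent == m$parent & e$child == m$child), ],
                      data.frame(parent = m$child, child = m$parent)))
    g <- networkStructure(fx$cands, e2, fx$layers)
  }
  mv <- legalMoves(g)
  # brute force: try every conceivable single-edge change through the
  # validating constructor
  e <- structureEdges(g)[, c("parent", "child")]
  key <- paste(e$parent, e$child)
  ok <- function(tab) !inherits(try(networkStructure(fx$cands, tab,
                                                     fx$layers),
                                    silent = TRUE), "try-error")
  expected <- list()
  for (r in seq_len(nrow(edgeTable(fx$cands)))) {
    p <- edgeTable(fx$cands)$parent[r]; ch <- edgeTable(fx$cands)$child[r]
    if (paste(p, ch) %in% key) {
      expected[[length(expected) + 1]] <- c("delete", p, ch)
      rest <- e[key != paste(p, ch), ]
      rev <- rbind(rest, data.frame(parent = ch, child = p))
      if (paste(ch, p) %in% paste(edgeTable(fx$cands)$parent,
                                  edgeTable(fx$cands)$child) && ok(rev))
        expected[[length(expected) + 1]] <- c("reverse", p, ch)
    } else if (ok(rbind(e, data.frame(parent = p, child = ch)))) {
      expected[[length(expected) + 1]] <- c("add", p, ch)
    }
  }
  expMat <- do.call(rbind, expected)
  expect_setequal(paste(mv$type, mv$parent, mv$child),
                  paste(expMat[, 1], expMat[, 2], expMat[, 3]))
})

test_that("pk-seeded initial structures honor the curated edges and limits", {
  fx <- makeMcmcFixture()
  pk <- data.frame(src_gene = c("G01", "G02"), dst_gene = c("G02", "G03"),
                   edge_type = "present")
  b <- buildPriorMatrix(fx$cands, pk = pk)
  g <- initialStructure(fx$cands, fx$layers, mode = "pk_seeded", b = b,
                        seed = 1)
  e <- structureEdges(g)
  expect_setequal(paste(e$parent, e$child), c("G01 G02", "G02 G03"))
  expect_identical(
    structureEdges(initialStructure(fx$cands, fx$layers, "empty")),
    structureEdges(networkStructure(fx$cands, integer(0), fx$layers)))
})

test_that("identical seeds give identical runs and snapshots are valid DAGs", {
  fx <- makeMcmcFixture()
  st <- mcmcSettings(1500, burnIn = 300, thin = 10, seed = 77)
  r1 <- runMcmc(fx$ds, fx$layers, fx$pm, st, candidates = fx$cands)
  r2 <- runMcmc(fx$ds, fx$layers, fx$pm, st, candidates = fx$cands)
  expect_identical(r1@trace@logScore, r2@trace@logScore)
  expect_identical(r1@trace@snapshots, r2@trace@snapshots)
  expect_identical(priorValues(r1@prior), priorValues(r2@prior))
  for (s in r1@trace@snapshots)
    expect_s4_class(networkStructure(fx$cands, s, fx$layers),
                    "NetworkStructure")
})

test_that("total = burn-in + thin yields exactly one snapshot", {
  fx <- makeMcmcFixture()
  st <- mcmcSettings(120, burnIn = 100, thin = 20, seed = 5)
  run <- runMcmc(fx$ds, fx$layers, fx$pm, st, candidates = fx$cands)
  expect_length(run@trace@snapshots, 1L)
  expect_identical(run@trace@snapshotIter, 120L)
  expect_length(run@trace@logScore, 120L)
})

test_that("incremental scores agree with full rescoring at run end", {
  fx <- makeMcmcFixture()
  st <- mcmcSettings(800, burnIn = 100, thin = 700, seed = 12)
  run <- runMcmc(fx$ds, fx$layers, fx$pm, st, candidates = fx$cands)
  snap <- run@trace@snapshots[[length(run@trace@snapshots)]]
  g <- networkStructure(fx$cands, snap, fx$layers)
  cache <- newScoreCache(fx$ds)
  expect_equal(bgeNetworkScore(g, cache),
               run@trace@logScore[run@trace@snapshotIter[
                 length(run@trace@snapshotIter)]],
               tolerance = 1e-9)
})

test_that("2-node edge frequencies match the enumerated posterior", {
  ds <- makeGeDataset(25, c("A", "B"), seed = 41)
  layers <- layerDefinition(ds)
  cands <- candidateEdges(ds, layers)
  b <- buildPriorMatrix(cands)
  pm <- priorModel(b, beta = 0, sampleBeta = FALSE)
  cache <- newScoreCache(ds)
  structs <- list(integer(0), 1L, 2L)
  sc <- vapply(structs, function(idx)
    bgeNetworkScore(networkStructure(cands, idx, layers), cache),
    numeric(1))
  post <- exp(sc - max(sc)); post <- post / sum(post)
  st <- mcmcSettings(100000, burnIn = 2000, thin = 1, seed = 8,
                     phase1Fraction = 0, sampleBeta = FALSE, betaInit = 0)
  run <- runMcmc(ds, layers, pm, st, candidates = cands,
                 initMode = "empty")
  w <- edgeWeights(run@trace)
  expect_lt(abs(w[["A->B"]] - post[2]), 0.02)
  expect_lt(abs(w[["B->A"]] - post[3]), 0.02)
})

test_that("disabling beta sampling freezes beta; b = 0.5 makes it uniform", {
  ds <- makeGeDataset(20, c("A", "B"), seed = 51)
  layers <- layerDefinition(ds)
  cands <- candidateEdges(ds, layers)
  b <- buildPriorMatrix(cands)
  pmFix <- priorModel(b, beta = 2.5, sampleBeta = FALSE)
  st <- mcmcSettings(2000, burnIn = 200, thin = 10, seed = 2,
                     phase1Fraction = 0, sampleBeta = FALSE,
                     betaInit = 2.5)
  run <- runMcmc(ds, layers, pmFix, st, candidates = cands,
                 initMode = "empty")
  expect_true(all(run@trace@beta == 2.5))
  expect_identical(run@trace@proposed[["beta"]], 0L)
  # b identically 0.5: every beta proposal is accepted and the chain is a
  # reflected random walk, uniform on [0, betaMax] in the long run
  pmU <- priorModel(b, beta = 1, betaMax = 10, sampleBeta = TRUE)
  stU <- mcmcSettings(60000, burnIn = 10000, thin = 10, seed = 3,
                      phase1Fraction = 0)
  runU <- runMcmc(ds, layers, pmU, stU, candidates = cands,
                  initMode = "empty")
  expect_identical(runU@trace@accepted[["beta"]],
                   runU@trace@proposed[["beta"]])
  bt <- runU@trace@beta[-(1:10000)]
  expect_gt(mean(bt), 2.5)
  expect_lt(mean(bt), 7.5)
  expect_gt(max(bt), 8); expect_lt(min(bt), 2)
})

test_that("a structure contradicting a concentrated prior pulls beta down", {
  ds <- makeGeDataset(30, c("A", "B", "C"), seed = 61)
  layers <- layerDefinition(ds)
  cands <- candidateEdges(ds, layers)
  # prior insists on edges the data do not support (independent columns)
  pk <- data.frame(src_gene = c("A", "B", "C", "A", "B", "C"),
                   dst_gene = c("B", "C", "A", "C", "A", "B"),
                   edge_type = "present")
  b <- buildPriorMatrix(cands, pk = pk)
  pm <- priorModel(b, beta = 5, betaMax = 10, sampleBeta = TRUE)
  st <- mcmcSettings(30000, burnIn = 5000, thin = 10, seed = 4,
                     phase1Fraction = 0, betaInit = 5)
  run <- runMcmc(ds, layers, pm, st, candidates = cands,
                 initMode = "empty")
  expect_lt(mean(run@trace@beta[-(1:5000)]), 5)
})

test_that("interrupted runs resume from checkpoint to the identical result", {
  fx <- makeMcmcFixture()
  st <- mcmcSettings(2000, burnIn = 400, thin = 10, seed = 19)
  ref <- runMcmc(fx$ds, fx$layers, fx$pm, st, candidates = fx$cands)
  cp <- withr::local_tempfile(fileext = ".json")
  intr <- runMcmc(fx$ds, fx$layers, fx$pm, st, candidates = fx$cands,
                  checkpointPath = cp, checkpointEvery = 500,
                  stopAfter = 1700)
  expect_s3_class(intr, "McmcInterrupt")
  expect_true(file.exists(cp))
  res <- runMcmc(fx$ds, fx$layers, fx$pm, st, candidates = fx$cands,
                 checkpointPath = cp, checkpointEvery = 500)
  expect_identical(ref@trace@logScore, res@trace@logScore)
  expect_identical(ref@trace@snapshots, res@trace@snapshots)
  expect_identical(ref@trace@beta, res@trace@beta)
  expect_identical(priorValues(ref@prior), priorValues(res@prior))
  expect_false(file.exists(cp))
  # a checkpoint from different settings is refused
  intr2 <- runMcmc(fx$ds, fx$layers, fx$pm, st, candidates = fx$cands,
                   checkpointPath = cp, checkpointEvery = 500,
                   stopAfter = 600)
  stOther <- mcmcSettings(2000, burnIn = 400, thin = 10, seed = 20)
  expect_error(runMcmc(fx$ds, fx$layers, fx$pm, stOther,
                       candidates = fx$cands, checkpointPath = cp),
               "different settings")
  unlink(cp)
})

test_that("acceptance counters account for every iteration", {
  fx <- makeMcmcFixture()
  st <- mcmcSettings(1000, burnIn = 200, thin = 10, seed = 23,
                     phase1Fraction = 0)
  run <- runMcmc(fx$ds, fx$layers, fx$pm, st, candidates = fx$cands)
  pr <- run@trace@proposed
  d <- nrow(nodeTable(fx$cands))
  expect_identical(sum(pr[c("add", "delete", "reverse")]), 1000L)
  expect_identical(pr[["beta"]], 1000L %/% d)
  expect_true(all(run@trace@accepted <= pr))
})
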