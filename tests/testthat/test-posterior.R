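makeTraceFixture <- function() {
  ds <- makeGeDataset(6, c("A", "B", "C"), seed = 71)
  layers <- layerDefinition(ds)
  cands <- candidateEdges(ds, layers)
  list(ds = ds, layers = layers, cands = cands)
}

fakeTrace <- function(cands, snapshots, snapshotIter, logScore = NULL,
                      logPrior = NULL, burnIn = 0L, thin = 1L) {
  n <- max(snapshotIter)
  if (is.null(logScore)) logScore <- numeric(n)
  if (is.null(logPrior)) logPrior <- numeric(n)
  cnt <- setNames(integer(4), c("add", "delete", "reverse", "beta"))
  new("PosteriorTrace", candidates = cands, snapshots = snapshots,
      snapshotIter = as.integer(snapshotIter), logScore = logScore,
      logPrior = logPrior, beta = numeric(n), accepted = cnt,
      proposed = cnt, burnIn = as.integer(burnIn), thin = as.integer(thin),
      seed = 1L)
}

test_that("edge weights are empirical snapshot frequencies", {
  fx <- makeTraceFixture()
  # candidate rows: use edges 1 and 3 with known frequencies
  tr <- fakeTrace(fx$cands,
                  snapshots = list(1L, c(1L, 3L), integer(0), 1L),
                  snapshotIter = c(10, 20, 30, 40), thin = 10L)
  w <- edgeWeights(tr)
  expect_equal(unname(w[1]), 0.75)
  expect_equal(unname(w[3]), 0.25)
  expect_equal(sum(w > 0), 2)
  expect_named(w, OmicsBN:::.edgeKey(edgeTable(fx$cands)$parent,
                                     edgeTable(fx$cands)$child))
  # extra burn-in / thinning subsample the recorded snapshots
  w2 <- edgeWeights(tr, burnIn = 10, thin = 20)
  expect_equal(unname(w2[1]), 1)      # snapshots at 20 and 40 retained
  expect_equal(unname(w2[3]), 0.5)
  expect_error(edgeWeights(tr, burnIn = 40), "burnIn")
})

test_that("quantile thresholding keeps ties and ignores zero weights", {
  w <- c("a->b" = 0.9, "b->a" = 0.2, "a->c" = 0.6, "c->a" = 0.6,
         "b->c" = 0, "c->b" = 0)
  kept <- thresholdEdges(w, mode = "quantile", value = 0.75)
  # 75% quantile of the nonzero weights (0.9, 0.2, 0.6, 0.6) = 0.675
  expect_setequal(kept, "a->b")
  kept2 <- thresholdEdges(w, mode = "quantile", value = 0.5)
  expect_setequal(kept2, c("a->b", "a->c", "c->a"))
  expect_setequal(thresholdEdges(w, mode = "absolute", value = 0.6),
                  c("a->b", "a->c", "c->a"))
  expect_error(thresholdEdges(w, mode = "quantile", value = 1.5), "\\[0")
})

test_that("CPDAG labelling keeps v-structures directed, chains undirected", {
  fx <- makeTraceFixture()
  chain <- networkStructure(fx$cands,
                            data.frame(parent = c("A", "B"),
                                       child = c("B", "C")), fx$layers)
  lab <- toCpdag(chain)
  expect_false(any(lab$compelled))
  vs <- networkStructure(fx$cands,
                         data.frame(parent = c("A", "C"),
                                    child = c("B", "B")), fx$layers)
  lab2 <- toCpdag(vs)
  expect_true(all(lab2$compelled))
})

test_that("cross-layer edges are always compelled in the CPDAG", {
  n <- 8
  sm <- paste0("s", 1:n)
  ge <- matrix(rnorm(n * 2), n, 2, dimnames = list(sm, c("A", "B")))
  cnv <- matrix(rnorm(n), n, 1, dimnames = list(sm, "A"))
  ds <- omicsDataset(ge, cnv = cnv)
  layers <- layerDefinition(ds)
  cands <- candidateEdges(ds, layers)
  g <- networkStructure(cands,
                        data.frame(parent = c("cnv_A", "A"),
                                   child = c("A", "B")), layers)
  lab <- toCpdag(g)
  expect_true(lab$compelled[lab$parent == "cnv_A"])
})

test_that("weighted networks collapse bidirected pairs into skeleton edges", {
  fx <- makeTraceFixture()
  w <- setNames(numeric(nrow(edgeTable(fx$cands))),
                OmicsBN:::.edgeKey(edgeTable(fx$cands)$parent,
                                   edgeTable(fx$cands)$child))
  w[["A->B"]] <- 0.55; w[["B->A"]] <- 0.40; w[["B->C"]] <- 0.80
  net <- weightedNetwork(w, fx$cands, fx$layers, mode = "absolute",
                         value = 0.4)
  e <- networkEdges(net)
  ab <- e[(e$parent == "A" & e$child == "B") |
            (e$parent == "B" & e$child == "A"), ]
  expect_equal(nrow(ab), 1)
  expect_false(ab$directed)
  expect_equal(ab$weight, 0.95)
  expect_true(all(e$weight >= 0 & e$weight <= 1))
})

test_that("binary segmentation finds a planted mean shift and no false ones", {
  fx <- makeTraceFixture()
  set.seed(88)
  n <- 400
  shifted <- c(rnorm(200, 0, 0.3), rnorm(200, 3, 0.3))
  tr <- fakeTrace(fx$cands,
                  snapshots = rep(list(integer(0)), n),
                  snapshotIter = seq_len(n), logScore = shifted)
  rep1 <- convergenceCheck(tr, minseglen = 50)
  expect_false(rep1@converged)
  expect_true(any(abs(rep1@changepoints - 200) <= 5))

  flat <- rnorm(n, 0, 0.3)
  tr2 <- fakeTrace(fx$cands, snapshots = rep(list(integer(0)), n),
                   snapshotIter = seq_len(n), logScore = flat)
  rep2 <- convergenceCheck(tr2, minseglen = 50)
  expect_true(rep2@converged)
  expect_length(rep2@changepoints, 0)
  expect_error(convergenceCheck(tr2, minseglen = 10000), "too short")
})

test_that("network exports round trip (TSV) and parse (GraphML, SIF)", {
  fx <- makeTraceFixture()
  w <- setNames(numeric(nrow(edgeTable(fx$cands))),
                OmicsBN:::.edgeKey(edgeTable(fx$cands)$parent,
                                   edgeTable(fx$cands)$child))
  w[["A->B"]] <- 0.9; w[["B->C"]] <- 0.7
  net <- weightedNetwork(w, fx$cands, fx$layers, mode = "absolute",
                         value = 0.5)
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "net.tsv")
  exportNetwork(net, tsv, "tsv")
  back <- importNetwork(tsv)
  expect_equal(networkEdges(back)$weight, networkEdges(net)$weight)
  expect_equal(networkEdges(back)$parent, networkEdges(net)$parent)

  sif <- file.path(dir, "net.sif")
  exportNetwork(net, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, nrow(networkEdges(net)))
  expect_true(all(grepl("\tGE-GE\t", lines)))

  gml <- file.path(dir, "net.graphml")
  exportNetwork(net, gml, "graphml")
  doc <- xml2::read_xml(gml)
  expect_match(xml2::xml_ns(doc)[[1]], "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(networkEdges(net)))
  expect_equal(sort(igraph::E(g)$weight),
               sort(networkEdges(net)$weight))
})

test_that("diagnostic plots are written as nonempty PNG files", {
  fx <- makeTraceFixture()
  set.seed(9)
  tr <- fakeTrace(fx$cands, snapshots = rep(list(1L), 100),
                  snapshotIter = seq_len(100),
                  logScore = rnorm(100), burnIn = 10L)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "trace.png")
  tracePlot(tr, p1)
  expect_gt(file.size(p1), 0)
  w <- setNames(numeric(nrow(edgeTable(fx$cands))),
                OmicsBN:::.edgeKey(edgeTable(fx$cands)$parent,
                                   edgeTable(fx$cands)$child))
  w[["A->B"]] <- 0.9
  net <- weightedNetwork(w, fx$cands, fx$layers, mode = "absolute",
                         value = 0.5)
  p2 <- file.path(dir, "network.png")
  networkPlot(net, p2)
  expect_gt(file.size(p2), 0)
})
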