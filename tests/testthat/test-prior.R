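makePriorFixture <- function() {
  ds <- makeGeDataset(6, c("A", "B", "C"), seed = 9)
  layers <- layerDefinition(ds)
  cands <- candidateEdges(ds, layers)
  list(ds = ds, layers = layers, cands = cands)
}

test_that("prior matrix encodes curated, TF and default beliefs", {
  fx <- makePriorFixture()
  pk <- data.frame(src_gene = c("A", "B", "Z"),
                   dst_gene = c("B", "C", "A"),
                   edge_type = c("present", "absent", "present"))
  tf <- data.frame(TF = c("A", "C"), target = c("C", "B"))
  expect_message(b <- buildPriorMatrix(fx$cands, pk = pk, tfTargets = tf),
                 "1 prior-knowledge row")
  v <- priorValues(b); pr <- priorProvenance(b)
  expect_equal(v[["A->B"]], 0.99)
  expect_equal(v[["B->C"]], 0.01)
  expect_identical(pr[["A->B"]], "curated")
  expect_equal(v[["A->C"]], 0.99)
  expect_identical(pr[["A->C"]], "tf_target")
  expect_equal(v[["B->A"]], 0.5)
  expect_identical(pr[["B->A"]], "default")
  # curated beats tf_target when both name an edge
  pk2 <- data.frame(src_gene = "A", dst_gene = "C", edge_type = "absent")
  b2 <- buildPriorMatrix(fx$cands, pk = pk2, tfTargets = tf)
  expect_equal(priorValues(b2)[["A->C"]], 0.01)
  expect_identical(priorProvenance(b2)[["A->C"]], "curated")
})

test_that("graph energy sums belief deviations over candidate edges", {
  fx <- makePriorFixture()
  pk <- data.frame(src_gene = "A", dst_gene = "B", edge_type = "present")
  b <- buildPriorMatrix(fx$cands, pk = pk)
  g <- networkStructure(fx$cands,
                        data.frame(parent = "A", child = "B"), fx$layers)
  # A->B present (|0.99 - 1|), five default edges absent (|0.5 - 0|)
  expect_equal(graphEnergy(g, b), 0.01 + 5 * 0.5)
  g0 <- networkStructure(fx$cands, integer(0), fx$layers)
  expect_equal(graphEnergy(g0, b), 0.99 + 5 * 0.5)
})

test_that("log structure prior matches the stated formula", {
  fx <- makePriorFixture()
  b <- buildPriorMatrix(fx$cands)
  pm <- priorModel(b, beta = 1.7, sampleBeta = FALSE)
  g <- networkStructure(fx$cands,
                        data.frame(parent = "A", child = "B"), fx$layers)
  bv <- priorValues(b)
  logZ <- sum(log(exp(-1.7 * bv) + exp(-1.7 * (1 - bv))))
  expect_equal(logStructurePrior(g, pm),
               -1.7 * graphEnergy(g, b) - logZ, tolerance = 1e-12)
  pm0 <- priorModel(b, beta = 0, sampleBeta = FALSE)
  # beta = 0: flat over structures
  g2 <- networkStructure(fx$cands,
                         data.frame(parent = "B", child = "C"), fx$layers)
  expect_equal(logStructurePrior(g, pm0), logStructurePrior(g2, pm0))
})

test_that("empirical update clamps frequencies and spares curated entries", {
  fx <- makePriorFixture()
  pk <- data.frame(src_gene = "A", dst_gene = "B", edge_type = "present")
  b <- buildPriorMatrix(fx$cands, pk = pk)
  w <- c("A->B" = 0.1, "B->A" = 0.995, "A->C" = 0.4)
  b2 <- empiricalPriorUpdate(b, w)
  v <- priorValues(b2); pr <- priorProvenance(b2)
  expect_equal(v[["A->B"]], 0.99)          # curated untouched
  expect_identical(pr[["A->B"]], "curated")
  expect_equal(v[["B->A"]], 0.99)          # clamped from above
  expect_equal(v[["A->C"]], 0.4)
  expect_equal(v[["C->A"]], 0.01)          # missing key -> frequency 0
  expect_true(all(pr[names(pr) != "A->B"] == "empirical"))
  expect_error(empiricalPriorUpdate(b, c("A->C" = 1.2)), "\\[0,1\\]")
})

test_that("prior matrix round trips through its TSV representation", {
  fx <- makePriorFixture()
  pk <- data.frame(src_gene = "A", dst_gene = "B", edge_type = "present")
  b <- buildPriorMatrix(fx$cands, pk = pk)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePriorMatrix(b, path)
  df <- read.delim(path)
  expect_equal(nrow(df), length(priorValues(b)))
  expect_equal(df$belief[df$parent == "A" & df$child == "B"], 0.99)
  pkPath <- withr::local_tempfile(fileext = ".tsv")
  write.table(pk, pkPath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(readPriorKnowledge(pkPath)$edge_type, "present")
  bad <- data.frame(src_gene = "A", dst_gene = "B", edge_type = "maybe")
  write.table(bad, pkPath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readPriorKnowledge(pkPath), "malformed edge_type")
})
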