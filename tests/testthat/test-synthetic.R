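test_that("generated ground truths are layered DAGs within the limits", {
  gt <- generateTrueNetwork(12, edgeProb = 0.3, pCnv = 0.5,
                            probesPerGene = 2, noiseProbesPerGene = 1,
                            fanInMax = 3, seed = 2)
  e <- trueEdges(gt)
  expect_false(OmicsBN:::.hasCycle(e$parent, e$child))
  geE <- e[!grepl("^cnv_|^cg", e$parent), ]
  expect_true(all(table(factor(geE$child, levels = gt@nodes$id)) <= 3))
  expect_true(all(abs(e$coef) >= 0.5 & abs(e$coef) <= 1.5))
  # noise probes exist as nodes but never as parents
  noise <- gt@nodes$id[grepl("^cg.*_n\\d+$", gt@nodes$id)]
  expect_length(noise, 12)
  expect_false(any(e$parent %in% noise))
  expect_identical(trueEdges(generateTrueNetwork(12, edgeProb = 0.3,
                                                 pCnv = 0.5,
                                                 probesPerGene = 2,
                                                 noiseProbesPerGene = 1,
                                                 fanInMax = 3, seed = 2)),
                   e)
})

test_that("simulated data follow the structural equations", {
  gt <- generateTrueNetwork(6, edgeProb = 0, pCnv = 0, probesPerGene = 0,
                            seed = 3)
  expect_equal(nrow(trueEdges(gt)), 0)
  ds <- simulateDataset(gt, 5000, seed = 4)
  expect_equal(dim(geMatrix(ds)), c(5000, 6))
  # with no edges every gene is its own root: unit-variance noise
  expect_true(all(abs(apply(geMatrix(ds), 2, sd) - 1) < 0.1))

  gt2 <- generateTrueNetwork(2, edgeProb = 1, seed = 5)
  e <- trueEdges(gt2)
  expect_equal(nrow(e), 1)
  ds2 <- simulateDataset(gt2, 5000, seed = 6)
  X <- geMatrix(ds2)
  fit <- lm(X[, e$child] ~ X[, e$parent])
  expect_equal(unname(coef(fit)[2]), e$coef, tolerance = 0.05)
  expect_equal(summary(fit)$sigma, gt2@noiseSd[[e$child]],
               tolerance = 0.05)
  expect_identical(geMatrix(simulateDataset(gt2, 10, seed = 7)),
                   geMatrix(simulateDataset(gt2, 10, seed = 7)))
})

test_that("prior corruption keeps the requested true/false mix", {
  gt <- generateTrueNetwork(10, edgeProb = 0.4, seed = 8)
  e <- trueEdges(gt)
  geEdges <- e[!grepl("^cnv_|^cg", e$parent), ]
  pk <- corruptPrior(gt, trueFrac = 0.5, falseFrac = 0.2, seed = 9)
  expect_true(all(pk$edge_type == "present"))
  keyTrue <- paste(geEdges$parent, geEdges$child)
  keyPk <- paste(pk$src_gene, pk$dst_gene)
  nTrue <- sum(keyPk %in% keyTrue)
  nFalse <- sum(!keyPk %in% keyTrue)
  expect_equal(nTrue, floor(0.5 * nrow(geEdges)))
  expect_equal(nFalse, floor(0.2 * nrow(geEdges)))
  expect_identical(corruptPrior(gt, 0.5, 0.2, seed = 9), pk)
})

test_that("simulated studies round trip through files", {
  gt <- generateTrueNetwork(5, edgeProb = 0.3, pCnv = 1, probesPerGene = 1,
                            seed = 10)
  dir <- withr::local_tempdir()
  files <- simulateToFiles(gt, 30, dir, seed = 11)
  ds <- readOmicsData(files[["ge"]], cnvPath = files[["cnv"]],
                      methPath = files[["meth"]],
                      annotPath = files[["annot"]])
  ref <- simulateDataset(gt, 30, seed = 11)
  expect_equal(geMatrix(ds), geMatrix(ref))
  expect_equal(cnvMatrix(ds), cnvMatrix(ref))
  truth <- read.delim(file.path(dir, "truth_edges.tsv"))
  expect_equal(nrow(truth), nrow(trueEdges(gt)))
  meta <- jsonlite::read_json(file.path(dir, "truth_meta.json"))
  expect_equal(meta$generation_seed, 10)
  expect_equal(meta$simulation_seed, 11)
})
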