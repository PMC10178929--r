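test_that("matrices are aligned by sample id and validated", {
  ge <- matrix(rnorm(12), 4, 3,
               dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  cnv <- matrix(rnorm(8), 4, 2,
                dimnames = list(paste0("s", c(3, 1, 4, 2)), c("A", "B")))
  ds <- omicsDataset(ge, cnv = cnv)
  expect_identical(rownames(cnvMatrix(ds)), rownames(geMatrix(ds)))
  expect_identical(cnvMatrix(ds)["s3", "A"], cnv["s3", "A"])

  cnvBad <- cnv; rownames(cnvBad)[1] <- "s9"
  expect_error(omicsDataset(ge, cnv = cnvBad), "sample sets differ")

  geNA <- ge; geNA[2, 2] <- NA
  expect_error(omicsDataset(geNA), "missing value.*'s2'.*'B'")
})

test_that("probes without a usable gene annotation are dropped loudly", {
  ge <- matrix(rnorm(12), 4, 3,
               dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  meth <- matrix(rnorm(8), 4, 2,
                 dimnames = list(paste0("s", 1:4), c("p1", "p2")))
  pmTab <- data.frame(probe_id = c("p1", "p2"), gene_id = c("A", "ZZZ"))
  expect_warning(ds <- omicsDataset(ge, meth = meth, probeMap = pmTab),
                 "probe")
  expect_identical(colnames(methMatrix(ds)), "p1")
  expect_identical(probeMap(ds)$probe_id, "p1")
  expect_error(omicsDataset(ge, meth = meth), "annotation")
})

test_that("TSV round trip preserves matrices and flags bad cells", {
  ge <- matrix(rnorm(12), 4, 3,
               dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  meth <- matrix(runif(8), 4, 2,
                 dimnames = list(paste0("s", 1:4), c("p1", "p2")))
  pmTab <- data.frame(probe_id = c("p1", "p2"), gene_id = c("A", "B"))
  ds <- omicsDataset(ge, meth = meth, probeMap = pmTab)
  dir <- withr::local_tempdir()
  files <- writeOmicsData(ds, dir)
  ds2 <- readOmicsData(files[["ge"]], methPath = files[["meth"]],
                       annotPath = files[["annot"]])
  expect_equal(geMatrix(ds2), geMatrix(ds))
  expect_equal(methMatrix(ds2), methMatrix(ds))

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("sample_id\tA\tB", "s1\t1.0\toops", "s2\t2\t3"), bad)
  expect_error(readOmicsData(bad), "non-numeric cell.*row 1.*'B'")
})

test_that("probe filter reproduces lm R-squared and slope p-value", {
  set.seed(4)
  n <- 40
  g <- rnorm(n)
  meth <- cbind(p1 = -0.8 * g + rnorm(n, 0, 0.4), p2 = rnorm(n))
  rownames(meth) <- paste0("s", 1:n)
  ge <- matrix(g, n, 1, dimnames = list(paste0("s", 1:n), "A"))
  ds <- omicsDataset(ge, meth = meth,
                     probeMap = data.frame(probe_id = c("p1", "p2"),
                                           gene_id = c("A", "A")))
  mf <- filterMethProbes(ds, rSquaredThres = 0.3, pValThres = 0.05)
  rep <- filterReport(mf)
  for (i in 1:2) {
    fit <- summary(lm(ge[, "A"] ~ meth[, i]))
    expect_equal(rep$r_squared[i], fit$r.squared, tolerance = 1e-12)
    expect_equal(rep$p_value[i], fit$coefficients[2, 4], tolerance = 1e-12)
  }
  expect_identical(rep$retained, c(TRUE, FALSE))
  expect_identical(colnames(methMatrix(filteredDataset(mf))), "p1")
})

test_that("zero-variance probes are dropped with a warning", {
  n <- 10
  ge <- matrix(rnorm(n), n, 1, dimnames = list(paste0("s", 1:n), "A"))
  meth <- matrix(1, n, 1, dimnames = list(paste0("s", 1:n), "p1"))
  ds <- omicsDataset(ge, meth = meth,
                     probeMap = data.frame(probe_id = "p1", gene_id = "A"))
  expect_warning(mf <- filterMethProbes(ds), "zero-variance")
  rep <- filterReport(mf)
  expect_equal(rep$r_squared, 0)
  expect_equal(rep$p_value, 1)
  expect_false(rep$retained)
  expect_null(methMatrix(filteredDataset(mf)))
})
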