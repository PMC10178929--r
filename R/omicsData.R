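#' Construct a multi-omics dataset
#'
#' Aligns the supplied matrices by sample id and validates them. Rows are
#' samples, columns are features. `cnv` columns must use the gene ids of
#' `ge`; `meth` columns are probe ids resolved through `probeMap`. Probes
#' whose gene is absent from `ge` (or that lack an annotation row) are
#' dropped with a warning.
#'
#' @param ge numeric matrix of gene expression, samples x genes.
#' @param cnv optional numeric matrix of copy-number estimates.
#' @param meth optional numeric matrix of methylation levels (beta/M values).
#' @param probeMap data.frame with columns `probe_id`, `gene_id`; required
#'   when `meth` is given.
#' @param geneSymbols optional named character vector gene id -> symbol.
#' @return an [OmicsDataset-class].
#' @examples
#' ge <- matrix(rnorm(12), 4, 3,
#'              dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
#' ds <- omicsDataset(ge)
#' @export
omicsDataset <- function(ge, cnv = NULL, meth = NULL, probeMap = NULL,
                         geneSymbols = character(0)) {
  ge <- .asOmicsMatrix(ge, "ge")
  mats <- list(ge = ge)
  if (!is.null(cnv)) mats$cnv <- .asOmicsMatrix(cnv, "cnv")
  if (!is.null(meth)) {
    if (is.null(probeMap))
      stop("methylation data require a probe annotation (probeMap)",
           call. = FALSE)
    mats$meth <- .asOmicsMatrix(meth, "meth")
  }
  samples <- rownames(ge)
  for (nm in names(mats)[-1]) {
    s <- rownames(mats[[nm]])
    if (!setequal(s, samples)) {
      off <- c(setdiff(samples, s), setdiff(s, samples))
      stop(sprintf("sample sets differ between ge and %s: %s", nm,
                   paste(off, collapse = ", ")), call. = FALSE)
    }
    mats[[nm]] <- mats[[nm]][samples, , drop = FALSE]
  }
  if (!is.null(mats$meth)) {
    probeMap <- as.data.frame(probeMap, stringsAsFactors = FALSE)
    keep <- colnames(mats$meth) %in%
      probeMap$probe_id[probeMap$gene_id %in% colnames(ge)]
    if (!all(keep)) {
      warning(sum(!keep), " methylation probe(s) without a usable gene ",
              "annotation dropped: ",
              paste(utils::head(colnames(mats$meth)[!keep], 5),
                    collapse = ", "), call. = FALSE)
      mats$meth <- mats$meth[, keep, drop = FALSE]
    }
    probeMap <- probeMap[probeMap$probe_id %in% colnames(mats$meth), ,
                         drop = FALSE]
    rownames(probeMap) <- NULL
  } else probeMap <- NULL
  new("OmicsDataset", ge = mats$ge, cnv = mats$cnv, meth = mats$meth,
      probeMap = probeMap, geneSymbols = geneSymbols)
}

.asOmicsMatrix <- function(m, what) {
  m <- as.matrix(m)
  if (!is.numeric(m))
    stop(sprintf("non-numeric values in %s matrix", what), call. = FALSE)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "missing value in %s at sample '%s', feature '%s'; impute upstream",
      what, rownames(m)[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  m
}

#' Read a multi-omics dataset from TSV files
#'
#' Each matrix file is tab-separated with a header row of feature ids and the
#' sample id in the first column. The annotation file has columns `probe_id`
#' and `gene_id`; the optional gene annotation has `gene_id`, `gene_symbol`.
#'
#' @param gePath path to the gene-expression TSV (required).
#' @param cnvPath,methPath optional paths to copy-number / methylation TSVs.
#' @param annotPath probe annotation TSV; required when `methPath` is given.
#' @param geneAnnotPath optional gene-symbol TSV.
#' @return an [OmicsDataset-class].
#' @export
readOmicsData <- function(gePath, cnvPath = NULL, methPath = NULL,
                          annotPath = NULL, geneAnnotPath = NULL) {
  if (!is.null(methPath) && is.null(annotPath))
    stop("methylation data require an annotation file (annotPath)",
         call. = FALSE)
  syms <- character(0)
  if (!is.null(geneAnnotPath)) {
    ga <- utils::read.delim(geneAnnotPath, stringsAsFactors = FALSE)
    syms <- setNames(as.character(ga$gene_symbol), ga$gene_id)
  }
  omicsDataset(
    ge = .readMatrixTSV(gePath),
    cnv = if (!is.null(cnvPath)) .readMatrixTSV(cnvPath),
    meth = if (!is.null(methPath)) .readMatrixTSV(methPath),
    probeMap = if (!is.null(annotPath))
      utils::read.delim(annotPath, stringsAsFactors = FALSE),
    geneSymbols = syms
  )
}

.readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  rn <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))) &
                     !is.na(df[[j]]))[1]
      stop(sprintf("non-numeric cell in %s: row %d, column '%s'",
                   path, if (is.na(bad)) NA_integer_ else bad,
                   names(df)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(df)
  rownames(m) <- rn
  m
}

#' Write a dataset back to the TSV conventions [readOmicsData()] reads
#'
#' @param ds an [OmicsDataset-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named character vector of files written.
#' @export
writeOmicsData <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(ge = file.path(dir, "ge.tsv"))
  .writeMatrixTSV(ds@ge, files["ge"])
  if (!is.null(ds@cnv)) {
    files["cnv"] <- file.path(dir, "cnv.tsv")
    .writeMatrixTSV(ds@cnv, files["cnv"])
  }
  if (!is.null(ds@meth)) {
    files["meth"] <- file.path(dir, "meth.tsv")
    .writeMatrixTSV(ds@meth, files["meth"])
    files["annot"] <- file.path(dir, "annot.tsv")
    utils::write.table(ds@probeMap, files["annot"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(files)
}

.writeMatrixTSV <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @describeIn omicsDataset gene-expression matrix accessor
#' @param ds an [OmicsDataset-class].
#' @export
geMatrix <- function(ds) ds@ge

#' @describeIn omicsDataset copy-number matrix accessor (or NULL)
#' @export
cnvMatrix <- function(ds) ds@cnv

#' @describeIn omicsDataset methylation matrix accessor (or NULL)
#' @export
methMatrix <- function(ds) ds@meth

#' @describeIn omicsDataset sample identifiers
#' @export
sampleIDs <- function(ds) rownames(ds@ge)

#' @describeIn omicsDataset probe -> gene annotation
#' @export
probeMap <- function(ds) ds@probeMap

setMethod("show", "OmicsDataset", function(object) {
  cat("OmicsDataset:", nrow(object@ge), "samples\n")
  cat("  GE  :", ncol(object@ge), "genes\n")
  if (!is.null(object@cnv)) cat("  CNV :", ncol(object@cnv), "genes\n")
  if (!is.null(object@meth)) cat("  METH:", ncol(object@meth), "probes\n")
})

#' Filter methylation probes by regression on their gene's expression
#'
#' For every probe, fits a simple least-squares regression between the
#' mapped gene's expression and the probe's methylation level and records the
#' coefficient of determination R^2 together with the two-sided p-value of
#' the slope (t statistic on n-2 degrees of freedom). A probe is retained
#' when `r_squared >= rSquaredThres` and `p_value <= pValThres`. Probes with
#' zero variance score R^2 = 0, p = 1 and are dropped with a warning.
#'
#' @param ds an [OmicsDataset-class] with methylation data.
#' @param rSquaredThres minimal R^2 for retention (default 0.3).
#' @param pValThres maximal slope p-value for retention (default 0.05).
#' @return a [MethFilterResult-class]; `filterReport()` gives the per-probe
#'   table, `filteredDataset()` the dataset with failing probes removed.
#' @export
filterMethProbes <- function(ds, rSquaredThres = 0.3, pValThres = 0.05) {
  if (is.null(ds@meth))
    stop("dataset has no methylation data", call. = FALSE)
  n <- nrow(ds@ge)
  if (n < 3L) stop("at least 3 samples needed for the probe filter",
                   call. = FALSE)
  probes <- colnames(ds@meth)
  genes <- ds@probeMap$gene_id[match(probes, ds@probeMap$probe_id)]
  r2 <- p <- numeric(length(probes))
  for (i in seq_along(probes)) {
    x <- ds@meth[, i]
    y <- ds@ge[, genes[i]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero-variance column for probe ", probes[i],
              "; probe dropped", call. = FALSE)
      r2[i] <- 0; p[i] <- 1
      next
    }
    r <- stats::cor(x, y)
    r2[i] <- r * r
    if (1 - r2[i] <= 0) p[i] <- 0
    else {
      tstat <- r * sqrt((n - 2) / (1 - r2[i]))
      p[i] <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  retained <- r2 >= rSquaredThres & p <= pValThres
  report <- data.frame(probe_id = probes, gene_id = genes,
                       r_squared = r2, p_value = p, retained = retained,
                       stringsAsFactors = FALSE)
  kept <- ds
  kept@meth <- ds@meth[, retained, drop = FALSE]
  kept@probeMap <- ds@probeMap[ds@probeMap$probe_id %in% probes[retained], ,
                               drop = FALSE]
  if (ncol(kept@meth) == 0L) { kept@meth <- NULL; kept@probeMap <- NULL }
  methods::validObject(kept)
  new("MethFilterResult", report = report, dataset = kept,
      thresholds = c(r_squared = rSquaredThres, p_value = pValThres))
}

#' @describeIn filterMethProbes per-probe regression report
#' @param x a [MethFilterResult-class].
#' @export
filterReport <- function(x) x@report

#' @describeIn filterMethProbes dataset with failing probes removed
#' @export
filteredDataset <- function(x) x@dataset

#' Write the probe-filter report and filtered methylation matrix
#'
#' @param x a [MethFilterResult-class].
#' @param reportPath TSV path for the per-probe report.
#' @param methPath optional TSV path for the filtered methylation matrix.
#' @return invisibly, `x`.
#' @export
writeFilterReport <- function(x, reportPath, methPath = NULL) {
  utils::write.table(x@report, reportPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(methPath) && !is.null(x@dataset@meth))
    .writeMatrixTSV(x@dataset@meth, methPath)
  invisible(x)
}

setMethod("show", "MethFilterResult", function(object) {
  cat("MethFilterResult:", sum(object@report$retained), "of",
      nrow(object@report), "probes retained (R^2 >=",
      object@thresholds[["r_squared"]], ", p <=",
      object@thresholds[["p_value"]], ")\n")
})
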