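# belief assigned to curated interactions; kept off 0/1 so that no structure
# has prior probability zero (the sampler stays ergodic)
.PK_EPS <- 0.01

#' Read a curated prior-knowledge edge list
#'
#' TSV with columns `src_gene`, `dst_gene`, `edge_type` where `edge_type` is
#' `present` or `absent`.
#'
#' @param path TSV path.
#' @return data.frame with the three columns.
#' @export
readPriorKnowledge <- function(path) {
  pk <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("src_gene", "dst_gene", "edge_type")
  if (!all(need %in% names(pk)))
    stop("prior-knowledge table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(pk$edge_type), c("present", "absent"))
  if (length(bad))
    stop("malformed edge_type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  pk
}

#' Build the biological prior matrix over a candidate edge set
#'
#' Every candidate edge gets a belief in \[0,1\]: curated `present` edges map
#' to 0.99, curated `absent` to 0.01, TF->target interactions (when not
#' already curated) to 0.99 with provenance `tf_target`, and everything else
#' to the uninformative 0.5 with provenance `default`. Prior rows naming
#' genes outside the candidate node set are ignored (a count is messaged).
#'
#' @param candidates a [CandidateEdgeSet-class].
#' @param pk optional data.frame as from [readPriorKnowledge()].
#' @param tfTargets optional two-column data.frame (`TF`, `target`) or a
#'   0/1 incidence matrix with TFs in columns and targets in rows.
#' @return a [PriorMatrix-class].
#' @export
buildPriorMatrix <- function(candidates, pk = NULL, tfTargets = NULL) {
  e <- candidates@edges
  keys <- .edgeKey(e$parent, e$child)
  b <- setNames(rep(0.5, length(keys)), keys)
  prov <- setNames(rep("default", length(keys)), keys)
  if (!is.null(tfTargets)) {
    if (is.matrix(tfTargets)) {
      idx <- which(tfTargets != 0, arr.ind = TRUE)
      tfTargets <- data.frame(TF = colnames(tfTargets)[idx[, 2]],
                              target = rownames(tfTargets)[idx[, 1]],
                              stringsAsFactors = FALSE)
    }
    tkeys <- .edgeKey(tfTargets$TF, tfTargets$target)
    known <- tkeys %in% keys
    b[tkeys[known]] <- 1 - .PK_EPS
    prov[tkeys[known]] <- "tf_target"
  }
  if (!is.null(pk) && nrow(pk)) {
    if (!all(c("src_gene", "dst_gene", "edge_type") %in% names(pk)))
      stop("prior-knowledge table needs columns src_gene, dst_gene, ",
           "edge_type", call. = FALSE)
    bad <- setdiff(unique(pk$edge_type), c("present", "absent"))
    if (length(bad))
      stop("malformed edge_type value(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    pkeys <- .edgeKey(pk$src_gene, pk$dst_gene)
    known <- pkeys %in% keys
    if (any(!known))
      message(sum(!known), " prior-knowledge row(s) outside the candidate ",
              "edge set ignored")
    b[pkeys[known]] <- ifelse(pk$edge_type[known] == "present",
                              1 - .PK_EPS, .PK_EPS)
    prov[pkeys[known]] <- "curated"
  }
  new("PriorMatrix", values = b, provenance = prov)
}

#' @describeIn buildPriorMatrix belief values accessor
#' @param x a [PriorMatrix-class].
#' @export
priorValues <- function(x) x@values

#' @describeIn buildPriorMatrix provenance accessor
#' @export
priorProvenance <- function(x) x@provenance

setMethod("show", "PriorMatrix", function(object) {
  cat("PriorMatrix over", length(object@values), "candidate edges\n")
  print(table(object@provenance))
})

#' Write a prior matrix as TSV with provenance
#'
#' @param x a [PriorMatrix-class].
#' @param path output TSV path (columns parent, child, belief, provenance).
#' @return invisibly, the data.frame written.
#' @export
writePriorMatrix <- function(x, path) {
  pc <- do.call(rbind, strsplit(names(x@values), "->", fixed = TRUE))
  df <- data.frame(parent = pc[, 1], child = pc[, 2],
                   belief = unname(x@values),
                   provenance = unname(x@provenance),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Construct the energy-based structure prior model
#'
#' @param b a [PriorMatrix-class].
#' @param beta initial/fixed inverse temperature (default 1).
#' @param betaMax upper bound for sampled beta (default 10).
#' @param sampleBeta sample beta by Metropolis-Hastings? (default TRUE)
#' @return a [PriorModel-class].
#' @export
priorModel <- function(b, beta = 1, betaMax = 10, sampleBeta = TRUE) {
  pm <- new("PriorModel", b = b, beta = beta, betaMax = betaMax,
            sampleBeta = sampleBeta)
  methods::validObject(pm)
  pm
}

#' Energy of a structure under the biological prior
#'
#' E(G) = sum over candidate edges (i,j) of |b(i,j) - a(i,j)| where a is the
#' 0/1 edge indicator of G. Low energy means the structure agrees with the
#' prior beliefs.
#'
#' @param g a [NetworkStructure-class].
#' @param b a [PriorMatrix-class] over the same candidate set.
#' @return nonnegative scalar.
#' @export
graphEnergy <- function(g, b) {
  vals <- b@values
  e <- g@candidates@edges
  if (length(vals) != nrow(e))
    stop("prior matrix and candidate set sizes differ", call. = FALSE)
  a <- numeric(length(vals))
  a[g@edgeIdx] <- 1
  sum(abs(vals - a))
}

# log of the edge-factorized pseudo partition function Z(beta); ignores the
# acyclicity constraint (each candidate edge treated as independently in/out)
.logPseudoZ <- function(bvals, beta) {
  sum(log(exp(-beta * bvals) + exp(-beta * (1 - bvals))))
}

#' Log structure prior
#'
#' Returns `-beta * E(G) - log Z(beta)` where `Z(beta)` is the
#' edge-factorized pseudo partition function
#' `prod_e [exp(-beta b_e) + exp(-beta (1 - b_e))]`. Within a fixed beta the
#' normalization is a constant; across beta values it makes the joint
#' (structure, beta) moves well defined.
#'
#' @param g a [NetworkStructure-class].
#' @param pm a [PriorModel-class].
#' @return log prior density (unnormalized over structures).
#' @export
logStructurePrior <- function(g, pm) {
  -pm@beta * graphEnergy(g, pm@b) - .logPseudoZ(pm@b@values, pm@beta)
}

#' Complete missing prior knowledge from phase-1 edge frequencies
#'
#' Entries with provenance `default` are replaced by the phase-1 posterior
#' edge frequency clamped to \[0.01, 0.99\] and flagged `empirical`; curated
#' and TF-target entries are never overwritten.
#'
#' @param b a [PriorMatrix-class].
#' @param phase1Weights named numeric vector of phase-1 edge frequencies
#'   (keys "parent->child"; missing keys count as frequency 0).
#' @return the completed [PriorMatrix-class].
#' @export
empiricalPriorUpdate <- function(b, phase1Weights) {
  if (length(phase1Weights) &&
      (any(phase1Weights < 0) || any(phase1Weights > 1)))
    stop("phase-1 edge frequencies must lie in [0,1]", call. = FALSE)
  vals <- b@values
  prov <- b@provenance
  open <- names(vals)[prov == "default"]
  w <- phase1Weights[open]
  w[is.na(w)] <- 0
  vals[open] <- pmin(pmax(unname(w), .PK_EPS), 1 - .PK_EPS)
  prov[open] <- "empirical"
  new("PriorMatrix", values = vals, provenance = prov)
}
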