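# Independent oracles used across the suite. These deliberately avoid the
# package's own closed-form BGe implementation: the subset marginal
# likelihood is rebuilt from the sequential multivariate-t predictive of the
# conjugate normal-Wishart model, and Markov equivalence is decided from the
# skeleton + v-structure characterization.

# log p(X_A) via the chain rule of one-step-ahead multivariate-t predictives
# under the normal-Wishart prior restricted to the subset A.
oracleSubsetLogMl <- function(X, nu, alphaMu, alphaW, Tm, idx) {
  l <- length(idx)
  if (l == 0) return(0)
  Xa <- X[, idx, drop = FALSE]
  mu <- nu[idx]
  kap <- alphaMu
  a <- alphaW - ncol(X) + l
  Tk <- Tm[idx, idx, drop = FALSE]
  ll <- 0
  for (k in seq_len(nrow(Xa))) {
    x <- Xa[k, ]
    v <- a - l + 1
    Sig <- Tk * (kap + 1) / (kap * v)
    dlt <- x - mu
    Q <- drop(t(dlt) %*% solve(Sig) %*% dlt)
    ll <- ll + lgamma((v + l) / 2) - lgamma(v / 2) - (l / 2) * log(v * pi) -
      0.5 * determinant(Sig)$modulus - ((v + l) / 2) * log1p(Q / v)
    mu2 <- (kap * mu + x) / (kap + 1)
    Tk <- Tk + tcrossprod(dlt) * kap / (kap + 1)
    mu <- mu2; kap <- kap + 1; a <- a + 1
  }
  as.numeric(ll)
}

oracleLocalScore <- function(X, node, parents, hp) {
  ids <- colnames(X)
  fam <- match(c(parents, node), ids)
  par <- match(parents, ids)
  oracleSubsetLogMl(X, hp@nu, hp@alphaMu, hp@alphaW, hp@tMatrix, fam) -
    oracleSubsetLogMl(X, hp@nu, hp@alphaMu, hp@alphaW, hp@tMatrix, par)
}

# all acyclic subsets of the candidate edge rows (row indices into
# candidates@edges); exhaustive over 2^m subsets, fine for m <= 12
allDagEdgeSets <- function(cands) {
  m <- nrow(cands@edges)
  out <- list()
  for (bits in 0:(2^m - 1)) {
    idx <- which(bitwAnd(bits, 2^(seq_len(m) - 1)) > 0)
    e <- cands@edges[idx, , drop = FALSE]
    if (nrow(e) == 0 ||
        !getFromNamespace(".hasCycle", "OmicsBN")(e$parent, e$child))
      out[[length(out) + 1L]] <- as.integer(sort(idx))
  }
  out
}

# canonical key of a DAG's Markov equivalence class: sorted skeleton pairs
# plus sorted v-structure triples (u -> w <- v, u and v non-adjacent)
equivClassKey <- function(parent, child) {
  if (length(parent) == 0) return("(empty)")
  skel <- matrix(apply(cbind(parent, child), 1, sort), ncol = 2,
                 byrow = TRUE)
  skel <- unique(skel)
  skelKey <- paste(sort(paste(skel[, 1], skel[, 2], sep = "--")),
                   collapse = ";")
  adjKey <- paste0(parent, "|", child)
  vs <- character(0)
  for (w in unique(child)) {
    pars <- sort(parent[child == w])
    if (length(pars) < 2) next
    for (a in seq_along(pars)) for (b in seq_along(pars)) {
      if (a >= b) next
      u <- pars[a]; v <- pars[b]
      adjacent <- paste0(u, "|", v) %in% adjKey || paste0(v, "|", u) %in%
        adjKey
      if (!adjacent) vs <- c(vs, paste(u, v, w, sep = "*"))
    }
  }
  paste(skelKey, paste(sort(vs), collapse = ";"), sep = " // ")
}

# canonical key of the package's CPDAG labelling of a DAG
cpdagKey <- function(g) {
  lab <- toCpdag(g)
  if (nrow(lab) == 0) return("")
  dir <- lab[lab$compelled, , drop = FALSE]
  und <- lab[!lab$compelled, , drop = FALSE]
  undPairs <- if (nrow(und)) apply(cbind(und$parent, und$child), 1,
                                   function(r) paste(sort(r),
                                                     collapse = "--"))
    else character(0)
  paste(paste(sort(paste(dir$parent, dir$child, sep = "->")),
              collapse = ";"),
        paste(sort(undPairs), collapse = ";"), sep = " // ")
}

makeGeDataset <- function(n, ids, seed) {
  set.seed(seed)
  ge <- matrix(rnorm(n * length(ids)), n, length(ids),
               dimnames = list(sprintf("s%03d", seq_len(n)), ids))
  omicsDataset(ge)
}
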