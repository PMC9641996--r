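# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: likelihoods by exhaustive enumeration over
# internal-node states, parsimony by exhaustive labeling, densities by a
# generic multivariate-normal routine.

# Random non-ultrametric test tree with uniform branch lengths.
random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1.5)
  tr
}

# Exhaustive-enumeration Mk likelihood and marginals (trees <= 6 tips).
oracle_mk_enum <- function(tree, tip_states, Q, prior = NULL) {
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge; el <- po$edge.length
  ntip <- length(po$tip.label); k <- nrow(Q); nint <- po$Nnode
  if (is.null(prior)) prior <- rep(1 / k, k)
  Pm <- lapply(seq_len(nrow(edge)),
               function(e) as.matrix(Matrix::expm(Q * el[e])))
  tipidx <- match(tip_states[po$tip.label], rownames(Q))
  grid <- as.matrix(expand.grid(rep(list(1:k), nint)))
  total <- 0
  marg <- matrix(0, nint, k)
  for (g in seq_len(nrow(grid))) {
    a <- c(tipidx, grid[g, ])
    pr <- prior[a[ntip + 1]]
    for (e in seq_len(nrow(edge)))
      pr <- pr * Pm[[e]][a[edge[e, 1]], a[edge[e, 2]]]
    total <- total + pr
    marg[cbind(seq_len(nint), grid[g, ])] <-
      marg[cbind(seq_len(nint), grid[g, ])] + pr
  }
  list(lik = total, marg = marg / total)
}

# Exhaustive-labeling parsimony oracle (trees <= 6 tips).
oracle_sankoff <- function(tree, tip_states, states, C) {
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  ntip <- length(po$tip.label); k <- nrow(C); nint <- po$Nnode
  tipidx <- match(tip_states[po$tip.label], states)
  grid <- as.matrix(expand.grid(rep(list(1:k), nint)))
  best <- Inf; sets <- vector("list", nint)
  for (g in seq_len(nrow(grid))) {
    a <- c(tipidx, grid[g, ])
    cost <- 0
    for (e in seq_len(nrow(edge))) cost <- cost + C[a[edge[e, 1]], a[edge[e, 2]]]
    if (cost < best - 1e-12) {
      best <- cost
      sets <- lapply(seq_len(nint), function(i) unname(grid[g, i]))
    } else if (abs(cost - best) < 1e-12) {
      for (i in seq_len(nint))
        sets[[i]] <- union(sets[[i]], unname(grid[g, i]))
    }
  }
  list(cost = best, sets = lapply(sets, sort))
}

# Fitch change count for a binary trait on a (bi/multifurcating) tree:
# classical set-intersection pass, independent of the Sankoff DP.
oracle_fitch <- function(tree, tip_states) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  sets <- vector("list", ntip + po$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tip_states[[po$tip.label[i]]]
  changes <- 0
  for (node in unique(po$edge[, 1])) {
    kids <- po$edge[po$edge[, 1] == node, 2]
    s <- sets[[kids[1]]]
    for (kk in kids[-1]) {
      inter <- intersect(s, sets[[kk]])
      if (length(inter)) s <- inter
      else { s <- union(s, sets[[kk]]); changes <- changes + 1 }
    }
    sets[[node]] <- s
  }
  changes
}

# Generic multivariate normal log-density (solve/determinant route,
# independent of the package's chol/backsolve path).
oracle_mvn_logdens <- function(x, mean, Sigma) {
  n <- length(x)
  r <- x - mean
  -0.5 * (n * log(2 * pi) + determinant(Sigma, logarithm = TRUE)$modulus +
            t(r) %*% solve(Sigma) %*% r)[1]
}

# Small hand-written hit table builder.
hit_row <- function(q, s, bitscore = 100, evalue = 2^(-bitscore),
                    pident = 95, length = 500, qlen = 600, slen = 600) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = length,
             qlen = qlen, slen = slen, evalue = evalue, bitscore = bitscore)
}
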