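# Internal tree helpers shared by the likelihood, mapping and BM code.
# Trees are ape "phylo" objects: tips 1..n, root n+1, edge matrix parent/child.

.check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths not allowed")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  invisible(tree)
}

# Postorder edge ordering: every child row appears before the row in which
# that node is itself the child's parent.
.postorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(tree = tr, edge = tr$edge, el = tr$edge.length,
       ntip = length(tr$tip.label), nnode = tr$Nnode,
       root = length(tr$tip.label) + 1L)
}

# Depth of every node from the root (sum of branch lengths).
.node_depths <- function(tree) {
  po <- .postorder(tree)
  depth <- numeric(po$ntip + po$nnode)
  for (e in rev(seq_len(nrow(po$edge)))) {   # preorder
    depth[po$edge[e, 2L]] <- depth[po$edge[e, 1L]] + po$el[e]
  }
  depth
}

# Validate a rate matrix: non-negative off-diagonals, zero row sums.
.check_q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be a square matrix")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("Q off-diagonal entries must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-8 * (1 + max(abs(Q)))))
    stop("Q rows must sum to zero")
  invisible(Q)
}

# Transition probability matrices exp(Q t) for a vector of branch lengths.
# Eigendecomposition of Q once, then one small matrix product per branch;
# falls back to ape::matexpo when Q is (numerically) defective.
.tp_array <- function(Q, tvec) {
  k <- nrow(Q)
  P <- array(0, dim = c(k, k, length(tvec)))
  if (all(Q == 0)) {
    for (e in seq_along(tvec)) P[, , e] <- diag(k)
    return(P)
  }
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- !is.null(eg) &&
    tryCatch(rcond(eg$vectors) > 1e-10, error = function(e) FALSE)
  if (ok) {
    V <- eg$vectors
    Vi <- solve(V)
    E <- exp(outer(eg$values, tvec))          # k x nedge
    for (m in seq_len(k)) {                   # P_e = sum_m E[m,e] V[,m] Vi[m,]
      B <- V[, m] %o% Vi[m, ]                 # k x k
      P <- P + outer(B, E[m, ])
    }
    P <- Re(P)
    P[P < 0] <- 0
    sums <- P[, 1, ]
    for (j in 2:k) sums <- sums + P[, j, ]    # k x nedge row sums
    for (j in seq_len(k)) P[, j, ] <- P[, j, ] / sums
  } else {
    # defective Q: scaling-and-squaring (ape::matexpo is inaccurate for
    # non-reversible matrices)
    for (e in seq_along(tvec)) {
      M <- as.matrix(Matrix::expm(Q * tvec[e]))
      M[M < 0] <- 0
      P[, , e] <- M / rowSums(M)
    }
  }
  if (any(!is.finite(P))) stop("non-finite transition probabilities exp(Q t)")
  P
}

# Stationary distribution of Q (left null vector, normalised).
.stationary_dist <- function(Q) {
  k <- nrow(Q)
  if (all(Q == 0)) return(rep(1 / k, k))
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0] <- 0
  pi / sum(pi)
}

.root_prior_vec <- function(root_prior, Q, k) {
  if (is.numeric(root_prior)) {
    if (length(root_prior) != k || any(root_prior < 0))
      stop("numeric root prior must be a non-negative vector of length k")
    return(root_prior / sum(root_prior))
  }
  switch(match.arg(root_prior, c("equal", "stationary")),
         equal = rep(1 / k, k),
         stationary = .stationary_dist(Q))
}
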