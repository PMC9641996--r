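#' Transition-cost matrices for Sankoff parsimony
#'
#' `all_equal`: every change costs 1. `exponential`: for ordered states,
#' cost(i, j) = 2^|i-j| - 1, so a direct two-step jump (cost 3) is dearer
#' than two single steps (cost 2), favouring intermediate states.
#'
#' @param k number of states.
#' @param scheme `"all_equal"` or `"exponential"`, or a user k x k matrix
#'   passed straight through after validation.
#' @return k x k numeric cost matrix with zero diagonal.
#' @export
parsimony_costs <- function(k, scheme = c("all_equal", "exponential")) {
  if (is.matrix(scheme)) {
    if (nrow(scheme) != k || ncol(scheme) != k || any(diag(scheme) != 0) ||
        any(scheme < 0)) stop("invalid custom cost matrix")
    return(scheme)
  }
  scheme <- match.arg(scheme)
  ij <- abs(outer(seq_len(k), seq_len(k), "-"))
  C <- switch(scheme,
              all_equal = (ij > 0) * 1,
              exponential = 2^ij - 1)
  C
}

#' Sankoff parsimony ancestral reconstruction
#'
#' Minimum-cost ancestral labelings under an arbitrary transition-cost
#' matrix, by dynamic programming up the tree and a downward pass that
#' recovers, for every node, the set of states attaining the global minimum
#' in at least one optimal labeling. Missing tips are treated as
#' all-states-possible.
#'
#' @inheritParams mk_loglik
#' @param cost_scheme `"all_equal"`, `"exponential"` (ordered states in the
#'   trait's declared state order), or a custom k x k matrix.
#' @return object of class `sankoff_recon`: `total_cost`, `node_sets` (list
#'   of state-label vectors per node, tips first), `cost_scheme`, `states`.
#' @export
sankoff_parsimony <- function(tree, trait, cost_scheme = "all_equal") {
  .check_tree(tree)
  tr <- .resolve_trait(trait, tree)
  k <- tr$k
  C <- parsimony_costs(k, cost_scheme)
  po <- .postorder(tree)
  nnode <- po$ntip + po$nnode
  S <- matrix(0, nnode, k)
  for (i in seq_len(po$ntip)) {
    if (!is.na(tr$idx[i])) {
      S[i, ] <- Inf
      S[i, tr$idx[i]] <- 0
    }
  }
  # msg[e, i] = min_l C[i, l] + S[child_e, l]
  msg <- matrix(0, nrow(po$edge), k)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    m <- vapply(seq_len(k), function(i) min(C[i, ] + S[ch, ]), 0)
    msg[e, ] <- m
    S[par, ] <- S[par, ] + m
  }
  total <- min(S[po$root, ])
  # Downward: D[v, j] = min cost of the rest of the tree given state j at v
  D <- matrix(0, nnode, k)
  children <- split(seq_len(nrow(po$edge)), po$edge[, 1L])
  for (e in rev(seq_len(nrow(po$edge)))) {   # preorder
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    sib <- setdiff(children[[as.character(par)]], e)
    above <- D[par, ]
    for (s in sib) above <- above + msg[s, ]
    D[ch, ] <- vapply(seq_len(k), function(j) min(above + C[, j]), 0)
  }
  G <- S + D
  eps <- 1e-9 * (1 + abs(total))
  node_sets <- lapply(seq_len(nnode), function(v)
    tr$states[which(G[v, ] <= total + eps)])
  names(node_sets) <- c(po$tree$tip.label,
                        paste0("node", (po$ntip + 1L):nnode))
  structure(list(total_cost = total, node_sets = node_sets,
                 cost_scheme = if (is.matrix(cost_scheme)) "custom" else cost_scheme,
                 states = tr$states),
            class = "sankoff_recon")
}

#' @export
print.sankoff_recon <- function(x, ...) {
  cat(sprintf("Sankoff parsimony (%s costs): total cost %g over %d nodes\n",
              x$cost_scheme, x$total_cost, length(x$node_sets)))
  invisible(x)
}
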