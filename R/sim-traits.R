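#' Simulate a discrete trait with its full character history
#'
#' Evolves a continuous-time Markov chain with rate matrix `q` down the
#' tree from `root_state`, recording the complete history: per-branch
#' (state, duration) segments, node states, and the true transition counts
#' that downstream reconstructions try to recover.
#'
#' @param tree rooted `phylo`.
#' @param q rate matrix; dimnames name the states (defaults `"1".."k"`).
#' @param root_state state label at the root (default: first state).
#' @param seed integer seed.
#' @return object of class `sim_discrete`: `tip_states` (named vector),
#'   `node_states` (all nodes, ape numbering), `histories` (per-edge of the
#'   postorder tree: integer `states`, `durations`), `edge`,
#'   `transition_counts` (k x k), `true_transition_count` (named per-state
#'   count of entries into each state), `states`, `tree`.
#' @export
simulate_discrete_trait <- function(tree, q, root_state = NULL, seed = 1L) {
  .check_tree(tree); .check_q(q)
  k <- nrow(q)
  states <- rownames(q)
  if (is.null(states)) states <- as.character(seq_len(k))
  if (is.null(root_state)) root_state <- states[1]
  r0 <- match(root_state, states)
  if (is.na(r0)) stop("root_state not in state space")
  set.seed(as.integer(seed))
  po <- .postorder(tree)
  nnode <- po$ntip + po$nnode
  node_states <- integer(nnode)
  node_states[po$root] <- r0
  histories <- vector("list", nrow(po$edge))
  tc <- matrix(0L, k, k, dimnames = list(states, states))
  for (e in rev(seq_len(nrow(po$edge)))) {   # preorder
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    s <- node_states[par]
    t_left <- po$el[e]
    seg_states <- s; seg_dur <- numeric(0); t_used <- 0
    repeat {
      rate <- -q[s, s]
      if (rate <= 0) break
      w <- rexp(1, rate)
      if (t_used + w >= t_left) break
      t_used <- t_used + w
      seg_dur <- c(seg_dur, w)
      nxt <- sample.int(k, 1L, prob = pmax(q[s, ], 0) * (seq_len(k) != s))
      tc[s, nxt] <- tc[s, nxt] + 1L
      s <- nxt
      seg_states <- c(seg_states, s)
    }
    seg_dur <- c(seg_dur, t_left - t_used)
    histories[[e]] <- list(states = seg_states, durations = seg_dur)
    node_states[ch] <- s
  }
  tip_states <- setNames(states[node_states[seq_len(po$ntip)]],
                         po$tree$tip.label)
  entries <- setNames(colSums(tc), states)
  structure(list(tip_states = tip_states, node_states = node_states,
                 histories = histories, edge = po$edge,
                 transition_counts = tc, true_transition_count = entries,
                 states = states, tree = po$tree),
            class = "sim_discrete")
}

#' Simulate a continuous trait under lambda-transformed Brownian motion
#'
#' Applies [lambda_transform] to the tree and runs Brownian motion with
#' rate `sigma2` from `root_value`, so tips i, j have covariance
#' `sigma2 * lambda * shared path` and variance `sigma2 * root-to-tip
#' length`.
#'
#' @param tree rooted `phylo`.
#' @param sigma2 BM variance rate (> 0).
#' @param lambda_true Pagel's lambda in `[0, 1]`.
#' @param root_value trait value at the root.
#' @param seed integer seed.
#' @return list: `tip_values` (named vector), `node_values` (all nodes of
#'   the lambda-transformed tree), `tree` (transformed), `root_value`.
#' @export
simulate_continuous_trait <- function(tree, sigma2 = 1, lambda_true = 1,
                                      root_value = 0, seed = 1L) {
  .check_tree(tree)
  stopifnot(sigma2 > 0, lambda_true >= 0, lambda_true <= 1)
  set.seed(as.integer(seed))
  trl <- lambda_transform(tree, lambda_true)
  po <- .postorder(trl)
  nnode <- po$ntip + po$nnode
  vals <- numeric(nnode)
  vals[po$root] <- root_value
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    vals[ch] <- vals[par] + rnorm(1, 0, sqrt(sigma2 * po$el[e]))
  }
  list(tip_values = setNames(vals[seq_len(po$ntip)], po$tree$tip.label),
       node_values = vals, tree = trl, root_value = root_value)
}
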