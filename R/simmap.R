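# Stochastic character mapping: joint node-state sampling from the
# conditional distribution, then branch histories by uniformization
# conditioned on the sampled endpoint states.

# Sample one path of the CTMC Q on [0, t] given X(0)=a, X(t)=b, by
# uniformization. `cache` is an environment holding mu, R and its powers.
.sample_branch_path <- function(a, b, t, cache, max_jumps = 10000L,
                                Pab = NULL) {
  mu <- cache$mu
  if (mu == 0 || t == 0) {
    if (a != b) stop("impossible endpoint conditioning on zero-rate/zero-length branch")
    return(list(states = a, durations = t))
  }
  if (is.null(Pab)) Pab <- cache$P_lookup(t)[a, b]
  u <- runif(1) * Pab
  # fast path: no jump at all (dominant on low-rate branches)
  if (a == b && exp(-mu * t) >= u) return(list(states = a, durations = t))
  R <- cache$R
  k <- nrow(R)
  Rpow <- function(n) {       # R^n, cached
    while (length(cache$pows) < n + 1L)
      cache$pows[[length(cache$pows) + 1L]] <-
        cache$pows[[length(cache$pows)]] %*% R
    cache$pows[[n + 1L]]
  }
  n <- 0L
  acc <- 0
  repeat {
    term <- dpois(n, mu * t) * Rpow(n)[a, b]
    acc <- acc + term
    if (acc >= u || n >= max_jumps) break
    n <- n + 1L
  }
  if (n >= max_jumps && acc < u)
    stop(sprintf("uniformization cap (%d) reached on a branch (a=%d,b=%d,t=%g)",
                 max_jumps, a, b, t))
  if (n == 0L) return(list(states = a, durations = t))
  # intermediate states of the uniformized chain
  s <- integer(n + 1L); s[1L] <- a; s[n + 1L] <- b
  if (n > 1L) for (i in 2:n) {
    w <- R[s[i - 1L], ] * Rpow(n + 1L - i)[, b]
    s[i] <- sample.int(k, 1L, prob = w)
  }
  jumps <- sort(runif(n)) * t
  # collapse virtual (self) jumps
  keep <- which(s[-1L] != s[-(n + 1L)])
  if (!length(keep)) return(list(states = a, durations = t))
  states <- c(s[1L], s[keep + 1L])
  bounds <- c(0, jumps[keep], t)
  durations <- diff(bounds)
  durations[length(durations)] <- t - sum(durations[-length(durations)])
  list(states = states, durations = durations)
}

#' Stochastic character maps under a fixed Mk rate matrix
#'
#' Samples `nsim` full character histories conditional on the tip data:
#' node states are drawn from their joint conditional distribution (root
#' from the posterior, then each child given its parent), and each branch
#' history is drawn by uniformization conditioned on its endpoints. The
#' rate matrix is held fixed ("empirical" mapping, typically the MLE of the
#' chosen model).
#'
#' @inheritParams mk_loglik
#' @param nsim number of maps (>= 1).
#' @param seed integer seed; mandatory for reproducibility.
#' @param max_jumps cap on uniformized jumps per branch; breaching it is an
#'   error, not a silent fallback.
#' @return object of class `simmap_set`: `maps` (list; each map has
#'   `node_states` and per-edge `histories` with `states`/`durations` in
#'   parent-to-child time order), `edge` matrix and `edge.length` of the
#'   postorder tree, `node_freq` (node x state frequency matrix),
#'   `dwell` (per-state mean total time), `transition_counts` (mean k x k
#'   matrix), `per_map_transitions` (list of k x k matrices), `states`.
#' @export
stochastic_map <- function(tree, trait, Q, nsim = 100L, seed = 1L,
                           root_prior = "equal", max_jumps = 10000L) {
  stopifnot(nsim >= 1)
  set.seed(as.integer(seed))
  pr <- .pruning(tree, trait, Q, root_prior)
  po <- pr$po; k <- pr$k
  nedge <- nrow(po$edge)
  nnode <- po$ntip + po$nnode
  preord <- rev(seq_len(nedge))
  cache <- new.env(parent = emptyenv())
  cache$mu <- max(-diag(Q)) * 1.05
  cache$R <- if (cache$mu > 0) diag(k) + Q / cache$mu else diag(k)
  cache$pows <- list(diag(k))
  Pmap <- lapply(seq_len(nedge), function(e) pr$P[, , e])
  names(Pmap) <- as.character(seq_len(nedge))
  el_by_edge <- po$el
  cache$P_lookup <- function(t) {
    e <- match(TRUE, el_by_edge == t)
    if (!is.na(e)) Pmap[[e]] else .tp_array(Q, t)[, , 1]
  }

  root_post <- pr$prior * pr$up[po$root, ]
  root_post <- root_post / sum(root_post)
  maps <- vector("list", nsim)
  node_freq <- matrix(0, nnode, k)
  dwell <- numeric(k)
  tc_mean <- matrix(0, k, k)
  per_map_tc <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    node_states <- integer(nnode)
    node_states[po$root] <- sample.int(k, 1L, prob = root_post)
    hist <- vector("list", nedge)
    tc <- matrix(0L, k, k)
    for (e in preord) {
      par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
      j <- node_states[par]
      w <- pr$P[j, , e] * pr$up[ch, ]
      node_states[ch] <- sample.int(k, 1L, prob = w)
      h <- .sample_branch_path(j, node_states[ch], po$el[e], cache, max_jumps,
                               Pab = pr$P[j, node_states[ch], e])
      hist[[e]] <- h
      if (length(h$states) > 1L) {
        from <- h$states[-length(h$states)]
        to <- h$states[-1L]
        for (i in seq_along(from)) tc[from[i], to[i]] <- tc[from[i], to[i]] + 1L
        for (i in seq_along(h$states))
          dwell[h$states[i]] <- dwell[h$states[i]] + h$durations[i]
      } else {
        dwell[h$states] <- dwell[h$states] + h$durations
      }
    }
    node_freq[cbind(seq_len(nnode), node_states)] <-
      node_freq[cbind(seq_len(nnode), node_states)] + 1
    tc_mean <- tc_mean + tc
    per_map_tc[[s]] <- tc
    maps[[s]] <- list(node_states = node_states, histories = hist)
  }
  node_freq <- node_freq / nsim
  colnames(node_freq) <- pr$states
  rownames(node_freq) <- c(po$tree$tip.label,
                           paste0("node", (po$ntip + 1L):nnode))
  dimnames(tc_mean) <- list(pr$states, pr$states)
  structure(list(maps = maps, tree = po$tree, edge = po$edge,
                 edge.length = po$el, states = pr$states,
                 node_freq = node_freq, dwell = dwell / nsim,
                 transition_counts = tc_mean / nsim,
                 per_map_transitions = per_map_tc, nsim = nsim),
            class = "simmap_set")
}

#' @export
print.simmap_set <- function(x, ...) {
  cat(sprintf("simmap_set: %d maps, %d states (%s), mean transitions %.2f\n",
              x$nsim, length(x$states), paste(x$states, collapse = ","),
              sum(x$transition_counts)))
  invisible(x)
}

# Count entries into / exits from `derived` over one explicit history.
# `histories` is a per-edge list of (states, durations) integer-coded.
.count_history <- function(histories, derived_idx) {
  origins <- 0L; reversals <- 0L
  branches_o <- integer(0); branches_r <- integer(0)
  for (e in seq_along(histories)) {
    h <- histories[[e]]
    if (length(h$states) > 1L) {
      from <- h$states[-length(h$states)]
      to <- h$states[-1L]
      o <- sum(to == derived_idx & from != derived_idx)
      r <- sum(from == derived_idx & to != derived_idx)
      origins <- origins + o; reversals <- reversals + r
      if (o > 0) branches_o <- c(branches_o, e)
      if (r > 0) branches_r <- c(branches_r, e)
    }
  }
  list(n_origins = origins, n_reversals = reversals,
       origin_branches = branches_o, reversal_branches = branches_r)
}

#' Count independent origins and reversals of a derived state
#'
#' For a single explicit history (e.g. the recorded truth of
#' [simulate_discrete_trait], or one sampled map) the counts are exact: an
#' origin is a change point entering the derived state, a reversal a change
#' point leaving it. For a [stochastic_map] set, the posterior distribution
#' over maps is summarised (mean, sd, tabulated counts).
#'
#' @param x a `simmap_set`, a single map's history (list with per-edge
#'   `states`/`durations`), or a `sim_discrete` truth object.
#' @param derived_state state label whose gains/losses are counted.
#' @return list with `derived_state`, `n_origins`, `n_reversals` (posterior
#'   means for map sets), and for map sets `sd_origins`, `sd_reversals`,
#'   `origin_distribution`; for single histories also the branch lists.
#' @export
count_transitions <- function(x, derived_state) {
  if (inherits(x, "sim_discrete")) {
    states <- x$states
    d <- match(derived_state, states)
    if (is.na(d)) stop("derived_state not in state space")
    res <- .count_history(x$histories, d)
    return(c(list(derived_state = derived_state), res))
  }
  if (inherits(x, "simmap_set")) {
    d <- match(derived_state, x$states)
    if (is.na(d)) stop("derived_state not in state space")
    per <- vapply(x$maps, function(m)
      unlist(.count_history(m$histories, d)[c("n_origins", "n_reversals")]),
      numeric(2))
    return(list(derived_state = derived_state,
                n_origins = mean(per[1, ]), n_reversals = mean(per[2, ]),
                sd_origins = sd(per[1, ]), sd_reversals = sd(per[2, ]),
                origin_distribution = table(per[1, ])))
  }
  if (is.list(x) && !is.null(x$histories) && !is.null(x$states)) {
    d <- match(derived_state, x$states)
    if (is.na(d)) stop("derived_state not in state space")
    return(c(list(derived_state = derived_state),
             .count_history(x$histories, d)))
  }
  stop("unsupported input to count_transitions")
}

#' Write a map set as SIMMAP-annotated Newick strings
#'
#' Each branch is annotated `{state,duration:state,duration...}` in
#' parent-to-child order, the conventional stochastic-mapping exchange
#' format.
#'
#' @param x a `simmap_set`.
#' @param path output file; one tree per line.
#' @return invisibly, the character vector of annotated trees.
#' @export
write_simmap <- function(x, path) {
  tr <- x$tree
  ntip <- length(tr$tip.label)
  lines <- vapply(x$maps, function(m) {
    lab <- function(node) {
      ch <- which(x$edge[, 1L] == node)
      core <- if (!length(ch)) tr$tip.label[node]
      else paste0("(", paste(vapply(x$edge[ch, 2L], lab, ""), collapse = ","), ")")
      e <- which(x$edge[, 2L] == node)
      if (!length(e)) return(core)
      h <- m$histories[[e]]
      ann <- paste(sprintf("%s,%g", x$states[h$states], h$durations),
                   collapse = ":")
      paste0(core, ":{", ann, "}")
    }
    paste0(lab(ntip + 1L), ";")
  }, "")
  writeLines(lines, path)
  invisible(lines)
}
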