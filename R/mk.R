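#' Discrete trait container
#'
#' Couples an ordered state space with tip observations. Most functions also
#' accept a plain named vector of states (names = tip labels), in which case
#' the state space is the sorted set of observed states.
#'
#' @param tip_states named character vector, names are tip labels; `NA` marks
#'   a missing observation.
#' @param states ordered character vector of state labels; defaults to the
#'   sorted unique observed states. The order matters for ordered-state
#'   parsimony costs.
#' @return an object of class `discrete_trait`.
#' @export
discrete_trait <- function(tip_states, states = NULL) {
  tip_states <- vapply(tip_states, as.character, "", USE.NAMES = TRUE)
  if (is.null(states)) states <- sort(unique(tip_states[!is.na(tip_states)]))
  bad <- setdiff(unique(tip_states[!is.na(tip_states)]), states)
  if (length(bad)) stop("observed states not in state space: ",
                        paste(bad, collapse = ", "))
  structure(list(states = states, tip_states = tip_states),
            class = "discrete_trait")
}

# Normalise a trait argument against a tree: integer state index per tip
# (NA = missing), in tree tip order.
.resolve_trait <- function(trait, tree, states = NULL) {
  if (inherits(trait, "discrete_trait")) {
    states <- trait$states
    trait <- trait$tip_states
  }
  if (is.null(names(trait))) stop("tip states must be named by tip label")
  if (is.null(states)) states <- sort(unique(as.character(trait[!is.na(trait)])))
  miss <- setdiff(tree$tip.label, names(trait))
  x <- rep(NA_character_, length(tree$tip.label))
  names(x) <- tree$tip.label
  known <- intersect(tree$tip.label, names(trait))
  x[known] <- as.character(trait[known])
  idx <- match(x, states)
  if (any(!is.na(x) & is.na(idx))) stop("tip state outside the state space")
  list(states = states, k = length(states), idx = idx)
}

# Precomputed pruning context: postorder tree + tip partial template.
.mk_context <- function(tree, trait, states = NULL) {
  .check_tree(tree)
  tr <- .resolve_trait(trait, tree, states)
  po <- .postorder(tree)
  k <- tr$k
  nnode <- po$ntip + po$nnode
  up0 <- matrix(1, nnode, k)
  for (i in seq_len(po$ntip)) {
    if (!is.na(tr$idx[i])) {
      up0[i, ] <- 0
      up0[i, tr$idx[i]] <- 1
    }
  }
  list(po = po, up0 = up0, k = k, states = tr$states, tip_idx = tr$idx)
}

# Felsenstein pruning over a precomputed context.
.pruning_ctx <- function(ctx, Q, root_prior = "equal") {
  po <- ctx$po; k <- ctx$k
  P <- .tp_array(Q, po$el)
  up <- ctx$up0
  lsc <- numeric(nrow(up))
  msg <- matrix(0, nrow(po$edge), k)  # per-edge message child -> parent
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    m <- P[, , e] %*% up[ch, ]
    msg[e, ] <- m
    up[par, ] <- up[par, ] * m
    lsc[par] <- lsc[par] + lsc[ch]
    mx <- max(up[par, ])
    if (mx <= 0) stop("zero likelihood: incompatible tip data / Q")
    up[par, ] <- up[par, ] / mx
    lsc[par] <- lsc[par] + log(mx)
  }
  prior <- .root_prior_vec(root_prior, Q, k)
  lnL <- log(sum(prior * up[po$root, ])) + lsc[po$root]
  list(lnL = lnL, up = up, lsc = lsc, msg = msg, P = P, po = po,
       prior = prior, states = ctx$states, tip_idx = ctx$tip_idx, k = k)
}

# One-shot pruning (validates Q and the trait/Q state-space match).
.pruning <- function(tree, trait, Q, root_prior = "equal") {
  .check_q(Q)
  ctx <- .mk_context(tree, trait, rownames(Q))
  if (ctx$k != nrow(Q)) stop("state space size does not match dim(Q)")
  .pruning_ctx(ctx, Q, root_prior)
}

#' Mk-model log-likelihood by Felsenstein pruning
#'
#' Likelihood of discrete tip states under a continuous-time Markov (Mk)
#' model with rate matrix `Q`, computed by the pruning algorithm with
#' per-branch transition matrices \eqn{e^{Qt}}. Tips with missing states
#' contribute an all-ones partial vector.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param trait a [discrete_trait] or named vector of tip states.
#' @param Q rate matrix (rows sum to 0, non-negative off-diagonals); row
#'   names, if present, name the states.
#' @param root_prior `"equal"` (default 1/k), `"stationary"`, or a numeric
#'   vector of length k.
#' @return the log-likelihood (numeric scalar).
#' @export
mk_loglik <- function(tree, trait, Q, root_prior = "equal") {
  .pruning(tree, trait, Q, root_prior)$lnL
}

#' Marginal ancestral state probabilities ("pies")
#'
#' Marginal posterior probability of each state at every node, combining the
#' upward conditional likelihoods with a downward pass. Tips with observed
#' states get degenerate vectors.
#'
#' @inheritParams mk_loglik
#' @return matrix (nodes x states); rows ordered tips then internal nodes in
#'   ape numbering, rownames are tip labels / `"node<N>"`.
#' @export
marginal_ancestrals <- function(tree, trait, Q, root_prior = "equal") {
  pr <- .pruning(tree, trait, Q, root_prior)
  po <- pr$po; k <- pr$k
  nnode <- po$ntip + po$nnode
  down <- matrix(0, nnode, k)
  down[po$root, ] <- pr$prior
  children <- split(seq_len(nrow(po$edge)), po$edge[, 1L])
  for (e in rev(seq_len(nrow(po$edge)))) {      # preorder
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    sib <- setdiff(children[[as.character(par)]], e)
    flow <- down[par, ]
    for (s in sib) flow <- flow * pr$msg[s, ]
    dv <- as.numeric(crossprod(pr$P[, , e], flow))  # sum_j flow_j P[j,i]
    tot <- sum(dv)
    down[ch, ] <- if (tot > 0) dv / tot else rep(1 / k, k)
  }
  marg <- down * pr$up
  marg <- marg / rowSums(marg)
  colnames(marg) <- pr$states
  rownames(marg) <- c(po$tree$tip.label,
                      paste0("node", (po$ntip + 1L):nnode))
  marg
}

# Build Q from a log-rate parameter vector for a given model.
.mk_build_q <- function(logpar, k, model) {
  r <- exp(logpar)
  Q <- matrix(0, k, k)
  if (model == "ER") {
    Q[] <- r[1]
  } else if (model == "SYM") {
    p <- 1L
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      Q[i, j] <- Q[j, i] <- r[p]; p <- p + 1L
    }
  } else { # ARD: row-wise off-diagonal order
    p <- 1L
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
      Q[i, j] <- r[p]; p <- p + 1L
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

.mk_npar <- function(model, k) {
  switch(model, ER = 1L, SYM = as.integer(k * (k - 1) / 2),
         ARD = as.integer(k * (k - 1)))
}

#' Fit an Mk model (ER, SYM or ARD) by maximum likelihood
#'
#' Rates are optimised on the log scale with bounded quasi-Newton iterations
#' from a deterministic grid of starting values (multi-start), so fits are
#' reproducible without a seed. AICc uses the number of tips as the sample
#' size.
#'
#' @inheritParams mk_loglik
#' @param model `"ER"` (one rate), `"SYM"` (symmetric), or `"ARD"` (all
#'   rates different).
#' @param states optional explicit state space (ordering matters only for
#'   labelling here).
#' @param lower,upper bounds for each rate.
#' @return an object of class `mk_fit`: `model`, `Q`, `lnL`, `k_free`,
#'   `aicc`, `states`, `convergence`.
#' @export
fit_mk <- function(tree, trait, model = c("ER", "SYM", "ARD"),
                   root_prior = "equal", states = NULL,
                   lower = 1e-8, upper = 1e3) {
  model <- match.arg(model)
  .check_tree(tree)
  tr <- .resolve_trait(trait, tree, states)
  k <- tr$k
  n <- length(tree$tip.label)
  obs <- tr$idx[!is.na(tr$idx)]
  npar <- .mk_npar(model, k)
  trait_v <- setNames(tr$states[tr$idx], tree$tip.label)
  if (length(unique(obs)) < 2) {
    warning("all observed tips share one state: boundary fit at the lower rate bound")
    Q <- .mk_build_q(rep(log(lower), npar), k, model)
    rownames(Q) <- colnames(Q) <- tr$states
    lnL <- mk_loglik(tree, trait_v, Q, root_prior)
  } else {
    ctx <- .mk_context(tree, trait_v, tr$states)
    negll <- function(lp) {
      Q <- .mk_build_q(lp, k, model)
      ll <- tryCatch(.pruning_ctx(ctx, Q, root_prior)$lnL,
                     error = function(e) -Inf)
      if (!is.finite(ll)) 1e10 else -ll
    }
    tl <- sum(tree$edge.length)
    r0 <- max(length(unique(obs)) / max(tl, 1e-8), 10 * lower)
    best <- NULL
    for (mult in c(0.2, 1, 5)) {
      st <- rep(log(min(max(r0 * mult, lower * 1.01), upper * 0.99)), npar)
      fit <- tryCatch(
        nlminb(st, negll, lower = log(lower), upper = log(upper),
               control = list(iter.max = 500, eval.max = 1000)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
        best <- fit
    }
    if (is.null(best)) stop("Mk optimisation failed for all starts")
    Q <- .mk_build_q(best$par, k, model)
    rownames(Q) <- colnames(Q) <- tr$states
    lnL <- -best$objective
  }
  aicc <- -2 * lnL + 2 * npar + 2 * npar * (npar + 1) / (n - npar - 1)
  structure(list(model = model, Q = Q, lnL = lnL, k_free = npar,
                 aicc = aicc, states = tr$states, n_tips = n),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk fit (%s): lnL = %.4f, k_free = %d, AICc = %.4f\n",
              x$model, x$lnL, x$k_free, x$aicc))
  print(round(x$Q, 6))
  invisible(x)
}

#' Likelihood-ratio comparison of nested Mk fits
#'
#' Compares a simple fit nested in a complex one (ER in SYM in ARD) with the
#' chi-square likelihood-ratio test
#' \eqn{p = P(\chi^2_{\Delta k} > |2\Delta \ell|)} and reports AICc for both.
#' The complex model is chosen when `p < alpha`.
#'
#' @param fit_simple,fit_complex `mk_fit` objects with
#'   `fit_simple$k_free <= fit_complex$k_free`.
#' @param alpha significance level (default 0.05).
#' @return list with `stat`, `df`, `p`, `chosen` (model string), and the
#'   AICc of both fits.
#' @export
compare_models_lrt <- function(fit_simple, fit_complex, alpha = 0.05) {
  if (fit_complex$k_free < fit_simple$k_free)
    stop("fit_complex must have at least as many free parameters")
  df <- fit_complex$k_free - fit_simple$k_free
  stat <- abs(2 * (fit_simple$lnL - fit_complex$lnL))
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  chosen <- if (df > 0 && p < alpha) fit_complex$model else fit_simple$model
  list(stat = stat, df = df, p = p, chosen = chosen, alpha = alpha,
       aicc_simple = fit_simple$aicc, aicc_complex = fit_complex$aicc)
}

#' Fit ER/SYM/ARD and choose a model along the nested LRT path
#'
#' Fits the requested models and walks the nesting chain ER -> SYM -> ARD,
#' moving to the more complex model whenever its LRT p-value is below
#' `alpha`. Returns all fits plus the model-choice table.
#'
#' @inheritParams fit_mk
#' @param models character vector among ER, SYM, ARD.
#' @param alpha LRT significance level.
#' @return list(fits, table, chosen).
#' @export
choose_mk_model <- function(tree, trait, models = c("ER", "SYM", "ARD"),
                            root_prior = "equal", alpha = 0.05) {
  models <- match.arg(models, c("ER", "SYM", "ARD"), several.ok = TRUE)
  fits <- lapply(models, function(m) fit_mk(tree, trait, m, root_prior))
  names(fits) <- models
  tab <- data.frame(model = models,
                    lnL = vapply(fits, `[[`, 0, "lnL"),
                    k_free = vapply(fits, `[[`, 0L, "k_free"),
                    aicc = vapply(fits, `[[`, 0, "aicc"),
                    lrt_p = NA_real_)
  chain <- intersect(c("ER", "SYM", "ARD"), models)
  chosen <- chain[1]
  if (length(chain) > 1) {
    for (i in 2:length(chain)) {
      cmp <- compare_models_lrt(fits[[chosen]], fits[[chain[i]]], alpha)
      tab$lrt_p[tab$model == chain[i]] <- cmp$p
      if (cmp$chosen == chain[i]) chosen <- chain[i]
    }
  }
  list(fits = fits, table = tab, chosen = chosen)
}
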