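# Pagel's lambda and Brownian-motion ancestral states.
#
# The BM covariance of tip i and j is sigma2 * C[i, j], with C[i, j] the
# shared root-to-MRCA path length; Pagel's lambda multiplies the
# off-diagonal of C while preserving tip variances.

# Resolve a continuous trait to a numeric vector in tree tip order.
.resolve_cont <- function(trait, tree) {
  if (is.null(names(trait))) stop("trait values must be named by tip label")
  x <- trait[tree$tip.label]
  names(x) <- tree$tip.label
  x
}

#' Pagel's lambda branch-length transform
#'
#' Scales internal branch lengths by `lambda` and stretches each terminal
#' branch so every root-to-tip distance is preserved: off-diagonal
#' phylogenetic covariances shrink by `lambda`, tip variances are unchanged.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param lambda value in `[0, lambda_max(tree)]`; `lambda_max` is the
#'   largest value keeping all terminal branches non-negative,
#'   `min(depth(tip)/depth(parent))`, always >= 1.
#' @return the transformed `phylo`.
#' @export
lambda_transform <- function(tree, lambda) {
  .check_tree(tree)
  lmax <- lambda_max(tree)
  if (lambda < 0 || lambda > lmax + 1e-12)
    stop(sprintf("lambda must lie in [0, %.6f]", lmax))
  depth <- .node_depths(tree)
  ntip <- length(tree$tip.label)
  tr <- tree
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2L]
    tr$edge.length[e] <- if (ch > ntip) lambda * tree$edge.length[e]
    else depth[ch] - lambda * depth[tr$edge[e, 1L]]
  }
  tr
}

#' Largest admissible Pagel's lambda for a tree
#' @param tree rooted `phylo` with branch lengths.
#' @return numeric scalar >= 1.
#' @export
lambda_max <- function(tree) {
  depth <- .node_depths(tree)
  ntip <- length(tree$tip.label)
  term <- tree$edge[, 2L] <= ntip
  pd <- depth[tree$edge[term, 1L]]
  td <- depth[tree$edge[term, 2L]]
  if (all(pd <= 0)) Inf else min(td[pd > 0] / pd[pd > 0])
}

# Lambda-transformed tip covariance (off-diagonal scaled, diagonal kept).
.lambda_vcv <- function(C, lambda) {
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

# Gaussian phylogenetic machinery: GLS mean, quadratic form, log-det.
.phylo_gauss <- function(C, x) {
  R <- tryCatch(chol(C), error = function(e)
    chol(C + diag(1e-8 * mean(diag(C)), nrow(C))))
  one <- rep(1, length(x))
  Ci_x <- backsolve(R, backsolve(R, x, transpose = TRUE))
  Ci_1 <- backsolve(R, backsolve(R, one, transpose = TRUE))
  z0 <- sum(Ci_x) / sum(Ci_1)
  r <- x - z0
  Ci_r <- backsolve(R, backsolve(R, r, transpose = TRUE))
  list(z0 = z0, quad = sum(r * Ci_r), logdet = 2 * sum(log(diag(R))),
       sum_Ci = sum(Ci_1))
}

#' Brownian-motion log-likelihood on a tree
#'
#' Multivariate normal log-density of the tip values with mean `z0` and
#' covariance `sigma2 * C(tree)`.
#'
#' @param tree rooted `phylo`.
#' @param trait named numeric tip values.
#' @param sigma2 BM variance rate (> 0).
#' @param z0 root value.
#' @return log-likelihood scalar.
#' @export
bm_loglik <- function(tree, trait, sigma2, z0) {
  .check_tree(tree)
  stopifnot(sigma2 > 0)
  x <- .resolve_cont(trait, tree)
  if (anyNA(x)) stop("missing trait values; prune the tree first")
  C <- ape::vcv.phylo(tree)[names(x), names(x)]
  n <- length(x)
  R <- tryCatch(chol(C), error = function(e)
    stop("singular phylogenetic covariance (duplicate zero-length tips?)"))
  r <- x - z0
  Ci_r <- backsolve(R, backsolve(R, r, transpose = TRUE))
  -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(R))) +
            sum(r * Ci_r) / sigma2)
}

#' Maximum-likelihood Pagel's lambda
#'
#' Profiles sigma^2 and the root value analytically at each lambda and
#' maximises over lambda in `[0, lambda_max]` by bounded one-dimensional
#' optimisation (tolerance 1e-8) with a refinement pass. The reported
#' p-value compares the fit against lambda = 0 with a chi-square(1)
#' likelihood-ratio test (optionally halved for the boundary).
#'
#' @param tree rooted `phylo`.
#' @param trait named numeric tip values (tips with `NA` are dropped with a
#'   warning).
#' @param boundary_correction if `TRUE`, use the 50:50 chi-square mixture
#'   appropriate when the null value 0 sits on the parameter boundary.
#' @param upper upper bound of the lambda search; default
#'   `min(lambda_max(tree), 1)`. Raise it explicitly to allow lambda > 1.
#' @return object of class `lambda_fit`: `lambda`, `sigma2`, `z0`, `lnL`,
#'   `lnL0` (at lambda = 0), `p_vs_zero`.
#' @export
fit_lambda <- function(tree, trait, boundary_correction = FALSE,
                       upper = NULL) {
  .check_tree(tree)
  x <- .resolve_cont(trait, tree)
  if (anyNA(x)) {
    warning("dropping ", sum(is.na(x)), " tips with missing trait values")
    tree <- ape::drop.tip(tree, names(x)[is.na(x)])
    x <- x[tree$tip.label]
  }
  n <- length(x)
  if (n < 3) stop("need >= 3 tips with data")
  if (sd(x) == 0) stop("no variance: constant trait")
  C <- ape::vcv.phylo(tree)[names(x), names(x)]
  if (is.null(upper)) upper <- min(lambda_max(tree), 1)
  prof <- function(lam) {
    g <- .phylo_gauss(.lambda_vcv(C, lam), x)
    s2 <- g$quad / n
    list(lnL = -0.5 * (n * log(2 * pi * s2) + g$logdet + n),
         sigma2 = s2, z0 = g$z0)
  }
  obj <- function(lam) -prof(lam)$lnL
  opt <- optimize(obj, c(0, upper), tol = 1e-8)
  # refine near the optimum and compare with the boundaries
  lo <- max(0, opt$minimum - 1e-3); hi <- min(upper, opt$minimum + 1e-3)
  opt2 <- optimize(obj, c(lo, hi), tol = 1e-10)
  cand <- c(opt$minimum, opt2$minimum, 0, upper)
  vals <- vapply(cand, obj, 0)
  lam_hat <- cand[which.min(vals)]
  at <- prof(lam_hat)
  lnL0 <- prof(0)$lnL
  stat <- max(0, 2 * (at$lnL - lnL0))
  p <- pchisq(stat, 1, lower.tail = FALSE)
  if (boundary_correction) p <- if (stat == 0) 1 else p / 2
  structure(list(lambda = lam_hat, sigma2 = at$sigma2, z0 = at$z0,
                 lnL = at$lnL, lnL0 = lnL0, p_vs_zero = p, n = n),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("Pagel's lambda: %.4f (sigma2 = %.4g, z0 = %.4g, lnL = %.4f, p vs 0 = %.3g)\n",
              x$lambda, x$sigma2, x$z0, x$lnL, x$p_vs_zero))
  invisible(x)
}

#' Compare phylogenetic signal on two trees of the same tips
#'
#' Fits Pagel's lambda for the same trait on two alternative trees
#' (typically a phylogram and a chronogram) and reports both fits side by
#' side, the usual basis for choosing which tree to reconstruct on.
#'
#' @param tree_a,tree_b two `phylo` objects sharing the trait's tips.
#' @param trait named numeric tip values.
#' @param labels length-2 labels for the report.
#' @return data.frame with one row per tree: lambda, sigma2, lnL, p.
#' @export
compare_lambda_trees <- function(tree_a, tree_b, trait,
                                 labels = c("phylogram", "chronogram")) {
  fa <- fit_lambda(tree_a, trait)
  fb <- fit_lambda(tree_b, trait)
  data.frame(tree = labels,
             lambda = c(fa$lambda, fb$lambda),
             sigma2 = c(fa$sigma2, fb$sigma2),
             lnL = c(fa$lnL, fb$lnL),
             p_vs_zero = c(fa$p_vs_zero, fb$p_vs_zero))
}

#' Brownian-motion ancestral states with variances and 95% CIs
#'
#' Maximum-likelihood ancestral values under BM. For each internal node the
#' tree is implicitly re-rooted at that node and the GLS estimate
#' \eqn{(1'C_v^{-1}y)/(1'C_v^{-1}1)} with variance
#' \eqn{\hat\sigma^2/(1'C_v^{-1}1)} is computed; \eqn{\hat\sigma^2} is the
#' (n-1)-denominator GLS estimate at the root, which keeps the nominal 95%
#' interval close to its stated coverage. CI = estimate +/- 1.96 sd.
#'
#' @param tree rooted `phylo`.
#' @param trait named numeric tip values; tips with `NA` are pruned with a
#'   warning.
#' @return data.frame (one row per internal node, ape numbering): `node`,
#'   `estimate`, `var`, `ci_low`, `ci_high`; attribute `sigma2`.
#' @export
anc_bm <- function(tree, trait) {
  .check_tree(tree)
  x <- .resolve_cont(trait, tree)
  if (anyNA(x)) {
    warning("dropping ", sum(is.na(x)), " tips with missing trait values")
    tree <- ape::drop.tip(tree, names(x)[is.na(x)])
    x <- x[tree$tip.label]
  }
  n <- length(x)
  if (n < 2) stop("need >= 2 tips with data")
  ntip <- n
  nnode <- tree$Nnode
  D <- ape::dist.nodes(tree)
  tipid <- seq_len(ntip)
  C_root <- ape::vcv.phylo(tree)[tree$tip.label, tree$tip.label]
  g <- .phylo_gauss(C_root, x)
  sigma2 <- g$quad / max(n - 1, 1)
  out <- data.frame(node = (ntip + 1L):(ntip + nnode),
                    estimate = NA_real_, var = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_)
  for (r in seq_len(nnode)) {
    v <- ntip + r
    dv <- D[v, tipid]
    Cv <- (outer(dv, dv, "+") - D[tipid, tipid]) / 2
    diag(Cv) <- dv
    gv <- .phylo_gauss(Cv + 1e-12 * diag(ntip) * max(dv, 1), x)
    est <- gv$z0
    va <- sigma2 / gv$sum_Ci
    out$estimate[r] <- est
    out$var[r] <- va
    out$ci_low[r] <- est - 1.96 * sqrt(va)
    out$ci_high[r] <- est + 1.96 * sqrt(va)
  }
  attr(out, "sigma2") <- sigma2
  out
}
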