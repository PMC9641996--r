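# Matched-pairs tests of symmetry screening alignments for violations of
# the stationarity / reversibility / homogeneity (SRH) conditions.
# Bowker tests full symmetry of the 4x4 divergence matrix, Stuart its
# marginal component, and the internal test the remainder.

#' Paired site-pattern counts for two taxa
#'
#' 4x4 matrix `n[i, j]` = number of aligned columns (restricted to the
#' selected codon positions) where taxon A carries base i and taxon B base
#' j (order A, C, G, T). Columns with a gap or ambiguity in either taxon
#' are excluded pairwise.
#'
#' @param aln character matrix (rows = taxa, columns = sites), codon-framed
#'   from column 1.
#' @param taxon_a,taxon_b row names in `aln`.
#' @param positions subset of 1:3.
#' @return object of class `paired_counts`: `n` (4x4), `taxon_a`,
#'   `taxon_b`, `total`.
#' @export
paired_site_counts <- function(aln, taxon_a, taxon_b, positions = c(1L, 2L)) {
  for (tx in c(taxon_a, taxon_b))
    if (!tx %in% rownames(aln)) stop("taxon absent from alignment: ", tx)
  stopifnot(all(positions %in% 1:3))
  cp <- ((seq_len(ncol(aln)) - 1L) %% 3L) + 1L
  keep <- cp %in% positions
  a <- toupper(aln[taxon_a, keep])
  b <- toupper(aln[taxon_b, keep])
  ok <- a %in% .BASES & b %in% .BASES
  n <- table(factor(a[ok], .BASES), factor(b[ok], .BASES))
  n <- matrix(as.integer(n), 4, 4, dimnames = list(.BASES, .BASES))
  structure(list(n = n, taxon_a = taxon_a, taxon_b = taxon_b,
                 total = sum(n)),
            class = "paired_counts")
}

.counts_mat <- function(counts) {
  if (inherits(counts, "paired_counts")) counts$n else counts
}

#' Bowker's test of symmetry
#'
#' \eqn{S = \sum_{i<j} (n_{ij}-n_{ji})^2/(n_{ij}+n_{ji})} over the pairs
#' with \eqn{n_{ij}+n_{ji}>0}; df = number of such pairs (at most 6). A
#' fully diagonal matrix has df 0 and p = 1 (no detectable asymmetry).
#'
#' @param counts a [paired_site_counts] result or plain 4x4 matrix.
#' @return list(stat, df, p).
#' @export
bowker_test <- function(counts) {
  n <- .counts_mat(counts)
  stat <- 0; df <- 0L
  for (i in 1:3) for (j in (i + 1):4) {
    tot <- n[i, j] + n[j, i]
    if (tot > 0) {
      stat <- stat + (n[i, j] - n[j, i])^2 / tot
      df <- df + 1L
    }
  }
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(stat = stat, df = df, p = p)
}

#' Stuart's test of marginal symmetry
#'
#' With u the first three components of (row sums - column sums) and V the
#' 3x3 matrix `V[i,i] = row_i + col_i - 2 n_ii`,
#' `V[i,j] = -(n_ij + n_ji)`, the statistic is \eqn{u^T V^{-1} u} on 3 df.
#' A singular V is reported as degenerate with p = 1.
#'
#' @inheritParams bowker_test
#' @return list(stat, df = 3, p, degenerate).
#' @export
stuart_test <- function(counts) {
  n <- .counts_mat(counts)
  u <- (rowSums(n) - colSums(n))[1:3]
  V <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    V[i, j] <- if (i == j) rowSums(n)[i] + colSums(n)[i] - 2 * n[i, i]
    else -(n[i, j] + n[j, i])
  }
  ok <- tryCatch(rcond(V) > 1e-12, error = function(e) FALSE)
  if (!ok)
    return(list(stat = NA_real_, df = 3L, p = 1, degenerate = TRUE))
  stat <- as.numeric(t(u) %*% solve(V, u))
  list(stat = stat, df = 3L, p = pchisq(stat, 3, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Internal symmetry test
#'
#' Difference between Bowker's and Stuart's statistics on
#' `bowker_df - 3` degrees of freedom; a negative difference is clipped to
#' 0 and flagged, and df < 1 (or a degenerate Stuart test) yields p = 1
#' with a flag.
#'
#' @inheritParams bowker_test
#' @return list(stat, df, p, flagged).
#' @export
internal_symmetry_test <- function(counts) {
  b <- bowker_test(counts)
  s <- stuart_test(counts)
  df <- b$df - 3L
  if (df < 1L || s$degenerate)
    return(list(stat = NA_real_, df = df, p = 1, flagged = TRUE))
  stat <- b$stat - s$stat
  flagged <- stat < 0
  if (flagged) stat <- 0
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       flagged = flagged)
}

#' SRH screen of one alignment
#'
#' Runs the three matched-pairs symmetry tests on every taxon pair at the
#' selected codon positions. The cluster fails when the minimum Bowker
#' p-value over pairs is below `alpha` (after optional Bonferroni
#' correction over the number of pairs); degenerate tables count as passes.
#'
#' @param aln character matrix (rows = taxa).
#' @param positions codon positions tested (default 1 and 2; the third
#'   position is conventionally discarded).
#' @param alpha significance level.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @param test which test drives the verdict (default `"bowker"`, the
#'   omnibus screen; `"stuart"` and `"internal"` exposed as options).
#' @return object of class `srh_result`: `pairs` (per-pair data.frame of
#'   all three tests), `verdict` (`"pass"`/`"fail"`), `alpha`, `positions`.
#' @export
srh_filter_cluster <- function(aln, positions = c(1L, 2L), alpha = 0.05,
                               correction = c("none", "bonferroni"),
                               test = c("bowker", "stuart", "internal")) {
  correction <- match.arg(correction)
  test <- match.arg(test)
  taxa <- rownames(aln)
  if (length(taxa) < 2) stop("need >= 2 taxa")
  combs <- utils::combn(taxa, 2)
  rows <- vector("list", ncol(combs))
  for (c_i in seq_len(ncol(combs))) {
    pc <- paired_site_counts(aln, combs[1, c_i], combs[2, c_i], positions)
    b <- bowker_test(pc); s <- stuart_test(pc); int <- internal_symmetry_test(pc)
    rows[[c_i]] <- data.frame(
      taxon_a = pc$taxon_a, taxon_b = pc$taxon_b, n_sites = pc$total,
      bowker_stat = b$stat, bowker_df = b$df, bowker_p = b$p,
      stuart_stat = s$stat, stuart_p = s$p,
      internal_stat = int$stat, internal_df = int$df, internal_p = int$p)
  }
  pairs <- do.call(rbind, rows)
  pcol <- switch(test, bowker = pairs$bowker_p, stuart = pairs$stuart_p,
                 internal = pairs$internal_p)
  thr <- if (correction == "bonferroni") alpha / nrow(pairs) else alpha
  verdict <- if (any(pcol < thr, na.rm = TRUE)) "fail" else "pass"
  structure(list(pairs = pairs, verdict = verdict, alpha = alpha,
                 correction = correction, positions = positions, test = test),
            class = "srh_result")
}

#' @export
print.srh_result <- function(x, ...) {
  cat(sprintf("SRH screen (%s, positions %s, alpha %.3g, %s): %s (min p = %.3g over %d pairs)\n",
              x$test, paste(x$positions, collapse = "+"), x$alpha,
              x$correction, x$verdict,
              min(x$pairs$bowker_p, na.rm = TRUE), nrow(x$pairs)))
  invisible(x)
}
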