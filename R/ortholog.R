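# Ortholog-cluster filtering and representative-transcript selection.
#
# Hit tables are BLAST outfmt-6-extended data.frames with columns
# qseqid, sseqid, pident, length, qlen, slen, evalue, bitscore.

.check_hits <- function(hits, need = c("qseqid", "sseqid", "pident", "length",
                                       "qlen", "slen", "evalue", "bitscore")) {
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hit table missing columns: ",
                         paste(miss, collapse = ", "))
  invisible(hits)
}

#' Flag contaminant transcripts from a contaminant-database hit table
#'
#' General databases flag a transcript when a hit has identity > 90 and
#' query coverage > 25% (coverage = 100 * alignment length / query length);
#' the cricket (feeder-insect) screen flags on identity >= 90 with no
#' coverage requirement. Thresholds use strict/inclusive comparisons
#' exactly as stated.
#'
#' @param hits hit data.frame (queries are the transcripts under test,
#'   subjects the contaminant database).
#' @param db_kind `"general"` or `"cricket"`.
#' @param min_identity,min_coverage thresholds (defaults 90 and 25).
#' @return character vector of flagged transcript ids (unique).
#' @export
flag_contaminants <- function(hits, db_kind = c("general", "cricket"),
                              min_identity = 90, min_coverage = 25) {
  db_kind <- match.arg(db_kind)
  .check_hits(hits, c("qseqid", "pident", "length", "qlen"))
  bad <- which(is.na(hits$qlen) | hits$qlen <= 0)
  if (length(bad))
    stop("qlen missing or zero in hit row(s): ",
         paste(head(bad, 5), collapse = ", "),
         " (query ", hits$qseqid[bad[1]], ")")
  flagged <- if (db_kind == "general") {
    coverage <- 100 * hits$length / hits$qlen
    hits$pident > min_identity & coverage > min_coverage
  } else {
    hits$pident >= min_identity
  }
  unique(hits$qseqid[flagged])
}

# Global identity between two sequences: position-wise for equal lengths,
# Needleman-Wunsch via Biostrings otherwise.
.pairwise_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    return(mean(x == y))
  }
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings needed for unequal-length global identity")
  al <- Biostrings::pairwiseAlignment(a, b, type = "global")
  Biostrings::pid(al, type = "PID1") / 100
}

#' Greedy redundancy reduction (CD-HIT-style)
#'
#' Longest-first greedy clustering: records are visited by length
#' (descending), ties by transcript id (ascending); a record is dropped
#' when its global identity to an already-retained record is at or above
#' the threshold. Deterministic given that ordering.
#'
#' @param records data.frame with `transcript_id`, `sequence` (and
#'   optionally `species_id`, `length`).
#' @param identity_threshold fraction in (0.5, 1]; default 0.995 mirrors the
#'   usual CD-HIT setting for isoform collapse.
#' @return the retained subset of `records` (original row order not
#'   preserved; sorted by the visiting order).
#' @export
reduce_redundancy <- function(records, identity_threshold = 0.995) {
  stopifnot(identity_threshold > 0.5, identity_threshold <= 1)
  if (!nrow(records)) return(records)
  if (is.null(records$length)) records$length <- nchar(records$sequence)
  ord <- order(-records$length, records$transcript_id)
  records <- records[ord, , drop = FALSE]
  keep <- logical(nrow(records))
  kept_idx <- integer(0)
  for (i in seq_len(nrow(records))) {
    dup <- FALSE
    for (j in kept_idx) {
      if (.pairwise_identity(records$sequence[i], records$sequence[j]) >=
          identity_threshold) { dup <- TRUE; break }
    }
    if (!dup) { keep[i] <- TRUE; kept_idx <- c(kept_idx, i) }
  }
  records[keep, , drop = FALSE]
}

#' Retain clusters covering a minimum fraction of the species
#'
#' A cluster passes when its number of distinct species is at least
#' `min_fraction * n_species_total` (inclusive >=, no rounding: 84/104
#' passes at 0.8, 83/104 fails).
#'
#' @param clusters data.frame with `cluster_id`, `species_id`,
#'   `transcript_id`.
#' @param n_species_total total species in the study.
#' @param min_fraction minimum species fraction (default 0.8).
#' @return list: `clusters` (retained rows), `report` (per-cluster
#'   data.frame cluster_id/n_species/decision/reason).
#' @export
filter_clusters_by_coverage <- function(clusters, n_species_total,
                                        min_fraction = 0.8) {
  stopifnot(n_species_total >= 1)
  ids <- unique(clusters$cluster_id)
  nsp <- vapply(ids, function(cid)
    length(unique(clusters$species_id[clusters$cluster_id == cid])), 0L)
  empty <- nsp == 0
  if (any(empty)) warning("dropping empty cluster(s): ",
                          paste(ids[empty], collapse = ", "))
  thr <- min_fraction * n_species_total
  pass <- nsp >= thr & !empty
  report <- data.frame(cluster_id = ids, n_species = nsp,
                       decision = ifelse(pass, "retained", "dropped"),
                       reason = ifelse(pass, "",
                                       ifelse(empty, "empty",
                                              sprintf("%d < %.1f", nsp, thr))))
  list(clusters = clusters[clusters$cluster_id %in% ids[pass], , drop = FALSE],
       report = report)
}

#' Cumulative best-hit scores within a cluster
#'
#' For each member transcript t, the score is the sum over the other
#' species s' of the maximum bitscore among t's hits to transcripts of s'
#' inside the cluster (0 when there is no hit).
#'
#' @param members data.frame with `species_id`, `transcript_id` (one
#'   cluster's membership).
#' @param hits hit data.frame; rows whose query or subject is outside the
#'   cluster are ignored.
#' @return named numeric vector, one score per member transcript.
#' @export
cumulative_scores <- function(members, hits) {
  ids <- members$transcript_id
  sp_of <- setNames(members$species_id, ids)
  scores <- setNames(numeric(length(ids)), ids)
  h <- hits[hits$qseqid %in% ids & hits$sseqid %in% ids, , drop = FALSE]
  if (!nrow(h)) return(scores)
  h$ssp <- sp_of[h$sseqid]
  h <- h[sp_of[h$qseqid] != h$ssp, , drop = FALSE]
  if (!nrow(h)) return(scores)
  agg <- aggregate(bitscore ~ qseqid + ssp, data = h, FUN = max)
  tot <- tapply(agg$bitscore, agg$qseqid, sum)
  scores[names(tot)] <- tot
  scores
}

# Best e-value of transcript t against any member of `targets`.
# Ties by e-value resolved later; returns c(evalue, bitscore_at_best).
.best_hit <- function(t, targets, hits) {
  h <- hits[(hits$qseqid == t & hits$sseqid %in% targets) |
              (hits$sseqid == t & hits$qseqid %in% targets), , drop = FALSE]
  if (!nrow(h)) return(c(Inf, 0))
  i <- order(h$evalue, -h$bitscore)[1]
  c(h$evalue[i], h$bitscore[i])
}

# Tie-break helper: order transcripts by score desc, length desc, id asc.
.rank_members <- function(ids, scores, lengths) {
  if (is.null(lengths)) lengths <- rep(0, length(ids))
  ord <- order(-scores[ids], -lengths, ids)
  ids[ord]
}

#' Two-list division of a (possibly chimeric) cluster
#'
#' One division round seeds list A with the maximum-cumulative-score
#' transcript and list B with the minimum; every other transcript joins the
#' seed to which it has the more significant best e-value (no hit = infinite
#' e-value; e-value ties broken by higher bitscore, then towards the
#' max-score seed). The longer list is divided again (`rounds = 2` by
#' default, mirroring one repetition), and the final longest list is
#' returned first. Clusters with fewer than two transcripts are returned
#' unchanged as the longest list.
#'
#' @param members one cluster's membership data.frame (`species_id`,
#'   `transcript_id`, optional `length`).
#' @param hits hit data.frame.
#' @param rounds number of division rounds applied to the running longest
#'   list (>= 1).
#' @return list: `longest_list`, `other_list` (character vectors of
#'   transcript ids; disjoint, union = input).
#' @export
split_chimeric_cluster <- function(members, hits, rounds = 2L) {
  ids <- members$transcript_id
  if (length(ids) < 2)
    return(list(longest_list = ids, other_list = character(0)))
  lens <- if (is.null(members$length)) setNames(rep(0, length(ids)), ids)
  else setNames(members$length, ids)

  divide_once <- function(sub_ids) {
    sub <- members[members$transcript_id %in% sub_ids, , drop = FALSE]
    sc <- cumulative_scores(sub, hits)
    ranked <- .rank_members(sub_ids, sc, lens[sub_ids])
    seed_a <- ranked[1]                       # max cumulative score
    seed_b <- ranked[length(ranked)]          # min cumulative score
    la <- seed_a; lb <- seed_b
    for (t in setdiff(sub_ids, c(seed_a, seed_b))) {
      ba <- .best_hit(t, seed_a, hits)
      bb <- .best_hit(t, seed_b, hits)
      to_a <- if (ba[1] != bb[1]) ba[1] < bb[1]
      else if (ba[2] != bb[2]) ba[2] > bb[2]
      else TRUE                               # tie: towards the max-score seed
      if (to_a) la <- c(la, t) else lb <- c(lb, t)
    }
    list(a = la, b = lb)
  }

  current <- ids
  other <- character(0)
  for (r in seq_len(max(1L, rounds))) {
    if (length(current) < 2) break
    d <- divide_once(current)
    longest <- if (length(d$a) >= length(d$b)) d$a else d$b
    other <- c(other, setdiff(current, longest))
    current <- longest
  }
  list(longest_list = current, other_list = other)
}

#' Select one representative transcript per species
#'
#' Within the final longest list of the two-list division, each species is
#' represented by its transcript of maximal cumulative score (computed
#' within that list). Each species present in the cluster but absent from
#' the longest list contributes the transcript with the best e-value
#' against any member of the longest list (falling back to cluster-wide
#' cumulative score when it has no such hit). The result has at most one
#' transcript per species and covers every species in the cluster.
#'
#' @inheritParams split_chimeric_cluster
#' @return named character vector: species_id -> transcript_id.
#' @export
select_representatives <- function(members, hits, rounds = 2L) {
  ids <- members$transcript_id
  sp_of <- setNames(members$species_id, ids)
  lens <- if (is.null(members$length)) setNames(rep(0, length(ids)), ids)
  else setNames(members$length, ids)
  division <- split_chimeric_cluster(members, hits, rounds)
  L <- division$longest_list
  subL <- members[members$transcript_id %in% L, , drop = FALSE]
  scL <- cumulative_scores(subL, hits)
  reps <- character(0)
  for (sp in unique(subL$species_id)) {
    cand <- subL$transcript_id[subL$species_id == sp]
    reps[sp] <- .rank_members(cand, scL, lens[cand])[1]
  }
  missing_sp <- setdiff(unique(members$species_id), names(reps))
  if (length(missing_sp)) {
    sc_all <- cumulative_scores(members, hits)
    for (sp in missing_sp) {
      cand <- ids[sp_of[ids] == sp]
      best <- t(vapply(cand, .best_hit, numeric(2), targets = L, hits = hits))
      ord <- order(best[, 1], -best[, 2], -sc_all[cand], cand)
      reps[sp] <- cand[ord[1]]
    }
  }
  reps
}
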