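# End-to-end orchestration: contaminant removal -> redundancy -> coverage
# filter -> representatives -> blocks -> SRH -> supermatrix, then optional
# discrete/continuous ancestral reconstructions. Every stage writes plain
# files so it can be rerun in isolation; a manifest records config, seed
# and per-stage counts.

#' Pipeline configuration
#'
#' @param clusters,hits,contaminant_hits,fasta_dir,aln_dir,tree,traits
#'   input paths (`contaminant_hits`, `fasta_dir`, `aln_dir`, `tree`,
#'   `traits` optional; `aln_dir` holds one `<cluster_id>.fasta` per gene
#'   with an optional `<cluster_id>.blocks.tsv` of start/end coordinates).
#' @param out output directory.
#' @param n_species total species count for the coverage rule (inferred
#'   from the cluster table when `NULL`).
#' @param min_frac coverage-filter species fraction (default 0.8).
#' @param min_block_coverage,min_block_nt conserved-block thresholds.
#' @param positions codon positions kept (default 1, 2).
#' @param alpha SRH significance level.
#' @param models Mk models fitted for discrete traits.
#' @param nsim stochastic maps per trait.
#' @param seed integer seed for all stochastic stages (mandatory).
#' @param rounds chimera-division rounds.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(clusters, hits, out,
                            contaminant_hits = NULL, fasta_dir = NULL,
                            aln_dir = NULL, tree = NULL, traits = NULL,
                            n_species = NULL, min_frac = 0.8,
                            min_block_coverage = 0.5, min_block_nt = 100,
                            positions = c(1L, 2L), alpha = 0.05,
                            models = c("ER", "SYM", "ARD"), nsim = 100L,
                            seed = 1L, rounds = 2L) {
  stopifnot(min_frac > 0, min_frac <= 1, alpha > 0, alpha < 1,
            min_block_coverage >= 0, min_block_coverage < 1,
            min_block_nt >= 0, nsim >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

.stage_log <- function(log, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  cat(line, "\n", file = log, append = TRUE)
}

#' Run the full pipeline
#'
#' Executes the stages in order, writing per-stage outputs plus
#' `manifest.json` (config hash, seed, per-stage counts) under
#' `config$out`. Reruns with an identical config are bit-identical apart
#' from the log's timestamps.
#'
#' @param config a [pipeline_config].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("clusters", "hits")) {
    if (!file.exists(config[[f]]))
      stop("missing input '", f, "': ", config[[f]])
  }
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(config$out, "pipeline.log")
  cat("", file = log)
  counts <- list()

  clusters <- read_cluster_table(config$clusters)
  hits <- read_hit_table(config$hits)
  counts$clusters_in <- length(unique(clusters$cluster_id))
  counts$transcripts_in <- nrow(clusters)
  .stage_log(log, sprintf("inputs: %d clusters, %d memberships",
                          counts$clusters_in, counts$transcripts_in))

  # contaminants
  contam <- character(0)
  if (!is.null(config$contaminant_hits) &&
      file.exists(config$contaminant_hits)) {
    ch <- read_hit_table(config$contaminant_hits)
    contam <- flag_contaminants(ch, "general")
    clusters <- clusters[!clusters$transcript_id %in% contam, , drop = FALSE]
  }
  counts$contaminants_flagged <- length(contam)
  .stage_log(log, sprintf("contaminants flagged: %d", length(contam)))

  # coverage filter
  n_sp <- if (is.null(config$n_species))
    length(unique(clusters$species_id)) else config$n_species
  cov <- filter_clusters_by_coverage(clusters, n_sp, config$min_frac)
  write.table(cov$report, file.path(config$out, "filter_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  clusters <- cov$clusters
  counts$clusters_after_coverage <- length(unique(clusters$cluster_id))
  .stage_log(log, sprintf("coverage filter: %d clusters retained",
                          counts$clusters_after_coverage))

  # representatives
  reps_rows <- list()
  for (cid in unique(clusters$cluster_id)) {
    mem <- clusters[clusters$cluster_id == cid, , drop = FALSE]
    reps <- select_representatives(mem, hits, config$rounds)
    reps_rows[[cid]] <- data.frame(cluster_id = cid,
                                   species_id = names(reps),
                                   transcript_id = unname(reps))
  }
  reps_df <- do.call(rbind, reps_rows)
  rownames(reps_df) <- NULL
  write_cluster_table(reps_df, file.path(config$out, "representatives.tsv"))
  counts$representative_rows <- nrow(reps_df)
  .stage_log(log, sprintf("representatives: %d species x cluster rows",
                          nrow(reps_df)))

  # per-gene alignments -> blocks -> SRH -> supermatrix
  counts$genes_with_alignment <- 0L
  counts$genes_kept_blocks <- 0L
  counts$srh_pass <- 0L
  counts$supermatrix_columns <- 0L
  if (!is.null(config$aln_dir) && dir.exists(config$aln_dir)) {
    genes <- list(); srh_rows <- list()
    for (cid in unique(reps_df$cluster_id)) {
      fa <- file.path(config$aln_dir, paste0(cid, ".fasta"))
      if (!file.exists(fa)) next
      counts$genes_with_alignment <- counts$genes_with_alignment + 1L
      aln <- read_alignment_fasta(fa)
      bt <- file.path(config$aln_dir, paste0(cid, ".blocks.tsv"))
      blocks <- if (file.exists(bt))
        read.table(bt, header = TRUE, sep = "\t")
      else data.frame(start = 1L, end = ncol(aln))
      sel <- select_blocks(list(gene_id = cid, alignment_length = ncol(aln),
                                blocks = blocks),
                           config$min_block_coverage, config$min_block_nt)
      if (!sel$kept) next
      counts$genes_kept_blocks <- counts$genes_kept_blocks + 1L
      srh <- srh_filter_cluster(aln, config$positions, config$alpha)
      srh_rows[[cid]] <- cbind(cluster_id = cid, srh$pairs,
                               verdict = srh$verdict)
      if (srh$verdict != "pass") next
      counts$srh_pass <- counts$srh_pass + 1L
      # map alignment rows (transcripts or species) to species labels
      rn <- rownames(aln)
      mp <- reps_df[reps_df$cluster_id == cid, ]
      hit_tx <- match(rn, mp$transcript_id)
      rownames(aln) <- ifelse(is.na(hit_tx), rn, mp$species_id[hit_tx])
      genes[[cid]] <- list(aln = aln, blocks = sel$blocks)
    }
    if (length(srh_rows)) {
      srh_df <- do.call(rbind, srh_rows)
      rownames(srh_df) <- NULL
      write.table(srh_df, file.path(config$out, "srh_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (length(genes)) {
      sm <- build_supermatrix(genes, config$positions)
      write_supermatrix(sm, file.path(config$out, "supermatrix.phy"),
                        file.path(config$out, "partitions.txt"),
                        file.path(config$out, "supermatrix.fasta"))
      counts$supermatrix_columns <- ncol(sm$matrix)
      counts$supermatrix_taxa <- length(sm$taxa)
    }
  }
  .stage_log(log, sprintf("matrix: %d genes kept, %d SRH-pass, %d columns",
                          counts$genes_kept_blocks, counts$srh_pass,
                          counts$supermatrix_columns))

  # ancestral reconstructions
  if (!is.null(config$tree) && file.exists(config$tree) &&
      !is.null(config$traits) && file.exists(config$traits)) {
    tree <- ape::read.tree(config$tree)
    tdf <- utils::read.csv(config$traits, stringsAsFactors = FALSE)
    model_rows <- list(); trans_rows <- list()
    for (tn in unique(tdf$trait_name)) {
      v <- setNames(tdf$value[tdf$trait_name == tn],
                    tdf$species[tdf$trait_name == tn])
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num)) {  # discrete
        mc <- choose_mk_model(tree, v, config$models, alpha = config$alpha)
        model_rows[[tn]] <- cbind(trait = tn, mc$table,
                                  chosen = mc$table$model == mc$chosen)
        best_q <- mc$fits[[mc$chosen]]$Q
        marg <- marginal_ancestrals(tree, v, best_q)
        mdf <- data.frame(node = rep(rownames(marg), ncol(marg)),
                          state = rep(colnames(marg), each = nrow(marg)),
                          probability = as.vector(marg))
        write.table(mdf, file.path(config$out,
                                   sprintf("marginals_%s.tsv", tn)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        sm <- stochastic_map(tree, v, best_q, nsim = config$nsim,
                             seed = config$seed)
        for (st in sm$states) {
          ct <- count_transitions(sm, st)
          trans_rows[[paste(tn, st)]] <-
            data.frame(trait = tn, derived_state = st,
                       mean_origins = ct$n_origins,
                       mean_reversals = ct$n_reversals,
                       sd_origins = ct$sd_origins)
        }
      } else {           # continuous
        lam <- fit_lambda(tree, num)
        anc <- anc_bm(tree, num)
        write.table(anc, file.path(config$out, sprintf("anc_%s.tsv", tn)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
          list(trait = tn, lambda = lam$lambda, sigma2 = lam$sigma2,
               z0 = lam$z0, lnL = lam$lnL, p_vs_zero = lam$p_vs_zero),
          file.path(config$out, sprintf("lambda_%s.json", tn)),
          auto_unbox = TRUE, digits = NA)
      }
    }
    if (length(model_rows)) {
      mt <- do.call(rbind, model_rows); rownames(mt) <- NULL
      write.table(mt, file.path(config$out, "model_choice.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      counts$model_fits <- nrow(mt)
    }
    if (length(trans_rows)) {
      tt <- do.call(rbind, trans_rows); rownames(tt) <- NULL
      write.table(tt, file.path(config$out, "transitions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .stage_log(log, "ancestral reconstructions done")
  }

  cfg_plain <- unclass(config)
  cfg_json <- file.path(config$out, "config.json")
  jsonlite::write_json(cfg_plain, cfg_json, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  manifest <- list(config_hash = unname(tools::md5sum(cfg_json)),
                   seed = config$seed, counts = counts,
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Consolidated report of a finished run
#'
#' Collects the stage outputs of [run_pipeline] into one JSON report (and
#' returns it): filter funnel, SRH summary, model-choice table, transition
#' summaries. Regenerating the report from the same run directory is
#' byte-identical. An incomplete run produces a partial report flagged
#' `complete = FALSE`.
#'
#' @param run_dir output directory of [run_pipeline].
#' @return invisibly, the report list (also written to `report.json`).
#' @export
write_report <- function(run_dir) {
  mf <- file.path(run_dir, "manifest.json")
  report <- list(complete = file.exists(mf))
  if (report$complete)
    report$manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (f in c("filter_report", "srh_report", "model_choice", "transitions")) {
    p <- file.path(run_dir, paste0(f, ".tsv"))
    if (file.exists(p))
      report[[f]] <- read.table(p, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  }
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `matrix`, `srh`, `asr-discrete`,
#' `asr-continuous` and `report` subcommands used by the
#' `inst/exec/gerrophylo` wrapper. Flags are `--name value` pairs mirroring
#' the arguments of the underlying functions; `--config file.json` loads a
#' JSON [pipeline_config]. Exit codes: 0 ok, 2 input error, 3 numerical
#' failure.
#'
#' @param args character vector (default: the process command line).
#' @return exit status, invisibly.
#' @export
gerrophylo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  fail <- function(code, msg) { message("error: ", msg); invisible(code) }
  if (!length(args)) return(fail(2, "usage: gerrophylo <simulate|matrix|srh|asr-discrete|asr-continuous|report> [--flag value ...]"))
  cmd <- args[1]; rest <- args[-1]
  opts <- list()
  i <- 1
  while (i <= length(rest)) {
    if (!startsWith(rest[i], "--")) return(fail(2, paste("bad flag:", rest[i])))
    opts[[substring(rest[i], 3)]] <- if (i < length(rest)) rest[i + 1] else ""
    i <- i + 2
  }
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  res <- tryCatch(switch(
    cmd,
    simulate = {
      cfg <- sim_config(seed = as.integer(num(opts$seed, 1)),
                        n_species = as.integer(num(opts[["n-species"]], 20)),
                        n_clusters = as.integer(num(opts[["n-clusters"]], 50)))
      write_sim_clusters(simulate_ortholog_clusters(cfg), opts$out)
      0
    },
    matrix = {
      cfg <- pipeline_config(
        clusters = opts$clusters, hits = opts$hits, out = opts$out,
        contaminant_hits = opts[["contaminant-hits"]],
        fasta_dir = opts[["fasta-dir"]], aln_dir = opts[["aln-dir"]],
        n_species = if (is.null(opts[["n-species"]])) NULL
        else as.integer(opts[["n-species"]]),
        min_frac = num(opts[["min-frac"]], 0.8),
        seed = as.integer(num(opts$seed, 1)))
      run_pipeline(cfg); 0
    },
    srh = {
      aln <- read_alignment_fasta(opts$aln)
      pos <- as.integer(strsplit(if (is.null(opts$positions)) "12"
                                 else opts$positions, "")[[1]])
      r <- srh_filter_cluster(aln, pos, num(opts$alpha, 0.05))
      write.table(r$pairs, opts$out, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      message("verdict: ", r$verdict); 0
    },
    "asr-discrete" = {
      tree <- ape::read.tree(opts$tree)
      trait <- read_trait_csv(opts$trait)
      mc <- choose_mk_model(tree, trait)
      sm <- stochastic_map(tree, trait, mc$fits[[mc$chosen]]$Q,
                           nsim = as.integer(num(opts$nsim, 100)),
                           seed = as.integer(num(opts$seed, 1)))
      write_simmap(sm, file.path(opts$out))
      message("chosen model: ", mc$chosen); 0
    },
    "asr-continuous" = {
      tree <- ape::read.tree(opts$tree)
      trait <- read_trait_csv(opts$trait)
      anc <- anc_bm(tree, trait)
      write.table(anc, opts$out, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      0
    },
    report = { write_report(opts[["run-dir"]]); 0 },
    NULL), error = function(e) {
      message("error: ", conditionMessage(e))
      if (grepl("not found|missing", conditionMessage(e))) 2 else 3
    })
  if (is.null(res)) return(fail(2, paste("unknown subcommand:", cmd)))
  invisible(res)
}
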