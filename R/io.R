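# Readers and writers for the plain-text interchange formats: hit TSV
# (outfmt-6 extended dialect), cluster TSV, block TSV, trait CSV, FASTA.

.HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "qlen", "slen",
               "evalue", "bitscore")

#' Read / write a BLAST-style hit table
#'
#' Tab-separated with columns qseqid, sseqid, pident, length, qlen, slen,
#' evalue, bitscore. A header line is optional and `#` comment lines are
#' ignored.
#'
#' @param path file path.
#' @return data.frame with the eight standard columns.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(setNames(as.data.frame(matrix(nrow = 0, ncol = 8)), .HIT_COLS))
  has_header <- grepl("^qseqid\\b", lines[1])
  df <- read.table(text = lines, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE)
  if (!has_header) names(df) <- .HIT_COLS[seq_len(ncol(df))]
  .check_hits(df)
  df
}

#' @rdname read_hit_table
#' @param hits hit data.frame.
#' @param header write the header line?
#' @export
write_hit_table <- function(hits, path, header = TRUE) {
  write.table(hits[, .HIT_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read / write a cluster membership table
#'
#' Tab-separated `cluster_id`, `species_id`, `transcript_id` (header
#' optional, `#` comments ignored).
#' @param path file path.
#' @return data.frame.
#' @export
read_cluster_table <- function(path) {
  if (!file.exists(path)) stop("cluster table not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  has_header <- grepl("^cluster_id\\b", lines[1])
  df <- read.table(text = lines, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE)
  if (!has_header) names(df) <- c("cluster_id", "species_id", "transcript_id")
  df
}

#' @rdname read_cluster_table
#' @param clusters cluster data.frame.
#' @export
write_cluster_table <- function(clusters, path) {
  write.table(clusters[, c("cluster_id", "species_id", "transcript_id")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a trait table
#'
#' CSV with columns `species`, `trait_name`, `value` (discrete state label
#' or numeric).
#' @param path file path.
#' @param trait_name optional filter; with a single trait the value column
#'   is returned as a named vector.
#' @return named vector (one trait) or the full data.frame.
#' @export
read_trait_csv <- function(path, trait_name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(trait_name)) df <- df[df$trait_name == trait_name, ]
  if (length(unique(df$trait_name)) == 1) {
    v <- df$value
    suppressWarnings(num <- as.numeric(v))
    if (!anyNA(num)) v <- num
    return(setNames(v, df$species))
  }
  df
}

#' @rdname read_trait_csv
#' @param values named vector (names = species).
#' @export
write_trait_csv <- function(values, trait_name, path) {
  utils::write.csv(data.frame(species = names(values),
                              trait_name = trait_name,
                              value = unname(values)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-species transcript FASTA files
#'
#' @param transcripts data.frame with `species_id`, `transcript_id`,
#'   `sequence`.
#' @param dir output directory (one `<species>.fasta` each).
#' @return invisibly, the file paths.
#' @export
write_species_fasta <- function(transcripts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sp in unique(transcripts$species_id)) {
    sub <- transcripts[transcripts$species_id == sp, ]
    p <- file.path(dir, paste0(sp, ".fasta"))
    writeLines(rbind(paste0(">", sub$transcript_id), sub$sequence), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a FASTA alignment into a character matrix
#'
#' @param path FASTA file of aligned, equal-length sequences.
#' @return uppercase character matrix, rows named by sequence id.
#' @export
read_alignment_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  chr <- lapply(as.character(dna), toupper)
  len <- unique(lengths(chr))
  if (length(len) != 1) stop("sequences are not aligned (unequal lengths)")
  mat <- do.call(rbind, chr)
  rownames(mat) <- names(chr)
  mat
}

#' @rdname read_alignment_fasta
#' @param aln character matrix (rows = taxa).
#' @export
write_alignment_fasta <- function(aln, path) {
  writeLines(rbind(paste0(">", rownames(aln)),
                   apply(aln, 1, paste, collapse = "")), path)
  invisible(path)
}

#' Write all synthetic-cluster inputs to a directory
#'
#' Materialises a [simulate_ortholog_clusters] result as the plain-text
#' files the pipeline consumes: per-species FASTA, hit and contaminant-hit
#' TSVs, cluster TSV, Newick tree, and a truth JSON.
#'
#' @param sim a `sim_clusters` object.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_sim_clusters <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_species_fasta(sim$transcripts, file.path(dir, "fasta"))
  write_hit_table(sim$hits, file.path(dir, "hits.tsv"))
  write_hit_table(sim$contaminant_hits, file.path(dir, "contaminant_hits.tsv"))
  write_cluster_table(sim$clusters, file.path(dir, "clusters.tsv"))
  ape::write.tree(sim$truth$tree, file.path(dir, "tree.nwk"))
  truth <- list(chimera_map = sim$truth$chimera_map,
                contaminant_ids = sim$truth$contaminant_ids,
                families = sim$truth$families)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
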