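# Conserved-block selection and codon-position-1+2 supermatrix assembly.

#' Conserved-block filter for one gene
#'
#' A gene is kept when its cumulative block length both covers more than
#' `min_coverage` of the alignment length (strict >) and reaches at least
#' `min_total_nt` nucleotides (inclusive >=). Both conditions apply to the
#' cumulative kept length across blocks.
#'
#' @param block_set list with `gene_id`, `alignment_length`, and `blocks`
#'   (data.frame `start`, `end`, 1-based inclusive, disjoint, sorted).
#' @param min_coverage minimum fraction of the alignment covered (default
#'   0.5).
#' @param min_total_nt minimum cumulative block length (default 100).
#' @return list: `gene_id`, `kept` (logical), `total_nt`, `coverage`,
#'   `blocks` (the input blocks when kept, empty otherwise).
#' @export
select_blocks <- function(block_set, min_coverage = 0.5, min_total_nt = 100) {
  b <- block_set$blocks
  stopifnot(all(b$start >= 1), all(b$end >= b$start),
            all(b$end <= block_set$alignment_length))
  if (nrow(b) > 1) {
    b <- b[order(b$start), , drop = FALSE]
    if (any(b$start[-1] <= b$end[-nrow(b)])) stop("blocks overlap")
  }
  total <- sum(b$end - b$start + 1)
  coverage <- total / block_set$alignment_length
  kept <- coverage > min_coverage && total >= min_total_nt
  list(gene_id = block_set$gene_id, kept = kept, total_nt = total,
       coverage = coverage,
       blocks = if (kept) b else b[0, , drop = FALSE])
}

# Trim a block inward to codon boundaries (start == 1 mod 3, length % 3 == 0).
.codon_trim <- function(start, end, on_violation = c("trim", "error")) {
  on_violation <- match.arg(on_violation)
  s <- start; e <- end
  if ((s - 1L) %% 3L != 0L || (e - s + 1L) %% 3L != 0L) {
    if (on_violation == "error")
      stop(sprintf("block %d-%d violates codon framing", start, end))
    s <- s + ((3L - (s - 1L) %% 3L) %% 3L)
    e <- e - (e - s + 1L) %% 3L
    if (e < s) return(NULL)
    warning(sprintf("block %d-%d trimmed to codon frame %d-%d",
                    start, end, s, e))
  }
  c(s, e)
}

#' Build a codon-position-1+2 supermatrix from kept gene blocks
#'
#' Concatenates, per gene, the conserved-block columns restricted to the
#' selected codon positions (default 1 and 2; the third position is
#' discarded). Blocks must be codon-framed; out-of-frame blocks are trimmed
#' inward to the nearest codon boundary with a warning (or rejected with
#' `on_frame_violation = "error"`). Taxa absent from a gene are padded with
#' gaps, and per-gene partitions over the concatenation are recorded.
#'
#' @param genes named list; each element has `aln` (character matrix, rows
#'   = taxa) and `blocks` (data.frame `start`/`end`, nt coordinates).
#' @param codon_positions subset of 1:3 to keep per codon (default c(1, 2)).
#' @param taxa optional explicit taxon universe; defaults to the union over
#'   genes.
#' @param on_frame_violation `"trim"` (default, per the block filter's
#'   design) or `"error"`.
#' @return object of class `supermatrix`: `taxa`, `matrix` (character,
#'   taxa x columns), `partitions` (gene_id/start/end, 1-based inclusive,
#'   tiling the concatenation), `missing_fraction` (per taxon).
#' @export
build_supermatrix <- function(genes, codon_positions = c(1L, 2L),
                              taxa = NULL,
                              on_frame_violation = c("trim", "error")) {
  on_frame_violation <- match.arg(on_frame_violation)
  stopifnot(length(genes) >= 1, all(codon_positions %in% 1:3))
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(genes, function(g) rownames(g$aln)))))
  pieces <- list(); parts <- list(); pos <- 0L
  for (gid in names(genes)) {
    g <- genes[[gid]]
    cols <- integer(0)
    for (r in seq_len(nrow(g$blocks))) {
      tr <- .codon_trim(g$blocks$start[r], g$blocks$end[r], on_frame_violation)
      if (is.null(tr)) next
      idx <- tr[1]:tr[2]
      cpos <- ((idx - tr[1]) %% 3L) + 1L     # codon position within the block
      cols <- c(cols, idx[cpos %in% codon_positions])
    }
    if (!length(cols)) next
    seg <- matrix("-", length(taxa), length(cols),
                  dimnames = list(taxa, NULL))
    common <- intersect(taxa, rownames(g$aln))
    seg[common, ] <- g$aln[common, cols, drop = FALSE]
    pieces[[gid]] <- seg
    parts[[gid]] <- data.frame(gene_id = gid, start = pos + 1L,
                               end = pos + length(cols))
    pos <- pos + length(cols)
  }
  if (!length(pieces)) stop("no gene contributed any columns")
  mat <- do.call(cbind, pieces)
  partitions <- do.call(rbind, parts)
  rownames(partitions) <- NULL
  miss <- rowMeans(mat == "-" | mat == "?" | mat == "N")
  structure(list(taxa = taxa, matrix = mat, partitions = partitions,
                 missing_fraction = miss),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d columns, %d partitions, mean missing %.1f%%\n",
              length(x$taxa), ncol(x$matrix), nrow(x$partitions),
              100 * mean(x$missing_fraction)))
  invisible(x)
}

#' Write / read a supermatrix in relaxed PHYLIP with a RAxML partition file
#'
#' `write_supermatrix` writes relaxed PHYLIP (`ntaxa nchar` header, one
#' `name  sequence` line per taxon), a FASTA copy, and a RAxML-style
#' partition file (`DNA, gene42 = 1201-1400`). `read_supermatrix` reads the
#' pair back into an identical object.
#'
#' @param x a `supermatrix`.
#' @param phylip,partition,fasta output paths (`fasta = NULL` to skip).
#' @return `write_supermatrix`: invisibly, the paths; `read_supermatrix`:
#'   a `supermatrix`.
#' @export
write_supermatrix <- function(x, phylip, partition, fasta = NULL) {
  seqs <- apply(x$matrix, 1, paste, collapse = "")
  writeLines(c(sprintf("%d %d", length(x$taxa), ncol(x$matrix)),
               sprintf("%s  %s", names(seqs), seqs)), phylip)
  writeLines(sprintf("DNA, %s = %d-%d", x$partitions$gene_id,
                     x$partitions$start, x$partitions$end), partition)
  if (!is.null(fasta))
    writeLines(rbind(paste0(">", names(seqs)), seqs), fasta)
  invisible(c(phylip = phylip, partition = partition))
}

#' @rdname write_supermatrix
#' @export
read_supermatrix <- function(phylip, partition) {
  lines <- readLines(phylip)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- strsplit(trimws(lines[-1]), "\\s+")
  taxa <- vapply(body, `[[`, "", 1L)
  seqs <- vapply(body, `[[`, "", 2L)
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- taxa
  stopifnot(nrow(mat) == hdr[1], ncol(mat) == hdr[2])
  pl <- readLines(partition)
  m <- regmatches(pl, regexec("^\\s*DNA,\\s*(\\S+)\\s*=\\s*(\\d+)-(\\d+)", pl))
  partitions <- data.frame(
    gene_id = vapply(m, `[[`, "", 2L),
    start = as.integer(vapply(m, `[[`, "", 3L)),
    end = as.integer(vapply(m, `[[`, "", 4L)))
  miss <- rowMeans(mat == "-" | mat == "?" | mat == "N")
  structure(list(taxa = taxa, matrix = mat, partitions = partitions,
                 missing_fraction = miss),
            class = "supermatrix")
}
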