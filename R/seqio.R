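# Sequence and annotation I/O.
#
# Conventions used throughout the package:
#   * DNA alphabet is strictly {A,C,G,T}; IUPAC ambiguity codes are rejected
#     because positional-weight scoring over ambiguous bases is undefined.
#   * Gene tables are 1-based inclusive (GFF-style coordinates).
#   * All internal intervals and BED output are 0-based half-open on the
#     forward strand.

.BASES <- c("A", "C", "G", "T")

.check_dna <- function(seq, id = "sequence") {
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    stop(sprintf("alphabet error: record '%s' contains non-ACGT residue '%s' at offset %d",
                 id, substr(seq, bad, bad), as.integer(bad)), call. = FALSE)
  }
  invisible(seq)
}

.seq2int <- function(seq) match(strsplit(seq, "", fixed = TRUE)[[1L]], .BASES)

#' Read a FASTA file of DNA sequences
#'
#' Parses a plain FASTA file into a named character vector. Sequence lines
#' are uppercased and all whitespace inside them (including stray internal
#' spaces) is removed before validation, so oligo sequences transcribed from
#' print survive ingestion. Records are returned in file order.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return Named character vector of DNA sequences over \code{A,C,G,T};
#'   names are the first whitespace-delimited token of each header.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "acgt", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("format error: empty FASTA file '%s'", path), call. = FALSE)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) stop(sprintf("format error: '%s' does not start with a FASTA header", path), call. = FALSE)
  rec <- cumsum(is_hdr)
  ids <- vapply(strsplit(sub("^>", "", lines[is_hdr]), "\\s+"), `[`, "", 1L)
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]), paste, "", collapse = "")
  # records with no body lines would drop out of the split; refuse them
  if (length(seqs) != sum(is_hdr) || any(!nzchar(seqs))) {
    stop(sprintf("format error: record with empty sequence in '%s'", path), call. = FALSE)
  }
  seqs <- toupper(gsub("[[:space:]]+", "", seqs))
  names(seqs) <- ids
  for (i in seq_along(seqs)) .check_dna(seqs[[i]], ids[[i]])
  seqs
}

#' Write DNA sequences as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line-wrap width for sequence bodies.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.GENE_COLS <- c("genome_id", "contig_id", "gene_id", "start", "end",
                "strand", "ortholog_group", "product")

#' Read a tab-separated gene annotation table
#'
#' The table must carry a header row naming the eight fields
#' \code{genome_id, contig_id, gene_id, start, end, strand, ortholog_group,
#' product}. Coordinates are 1-based inclusive; strand is \code{+} or
#' \code{-}. Invariants (start <= end, known strand, unique gene ids per
#' genome) are enforced on load with row-numbered diagnostics.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the eight canonical columns.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  missing <- setdiff(.GENE_COLS, names(df))
  if (length(missing)) {
    stop(sprintf("format error: gene table '%s' lacks column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- df[, .GENE_COLS]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  validate_gene_table(df)
}

#' @rdname read_gene_table
#' @param genes A candidate gene annotation data.frame to validate.
#' @export
validate_gene_table <- function(genes) {
  bad <- which(is.na(genes$start) | is.na(genes$end) | genes$start > genes$end)
  if (length(bad)) {
    stop(sprintf("coordinate error: start > end (or non-numeric) at row %d", bad[1L]),
         call. = FALSE)
  }
  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("format error: unknown strand symbol '%s' at row %d",
                 genes$strand[bad[1L]], bad[1L]), call. = FALSE)
  }
  key <- paste(genes$genome_id, genes$gene_id)
  if (anyDuplicated(key)) {
    stop(sprintf("format error: duplicated (genome_id, gene_id) pair '%s'",
                 key[duplicated(key)][1L]), call. = FALSE)
  }
  genes
}

#' Write a gene annotation table as TSV
#' @param genes Gene annotation data.frame (see \code{\link{read_gene_table}}).
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, .GENE_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' Vectorized; strictly \code{A,C,G,T}. Applying it twice is the identity.
#'
#' @param x Character vector of DNA strings (may include "").
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GTGT")  # "ACAC"
#' @export
reverse_complement <- function(x) {
  for (i in seq_along(x)) if (nzchar(x[i])) .check_dna(x[i])
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

#' Length of the longest common substring of two DNA strings
#'
#' Forward-strand only, contiguous match. Used to relate overlapping
#' promoter fragments (e.g. a crystallization duplex to the operator
#' fragment it was excised from).
#'
#' @param a,b Non-empty DNA strings.
#' @return Integer length of the longest substring present in both.
#' @export
longest_common_substring <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  prev <- integer(length(bv))
  best <- 0L
  for (i in seq_along(av)) {
    cur <- integer(length(bv))
    hit <- which(bv == av[i])
    if (length(hit)) {
      cur[hit] <- c(0L, prev)[hit] + 1L   # prev[j-1] + 1, with prev[0] == 0
      m <- max(cur[hit])
      if (m > best) best <- m
    }
    prev <- cur
  }
  best
}

#' Bundle genomes and annotations into a genome set
#'
#' A genome set is the multi-genome container the regulon pipeline operates
#' on: per-genome contig sequences plus a single gene table spanning all
#' genomes, with an ortholog-group index. Every annotation must resolve to a
#' loaded contig and lie within its bounds.
#'
#' @param contigs Named list (genome_id -> named character vector of contig
#'   sequences).
#' @param genes Gene annotation data.frame covering the same genomes.
#' @return An object of class \code{genome_set} with elements
#'   \code{contigs}, \code{genes} and \code{ortholog_index}.
#' @export
genome_set <- function(contigs, genes) {
  stopifnot(is.list(contigs), length(contigs) >= 1L, !is.null(names(contigs)))
  genes <- validate_gene_table(genes)
  for (i in seq_len(nrow(genes))) {
    g <- genes$genome_id[i]
    if (is.null(contigs[[g]])) {
      stop(sprintf("unresolved genome '%s' for gene '%s'", g, genes$gene_id[i]),
           call. = FALSE)
    }
    ctg <- contigs[[g]][[genes$contig_id[i]]]
    if (is.null(ctg)) {
      stop(sprintf("unresolved contig '%s' for gene '%s'",
                   genes$contig_id[i], genes$gene_id[i]), call. = FALSE)
    }
    if (genes$start[i] < 1L || genes$end[i] > nchar(ctg)) {
      stop(sprintf("coordinate error: gene '%s' outside contig bounds",
                   genes$gene_id[i]), call. = FALSE)
    }
  }
  idx <- split(seq_len(nrow(genes)), genes$ortholog_group)
  idx[[""]] <- NULL
  structure(list(contigs = contigs, genes = genes, ortholog_index = idx),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("genome_set: %d genome(s), %d gene(s), %d ortholog group(s)\n",
              length(x$contigs), nrow(x$genes), length(x$ortholog_index)))
  invisible(x)
}

#' Extract the upstream (promoter) region of a gene
#'
#' Returns up to \code{window} nt immediately 5' of the gene's translational
#' start, truncated wherever it would overlap the body of another annotated
#' gene on the same contig, reported on the coding strand of the target
#' gene. A gene with zero available upstream sequence yields an empty-region
#' result (\code{start == end}), not an error.
#'
#' @param gs A \code{genome_set}.
#' @param genome_id,gene_id Identify the target gene.
#' @param window Maximum upstream length in nt (default 300).
#' @return List with \code{seq} (coding-strand sequence, possibly ""),
#'   \code{genome_id}, \code{contig_id}, \code{start}, \code{end} (0-based
#'   half-open contig interval) and \code{strand}.
#' @export
extract_upstream <- function(gs, genome_id, gene_id, window = 300L) {
  stopifnot(inherits(gs, "genome_set"), window >= 1L)
  g <- gs$genes
  i <- which(g$genome_id == genome_id & g$gene_id == gene_id)
  if (length(i) != 1L) stop(sprintf("gene '%s' not found in genome '%s'", gene_id, genome_id), call. = FALSE)
  contig <- gs$contigs[[genome_id]][[g$contig_id[i]]]
  clen <- nchar(contig)
  # other gene bodies on the same contig, as 0-based half-open intervals
  j <- which(g$genome_id == genome_id & g$contig_id == g$contig_id[i])
  j <- setdiff(j, i)
  b0 <- g$start[j] - 1L
  b1 <- g$end[j]
  if (g$strand[i] == "+") {
    hi <- g$start[i] - 1L            # 0-based end of region
    lo <- max(0L, hi - window)
    ov <- which(b1 > lo & b0 < hi)
    if (length(ov)) lo <- min(hi, max(lo, max(b1[ov])))
    seq <- if (hi > lo) substr(contig, lo + 1L, hi) else ""
  } else {
    lo <- g$end[i]                   # 0-based start of region
    hi <- min(clen, lo + window)
    ov <- which(b1 > lo & b0 < hi)
    if (length(ov)) hi <- max(lo, min(hi, min(b0[ov])))
    seq <- if (hi > lo) reverse_complement(substr(contig, lo + 1L, hi)) else ""
  }
  list(seq = seq, genome_id = genome_id, contig_id = g$contig_id[i],
       start = lo, end = hi, strand = g$strand[i])
}

.empty_sites <- function() {
  data.frame(sequence_id = character(0), start = integer(0), end = integer(0),
             name = character(0), strand = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write site calls as BED6
#'
#' Columns: chrom, 0-based start, half-open end, name (ortholog group where
#' known, otherwise "site"), score min-max scaled to integer 0-1000 over the
#' written set (all 1000 when the scores are constant), strand. Rows are
#' sorted by (chrom, start). An empty call set yields a header-only file.
#'
#' @param sites Site-call data.frame with columns \code{sequence_id},
#'   \code{start}, \code{end}, \code{strand}, \code{score} and optionally
#'   \code{name}.
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED6 site calls (regscan)", con)
  if (nrow(sites) == 0L) return(invisible(path))
  nm <- if (!is.null(sites$name)) sites$name else rep("site", nrow(sites))
  nm[!nzchar(nm)] <- "site"
  rng <- range(sites$score)
  scaled <- if (diff(rng) == 0) rep(1000L, nrow(sites)) else
    as.integer(round((sites$score - rng[1L]) / diff(rng) * 1000))
  ord <- order(sites$sequence_id, sites$start)
  writeLines(paste(sites$sequence_id[ord], sites$start[ord], sites$end[ord],
                   nm[ord], scaled[ord], sites$strand[ord], sep = "\t"), con)
  invisible(path)
}

#' Read a BED6 file of site calls
#' @param path Path to a BED6 file (comment lines starting with '#' are skipped).
#' @return Data.frame with columns sequence_id, start, end, name, score, strand.
#' @export
read_sites_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(.empty_sites())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 6L)) stop("format error: BED line with fewer than 6 columns", call. = FALSE)
  data.frame(sequence_id = vapply(parts, `[`, "", 1L),
             start = as.integer(vapply(parts, `[`, "", 2L)),
             end = as.integer(vapply(parts, `[`, "", 3L)),
             name = vapply(parts, `[`, "", 4L),
             score = as.numeric(vapply(parts, `[`, "", 5L)),
             strand = vapply(parts, `[`, "", 6L),
             stringsAsFactors = FALSE)
}

# run expr with a private, restorable RNG stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
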