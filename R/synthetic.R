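# Synthetic multi-genome benchmark: AT-rich intergenic background, planted
# PWM-sampled semipalindromic sites in single or tandem architecture, and
# tunable cross-genome conservation. Planted sites replace background (no
# insertion), so all coordinates are stable; the generator records ground
# truth for recovery evaluation.

#' Configuration for the synthetic genome generator
#'
#' Defaults emulate the Bacteroides study setting: 8 genomes sharing one
#' ortholog set, 60% AT background (A=T=0.30, C=G=0.20; Bacteroides
#' intergenic regions are AT-rich), intergenic lengths 200-400 nt (every
#' gene then heads its own operon under the 100-nt operon gap), one group
#' carrying a tandem pair with a 3-nt spacer, and conservation probability
#' 0.9 per genome.
#'
#' @param n_genomes Number of genomes.
#' @param genes_per_genome Genes per genome; gene i belongs to ortholog
#'   group OGi in every genome.
#' @param background Named base frequencies (A,C,G,T), summing to 1.
#' @param intergenic_range Length-2 integer range of intergenic lengths.
#' @param gene_length Length of every gene body in nt.
#' @param planted Data.frame with columns \code{group},
#'   \code{architecture} ("single" or "tandem") and \code{spacer} (nt,
#'   ignored for "single").
#' @param conservation Probability that a planted group receives its
#'   site(s) in any given genome.
#' @param upstream_window Window (nt) upstream of the target gene within
#'   which sites are planted; matches the scanner's default.
#' @param pwm A \code{pwm} whose positional frequencies sites are sampled
#'   from; default is \code{\link{araR_site_pwm}()}, the AraR profile at
#'   the genome-collection count depth (sites drawn from the raw four-
#'   sequence fixture matrix would be too diffuse to stand for real
#'   operator sites).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return Validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_genomes = 8L, genes_per_genome = 20L,
                             background = c(A = 0.30, C = 0.20, G = 0.20, T = 0.30),
                             intergenic_range = c(200L, 400L),
                             gene_length = 600L,
                             planted = data.frame(group = "OG001",
                                                  architecture = "tandem",
                                                  spacer = 3L,
                                                  stringsAsFactors = FALSE),
                             conservation = 0.9,
                             upstream_window = 300L,
                             pwm = NULL, seed = 1L) {
  stopifnot(n_genomes >= 1L, genes_per_genome >= 1L,
            abs(sum(background) - 1) < 1e-9, all(background >= 0),
            identical(names(background), c("A", "C", "G", "T")),
            length(intergenic_range) == 2L,
            intergenic_range[1L] <= intergenic_range[2L],
            conservation >= 0, conservation <= 1,
            all(planted$architecture %in% c("single", "tandem")),
            all(is.na(planted$spacer) | planted$spacer >= 0L))
  if (is.null(pwm)) pwm <- araR_site_pwm()
  blk <- pwm$width + ifelse(planted$architecture == "tandem",
                            pwm$width + planted$spacer, 0L)
  if (any(blk > min(intergenic_range[1L], upstream_window))) {
    stop("config error: intergenic region too short for the requested architecture",
         call. = FALSE)
  }
  structure(list(n_genomes = as.integer(n_genomes),
                 genes_per_genome = as.integer(genes_per_genome),
                 background = background,
                 intergenic_range = as.integer(intergenic_range),
                 gene_length = as.integer(gene_length),
                 planted = planted, conservation = conservation,
                 upstream_window = as.integer(upstream_window),
                 pwm = pwm, seed = as.integer(seed)),
            class = "synthetic_config")
}

.random_dna <- function(n, freqs) {
  paste(sample(.BASES, n, replace = TRUE, prob = freqs), collapse = "")
}

.sample_site_now <- function(object) {
  f <- column_information(object)$freq
  paste(vapply(seq_len(object$width),
               function(k) sample(.BASES, 1L, prob = f[, k]), ""),
        collapse = "")
}

#' Generate a synthetic genome set with planted sites
#'
#' Per genome: an i.i.d. background contig carrying
#' \code{genes_per_genome} gene bodies separated by random intergenic
#' stretches, gene strands drawn uniformly; then, for every planted group,
#' with probability \code{conservation} its site(s) are sampled from the
#' PWM and written over background at a uniform-random admissible offset in
#' the target gene's upstream window, on the gene's coding strand (tandem =
#' two sampled boxes separated by exactly the configured spacer of retained
#' background). Fully deterministic given \code{config$seed}.
#'
#' @param config A \code{synthetic_config}.
#' @return List of class \code{synthetic_genomes}: \code{genome_set},
#'   \code{truth} (realized planted sites, 0-based half-open contig
#'   coordinates), \code{conservation} (genome x group realization table),
#'   \code{config}.
#' @export
generate_genome_set <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(config$seed, .generate_genome_set_impl(config))
}

.generate_genome_set_impl <- function(config) {
  L <- config$pwm$width
  contigs <- list()
  genes <- list()
  truth <- list()
  cons <- list()
  for (gi in seq_len(config$n_genomes)) {
    gid <- sprintf("g%02d", gi)
    cid <- "c1"
    ng <- config$genes_per_genome
    inter <- sample(seq(config$intergenic_range[1L], config$intergenic_range[2L]),
                    ng + 1L, replace = TRUE)
    strands <- sample(c("+", "-"), ng, replace = TRUE)
    starts <- integer(ng)  # 1-based inclusive
    pos <- 0L
    for (i in seq_len(ng)) {
      pos <- pos + inter[i]
      starts[i] <- pos + 1L
      pos <- pos + config$gene_length
    }
    clen <- pos + inter[ng + 1L]
    contig <- strsplit(.random_dna(clen, config$background), "", fixed = TRUE)[[1L]]
    ends <- starts + config$gene_length - 1L
    genes[[gi]] <- data.frame(
      genome_id = gid, contig_id = cid,
      gene_id = sprintf("%s_g%03d", gid, seq_len(ng)),
      start = starts, end = ends, strand = strands,
      ortholog_group = sprintf("OG%03d", seq_len(ng)),
      product = "synthetic protein", stringsAsFactors = FALSE)
    for (pi in seq_len(nrow(config$planted))) {
      row <- config$planted[pi, ]
      tgt <- match(row$group, genes[[gi]]$ortholog_group)
      if (is.na(tgt)) next
      conserved <- stats::runif(1L) < config$conservation
      cons[[length(cons) + 1L]] <- data.frame(
        genome_id = gid, group = row$group, conserved = conserved,
        stringsAsFactors = FALSE)
      if (!conserved) next
      nsites <- if (row$architecture == "tandem") 2L else 1L
      blk <- nsites * L + if (nsites == 2L) row$spacer else 0L
      boxes <- vapply(seq_len(nsites), function(z) .sample_site_now(config$pwm), "")
      st <- starts[tgt]; en <- ends[tgt]; strand <- strands[tgt]
      if (strand == "+") {
        hi <- st - 1L                               # 0-based end of promoter
        lo <- max(if (tgt > 1L) ends[tgt - 1L] else 0L, hi - config$upstream_window)
      } else {
        lo <- en                                    # 0-based start of promoter
        hi <- min(if (tgt < ng) starts[tgt + 1L] - 1L else clen,
                  lo + config$upstream_window)
      }
      a <- lo + sample.int(hi - lo - blk + 1L, 1L) - 1L   # block start, 0-based
      # contig-order boxes: on '-' genes the coding-order pair appears
      # reverse-complemented, second box first
      if (strand == "+") {
        ordered <- boxes
      } else {
        ordered <- rev(reverse_complement(boxes))
      }
      off <- a
      for (z in seq_len(nsites)) {
        contig[(off + 1L):(off + L)] <- strsplit(ordered[z], "", fixed = TRUE)[[1L]]
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = gid, contig_id = cid, start = off, end = off + L,
          strand = strand, group = row$group,
          architecture = row$architecture, stringsAsFactors = FALSE)
        off <- off + L + if (nsites == 2L) row$spacer else 0L
      }
    }
    contigs[[gid]] <- stats::setNames(paste(contig, collapse = ""), cid)
  }
  gs <- genome_set(contigs, do.call(rbind, c(genes, list(make.row.names = FALSE))))
  truth_df <- if (length(truth)) do.call(rbind, c(truth, list(make.row.names = FALSE))) else
    data.frame(genome_id = character(0), contig_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               group = character(0), architecture = character(0),
               stringsAsFactors = FALSE)
  cons_df <- if (length(cons)) do.call(rbind, c(cons, list(make.row.names = FALSE))) else
    data.frame(genome_id = character(0), group = character(0),
               conserved = logical(0), stringsAsFactors = FALSE)
  structure(list(genome_set = gs, truth = truth_df, conservation = cons_df,
                 config = config),
            class = "synthetic_genomes")
}

#' @export
print.synthetic_genomes <- function(x, ...) {
  cat(sprintf("synthetic_genomes: %d genome(s), %d gene(s)/genome, %d planted site(s)\n",
              x$config$n_genomes, x$config$genes_per_genome, nrow(x$truth)))
  invisible(x)
}

#' Mononucleotide shuffle of a DNA sequence
#'
#' Uniform random permutation of the residues; base composition and length
#' are preserved exactly. This is the negative-control construction used in
#' operator-binding assays ("shuffled sequence").
#'
#' @param seq DNA string.
#' @param seed Optional integer seed.
#' @return Shuffled DNA string.
#' @export
shuffle_control <- function(seq, seed = NULL) {
  .check_dna(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  .with_seed(seed, paste(sample(v), collapse = ""))
}

#' Precision and recall of predicted sites against planted truth
#'
#' A predicted site matches a truth site when both lie on the same genome
#' and contig, the intervals overlap, and the start offset is at most
#' \code{tolerance} nt (strand-agnostic). Matching is one-to-one, greedy by
#' descending prediction score. With zero predictions precision is reported
#' as 1.0 together with \code{zero_prediction_flag = TRUE} (documented
#' convention keeping monotonicity analyses well-defined).
#'
#' @param predicted Data.frame with columns \code{genome_id},
#'   \code{contig_id}, \code{start}, \code{end} and \code{score}.
#' @param truth Truth data.frame from \code{\link{generate_genome_set}}.
#' @param tolerance Maximum start offset in nt (default 1).
#' @return List: \code{precision}, \code{recall}, \code{n_predicted},
#'   \code{n_truth}, \code{n_matched}, \code{zero_prediction_flag},
#'   \code{per_genome} table.
#' @export
evaluate_recovery <- function(predicted, truth, tolerance = 1L) {
  npred <- nrow(predicted)
  ntruth <- nrow(truth)
  used <- logical(ntruth)
  matched_pred <- logical(npred)
  if (npred > 0L) {
    ord <- order(-predicted$score)
    for (i in ord) {
      cand <- which(!used &
                    truth$genome_id == predicted$genome_id[i] &
                    truth$contig_id == predicted$contig_id[i] &
                    truth$start < predicted$end[i] &
                    truth$end > predicted$start[i] &
                    abs(truth$start - predicted$start[i]) <= tolerance)
      if (length(cand)) {
        used[cand[1L]] <- TRUE
        matched_pred[i] <- TRUE
      }
    }
  }
  per_genome <- NULL
  if (ntruth > 0L || npred > 0L) {
    gids <- sort(unique(c(truth$genome_id, predicted$genome_id)))
    per_genome <- data.frame(
      genome_id = gids,
      n_truth = vapply(gids, function(g) sum(truth$genome_id == g), 0L),
      n_predicted = vapply(gids, function(g) sum(predicted$genome_id == g), 0L),
      n_matched = vapply(gids, function(g) sum(used & truth$genome_id == g), 0L),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  list(precision = if (npred == 0L) 1.0 else sum(matched_pred) / npred,
       recall = if (ntruth == 0L) 1.0 else sum(used) / ntruth,
       n_predicted = npred, n_truth = ntruth, n_matched = sum(used),
       zero_prediction_flag = npred == 0L,
       per_genome = per_genome)
}

#' Write a synthetic genome set to a directory
#'
#' One FASTA per genome, a combined gene table, the ground-truth BED and a
#' key=value snapshot of the generating configuration.
#'
#' @param x A \code{synthetic_genomes} object.
#' @param dir Output directory (created if needed).
#' @export
write_synthetic <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_genomes"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (gid in names(x$genome_set$contigs)) {
    write_fasta(x$genome_set$contigs[[gid]], file.path(dir, paste0(gid, ".fasta")))
  }
  write_gene_table(x$genome_set$genes, file.path(dir, "genes.tsv"))
  tr <- x$truth
  write_sites_bed(data.frame(sequence_id = paste(tr$genome_id, tr$contig_id, sep = ":"),
                             start = tr$start, end = tr$end, name = tr$group,
                             strand = tr$strand, score = rep(1, nrow(tr)),
                             stringsAsFactors = FALSE),
                  file.path(dir, "truth.bed"))
  cfg <- x$config
  writeLines(c(sprintf("n_genomes=%d", cfg$n_genomes),
               sprintf("genes_per_genome=%d", cfg$genes_per_genome),
               sprintf("conservation=%g", cfg$conservation),
               sprintf("seed=%d", cfg$seed)),
             file.path(dir, "config.txt"))
  invisible(dir)
}
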