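# Regulon assembly: operons from gene annotations, cross-species
# consistency filtering of candidate target groups, and the end-to-end
# regulon table.

#' Assemble operons from gene annotations
#'
#' Maximal runs of same-strand adjacent genes on one contig whose
#' intergenic gaps do not exceed \code{max_gap} (default 100 nt, the
#' standard bacterial co-transcription heuristic) become operons. The
#' leading gene is the 5'-most gene on the coding strand; its promoter is
#' where regulator sites are sought.
#'
#' @param genes Gene annotation data.frame (1-based inclusive coordinates),
#'   possibly spanning several genomes.
#' @param max_gap Maximum intergenic gap in nt within an operon.
#' @return Data.frame: \code{genome_id}, \code{contig_id}, \code{operon_id},
#'   \code{strand}, \code{n_genes}, \code{genes} (comma-joined, genomic
#'   order), \code{leading_gene}, \code{start}, \code{end}.
#' @export
assemble_operons <- function(genes, max_gap = 100L) {
  genes <- validate_gene_table(genes)
  out <- list()
  for (gid in unique(genes$genome_id)) {
    counter <- 0L
    gg <- genes[genes$genome_id == gid, , drop = FALSE]
    for (cid in unique(gg$contig_id)) {
      cc <- gg[gg$contig_id == cid, , drop = FALSE]
      cc <- cc[order(cc$start), , drop = FALSE]
      n <- nrow(cc)
      # break before gene i+1 when strand flips or the intergenic gap is too wide
      brk <- if (n > 1L) {
        (cc$strand[-n] != cc$strand[-1L]) | (cc$start[-1L] - cc$end[-n] - 1L > max_gap)
      } else logical(0)
      run <- cumsum(c(0L, as.integer(brk)))
      for (r in unique(run)) {
        m <- cc[run == r, , drop = FALSE]
        counter <- counter + 1L
        lead <- if (m$strand[1L] == "+") m$gene_id[1L] else m$gene_id[nrow(m)]
        out[[length(out) + 1L]] <- data.frame(
          genome_id = gid, contig_id = cid,
          operon_id = sprintf("%s_op%03d", gid, counter),
          strand = m$strand[1L], n_genes = nrow(m),
          genes = paste(m$gene_id, collapse = ","),
          leading_gene = lead, start = min(m$start), end = max(m$end),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cross-species consistency verdict for candidate target groups
#'
#' An ortholog group is accepted as a regulon member iff the number of
#' genomes carrying a predicted site in its promoter is at least
#' \code{max(min_genomes, ceiling(min_fraction * n_genomes_with_group))}.
#' The rule quantifies the qualitative "conserved across species" filter of
#' comparative regulon reconstruction; both knobs are configurable.
#'
#' @param n_with_site Integer vector: genomes with a site, per group.
#' @param n_with_group Integer vector: genomes carrying the group.
#' @param min_genomes Minimum absolute genome support (default 2).
#' @param min_fraction Minimum fraction of group-carrying genomes (default 0.5).
#' @return Character vector, \code{"member"} or \code{"rejected"}.
#' @export
consistency_check <- function(n_with_site, n_with_group, min_genomes = 2L,
                              min_fraction = 0.5) {
  if (any(n_with_group == 0L)) {
    stop("value error: ortholog group absent from all genomes", call. = FALSE)
  }
  stopifnot(all(n_with_site <= n_with_group))
  need <- pmax(min_genomes, ceiling(min_fraction * n_with_group))
  ifelse(n_with_site >= need, "member", "rejected")
}

#' Reconstruct the regulon across a genome set
#'
#' End-to-end orchestration: assemble operons, extract and scan the
#' promoter of every operon's leading gene, call tandem architectures, and
#' apply the cross-species consistency check to every ortholog group that
#' leads at least one operon. Re-running on identical inputs is
#' bit-identical.
#'
#' @param gs A \code{genome_set}.
#' @param object A \code{pwm}.
#' @param threshold A \code{score_threshold} or numeric.
#' @param window Upstream window in nt.
#' @param max_gap Operon gap in nt.
#' @param allowed_spacers Tandem spacer lengths in nt.
#' @param min_genomes,min_fraction Consistency-check knobs.
#' @return Object of class \code{regulon_table}: \code{summary} (one row
#'   per ortholog group with genome support and verdict), \code{evidence}
#'   (one row per group x genome), \code{sites} (contig-coordinate calls),
#'   \code{tandems}, and \code{params}.
#' @export
build_regulon_table <- function(gs, object, threshold, window = 300L,
                                max_gap = 100L, allowed_spacers = c(3L, 42L),
                                min_genomes = 2L, min_fraction = 0.5) {
  stopifnot(inherits(gs, "genome_set"))
  if (length(gs$contigs) == 0L || nrow(gs$genes) == 0L) {
    stop("value error: empty genome set", call. = FALSE)
  }
  ops <- assemble_operons(gs$genes, max_gap = max_gap)
  sites <- scan_upstream_regions(gs, object, threshold, window = window,
                                 max_gap = max_gap)
  # tandems are called within each promoter region (operon-local coordinates)
  tand <- detect_tandem(
    data.frame(sequence_id = sites$operon_id, start = sites$region_start,
               end = sites$region_start + object$width, strand = sites$strand,
               score = sites$score, stringsAsFactors = FALSE),
    allowed_spacers = allowed_spacers)

  g <- gs$genes
  lead_og <- g$ortholog_group[match(paste(ops$genome_id, ops$leading_gene),
                                    paste(g$genome_id, g$gene_id))]
  ops$ortholog_group <- lead_og
  ops <- ops[nzchar(ops$ortholog_group), , drop = FALSE]
  groups <- sort(unique(ops$ortholog_group))
  ev <- list()
  for (og in groups) {
    sub <- ops[ops$ortholog_group == og, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      ssub <- sites[sites$operon_id == sub$operon_id[i], , drop = FALSE]
      tsub <- tand[tand$sequence_id == sub$operon_id[i], , drop = FALSE]
      ev[[length(ev) + 1L]] <- data.frame(
        ortholog_group = og, genome_id = sub$genome_id[i],
        operon_id = sub$operon_id[i], n_sites = nrow(ssub),
        n_tandems = nrow(tsub),
        best_score = if (nrow(ssub)) max(ssub$score) else NA_real_,
        has_site = nrow(ssub) > 0L, stringsAsFactors = FALSE)
    }
  }
  evidence <- do.call(rbind, c(ev, list(make.row.names = FALSE)))
  agg_grp <- tapply(evidence$genome_id, evidence$ortholog_group,
                    function(x) length(unique(x)))
  agg_site <- tapply(evidence$genome_id[evidence$has_site],
                     factor(evidence$ortholog_group[evidence$has_site],
                            levels = groups),
                     function(x) length(unique(x)))
  n_grp <- as.integer(agg_grp[groups])
  n_site <- as.integer(agg_site[groups])
  n_site[is.na(n_site)] <- 0L
  summary_df <- data.frame(
    ortholog_group = groups, n_genomes_with_group = n_grp,
    n_genomes_with_site = n_site,
    verdict = consistency_check(n_site, n_grp, min_genomes, min_fraction),
    stringsAsFactors = FALSE)
  structure(list(summary = summary_df, evidence = evidence, sites = sites,
                 tandems = tand,
                 params = list(window = window, max_gap = max_gap,
                               allowed_spacers = allowed_spacers,
                               min_genomes = min_genomes,
                               min_fraction = min_fraction,
                               threshold = .threshold_value(threshold))),
            class = "regulon_table")
}

#' @export
print.regulon_table <- function(x, ...) {
  cat(sprintf("regulon_table: %d ortholog group(s), %d member(s), %d site call(s), %d tandem(s)\n",
              nrow(x$summary), sum(x$summary$verdict == "member"),
              nrow(x$sites), nrow(x$tandems)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Site calls belonging to member groups
#' @param x A \code{regulon_table}.
#' @return Subset of \code{x$sites} whose ortholog group verdict is "member".
#' @export
member_sites <- function(x) {
  stopifnot(inherits(x, "regulon_table"))
  members <- x$summary$ortholog_group[x$summary$verdict == "member"]
  x$sites[x$sites$ortholog_group %in% members, , drop = FALSE]
}
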