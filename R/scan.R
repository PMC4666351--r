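# Genome scanning: threshold scan of sequences and upstream regions, greedy
# overlap resolution, tandem-architecture detection, and lifting of
# region-local calls back to contig coordinates.

# Vectorized forward-window scores of one sequence. Positions are
# accumulated as mirror pairs (k, L+1-k): for a symmetrized matrix the pair
# sums of a window and of its reverse complement are the same doubles, so
# the two strands score bitwise identically (addition is commutative).
.scan_scores <- function(weights, seq) {
  L <- ncol(weights)
  n <- nchar(seq)
  if (n < L) return(numeric(0))
  idx <- .seq2int(seq)
  nw <- n - L + 1L
  term <- function(k) weights[cbind(idx[k:(nw + k - 1L)], k)]
  sc <- numeric(nw)
  for (k in seq_len(L %/% 2L)) sc <- sc + (term(k) + term(L + 1L - k))
  if (L %% 2L == 1L) sc <- sc + term((L + 1L) %/% 2L)
  sc
}

#' Scan one sequence for sites above the training threshold
#'
#' Every window on both strands is scored; windows with score >= threshold
#' become candidates, and overlapping candidates are resolved greedily
#' (highest score first, ties by smaller start then '+' strand). For a
#' palindrome-symmetrized matrix the two strands score identically, so each
#' window is reported once as a single '+' call. Calls below the threshold
#' are never reported; a sequence shorter than the matrix width yields an
#' empty result, not an error.
#'
#' @param object A \code{pwm}.
#' @param threshold A \code{score_threshold} or bare numeric.
#' @param seq DNA string to scan.
#' @param sequence_id Identifier recorded in the calls.
#' @return Data.frame of site calls sorted by start: \code{sequence_id},
#'   0-based half-open \code{start}/\code{end}, \code{strand}, \code{score},
#'   \code{passed}.
#' @export
scan_sequence <- function(object, threshold, seq, sequence_id = "seq") {
  stopifnot(inherits(object, "pwm"))
  theta <- .threshold_value(threshold)
  L <- object$width
  .check_dna(seq, sequence_id)
  empty <- data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), passed = logical(0),
                      stringsAsFactors = FALSE)
  fwd <- .scan_scores(object$weights, seq)
  if (length(fwd) == 0L) return(empty)
  if (object$symmetrized) {
    cand <- data.frame(start = seq_along(fwd) - 1L, strand = "+", score = fwd,
                       stringsAsFactors = FALSE)
  } else {
    # score of the '-' strand window at the same interval = forward score of
    # its reverse complement, i.e. the mirrored position of the rc scan
    rev_sc <- rev(.scan_scores(object$weights, reverse_complement(seq)))
    cand <- data.frame(start = rep(seq_along(fwd) - 1L, 2L),
                       strand = rep(c("+", "-"), each = length(fwd)),
                       score = c(fwd, rev_sc), stringsAsFactors = FALSE)
  }
  cand <- cand[cand$score >= theta, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(-cand$score, cand$start, cand$strand), , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(abs(cand$start[keep] - cand$start[i]) < L)) keep <- c(keep, i)
  }
  sel <- cand[keep, , drop = FALSE]
  sel <- sel[order(sel$start), , drop = FALSE]
  data.frame(sequence_id = sequence_id, start = sel$start, end = sel$start + L,
             strand = sel$strand, score = sel$score, passed = TRUE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect tandem binding-site architectures
#'
#' Pairs adjacent site calls on the same sequence whose end-to-start gap is
#' one of the allowed spacer lengths (default 3 and 42 nt, the two
#' architectures observed in araMPRDAB promoters). Pairing is
#' leftmost-first and each site joins at most one tandem.
#'
#' @param sites Site-call data.frame (as from \code{\link{scan_sequence}}).
#' @param allowed_spacers Integer vector of admissible gaps in nt.
#' @return Data.frame of tandem calls: \code{sequence_id},
#'   \code{first_start}, \code{first_end}, \code{second_start},
#'   \code{second_end}, \code{spacer}, \code{first_score}, \code{second_score}.
#' @export
detect_tandem <- function(sites, allowed_spacers = c(3L, 42L)) {
  out <- data.frame(sequence_id = character(0), first_start = integer(0),
                    first_end = integer(0), second_start = integer(0),
                    second_end = integer(0), spacer = integer(0),
                    first_score = numeric(0), second_score = numeric(0),
                    stringsAsFactors = FALSE)
  if (is.null(sites) || nrow(sites) < 2L) return(out)
  for (sid in unique(sites$sequence_id)) {
    s <- sites[sites$sequence_id == sid, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    i <- 1L
    while (i < nrow(s)) {
      spacer <- s$start[i + 1L] - s$end[i]
      if (spacer %in% allowed_spacers) {
        out <- rbind(out, data.frame(
          sequence_id = sid, first_start = s$start[i], first_end = s$end[i],
          second_start = s$start[i + 1L], second_end = s$end[i + 1L],
          spacer = as.integer(spacer), first_score = s$score[i],
          second_score = s$score[i + 1L], stringsAsFactors = FALSE))
        i <- i + 2L   # a site joins at most one tandem
      } else {
        i <- i + 1L
      }
    }
  }
  out
}

#' Scan the promoter regions of all operons in a genome set
#'
#' Assembles operons per genome, extracts the upstream region of each
#' operon's leading gene, scans it, and lifts the calls back to contig
#' coordinates (strand-aware). Ordering is deterministic (genome, contig,
#' start).
#'
#' @param gs A \code{genome_set}.
#' @param object A \code{pwm}.
#' @param threshold A \code{score_threshold} or numeric.
#' @param window Upstream window in nt (default 300).
#' @param max_gap Operon assembly gap in nt (default 100).
#' @return Data.frame of contig-coordinate calls with columns
#'   \code{genome_id}, \code{contig_id}, \code{start}, \code{end},
#'   \code{strand}, \code{score}, \code{ortholog_group}, \code{operon_id},
#'   \code{gene_id} (the leading gene), and region-local \code{region_start}.
#' @export
scan_upstream_regions <- function(gs, object, threshold, window = 300L,
                                  max_gap = 100L) {
  stopifnot(inherits(gs, "genome_set"))
  ops <- assemble_operons(gs$genes, max_gap = max_gap)
  rows <- vector("list", nrow(ops))
  for (i in seq_len(nrow(ops))) {
    up <- extract_upstream(gs, ops$genome_id[i], ops$leading_gene[i], window = window)
    if (!nzchar(up$seq)) next
    calls <- scan_sequence(object, threshold, up$seq, sequence_id = ops$operon_id[i])
    if (nrow(calls) == 0L) next
    if (up$strand == "+") {
      cstart <- up$start + calls$start
      cstrand <- calls$strand
    } else {
      cstart <- up$end - calls$end
      cstrand <- ifelse(calls$strand == "+", "-", "+")
    }
    g <- gs$genes
    og <- g$ortholog_group[g$genome_id == ops$genome_id[i] & g$gene_id == ops$leading_gene[i]]
    rows[[i]] <- data.frame(
      genome_id = ops$genome_id[i], contig_id = ops$contig_id[i],
      start = cstart, end = cstart + object$width, strand = cstrand,
      score = calls$score, ortholog_group = og, operon_id = ops$operon_id[i],
      gene_id = ops$leading_gene[i], region_start = calls$start,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(genome_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      score = numeric(0), ortholog_group = character(0),
                      operon_id = character(0), gene_id = character(0),
                      region_start = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$genome_id, out$contig_id, out$start), , drop = FALSE]
}
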