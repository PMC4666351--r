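# Conserved-profile discovery: one fixed-width instance per input region
# (OOPS), chosen to maximize the total information content of the instance
# alignment. Optimization is deterministic seeded multi-restart coordinate
# ascent; a brute-force enumerator serves as the exactness oracle at small
# problem sizes.

.total_ic <- function(counts, pseudocount) {
  f <- sweep(counts + pseudocount, 2L, colSums(counts + pseudocount), "/")
  sum(2 + colSums(f * log2(f)))
}

# all candidate windows of one region as strings (fwd and, optionally, rc)
.region_windows <- function(region, L, both_strands) {
  n <- nchar(region)
  starts <- seq_len(n - L + 1L)
  fwd <- substring(region, starts, starts + L - 1L)
  if (!both_strands) {
    data.frame(start = starts - 1L, strand = "+", window = fwd,
               stringsAsFactors = FALSE)
  } else {
    data.frame(start = c(starts, starts) - 1L,
               strand = rep(c("+", "-"), each = length(starts)),
               window = c(fwd, reverse_complement(fwd)),
               stringsAsFactors = FALSE)
  }
}

.instance_df <- function(ids, cand, pick, L) {
  data.frame(sequence_id = ids,
             start = vapply(seq_along(cand), function(i) cand[[i]]$start[pick[i]], 0L),
             end = vapply(seq_along(cand), function(i) cand[[i]]$start[pick[i]], 0L) + L,
             strand = vapply(seq_along(cand), function(i) cand[[i]]$strand[pick[i]], ""),
             site = vapply(seq_along(cand), function(i) cand[[i]]$window[pick[i]], ""),
             stringsAsFactors = FALSE)
}

.discovery_result <- function(ids, cand, pick, L, palindromic, pseudocount,
                              restarts_used, seed, trace) {
  inst <- .instance_df(ids, cand, pick, L)
  counts <- build_count_matrix(inst$site)
  fit <- pwm(counts = counts, pseudocount = pseudocount, symmetrize = palindromic)
  inst$score <- score_window(fit, inst$site)
  structure(list(pwm = fit, instances = inst,
                 objective = .total_ic(counts, pseudocount),
                 restarts_used = restarts_used, seed = seed, trace = trace),
            class = "discovery")
}

#' @export
print.discovery <- function(x, ...) {
  cat(sprintf("discovery: %d instance(s), width %d, objective %.4f bits\n",
              nrow(x$instances), x$pwm$width, x$objective))
  cat("consensus:", consensus_sequence(x$pwm), "\n")
  invisible(x)
}

.self_complementarity <- function(window) {
  v <- strsplit(window, "", fixed = TRUE)[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sum(v == comp[rev(v)])
}

#' Discover a conserved fixed-width motif across promoter regions
#'
#' Picks one instance (window) per input region so that the total
#' information content of the instance alignment is maximized -- the
#' standard conserved-profile criterion, and what a sequence logo of the
#' result visualizes. Optimization is coordinate ascent: starting from
#' seeded initial assignments, each region's instance is iteratively
#' reassigned to the window that maximizes the alignment information given
#' all other instances (a leave-one-out profile score), until a full pass
#' changes nothing or the pass cap is reached. The first restart is
#' initialized at each region's most self-complementary window; further
#' restarts use seed-driven random windows. The objective is non-decreasing
#' within every restart, and the whole procedure is deterministic given
#' \code{seed}.
#'
#' With \code{palindromic = TRUE} (semipalindromic homodimer sites) only
#' forward-strand windows are considered and the returned matrix is
#' symmetrized, which makes strand choice moot; otherwise both strands
#' compete and instances may be reverse-complement windows.
#'
#' @param regions Named character vector of promoter sequences, each at
#'   least \code{width} nt long.
#' @param width Motif width L in nt (default 21).
#' @param palindromic Logical (default TRUE).
#' @param seed Integer seed driving restart initialization.
#' @param restarts Number of restarts (default 20).
#' @param pseudocount Pseudocount for the objective and the returned matrix.
#' @return An object of class \code{discovery}: \code{pwm}, per-region
#'   \code{instances} (0-based half-open coordinates), \code{objective}
#'   (total IC, bits), \code{restarts_used}, \code{seed}, and \code{trace}
#'   (objective after every pass of the winning restart).
#' @seealso \code{\link{brute_force_profile_oracle}}
#' @export
discover_profile <- function(regions, width = 21L, palindromic = TRUE,
                             seed = 1L, restarts = 20L, pseudocount = 0.5) {
  ids <- if (is.null(names(regions))) paste0("region", seq_along(regions)) else names(regions)
  short <- which(nchar(regions) < width)
  if (length(short)) {
    stop(sprintf("width error: region '%s' is shorter than the motif width %d",
                 ids[short[1L]], width), call. = FALSE)
  }
  nreg <- length(regions)
  cand <- lapply(regions, .region_windows, L = width, both_strands = !palindromic)
  names(cand) <- NULL
  # integer-encoded candidate windows for fast count updates
  enc <- lapply(cand, function(cd) lapply(cd$window, .seq2int))

  ascend <- function(pick) {
    counts <- matrix(0L, 4L, width)
    for (i in seq_len(nreg)) {
      idx <- enc[[i]][[pick[i]]]
      counts[cbind(idx, seq_len(width))] <- counts[cbind(idx, seq_len(width))] + 1L
    }
    trace <- .total_ic(counts, pseudocount)
    for (pass in seq_len(200L)) {
      changed <- FALSE
      for (i in seq_len(nreg)) {
        idx <- enc[[i]][[pick[i]]]
        counts[cbind(idx, seq_len(width))] <- counts[cbind(idx, seq_len(width))] - 1L
        objs <- vapply(enc[[i]], function(e) {
          counts[cbind(e, seq_len(width))] <- counts[cbind(e, seq_len(width))] + 1L
          .total_ic(counts, pseudocount)
        }, 0)
        # deterministic tie-break: best objective, then smaller start, then '+'
        best <- which(objs > max(objs) - 1e-12)
        j <- best[order(cand[[i]]$start[best], cand[[i]]$strand[best])][1L]
        idx <- enc[[i]][[j]]
        counts[cbind(idx, seq_len(width))] <- counts[cbind(idx, seq_len(width))] + 1L
        if (j != pick[i]) { pick[i] <- j; changed <- TRUE }
      }
      trace <- c(trace, .total_ic(counts, pseudocount))
      if (!changed) break
    }
    list(pick = pick, objective = trace[length(trace)], trace = trace)
  }

  runs <- .with_seed(seed, {
    lapply(seq_len(max(1L, restarts)), function(r) {
      pick <- if (r == 1L) {
        vapply(cand, function(cd) {
          sc <- vapply(cd$window, .self_complementarity, 0L)
          which.max(sc)  # ties -> smallest start (and '+' first in layout)
        }, 0L)
      } else {
        vapply(cand, function(cd) sample.int(nrow(cd), 1L), 0L)
      }
      ascend(pick)
    })
  })
  objs <- vapply(runs, `[[`, 0, "objective")
  win <- runs[[which.max(objs)]]  # ties -> earliest restart
  .discovery_result(ids, cand, win$pick, width, palindromic, pseudocount,
                    restarts_used = length(runs), seed = seed, trace = win$trace)
}

#' Exhaustive-profile oracle for small inputs
#'
#' Enumerates every combination of one forward-strand window per region and
#' returns the combination maximizing total information content; ties are
#' broken by the lexicographically smallest start-position vector. The
#' search space (product of window counts) is capped at 1e6; larger inputs
#' must use \code{\link{discover_profile}}. Used as the exactness oracle for
#' the coordinate-ascent optimizer.
#'
#' @inheritParams discover_profile
#' @return A \code{discovery} object (restarts_used = 0).
#' @export
brute_force_profile_oracle <- function(regions, width = 21L, palindromic = TRUE,
                                       pseudocount = 0.5) {
  ids <- if (is.null(names(regions))) paste0("region", seq_along(regions)) else names(regions)
  short <- which(nchar(regions) < width)
  if (length(short)) {
    stop(sprintf("width error: region '%s' is shorter than the motif width %d",
                 ids[short[1L]], width), call. = FALSE)
  }
  nwin <- nchar(regions) - width + 1L
  if (prod(as.numeric(nwin)) > 1e6) {
    stop("size error: search space exceeds 1e6 window combinations; use discover_profile", call. = FALSE)
  }
  cand <- lapply(regions, .region_windows, L = width, both_strands = FALSE)
  names(cand) <- NULL
  enc <- lapply(cand, function(cd) lapply(cd$window, .seq2int))
  nreg <- length(regions)
  best <- -Inf
  best_pick <- NULL
  counts <- matrix(0L, 4L, width)
  rec <- function(i) {
    if (i > nreg) {
      obj <- .total_ic(counts, pseudocount)
      # strict improvement only: enumeration order is lexicographic in starts
      if (obj > best + 1e-12) { best <<- obj; best_pick <<- pick }
      return(invisible())
    }
    for (j in seq_len(nwin[i])) {
      idx <- enc[[i]][[j]]
      counts[cbind(idx, seq_len(width))] <<- counts[cbind(idx, seq_len(width))] + 1L
      pick[i] <<- j
      rec(i + 1L)
      counts[cbind(idx, seq_len(width))] <<- counts[cbind(idx, seq_len(width))] - 1L
    }
  }
  pick <- integer(nreg)
  rec(1L)
  .discovery_result(ids, cand, best_pick, width, palindromic, pseudocount,
                    restarts_used = 0L, seed = NA_integer_, trace = best)
}
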