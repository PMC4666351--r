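# Position weight matrix model.
#
# Weights are centered log-counts: w(b,k) = ln(n(b,k)+c) - mean_b ln(n(b,k)+c),
# so every column sums to zero and a score of 0 is the uninformative baseline.
# A window's score is the sum of its positional weights. Palindromic
# symmetrization averages each weight with its reverse-complement mirror,
# w'(b,k) = (w(b,k) + w(comp(b), L-1-k)) / 2, which makes scores exactly
# strand-invariant.

#' Per-position base counts of an aligned site set
#'
#' @param sites Character vector of equal-length DNA strings (the training
#'   set); must be non-empty.
#' @return Integer matrix (4 x L, rows A,C,G,T) with an \code{"n_sites"}
#'   attribute; every column sums to \code{length(sites)}.
#' @export
build_count_matrix <- function(sites) {
  if (length(sites) == 0L) stop("value error: empty training set", call. = FALSE)
  L <- nchar(sites[1L])
  if (any(nchar(sites) != L)) stop("width error: training sites have unequal lengths", call. = FALSE)
  m <- matrix(0L, 4L, L, dimnames = list(.BASES, NULL))
  for (s in sites) {
    idx <- .seq2int(.check_dna(s))
    m[cbind(idx, seq_len(L))] <- m[cbind(idx, seq_len(L))] + 1L
  }
  attr(m, "n_sites") <- length(sites)
  m
}

.weights_from_counts <- function(counts, pseudocount, symmetrize) {
  counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts))
  lw <- log(counts + pseudocount)
  w <- sweep(lw, 2L, colMeans(lw))
  if (symmetrize) {
    L <- ncol(w)
    w <- (w + w[4:1, L:1, drop = FALSE]) / 2
  }
  dimnames(w) <- list(.BASES, NULL)
  w
}

#' Fit a position weight matrix to aligned binding sites
#'
#' The fitting function at the core of the package. Weights are centered
#' log-counts with a pseudocount, \eqn{w(b,k) = \ln(n(b,k)+c) - \frac{1}{4}
#' \sum_{b'} \ln(n(b',k)+c)}, so columns sum to zero. With
#' \code{symmetrize = TRUE} (the default, appropriate for semipalindromic
#' sites bound by homodimers) weights are averaged with their
#' reverse-complement mirror, making every window score identical on both
#' strands.
#'
#' @param sites Character vector of equal-length training sites, or
#'   \code{NULL} if \code{counts} is given.
#' @param pseudocount Positive pseudocount \code{c} added to every count
#'   (default 0.5; guards against -Inf with small training sets).
#' @param symmetrize Logical; enforce palindromic symmetry of the weights.
#' @param counts Optional precomputed count matrix from
#'   \code{\link{build_count_matrix}}.
#' @return An object of class \code{pwm}: list with \code{weights} (4 x L),
#'   \code{counts}, \code{n_sites}, \code{width}, \code{pseudocount},
#'   \code{symmetrized}.
#' @seealso \code{\link{score_window}}, \code{\link{min_training_threshold}},
#'   \code{\link{scan_sequence}}
#' @examples
#' m <- pwm(c("ACGCA", "ACGCA", "ACACA"))
#' coef(m)
#' predict(m, "ACGCA")
#' @export
pwm <- function(sites = NULL, pseudocount = 0.5, symmetrize = TRUE, counts = NULL) {
  stopifnot(pseudocount > 0)
  if (is.null(counts)) counts <- build_count_matrix(sites)
  n <- attr(counts, "n_sites")
  if (is.null(n)) n <- max(colSums(counts))
  structure(list(weights = .weights_from_counts(counts, pseudocount, symmetrize),
                 counts = counts, n_sites = as.integer(n),
                 width = ncol(counts), pseudocount = pseudocount,
                 symmetrized = isTRUE(symmetrize)),
            class = "pwm")
}

#' Score fixed-width windows against a PWM
#'
#' The score of a window is the sum of its positional nucleotide weights,
#' \eqn{S = \sum_k w(s_k, k)}.
#'
#' @param object A \code{pwm}.
#' @param windows Character vector of DNA strings, each of length equal to
#'   the matrix width.
#' @return Numeric vector of scores.
#' @export
score_window <- function(object, windows) {
  stopifnot(inherits(object, "pwm"))
  if (any(nchar(windows) != object$width)) {
    stop(sprintf("width error: window length != %d", object$width), call. = FALSE)
  }
  w <- object$weights
  L <- object$width
  # mirror-pair accumulation, identical to the scanner's, so that a score
  # recorded during a scan re-checks bitwise against score_window and a
  # symmetrized matrix scores both strands identically
  vapply(windows, function(s) {
    idx <- .seq2int(.check_dna(s))
    t <- w[cbind(idx, seq_len(L))]
    sc <- 0
    for (k in seq_len(L %/% 2L)) sc <- sc + (t[k] + t[L + 1L - k])
    if (L %% 2L == 1L) sc <- sc + t[(L + 1L) %/% 2L]
    sc
  }, 0, USE.NAMES = FALSE)
}

#' @export
predict.pwm <- function(object, newdata, ...) score_window(object, newdata)

#' @export
coef.pwm <- function(object, ...) object$weights

#' Minimum-training-score threshold
#'
#' The acceptance threshold for genome scanning is the lowest score observed
#' in the training set against the matrix that set defined; by construction
#' every training site passes it.
#'
#' @param object A \code{pwm}.
#' @param sites The training sites (equal-length, width L).
#' @return An object of class \code{score_threshold}: list with
#'   \code{threshold}, per-site \code{scores}, and a \code{source} string.
#' @export
min_training_threshold <- function(object, sites) {
  if (length(sites) == 0L) stop("value error: empty training set", call. = FALSE)
  sc <- score_window(object, sites)
  structure(list(threshold = min(sc), scores = sc,
                 source = sprintf("minimum over %d training sites", length(sites))),
            class = "score_threshold")
}

#' @export
print.score_threshold <- function(x, ...) {
  cat(sprintf("score threshold: %.4f (%s)\n", x$threshold, x$source))
  invisible(x)
}

.threshold_value <- function(threshold) {
  if (inherits(threshold, "score_threshold")) threshold$threshold else as.numeric(threshold)
}

#' Per-column information content and logo letter heights
#'
#' With pseudocounted frequencies \eqn{f(b,k) = (n(b,k)+c)/(N+4c)}, the
#' information content of column k is \eqn{IC_k = 2 + \sum_b f \log_2 f}
#' bits, bounded by [0, 2]. Letter heights are \eqn{f \cdot IC_k}, the
#' quantities a sequence-logo plotter stacks.
#'
#' @param counts A count matrix from \code{\link{build_count_matrix}}, or a
#'   \code{pwm} (its counts are used).
#' @param pseudocount Positive pseudocount (default 0.5).
#' @return List with \code{ic} (length-L numeric, bits), \code{heights}
#'   (4 x L) and \code{freq} (4 x L).
#' @export
column_information <- function(counts, pseudocount = 0.5) {
  if (inherits(counts, "pwm")) {
    pseudocount <- counts$pseudocount
    counts <- counts$counts
  }
  stopifnot(pseudocount > 0)
  f <- sweep(counts + pseudocount, 2L, colSums(counts + pseudocount), "/")
  ic <- 2 + colSums(f * log2(f))
  ic <- pmax(ic, 0)  # clip tiny negative rounding
  list(ic = ic, heights = sweep(f, 2L, ic, "*"), freq = f)
}

#' Write a logo table consumable by standard logo plotters
#' @param counts Count matrix or \code{pwm}.
#' @param path Output TSV path.
#' @param pseudocount Pseudocount when \code{counts} is a matrix.
#' @export
write_logo_tsv <- function(counts, path, pseudocount = 0.5) {
  li <- column_information(counts, pseudocount)
  df <- data.frame(position = seq_along(li$ic), ic_bits = li$ic,
                   t(li$heights), check.names = FALSE)
  names(df)[3:6] <- .BASES
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Consensus sequence of a PWM
#'
#' Per-position argmax base; ties broken by the fixed base order
#' A < C < G < T.
#'
#' @param object A \code{pwm}.
#' @return A DNA string of the matrix width.
#' @export
consensus_sequence <- function(object) {
  stopifnot(inherits(object, "pwm"))
  paste(.BASES[apply(object$weights, 2L, which.max)], collapse = "")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: width %d, %d training site(s), pseudocount %g, %s\n",
              x$width, x$n_sites, x$pseudocount,
              if (x$symmetrized) "palindrome-symmetrized" else "unsymmetrized"))
  cat("consensus:", consensus_sequence(x), "\n")
  invisible(x)
}

#' @export
summary.pwm <- function(object, ...) {
  li <- column_information(object)
  structure(list(width = object$width, n_sites = object$n_sites,
                 pseudocount = object$pseudocount,
                 symmetrized = object$symmetrized,
                 consensus = consensus_sequence(object),
                 ic = li$ic, total_ic = sum(li$ic)),
            class = "summary.pwm")
}

#' @export
print.summary.pwm <- function(x, ...) {
  cat(sprintf("pwm: width %d, %d sites, total information %.3f bits\n",
              x$width, x$n_sites, x$total_ic))
  cat("consensus:", x$consensus, "\n")
  cat("per-column IC (bits):\n")
  print(round(x$ic, 3))
  invisible(x)
}

#' @export
plot.pwm <- function(x, ...) {
  li <- column_information(x)
  L <- x$width
  graphics::plot(NULL, xlim = c(0.5, L + 0.5), ylim = c(0, 2),
                 xlab = "position", ylab = "information (bits)", ...)
  cols <- c(A = "forestgreen", C = "blue3", G = "orange2", T = "red3")
  for (k in seq_len(L)) {
    h <- sort(li$heights[, k])      # stack smallest first
    y0 <- 0
    for (b in names(h)) {
      if (h[[b]] > 0.01) {
        graphics::rect(k - 0.45, y0, k + 0.45, y0 + h[[b]],
                       col = grDevices::adjustcolor(cols[[b]], 0.25),
                       border = NA)
        graphics::text(k, y0 + h[[b]] / 2, b, col = cols[[b]],
                       cex = min(1.4, 0.5 + h[[b]]))
      }
      y0 <- y0 + h[[b]]
    }
  }
  invisible(x)
}

#' Sample sites from the PWM's positional base frequencies
#'
#' Draws each position independently from
#' \eqn{f(b,k) = (n(b,k)+c)/(N+4c)}; deterministic given \code{seed}.
#'
#' @param object A \code{pwm} carrying counts.
#' @param nsim Number of sites to draw.
#' @param seed Optional integer seed (the global RNG state is restored).
#' @param ... Unused.
#' @return Character vector of \code{nsim} sites of the matrix width.
#' @export
simulate.pwm <- function(object, nsim = 1, seed = NULL, ...) {
  stopifnot(inherits(object, "pwm"))
  f <- column_information(object)$freq
  .with_seed(seed, {
    vapply(seq_len(nsim), function(i) {
      paste(vapply(seq_len(object$width),
                   function(k) sample(.BASES, 1L, prob = f[, k]), ""),
            collapse = "")
    }, "")
  })
}

#' @rdname simulate.pwm
#' @param n Number of sites to draw.
#' @export
sample_site <- function(object, n = 1, seed = NULL) simulate.pwm(object, nsim = n, seed = seed)

#' Serialize a PWM to a plain-text file
#'
#' Header records width, pseudocount, symmetrization and training-set size;
#' then four labeled weight rows and four labeled count rows.
#'
#' @param object A \code{pwm}.
#' @param path Output path.
#' @export
write_pwm <- function(object, path) {
  stopifnot(inherits(object, "pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# regscan pwm\nwidth\t%d\npseudocount\t%.17g\nsymmetrized\t%s\nn_sites\t%d",
                     object$width, object$pseudocount,
                     tolower(object$symmetrized), object$n_sites), con)
  for (b in .BASES) {
    writeLines(paste(c(paste0("w_", b), sprintf("%.17g", object$weights[b, ])), collapse = "\t"), con)
  }
  for (b in .BASES) {
    writeLines(paste(c(paste0("n_", b), object$counts[b, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a PWM written by \code{\link{write_pwm}}
#' @param path Path to the serialized matrix.
#' @return A \code{pwm} object.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  getrow <- function(key) as.numeric(kv[[which(keys == key)]][-1L])
  width <- as.integer(getrow("width"))
  w <- do.call(rbind, lapply(paste0("w_", .BASES), getrow))
  n <- do.call(rbind, lapply(paste0("n_", .BASES), getrow))
  dimnames(w) <- dimnames(n) <- list(.BASES, NULL)
  n <- matrix(as.integer(n), 4L, width, dimnames = dimnames(n))
  n_sites <- as.integer(getrow("n_sites"))
  attr(n, "n_sites") <- n_sites
  structure(list(weights = w, counts = n, n_sites = n_sites, width = width,
                 pseudocount = getrow("pseudocount"),
                 symmetrized = identical(kv[[which(keys == "symmetrized")]][2L], "true")),
            class = "pwm")
}
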