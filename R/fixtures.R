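# Packaged worked-example fixtures: the four operator-region oligos from
# the B. thetaiotaomicron AraR study system (EMSA fragments of the BT0356
# and BT0365 promoters, the shuffled negative control, and the
# crystallization duplex), plus the reference PWM/threshold built from
# them.

.fixture_env <- new.env(parent = emptyenv())

#' The packaged AraR operator oligos
#'
#' Four DNA fragments: the 65-bp BT0356 (araM) promoter fragment carrying
#' two tandem AraR boxes, the 41-bp BT0365 promoter fragment carrying a
#' single box, a 65-bp mononucleotide-shuffled negative control, and the
#' 27-bp duplex used for protein-DNA crystallization. Lowercase cytosine
#' flanks of the synthetic oligos are ordinary sequence (uppercased on
#' ingest).
#'
#' @return Named character vector of the four sequences.
#' @export
araR_oligos <- function() {
  read_fasta(system.file("extdata", "araR_oligos.fasta", package = "regscan",
                         mustWork = TRUE))
}

#' Promoter cores of the fixture oligos
#'
#' The three operator-bearing sequences with their five-cytosine synthesis
#' flanks removed: the 55-nt BT0356 core, the 31-nt BT0365 core, and the
#' 27-bp crystallization duplex (no flanks). These are the inputs to the
#' fixture motif discovery.
#'
#' @return Named character vector of three sequences.
#' @export
araR_promoter_cores <- function() {
  o <- araR_oligos()
  strip <- function(s) substr(s, 6L, nchar(s) - 5L)
  c(BT0356_core = strip(o[["BT0356_oligo"]]),
    BT0365_core = strip(o[["BT0365_oligo"]]),
    crystallization_duplex = o[["crystallization_duplex"]])
}

#' Fixture PWM, training set and threshold for the worked examples
#'
#' Builds the reference AraR model from the packaged promoter cores:
#' (1) the exhaustive oracle selects the best 21-nt palindromic window in
#' each core; (2) because tandem promoters contribute both of their boxes
#' to a binding-site training collection, each selected window's tandem
#' partner -- a window at an allowed spacer (3 or 42 nt) on either side with
#' a positive score against the stage-1 matrix -- is added to the training
#' set; (3) the final matrix (symmetrized, pseudocount \code{pseudocount})
#' is fitted to the augmented set and the threshold is the minimum training
#' score. On the packaged fixtures this yields four training sites and a
#' scanner that reproduces the experimentally validated site counts
#' (two boxes on BT0356 with a 3-bp spacer, one on BT0365, none on the
#' shuffled control).
#'
#' The result is cached for the session; pass a non-default
#' \code{pseudocount} to rebuild.
#'
#' @param pseudocount Pseudocount for the PWM (default 0.5).
#' @param allowed_spacers Spacers searched for tandem partners.
#' @return List: \code{pwm}, \code{threshold} (a \code{score_threshold}),
#'   \code{training_sites}, \code{oracle} (the stage-1 \code{discovery}).
#' @export
araR_fixture_model <- function(pseudocount = 0.5, allowed_spacers = c(3L, 42L)) {
  key <- sprintf("model_%.17g_%s", pseudocount, paste(allowed_spacers, collapse = "_"))
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  cores <- araR_promoter_cores()
  orc <- brute_force_profile_oracle(cores, width = 21L, palindromic = TRUE,
                                    pseudocount = pseudocount)
  L <- orc$pwm$width
  training <- character(0)
  for (i in seq_len(nrow(orc$instances))) {
    region <- cores[[orc$instances$sequence_id[i]]]
    start0 <- orc$instances$start[i]
    training <- c(training, orc$instances$site[i])
    for (sp in allowed_spacers) {
      for (dir in c(-1L, 1L)) {
        p0 <- start0 + dir * (L + sp)
        if (p0 >= 0L && p0 + L <= nchar(region)) {
          w <- substr(region, p0 + 1L, p0 + L)
          if (score_window(orc$pwm, w) > 0) training <- c(training, w)
        }
      }
    }
  }
  fit <- pwm(training, pseudocount = pseudocount, symmetrize = TRUE)
  res <- list(pwm = fit,
              threshold = min_training_threshold(fit, training),
              training_sites = training, oracle = orc)
  .fixture_env[[key]] <- res
  res
}

#' The AraR site profile at genome-collection count depth
#'
#' The packaged worked-example matrix is estimated from only four printed
#' operator sequences, so its positional frequencies are diffuse. The
#' original motif collection behind the AraR logo comprises on the order of
#' fifty sites from seventeen genomes; sites drawn from a matrix at that
#' count depth are near-consensus, as real operator sites are. This helper
#' rescales the fixture count matrix to \code{depth} observations per
#' column (preserving the positional frequencies) and refits the weights --
#' the default planting and scanning matrix of the synthetic benchmark.
#'
#' @param depth Total count per column (default 50).
#' @param pseudocount Pseudocount for the refitted weights.
#' @return A \code{pwm}.
#' @export
araR_site_pwm <- function(depth = 50, pseudocount = 0.5) {
  fx <- araR_fixture_model(pseudocount = pseudocount)
  counts <- fx$pwm$counts * (depth / fx$pwm$n_sites)
  attr(counts, "n_sites") <- depth
  pwm(counts = counts, pseudocount = pseudocount, symmetrize = TRUE)
}
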