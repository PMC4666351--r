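---
title: "Reconstructing a bacterial regulon from semipalindromic operator sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing a bacterial regulon from semipalindromic operator sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regscan)
```

## The procedure and its assumptions

`regscan` reconstructs the regulon of a DNA-binding transcription factor
across a set of related bacterial genomes using sequence information only.
The worked examples are built around AraR, an arabinose-responsive
repressor found in *Bacteroides* species, which binds a 21-bp
semipalindromic operator with GTGT/ACAC arms, frequently as a tandem pair
of boxes in the promoters of arabinose-utilization (*araMPRDAB*) operons.

The pipeline assumes:

* the motif has fixed width and is bound by a homodimer, so sites are
  approximately reverse-complement symmetric (semipalindromic);
* each training promoter carries at least one site (one-occurrence-per-
  sequence during discovery);
* regulation is conserved, so true targets carry predicted sites in the
  orthologous promoters of multiple genomes, while spurious hits do not;
* operons are runs of co-directional genes with short intergenic gaps, and
  regulator sites sit in the promoter of the operon's leading gene.

## The scoring model

Given N aligned training sites of width L, per-position base counts
n(b,k) define centered log-count weights

$$w(b,k) = \ln(n(b,k)+c) - \tfrac{1}{4}\sum_{b'} \ln(n(b',k)+c),$$

with pseudocount c. Columns sum to zero, so a window score
$S=\sum_k w(s_k,k)$ of 0 is the uninformative baseline and no explicit
background model is needed: the scanning threshold is *relative*, the
lowest score observed in the training set against its own matrix
(`min_training_threshold()`). Every training site passes the threshold by
construction; candidate genomic sites must do at least as well as the
weakest curated site.

Palindromic symmetrization averages each weight with its
reverse-complement mirror. Scores are then strand-invariant — and in this
implementation *bitwise* strand-invariant, because window scores
accumulate mirror-position pairs (k, L+1−k) before summing, so a window
and its reverse complement add the same doubles in the same order.

Tunable parameters, with defaults:

| parameter | default | units | role |
|---|---|---|---|
| motif width L | 21 | nt | fixed by the AraR operator |
| pseudocount c | 0.5 | counts | avoids −Inf with small training sets |
| symmetrize | TRUE | — | semipalindromic (homodimer) mode |
| upstream window | 300 | nt | promoter length scanned 5′ of a leading gene |
| operon gap | 100 | nt | max intergenic distance within an operon |
| tandem spacers | 3, 42 | nt | allowed end-to-start gaps between paired boxes |
| consistency | ≥2 genomes and ≥50% | — | cross-species membership rule |

The upstream window is not dictated by the biology of any one promoter;
300 nt comfortably covers the printed AraR promoter fragments and typical
*Bacteroides* intergenic lengths, and it is exposed as a parameter.
Spacers are measured end-to-start (the intervening gap), matching the
usual "separated by 3 bp" reading; this too is configurable.

## Motif discovery and its oracle

`discover_profile()` selects one window per input region to maximize the
total information content (IC) of the instance alignment, computed with
pseudocounted frequencies — the standard conserved-profile criterion, and
what a sequence logo of the result displays. Optimization is coordinate
ascent: each region's instance is reassigned to the window maximizing the
alignment IC given all other instances (a leave-one-out profile score).
This makes the objective provably non-decreasing within a restart (the
`trace` element exposes it), and termination certain. The first restart
starts from each region's most self-complementary window — a cheap
palindrome prior — and the remaining restarts (default 20) from
seed-driven random windows. Everything is deterministic given the seed.

Because coordinate ascent can in principle stall in local optima,
`brute_force_profile_oracle()` enumerates all window combinations (capped
at 10^6) and the test suite asserts the ascent attains the exhaustive
optimum on fixture-scale inputs. The objective choice (IC rather than,
say, log-likelihood under an explicit background) is a design decision;
only oracle-relative optimality is asserted, never absolute site scores.

## The fixture model

The packaged worked examples are the operator fragments validated by
EMSA: the 65-bp BT0356 (*araM*) promoter fragment with two tandem boxes,
the 41-bp BT0365 fragment with one box, a shuffled negative control, and
the 27-bp crystallization duplex spanning the BT0356 operator core.
`araR_fixture_model()` builds the reference model in three steps:

1. exhaustive palindromic discovery over the three promoter cores (the
   oligos with their five-cytosine synthesis flanks stripped) yields one
   21-nt window per core;
2. each window's *tandem partner* — a window at an allowed spacer (3 or
   42 nt) on either side scoring above the uninformative baseline — is
   added to the training set. This mirrors how operator collections are
   actually curated: a tandem promoter contributes both of its boxes, and
   the upstream BT0356 box is a genuine, experimentally bound operator.
   Without this step the three-window training set would exclude its own
   tandem partner and the minimum-score threshold would reject one of the
   two validated boxes;
3. the final symmetrized matrix (c = 0.5) is fitted to the augmented set
   (four sites) and θ is the minimum training score.

```{r}
fx <- araR_fixture_model()
summary(fx$pwm)
fx$threshold
```

With this model the scanner reports exactly the experimentally observed
architecture: two boxes 3 bp apart on BT0356, one box on BT0365, nothing
on the shuffled control.

## The synthetic benchmark

`generate_genome_set()` emulates the statistical structure the analysis
assumes: AT-rich background (A = T = 0.30, matching *Bacteroides*
intergenic composition), genes of 600 nt separated by 200–400-nt
intergenic stretches (every gene then heads its own operon under the
100-nt gap rule), random gene strands, and for each planted ortholog
group, with probability p_c per genome, PWM-sampled site(s) written over
background at a uniform admissible offset in the target gene's upstream
window — single boxes or tandem pairs with an exact configured spacer.
Sites replace background rather than insert, keeping all coordinates
stable; ground truth is recorded per genome.

Two deliberate idealizations: the planting matrix defaults to
`araR_site_pwm()`, the fixture profile rescaled to a count depth of 50
observations per column. The desk fixture itself has only four training
sequences, and sites sampled from so flat a frequency profile are too
degenerate to stand for real operator sites; the original AraR motif
collection comprises on the order of fifty sites from seventeen genomes,
and at that depth sampled sites are near-consensus, as genuine operators
are. Second, genomes are generated independently — there is no
phylogenetic correlation, site turnover, or indel process — so passing
the benchmark demonstrates correct scanning, coordinate lifting and
consistency logic, not robustness to realistic evolutionary noise.

The benchmark recipe (documented sizes, used by the test suite): 8
genomes × 20 genes, one tandem(3) group planted at p_c = 0.9, genome-set
seed 1, threshold from 10 sites sampled with seed 101. It yields
site-level precision 1.0 and recall 0.93, with the planted group the sole
member. Membership monotonicity is checked over 20 genome-set seeds per
conservation level on the grid {0.25, 0.5, 0.75, 1.0} (the run takes
under a minute at these sizes). With 8 genomes the membership rule needs
sites in ≥4 genomes, so the expected membership rate rises steeply across
that grid.

## Numerical choices and degenerate inputs

* Ambiguity codes are rejected at ingest: PWM scores over IUPAC codes are
  undefined, and silent recoding would corrupt counts. Errors name the
  record and offset.
* Gene tables are 1-based inclusive; all internal intervals and BED
  output are 0-based half-open. One conversion at each boundary.
* Ties in greedy overlap resolution break by score, then smaller start,
  then '+' strand; consensus ties break by the fixed order A<C<G<T;
  discovery ties break by smaller start then '+'. All deterministic.
* A gene at a contig edge yields an empty promoter (a signal, not an
  error); sequences shorter than L scan to an empty call set.
* BED scores are min-max scaled to 0–1000 over the written set (both ends
  map to 1000 when all scores are equal), so raw scores do not round-trip
  through BED; coordinates, names and strands do.
* With zero predictions, precision is reported as 1.0 plus an explicit
  flag, keeping conservation-sweep analyses well-defined.
* Seeded functions snapshot and restore the caller's RNG state.

## Known limitations

Single-box, fixed-width model: no dinucleotide dependence, no variable
spacers within a box, no p-value calibration of scores (the threshold is
training-relative by design). The 42-nt tandem variant is treated as a
plain gap with no internal structure. Operon assembly is a distance
heuristic; transcription-unit boundaries from expression data would be
better where available. The consistency rule's defaults (≥2 genomes,
≥50%) quantify a qualitative practice and should be revisited for genome
sets with strong phylogenetic clustering, which the independence
assumption of the benchmark does not model.
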