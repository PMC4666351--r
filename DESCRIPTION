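Package: regscan
Title: Comparative-Genomics Reconstruction of Bacterial Regulons from
    Semipalindromic Binding-Site Motifs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs transcription-factor regulons across bacterial
    genomes by conserved-motif discovery in orthologous promoter regions,
    position-weight-matrix scanning with a minimum-training-score threshold,
    tandem binding-site architecture detection, operon assembly, and a
    cross-species consistency check. Includes the AraR operator fragments
    from Bacteroides thetaiotaomicron as worked-example fixtures and a
    synthetic multi-genome generator with planted sites for benchmarking
    site recovery. The core model is a centered log-count position weight
    matrix with optional palindromic symmetrization, fitted by pwm() and
    exposed through the standard print, summary, coef, predict, plot and
    simulate methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), Biostrings, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
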