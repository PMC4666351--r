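# Shared test helpers: seeded random sequences and a tiny two-genome set
# built in code.

random_dna <- function(n, freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       seed = NULL) {
  draw <- function() paste(sample(names(freqs), n, replace = TRUE, prob = freqs),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# two genomes, one contig each, two co-directional gene pairs; group OG1
# leads an operon in both genomes
tiny_gene_table <- function() {
  data.frame(
    genome_id = rep(c("gA", "gB"), each = 2L),
    contig_id = "c1",
    gene_id = c("gA_1", "gA_2", "gB_1", "gB_2"),
    start = c(501L, 1101L, 601L, 1201L),
    end = c(1050L, 1650L, 1150L, 1750L),
    strand = "+",
    ortholog_group = rep(c("OG1", "OG2"), 2L),
    product = "p",
    stringsAsFactors = FALSE)
}

tiny_genome_set <- function(seed = 11L) {
  genes <- tiny_gene_table()
  contigs <- list(
    gA = c(c1 = random_dna(2000L, seed = seed)),
    gB = c(c1 = random_dna(2000L, seed = seed + 1L)))
  genome_set(contigs, genes)
}
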