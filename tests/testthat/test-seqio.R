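test_that("FASTA ingest cleans whitespace, uppercases and preserves record order", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">one desc", "acgTA CGT",            # stray internal space
               ">two", "AAA", "CCC", "GGG",          # wrapped body
               ">three", "AAACCCGGG"), fa)           # same body, one line
  seqs <- read_fasta(fa)
  expect_identical(names(seqs), c("one", "two", "three"))
  expect_identical(unname(seqs[1]), "ACGTACGT")
  expect_identical(unname(seqs[2]), unname(seqs[3]))
})

test_that("FASTA errors: empty file, ambiguity codes, empty record", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "empty FASTA")
  writeLines(c(">x", "ACGNACGT"), fa)
  expect_error(read_fasta(fa), "alphabet error.*'x'.*offset 4")
  writeLines(c(">x", ">y", "ACGT"), fa)
  expect_error(read_fasta(fa), "format error")
})

test_that("packaged negative-control oligo ingests to 65 nt despite the stray space", {
  o <- araR_oligos()
  expect_identical(unname(nchar(o[["shuffled_control"]])), 65L)
  expect_false(grepl("[^ACGT]", o[["shuffled_control"]]))
})

test_that("FASTA parsing agrees with Biostrings on a clean file", {
  skip_if_not_installed("Biostrings")
  fa <- withr::local_tempfile(fileext = ".fasta")
  set.seed(5)
  seqs <- setNames(vapply(1:4, function(i) random_dna(80L), ""), paste0("s", 1:4))
  write_fasta(seqs, fa)
  ref <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(ref), seqs)
})

test_that("gene table parses, validates and round-trips", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  genes <- tiny_gene_table()
  write_gene_table(genes, tsv)
  back <- read_gene_table(tsv)
  expect_identical(back, genes)

  # single-base gene is a legal boundary case
  genes2 <- genes; genes2$end[1] <- genes2$start[1]
  expect_silent(validate_gene_table(genes2))

  genes3 <- genes; genes3$start[2] <- genes3$end[2] + 10L
  expect_error(validate_gene_table(genes3), "coordinate error.*row 2")
  genes4 <- genes; genes4$strand[3] <- "."
  expect_error(validate_gene_table(genes4), "unknown strand.*row 3")
})

test_that("reverse complement: worked values and involution", {
  expect_identical(reverse_complement("GTGT"), "ACAC")
  expect_identical(reverse_complement(""), "")
  # frozen from an independent complement-then-reverse evaluation
  expect_identical(reverse_complement("AAAAGTGTTACTTTTACACCC"), "GGGTGTAAAAGTAACACTTTT")
  set.seed(17)
  xs <- vapply(1:500, function(i) random_dna(sample(1:60, 1L)), "")
  expect_identical(reverse_complement(reverse_complement(xs)), xs)
})

test_that("reverse complement agrees with Biostrings", {
  skip_if_not_installed("Biostrings")
  set.seed(23)
  xs <- vapply(1:50, function(i) random_dna(sample(1:40, 1L)), "")
  ref <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(xs)))
  expect_identical(reverse_complement(xs), unname(ref))
})

test_that("longest common substring: identities and fixture relationship", {
  expect_identical(longest_common_substring("ACGTACGT", "ACGTACGT"), 8L)
  expect_identical(longest_common_substring("AAA", "GGG"), 0L)
  expect_identical(longest_common_substring("XABCY", "ZABCW"), 3L)
  # crystallization duplex vs BT0356 core: shares the 22-nt operator core
  # plus one flanking base common by chance
  lcs <- longest_common_substring(araR_oligos()[["crystallization_duplex"]],
                                  araR_promoter_cores()[["BT0356_core"]])
  expect_gte(lcs, 22L)
  expect_identical(lcs, 23L)
})

test_that("upstream extraction follows strand, window and neighbor truncation", {
  genes <- data.frame(
    genome_id = "g", contig_id = "c1",
    gene_id = c("left", "plus", "minus"),
    start = c(101L, 501L, 1201L), end = c(460L, 900L, 1500L),
    strand = c("+", "+", "-"),
    ortholog_group = "", product = "", stringsAsFactors = FALSE)
  gs <- genome_set(list(g = c(c1 = random_dna(2000L, seed = 3L))), genes)

  # + strand, truncated by the neighbor ending 40 nt before the start
  up <- extract_upstream(gs, "g", "plus", window = 300L)
  expect_identical(c(up$start, up$end), c(460L, 500L))
  expect_identical(nchar(up$seq), 40L)

  # - strand: region is 3' of the gene body, reverse-complemented
  up2 <- extract_upstream(gs, "g", "minus", window = 300L)
  expect_identical(c(up2$start, up2$end), c(1500L, 1800L))
  contig <- gs$contigs$g[["c1"]]
  expect_identical(up2$seq, reverse_complement(substr(contig, 1501L, 1800L)))

  # contig edge with zero upstream: empty-region signal, not an error
  up3 <- extract_upstream(gs, "g", "left", window = 300L)
  expect_identical(up3$seq, substr(contig, 1L, 100L))
  genes$start[1] <- 1L
  gs2 <- genome_set(gs$contigs, genes)
  expect_identical(extract_upstream(gs2, "g", "left")$seq, "")
})

test_that("upstream regions never overlap annotated gene bodies", {
  for (seed in 1:5) {
    cfg <- synthetic_config(n_genomes = 1L, genes_per_genome = 8L,
                            conservation = 0, seed = seed)
    sim <- generate_genome_set(cfg)
    gs <- sim$genome_set
    for (i in seq_len(nrow(gs$genes))) {
      up <- extract_upstream(gs, gs$genes$genome_id[i], gs$genes$gene_id[i])
      b0 <- gs$genes$start - 1L
      b1 <- gs$genes$end
      expect_false(any(b1 > up$start & b0 < up$end &
                       gs$genes$contig_id == up$contig_id))
    }
  }
})

test_that("BED6 output: coordinates, degenerate scaling, round trip", {
  bed <- withr::local_tempfile(fileext = ".bed")
  sites <- data.frame(sequence_id = c("s", "s"), start = c(4L, 40L),
                      end = c(25L, 61L), strand = "+", score = c(7.5, 7.5),
                      stringsAsFactors = FALSE)
  write_sites_bed(sites, bed)
  back <- read_sites_bed(bed)
  expect_identical(back$start, c(4L, 40L))
  expect_identical(back$end, c(25L, 61L))
  expect_identical(back$score, c(1000, 1000))  # min == max -> both 1000
  expect_identical(back$name, c("site", "site"))

  write_sites_bed(sites[0, ], bed)
  expect_identical(nrow(read_sites_bed(bed)), 0L)
  expect_true(startsWith(readLines(bed)[1], "#"))
})
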