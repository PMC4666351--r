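test_that("site sampling is seed-deterministic and follows the positional frequencies", {
  p <- araR_site_pwm()
  expect_identical(sample_site(p, 5L, seed = 7L), sample_site(p, 5L, seed = 7L))
  expect_identical(simulate(p, nsim = 3L, seed = 7L), sample_site(p, 3L, seed = 7L))
  draws <- sample_site(p, 10000L, seed = 1L)
  emp <- build_count_matrix(draws) / 10000
  f <- column_information(p)$freq
  expect_lt(max(abs(emp - f)), 0.02)
})

test_that("generation honors architecture, conservation and determinism", {
  # full conservation, tandem(3): exactly 2 sites x genomes, gap exactly 3
  cfg <- synthetic_config(n_genomes = 8L, genes_per_genome = 4L,
                          conservation = 1, seed = 2L)
  sim <- generate_genome_set(cfg)
  expect_identical(nrow(sim$truth), 16L)
  for (g in unique(sim$truth$genome_id)) {
    tr <- sim$truth[sim$truth$genome_id == g, ]
    tr <- tr[order(tr$start), ]
    expect_identical(tr$start[2] - tr$end[1], 3L)
  }
  # planted sequence actually sits at the truth interval on the coding strand
  i <- 1L
  contig <- sim$genome_set$contigs[[sim$truth$genome_id[i]]][[sim$truth$contig_id[i]]]
  w <- substr(contig, sim$truth$start[i] + 1L, sim$truth$end[i])
  if (sim$truth$strand[i] == "-") w <- reverse_complement(w)
  expect_gt(score_window(cfg$pwm, w), 25)

  # tandem(42)
  cfg42 <- synthetic_config(n_genomes = 2L, genes_per_genome = 3L,
                            conservation = 1, seed = 3L,
                            planted = data.frame(group = "OG001",
                                                 architecture = "tandem",
                                                 spacer = 42L))
  s42 <- generate_genome_set(cfg42)
  tr <- s42$truth[s42$truth$genome_id == "g01", ]
  expect_identical(tr$start[2] - tr$end[1], 42L)

  # zero conservation
  cfg0 <- synthetic_config(n_genomes = 3L, genes_per_genome = 3L,
                           conservation = 0, seed = 4L)
  expect_identical(nrow(generate_genome_set(cfg0)$truth), 0L)

  # bit-identical reproduction
  expect_identical(generate_genome_set(cfg), sim)

  # impossible architecture is rejected at configuration time
  expect_error(synthetic_config(intergenic_range = c(30L, 60L)), "config error")
})

test_that("truth intervals always lie upstream of their target operon's leading gene", {
  for (seed in 1:3) {
    cfg <- synthetic_config(n_genomes = 3L, genes_per_genome = 6L,
                            conservation = 1, seed = seed)
    sim <- generate_genome_set(cfg)
    genes <- sim$genome_set$genes
    for (i in seq_len(nrow(sim$truth))) {
      tr <- sim$truth[i, ]
      gene <- genes[genes$genome_id == tr$genome_id &
                    genes$ortholog_group == tr$group, ]
      if (gene$strand == "+") {
        expect_lte(tr$end, gene$start - 1L)
        expect_gte(tr$start, gene$start - 1L - cfg$upstream_window)
      } else {
        expect_gte(tr$start, gene$end)
        expect_lte(tr$end, gene$end + cfg$upstream_window)
      }
      # never inside any gene body
      expect_false(any(genes$genome_id == tr$genome_id &
                       genes$start - 1L < tr$end & genes$end > tr$start))
    }
  }
})

test_that("mononucleotide shuffle preserves composition and length", {
  s <- araR_oligos()[["BT0356_oligo"]]
  sh <- shuffle_control(s, seed = 1L)
  expect_identical(nchar(sh), nchar(s))
  expect_identical(sort(strsplit(sh, "")[[1]]), sort(strsplit(s, "")[[1]]))
  expect_identical(shuffle_control(s, seed = 1L), sh)
  expect_false(shuffle_control(s, seed = 2L) == sh)
})

test_that("recovery evaluation: exact match, shifts, and the zero-prediction convention", {
  tr <- data.frame(genome_id = "g", contig_id = "c1", start = c(10L, 100L),
                   end = c(31L, 121L), strand = "+", group = "OG001",
                   architecture = "single", stringsAsFactors = FALSE)
  pred <- data.frame(genome_id = "g", contig_id = "c1", start = tr$start,
                     end = tr$end, score = c(5, 4), stringsAsFactors = FALSE)
  ev <- evaluate_recovery(pred, tr)
  expect_identical(c(ev$precision, ev$recall), c(1, 1))

  ev0 <- evaluate_recovery(pred[0, ], tr)
  expect_identical(ev0$precision, 1.0)
  expect_identical(ev0$recall, 0)
  expect_true(ev0$zero_prediction_flag)

  shifted <- pred; shifted$start <- shifted$start + 1L; shifted$end <- shifted$end + 1L
  expect_identical(evaluate_recovery(shifted, tr, tolerance = 1L)$recall, 1)
  expect_identical(evaluate_recovery(shifted, tr, tolerance = 0L)$recall, 0)

  # one-to-one greedy matching: two predictions on one truth site count once
  dup <- rbind(pred[1, ], pred[1, ])
  evd <- evaluate_recovery(dup, tr[1, ])
  expect_identical(evd$n_matched, 1L)
  expect_identical(evd$precision, 0.5)
})

test_that("synthetic output files round-trip through the standard readers", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_genomes = 2L, genes_per_genome = 3L,
                          conservation = 1, seed = 6L)
  sim <- generate_genome_set(cfg)
  write_synthetic(sim, dir)
  expect_identical(read_fasta(file.path(dir, "g01.fasta"))[["c1"]],
                   sim$genome_set$contigs$g01[["c1"]])
  genes <- read_gene_table(file.path(dir, "genes.tsv"))
  expect_identical(genes, sim$genome_set$genes)
  bed <- read_sites_bed(file.path(dir, "truth.bed"))
  expect_identical(nrow(bed), nrow(sim$truth))
})
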