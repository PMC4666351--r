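test_that("count matrix tallies exact per-position base counts", {
  m <- build_count_matrix(c("AC", "AC"))
  expect_identical(unname(m["A", 1]), 2L)
  expect_identical(unname(m["C", 2]), 2L)
  expect_identical(sum(m), 4L)
  m1 <- build_count_matrix("ACGT")
  expect_true(all(colSums(m1) == 1L))
  m4 <- build_count_matrix(c("A", "C", "G", "T"))
  expect_true(all(m4[, 1] == 1L))
  expect_error(build_count_matrix(c("AC", "ACG")), "width error")
  expect_error(build_count_matrix(character(0)), "value error")
})

test_that("centered log-count weights match hand-evaluated values", {
  # column (2,0,0,0), c = 0.5: w(A) = ln 2.5 - (ln 2.5 + 3 ln 0.5)/4
  m <- pwm(c("A", "A"), pseudocount = 0.5, symmetrize = FALSE)
  expect_equal(unname(coef(m)["A", 1]), 1.2071, tolerance = 5e-4)
  expect_equal(unname(coef(m)["C", 1]), -0.4024, tolerance = 5e-4)
  # uniform column -> all weights zero
  mu <- pwm(c("A", "C", "G", "T"), symmetrize = FALSE)
  expect_equal(max(abs(coef(mu))), 0)
})

test_that("every built matrix has zero-sum columns and symmetrization is exact", {
  set.seed(31)
  for (i in 1:20) {
    sites <- vapply(seq_len(sample(1:15, 1L)), function(j) random_dna(12L), "")
    for (sym in c(TRUE, FALSE)) {
      m <- pwm(sites, pseudocount = runif(1, 0.1, 2), symmetrize = sym)
      expect_lt(max(abs(colSums(coef(m)))), 1e-9)
      if (sym) {
        w <- coef(m)
        expect_identical(w, w[4:1, ncol(w):1, drop = FALSE],
                         ignore_attr = TRUE)
      }
    }
  }
})

test_that("window scores are sums of positional weights (naive-loop oracle)", {
  set.seed(37)
  sites <- vapply(1:8, function(i) random_dna(9L), "")
  m <- pwm(sites)
  w <- coef(m)
  naive <- function(s) {
    tot <- 0
    for (k in seq_len(nchar(s))) tot <- tot + w[substr(s, k, k), k]
    tot
  }
  wins <- vapply(1:50, function(i) random_dna(9L), "")
  expect_equal(score_window(m, wins), vapply(wins, naive, 0, USE.NAMES = FALSE),
               tolerance = 1e-12)
  expect_identical(score_window(m, wins), predict(m, wins))
  expect_error(score_window(m, "ACGT"), "width error")
  # consensus window scores the sum of column maxima
  expect_equal(score_window(m, consensus_sequence(m)), sum(apply(w, 2, max)),
               tolerance = 1e-12)
})

test_that("single 21-nt training site scores 21 x 0.8240 against its own matrix", {
  site <- random_dna(21L, seed = 41L)
  m <- pwm(site, pseudocount = 0.5, symmetrize = FALSE)
  expect_equal(score_window(m, site), 17.304, tolerance = 0.01)
})

test_that("minimum-training-score threshold is sound and monotone", {
  set.seed(43)
  sites <- vapply(1:6, function(i) random_dna(11L), "")
  m <- pwm(sites)
  th <- min_training_threshold(m, sites)
  expect_true(all(score_window(m, sites) >= th$threshold))
  expect_identical(min_training_threshold(m, sites[1])$threshold,
                   score_window(m, sites[1]))
  # adding a lower-scoring site never raises the threshold
  extra <- c(sites, random_dna(11L))
  expect_lte(min_training_threshold(m, extra)$threshold, th$threshold)
  expect_error(min_training_threshold(m, character(0)), "value error")
})

test_that("column information matches hand values and entropy bounds", {
  mu <- build_count_matrix(c("A", "C", "G", "T"))
  expect_equal(column_information(mu, 0.5)$ic, 0)
  m4 <- build_count_matrix(c("A", "A", "A", "A"))
  expect_equal(column_information(m4, 0.5)$ic, 0.792, tolerance = 5e-3)
  set.seed(47)
  for (i in 1:10) {
    sites <- vapply(seq_len(sample(2:20, 1L)), function(j) random_dna(7L), "")
    ic <- column_information(build_count_matrix(sites), 0.5)$ic
    expect_true(all(ic >= 0 & ic <= 2))
  }
})

test_that("consensus uses the documented A<C<G<T tie-break and mirrors under symmetry", {
  expect_identical(consensus_sequence(pwm(c("AC", "AC"))), "AC")
  zero <- pwm(c("A", "C", "G", "T"))          # uniform -> all ties
  expect_identical(consensus_sequence(zero), "A")
  set.seed(53)
  for (i in 1:10) {
    sites <- vapply(1:6, function(j) random_dna(10L), "")
    m <- pwm(sites, symmetrize = TRUE)
    cons <- consensus_sequence(m)
    w <- coef(m)
    # wherever the column argmax is strict, the consensus is palindromic
    strict <- vapply(seq_len(ncol(w)), function(k) {
      s <- sort(w[, k], decreasing = TRUE); s[1] - s[2] > 1e-9
    }, TRUE)
    rc <- strsplit(reverse_complement(cons), "")[[1]]
    expect_true(all(strsplit(cons, "")[[1]][strict & rev(strict)] ==
                    rc[strict & rev(strict)]))
  }
})

test_that("PWM serialization round-trips weights, counts and flags", {
  set.seed(59)
  m <- pwm(vapply(1:5, function(i) random_dna(8L), ""), pseudocount = 0.25)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pwm(m, f)
  back <- read_pwm(f)
  expect_identical(coef(back), coef(m))
  expect_identical(back$counts, m$counts)
  expect_identical(back$pseudocount, m$pseudocount)
  expect_identical(back$symmetrized, m$symmetrized)
  expect_identical(back$width, m$width)
})

test_that("print, summary and plot methods run", {
  m <- araR_fixture_model()$pwm
  expect_output(print(m), "width 21")
  s <- summary(m)
  expect_output(print(s), "total information")
  expect_equal(s$total_ic, sum(column_information(m)$ic))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(m))
})
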