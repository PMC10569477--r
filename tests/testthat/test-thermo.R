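test_that("GC fraction and its expansion extremes are exact", {
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("ATAT"), 0.0)
  expect_equal(gc_fraction("ACGT"), 0.5)
  expect_error(gc_fraction(""), "empty|invalid")
  ## extremes vs enumeration
  set.seed(21)
  for (i in 1:30) {
    s <- rand_iupac(sample(8:12, 1), p_degenerate = 0.3)
    got <- gc_extremes(s)
    want <- range(vapply(oracle_expand(s), gc_fraction, numeric(1)))
    expect_equal(unname(got), want)
  }
})

test_that("melting temperature follows the composition formulas", {
  expect_equal(melting_temperature("ACGTACGTACGT"), 36)      # Wallace, 6 GC
  s20 <- paste0(strrep("G", 5), strrep("C", 5), strrep("AT", 5))
  expect_equal(melting_temperature(s20), 64.9 + 41 * (10 - 16.4) / 20)
  expect_equal(melting_temperature(strrep("A", 10)), 20)
  expect_equal(melting_temperature(strrep("G", 10)), 40)
  expect_error(melting_temperature("ACGTACG"), "shorter")
  ## Wallace Tm depends only on composition
  expect_equal(melting_temperature("AAACCCGGGTTT"),
               melting_temperature("ACGTACGTACGT"))
})

test_that("Tm extremes over expansions match enumeration (degeneracy <= 64)", {
  set.seed(22)
  for (i in 1:30) {
    repeat {
      s <- rand_iupac(sample(c(10, 14, 18), 1), p_degenerate = 0.25)
      if (degeneracy(s) <= 64) break
    }
    got <- tm_extremes(s)
    want <- range(vapply(oracle_expand(s), melting_temperature, numeric(1)))
    expect_equal(unname(got), want)
  }
})

test_that("hairpin detection agrees with the exhaustive oracle", {
  hp <- find_hairpins("GGGGAAACCCC", stem_min = 4, loop_min = 3)
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$stem_start, 1L)
  expect_equal(hp$stem_len, 4L)
  expect_equal(hp$loop_len, 3L)
  expect_equal(nrow(find_hairpins(strrep("A", 11))), 0L)
  expect_error(find_hairpins("ACGT", stem_min = 2), "stem_min")
  set.seed(23)
  for (i in 1:60) {
    s <- rand_dna(sample(12:20, 1))
    got <- find_hairpins(s)
    want <- oracle_hairpins(s)
    expect_equal(got[order(got$stem_start, got$stem_len, got$loop_len), ],
                 want[order(want$stem_start, want$stem_len, want$loop_len), ],
                 ignore_attr = TRUE)
  }
  ## degenerate oligos: flagged iff some expansion is flagged
  for (i in 1:15) {
    s <- rand_iupac(14, p_degenerate = 0.2)
    if (degeneracy(s) > 64) next
    expect_equal(nrow(find_hairpins(s)) > 0,
                 nrow(oracle_hairpins(s)) > 0)
  }
})

test_that("dimer runs agree with the exhaustive oracle", {
  expect_equal(dimer_runs("ACGTACGT", "ACGTACGT")$max_run, 8L)
  expect_equal(dimer_runs("AAAAA", "CCCCC")$max_run, 0L)
  set.seed(24)
  for (i in 1:80) {
    a <- rand_dna(sample(5:12, 1))
    b <- rand_dna(sample(5:12, 1))
    expect_identical(unlist(dimer_runs(a, b)), unlist(oracle_dimer(a, b)))
    expect_identical(unlist(dimer_runs(a, a)), unlist(oracle_dimer(a, a)))
  }
})

test_that("qc_primer applies every guideline and reports without throwing", {
  r <- design_rules()
  q <- qc_primer(strrep("A", 24), r)
  expect_false(q$pass_length)
  expect_false(q$pass_polyN)
  expect_false(q$verdict)
  ## 20-mer with 9 GC: Tm 49.73 sits just under the lower bound
  s <- paste0(strrep("GCAT", 4), "GAAT")
  expect_equal(nchar(s), 20L)
  expect_equal(sum(strsplit(s, "")[[1]] %in% c("G", "C")), 9L)
  q <- qc_primer(s, r)
  expect_true(q$pass_length)
  expect_false(q$pass_tm)
  expect_equal(q$tm_min, 64.9 + 41 * (9 - 16.4) / 20)
  q <- qc_primer(strrep("GC", 10), r)
  expect_false(q$pass_gc)
  expect_false(q$pass_dimer)   # fully self-complementary
  ## a known-good 22-mer designed under these rules passes
  q <- qc_primer("TCTAACTCTTGGACGTATTCGG", r)
  expect_true(q$verdict)
})
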