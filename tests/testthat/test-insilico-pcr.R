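test_that("primer matching finds planted sites and honours IUPAC codes", {
  set.seed(51)
  primer <- "ACGTACGTACGTACGTA"
  tpl <- plant_primer_sites(200, primer, "TTGACCTGAGTCAGGAT", 60,
                            seed = 3)$template
  hits <- match_primer(primer, tpl$seq)
  expect_equal(nrow(hits[hits$strand == "+", ]), 1L)
  expect_equal(hits$mismatches[1], 0L)
  ## degenerate position covers the template base
  t2 <- "GGGGACGGGG"
  expect_equal(nrow(match_primer("AY", t2)), nrow(match_primer("AC", t2)))
  h <- match_primer("ACR", "TTACGTT")
  expect_true(any(h$strand == "+" & h$start == 3))
  ## N in the template matches nothing under the strict policy
  expect_equal(nrow(match_primer("ACGG", "TTANGGTT")), 0L)
  expect_equal(nrow(match_primer("ACGG", "TTANGGTT", n_policy = "any")), 1L)
  expect_equal(nrow(match_primer("ACGTACGT", "ACG")), 0L)
})

test_that("matching equals brute-force expansion scanning", {
  set.seed(52)
  for (i in 1:40) {
    primer <- rand_iupac(sample(5:8, 1), p_degenerate = 0.3)
    tpl <- rand_dna(sample(20:40, 1))
    for (mm in 0:1) {
      got <- match_primer(primer, tpl, max_mismatch = mm,
                          three_prime_exact = if (i %% 2) 2L else 0L)
      want <- oracle_match(primer, tpl, max_mismatch = mm,
                           three_prime_exact = if (i %% 2) 2L else 0L)
      expect_equal(got[, c("strand", "start", "end", "mismatches")], want,
                   ignore_attr = TRUE)
    }
  }
})

test_that("minus-strand matching equals plus-strand matching of the rc primer", {
  set.seed(53)
  for (i in 1:20) {
    primer <- rand_iupac(8, p_degenerate = 0.2)
    tpl <- rand_dna(60)
    h <- match_primer(primer, tpl, max_mismatch = 1)
    h_rc <- match_primer(reverse_complement(primer), tpl, max_mismatch = 1)
    minus <- h[h$strand == "-", c("start", "end", "mismatches")]
    plus_rc <- h_rc[h_rc$strand == "+", c("start", "end", "mismatches")]
    expect_equal(minus, plus_rc, ignore_attr = TRUE)
  }
})

test_that("amplicon prediction recovers planted products with exact sizes", {
  fw <- "TCTAACTCTTGGACGTATTCGG"
  rv <- "CCTCWGACACAWACTASCGTA"
  pl <- plant_primer_sites(1200, fw, rv, 850, seed = 9)
  amp <- predict_amplicons(setNames(fw, "F"), setNames(rv, "R"),
                           pl$template)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$product_length, 850L)
  expect_equal(amp$product_start, pl$truth$fw_start)
  expect_equal(nchar(amp$sequence), 850L)
  ## product length always equals the coordinate arithmetic
  expect_equal(amp$product_length, amp$product_end - amp$product_start + 1L)
  ## reversing the primer roles yields no product
  none <- predict_amplicons(setNames(rv, "R"), setNames(fw, "F"),
                            pl$template)
  expect_equal(nrow(none), 0L)
})

test_that("abutting primers give the minimal product and bounds apply", {
  fw <- "ACGTACGTACGTACGTA"
  rv <- "TTGACCTGAGTCAGGAT"
  pl <- plant_primer_sites(300, fw, rv, nchar(fw) + nchar(rv), seed = 11)
  amp <- predict_amplicons(setNames(fw, "F"), setNames(rv, "R"),
                           pl$template, size_min = 10)
  expect_equal(amp$product_length, nchar(fw) + nchar(rv))
  ## size window excludes the product
  amp2 <- predict_amplicons(setNames(fw, "F"), setNames(rv, "R"),
                            pl$template, size_min = 100, size_max = 3000)
  expect_equal(nrow(amp2), 0L)
})

test_that("coverage matrix counts targets per variant and per mix", {
  ## two variants covering disjoint constructed clades of 3 + 3
  va <- "ACGTACGTACGTACGTA"
  vb <- "TGCATGCATGCATGCAT"
  tpls <- data.frame(
    id = paste0("s", 1:6),
    seq = c(vapply(1:3, function(i) paste0(rand_dna(20), va, rand_dna(20)),
                   character(1)),
            vapply(1:3, function(i) paste0(rand_dna(20), vb, rand_dna(20)),
                   character(1))))
  cov <- coverage_matrix(list(mix1 = c(A = va, B = vb)), tpls)
  expect_equal(unname(cov$variant_counts), c(3, 3))
  expect_equal(unname(cov$mix_unions), 6)
  expect_error(coverage_matrix(list(m = c(A = va)),
                               rbind(tpls, tpls[1, ])), "duplicate")
})

test_that("union coverage grows monotonically as variants join a mix", {
  set.seed(54)
  tpls <- data.frame(id = paste0("s", 1:8),
                     seq = vapply(1:8, function(i) rand_dna(120),
                                  character(1)))
  vars <- vapply(1:4, function(i) {
    substr(tpls$seq[sample(8, 1)], 30, 47)
  }, character(1))
  names(vars) <- paste0("v", 1:4)
  prev <- -1
  for (k in 1:4) {
    cov <- coverage_matrix(list(m = vars[1:k]), tpls)
    expect_gte(unname(cov$mix_unions), prev)
    prev <- unname(cov$mix_unions)
  }
})
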