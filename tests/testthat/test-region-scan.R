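make_aln <- function(rows) as_alignment(setNames(rows, paste0("t", seq_along(rows))))

test_that("column conservation reports majority, fraction, ties and gaps", {
  aln <- make_aln(c("AAA", "AAC", "A-G", "CAT"))
  cc <- column_conservation(aln)
  expect_equal(cc$majority_base[1], "A")
  expect_equal(cc$majority_fraction[1], 0.75)
  expect_true(cc$has_gap[2])
  ## column 3: one each of A,C,G,T -> alphabetical tie-break
  expect_equal(cc$majority_base[3], "A")
  expect_equal(cc$majority_fraction[3], 0.25)
})

test_that("scan_windows equals the exhaustive filter on small alignments", {
  rules <- design_rules()
  set.seed(31)
  base <- rand_dna(30)
  for (i in 1:20) {
    rows <- vapply(1:5, function(k) {
      chars <- strsplit(base, "")[[1]]
      mut <- which(runif(30) < 0.12)
      if (length(mut))
        chars[mut] <- sample(c("A", "C", "G", "T"), length(mut), TRUE)
      paste(chars, collapse = "")
    }, character(1))
    aln <- make_aln(rows)
    for (ori in c("fw", "rv")) {
      got <- scan_windows(aln, rules, ori)
      want <- oracle_scan(aln, rules, ori)
      got <- got[order(got$start, got$end), c("start", "end", "consensus")]
      want <- want[order(want$start, want$end), ]
      expect_equal(got, want, ignore_attr = TRUE)
    }
    base <- rand_dna(30)
  }
})

test_that("scan_windows is invariant to row order and finds planted blocks", {
  ## planted QC-clean block inside a divergent background
  fam <- simulate_gene_family(family_spec(
    n_taxa = 12, gene_length = 120,
    conserved_blocks = list(c(41, 22, 0)),
    block_consensus = list("TCTAACTCTTGGACGTATTCGG"),
    background_divergence = 0.5, seed = 5))
  res <- scan_windows(fam$alignment)
  expect_gt(nrow(res), 0)
  ## the top-ranked window lies in the fully conserved planted block
  expect_equal(res$mean_conservation[1], 1)
  expect_gte(res$start[1], 41)
  expect_lte(res$end[1], 62)
  ## permuting rows changes nothing
  perm <- sample(length(fam$alignment$ids))
  aln2 <- as_alignment(fam$alignment$seqs[perm])
  res2 <- scan_windows(aln2)
  expect_equal(res, res2)
  ## gaps across the only conserved block remove all candidates
  seqs <- fam$alignment$seqs
  substr(seqs[3], 41, 62) <- strrep("-", 22)
  expect_equal(nrow(scan_windows(as_alignment(seqs))), 0L)
})

test_that("pair_regions does the coordinate arithmetic and enforces rules", {
  fw <- data.frame(start = 112, end = 131, length = 20, orientation = "fw",
                   consensus = "x", tm = 52, gc = 0.45,
                   mean_conservation = 1)
  rv <- data.frame(start = 973, end = 989, length = 17, orientation = "rv",
                   consensus = "y", tm = 53, gc = 0.45,
                   mean_conservation = 1)
  pr <- pair_regions(fw, rv, min_product = 400)
  expect_equal(pr$product_span, 989 - 112 + 1)   # 878 alignment columns
  ## Tm difference beyond the +-4 C guideline is rejected
  rv$tm <- 57.5
  expect_message(pr <- pair_regions(fw, rv), "tm=1")
  expect_equal(nrow(pr), 0L)
  ## reverse window upstream of forward is rejected
  rv$tm <- 53; rv$start <- 10; rv$end <- 26
  expect_message(pr <- pair_regions(fw, rv), "order=1")
  expect_equal(nrow(pr), 0L)
})

test_that("pair ranking maximizes product span as a total order", {
  fw <- data.frame(start = c(10, 40), end = c(29, 59), length = 20,
                   orientation = "fw", consensus = "x", tm = 52, gc = 0.4,
                   mean_conservation = 1)
  rv <- data.frame(start = c(500, 700), end = c(519, 719), length = 20,
                   orientation = "rv", consensus = "y", tm = 52, gc = 0.4,
                   mean_conservation = 1)
  pr <- pair_regions(fw, rv, min_product = 100)
  expect_equal(nrow(pr), 4L)
  expect_equal(pr$product_span, sort(pr$product_span, decreasing = TRUE))
  expect_equal(pr$product_span[1], 719 - 10 + 1)
})
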