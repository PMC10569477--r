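test_that("minimal variant consensus enforces the degeneracy rules", {
  rules <- design_rules()
  r <- minimal_variant_for_group(rep("ACGTACGTACGTACGTA", 2), rules)
  expect_true(r$feasible)
  expect_equal(r$seq, "ACGTACGTACGTACGTA")
  expect_equal(r$n_degenerate, 0L)
  ## two rows differing at positions 3 and 9 only
  a <- "ACGTACGTACGTACGTA"
  b <- a; substr(b, 3, 3) <- "T"; substr(b, 9, 9) <- "C"
  r <- minimal_variant_for_group(c(a, b), rules)
  expect_true(r$feasible)
  expect_equal(r$n_degenerate, 2L)
  ## five differing positions exceed the limit of four
  b <- a
  for (p in c(1, 3, 5, 7, 9)) substr(b, p, p) <- "T"
  r <- minimal_variant_for_group(c(a, b), rules)
  expect_false(r$feasible)
  expect_match(r$reason, "too many")
  ## adjacent differences are forbidden even when few
  b <- a; substr(b, 5, 5) <- "T"; substr(b, 6, 6) <- "G"
  r <- minimal_variant_for_group(c(a, b), rules)
  expect_false(r$feasible)
  expect_match(r$reason, "consecutive")
  expect_error(minimal_variant_for_group(character(0)), "empty")
})

test_that("identical targets collapse to one exact variant", {
  mix <- partition_targets(setNames(rep("ACGTACGTACGTACGTA", 4),
                                    paste0("t", 1:4)))
  expect_length(mix$variants, 1L)
  expect_equal(mix$variants[[1]]$n_degenerate, 0L)
  expect_setequal(mix$union_coverage, paste0("t", 1:4))
})

test_that("exact partitioning matches brute force over all set partitions", {
  rules <- design_rules()
  set.seed(41)
  for (trial in 1:25) {
    n <- sample(4:7, 1)
    base <- rand_dna(18)
    rows <- vapply(1:n, function(k) {
      chars <- strsplit(base, "")[[1]]
      mut <- sample(18, sample(0:4, 1))
      if (length(mut))
        chars[mut] <- sample(c("A", "C", "G", "T"), length(mut), TRUE)
      paste(chars, collapse = "")
    }, character(1))
    names(rows) <- paste0("t", 1:n)
    mix <- partition_targets(rows, rules, method = "exact")
    expect_equal(length(mix$variants),
                 oracle_min_partition(unique(unname(rows)), rules))
    ## every emitted variant covers its group exactly
    for (v in mix$variants)
      expect_setequal(v$covered_ids,
                      names(rows)[variant_covers(v$seq, rows)])
  }
})

test_that("greedy partitioning covers everything and respects the rules", {
  rules <- design_rules()
  set.seed(42)
  base <- rand_dna(20)
  rows <- vapply(1:20, function(k) {
    chars <- strsplit(base, "")[[1]]
    mut <- sample(20, sample(0:6, 1))
    if (length(mut))
      chars[mut] <- sample(c("A", "C", "G", "T"), length(mut), TRUE)
    paste(chars, collapse = "")
  }, character(1))
  names(rows) <- paste0("t", 1:20)
  mix <- partition_targets(rows, rules, method = "greedy")
  expect_setequal(mix$union_coverage, names(rows))
  for (v in mix$variants) {
    expect_lte(count_degenerate_positions(v$seq), rules$max_degenerate)
    dp <- degenerate_positions(v$seq)
    if (length(dp) > 1) expect_gt(min(diff(dp)), 1)
  }
  ## coverage order: G1 covers at least as many targets as later variants
  sizes <- vapply(mix$variants, function(v) length(v$covered_ids), integer(1))
  expect_equal(sizes, sort(sizes, decreasing = TRUE))
})

test_that("relaxation adds one well-placed degeneracy and never loses coverage", {
  rules <- design_rules()
  ## constructed case: one added Y gains exactly two targets
  v <- "ACGTACGTACGTACGTA"
  gain1 <- v; substr(gain1, 6, 6) <- "T"      # C -> T at position 6
  rows <- setNames(c(v, v, gain1, gain1, "TTTTTTTTTTTTTTTTT"),
                   paste0("t", 1:5))
  r <- relax_variant(v, rows, rules, name = "Fw1_G1")
  expect_equal(r$gain, 2L)
  expect_equal(r$position, 6L)
  expect_equal(substr(r$seq, 6, 6), "Y")
  expect_equal(r$name, "Fw1_G1n")
  expect_setequal(r$covered_ids, paste0("t", 1:4))
  ## brute force over all single-position widenings confirms optimality
  best_gain <- 0L
  for (p in seq_len(nchar(v))) {
    for (code in c("R", "Y", "S", "W", "K", "M", "N")) {
      cand <- v; substr(cand, p, p) <- code
      if (count_degenerate_positions(cand) != 1) next
      g <- sum(variant_covers(cand, rows)) - sum(variant_covers(v, rows))
      best_gain <- max(best_gain, g)
    }
  }
  expect_equal(r$gain, best_gain)
  ## a variant already covering everything comes back unchanged
  r2 <- relax_variant(v, setNames(rep(v, 3), paste0("s", 1:3)), rules)
  expect_equal(r2$seq, v)
  expect_equal(r2$gain, 0L)
  ## at the degeneracy limit relaxation refuses
  at_limit <- "RCGTYCGTWCGTKCGTA"
  expect_error(relax_variant(at_limit, rows, rules), "degeneracy limit")
})

test_that("relaxed coverage is a superset of the original coverage", {
  rules <- design_rules()
  set.seed(43)
  for (trial in 1:20) {
    base <- rand_dna(18)
    rows <- vapply(1:10, function(k) {
      chars <- strsplit(base, "")[[1]]
      mut <- sample(18, sample(0:3, 1))
      if (length(mut))
        chars[mut] <- sample(c("A", "C", "G", "T"), length(mut), TRUE)
      paste(chars, collapse = "")
    }, character(1))
    names(rows) <- paste0("t", 1:10)
    v <- minimal_variant_for_group(rows[1:2], rules)
    if (!v$feasible || v$n_degenerate >= rules$max_degenerate) next
    r <- relax_variant(v$seq, rows, rules)
    before <- names(rows)[variant_covers(v$seq, rows)]
    expect_true(all(before %in% r$covered_ids))
  }
})

test_that("spacing score is the minimal gap between degeneracies", {
  s <- "ACGTACGTACGTACGTA"
  substr(s, 3, 3) <- "R"; substr(s, 9, 9) <- "Y"; substr(s, 15, 15) <- "W"
  expect_equal(spacing_score(s), 6)
  expect_equal(spacing_score("ACGTACGTACGTACGTA"), Inf)
  expect_equal(spacing_score("ACRTACGTACGTACGTA"), Inf)
  s2 <- "ACRYACGTACGTACGTA"
  expect_equal(spacing_score(s2), 1)
})
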