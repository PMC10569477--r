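## Brute-force reference implementations, deliberately written along
## different paths than the package code they check.

.ora_codes <- Biostrings::IUPAC_CODE_MAP

## expansion by recursive cartesian product over the Biostrings code map
oracle_expand <- function(seq) {
  sets <- strsplit(.ora_codes[strsplit(seq, "")[[1]]], "")
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste,
             collapse = ""))
}

.ora_comp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## sliding-window matching by full expansion enumeration
oracle_match <- function(primer, template, max_mismatch = 0L,
                         three_prime_exact = 0L) {
  L <- nchar(primer)
  Tn <- nchar(template)
  hits <- list()
  tchars <- strsplit(template, "")[[1]]
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else .ora_comp(primer)
    exps <- oracle_expand(pat)
    if (L > Tn) next
    for (start in 1:(Tn - L + 1)) {
      win <- tchars[start:(start + L - 1)]
      best <- Inf
      for (e in exps) {
        ec <- strsplit(e, "")[[1]]
        mm <- sum(ec != win | win == "N")
        if (three_prime_exact > 0) {
          p3 <- if (strand == "+") (L - three_prime_exact + 1):L
                else 1:three_prime_exact
          if (any(ec[p3] != win[p3] | win[p3] == "N")) next
        }
        best <- min(best, mm)
      }
      if (best <= max_mismatch)
        hits[[length(hits) + 1]] <- data.frame(strand = strand,
                                               start = as.integer(start),
                                               end = as.integer(start + L - 1),
                                               mismatches = as.integer(best))
    }
  }
  if (length(hits) == 0)
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0)))
  df <- do.call(rbind, hits)
  df[order(df$start, df$strand), , drop = FALSE]
}

## exhaustive hairpin scan via substring reverse-complement comparison
oracle_hairpins <- function(seq, stem_min = 4L, loop_min = 3L) {
  n <- nchar(seq)
  exps <- oracle_expand(seq)
  found <- list()
  for (i in 1:max(1, n)) {
    for (len in stem_min:max(stem_min, n)) {
      for (loop in loop_min:max(loop_min, n)) {
        j <- i + len + loop            # stem2 start
        if (j + len - 1 > n) next
        hit <- any(vapply(exps, function(e) {
          s1 <- substr(e, i, i + len - 1)
          s2 <- substr(e, j, j + len - 1)
          s1 == .ora_comp(s2)
        }, logical(1)))
        if (hit) found[[length(found) + 1]] <- c(i, len, loop)
      }
    }
  }
  if (length(found) == 0)
    return(data.frame(stem_start = integer(0), stem_len = integer(0),
                      loop_len = integer(0)))
  df <- as.data.frame(do.call(rbind, found))
  names(df) <- c("stem_start", "stem_len", "loop_len")
  df
}

## dimer runs by explicit offset sliding of a against reversed b
oracle_dimer <- function(a, b) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  pairs_ok <- function(x, y) {       # can x pair with y for some expansion
    ex <- strsplit(.ora_codes[x], "")[[1]]
    ey <- strsplit(.ora_codes[y], "")[[1]]
    any(vapply(ex, function(u) comp[[u]] %in% ey, logical(1)))
  }
  la <- length(ac); lb <- length(bc)
  max_run <- 0L; max_3p <- 0L
  for (s in 2:(la + lb)) {
    run <- 0L
    for (i in max(1, s - lb):min(la, s - 1)) {
      j <- s - i
      if (pairs_ok(ac[i], bc[j])) run <- run + 1L else run <- 0L
      max_run <- max(max_run, run)
      if (i == la) max_3p <- max(max_3p, run)
    }
  }
  list(max_run = max_run, max_3prime_run = max_3p)
}

## exhaustive window filter over a small alignment
oracle_scan <- function(aln, rules, orientation) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  n <- nrow(m)
  out <- list()
  for (len in rules$primer_len_min:rules$primer_len_max) {
    if (len > ncol(m)) next
    for (start in 1:(ncol(m) - len + 1)) {
      cols <- start:(start + len - 1)
      if (any(m[, cols] == "-")) next
      fracs <- numeric(len); maj <- character(len)
      for (k in seq_along(cols)) {
        tb <- table(factor(m[, cols[k]], levels = c("A", "C", "G", "T")))
        maj[k] <- names(tb)[which.max(tb)]
        fracs[k] <- max(tb) / n
      }
      if (mean(fracs) < rules$conservation_threshold) next
      oligo <- paste(maj, collapse = "")
      if (orientation == "rv") oligo <- .ora_comp(oligo)
      if (!qc_primer(oligo, rules)$verdict) next
      out[[length(out) + 1]] <- data.frame(start = start,
                                           end = start + len - 1,
                                           consensus = oligo)
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      consensus = character(0)))
  do.call(rbind, out)
}

## all set partitions of 1..n (for exact minimum-partition checking)
oracle_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- oracle_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

## smallest number of groups whose consensus obeys the degeneracy rules
oracle_min_partition <- function(rows, rules) {
  n <- length(rows)
  best <- Inf
  for (p in oracle_partitions(n)) {
    ok <- all(vapply(p, function(g)
      minimal_variant_for_group(rows[g], rules)$feasible, logical(1)))
    if (ok) best <- min(best, length(p))
  }
  best
}

## independent validator of the published degeneracy rules for an oligo
oracle_rules_ok <- function(seq, rules) {
  chars <- strsplit(seq, "")[[1]]
  deg <- nchar(.ora_codes[chars]) > 1
  n <- nchar(seq)
  tm <- range(vapply(oracle_expand(seq), function(e) {
    gc <- sum(strsplit(e, "")[[1]] %in% c("G", "C"))
    if (n < 14) 2 * (n - gc) + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
  }, numeric(1)))
  gc_max <- max(vapply(oracle_expand(seq), function(e)
    mean(strsplit(e, "")[[1]] %in% c("G", "C")), numeric(1)))
  n >= rules$primer_len_min && n <= rules$primer_len_max &&
    sum(deg) <= rules$max_degenerate &&
    !any(deg[-1] & deg[-n]) &&
    tm[1] >= rules$tm_min && tm[2] <= rules$tm_max &&
    gc_max < rules$gc_max
}

## random concrete / degenerate sequences
rand_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
rand_iupac <- function(len, p_degenerate = 0.2) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  k <- which(runif(len) < p_degenerate)
  chars[k] <- sample(c("R", "Y", "S", "W", "K", "M", "N"), length(k),
                     replace = TRUE)
  paste(chars, collapse = "")
}

## random additive distance matrix from a random tree (patristic
## distances on a tree are additive by construction)
rand_additive <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) runif(k, 0.05, 1))
  list(tree = ape::unroot(tr), d = ape::cophenetic.phylo(tr))
}
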