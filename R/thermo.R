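#' GC fraction of a concrete sequence
#'
#' @param seq concrete {A,C,G,T} string.
#' @return (G+C)/length.
#' @export
gc_fraction <- function(seq) {
  seq <- normalize_seq(seq)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  chars <- .seq_chars(seq)
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("gc_fraction expects a concrete sequence", call. = FALSE)
  mean(chars %in% c("G", "C"))
}

## min / max number of G+C bases over all expansions of a degenerate oligo.
## A position can be GC iff its code contains G or C; it must be GC iff the
## code contains neither A nor T.
gc_count_range <- function(seq) {
  m <- seq_to_mask(normalize_seq(seq))
  can_gc <- bitwAnd(m, 6L) > 0L            # G=4 | C=2
  must_gc <- bitwAnd(m, 9L) == 0L          # no A=1, no T=8
  c(min = sum(must_gc), max = sum(can_gc))
}

#' GC-fraction extremes over the expansions of a degenerate oligo
#' @param seq IUPAC string.
#' @return named vector `c(min=, max=)` of GC fractions.
#' @export
gc_extremes <- function(seq) {
  r <- gc_count_range(seq)
  r / nchar(normalize_seq(seq))
}

tm_from_composition <- function(len, gc, method) {
  switch(method,
         wallace    = 2 * (len - gc) + 4 * gc,
         basic_long = 64.9 + 41 * (gc - 16.4) / len,
         stop("unknown Tm method: ", method, call. = FALSE))
}

#' Melting temperature of a concrete oligo
#'
#' Composition-based estimates in the style of OligoCalc's "basic" mode:
#' the Wallace rule `2(A+T) + 4(G+C)` for short oligos (< 14 bases) and
#' `64.9 + 41 (GC - 16.4) / length` for longer ones.  `method = "auto"`
#' (the default) selects by length.
#'
#' @param seq concrete {A,C,G,T} string of length >= 8.
#' @param method `"auto"`, `"wallace"` or `"basic_long"`.
#' @return temperature in degrees C.
#' @examples
#' melting_temperature("ACGTACGTACGT")  # Wallace: 36
#' @export
melting_temperature <- function(seq, method = c("auto", "wallace",
                                                "basic_long")) {
  method <- match.arg(method)
  seq <- normalize_seq(seq)
  len <- nchar(seq)
  if (len < 8L) stop("sequence shorter than 8 bases: Tm unreliable",
                     call. = FALSE)
  chars <- .seq_chars(seq)
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("melting_temperature expects a concrete sequence; use tm_extremes",
         call. = FALSE)
  if (method == "auto") method <- if (len < 14L) "wallace" else "basic_long"
  tm_from_composition(len, sum(chars %in% c("G", "C")), method)
}

#' Tm extremes over the expansions of a degenerate oligo
#'
#' Both composition formulas are monotone increasing in the G+C count at
#' fixed length, so the extremes follow from the per-position GC bounds
#' without enumerating expansions.
#'
#' @param seq IUPAC string of length >= 8.
#' @param method as in [melting_temperature()].
#' @return named vector `c(min=, max=)` in degrees C.
#' @export
tm_extremes <- function(seq, method = c("auto", "wallace", "basic_long")) {
  method <- match.arg(method)
  seq <- normalize_seq(seq)
  len <- nchar(seq)
  if (len < 8L) stop("sequence shorter than 8 bases: Tm unreliable",
                     call. = FALSE)
  if (method == "auto") method <- if (len < 14L) "wallace" else "basic_long"
  r <- gc_count_range(seq)
  c(min = tm_from_composition(len, r[["min"]], method),
    max = tm_from_composition(len, r[["max"]], method))
}

#' Longest homopolymer run, worst case over expansions
#'
#' For a degenerate oligo this is the longest run achievable by any single
#' expansion: the maximum over the four bases of the longest run of
#' positions whose code contains that base.
#'
#' @param seq IUPAC string.
#' @return run length in bases (0 for the empty string).
#' @export
longest_homopolymer <- function(seq) {
  m <- seq_to_mask(normalize_seq(seq))
  if (length(m) == 0L) return(0L)
  best <- 0L
  for (bit in c(1L, 2L, 4L, 8L)) {
    has <- bitwAnd(m, bit) > 0L
    r <- rle(has)
    runs <- r$lengths[r$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  as.integer(best)
}

## TRUE where some expansion of code a can Watson-Crick pair with some
## expansion of code b (vectorized over b).
.can_pair <- function(mask_a, mask_b) bitwAnd(mask_a, .comp_mask(mask_b)) > 0L

#' Find hairpin-forming sites in an oligo
#'
#' Reports every placement `(stem_start, stem_len, loop_len)` where the
#' stem at `stem_start` can pair antiparallel with a downstream stem
#' separated by a loop: position `stem_start + k` pairs with the base
#' `loop_len + 2*(stem_len - k) - 1` bases downstream, for all `k`.
#' For degenerate oligos a pairing counts when some expansion achieves it
#' (worst case over the pool).
#'
#' @param seq IUPAC string.
#' @param stem_min minimal stem length (>= 3).
#' @param loop_min minimal loop length.
#' @return data.frame with columns `stem_start`, `stem_len`, `loop_len`
#'   (1-based; zero rows when none).
#' @export
find_hairpins <- function(seq, stem_min = 4L, loop_min = 3L) {
  if (stem_min < 3L) stop("stem_min must be >= 3", call. = FALSE)
  if (loop_min < 0L) stop("loop_min must be >= 0", call. = FALSE)
  m <- seq_to_mask(normalize_seq(seq))
  n <- length(m)
  out <- list()
  if (n >= 2L * stem_min + loop_min) {
    for (i in seq_len(n - 2L * stem_min - loop_min + 1L)) {
      for (loop in loop_min:(n - i + 1L - 2L * stem_min)) {
        max_len <- (n - i + 1L - loop) %/% 2L
        if (max_len < stem_min) next
        for (len in stem_min:max_len) {
          ## stem2 occupies [i+len+loop, i+2*len+loop-1]
          k <- 0:(len - 1L)
          u <- i + k
          v <- i + 2L * len + loop - 1L - k
          if (v[length(v)] > n) next
          if (all(.can_pair(m[u], m[v])))
            out[[length(out) + 1L]] <- c(i, len, loop)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(stem_start = integer(0), stem_len = integer(0),
                      loop_len = integer(0)))
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("stem_start", "stem_len", "loop_len")
  df
}

#' Longest complementary runs between two oligos
#'
#' Slides `a` against the reverse of `b` over all ungapped offsets
#' (antiparallel annealing) and records the longest contiguous
#' Watson-Crick complementary run, plus the longest run that covers the
#' 3'-terminal base of `a`.  `dimer_runs(a, a)` screens self-dimers; the
#' two molecules are independent draws from the pool, so degenerate
#' positions may pair when any pair of expansions can.
#'
#' @param a,b IUPAC strings.
#' @return list with `max_run` and `max_3prime_run` (bases).
#' @export
dimer_runs <- function(a, b) {
  ma <- seq_to_mask(normalize_seq(a))
  mb <- seq_to_mask(normalize_seq(b))
  la <- length(ma); lb <- length(mb)
  max_run <- 0L; max_3p <- 0L
  for (s in 2L:(la + lb)) {
    i <- max(1L, s - lb):min(la, s - 1L)
    j <- s - i
    comp <- .can_pair(ma[i], mb[j])
    r <- rle(comp)
    ends <- cumsum(r$lengths)
    runs <- r$lengths[r$values]
    if (length(runs)) max_run <- max(max_run, max(runs))
    ## run covering the 3' terminal base of a (i == la, the last element)
    if (i[length(i)] == la && r$values[length(r$values)])
      max_3p <- max(max_3p, r$lengths[length(r$lengths)])
  }
  list(max_run = as.integer(max_run), max_3prime_run = as.integer(max_3p))
}

#' Thermodynamic and structural QC of one primer
#'
#' Applies the binding-region guidelines to a (possibly degenerate) oligo:
#' length 17-22, Tm within \[50, 65\] degrees C at the extremes over all
#' expansions, worst-case GC fraction below 50 %, no homopolymer run
#' longer than allowed, no hairpin with stem >= `hairpin_stem_min` and
#' loop >= `hairpin_loop_min`, and no 3'-anchored self-complementary run
#' of `dimer_run_max` bases or more.
#'
#' @param seq IUPAC oligo sequence (5' to 3').
#' @param rules [design_rules()] record.
#' @return object of class `dgm_qc`: a list with the measured statistics,
#'   one logical `pass_*` flag per guideline and an overall `verdict`.
#'   Failures are reported, never thrown.
#' @export
qc_primer <- function(seq, rules = design_rules()) {
  seq <- normalize_seq(seq)
  len <- nchar(seq)
  gc <- gc_extremes(seq)
  tm <- if (len >= 8L) tm_extremes(seq) else c(min = NA_real_, max = NA_real_)
  homo <- longest_homopolymer(seq)
  hp <- find_hairpins(seq, rules$hairpin_stem_min, rules$hairpin_loop_min)
  dim_self <- dimer_runs(seq, seq)
  rep <- list(
    seq = seq,
    length = len,
    n_degenerate = count_degenerate_positions(seq),
    degeneracy = degeneracy(seq),
    tm_min = unname(tm["min"]), tm_max = unname(tm["max"]),
    gc_min = unname(gc["min"]), gc_max = unname(gc["max"]),
    longest_homopolymer = homo,
    hairpins = hp,
    max_self_dimer_run = dim_self$max_run,
    max_3prime_dimer_run = dim_self$max_3prime_run,
    pass_length = len >= rules$primer_len_min & len <= rules$primer_len_max,
    pass_tm = !is.na(tm["min"]) && tm[["min"]] >= rules$tm_min &&
      tm[["max"]] <= rules$tm_max,
    pass_gc = gc[["max"]] < rules$gc_max,
    pass_polyN = homo <= rules$polyN_max_run,
    pass_hairpin = nrow(hp) == 0L,
    pass_dimer = dim_self$max_3prime_run < rules$dimer_run_max
  )
  rep$verdict <- with(rep, pass_length && pass_tm && pass_gc && pass_polyN &&
                        pass_hairpin && pass_dimer)
  structure(rep, class = "dgm_qc")
}

#' @export
print.dgm_qc <- function(x, ...) {
  cat(sprintf("QC report for %s (%d nt, %d degenerate, degeneracy %d)\n",
              x$seq, x$length, x$n_degenerate, x$degeneracy))
  cat(sprintf("  Tm [%.2f, %.2f] C   GC [%.3f, %.3f]\n",
              x$tm_min, x$tm_max, x$gc_min, x$gc_max))
  cat(sprintf("  homopolymer %d, hairpins %d, self-dimer %d (3' %d)\n",
              x$longest_homopolymer, nrow(x$hairpins),
              x$max_self_dimer_run, x$max_3prime_dimer_run))
  flags <- unlist(x[grep("^pass_", names(x))])
  cat("  flags:", paste(names(flags)[!flags], collapse = " "),
      if (all(flags)) "(all pass)" else "", "\n")
  cat("  verdict:", if (x$verdict) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' QC a set of primers into a table
#'
#' @param seqs named character vector of IUPAC oligos.
#' @param rules [design_rules()] record.
#' @return data.frame, one row per primer, one column per statistic/flag
#'   (hairpins summarized as a count).  Suitable for TSV export.
#' @export
qc_table <- function(seqs, rules = design_rules()) {
  if (is.null(names(seqs))) names(seqs) <- paste0("primer", seq_along(seqs))
  rows <- lapply(names(seqs), function(nm) {
    q <- qc_primer(seqs[[nm]], rules)
    data.frame(name = nm, seq = q$seq, length = q$length,
               n_degenerate = q$n_degenerate, degeneracy = q$degeneracy,
               tm_min = q$tm_min, tm_max = q$tm_max,
               gc_min = q$gc_min, gc_max = q$gc_max,
               longest_homopolymer = q$longest_homopolymer,
               n_hairpins = nrow(q$hairpins),
               max_self_dimer_run = q$max_self_dimer_run,
               max_3prime_dimer_run = q$max_3prime_dimer_run,
               pass_length = q$pass_length, pass_tm = q$pass_tm,
               pass_gc = q$pass_gc, pass_polyN = q$pass_polyN,
               pass_hairpin = q$pass_hairpin, pass_dimer = q$pass_dimer,
               verdict = q$verdict)
  })
  do.call(rbind, rows)
}
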