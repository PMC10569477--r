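#' Extract a gap-free window from an alignment
#'
#' @param aln `dgm_alignment`.
#' @param start,end 1-based inclusive alignment columns.
#' @param orientation `"fw"` (plus strand) or `"rv"` (rows are
#'   reverse-complemented so they read in the orientation of the oligo).
#' @return named character vector of window sequences, one per row.
#' @export
extract_window <- function(aln, start, end, orientation = c("fw", "rv")) {
  orientation <- match.arg(orientation)
  stopifnot(start >= 1L, end <= aln$n_columns, start <= end)
  rows <- substr(aln$seqs, start, end)
  if (any(grepl("-", rows, fixed = TRUE))) {
    bad <- aln$ids[grepl("-", rows, fixed = TRUE)]
    stop("window ", start, "..", end, " contains gaps in: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (orientation == "rv")
    rows <- vapply(rows, reverse_complement, character(1), USE.NAMES = FALSE)
  setNames(rows, aln$ids)
}

## rows -> integer mask matrix (n x L); ambiguity codes in targets widen
## the observed set at that column.
.row_masks <- function(rows) {
  do.call(rbind, lapply(rows, seq_to_mask))
}

## consensus IUPAC string from a combined column mask vector
.mask_consensus <- function(colmask) {
  paste(MASK_TO_CODE[colmask], collapse = "")
}

## popcounts of the mask values 0..15 (indexed as mask + 1)
.popcount4 <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L, 1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)

## degenerate-rule check on a column mask vector:
## at most max_deg positions with >1 base, none adjacent
.mask_rule_check <- function(colmask, max_deg) {
  deg <- .popcount4[colmask + 1L] > 1L
  nd <- sum(deg)
  if (nd > max_deg) return(list(ok = FALSE, reason = "too many degeneracies",
                                n_deg = nd))
  if (nd > 1L && any(deg[-1L] & deg[-length(deg)]))
    return(list(ok = FALSE, reason = "consecutive degeneracies", n_deg = nd))
  list(ok = TRUE, reason = NA_character_, n_deg = nd)
}

#' Minimal degenerate variant covering a group of target windows
#'
#' The minimal IUPAC consensus of the rows, accepted when it carries at
#' most `max_degenerate` degenerate positions and no two of them are
#' adjacent.
#'
#' @param rows character vector of equal-length, gap-free window
#'   sequences.
#' @param rules [design_rules()] record.
#' @return list with `feasible` (logical), `seq` (the consensus, also
#'   when infeasible), `n_degenerate`, and `reason` naming the violated
#'   rule when infeasible.
#' @export
minimal_variant_for_group <- function(rows, rules = design_rules()) {
  if (length(rows) == 0L) stop("empty group", call. = FALSE)
  rows <- vapply(rows, normalize_seq, character(1))
  if (length(unique(nchar(rows))) != 1L)
    stop("rows of unequal length", call. = FALSE)
  M <- .row_masks(rows)
  colmask <- Reduce(bitwOr, asplit(M, 1))
  chk <- .mask_rule_check(colmask, rules$max_degenerate)
  list(feasible = chk$ok, seq = .mask_consensus(colmask),
       n_degenerate = chk$n_deg, reason = chk$reason)
}

#' Does a degenerate primer cover a target window?
#'
#' Coverage means an exact full-length match of some expansion: every
#' target base (or every base an ambiguous target position may be) lies
#' within the primer's code at that position.
#'
#' @param primer IUPAC primer sequence.
#' @param rows character vector of target windows (same length as the
#'   primer).
#' @return logical vector.
#' @export
variant_covers <- function(primer, rows) {
  pm <- seq_to_mask(normalize_seq(primer))
  vapply(rows, function(r) {
    rm <- seq_to_mask(normalize_seq(r))
    length(rm) == length(pm) && all(bitwAnd(pm, rm) == rm)
  }, logical(1), USE.NAMES = !is.null(names(rows)))
}

#' Spread of the degenerate positions of a primer
#'
#' @param seq IUPAC primer sequence.
#' @return minimal pairwise distance between degenerate positions; `Inf`
#'   when the primer has at most one.  Larger is better (ties in variant
#'   selection favour well-spaced degeneracies).
#' @export
spacing_score <- function(seq) {
  pos <- degenerate_positions(seq)
  if (length(pos) <= 1L) return(Inf)
  min(diff(pos))
}

## ---- exact minimum partition (subset DP over unique sequences) ----

.partition_exact <- function(useqs, rules) {
  m <- length(useqs)
  M <- .row_masks(useqs)
  L <- ncol(M)
  n_masks <- bitwShiftL(1L, m)
  ## column masks per subset, built incrementally from the lowest set bit
  colmask <- matrix(0L, nrow = n_masks, ncol = L)
  feasible <- logical(n_masks)
  lowbit_member <- integer(n_masks)
  for (mask in seq_len(n_masks - 1L)) {
    low <- bitwAnd(mask, -mask)
    member <- as.integer(log2(low)) + 1L
    rest <- mask - low
    colmask[mask + 1L, ] <- bitwOr(colmask[rest + 1L, ], M[member, ])
    feasible[mask + 1L] <-
      .mask_rule_check(colmask[mask + 1L, ], rules$max_degenerate)$ok
  }
  best <- rep(Inf, n_masks); best[1L] <- 0
  choice <- integer(n_masks)
  for (mask in seq_len(n_masks - 1L)) {
    low <- bitwAnd(mask, -mask)
    ## enumerate submasks of mask that contain its lowest set bit
    sub <- mask
    while (sub > 0L) {
      if (bitwAnd(sub, low) != 0L && feasible[sub + 1L]) {
        cand <- 1 + best[bitwAnd(mask, bitwNot(sub)) + 1L]
        if (cand < best[mask + 1L]) {
          best[mask + 1L] <- cand
          choice[mask + 1L] <- sub
        }
      }
      sub <- bitwAnd(sub - 1L, mask)
    }
  }
  full <- n_masks - 1L
  groups <- list()
  mask <- full
  while (mask > 0L) {
    g <- choice[mask + 1L]
    if (g == 0L) break   # some singleton infeasible (ambiguity-heavy row)
    groups[[length(groups) + 1L]] <- which(bitwAnd(bitwShiftL(1L, 0:(m - 1L)),
                                                   g) != 0L)
    mask <- bitwAnd(mask, bitwNot(g))
  }
  uncovered <- integer(0)
  if (mask > 0L)
    uncovered <- which(bitwAnd(bitwShiftL(1L, 0:(m - 1L)), mask) != 0L)
  list(groups = groups, uncovered = uncovered)
}

## ---- greedy grow-from-seed set cover ----

.partition_greedy <- function(useqs, rules) {
  m <- length(useqs)
  M <- .row_masks(useqs)
  uncovered <- seq_len(m)
  groups <- list()
  bad <- integer(0)
  single_ok <- vapply(seq_len(m), function(i)
    .mask_rule_check(M[i, ], rules$max_degenerate)$ok, logical(1))
  bad <- which(!single_ok)
  uncovered <- setdiff(uncovered, bad)
  while (length(uncovered) > 0L) {
    grown <- lapply(uncovered, function(seed) {
      g <- seed
      gmask <- M[seed, ]
      repeat {
        cand <- setdiff(uncovered, g)
        if (length(cand) == 0L) break
        scores <- vapply(cand, function(x) {
          cm <- bitwOr(gmask, M[x, ])
          chk <- .mask_rule_check(cm, rules$max_degenerate)
          if (chk$ok) chk$n_deg else NA_integer_
        }, integer(1))
        if (all(is.na(scores))) break
        ord <- order(scores, useqs[cand], na.last = TRUE)
        pick <- cand[ord[1L]]
        if (is.na(scores[ord[1L]])) break
        g <- c(g, pick)
        gmask <- bitwOr(gmask, M[pick, ])
      }
      g
    })
    sizes <- lengths(grown)
    degs <- vapply(grown, function(g)
      .mask_rule_check(Reduce(bitwOr, asplit(M[g, , drop = FALSE], 1)),
                       rules$max_degenerate)$n_deg, integer(1))
    seqs <- vapply(grown, function(g)
      .mask_consensus(Reduce(bitwOr, asplit(M[g, , drop = FALSE], 1))),
      character(1))
    ord <- order(-sizes, degs, seqs)
    g <- sort(grown[[ord[1L]]])
    groups[[length(groups) + 1L]] <- g
    uncovered <- setdiff(uncovered, g)
  }
  list(groups = groups, uncovered = bad)
}

#' Partition a target panel into degenerate primer variants
#'
#' Splits the target windows into the fewest groups such that each group
#' admits a single degenerate oligo (at most `max_degenerate`
#' non-consecutive ambiguity codes, codes restricted to the bases actually
#' observed).  Exact subset-cover search when the number of distinct
#' window sequences is at most `exact_cutoff`; a greedy grow-from-seed
#' heuristic beyond (repeatedly emit the feasible group covering the most
#' uncovered targets; ties favour fewer degeneracies, then the
#' lexicographically smallest variant).
#'
#' @param rows named character vector of target window sequences (names =
#'   target ids).
#' @param rules [design_rules()] record.
#' @param name_prefix prefix for variant names; groups are named
#'   `<prefix>_G1`, `<prefix>_G2`, ... in order of decreasing coverage.
#' @param method `"auto"`, `"exact"` or `"greedy"`.
#' @param exact_cutoff maximum number of distinct sequences for the exact
#'   search under `method = "auto"`.
#' @return object of class `dgm_mix`: list with `name`, `variants` (each a
#'   list with `name`, `seq`, `n_degenerate`, `covered_ids`),
#'   `union_coverage` and `uncoverable` (ids whose window alone violates
#'   the degeneracy rules, e.g. ambiguity-riddled input).
#' @export
partition_targets <- function(rows, rules = design_rules(),
                              name_prefix = "Mix",
                              method = c("auto", "exact", "greedy"),
                              exact_cutoff = 12L) {
  method <- match.arg(method)
  if (length(rows) == 0L) stop("no targets", call. = FALSE)
  if (is.null(names(rows))) names(rows) <- paste0("t", seq_along(rows))
  rows <- vapply(rows, normalize_seq, character(1))
  if (length(unique(nchar(rows))) != 1L)
    stop("target windows of unequal length", call. = FALSE)
  useqs <- sort(unique(unname(rows)))
  ## sequences infeasible even alone (ambiguity-heavy input) are reported
  ## as uncoverable, not fatal
  single_ok <- vapply(useqs, function(s)
    minimal_variant_for_group(s, rules)$feasible, logical(1),
    USE.NAMES = FALSE)
  bad_seqs <- useqs[!single_ok]
  useqs <- useqs[single_ok]
  if (length(useqs) == 0L)
    stop("no coverable targets", call. = FALSE)
  if (method == "auto")
    method <- if (length(useqs) <= exact_cutoff) "exact" else "greedy"
  res <- switch(method,
                exact = .partition_exact(useqs, rules),
                greedy = .partition_greedy(useqs, rules))
  uncoverable <- names(rows)[rows %in% c(bad_seqs, useqs[res$uncovered])]
  if (length(uncoverable))
    warning("targets not coverable by any admissible variant: ",
            paste(uncoverable, collapse = ", "), call. = FALSE)
  variants <- lapply(res$groups, function(g) {
    mv <- minimal_variant_for_group(useqs[g], rules)
    ids <- names(rows)[variant_covers(mv$seq, rows)]
    list(seq = mv$seq, n_degenerate = mv$n_degenerate, covered_ids = ids)
  })
  ## order by decreasing coverage, then variant sequence
  ord <- order(-vapply(variants, function(v) length(v$covered_ids),
                       integer(1)),
               vapply(variants, `[[`, character(1), "seq"))
  variants <- variants[ord]
  for (k in seq_along(variants))
    variants[[k]]$name <- sprintf("%s_G%d", name_prefix, k)
  structure(list(name = name_prefix,
                 variants = variants,
                 union_coverage = sort(unique(unlist(
                   lapply(variants, `[[`, "covered_ids")))),
                 uncoverable = uncoverable,
                 method = method),
            class = "dgm_mix")
}

#' @export
print.dgm_mix <- function(x, ...) {
  cat(sprintf("Primer mix '%s': %d variants, union coverage %d targets\n",
              x$name, length(x$variants), length(x$union_coverage)))
  for (v in x$variants)
    cat(sprintf("  %-12s %s  (%d degenerate, covers %d)\n",
                v$name, v$seq, v$n_degenerate, length(v$covered_ids)))
  if (length(x$uncoverable))
    cat("  uncoverable:", paste(x$uncoverable, collapse = ", "), "\n")
  invisible(x)
}

#' Relax a variant by one additional degenerate position
#'
#' Searches every non-degenerate position that would not create adjacent
#' degeneracies and widens its code to the bases observed (at that
#' position) in targets that mismatch the variant there and nowhere else.
#' The position with the largest coverage gain wins; ties favour larger
#' [spacing_score()], then the leftmost position.  Mirrors the design of
#' "n"-suffixed alternative variants that trade one extra degeneracy for
#' broader strain coverage.
#'
#' @param variant IUPAC primer sequence (feasible, below the degeneracy
#'   limit).
#' @param rows named character vector of all target windows.
#' @param rules [design_rules()] record.
#' @param suffix appended to `name` for the relaxed variant.
#' @param name optional variant name (used to derive the relaxed name).
#' @return list with `seq`, `name`, `gain` (targets added), `position`
#'   (the widened position, NA when no gain) and `covered_ids`.  The
#'   input sequence is returned unchanged (gain 0) when no single
#'   widening adds coverage.
#' @export
relax_variant <- function(variant, rows, rules = design_rules(),
                          suffix = "n", name = NULL) {
  variant <- normalize_seq(variant)
  nd <- count_degenerate_positions(variant)
  if (nd >= rules$max_degenerate)
    stop("at degeneracy limit", call. = FALSE)
  rows <- vapply(rows, normalize_seq, character(1))
  pm <- seq_to_mask(variant)
  L <- length(pm)
  deg_pos <- degenerate_positions(variant)
  covered <- variant_covers(variant, rows)
  candidates <- setdiff(seq_len(L), deg_pos)
  candidates <- candidates[!(candidates - 1L) %in% deg_pos &
                             !(candidates + 1L) %in% deg_pos]
  best <- list(gain = 0L, position = NA_integer_, seq = variant,
               spacing = -Inf)
  for (p in candidates) {
    gains <- vapply(rows[!covered], function(r) {
      rm <- seq_to_mask(r)
      if (length(rm) != L) return(FALSE)
      ok_rest <- all(bitwAnd(pm[-p], rm[-p]) == rm[-p])
      ok_rest && bitwAnd(pm[p], rm[p]) != rm[p]
    }, logical(1))
    if (!any(gains)) next
    extra <- Reduce(bitwOr, lapply(rows[!covered][gains],
                                   function(r) seq_to_mask(r)[p]))
    new_mask <- pm
    new_mask[p] <- bitwOr(pm[p], extra)
    cand_seq <- .mask_consensus(new_mask)
    sp <- spacing_score(cand_seq)
    g <- sum(gains)
    if (g > best$gain ||
        (g == best$gain && g > 0L && sp > best$spacing)) {
      best <- list(gain = g, position = p, seq = cand_seq, spacing = sp)
    }
  }
  out_name <- if (is.null(name)) NULL else
    if (best$gain > 0L) paste0(name, suffix) else name
  list(seq = best$seq, name = out_name, gain = best$gain,
       position = best$position,
       covered_ids = names(rows)[variant_covers(best$seq, rows)])
}

#' Design forward and reverse primer mixes for a region pair
#'
#' Runs [partition_targets()] on the forward and reverse windows of an
#' alignment and, optionally, relaxes each forward variant by one
#' degeneracy where that widens coverage, mirroring the two mixes tested
#' in practice: mix A holds the minimal-degeneracy variants, mix B the
#' relaxed alternatives (falling back to the mix A variant where no
#' relaxation gains coverage).
#'
#' @param aln `dgm_alignment` of the target panel.
#' @param fw_region,rv_region length-2 integer vectors `c(start, end)` in
#'   alignment columns.
#' @param rules [design_rules()] record.
#' @param relax logical; also build the relaxed mix B.
#' @param fw_prefix,rv_prefix variant name prefixes.
#' @return list with elements `fw_mixA`, `fw_mixB` (if `relax`) and `rv`
#'   (each a `dgm_mix`).
#' @export
design_primer_mixes <- function(aln, fw_region, rv_region,
                                rules = design_rules(), relax = TRUE,
                                fw_prefix = "Fw1", rv_prefix = "Rv1") {
  fw_rows <- extract_window(aln, fw_region[1], fw_region[2], "fw")
  rv_rows <- extract_window(aln, rv_region[1], rv_region[2], "rv")
  fw_mixA <- partition_targets(fw_rows, rules, name_prefix = fw_prefix)
  rv_mix <- partition_targets(rv_rows, rules, name_prefix = rv_prefix)
  out <- list(fw_mixA = fw_mixA, rv = rv_mix)
  if (relax) {
    variants <- lapply(fw_mixA$variants, function(v) {
      if (v$n_degenerate >= rules$max_degenerate) return(v)
      r <- relax_variant(v$seq, fw_rows, rules, name = v$name)
      if (r$gain > 0L)
        list(seq = r$seq, n_degenerate = count_degenerate_positions(r$seq),
             covered_ids = r$covered_ids, name = r$name)
      else v
    })
    out$fw_mixB <- structure(
      list(name = paste0(fw_prefix, "_mixB"), variants = variants,
           union_coverage = sort(unique(unlist(
             lapply(variants, `[[`, "covered_ids")))),
           uncoverable = fw_mixA$uncoverable, method = fw_mixA$method),
      class = "dgm_mix")
  }
  out
}

#' Export a primer mix as a two-column synthesis table or FASTA
#'
#' @param mix `dgm_mix` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mix_tsv <- function(mix, path) {
  df <- data.frame(name = vapply(mix$variants, `[[`, character(1), "name"),
                   sequence = vapply(mix$variants, `[[`, character(1), "seq"))
  write_tsv(df, path)
}

#' @rdname write_mix_tsv
#' @export
write_mix_fasta <- function(mix, path) {
  df <- data.frame(id = vapply(mix$variants, `[[`, character(1), "name"),
                   seq = vapply(mix$variants, `[[`, character(1), "seq"))
  write_fasta(df, path)
}
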