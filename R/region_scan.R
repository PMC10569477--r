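#' Per-column conservation of an alignment
#'
#' For every column, the most frequent non-gap base (ties broken
#' alphabetically, A < C < G < T), its fraction among all rows, and
#' whether any row carries a gap.
#'
#' @param aln `dgm_alignment`.
#' @return data.frame with columns `column`, `majority_base`,
#'   `majority_fraction`, `has_gap` (one row per alignment column,
#'   1-based).
#' @export
column_conservation <- function(aln) {
  stopifnot(inherits(aln, "dgm_alignment"), length(aln$ids) > 0L)
  m <- aln_matrix(aln)
  n <- nrow(m)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, bases))
  top <- max.col(counts, ties.method = "first")   # alphabetical tie-break
  maj <- bases[top]
  frac <- counts[cbind(seq_len(ncol(m)), top)] / n
  all_gap <- rowSums(counts) == 0
  maj[all_gap] <- NA_character_
  data.frame(column = seq_len(ncol(m)),
             majority_base = maj,
             majority_fraction = frac,
             has_gap = colSums(m == "-") > 0)
}

#' Scan an alignment for candidate primer-binding windows
#'
#' Enumerates every gap-free window of allowed length whose mean
#' per-column majority fraction reaches the conservation threshold and
#' whose majority-base consensus passes [qc_primer()].  For reverse
#' windows the consensus is reverse-complemented before QC, since the
#' synthesized oligo is the minus-strand primer.
#'
#' @param aln `dgm_alignment`, at least `primer_len_min` columns wide.
#' @param rules [design_rules()] record.
#' @param orientation `"fw"` or `"rv"`.
#' @return data.frame of candidate regions sorted by `mean_conservation`
#'   (descending) then `start`: columns `start`, `end`, `length`,
#'   `orientation`, `consensus` (the oriented primer sequence), `tm`,
#'   `gc`, `mean_conservation`.  Coordinates are 1-based inclusive
#'   alignment columns.
#' @export
scan_windows <- function(aln, rules = design_rules(),
                         orientation = c("fw", "rv")) {
  orientation <- match.arg(orientation)
  if (aln$n_columns < rules$primer_len_min)
    stop("alignment narrower than primer_len_min", call. = FALSE)
  cons <- column_conservation(aln)
  frac <- cons$majority_fraction
  gap <- cons$has_gap
  maj <- cons$majority_base
  out <- list()
  for (len in rules$primer_len_min:rules$primer_len_max) {
    if (len > aln$n_columns) break
    for (start in seq_len(aln$n_columns - len + 1L)) {
      idx <- start:(start + len - 1L)
      if (any(gap[idx]) || anyNA(maj[idx])) next
      mc <- mean(frac[idx])
      if (mc < rules$conservation_threshold) next
      consensus <- paste(maj[idx], collapse = "")
      oligo <- if (orientation == "rv") reverse_complement(consensus)
               else consensus
      q <- qc_primer(oligo, rules)
      if (!q$verdict) next
      out[[length(out) + 1L]] <-
        data.frame(start = start, end = start + len - 1L, length = len,
                   orientation = orientation, consensus = oligo,
                   tm = (q$tm_min + q$tm_max) / 2, gc = q$gc_max,
                   mean_conservation = mc)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), orientation = character(0),
                      consensus = character(0), tm = numeric(0),
                      gc = numeric(0), mean_conservation = numeric(0)))
  df <- do.call(rbind, out)
  df <- df[order(-df$mean_conservation, df$start, df$end), ]
  rownames(df) <- NULL
  df
}

#' Pair forward and reverse candidate windows
#'
#' Admissible pairs have the forward window strictly upstream of the
#' reverse window, a product span of at least `min_product` alignment
#' columns, and consensus Tm values within `pair_tm_delta_max` of each
#' other.  Pairs are ranked by product span, largest first (the design
#' favours the longest amplifiable fragment).
#'
#' @param fw,rv candidate tables from [scan_windows()].
#' @param rules [design_rules()] record.
#' @param min_product minimal product span in alignment columns.
#' @return data.frame of pairs ranked by `product_span` descending, with
#'   columns `fw_start`, `fw_end`, `rv_start`, `rv_end`, `fw_consensus`,
#'   `rv_consensus`, `product_span`, `tm_delta`.  An attribute
#'   `"rejections"` counts rejected pairs per reason.
#' @export
pair_regions <- function(fw, rv, rules = design_rules(), min_product = 400L) {
  if (nrow(fw) == 0L || nrow(rv) == 0L)
    stop("empty candidate list", call. = FALSE)
  rej <- c(order = 0L, product = 0L, tm = 0L)
  out <- list()
  for (i in seq_len(nrow(fw))) {
    for (j in seq_len(nrow(rv))) {
      if (!(fw$end[i] < rv$start[j])) { rej["order"] <- rej["order"] + 1L; next }
      span <- rv$end[j] - fw$start[i] + 1L
      if (span < min_product) { rej["product"] <- rej["product"] + 1L; next }
      delta <- abs(fw$tm[i] - rv$tm[j])
      if (delta > rules$pair_tm_delta_max) { rej["tm"] <- rej["tm"] + 1L; next }
      out[[length(out) + 1L]] <-
        data.frame(fw_start = fw$start[i], fw_end = fw$end[i],
                   rv_start = rv$start[j], rv_end = rv$end[j],
                   fw_consensus = fw$consensus[i],
                   rv_consensus = rv$consensus[j],
                   product_span = span, tm_delta = delta)
    }
  }
  if (length(out) == 0L) {
    message("no admissible pair; rejections: ",
            paste(names(rej), rej, sep = "=", collapse = ", "))
    res <- data.frame(fw_start = integer(0), fw_end = integer(0),
                      rv_start = integer(0), rv_end = integer(0),
                      fw_consensus = character(0), rv_consensus = character(0),
                      product_span = integer(0), tm_delta = numeric(0))
  } else {
    res <- do.call(rbind, out)
    res <- res[order(-res$product_span, res$fw_start, res$rv_start), ]
    rownames(res) <- NULL
  }
  attr(res, "rejections") <- rej
  res
}
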