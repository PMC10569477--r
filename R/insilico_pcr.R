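## mismatch counts of a primer mask vector at every offset of a template
## mask vector; returns integer vector of length T - L + 1 (empty when the
## primer is longer than the template)
.mismatch_profile <- function(pm, tmask) {
  L <- length(pm); Tn <- length(tmask)
  if (L > Tn) return(integer(0))
  n_off <- Tn - L + 1L
  mism <- integer(n_off)
  for (j in seq_len(L)) {
    ok <- bitwAnd(pm[j], tmask[j:(j + n_off - 1L)]) > 0L
    mism <- mism + !ok
  }
  mism
}

## same, restricted to a subset of primer positions (for 3'-exact checks)
.mismatch_profile_at <- function(pm, tmask, positions) {
  L <- length(pm); Tn <- length(tmask)
  n_off <- Tn - L + 1L
  mism <- integer(n_off)
  for (j in positions) {
    ok <- bitwAnd(pm[j], tmask[j:(j + n_off - 1L)]) > 0L
    mism <- mism + !ok
  }
  mism
}

#' Locate binding sites of a degenerate primer on a template
#'
#' Finds every placement, on either strand, where the template is
#' compatible with some expansion of the primer at no more than
#' `max_mismatch` mismatches, with the 3'-terminal `three_prime_exact`
#' bases mismatch-free.  The default policy is strict: zero mismatches,
#' full length, `N` in the template matches nothing.
#'
#' @param primer IUPAC primer sequence (5' to 3').
#' @param template concrete template sequence (A/C/G/T/N), or a
#'   single-row data.frame with `id` and `seq`.
#' @param max_mismatch maximum mismatches allowed.
#' @param three_prime_exact number of 3'-terminal primer bases that must
#'   match exactly.
#' @param n_policy `"strict"` (template `N` matches nothing) or `"any"`.
#' @param primer_name,template_id labels carried into the hit table.
#' @return data.frame of hits: `template_id`, `strand` (`+`/`-`),
#'   `start`, `end` (1-based inclusive template coordinates of the primer
#'   footprint), `primer`, `mismatches`.
#' @export
match_primer <- function(primer, template, max_mismatch = 0L,
                         three_prime_exact = 0L,
                         n_policy = c("strict", "any"),
                         primer_name = "primer", template_id = "template") {
  n_policy <- match.arg(n_policy)
  if (is.data.frame(template)) {
    template_id <- template$id[1]
    template <- template$seq[1]
  }
  primer <- normalize_seq(primer)
  template <- normalize_seq(template)
  pm_fw <- seq_to_mask(primer)
  pm_rv <- seq_to_mask(reverse_complement(primer))
  tmask <- seq_to_mask(template, n_matches_nothing = n_policy == "strict")
  L <- length(pm_fw)
  hits <- list()
  scan_strand <- function(pm, strand) {
    mism <- .mismatch_profile(pm, tmask)
    if (length(mism) == 0L) return(NULL)
    ok <- mism <= max_mismatch
    if (three_prime_exact > 0L) {
      ## the primer's 3' end maps to the last positions of pm on '+' and
      ## to the first positions of the reverse-complemented pattern on '-'
      pos3 <- if (strand == "+") (L - three_prime_exact + 1L):L
              else seq_len(three_prime_exact)
      ok <- ok & .mismatch_profile_at(pm, tmask, pos3) == 0L
    }
    w <- which(ok)
    if (length(w) == 0L) return(NULL)
    data.frame(template_id = template_id, strand = strand,
               start = w, end = w + L - 1L,
               primer = primer_name, mismatches = mism[w])
  }
  res <- rbind(scan_strand(pm_fw, "+"), scan_strand(pm_rv, "-"))
  if (is.null(res))
    res <- data.frame(template_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      primer = character(0), mismatches = integer(0))
  res[order(res$start, res$strand), , drop = FALSE]
}

.mix_variants <- function(mix) {
  if (inherits(mix, "dgm_mix")) {
    setNames(vapply(mix$variants, `[[`, character(1), "seq"),
             vapply(mix$variants, `[[`, character(1), "name"))
  } else if (is.character(mix)) {
    if (is.null(names(mix))) names(mix) <- paste0("v", seq_along(mix))
    mix
  } else stop("mix must be a dgm_mix or a named character vector",
              call. = FALSE)
}

#' Predict PCR products of a forward/reverse primer mix pair
#'
#' Pairs every plus-strand hit of a forward-mix variant with every
#' minus-strand hit of a reverse-mix variant downstream of it, keeping
#' products whose length falls in `[size_min, size_max]`.  Placements
#' producing the same product are collapsed, keeping the
#' fewest-mismatch variant pair.
#'
#' @param fw_mix,rv_mix `dgm_mix` objects or named character vectors of
#'   IUPAC oligos.
#' @param template concrete template sequence or single-row data.frame
#'   with `id` and `seq`.
#' @param size_min,size_max allowed product length (bases, primers
#'   included).
#' @param max_mismatch,three_prime_exact,n_policy matching policy, as in
#'   [match_primer()].
#' @param template_id label for the template.
#' @return data.frame of amplicons: `template_id`, `fw_variant`,
#'   `rv_variant`, `product_start`, `product_end`, `product_length`,
#'   `fw_mismatches`, `rv_mismatches`, `sequence`.
#' @export
predict_amplicons <- function(fw_mix, rv_mix, template,
                              size_min = 100L, size_max = 3000L,
                              max_mismatch = 0L, three_prime_exact = 0L,
                              n_policy = c("strict", "any"),
                              template_id = "template") {
  n_policy <- match.arg(n_policy)
  if (is.data.frame(template)) {
    template_id <- template$id[1]
    template <- template$seq[1]
  }
  template <- normalize_seq(template)
  fw <- .mix_variants(fw_mix)
  rv <- .mix_variants(rv_mix)
  fw_hits <- do.call(rbind, lapply(names(fw), function(nm) {
    h <- match_primer(fw[[nm]], template, max_mismatch, three_prime_exact,
                      n_policy, primer_name = nm, template_id = template_id)
    h[h$strand == "+", , drop = FALSE]
  }))
  rv_hits <- do.call(rbind, lapply(names(rv), function(nm) {
    h <- match_primer(rv[[nm]], template, max_mismatch, three_prime_exact,
                      n_policy, primer_name = nm, template_id = template_id)
    h[h$strand == "-", , drop = FALSE]
  }))
  empty <- data.frame(template_id = character(0), fw_variant = character(0),
                      rv_variant = character(0), product_start = integer(0),
                      product_end = integer(0), product_length = integer(0),
                      fw_mismatches = integer(0), rv_mismatches = integer(0),
                      sequence = character(0))
  if (is.null(fw_hits) || is.null(rv_hits) ||
      nrow(fw_hits) == 0L || nrow(rv_hits) == 0L) return(empty)
  out <- list()
  for (i in seq_len(nrow(fw_hits))) {
    for (j in seq_len(nrow(rv_hits))) {
      if (!(fw_hits$start[i] < rv_hits$start[j])) next
      len <- rv_hits$end[j] - fw_hits$start[i] + 1L
      if (len < size_min || len > size_max) next
      out[[length(out) + 1L]] <-
        data.frame(template_id = template_id,
                   fw_variant = fw_hits$primer[i],
                   rv_variant = rv_hits$primer[j],
                   product_start = fw_hits$start[i],
                   product_end = rv_hits$end[j],
                   product_length = len,
                   fw_mismatches = fw_hits$mismatches[i],
                   rv_mismatches = rv_hits$mismatches[j],
                   sequence = substr(template, fw_hits$start[i],
                                     rv_hits$end[j]))
    }
  }
  if (length(out) == 0L) return(empty)
  df <- do.call(rbind, out)
  ## collapse duplicate products, keeping the fewest-mismatch pair
  df <- df[order(df$product_start, df$product_end,
                 df$fw_mismatches + df$rv_mismatches,
                 df$fw_variant, df$rv_variant), ]
  key <- paste(df$product_start, df$product_end)
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Strain-by-variant coverage matrix of primer mixes
#'
#' A cell is `TRUE` when the variant has at least one binding site on the
#' template under the active matching policy.  Column sums give the
#' "targets N strains" count per variant; per-mix unions summarize the
#' pooled coverage.
#'
#' @param mixes named list of `dgm_mix` objects (or named character
#'   vectors of oligos).
#' @param templates data.frame with columns `id`, `seq` (unique ids).
#' @param max_mismatch,three_prime_exact,n_policy matching policy.
#' @return object of class `dgm_coverage`: list with the logical `matrix`
#'   (rows = templates, columns = variants), `variant_counts`,
#'   `mix_unions` and `variant_mix` (the mix each column belongs to).
#' @export
coverage_matrix <- function(mixes, templates, max_mismatch = 0L,
                            three_prime_exact = 0L,
                            n_policy = c("strict", "any")) {
  n_policy <- match.arg(n_policy)
  stopifnot(is.data.frame(templates), all(c("id", "seq") %in%
                                            names(templates)))
  if (anyDuplicated(templates$id))
    stop("duplicate template ids: ",
         paste(unique(templates$id[duplicated(templates$id)]),
               collapse = ", "), call. = FALSE)
  if (!is.list(mixes) || inherits(mixes, "dgm_mix")) mixes <- list(mixes)
  if (is.null(names(mixes)))
    names(mixes) <- vapply(seq_along(mixes), function(i) {
      m <- mixes[[i]]
      if (inherits(m, "dgm_mix") && !is.null(m$name)) m$name
      else paste0("mix", i)
    }, character(1))
  var_list <- lapply(mixes, .mix_variants)
  variants <- unlist(unname(var_list))
  variant_mix <- rep(names(mixes), times = lengths(var_list))
  names(variant_mix) <- names(variants)
  mat <- matrix(FALSE, nrow = nrow(templates), ncol = length(variants),
                dimnames = list(templates$id, names(variants)))
  ## positional indexing: the same variant may sit in several mixes, so
  ## column names need not be unique
  for (r in seq_len(nrow(templates))) {
    for (k in seq_along(variants)) {
      h <- match_primer(variants[[k]], templates$seq[r], max_mismatch,
                        three_prime_exact, n_policy,
                        primer_name = names(variants)[k],
                        template_id = templates$id[r])
      mat[r, k] <- nrow(h) > 0L
    }
  }
  counts <- colSums(mat)
  unions <- vapply(names(mixes), function(mn) {
    sum(rowSums(mat[, variant_mix == mn, drop = FALSE]) > 0L)
  }, numeric(1))
  structure(list(matrix = mat,
                 variant_counts = counts,
                 mix_unions = unions,
                 variant_mix = variant_mix),
            class = "dgm_coverage")
}

#' @export
print.dgm_coverage <- function(x, ...) {
  cat(sprintf("Coverage: %d templates x %d variants\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("Per-variant counts:\n")
  print(x$variant_counts)
  cat("Per-mix union counts:\n")
  print(x$mix_unions)
  invisible(x)
}

#' Serialize a coverage matrix to TSV
#'
#' @param cov `dgm_coverage` object.
#' @param path output file; the boolean matrix is written with a leading
#'   `template_id` column and a trailing summary row of per-variant
#'   counts.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(cov, path) {
  df <- data.frame(template_id = rownames(cov$matrix),
                   cov$matrix, check.names = FALSE)
  tot <- data.frame(template_id = "#targets",
                    t(as.integer(cov$variant_counts)), check.names = FALSE)
  names(tot) <- names(df)
  write_tsv(rbind(df, tot), path)
}
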