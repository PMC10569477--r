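## IUPAC nucleotide ambiguity codes.  Stored as a named character vector of
## expansions; bitmasks (A=1, C=2, G=4, T=8) drive all matching arithmetic.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)

IUPAC_MASK <- vapply(IUPAC_CODES, function(x) {
  sum(.base_bits[strsplit(x, "")[[1]]])
}, integer(1))

## mask -> code lookup (index = mask value 1..15)
MASK_TO_CODE <- character(15L)
MASK_TO_CODE[IUPAC_MASK] <- names(IUPAC_MASK)

## complement of each code, IUPAC-aware (A<->T, C<->G on the expansion)
.comp_mask <- function(mask) {
  ((mask %% 2L) * 8L) +            # A -> T
    ((mask %/% 2L) %% 2L) * 4L +   # C -> G
    ((mask %/% 4L) %% 2L) * 2L +   # G -> C
    ((mask %/% 8L) %% 2L) * 1L     # T -> A
}
IUPAC_COMPLEMENT <- MASK_TO_CODE[.comp_mask(IUPAC_MASK)]
names(IUPAC_COMPLEMENT) <- names(IUPAC_MASK)

#' Normalize and validate a nucleotide sequence
#'
#' Upper-cases the input, maps RNA-style `U` to `T`, and verifies that every
#' character is a valid IUPAC nucleotide code (optionally allowing the gap
#' character `-`).
#'
#' @param seq single character string.
#' @param allow_gap logical; permit `-` (alignment rows only).
#' @param what label used in error messages.
#' @return the normalized sequence (upper-case, `U` mapped to `T`).
#' @examples
#' normalize_seq("acgu")   # "ACGT"
#' @export
normalize_seq <- function(seq, allow_gap = FALSE, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  chars <- strsplit(s, "")[[1]]
  ok <- chars %in% names(IUPAC_CODES) | (allow_gap & chars == "-")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("invalid character '%s' at position %d of %s",
                 chars[bad], bad, what), call. = FALSE)
  }
  s
}

.seq_chars <- function(seq) strsplit(seq, "")[[1]]

#' Convert a sequence to IUPAC bitmasks
#'
#' Each base becomes an integer bitmask over {A=1, C=2, G=4, T=8}; the gap
#' character and (optionally) `N` map to 0 so that they match nothing.
#'
#' @param seq character string (validated first).
#' @param n_matches_nothing logical; if `TRUE`, `N` maps to 0 (strict
#'   template policy) instead of 15.
#' @return integer vector of bitmasks.
#' @export
seq_to_mask <- function(seq, n_matches_nothing = FALSE) {
  chars <- .seq_chars(seq)
  m <- unname(IUPAC_MASK[chars])
  m[is.na(m)] <- 0L                      # gaps
  if (n_matches_nothing) m[chars == "N"] <- 0L
  m
}

#' Number of concrete sequences a degenerate oligo represents
#'
#' @param seq IUPAC nucleotide string.
#' @return integer: the product of per-position code sizes.
#' @examples
#' degeneracy("ACGT")  # 1
#' degeneracy("RYN")   # 16
#' @export
degeneracy <- function(seq) {
  seq <- normalize_seq(seq)
  prod(nchar(IUPAC_CODES[.seq_chars(seq)]))
}

#' Expand a degenerate sequence into all concrete sequences
#'
#' @param seq IUPAC nucleotide string.
#' @return character vector of all `degeneracy(seq)` concrete {A,C,G,T}
#'   sequences, sorted.
#' @examples
#' expand_degenerate("RY")  # "AC" "AT" "GC" "GT"
#' @export
expand_degenerate <- function(seq) {
  seq <- normalize_seq(seq)
  sets <- strsplit(unname(IUPAC_CODES[.seq_chars(seq)]), "")
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  sort(out)
}

#' Count degenerate positions
#'
#' @param seq IUPAC nucleotide string.
#' @return number of positions whose code expands to more than one base.
#' @export
count_degenerate_positions <- function(seq) {
  seq <- normalize_seq(seq)
  sum(nchar(IUPAC_CODES[.seq_chars(seq)]) > 1L)
}

#' Positions of degenerate bases
#' @param seq IUPAC nucleotide string.
#' @return integer vector of 1-based positions carrying an ambiguity code.
#' @export
degenerate_positions <- function(seq) {
  seq <- normalize_seq(seq)
  which(nchar(IUPAC_CODES[.seq_chars(seq)]) > 1L)
}

#' IUPAC-aware reverse complement
#'
#' @param seq IUPAC nucleotide string.
#' @return the reverse complement, with ambiguity codes complemented on
#'   their expansions (e.g. `Y` -> `R`).  Involution:
#'   `reverse_complement(reverse_complement(s)) == s`.
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_seq(seq)
  paste(rev(unname(IUPAC_COMPLEMENT[.seq_chars(seq)])), collapse = "")
}

#' Minimal IUPAC code for a set of observed bases
#'
#' @param bases character vector, subset of A/C/G/T (repeats allowed).
#' @return the unique IUPAC code whose expansion equals the observed set.
#' @export
iupac_code <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0L) stop("empty base set", call. = FALSE)
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("base set must be a subset of {A,C,G,T}", call. = FALSE)
  MASK_TO_CODE[sum(.base_bits[bases])]
}

#' Minimal degenerate consensus of per-column base sets
#'
#' @param columns list of character vectors, each the set of bases observed
#'   in one alignment column (subset of A/C/G/T).
#' @return single IUPAC string: per column, the minimal code covering
#'   exactly the observed set.
#' @examples
#' consensus_degenerate(list("A", c("C", "T"), "G"))  # "AYG"
#' @export
consensus_degenerate <- function(columns) {
  if (length(columns) == 0L) stop("no columns", call. = FALSE)
  paste(vapply(columns, iupac_code, character(1)), collapse = "")
}
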