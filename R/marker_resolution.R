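#' Pairwise p-distances of aligned sequences
#'
#' Fraction of differing sites per pair; positions where either sequence
#' has a gap are excluded from that pair's denominator (pairwise
#' deletion).  `N` is compared as an ordinary character.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
pairwise_pdistance <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named", call. = FALSE)
  seqs <- vapply(seqs, function(s) normalize_seq(s, allow_gap = TRUE),
                 character(1))
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences of unequal length", call. = FALSE)
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comparable <- m[i, ] != "-" & m[j, ] != "-"
      nc <- sum(comparable)
      if (nc == 0L)
        stop("no comparable sites between '", names(seqs)[i], "' and '",
             names(seqs)[j], "'", call. = FALSE)
      d[i, j] <- d[j, i] <- sum(m[i, comparable] != m[j, comparable]) / nc
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]); consistent
#' on additive matrices, i.e. it reconstructs the generating tree exactly
#' when the distances fit one.
#'
#' @param d symmetric distance matrix with dimnames, at least 3 taxa.
#' @return unrooted `phylo` tree (ape) with the matrix ids as tip labels.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (is.null(rownames(d))) stop("distance matrix must have ids",
                                 call. = FALSE)
  ape::nj(stats::as.dist(d))
}

## non-trivial bipartitions of an unrooted tree as canonical strings:
## each internal edge splits the leaves; the split is represented by the
## sorted side that does NOT contain the alphabetically first leaf.
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  edges <- tree$edge
  ## leaves below each internal node, by postorder accumulation
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (k in rev(seq_len(nrow(edges)))) {
    p <- edges[k, 1]; c <- edges[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  splits <- character(0)
  for (k in seq_len(nrow(edges))) {
    child <- edges[k, 2]
    if (child <= n) next                      # trivial split (single leaf)
    side <- sort(desc[[child]])
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (ref %in% side) side <- sort(setdiff(tree$tip.label, side))
    splits <- c(splits, paste(side, collapse = "|"))
  }
  unique(splits)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the non-trivial bipartitions of two unrooted
#' trees over the same leaf set.
#'
#' @param a,b `phylo` trees with identical tip labels.
#' @return integer RF distance.
#' @export
rf_distance <- function(a, b) {
  la <- sort(a$tip.label); lb <- sort(b$tip.label)
  if (!identical(la, lb)) {
    stop("leaf sets differ: only in first tree {",
         paste(setdiff(la, lb), collapse = ","),
         "}; only in second {", paste(setdiff(lb, la), collapse = ","),
         "}", call. = FALSE)
  }
  sa <- tree_bipartitions(a)
  sb <- tree_bipartitions(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Distance tree from in-silico amplicons
#'
#' Convenience wrapper: cut the amplified region out of the design
#' alignment (so no re-alignment is needed), compute p-distances and
#' return the NJ tree.
#'
#' @param aln `dgm_alignment`.
#' @param region length-2 vector `c(start, end)` in alignment columns
#'   (e.g. the span between the outer primer coordinates); `NULL` uses
#'   the whole alignment.
#' @return list with `tree` (`phylo`), `distances` (matrix) and
#'   `fragment` (the named character vector of cut sequences).
#' @export
amplicon_tree <- function(aln, region = NULL) {
  seqs <- aln$seqs
  if (!is.null(region))
    seqs <- setNames(substr(seqs, region[1], region[2]), aln$ids)
  d <- pairwise_pdistance(seqs)
  list(tree = nj_tree(d), distances = d, fragment = seqs)
}

#' Write a PHYLIP-style distance matrix as TSV
#' @param d distance matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path) {
  df <- data.frame(id = rownames(d), round(d, 6), check.names = FALSE)
  write_tsv(df, path)
}
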