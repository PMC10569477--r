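#' Read a FASTA file of nucleotide sequences
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that normalizes
#' sequences (upper-case, `U` -> `T`) and validates every character against
#' the IUPAC alphabet.
#'
#' @param path FASTA file.
#' @param allow_gap logical; permit the gap character `-` (for aligned
#'   input).
#' @return a data.frame with columns `id`, `description`, `seq`.
#' @export
read_fasta <- function(path, allow_gap = FALSE) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- vapply(seq_along(set), function(i) {
    normalize_seq(as.character(set[[i]]), allow_gap = allow_gap,
                  what = paste0("record '", ids[i], "'"))
  }, character(1))
  data.frame(id = ids, description = desc, seq = seqs,
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with columns `id`, `seq` (and optionally
#'   `description`).
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  headers <- records$id
  if (!is.null(records$description)) {
    has_desc <- !is.na(records$description) & records$description != ""
    headers[has_desc] <- paste(headers[has_desc],
                               records$description[has_desc])
  }
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a multiple sequence alignment from FASTA
#'
#' @param path aligned FASTA (gap character `-`).
#' @return an object of class `dgm_alignment`: list with `ids`, `seqs`
#'   (named character vector) and `n_columns`.  All rows must have equal
#'   length; offending ids are listed otherwise.
#' @export
read_alignment <- function(path) {
  rec <- read_fasta(path, allow_gap = TRUE)
  as_alignment(setNames(rec$seq, rec$id))
}

#' Build an alignment object from named sequences
#'
#' @param seqs named character vector of equal-length (gapped) sequences.
#' @return `dgm_alignment` object.
#' @export
as_alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("alignment rows must be named", call. = FALSE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    mode_w <- as.integer(names(sort(table(widths), decreasing = TRUE))[1])
    bad <- names(seqs)[widths != mode_w]
    stop("alignment rows of unequal length: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(ids = names(seqs), seqs = seqs,
                 n_columns = unname(widths[1])),
            class = "dgm_alignment")
}

#' @export
print.dgm_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns\n",
              length(x$ids), x$n_columns))
  invisible(x)
}

## alignment as a character matrix (rows = sequences)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- aln$ids
  m
}

#' Remove gaps from an alignment row
#' @param seq gapped sequence.
#' @return ungapped sequence.
#' @export
degap <- function(seq) gsub("-", "", seq, fixed = TRUE)

#' Read a primer table
#'
#' Expected TSV columns: `name`, `sequence`, `region_start`, `region_end`,
#' `orientation` (`fw`/`rv`); extra columns (e.g. `mix`) are preserved.
#'
#' @param path TSV file.
#' @return data.frame with normalized, validated primer sequences.
#' @export
read_primer_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "sequence", "region_start", "region_end", "orientation")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("primer table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(tab$orientation %in% c("fw", "rv")))
    stop("orientation must be 'fw' or 'rv'", call. = FALSE)
  tab$sequence <- vapply(seq_len(nrow(tab)), function(i) {
    normalize_seq(tab$sequence[i], what = paste0("primer '", tab$name[i], "'"))
  }, character(1))
  tab
}

#' Write a primer table
#' @param primers data.frame as returned by [read_primer_table()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_primer_table <- function(primers, path) {
  write.table(primers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## shared TSV writer for report tables
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
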