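## ---------------------------------------------------------------------
## Synthetic heterocyte-glycolipid-synthase (hglT-like) panel
##
## A fully synthetic, deterministic 24-sequence gene family engineered to
## exhibit the coverage structure of the real primer-design study this
## package automates: a forward binding region whose minimal-degeneracy
## variant (Fw1_G1, 3 ambiguity codes) covers 6 of 24 strains and whose
## one-degeneracy relaxation (Fw1_G1n, 4 codes) covers 8; a forward mix B
## of 7 variants and a reverse mix of 5 covering the whole panel; and an
## 857 bp Fw1+Rv1 product.  Base windows use only A<->T / G<->C
## polymorphisms (IUPAC codes W and S), so every expansion of every
## variant has the same GC count and the Tm window applies uniformly.
## ---------------------------------------------------------------------

.flip_base <- function(ch) chartr("ACGT", "TGCA", ch)

## window patterns: base string + per-clade flips + per-member states at
## variable positions.  `members` is a list: one integer vector of state
## indices per member; states index into `var_states`.
.apply_window_design <- function(base, design, n_members_per_clade) {
  chars0 <- .seq_chars(base)
  out <- list()
  for (cl in names(design)) {
    d <- design[[cl]]
    chars <- chars0
    if (length(d$flips))
      chars[d$flips] <- .flip_base(chars[d$flips])
    nm <- n_members_per_clade[[cl]]
    for (m in seq_len(nm)) {
      mc <- chars
      if (length(d$var)) {
        for (vi in seq_along(d$var)) {
          pos <- d$var[vi]
          ## alternate the two letters of the W/S pair across members,
          ## using the per-clade state table
          state <- d$states[[m]][vi]
          mc[pos] <- if (state == 2L) .flip_base(chars[pos]) else chars[pos]
        }
      }
      out[[paste0(cl, "_", m)]] <- paste(mc, collapse = "")
    }
  }
  out
}

.panel_fw_base <- "TCTAACTCTTGGACGTATTCGG"   # 22 nt, 10 G+C, QC-clean
.panel_rv_base <- "TACGCTAGTATGTGTCAGAGG"    # 21 nt (plus strand), 10 G+C

.panel_fw_design <- list(
  C1 = list(flips = integer(0), var = c(4L, 9L, 15L),
            states = list(c(1L, 1L, 1L), c(2L, 2L, 2L), c(1L, 2L, 1L),
                          c(2L, 1L, 2L), c(1L, 1L, 2L), c(2L, 2L, 1L))),
  Cs = list(flips = 12L, var = 4L,
            states = list(1L, 2L)),
  C2 = list(flips = c(1L, 6L, 11L, 16L, 21L), var = c(5L, 18L),
            states = list(c(1L, 2L), c(2L, 1L), c(1L, 1L), c(2L, 2L))),
  C3 = list(flips = c(1L, 3L, 6L, 11L, 16L, 21L), var = c(8L, 20L),
            states = list(c(1L, 1L), c(2L, 2L), c(1L, 2L))),
  C4 = list(flips = c(2L, 7L, 10L, 13L, 17L), var = c(6L, 14L),
            states = list(c(1L, 1L), c(2L, 2L), c(1L, 2L))),
  C5 = list(flips = c(3L, 5L, 8L, 14L, 19L, 22L), var = 11L,
            states = list(1L, 2L)),
  C6 = list(flips = c(2L, 9L, 13L, 18L, 21L), var = 16L,
            states = list(1L, 2L)),
  C7 = list(flips = c(1L, 5L, 10L, 15L, 20L, 22L), var = 7L,
            states = list(1L, 2L))
)

## reverse-region groups pool several clades; variability is assigned by
## position within the group
.panel_rv_design <- list(
  R1 = list(clades = c("C1", "Cs"), flips = integer(0),
            var = c(5L, 10L, 17L)),
  R2 = list(clades = c("C2", "C7"), flips = c(2L, 7L, 12L, 18L, 21L),
            var = c(4L, 9L, 14L, 20L)),
  R3 = list(clades = "C3", flips = c(1L, 6L, 11L, 16L, 19L),
            var = c(3L, 13L)),
  R4 = list(clades = c("C4", "C6"), flips = c(3L, 8L, 10L, 15L, 21L),
            var = c(6L, 12L, 18L)),
  R5 = list(clades = "C5", flips = c(2L, 5L, 9L, 14L, 17L, 20L),
            var = 11L)
)

.panel_clade_sizes <- c(C1 = 6L, Cs = 2L, C2 = 4L, C3 = 3L, C4 = 3L,
                        C5 = 2L, C6 = 2L, C7 = 2L)

#' Synthetic 24-sequence marker-gene panel with designed primer mixes
#'
#' A deterministic, fully synthetic stand-in for a published panel of
#' hglT orthologs: 24 gene sequences (1050 bp, gap-free) from 8 clades,
#' with two designed primer-binding regions (forward 112..133, reverse
#' 948..968) and a primer table of 14 degenerate oligos organised into
#' three mixes.  Engineered properties (all verified in the test suite):
#'
#' * `Fw1_G1` carries 3 degenerate bases and covers exactly 6 strains;
#'   its relaxation `Fw1_G1n` carries 4 and covers 8.
#' * `Fw1_G2af` is the one-degeneracy relaxation of `Fw1_G2` (4 -> 5
#'   strains).
#' * Mix `Fw1_mixB` holds 7 variants and mix `Rv1` holds 5; each covers
#'   all 24 strains in its region.
#' * `Fw1_mixB` + `Rv1` amplify a single 857 bp product from every
#'   strain, including the reference strain
#'   `syn_Anabaena_PCC7120`.
#'
#' @param seed RNG seed for the clade-structured background outside the
#'   designed windows (the windows, primers and coverage structure do not
#'   depend on it).
#' @return list with `alignment` (`dgm_alignment`), `templates`
#'   (data.frame `id`, `seq`; the panel is gap-free so templates equal
#'   rows), `primers` (primer table data.frame with a `mix` column),
#'   `mixes` (named list of named oligo vectors), `fw_region`,
#'   `rv_region`, `clades`, and `reference` (the reference strain id).
#' @export
synthetic_hglt_panel <- function(seed = 193L) {
  sizes <- .panel_clade_sizes
  n <- sum(sizes)
  fw_region <- c(112L, 133L)
  rv_region <- c(948L, 968L)
  L <- 1050L

  fw_windows <- .apply_window_design(.panel_fw_base, .panel_fw_design,
                                     as.list(sizes))

  ## reverse windows: assign member states within each pooled group
  rv_chars0 <- .seq_chars(.panel_rv_base)
  rv_windows <- list()
  for (gr in names(.panel_rv_design)) {
    d <- .panel_rv_design[[gr]]
    chars <- rv_chars0
    if (length(d$flips)) chars[d$flips] <- .flip_base(chars[d$flips])
    members <- unlist(lapply(d$clades, function(cl)
      paste0(cl, "_", seq_len(sizes[[cl]]))))
    for (k in seq_along(members)) {
      mc <- chars
      for (vi in seq_along(d$var)) {
        pos <- d$var[vi]
        ## alternate letters so both appear in every group
        if ((k + vi) %% 2L == 0L) mc[pos] <- .flip_base(chars[pos])
      }
      rv_windows[[members[k]]] <- paste(mc, collapse = "")
    }
  }

  member_keys <- names(fw_windows)
  clades <- rep(names(sizes), times = sizes)
  ids <- sprintf("syn_strain%02d", seq_len(n))
  ids[1] <- "syn_Anabaena_PCC7120"          # reference strain, clade C1
  names(clades) <- ids

  ## clade-structured background, then overwrite the designed windows
  fam <- simulate_gene_family(family_spec(
    n_taxa = n, gene_length = L,
    conserved_blocks = list(c(500, 1, 0)),   # placeholder; overwritten below
    background_divergence = 0.24,
    clade_structure = match(clades, names(sizes)),
    seed = seed))
  mat <- aln_matrix(fam$alignment)
  rownames(mat) <- ids
  for (k in seq_len(n)) {
    mat[k, fw_region[1]:fw_region[2]] <- .seq_chars(fw_windows[[member_keys[k]]])
    mat[k, rv_region[1]:rv_region[2]] <- .seq_chars(rv_windows[[member_keys[k]]])
  }
  seqs <- setNames(apply(mat, 1, paste, collapse = ""), ids)
  aln <- as_alignment(seqs)

  ## designed primer variants: minimal consensus per clade / group
  fw_seq_of <- function(cl) {
    keys <- paste0(cl, "_", seq_len(sizes[[cl]]))
    minimal_variant_for_group(unlist(fw_windows[keys]))$seq
  }
  rv_oligo_of <- function(gr) {
    d <- .panel_rv_design[[gr]]
    members <- unlist(lapply(d$clades, function(cl)
      paste0(cl, "_", seq_len(sizes[[cl]]))))
    reverse_complement(minimal_variant_for_group(unlist(rv_windows[members]))$seq)
  }
  fw_var <- c(Fw1_G1 = fw_seq_of("C1"), Fw1_G2 = fw_seq_of("C2"),
              Fw1_G3 = fw_seq_of("C3"), Fw1_G4 = fw_seq_of("C4"),
              Fw1_G5 = fw_seq_of("C5"), Fw1_G6 = fw_seq_of("C6"),
              Fw1_G7 = fw_seq_of("C7"))
  ## relaxed alternatives: one extra degeneracy widening strain coverage
  all_fw_rows <- setNames(unlist(fw_windows), ids)
  g1n <- relax_variant(fw_var[["Fw1_G1"]], all_fw_rows)
  g2af <- relax_variant(fw_var[["Fw1_G2"]], all_fw_rows)
  fw_var <- c(fw_var, Fw1_G1n = g1n$seq, Fw1_G2af = g2af$seq)
  rv_var <- setNames(vapply(names(.panel_rv_design), rv_oligo_of,
                            character(1)),
                     paste0("Rv1_G", seq_along(.panel_rv_design)))

  mixes <- list(
    Fw1_mixA = fw_var[c("Fw1_G1", "Fw1_G2", "Fw1_G3", "Fw1_G4", "Fw1_G5",
                        "Fw1_G6", "Fw1_G7")],
    Fw1_mixB = fw_var[c("Fw1_G1n", "Fw1_G2af", "Fw1_G3", "Fw1_G4",
                        "Fw1_G5", "Fw1_G6", "Fw1_G7")],
    Rv1 = rv_var
  )

  mix_of <- vapply(names(fw_var), function(nm) {
    paste(names(mixes)[vapply(mixes, function(m) nm %in% names(m),
                              logical(1))], collapse = ";")
  }, character(1))
  primers <- data.frame(
    name = c(names(fw_var), names(rv_var)),
    sequence = c(unname(fw_var), unname(rv_var)),
    region_start = c(rep(fw_region[1], length(fw_var)),
                     rep(rv_region[1], length(rv_var))),
    region_end = c(rep(fw_region[2], length(fw_var)),
                   rep(rv_region[2], length(rv_var))),
    orientation = c(rep("fw", length(fw_var)), rep("rv", length(rv_var))),
    mix = c(unname(mix_of), rep("Rv1", length(rv_var))))

  list(alignment = aln,
       templates = data.frame(id = ids, seq = unname(seqs)),
       primers = primers,
       mixes = mixes,
       fw_region = fw_region,
       rv_region = rv_region,
       clades = clades,
       reference = ids[1])
}

#' Members of a named mix in a primer table
#'
#' @param primers primer table with a semicolon-separated `mix` column.
#' @param mix_name mix to select.
#' @return the rows of `primers` belonging to the mix.
#' @export
mix_members <- function(primers, mix_name) {
  stopifnot("mix" %in% names(primers))
  sel <- vapply(strsplit(primers$mix, ";", fixed = TRUE),
                function(x) mix_name %in% x, logical(1))
  primers[sel, , drop = FALSE]
}

#' Write the synthetic panel to disk
#'
#' @param panel list from [synthetic_hglt_panel()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (aligned FASTA, ungapped template
#'   FASTA and primer table TSV).
#' @export
write_synthetic_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  aln_path <- file.path(dir, "synthetic_hglt_alignment.fasta")
  tpl_path <- file.path(dir, "synthetic_hglt_templates.fasta")
  prm_path <- file.path(dir, "synthetic_hglt_primers.tsv")
  write_fasta(data.frame(id = panel$alignment$ids,
                         seq = unname(panel$alignment$seqs)), aln_path)
  write_fasta(data.frame(id = panel$templates$id,
                         seq = panel$templates$seq), tpl_path)
  write_primer_table(panel$primers, prm_path)
  invisible(c(alignment = aln_path, templates = tpl_path,
              primers = prm_path))
}
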