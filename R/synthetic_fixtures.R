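## run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic gene family
#'
#' Describes a simulated family of marker-gene orthologs: a random root
#' sequence, clade-structured background substitutions (Jukes-Cantor-like:
#' uniform over the three alternative bases), and planted conserved blocks
#' whose per-column majority fraction is guaranteed to stay at or above
#' `1 - max_minor_fraction`.  No indels are simulated, so the family is
#' its own alignment.
#'
#' @param n_taxa number of sequences.
#' @param gene_length alignment columns.
#' @param conserved_blocks list of numeric vectors
#'   `c(start, length, max_minor_fraction)` (1-based start).
#' @param background_divergence per-site substitution probability from the
#'   root, outside the blocks.
#' @param clade_structure optional integer vector (length `n_taxa`)
#'   assigning taxa to clades; clade members share half of their
#'   substitutions.  `NULL` = independent taxa.
#' @param block_consensus optional list of concrete sequences used as
#'   block content (defaults to the random root slice).
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return object of class `dgm_family_spec`.
#' @export
family_spec <- function(n_taxa = 24L, gene_length = 1050L,
                        conserved_blocks = list(c(112, 20, 0.1),
                                                c(970, 20, 0.1)),
                        background_divergence = 0.25,
                        clade_structure = NULL,
                        block_consensus = NULL,
                        seed = 1L) {
  blocks <- do.call(rbind, lapply(conserved_blocks, function(b) {
    data.frame(start = as.integer(b[[1]]), length = as.integer(b[[2]]),
               max_minor_fraction = as.numeric(b[[3]]))
  }))
  stopifnot(n_taxa >= 2, gene_length >= 1,
            background_divergence >= 0, background_divergence <= 1,
            all(blocks$max_minor_fraction >= 0),
            all(blocks$max_minor_fraction <= 1),
            all(blocks$start >= 1),
            all(blocks$start + blocks$length - 1 <= gene_length))
  if (nrow(blocks) > 1L) {
    o <- order(blocks$start)
    b2 <- blocks[o, ]
    if (any(b2$start[-1] <= b2$start[-nrow(b2)] + b2$length[-nrow(b2)] - 1))
      stop("conserved blocks overlap", call. = FALSE)
  }
  if (!is.null(clade_structure))
    stopifnot(length(clade_structure) == n_taxa)
  if (!is.null(block_consensus)) {
    stopifnot(length(block_consensus) == nrow(blocks))
    for (i in seq_len(nrow(blocks)))
      stopifnot(nchar(block_consensus[[i]]) == blocks$length[i])
  }
  structure(list(n_taxa = as.integer(n_taxa),
                 gene_length = as.integer(gene_length),
                 blocks = blocks,
                 background_divergence = background_divergence,
                 clade_structure = clade_structure,
                 block_consensus = block_consensus,
                 seed = as.integer(seed)),
            class = "dgm_family_spec")
}

.mutate_bases <- function(bases, idx) {
  alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  pick <- ceiling(runif(length(idx)) * 3)
  vapply(seq_along(idx), function(k) {
    substr(alt[[bases[idx[k]]]], pick[k], pick[k])
  }, character(1))
}

#' Simulate a gene family with planted conserved blocks
#'
#' @param spec a [family_spec()].
#' @return list with `alignment` (`dgm_alignment`, gap-free), `truth`
#'   (block coordinates and clade assignment) and `spec`.  Byte-identical
#'   across runs for the same spec.
#' @export
simulate_gene_family <- function(spec) {
  stopifnot(inherits(spec, "dgm_family_spec"))
  n <- spec$n_taxa; L <- spec$gene_length
  blocks <- spec$blocks
  block_cols <- unlist(lapply(seq_len(nrow(blocks)), function(i)
    blocks$start[i]:(blocks$start[i] + blocks$length[i] - 1L)))
  bg_cols <- setdiff(seq_len(L), block_cols)
  clades <- spec$clade_structure
  if (is.null(clades)) clades <- seq_len(n)
  with_seed(spec$seed, {
    root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    mat <- matrix(rep(root, each = n), nrow = n)
    d <- spec$background_divergence
    p_clade <- if (length(unique(clades)) < n) d / 2 else 0
    p_taxon <- d - p_clade
    if (p_clade > 0) {
      for (cl in unique(clades)) {
        idx <- which(runif(length(bg_cols)) < p_clade)
        if (length(idx)) {
          new_bases <- .mutate_bases(root, bg_cols[idx])
          for (t in which(clades == cl))
            mat[t, bg_cols[idx]] <- new_bases
        }
      }
    }
    if (p_taxon > 0) {
      for (t in seq_len(n)) {
        idx <- which(runif(length(bg_cols)) < p_taxon)
        if (length(idx))
          mat[t, bg_cols[idx]] <- .mutate_bases(mat[t, ], bg_cols[idx])
      }
    }
    ## planted blocks: shared consensus plus bounded minority injection
    for (b in seq_len(nrow(blocks))) {
      cols <- blocks$start[b]:(blocks$start[b] + blocks$length[b] - 1L)
      content <- if (!is.null(spec$block_consensus))
        .seq_chars(normalize_seq(spec$block_consensus[[b]]))
      else root[cols]
      for (k in seq_along(cols)) mat[, cols[k]] <- content[k]
      kmax <- floor(blocks$max_minor_fraction[b] * n)
      if (kmax > 0L) {
        for (k in seq_along(cols)) {
          nm <- sample(0:kmax, 1L)
          if (nm > 0L) {
            taxa <- sample(n, nm)
            mat[taxa, cols[k]] <- .mutate_bases(mat[1, ], rep(cols[k], nm))
          }
        }
      }
    }
    ids <- sprintf("taxon%02d", seq_len(n))
    seqs <- setNames(apply(mat, 1, paste, collapse = ""), ids)
    ## self-validation: planted blocks satisfy their own conservation bound
    aln <- as_alignment(seqs)
    cons <- column_conservation(aln)
    for (b in seq_len(nrow(blocks))) {
      cols <- blocks$start[b]:(blocks$start[b] + blocks$length[b] - 1L)
      stopifnot(all(cons$majority_fraction[cols] >=
                      1 - blocks$max_minor_fraction[b]))
    }
    list(alignment = aln,
         truth = list(blocks = blocks,
                      clades = setNames(clades, ids)),
         spec = spec)
  })
}

#' Plant primer binding sites in a random template
#'
#' Embeds one random expansion of the forward primer and the reverse
#' complement of one random expansion of the reverse primer so that
#' [predict_amplicons()] recovers exactly one product of
#' `product_length`.  The remaining background is rejection-sampled until
#' neither primer has any unintended strict binding site.
#'
#' @param template_length total template length.
#' @param fw,rv IUPAC primer sequences.
#' @param product_length desired product length (>= `nchar(fw) +
#'   nchar(rv)`).
#' @param seed RNG seed.
#' @param id template id.
#' @return list with `template` (data.frame `id`, `seq`) and `truth`
#'   (`fw_start`, `rv_end`, `product_length`).
#' @export
plant_primer_sites <- function(template_length, fw, rv, product_length,
                               seed = 1L, id = "planted_template") {
  fw <- normalize_seq(fw); rv <- normalize_seq(rv)
  lf <- nchar(fw); lr <- nchar(rv)
  if (product_length < lf + lr)
    stop("product_length shorter than the two primer footprints",
         call. = FALSE)
  if (product_length > template_length)
    stop("product does not fit in the template", call. = FALSE)
  with_seed(seed, {
    fw_exp <- sample(expand_degenerate(fw), 1L)
    rv_exp <- sample(expand_degenerate(rv), 1L)
    fw_start <- sample.int(template_length - product_length + 1L, 1L)
    rv_end <- fw_start + product_length - 1L
    for (attempt in 1:100) {
      bases <- sample(c("A", "C", "G", "T"), template_length, replace = TRUE)
      bases[fw_start:(fw_start + lf - 1L)] <- .seq_chars(fw_exp)
      bases[(rv_end - lr + 1L):rv_end] <-
        .seq_chars(reverse_complement(rv_exp))
      seq <- paste(bases, collapse = "")
      fw_hits <- match_primer(fw, seq)
      rv_hits <- match_primer(rv, seq)
      ok <- nrow(fw_hits) == 1L && fw_hits$strand == "+" &&
        fw_hits$start == fw_start &&
        nrow(rv_hits) == 1L && rv_hits$strand == "-" &&
        rv_hits$end == rv_end
      if (ok)
        return(list(template = data.frame(id = id, seq = seq),
                    truth = list(fw_start = fw_start, rv_end = rv_end,
                                 product_length = product_length)))
    }
    stop("could not place primer sites without spurious matches",
         call. = FALSE)
  })
}

## planted-block contents engineered so that, for any background seed,
## the one-column flank extensions of each block pass primer QC (lengths
## 17-20 cannot pass the joint Tm/GC bounds at 9 G+C, so the recoverable
## windows are exactly the flank-extended 21/22-mers over the blocks)
.recovery_fw_block <- "GTAACTGACTCACCTGAGAA"   # 20 nt, 9 G+C
.recovery_rv_block <- "TTCGGTCTCTCTACAACAAC"   # 20 nt, 9 G+C

#' Benchmark family with planted primer-design truth
#'
#' Simulates a 24-taxon, 1050-column gene family with two invariant
#' conserved blocks at columns 112..131 (forward) and 970..989 (reverse)
#' inside a highly divergent background, so that window scanning must
#' recover exactly the planted regions and the top region pair spans
#' most of the gene.
#'
#' @param seed RNG seed for the background.
#' @return as [simulate_gene_family()].
#' @export
planted_design_family <- function(seed = 1L) {
  simulate_gene_family(family_spec(
    n_taxa = 24, gene_length = 1050,
    conserved_blocks = list(c(112, 20, 0), c(970, 20, 0)),
    block_consensus = list(.recovery_fw_block, .recovery_rv_block),
    background_divergence = 0.5,
    seed = seed))
}
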