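#' Primer design rules
#'
#' All numeric thresholds of the design procedure in one record.  The
#' defaults encode the guidelines the package implements: binding regions
#' of 17-22 bp with Tm between 50 and 65 degrees C, moderate GC content
#' (< 50 %), no long homopolymer runs, no hairpins or 3'-anchored dimers,
#' paired primers within 4 degrees C of each other, and at most four
#' non-consecutive degenerate positions per oligo.
#'
#' @param primer_len_min,primer_len_max allowed primer length (bases).
#' @param tm_min,tm_max allowed melting temperature (degrees C), applied to
#'   the extremes over all expansions of a degenerate oligo.
#' @param gc_max maximum GC fraction (exclusive), applied to the
#'   highest-GC expansion.
#' @param conservation_threshold fraction of alignment rows that must share
#'   the majority base for a column to count as conserved.
#' @param max_degenerate maximum degenerate positions per primer.
#' @param pair_tm_delta_max maximum Tm difference within a primer pair
#'   (degrees C).
#' @param polyN_max_run longest allowed homopolymer run (bases); longer
#'   runs are flagged.
#' @param hairpin_stem_min,hairpin_loop_min minimal stem and loop lengths
#'   (bases) for a hairpin to be flagged.
#' @param dimer_run_max bases of contiguous 3'-anchored complementarity
#'   allowed; runs of this length or more are flagged.
#' @return object of class `dgm_rules` (a validated list).
#' @examples
#' design_rules()
#' design_rules(gc_max = 0.6)
#' @export
design_rules <- function(primer_len_min = 17L, primer_len_max = 22L,
                         tm_min = 50, tm_max = 65,
                         gc_max = 0.50,
                         conservation_threshold = 0.75,
                         max_degenerate = 4L,
                         pair_tm_delta_max = 4,
                         polyN_max_run = 4L,
                         hairpin_stem_min = 4L, hairpin_loop_min = 3L,
                         dimer_run_max = 4L) {
  rules <- list(primer_len_min = as.integer(primer_len_min),
                primer_len_max = as.integer(primer_len_max),
                tm_min = tm_min, tm_max = tm_max, gc_max = gc_max,
                conservation_threshold = conservation_threshold,
                max_degenerate = as.integer(max_degenerate),
                pair_tm_delta_max = pair_tm_delta_max,
                polyN_max_run = as.integer(polyN_max_run),
                hairpin_stem_min = as.integer(hairpin_stem_min),
                hairpin_loop_min = as.integer(hairpin_loop_min),
                dimer_run_max = as.integer(dimer_run_max))
  with(rules, {
    stopifnot(primer_len_min <= primer_len_max,
              tm_min < tm_max,
              conservation_threshold > 0, conservation_threshold <= 1,
              max_degenerate >= 0, polyN_max_run >= 1,
              hairpin_stem_min >= 3, hairpin_loop_min >= 0,
              dimer_run_max >= 1)
  })
  structure(rules, class = "dgm_rules")
}

#' @export
print.dgm_rules <- function(x, ...) {
  cat("Primer design rules:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
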