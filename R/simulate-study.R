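#' Simulate a complete synthetic study
#'
#' Convenience wrapper running the whole generator: reference, population
#' genotypes and sample sheet, paired-end alignments around the sdY contig,
#' sequencing variant table and array genotypes, returning everything with
#' the ground-truth record.
#'
#' @param config a [sim_config()]; default configuration if omitted.
#' @param with_reference also build the reference sequences (off by
#'   default: most analyses never touch the bases).
#' @return list with `config`, `pop`, `aln`, `vt` (variant table), `array`,
#'   `truth` and optionally `reference`.
#' @export
simulate_study <- function(config = sim_config(), with_reference = FALSE) {
  pop <- simulate_population(config)
  aln <- simulate_alignments(config, pop$truth)
  vt <- simulate_variant_table(config, pop)
  arr <- simulate_array_genotypes(config, pop)
  out <- list(config = config, pop = pop, aln = aln, vt = vt, array = arr,
              truth = pop$truth)
  if (with_reference) out$reference <- build_reference(config)
  out
}
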