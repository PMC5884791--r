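#' Build the synthetic reference sequence set
#'
#' Generates one random DNA sequence per chromosome proxy plus the appended
#' sdY contig as an extra sequence, mirroring the study design in which a
#' 20 kb male-derived contig carrying sdY is appended to a female-derived
#' chromosome assembly.  Deterministic given the config seed.
#'
#' @param config a [sim_config()] object.
#' @return a [Biostrings::DNAStringSet] with `n_chromosomes + 1` sequences;
#'   the last is the sdY contig.
#' @export
build_reference <- function(config) {
  validate_sim_config(config)
  with_substream(config$seed, 1L, {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(config$n_chromosomes), function(i) {
      paste(sample(bases, config$chrom_length_bp, replace = TRUE),
            collapse = "")
    }, character(1))
    sdy <- paste(sample(bases, config$sdy_contig_length_bp, replace = TRUE),
                 collapse = "")
    out <- Biostrings::DNAStringSet(c(seqs, sdy))
    names(out) <- c(config$chrom_names, config$sdy_contig)
    out
  })
}

#' Write a reference to FASTA
#'
#' @param ref a `DNAStringSet` from [build_reference()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  Biostrings::writeXStringSet(ref, filepath = path, width = 80L)
  invisible(path)
}
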