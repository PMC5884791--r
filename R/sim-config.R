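#' Simulation configuration for the synthetic salmon sex-locus generator
#'
#' Builds a validated configuration object driving every synthetic-data
#' operation ([build_reference()], [simulate_population()],
#' [simulate_alignments()], [simulate_variant_table()],
#' [simulate_array_genotypes()]).  The defaults emulate the study design the
#' downstream analyses assume: six chromosomes standing in for Ssa02, Ssa03,
#' Ssa05, Ssa06, Ssa12 and Ssa25, a 20 kb sdY contig whose male-specific
#' region (MSR) ends at base 13,333, three male sex lineages (SL-02, SL-03,
#' SL-06) segregating in proportions 0.25/0.25/0.50, three populations with
#' Balding-Nichols drift (TAS and NA weakly diverged, EU strongly), and
#' residually tetrasomic homeolog block pairs with allele-frequency
#' correlation rho.
#'
#' Chromosome proxies: chr1 = Ssa02, chr2 = Ssa03, chr3 = Ssa05,
#' chr4 = Ssa06, chr5 = Ssa12, chr6 = Ssa25.  The default homeolog map pairs
#' chr1\[1, L/2\] with chr3, chr1\[L/2+1, L\] with chr5 and chr2 with chr4,
#' mirroring the Ssa02p-Ssa05, Ssa02q-Ssa12 and Ssa03-Ssa06 partnerships.
#'
#' @param n_chromosomes number of autosome proxies.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param sdy_contig_length_bp length of the appended sdY contig in bp.
#' @param msr_interval 1-based inclusive `c(start, end)` of the male-specific
#'   region on the sdY contig; the end is the MSR-MFCR junction.
#' @param homeolog_pairs list of homeolog block pairs; each element is a list
#'   with `a = c(chrom, start, end)`, `b = c(chrom, start, end)` (chrom as
#'   name), `rho` (genotype-copy probability) and `fraction` (fraction of
#'   sites in the block that mirror their partner).  `NULL` gives the default
#'   three-pair map described above.
#' @param pop_sizes named integer vector of diploid sample counts per
#'   population (TAS, NA, EU).
#' @param fst_drift named numeric vector of Balding-Nichols F per population.
#' @param sd_loci list of three sex-determining anchors, each a list with
#'   `chrom`, `pos` and `lineage` (one of "SL-02", "SL-03", "SL-06").
#' @param lineage_proportions named numeric vector of male lineage
#'   proportions; must sum to 1.
#' @param sd_link_window_bp half-width of the cassette-linked haplotype
#'   block around each sd anchor: carrier males share one haplotype over
#'   sites within this window, so nearby SNPs associate with maleness (and
#'   the association can leak through homeolog mirroring).
#' @param psex_discordance_rate probability that the recorded phenotypic sex
#'   disagrees with genotypic sex.
#' @param coverage_mean mean fold coverage of the sequencing simulation.
#' @param insert_mean,insert_sd paired-end insert size distribution (bp).
#' @param read_len read length (bp).
#' @param seq_error_rate per-base sequencing error rate.
#' @param array_error_rate per-genotype array call error rate.
#' @param n_dh_females number of double-haploid female genomes.
#' @param n_artifact_sites number of planted paralog-collapse artifact sites
#'   (heterozygous in every sample, double haploids included).
#' @param snp_spacing_bp mean spacing between simulated chromosome SNPs.
#' @param sdy_n_snps number of SNP sites simulated on the sdY contig.
#' @param msr_n_snps number of those falling inside the MSR (polymorphic
#'   among males).
#' @param hg_divergence fraction of MSR sites at which the two haplogroup
#'   core haplotypes differ.
#' @param within_hg_mut per-site mutation probability within a haplogroup
#'   (drives within-group divergence).
#' @param n_wgs_males,n_wgs_females numbers of males/females carried into the
#'   alignment and variant-table simulations.
#' @param orphan_mate_homeolog_frac fraction of translocated-male orphan
#'   mates placed on the lineage chromosome's homeolog partner rather than
#'   the lineage chromosome itself.
#' @param low_mq_fraction fraction of variant sites given low mapping
#'   quality.
#' @param female_msr_noise optional uniform read noise for females over the
#'   MSR (mimics contig-only mismapping); default 0.
#' @param seed integer seed from which all per-module substreams derive.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chromosomes = 6L,
                       chrom_length_bp = 500000L,
                       sdy_contig_length_bp = 20000L,
                       msr_interval = c(2001L, 13333L),
                       homeolog_pairs = NULL,
                       pop_sizes = stats::setNames(c(20L, 7L, 13L),
                                                   c("TAS", "NA", "EU")),
                       fst_drift = stats::setNames(c(0.04, 0.04, 0.17),
                                                   c("TAS", "NA", "EU")),
                       sd_loci = NULL,
                       lineage_proportions = c("SL-02" = 0.25,
                                               "SL-03" = 0.25,
                                               "SL-06" = 0.50),
                       sd_link_window_bp = 50000L,
                       psex_discordance_rate = 0.02,
                       coverage_mean = 40,
                       insert_mean = 400,
                       insert_sd = 50,
                       read_len = 150L,
                       seq_error_rate = 0.003,
                       array_error_rate = 0.01,
                       n_dh_females = 4L,
                       n_artifact_sites = 50L,
                       snp_spacing_bp = 500L,
                       sdy_n_snps = 163L,
                       msr_n_snps = 22L,
                       hg_divergence = 0.78,
                       within_hg_mut = 0.05,
                       n_wgs_males = 6L,
                       n_wgs_females = 6L,
                       orphan_mate_homeolog_frac = 1 / 3,
                       low_mq_fraction = 0.02,
                       female_msr_noise = 0,
                       seed = 1L) {
  chrom_names <- paste0("chr", seq_len(n_chromosomes))
  half <- chrom_length_bp %/% 2L
  if (is.null(homeolog_pairs)) {
    homeolog_pairs <- list(
      list(a = list(chrom = "chr1", start = 1L, end = half),
           b = list(chrom = "chr3", start = 1L, end = half),
           rho = 0.9, fraction = 0.5),
      list(a = list(chrom = "chr1", start = half + 1L, end = chrom_length_bp),
           b = list(chrom = "chr5", start = 1L, end = half),
           rho = 0.9, fraction = 0.5),
      list(a = list(chrom = "chr2", start = 1L, end = half),
           b = list(chrom = "chr4", start = 1L, end = half),
           rho = 0.9, fraction = 0.5)
    )
  }
  if (is.null(sd_loci)) {
    # SL-02 anchor inside the chr1/chr3 homeolog block so its (strong)
    # association can leak; SL-03/SL-06 anchors outside any block.
    sd_loci <- list(
      list(chrom = "chr1", pos = 200000L, lineage = "SL-02"),
      list(chrom = "chr2", pos = 400000L, lineage = "SL-03"),
      list(chrom = "chr4", pos = 400000L, lineage = "SL-06")
    )
  }
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_names = chrom_names,
    chrom_length_bp = as.integer(chrom_length_bp),
    sdy_contig = "sdY",
    sdy_contig_length_bp = as.integer(sdy_contig_length_bp),
    msr_interval = as.integer(msr_interval),
    homeolog_pairs = homeolog_pairs,
    pop_sizes = pop_sizes,
    fst_drift = fst_drift,
    sd_loci = sd_loci,
    lineage_proportions = lineage_proportions,
    sd_link_window_bp = as.integer(sd_link_window_bp),
    psex_discordance_rate = psex_discordance_rate,
    coverage_mean = coverage_mean,
    insert_mean = insert_mean,
    insert_sd = insert_sd,
    read_len = as.integer(read_len),
    seq_error_rate = seq_error_rate,
    array_error_rate = array_error_rate,
    n_dh_females = as.integer(n_dh_females),
    n_artifact_sites = as.integer(n_artifact_sites),
    snp_spacing_bp = as.integer(snp_spacing_bp),
    sdy_n_snps = as.integer(sdy_n_snps),
    msr_n_snps = as.integer(msr_n_snps),
    hg_divergence = hg_divergence,
    within_hg_mut = within_hg_mut,
    n_wgs_males = as.integer(n_wgs_males),
    n_wgs_females = as.integer(n_wgs_females),
    orphan_mate_homeolog_frac = orphan_mate_homeolog_frac,
    low_mq_fraction = low_mq_fraction,
    female_msr_noise = female_msr_noise,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1L, cfg$chrom_length_bp >= 1000L)
  if (length(cfg$msr_interval) != 2L ||
      cfg$msr_interval[1] < 1L ||
      cfg$msr_interval[2] <= cfg$msr_interval[1])
    stop("msr_interval must be an increasing 1-based [start, end] pair")
  if (cfg$msr_interval[2] > cfg$sdy_contig_length_bp)
    stop("sdY contig shorter than msr_interval")
  if (abs(sum(cfg$lineage_proportions) - 1) > 1e-8)
    stop("lineage proportions must sum to 1")
  rates <- c(cfg$psex_discordance_rate, cfg$seq_error_rate,
             cfg$array_error_rate, cfg$low_mq_fraction,
             cfg$orphan_mate_homeolog_frac, cfg$female_msr_noise,
             cfg$hg_divergence, cfg$within_hg_mut)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (any(cfg$fst_drift < 0 | cfg$fst_drift >= 1))
    stop("Balding-Nichols F must lie in [0, 1)")
  for (hp in cfg$homeolog_pairs) {
    if (hp$a$chrom == hp$b$chrom)
      stop("homeolog pair intervals must be non-syntenic (different chromosomes)")
    if (hp$a$start > hp$a$end || hp$b$start > hp$b$end)
      stop("malformed homeolog interval")
  }
  lineages <- vapply(cfg$sd_loci, `[[`, "", "lineage")
  if (!setequal(lineages, names(cfg$lineage_proportions)))
    stop("sd_loci lineages must match lineage_proportions names")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic salmon sex-locus simulation config\n")
  cat(sprintf("  %d chromosomes x %d bp + %s contig (%d bp)\n",
              x$n_chromosomes, x$chrom_length_bp, x$sdy_contig,
              x$sdy_contig_length_bp))
  cat(sprintf("  MSR [%d, %d] (junction at %d)\n",
              x$msr_interval[1], x$msr_interval[2], x$msr_interval[2]))
  cat(sprintf("  populations: %s\n",
              paste(names(x$pop_sizes), x$pop_sizes, sep = "=",
                    collapse = ", ")))
  cat(sprintf("  lineages: %s\n",
              paste(names(x$lineage_proportions), x$lineage_proportions,
                    sep = "=", collapse = ", ")))
  cat(sprintf("  coverage %gx, insert %g+/-%g, reads %d bp, seed %d\n",
              x$coverage_mean, x$insert_mean, x$insert_sd, x$read_len,
              x$seed))
  invisible(x)
}

# Run expr under a deterministic substream derived from (seed, offset),
# restoring the caller's RNG state afterwards.  All generator randomness
# flows through this helper so identical configs give identical outputs.
with_substream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) * 1000L + as.integer(offset)) %% .Machine$integer.max)
  expr
}
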