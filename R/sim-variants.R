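#' Simulate a variant table (sequencing-derived genotype calls)
#'
#' Layers a read-count noise model over the population genotypes: per-sample
#' depth is Poisson at the configured coverage (halved at male-specific
#' region sites in males, zero in females), alt-allele depth is binomial at
#' the genotype's allele fraction (0.5 for het, the sequencing error rate
#' for homozygotes), site mapping quality is Normal(58, 3) with a
#' configurable fraction of low-MQ sites, and a genotype is missing iff its
#' depth is zero.  Double-haploid females are homozygous everywhere except
#' the planted paralog-collapse artifact sites, where they (like every other
#' sample) show heterozygous calls.
#'
#' @param config a [sim_config()] object.
#' @param pop a `sim_population` from [simulate_population()].
#' @param samples sample ids to include; default all (double haploids
#'   included).
#' @return a [variant_table()].
#' @export
simulate_variant_table <- function(config, pop, samples = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  if (is.null(samples)) samples <- pop$samples$animal
  with_substream(config$seed, 4L, {
    sheet <- pop$samples[match(samples, pop$samples$animal), ]
    n <- length(samples)

    ## assemble site table: chromosome sites, then sdY MFCR + MSR sites
    chrom_sites <- data.frame(pop$map[, c("chrom", "pos", "ref", "alt")],
                              stringsAsFactors = FALSE)
    sdy_sites <- rbind(pop$mfcr_sites, pop$msr_sites)
    sdy_ord <- order(sdy_sites$pos)
    sdy_sites <- sdy_sites[sdy_ord, ]
    sites <- rbind(chrom_sites, sdy_sites[, c("chrom", "pos", "ref", "alt")])
    m <- nrow(sites)
    is_msr <- sites$chrom == config$sdy_contig &
      sites$pos >= config$msr_interval[1] &
      sites$pos <= config$msr_interval[2]

    ## genotype matrix (sites x samples)
    gt <- matrix(NA_integer_, m, n)
    gt[seq_len(nrow(chrom_sites)), ] <- t(pop$geno[samples, , drop = FALSE])
    sdy_gt <- matrix(NA_integer_, nrow(sdy_sites), n)
    # MFCR diploid sites
    mfcr_rows <- which(sdy_sites$pos %in% pop$mfcr_sites$pos &
                         !(sdy_sites$pos %in% pop$msr_sites$pos))
    if (length(mfcr_rows)) {
      mf_idx <- match(sdy_sites$pos[mfcr_rows], pop$mfcr_sites$pos)
      sdy_gt[mfcr_rows, ] <- t(pop$mfcr_geno[samples, mf_idx, drop = FALSE])
    }
    # MSR hemizygous sites: males carry the haplotype allele (called as a
    # homozygote), females carry nothing
    msr_rows <- which(sdy_sites$pos %in% pop$msr_sites$pos)
    males <- samples[sheet$GSEX == "M"]
    if (length(msr_rows) && length(males)) {
      ms_idx <- match(sdy_sites$pos[msr_rows], pop$msr_sites$pos)
      sdy_gt[msr_rows, sheet$GSEX == "M"] <-
        t(2L * pop$msr_hap[males, ms_idx, drop = FALSE])
    }
    gt[seq(nrow(chrom_sites) + 1L, m), ] <- sdy_gt

    ## depth model
    dp <- matrix(stats::rpois(m * n, config$coverage_mean), m, n)
    if (any(is_msr)) {
      male_cols <- which(sheet$GSEX == "M")
      female_cols <- which(sheet$GSEX == "F")
      dp[is_msr, male_cols] <- stats::rpois(sum(is_msr) * length(male_cols),
                                            config$coverage_mean / 2)
      dp[is_msr, female_cols] <- 0L
    }
    gt[dp == 0L] <- NA_integer_

    ## allele depths given genotype and depth
    af <- matrix(config$seq_error_rate, m, n)
    af[gt == 1L] <- 0.5
    af[gt == 2L] <- 1 - config$seq_error_rate
    ad_alt <- matrix(stats::rbinom(m * n, dp, af), m, n)
    ad_alt[is.na(gt)] <- 0L
    ad_ref <- dp - ad_alt

    ## site mapping quality
    mq <- stats::rnorm(m, 58, 3)
    low <- stats::runif(m) < config$low_mq_fraction
    mq[low] <- stats::runif(sum(low), 25, 45)
    sites$mq <- mq

    variant_table(sites, samples, gt, ad_ref, ad_alt, dp)
  })
}

#' Simulate array genotypes and sdY presence assays
#'
#' Exports the chromosome SNPs of a simulated population as 0/1/2 array
#' calls with independent per-genotype error flips, plus the three boolean
#' sdY probe-set calls per animal (all positive iff the animal carries the
#' sdY cassette).
#'
#' @param config a [sim_config()] object.
#' @param pop a `sim_population`.
#' @param assay_noise probability that one assay call flips; default 0.
#' @return list with `geno` (samples x sites dosage matrix), `map`
#'   (site data.frame), `samples`, and `assays` (samples x 3 logical).
#' @export
simulate_array_genotypes <- function(config, pop, assay_noise = 0) {
  stopifnot(inherits(pop, "sim_population"))
  with_substream(config$seed, 5L, {
    geno <- pop$geno
    n <- nrow(geno); m <- ncol(geno)
    if (config$array_error_rate > 0) {
      flip <- matrix(stats::runif(n * m) < config$array_error_rate, n, m)
      if (any(flip)) {
        # adding 1 or 2 mod 3 maps a dosage to one of the other two values
        shift <- sample(1:2, sum(flip), replace = TRUE)
        geno[flip] <- (geno[flip] + shift) %% 3L
      }
    }
    is_male <- pop$truth$per_sample_gsex[rownames(geno)] == "M"
    assays <- matrix(rep(is_male, 3L), ncol = 3L,
                     dimnames = list(rownames(geno),
                                     paste0("sdY_assay", 1:3)))
    if (assay_noise > 0) {
      fl <- matrix(stats::runif(n * 3L) < assay_noise, n, 3L)
      assays <- xor(assays, fl)
    }
    list(geno = geno, map = pop$map, samples = rownames(geno),
         assays = assays)
  })
}

#' Write and read generator ground truth as JSON
#'
#' @param truth a `truth_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  x <- unclass(truth)
  # named vectors must become JSON objects so names survive the round-trip
  for (field in c("lineage_by_male", "haplogroup_by_male",
                  "per_sample_gsex", "per_sample_psex"))
    if (!is.null(x[[field]])) x[[field]] <- as.list(x[[field]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @return for `read_truth`, the reconstructed `truth_record`.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("junction_pos", "lineage_by_male", "true_sd_loci",
                "artifact_sites", "per_sample_gsex", "per_sample_psex")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("truth record missing fields: ", paste(miss, collapse = ", "))
  x$junction_pos <- as.integer(x$junction_pos)
  x$lineage_by_male <- unlist(x$lineage_by_male)
  x$haplogroup_by_male <- unlist(x$haplogroup_by_male)
  x$per_sample_gsex <- unlist(x$per_sample_gsex)
  x$per_sample_psex <- unlist(x$per_sample_psex)
  x$true_sd_loci <- as.data.frame(x$true_sd_loci)
  x$artifact_sites <- as.data.frame(x$artifact_sites)
  x$mirrored_site_pairs <- as.data.frame(x$mirrored_site_pairs)
  structure(x, class = "truth_record")
}
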