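#' Site and genotype quality filtering
#'
#' Applies the sequencing-variant quality rules: sites with mapping quality
#' below `min_mq` are removed, genotypes with depth below `min_dp` are set
#' missing (and a site is dropped if that leaves no called genotype), and
#' multi-allelic or non-SNP records are removed when `biallelic_only` is
#' set.  Boundaries are inclusive on the keep side: mq = 50 and dp = 5
#' survive the defaults.
#'
#' @param table a [variant_table()].
#' @param min_mq minimum site mapping quality (sites below are removed).
#' @param min_dp minimum genotype depth (genotypes below are set missing).
#' @param biallelic_only drop multi-allelic and non-SNP records.
#' @return list with `table` (filtered) and `log` (named counts removed per
#'   rule).
#' @export
filter_variants <- function(table, min_mq = 50, min_dp = 5,
                            biallelic_only = TRUE) {
  stopifnot(inherits(table, "variant_table"))
  if (min_mq < 0 || min_dp < 0) stop("thresholds must be non-negative")
  log <- c(low_mq = 0L, not_biallelic_snp = 0L, low_dp_genotypes = 0L,
           all_missing = 0L)

  keep <- rep(TRUE, nrow(table$sites))
  low <- table$sites$mq < min_mq
  log["low_mq"] <- sum(low, na.rm = TRUE)
  keep[which(low)] <- FALSE

  if (biallelic_only) {
    bad <- grepl(",", table$sites$alt, fixed = TRUE) |
      nchar(table$sites$ref) != 1L | nchar(table$sites$alt) != 1L |
      !table$sites$ref %in% c("A", "C", "G", "T") |
      !table$sites$alt %in% c("A", "C", "G", "T")
    log["not_biallelic_snp"] <- sum(bad & keep)
    keep[bad] <- FALSE
  }

  gt <- table$gt
  low_dp <- table$dp < min_dp & !is.na(gt)
  log["low_dp_genotypes"] <- sum(low_dp[keep, , drop = FALSE])
  gt[low_dp] <- NA_integer_

  empty <- rowSums(!is.na(gt)) == 0L
  log["all_missing"] <- sum(empty & keep)
  keep[empty] <- FALSE

  out <- variant_table(table$sites[keep, , drop = FALSE], table$samples,
                       gt[keep, , drop = FALSE],
                       table$ad_ref[keep, , drop = FALSE],
                       table$ad_alt[keep, , drop = FALSE],
                       table$dp[keep, , drop = FALSE])
  list(table = out, log = log)
}

#' Double-haploid artifact filter
#'
#' A double-haploid genome carries two identical chromosome sets, so a
#' heterozygous call in one marks a genotyping artifact (typically a
#' collapsed paralog).  Every position at which any double-haploid sample is
#' called heterozygous is removed; the double-haploid samples themselves are
#' dropped from the surviving table.
#'
#' @param table a [variant_table()].
#' @param dh_samples ids of the double-haploid samples (must be in the
#'   table; must be non-empty).
#' @return list with `table` (filtered, DH samples dropped) and `removed`
#'   (data.frame of removed chrom/pos).
#' @export
double_haploid_filter <- function(table, dh_samples) {
  stopifnot(inherits(table, "variant_table"))
  if (length(dh_samples) == 0L) stop("dh_samples must be non-empty")
  if (!all(dh_samples %in% table$samples))
    stop("dh_samples must be a subset of the table samples")
  het <- table$gt[, dh_samples, drop = FALSE] == 1L
  bad <- rowSums(het, na.rm = TRUE) > 0L
  removed <- table$sites[bad, c("chrom", "pos")]
  rownames(removed) <- NULL
  keep_samples <- setdiff(table$samples, dh_samples)
  out <- subset_variant_table(table, which(!bad), keep_samples)
  list(table = out, removed = removed)
}

# normalise either a variant_table or an array genotype list to
# (sites, dosage sites x samples)
.as_dosage <- function(x) {
  if (inherits(x, "variant_table")) {
    list(sites = x$sites[, c("chrom", "pos", "ref", "alt")],
         geno = x$gt, samples = x$samples)
  } else if (is.list(x) && all(c("geno", "map") %in% names(x))) {
    list(sites = x$map[, c("chrom", "pos", "ref", "alt")],
         geno = t(x$geno), samples = rownames(x$geno))
  } else stop("expected a variant_table or an array genotype list")
}

#' Genotype concordance between two call sets
#'
#' Matches loci by (chrom, pos) requiring an identical ref/alt allele pair
#' (mismatched or swapped alleles exclude the locus), converts both sources
#' to 0/1/2 alt dosage, and reports concordance over the non-missing
#' genotype pairs of the shared samples.
#'
#' @param table,array_table each either a [variant_table()] or an array
#'   genotype list (as from [simulate_array_genotypes()]).
#' @return a `concordance_report`: list with `n_overlap_loci`,
#'   `n_compared_genotypes`, `n_concordant`, `concordance` and `per_locus`
#'   breakdown.
#' @export
genotype_concordance <- function(table, array_table) {
  a <- .as_dosage(table)
  b <- .as_dosage(array_table)
  shared_samples <- intersect(a$samples, b$samples)
  if (!length(shared_samples)) stop("no shared samples")
  ka <- paste(a$sites$chrom, a$sites$pos)
  kb <- paste(b$sites$chrom, b$sites$pos)
  common <- intersect(ka, kb)
  ia <- match(common, ka)
  ib <- match(common, kb)
  same_alleles <- a$sites$ref[ia] == b$sites$ref[ib] &
    a$sites$alt[ia] == b$sites$alt[ib]
  ia <- ia[same_alleles]; ib <- ib[same_alleles]
  if (!length(ia)) stop("no overlapping loci with matching alleles")
  ga <- a$geno[ia, shared_samples, drop = FALSE]
  gb <- b$geno[ib, shared_samples, drop = FALSE]
  both <- !is.na(ga) & !is.na(gb)
  agree <- ga == gb & both
  per_locus <- data.frame(
    chrom = a$sites$chrom[ia], pos = a$sites$pos[ia],
    n_compared = rowSums(both), n_concordant = rowSums(agree, na.rm = TRUE),
    stringsAsFactors = FALSE)
  n_comp <- sum(both)
  n_conc <- sum(agree, na.rm = TRUE)
  structure(list(n_overlap_loci = length(ia),
                 n_compared_genotypes = n_comp,
                 n_concordant = n_conc,
                 concordance = if (n_comp > 0) n_conc / n_comp else NA_real_,
                 per_locus = per_locus),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: %.4f (%d/%d genotypes at %d loci)\n",
              x$concordance, x$n_concordant, x$n_compared_genotypes,
              x$n_overlap_loci))
  invisible(x)
}

#' Binomial down-sampling of read depths
#'
#' Thins `ad_ref` and `ad_alt` independently by a binomial at `fraction`
#' (emulating read subsampling before re-calling), recomputes depth, and
#' re-calls genotypes: missing below depth 5, hom-ref below alt fraction
#' 0.2, hom-alt above 0.8, het otherwise.  `fraction = 1` returns the table
#' unchanged.
#'
#' @param table a [variant_table()].
#' @param fraction retention fraction in (0, 1].
#' @param seed RNG seed for the thinning draws.
#' @return a `variant_table` with thinned depths and re-called genotypes.
#' @export
downsample_depths <- function(table, fraction, seed = 1L) {
  stopifnot(inherits(table, "variant_table"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(table)
  with_substream(seed, 6L, {
    ad_ref <- matrix(stats::rbinom(length(table$ad_ref), table$ad_ref,
                                   fraction), nrow = nrow(table$ad_ref))
    ad_alt <- matrix(stats::rbinom(length(table$ad_alt), table$ad_alt,
                                   fraction), nrow = nrow(table$ad_alt))
    dp <- ad_ref + ad_alt
    frac_alt <- ifelse(dp > 0, ad_alt / dp, NA_real_)
    gt <- ifelse(dp < 5L, NA_integer_,
                 ifelse(frac_alt < 0.2, 0L,
                        ifelse(frac_alt > 0.8, 2L, 1L)))
    variant_table(table$sites, table$samples, gt, ad_ref, ad_alt, dp)
  })
}
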