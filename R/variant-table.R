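#' Construct a variant table
#'
#' The central genotype container: per-site metadata (chrom, pos, ref, alt,
#' site mapping quality) plus per site x sample genotype (alt-allele dosage
#' 0/1/2, `NA` = missing), allele depths and total depth.  Sites are kept
#' sorted by (chrom, pos) with chromosome order as first encountered.
#'
#' @param sites data.frame with columns chrom, pos, ref, alt, mq.
#' @param samples character vector of sample ids.
#' @param gt integer matrix (sites x samples) of dosages, `NA` missing.
#' @param ad_ref,ad_alt,dp integer matrices (sites x samples).
#' @return an object of class `variant_table`.
#' @export
variant_table <- function(sites, samples, gt, ad_ref, ad_alt, dp) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "mq") %in% names(sites)),
            nrow(sites) == nrow(gt), length(samples) == ncol(gt),
            all(dim(gt) == dim(ad_ref)), all(dim(gt) == dim(ad_alt)),
            all(dim(gt) == dim(dp)))
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  if (any(ad_ref + ad_alt > dp, na.rm = TRUE))
    stop("ad_ref + ad_alt must not exceed dp")
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  colnames(gt) <- colnames(ad_ref) <- colnames(ad_alt) <- colnames(dp) <-
    samples
  structure(list(sites = sites, samples = samples,
                 gt = gt[ord, , drop = FALSE],
                 ad_ref = ad_ref[ord, , drop = FALSE],
                 ad_alt = ad_alt[ord, , drop = FALSE],
                 dp = dp[ord, , drop = FALSE]),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              paste(unique(x$sites$chrom), collapse = ", ")))
  invisible(x)
}

#' Number of sites in a variant table
#' @param table a `variant_table`.
#' @return integer site count.
#' @export
n_sites <- function(table) nrow(table$sites)

# subset a variant_table by site index and/or sample ids
subset_variant_table <- function(table, site_idx = NULL, samples = NULL) {
  if (is.null(site_idx)) site_idx <- seq_len(nrow(table$sites))
  if (is.null(samples)) samples <- table$samples
  variant_table(table$sites[site_idx, , drop = FALSE], samples,
                table$gt[site_idx, samples, drop = FALSE],
                table$ad_ref[site_idx, samples, drop = FALSE],
                table$ad_alt[site_idx, samples, drop = FALSE],
                table$dp[site_idx, samples, drop = FALSE])
}

#' Write a variant table as VCF 4.2
#'
#' Emits plain-text VCF with INFO `MQ` and FORMAT `GT:AD:DP`; heterozygous
#' genotypes are written unphased (`0/1`), missing as `./.`.
#'
#' @param table a `variant_table`.
#' @param path output path.
#' @param contig_lengths optional named vector for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(table, path, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"),
             con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                       contig_lengths), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", table$samples), collapse = "\t"), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[table$gt + 1L], nrow = nrow(table$gt))
  gt_str[is.na(table$gt)] <- "./."
  cells <- matrix(sprintf("%s:%d,%d:%d", gt_str, table$ad_ref,
                          table$ad_alt, table$dp), nrow = nrow(table$gt))
  body <- apply(cells, 1L, paste, collapse = "\t")
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMQ=%.2f\tGT:AD:DP\t%s",
                   table$sites$chrom, table$sites$pos, table$sites$ref,
                   table$sites$alt, table$sites$mq, body)
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Uses vcfR to parse the file; requires FORMAT fields GT, AD and DP and a
#' site INFO MQ (absent MQ becomes `NA`).  Multi-allelic records are kept
#' (the alt column holds the comma-separated list) so that downstream
#' filtering can drop them by rule.
#'
#' @param path VCF path.
#' @return a `variant_table`.
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  info <- vcfR::extract.info(v, "MQ", as.numeric = TRUE)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      mq = as.numeric(info), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, "GT")
  gt <- matrix(NA_integer_, nrow = nrow(gt_raw), ncol = ncol(gt_raw))
  gt[gt_raw %in% c("0/0", "0|0")] <- 0L
  gt[gt_raw %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  gt[gt_raw %in% c("1/1", "1|1")] <- 2L
  ad <- vcfR::extract.gt(v, "AD")
  ad_ref <- matrix(as.integer(sub(",.*", "", ad)), nrow = nrow(ad))
  ad_alt <- matrix(as.integer(vapply(strsplit(ad, ","), function(x)
    if (length(x) >= 2) x[2] else NA_character_, "")), nrow = nrow(ad))
  dp <- matrix(as.integer(vcfR::extract.gt(v, "DP")), nrow = nrow(ad))
  dp[is.na(dp)] <- 0L
  ad_ref[is.na(ad_ref)] <- 0L
  ad_alt[is.na(ad_alt)] <- 0L
  variant_table(sites, colnames(gt_raw), gt, ad_ref, ad_alt, dp)
}
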