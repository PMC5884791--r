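#' Assign genotypic sex from sdY assay calls
#'
#' Three probe sets assay the presence of the sdY gene; an animal is male
#' when all three return a positive signal, female when none does, and
#' missing otherwise.
#'
#' @param assay_calls logical matrix (animals x 3) or length-3 logical
#'   vector.
#' @return character vector of "male" / "female" / "missing".
#' @export
assign_gsex <- function(assay_calls) {
  if (is.vector(assay_calls)) assay_calls <- matrix(assay_calls, nrow = 1L)
  if (ncol(assay_calls) != 3L) stop("expected three assay calls per animal")
  npos <- rowSums(assay_calls)
  out <- ifelse(npos == 3L, "male", ifelse(npos == 0L, "female", "missing"))
  stats::setNames(out, rownames(assay_calls))
}

#' Quality-control a GWAS genotype matrix
#'
#' Filters, in order: samples with more than `max_sample_missing` missing
#' genotypes, SNPs with call rate below `min_call_rate`, SNPs with minor
#' allele frequency below `min_maf`.  Boundaries keep: call rate exactly
#' 0.90, MAF exactly 0.01 and sample missingness exactly 0.05 all survive
#' the defaults.
#'
#' @param geno samples x sites dosage matrix (`NA` missing).
#' @param min_call_rate minimum per-SNP call rate.
#' @param min_maf minimum minor allele frequency.
#' @param max_sample_missing maximum per-sample missing fraction.
#' @return list with `geno` (filtered), `kept_sites`, `kept_samples` (index
#'   vectors into the input) and `log` (counts removed per step).
#' @export
qc_genotype_matrix <- function(geno, min_call_rate = 0.90, min_maf = 0.01,
                               max_sample_missing = 0.05) {
  miss_sample <- rowMeans(is.na(geno))
  keep_samples <- which(miss_sample <= max_sample_missing)
  g <- geno[keep_samples, , drop = FALSE]
  call_rate <- colMeans(!is.na(g))
  keep1 <- call_rate >= min_call_rate
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep2 <- keep1 & !is.na(maf) & maf >= min_maf
  if (!any(keep2) || !length(keep_samples)) stop("QC removed everything")
  list(geno = g[, keep2, drop = FALSE],
       kept_sites = which(keep2),
       kept_samples = keep_samples,
       log = c(samples_removed = nrow(geno) - length(keep_samples),
               low_call_rate = sum(!keep1),
               low_maf = sum(keep1 & !keep2)))
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum_k p_k (1 - p_k))` with `Z = M - 2p` the
#' column-centred dosage matrix.  Missing genotypes are mean-imputed before
#' centring; allele frequencies default to those observed in the data.
#'
#' @param geno samples x sites dosage matrix.
#' @param p optional per-site allele frequencies; default column means / 2.
#' @return symmetric samples x samples G matrix.
#' @export
grm_vanraden1 <- function(geno, p = NULL) {
  if (is.null(p)) p <- colMeans(geno, na.rm = TRUE) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stop("all sites monomorphic: zero denominator")
  M <- geno
  if (anyNA(M)) {
    mu <- 2 * p
    for (j in which(colSums(is.na(M)) > 0L))
      M[is.na(M[, j]), j] <- mu[j]
  }
  Z <- sweep(M, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  (G + t(G)) / 2
}

#' Additive (numerator) relationship matrix from a pedigree
#'
#' Tabular method: animals sorted so parents precede offspring,
#' `A_ij = (A_{j,sire(i)} + A_{j,dam(i)}) / 2` for j < i and
#' `A_ii = 1 + A_{sire(i),dam(i)} / 2`.  Unknown parents are coded "0" or
#' `NA`.
#'
#' @param pedigree data.frame with columns animal, sire, dam.
#' @return symmetric matrix with animal ids as dimnames.
#' @export
pedigree_a_matrix <- function(pedigree) {
  ped <- pedigree
  ids <- ped$animal
  n <- length(ids)
  sire <- match(ped$sire, ids)
  dam <- match(ped$dam, ids)
  # topological order: parents first
  depth <- rep(0L, n)
  repeat {
    nd <- pmax(ifelse(is.na(sire), 0L, depth[sire] + 1L),
               ifelse(is.na(dam), 0L, depth[dam] + 1L))
    if (all(nd == depth)) break
    if (max(nd) > n) stop("pedigree contains a cycle")
    depth <- nd
  }
  ord <- order(depth)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in ord) {
    s <- sire[i]; d <- dam[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
    for (j in ord) {
      if (j == i) break
      aij <- (if (!is.na(s)) A[j, s] else 0) / 2 +
        (if (!is.na(d)) A[j, d] else 0) / 2
      A[i, j] <- A[j, i] <- aij
    }
  }
  A
}

#' Pedigree verification against the genomic relationship matrix
#'
#' Compares pedigree (A) and genomic (G) relationship coefficients for
#' every animal pair; a pair is inconsistent when
#' `|A_ij - G_ij| > diff_threshold` and an animal is flagged when it
#' participates in at least `min_flags` inconsistencies (the diagonal is
#' never compared).
#'
#' @param pedigree data.frame with columns animal, sire, dam covering every
#'   animal in `G`.
#' @param G genomic relationship matrix with animal dimnames.
#' @param diff_threshold pairwise |A - G| tolerance.
#' @param min_flags inconsistency count at which an animal is flagged.
#' @return list with `flagged` (animal ids), `n_inconsistencies` (named
#'   counts) and `pairs` (data.frame of inconsistent pairs).
#' @export
pedigree_check <- function(pedigree, G, diff_threshold = 0.25,
                           min_flags = 2L) {
  ids <- rownames(G)
  if (!all(ids %in% pedigree$animal))
    stop("animals in G missing from pedigree: ",
         paste(setdiff(ids, pedigree$animal), collapse = ", "))
  A <- pedigree_a_matrix(pedigree)[ids, ids]
  diff <- abs(A - G)
  diag(diff) <- 0
  bad <- which(diff > diff_threshold & upper.tri(diff), arr.ind = TRUE)
  counts <- stats::setNames(rep(0L, length(ids)), ids)
  if (nrow(bad)) {
    tab <- table(c(ids[bad[, 1L]], ids[bad[, 2L]]))
    counts[names(tab)] <- as.integer(tab)
  }
  list(flagged = names(counts)[counts >= min_flags],
       n_inconsistencies = counts,
       pairs = data.frame(a = ids[bad[, 1L]], b = ids[bad[, 2L]],
                          A = A[bad], G = G[bad],
                          stringsAsFactors = FALSE))
}

#' Case-control association by per-SNP linear regression
#'
#' Ordinary least squares of the 0/1 phenotype on allele dosage with an
#' intercept, per SNP over pairwise-complete samples; the p-value comes
#' from the slope's t statistic.  Monomorphic SNPs (among the used samples)
#' are omitted.  Bonferroni and Benjamini-Hochberg adjusted p-values are
#' included.  P-values are floored at the smallest positive double, with
#' the corresponding capped `neg_log10_p`.
#'
#' @param geno samples x sites dosage matrix.
#' @param phenotype numeric 0/1 vector aligned with rows of `geno`.
#' @param map optional data.frame (chrom, pos) describing columns of
#'   `geno`; included in the result when given.
#' @return data.frame of class `assoc_result`: site, beta, p, neg_log10_p,
#'   p_bonf, p_bh, n_used.
#' @export
assoc_linear <- function(geno, phenotype, map = NULL) {
  stopifnot(nrow(geno) == length(phenotype))
  if (!all(stats::na.omit(phenotype) %in% 0:1))
    stop("phenotype must be coded 0/1")
  m <- ncol(geno)
  ok_y <- !is.na(phenotype)
  beta <- p <- rep(NA_real_, m)
  n_used <- integer(m)
  y_all <- phenotype
  for (j in seq_len(m)) {
    ok <- ok_y & !is.na(geno[, j])
    n <- sum(ok)
    n_used[j] <- n
    if (n < 3L) next
    x <- geno[ok, j]; y <- y_all[ok]
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) next
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    res <- y - mean(y) - b * (x - mean(x))
    rss <- sum(res^2)
    se <- sqrt(rss / (n - 2) / sxx)
    tt <- if (se > 0) b / se else Inf
    beta[j] <- b
    p[j] <- if (is.infinite(tt)) 0 else 2 * stats::pt(-abs(tt), n - 2)
  }
  keep <- !is.na(p)
  p <- pmax(p, .Machine$double.xmin)
  out <- data.frame(snp = seq_len(m)[keep])
  if (!is.null(map)) {
    out$chrom <- map$chrom[keep]
    out$pos <- map$pos[keep]
  }
  out$beta <- beta[keep]
  out$p <- p[keep]
  out$neg_log10_p <- -log10(p[keep])
  out$p_bonf <- pmin(p[keep] * sum(keep), 1)
  out$p_bh <- stats::p.adjust(p[keep], method = "BH")
  out$n_used <- n_used[keep]
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Chromosome-specific critical intervals
#'
#' For each chromosome, the threshold is the p-value of the
#' `ceiling(top_frac * n_chrom_snps)`-th most significant SNP; the critical
#' interval spans the minimum to maximum position of SNPs at or below that
#' threshold, with the peak at the most significant SNP.  A chromosome is
#' reported only when its peak passes a Bonferroni correction over all
#' tested SNPs at `genomewide_alpha`.
#'
#' @param results an `assoc_result` with chrom/pos columns.
#' @param top_frac fraction of a chromosome's SNPs defining the threshold.
#' @param genomewide_alpha genome-wide significance level for the
#'   reporting gate.
#' @return data.frame of intervals: chrom, start, stop, peak, peak_p,
#'   threshold, n_snps.
#' @export
critical_intervals <- function(results, top_frac = 0.005,
                               genomewide_alpha = 0.05) {
  if (!nrow(results)) stop("empty association results")
  if (is.null(results$chrom)) stop("results need chrom/pos columns")
  bonf <- genomewide_alpha / nrow(results)
  out <- list()
  for (ch in unique(results$chrom)) {
    r <- results[results$chrom == ch, ]
    peak_i <- which.min(r$p)
    if (r$p[peak_i] > bonf) next
    n_top <- ceiling(top_frac * nrow(r))
    thr <- sort(r$p)[n_top]
    sel <- r[r$p <= thr, ]
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = min(sel$pos), stop = max(sel$pos),
      peak = r$pos[peak_i], peak_p = r$p[peak_i], threshold = thr,
      n_snps = nrow(sel), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      stop = integer(), peak = integer(),
                      peak_p = numeric(), threshold = numeric(),
                      n_snps = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
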