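#' Windowed nucleotide diversity
#'
#' Per-site diversity is the unbiased heterozygosity
#' `pi_i = c (n - c) / (n (n - 1) / 2)` with `c` the alt-allele count among
#' the `n` called alleles of the population's samples; a window's value is
#' the sum of its per-site values divided by the full window length in bp
#' (monomorphic and missing sites contribute zero), over sliding windows of
#' `window_bp` advancing by `step_bp` along each chromosome.
#'
#' @param table a [variant_table()].
#' @param pop character vector of sample ids forming the population.
#' @param window_bp window length (bp).
#' @param step_bp step between window starts (bp); must not exceed
#'   `window_bp`.
#' @return data.frame of window statistics: chrom, start, end, value
#'   (per-bp diversity), n_variants.
#' @export
windowed_pi <- function(table, pop, window_bp = 20000, step_bp = 10000) {
  stopifnot(inherits(table, "variant_table"))
  if (step_bp > window_bp) stop("step_bp must not exceed window_bp")
  if (!length(pop) || !all(pop %in% table$samples))
    stop("pop must be a non-empty subset of the table samples")
  gt <- table$gt[, pop, drop = FALSE]
  n_alleles <- 2L * rowSums(!is.na(gt))
  c_alt <- rowSums(gt, na.rm = TRUE)
  pi_site <- ifelse(n_alleles >= 2L,
                    c_alt * (n_alleles - c_alt) /
                      (n_alleles * (n_alleles - 1) / 2),
                    0)
  out <- list()
  for (ch in unique(table$sites$chrom)) {
    idx <- which(table$sites$chrom == ch)
    pos <- table$sites$pos[idx]
    last <- max(pos)
    starts <- seq(1L, max(1L, last), by = step_bp)
    for (st in starts) {
      en <- st + window_bp - 1L
      inw <- idx[pos >= st & pos <= en]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = st, end = en,
        value = sum(pi_site[inw]) / window_bp,
        n_variants = length(inw), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Reference-allele-frequency comparison between populations
#'
#' Builds the 2-D histogram of per-SNP reference-allele frequencies for two
#' populations over their shared sites and reports both the Pearson
#' correlation and its square.
#'
#' @param freq_a,freq_b data.frames with columns chrom, pos, raf (per-SNP
#'   reference allele frequency in each population); see [raf_table()].
#' @param n_bins number of frequency bins per axis.
#' @return list with `bins` (n_bins x n_bins count matrix), `r` and `r2`.
#' @export
raf_correlation <- function(freq_a, freq_b, n_bins = 20) {
  ka <- paste(freq_a$chrom, freq_a$pos)
  kb <- paste(freq_b$chrom, freq_b$pos)
  common <- intersect(ka, kb)
  if (!length(common)) stop("no shared sites")
  x <- freq_a$raf[match(common, ka)]
  y <- freq_b$raf[match(common, kb)]
  br <- seq(0, 1, length.out = n_bins + 1L)
  bx <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L), n_bins)
  by <- pmin(pmax(findInterval(y, br, rightmost.closed = TRUE), 1L), n_bins)
  bins <- matrix(0L, n_bins, n_bins)
  for (i in seq_along(bx)) bins[bx[i], by[i]] <- bins[bx[i], by[i]] + 1L
  r <- if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else NA_real_
  list(bins = bins, r = r, r2 = r^2, n_sites = length(common))
}

#' Per-population reference allele frequencies
#'
#' @param table a [variant_table()].
#' @param pop sample ids of the population.
#' @return data.frame chrom, pos, raf (frequency of the reference-assembly
#'   allele among called genotypes).
#' @export
raf_table <- function(table, pop) {
  gt <- table$gt[, pop, drop = FALSE]
  n_alleles <- 2L * rowSums(!is.na(gt))
  alt <- rowSums(gt, na.rm = TRUE)
  data.frame(chrom = table$sites$chrom, pos = table$sites$pos,
             raf = ifelse(n_alleles > 0, 1 - alt / n_alleles, NA_real_),
             stringsAsFactors = FALSE)
}

#' Weir-Cockerham F_ST between two populations
#'
#' Computes the per-site Weir & Cockerham (1984) two-population estimator
#' `theta = a / (a + b + c)` from the variance components calculated from
#' sample sizes, allele frequencies and observed heterozygosities, then
#' summarises as the unweighted mean of per-site estimates with its sample
#' standard error.  A site contributes only if both populations have at
#' least two called diploid samples and the estimator's denominator is
#' defined (monomorphic sites are excluded).  The ratio-of-sums estimator
#' (sum of `a` over sum of `a + b + c`) is also reported.
#'
#' @param table a [variant_table()].
#' @param pop_a,pop_b sample id vectors; each needs >= 2 samples.
#' @return list with `per_site` (data.frame chrom, pos, theta), `mean`,
#'   `se` and `ratio_of_sums`.
#' @export
wc_fst <- function(table, pop_a, pop_b) {
  stopifnot(inherits(table, "variant_table"))
  if (length(pop_a) < 2L || length(pop_b) < 2L)
    stop("each population needs at least 2 samples")
  ga <- table$gt[, pop_a, drop = FALSE]
  gb <- table$gt[, pop_b, drop = FALSE]
  comp <- wc_components(ga, gb)
  denom <- comp$a + comp$b + comp$c
  ok <- comp$usable & !is.na(denom) & denom != 0
  theta <- ifelse(ok, comp$a / denom, NA_real_)
  vals <- theta[ok]
  list(per_site = data.frame(chrom = table$sites$chrom,
                             pos = table$sites$pos, theta = theta,
                             stringsAsFactors = FALSE),
       mean = mean(vals),
       se = stats::sd(vals) / sqrt(length(vals)),
       ratio_of_sums = sum(comp$a[ok]) / sum(denom[ok]),
       n_sites = sum(ok))
}

# Weir & Cockerham (1984) variance components for two populations, per
# site, from dosage matrices (sites x samples).
wc_components <- function(ga, gb) {
  n1 <- rowSums(!is.na(ga)); n2 <- rowSums(!is.na(gb))
  p1 <- rowSums(ga, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(gb, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(ga == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(gb == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  usable <- n1 >= 2L & n2 >= 2L & poly
  list(a = a, b = b, c = cc, usable = usable)
}

#' Neighbor-joining dendrogram from a pairwise F_ST matrix
#'
#' @param fst_matrix symmetric non-negative matrix of pairwise mean F_ST
#'   with population names as dimnames; >= 3 populations.
#' @return an [ape::phylo] tree (via [nj_tree()]).
#' @export
fst_dendrogram <- function(fst_matrix) {
  if (!isSymmetric(unname(as.matrix(fst_matrix)), tol = 1e-12))
    stop("F_ST matrix must be symmetric")
  if (any(fst_matrix < 0)) stop("F_ST matrix must be non-negative")
  nj_tree(as.matrix(fst_matrix))
}

#' Composite linkage disequilibrium r-squared between two sites
#'
#' Squared Pearson correlation of 0/1/2 dosage vectors over the
#' pairwise-complete samples (composite LD, appropriate for unphased
#' genotypes).
#'
#' @param dosage_x,dosage_y equal-length dosage vectors (`NA` missing).
#' @return r-squared, a single number.
#' @export
ld_r2 <- function(dosage_x, dosage_y) {
  if (length(dosage_x) != length(dosage_y))
    stop("dosage vectors must have equal length")
  ok <- !is.na(dosage_x) & !is.na(dosage_y)
  if (sum(ok) < 2L) stop("need at least 2 pairwise-complete samples")
  x <- dosage_x[ok]; y <- dosage_y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("r2 undefined: site monomorphic among compared samples")
  stats::cor(x, y)^2
}

#' Greedy LD-based SNP pruning
#'
#' Within sliding windows of `window_snps` sites advancing by `step_snps`,
#' repeatedly removes the later site of the currently worst pair while any
#' kept pair exceeds `r2_max`.
#'
#' @param geno samples x sites dosage matrix with sites in genomic order.
#' @param window_snps window size in SNPs (>= 2).
#' @param step_snps advance between windows in SNPs.
#' @param r2_max maximum tolerated pairwise r-squared.
#' @return integer vector of kept site (column) indices.
#' @export
ld_prune <- function(geno, window_snps = 500, step_snps = 5, r2_max = 0.3) {
  if (window_snps < 2L) stop("window must cover at least 2 SNPs")
  m <- ncol(geno)
  keep <- rep(TRUE, m)
  st <- 1L
  while (st <= m) {
    en <- min(st + window_snps - 1L, m)
    idx <- which(keep[st:en]) + st - 1L
    if (length(idx) >= 2L) {
      sub <- geno[, idx, drop = FALSE]
      sds <- apply(sub, 2L, stats::sd, na.rm = TRUE)
      poly <- sds > 0
      r2 <- matrix(0, length(idx), length(idx))
      if (sum(poly) >= 2L) {
        cc <- suppressWarnings(
          stats::cor(sub[, poly, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        cc[is.na(cc)] <- 0
        r2[poly, poly] <- cc
      }
      diag(r2) <- 0
      alive <- rep(TRUE, length(idx))
      repeat {
        r2a <- r2
        r2a[!alive, ] <- 0; r2a[, !alive] <- 0
        w <- which(r2a == max(r2a), arr.ind = TRUE)
        if (max(r2a) <= r2_max) break
        # drop the later (higher-index) member of the worst pair
        pair <- w[1L, ]
        alive[max(pair)] <- FALSE
      }
      keep[idx[!alive]] <- FALSE
    }
    if (en == m) break
    st <- st + step_snps
  }
  which(keep)
}

#' PCA of pairwise allele-sharing distance
#'
#' Computes the allele-sharing distance `D_ij = mean(|g_i - g_j| / 2)` over
#' sites (pairwise-complete), then classical multidimensional scaling
#' (double-centred `-D^2 / 2`, eigendecomposition); variance fractions are
#' eigenvalues over the sum of positive eigenvalues.
#'
#' @param geno samples x sites dosage matrix (ideally LD-pruned).
#' @param n_components number of axes to return (truncated to the number of
#'   available dimensions).
#' @return list with `coords` (samples x components), `var_frac`, and `dist`
#'   (the distance matrix).
#' @export
pca_distance <- function(geno, n_components = 10) {
  n <- nrow(geno)
  if (n < 3L) stop("need at least 3 samples")
  k <- min(n_components, n - 1L)
  D <- as.matrix(stats::dist(geno / 2, method = "manhattan")) / ncol(geno)
  mds <- stats::cmdscale(D, k = k, eig = TRUE)
  pos <- mds$eig[mds$eig > 0]
  got <- ncol(mds$points)
  var_frac <- mds$eig[seq_len(got)] / sum(pos)
  rownames(mds$points) <- rownames(geno)
  list(coords = mds$points, var_frac = var_frac, dist = D)
}
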