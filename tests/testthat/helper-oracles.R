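# Independent oracles and small fixture builders used across the suite.

# ---- Weir & Cockerham (1984) brute-force oracle -------------------------
# Independent transcription of the two-allele, r-population variance
# components, computed per site from genotype vectors via explicit loops
# (deliberately structured differently from the package implementation).
oracle_wc_theta <- function(g_pops) {
  r <- length(g_pops)
  n <- sapply(g_pops, function(g) sum(!is.na(g)))
  p <- sapply(g_pops, function(g) sum(g, na.rm = TRUE) / (2 * sum(!is.na(g))))
  h <- sapply(g_pops, function(g) mean(g[!is.na(g)] == 1))
  nbar <- mean(n)
  CV2_num <- sum(n^2)
  nc <- (r * nbar - CV2_num / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# ---- exhaustive 4-taxon least-squares oracle ----------------------------
# Enumerates the three unrooted quartet topologies, fits the five branch
# lengths of each by ordinary least squares against the six pairwise
# distances, and returns the best topology with its fitted lengths.
oracle_quartet <- function(d) {
  stopifnot(nrow(d) == 4L)
  labs <- rownames(d)
  tops <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  best <- NULL
  for (tp in tops) {
    A <- tp[1]; B <- tp[2]; C <- tp[3]; D <- tp[4]
    # unknowns: a, b, c, dd, e for topology AB|CD
    X <- rbind(c(1, 1, 0, 0, 0),   # d(A,B)
               c(0, 0, 1, 1, 0),   # d(C,D)
               c(1, 0, 1, 0, 1),   # d(A,C)
               c(1, 0, 0, 1, 1),   # d(A,D)
               c(0, 1, 1, 0, 1),   # d(B,C)
               c(0, 1, 0, 1, 1))   # d(B,D)
    y <- c(d[A, B], d[C, D], d[A, C], d[A, D], d[B, C], d[B, D])
    beta <- solve(crossprod(X), crossprod(X, y))
    rss <- sum((y - X %*% beta)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss,
                   cherry1 = sort(labs[c(A, B)]),
                   cherry2 = sort(labs[c(C, D)]),
                   lengths = stats::setNames(
                     as.numeric(beta),
                     c(labs[A], labs[B], labs[C], labs[D], "internal")))
    }
  }
  best
}

# splits of a phylo as canonical keys (re-derived here so tests do not
# depend on package internals)
oracle_tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ntip <- length(tips)
  keys <- character(0)
  for (node in unique(tree$edge[tree$edge[, 2] > ntip, 2])) {
    clade <- ape::extract.clade(tree, node)$tip.label
    side <- if (tips[1] %in% clade) setdiff(tips, clade) else clade
    if (length(side) >= 2 && length(side) <= ntip - 2)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  sort(unique(keys))
}

# ---- fixture builders ---------------------------------------------------

# minimal variant table from a dosage matrix (sites x samples)
toy_table <- function(gt, chrom = "chr1", pos = NULL, mq = 60,
                      dp_val = 20L) {
  m <- nrow(gt); n <- ncol(gt)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  samples <- colnames(gt)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(n))
  dp <- matrix(dp_val, m, n)
  dp[is.na(gt)] <- 0L
  ad_alt <- matrix(0L, m, n)
  ad_alt[!is.na(gt) & gt == 1L] <- dp_val %/% 2L
  ad_alt[!is.na(gt) & gt == 2L] <- dp_val
  ad_ref <- dp - ad_alt
  sites <- data.frame(chrom = rep_len(chrom, m), pos = pos,
                      ref = rep("A", m), alt = rep("G", m),
                      mq = rep_len(mq, m), stringsAsFactors = FALSE)
  variant_table(sites, samples, gt, ad_ref, ad_alt, dp)
}

# haplotype matrix with two planted groups: n1 + n2 males over m sites,
# groups differing at exactly `n_diff` sites, plus independent per-site
# allele flips at rate eps within each male
toy_haplogroups <- function(n1 = 6, n2 = 6, m = 60, n_diff = 47,
                            eps = 0.05) {
  males <- c(sprintf("g1_%02d", seq_len(n1)), sprintf("g2_%02d", seq_len(n2)))
  core1 <- sample(c(0L, 1L), m, replace = TRUE)
  flip_sites <- sample.int(m, n_diff)
  core2 <- core1
  core2[flip_sites] <- 1L - core2[flip_sites]
  take <- function(core) {
    mut <- stats::runif(m) < eps
    ifelse(mut, 1L - core, core)
  }
  hap <- rbind(t(vapply(seq_len(n1), function(i) take(core1), integer(m))),
               t(vapply(seq_len(n2), function(i) take(core2), integer(m))))
  alleles <- matrix(c("A", "G")[hap + 1L], nrow = n1 + n2,
                    dimnames = list(males, NULL))
  structure(list(males = males,
                 sites = data.frame(chrom = "sdY", pos = seq_len(m) * 10L,
                                    ref = "A", alt = "G",
                                    stringsAsFactors = FALSE),
                 alleles = alleles, n_het_flagged = 0L),
            class = "haplotype_matrix")
}

# single-population config used by several recovery tests
tas_only_config <- function(seed, n = 200L, ...) {
  sim_config(pop_sizes = stats::setNames(c(n, 0L, 0L), c("TAS", "NA", "EU")),
             n_dh_females = 0L, n_artifact_sites = 0L, seed = seed, ...)
}

# config with all homeolog pairs at the given rho / mirror fraction
rho_config <- function(seed, rho, fraction = 0.5, n = 300L, ...) {
  hp <- sim_config()$homeolog_pairs
  for (i in seq_along(hp)) {
    hp[[i]]$rho <- rho
    hp[[i]]$fraction <- fraction
  }
  sim_config(pop_sizes = stats::setNames(c(n, 0L, 0L), c("TAS", "NA", "EU")),
             n_dh_females = 0L, n_artifact_sites = 0L,
             homeolog_pairs = hp, seed = seed, ...)
}
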