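test_that("windowed diversity matches the per-site formula", {
  # one site, 10 called alleles, 5 alt: pi = (5*5/45)/20000
  gt <- matrix(1L, nrow = 1, ncol = 5)
  vt <- toy_table(gt, pos = 5000L)
  res <- windowed_pi(vt, vt$samples, window_bp = 20000, step_bp = 20000)
  expect_equal(res$value[1], (25 / 45) / 20000, tolerance = 1e-12)
  # fixed-alt site contributes zero
  vt2 <- toy_table(matrix(2L, nrow = 1, ncol = 5), pos = 5000L)
  res2 <- windowed_pi(vt2, vt2$samples, 20000, 20000)
  expect_equal(res2$value[1], 0)
  # empty window reports zero with no variants
  vt3 <- toy_table(matrix(1L, nrow = 1, ncol = 5), pos = 30001L)
  res3 <- windowed_pi(vt3, vt3$samples, 20000, 10000)
  expect_equal(res3$value[res3$start == 1], 0)
  expect_equal(res3$n_variants[res3$start == 1], 0L)
  expect_error(windowed_pi(vt, vt$samples, 10000, 20000), "step")
  # invariance to sample order; 1/window scaling
  cfg <- tas_only_config(seed = 31L, n = 20L)
  pop <- simulate_population(cfg)
  vt4 <- simulate_variant_table(cfg, pop)
  ids <- pop$samples$animal
  a <- windowed_pi(vt4, ids, 20000, 10000)
  b <- windowed_pi(vt4, rev(ids), 20000, 10000)
  expect_equal(a$value, b$value)
  w1 <- windowed_pi(vt4, ids, 50000, 50000)
  w2 <- windowed_pi(vt4, ids, 100000, 100000)
  expect_equal(sum(w1$value * 50000), sum(w2$value * 100000),
               tolerance = 1e-9)
})

test_that("reference-allele-frequency comparison behaves at the extremes", {
  set.seed(1)
  f <- data.frame(chrom = "chr1", pos = seq_len(5000) * 10L,
                  raf = runif(5000))
  same <- raf_correlation(f, f)
  expect_equal(same$r2, 1)
  expect_true(all(same$bins[upper.tri(same$bins) | lower.tri(same$bins)] == 0L))
  g <- f; g$raf <- runif(5000)
  indep <- raf_correlation(f, g)
  expect_lt(indep$r2, 0.02)
  anti <- f; anti$raf <- 1 - f$raf
  ac <- raf_correlation(f, anti)
  expect_equal(ac$r2, 1)
  expect_equal(ac$r, -1)
  expect_error(raf_correlation(f, data.frame(chrom = "chr9", pos = 1L,
                                             raf = 0.5)), "shared")
})

test_that("Weir-Cockerham estimator agrees with its textbook limits", {
  # populations fixed for different alleles, no hets -> theta = 1
  gt <- cbind(matrix(0L, 1, 6), matrix(2L, 1, 6))
  vt <- toy_table(gt)
  fst <- wc_fst(vt, vt$samples[1:6], vt$samples[7:12])
  expect_equal(fst$per_site$theta[1], 1)
  # same allele frequencies and het rates at large n -> mean near 0
  set.seed(2)
  p <- runif(2000, 0.1, 0.9)
  g1 <- matrix(rbinom(2000 * 60, 2, p), nrow = 2000)
  g2 <- matrix(rbinom(2000 * 60, 2, p), nrow = 2000)
  vt2 <- toy_table(cbind(g1, g2))
  fst2 <- wc_fst(vt2, vt2$samples[1:60], vt2$samples[61:120])
  expect_lt(abs(fst2$mean), 0.01)
  # monomorphic sites are excluded
  gt3 <- rbind(cbind(matrix(0L, 1, 4), matrix(0L, 1, 4)),
               cbind(matrix(1L, 1, 4), matrix(0L, 1, 4)))
  vt3 <- toy_table(gt3)
  fst3 <- wc_fst(vt3, vt3$samples[1:4], vt3$samples[5:8])
  expect_true(is.na(fst3$per_site$theta[1]))
  expect_equal(fst3$n_sites, 1L)
  expect_error(wc_fst(vt3, vt3$samples[1], vt3$samples[5:8]), "at least 2")
})

test_that("theta is invariant to population label and allele swaps", {
  set.seed(3)
  g1 <- matrix(rbinom(200 * 10, 2, 0.3), nrow = 200)
  g2 <- matrix(rbinom(200 * 10, 2, 0.6), nrow = 200)
  vt <- toy_table(cbind(g1, g2))
  a <- wc_fst(vt, vt$samples[1:10], vt$samples[11:20])
  b <- wc_fst(vt, vt$samples[11:20], vt$samples[1:10])
  expect_equal(a$per_site$theta, b$per_site$theta, tolerance = 1e-12)
  # ref/alt relabelling: dosage -> 2 - dosage
  vt2 <- toy_table(2L - cbind(g1, g2))
  c_ <- wc_fst(vt2, vt2$samples[1:10], vt2$samples[11:20])
  expect_equal(a$per_site$theta, c_$per_site$theta, tolerance = 1e-12)
})

test_that("F_ST dendrogram solves the three-point equations", {
  d <- matrix(c(0, 0.041, 0.178,
                0.041, 0, 0.172,
                0.178, 0.172, 0), nrow = 3,
              dimnames = list(c("TAS", "NA", "EU"), c("TAS", "NA", "EU")))
  tree <- fst_dendrogram(d)
  bl <- stats::setNames(tree$edge.length,
                        tree$tip.label[tree$edge[, 2]])
  expect_equal(unname(bl["TAS"]), (0.041 + 0.178 - 0.172) / 2,
               tolerance = 1e-10)
  expect_equal(unname(bl["NA"]), (0.041 + 0.172 - 0.178) / 2,
               tolerance = 1e-10)
  expect_equal(unname(bl["EU"]), (0.178 + 0.172 - 0.041) / 2,
               tolerance = 1e-10)
  expect_error(fst_dendrogram(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  # zero matrix -> star tree with zero lengths
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tz <- fst_dendrogram(z)
  expect_true(all(tz$edge.length == 0))
})

test_that("dosage r2 matches expectations at the extremes and under the null", {
  x <- c(0, 0, 1, 1, 2, 2)
  expect_equal(ld_r2(x, x), 1)
  expect_equal(ld_r2(x, rev(x)), 1)       # perfect negative correlation
  set.seed(4)
  a <- rbinom(1000, 2, 0.5); b <- rbinom(1000, 2, 0.5)
  expect_lt(ld_r2(a, b), 0.02)
  expect_error(ld_r2(rep(1, 6), x), "monomorphic")
  expect_error(ld_r2(x[1:3], x), "equal length")
})

test_that("LD pruning removes mirrored duplicates and spares independents", {
  set.seed(5)
  indep <- matrix(rbinom(50 * 40, 2, 0.5), nrow = 50)
  expect_equal(ld_prune(indep, window_snps = 40, step_snps = 5),
               seq_len(40))
  # duplicated adjacent site: exactly one survives
  dup <- cbind(indep[, 1], indep)
  kept <- ld_prune(dup, window_snps = 41, step_snps = 5)
  expect_equal(sum(kept %in% c(1L, 2L)), 1L)
  expect_error(ld_prune(indep, window_snps = 1), "window")
  # mirrored homeolog sites (rho = 1) lose one of each pair
  cfg <- rho_config(seed = 32L, rho = 1, fraction = 1, n = 60L,
                    snp_spacing_bp = 5000L)
  pop <- simulate_population(cfg)
  mp <- pop$truth$mirrored_site_pairs
  key <- paste(pop$map$chrom, pop$map$pos)
  ia <- match(paste(mp$chrom_a, mp$pos_a), key)
  ib <- match(paste(mp$chrom_b, mp$pos_b), key)
  # monomorphic pairs carry no LD signal; restrict to polymorphic ones
  poly <- apply(pop$geno[, ia, drop = FALSE], 2, stats::sd) > 0
  ia <- ia[poly]; ib <- ib[poly]
  sub <- pop$geno[, c(ia, ib)]
  kept2 <- ld_prune(sub, window_snps = ncol(sub), step_snps = 5)
  npairs <- length(ia)
  both_kept <- sum(kept2 <= npairs & (kept2 + npairs) %in% kept2)
  expect_equal(both_kept, 0L)
})

test_that("distance PCA separates drifted populations and ranks axes", {
  cfg <- sim_config(pop_sizes = stats::setNames(c(25L, 0L, 25L),
                                                c("TAS", "NA", "EU")),
                    fst_drift = stats::setNames(c(0.05, 0.05, 0.25),
                                                c("TAS", "NA", "EU")),
                    n_dh_females = 0L, n_artifact_sites = 0L, seed = 33L)
  pop <- simulate_population(cfg)
  res <- pca_distance(pop$geno, n_components = 4)
  labels <- pop$samples$population
  pc1 <- res$coords[, 1]
  expect_true(max(pc1[labels == "TAS"]) < min(pc1[labels == "EU"]) ||
                min(pc1[labels == "TAS"]) > max(pc1[labels == "EU"]))
  expect_lte(sum(res$var_frac), 1 + 1e-9)
  # duplicated sample: zero distance, identical coordinates
  geno2 <- rbind(pop$geno, dup = pop$geno[1, ])
  res2 <- pca_distance(geno2, n_components = 3)
  expect_equal(res2$dist[1, nrow(geno2)], 0)
  expect_equal(res2$coords[1, ], res2$coords[nrow(geno2), ],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pca_distance(pop$geno[1:2, ]), "3 samples")
})
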