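test_that("config validation rejects inconsistent geometry and rates", {
  expect_error(sim_config(msr_interval = c(2001L, 30000L)),
               "shorter than msr_interval")
  expect_error(sim_config(lineage_proportions = c("SL-02" = 0.5,
                                                  "SL-03" = 0.2,
                                                  "SL-06" = 0.2)),
               "sum to 1")
  expect_error(sim_config(psex_discordance_rate = 1.5), "rates")
  hp <- list(list(a = list(chrom = "chr1", start = 1L, end = 100L),
                  b = list(chrom = "chr1", start = 200L, end = 300L),
                  rho = 0.9, fraction = 0.5))
  expect_error(sim_config(homeolog_pairs = hp), "non-syntenic")
})

test_that("reference has one sequence per chromosome plus the sdY contig", {
  cfg <- sim_config(n_chromosomes = 3L, chrom_length_bp = 5000L,
                    sdy_contig_length_bp = 20000L)
  ref <- build_reference(cfg)
  expect_length(ref, 4L)
  expect_equal(names(ref)[4], "sdY")
  expect_equal(Biostrings::width(ref), c(5000L, 5000L, 5000L, 20000L))
})

test_that("generator outputs are byte-identical under the same seed", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length_bp = 20000L,
                    pop_sizes = stats::setNames(c(10L, 0L, 0L),
                                                c("TAS", "NA", "EU")),
                    sd_loci = list(
                      list(chrom = "chr1", pos = 5000L, lineage = "SL-02"),
                      list(chrom = "chr2", pos = 5000L, lineage = "SL-03"),
                      list(chrom = "chr2", pos = 15000L, lineage = "SL-06")),
                    homeolog_pairs = list(
                      list(a = list(chrom = "chr1", start = 1L, end = 10000L),
                           b = list(chrom = "chr2", start = 1L, end = 10000L),
                           rho = 0.9, fraction = 0.5)),
                    seed = 42L)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_reference(build_reference(cfg), f1)
  write_reference(build_reference(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$geno, p2$geno)
  expect_identical(p1$samples, p2$samples)
  a1 <- simulate_alignments(cfg, p1$truth)
  a2 <- simulate_alignments(cfg, p2$truth)
  expect_identical(a1$records, a2$records)
  v1 <- simulate_variant_table(cfg, p1)
  v2 <- simulate_variant_table(cfg, p2)
  expect_identical(v1$gt, v2$gt)
  expect_identical(v1$ad_alt, v2$ad_alt)
})

test_that("population model honours discordance and mirroring contracts", {
  # zero discordance: PSEX equals GSEX everywhere
  cfg0 <- tas_only_config(seed = 3L, n = 50L, psex_discordance_rate = 0)
  pop0 <- simulate_population(cfg0)
  expect_identical(pop0$samples$PSEX, pop0$samples$GSEX)
  # rho = 1, fraction = 1: mirrored partner sites are identical vectors
  cfg1 <- rho_config(seed = 4L, rho = 1, fraction = 1, n = 50L)
  pop1 <- simulate_population(cfg1)
  mp <- pop1$truth$mirrored_site_pairs
  expect_gt(nrow(mp), 0L)
  for (k in sample(nrow(mp), 10L)) {
    ja <- which(pop1$map$chrom == mp$chrom_a[k] & pop1$map$pos == mp$pos_a[k])
    jb <- which(pop1$map$chrom == mp$chrom_b[k] & pop1$map$pos == mp$pos_b[k])
    expect_identical(pop1$geno[, ja], pop1$geno[, jb])
  }
  # default discordance rate: PSEX/GSEX concordance near 98%
  cfg2 <- tas_only_config(seed = 5L, n = 2000L, snp_spacing_bp = 50000L)
  pop2 <- simulate_population(cfg2)
  conc <- mean(pop2$samples$PSEX == pop2$samples$GSEX)
  expect_gt(conc, 0.96); expect_lt(conc, 0.995)
})

test_that("zero-drift populations show near-zero Weir-Cockerham divergence", {
  cfg <- sim_config(pop_sizes = stats::setNames(c(150L, 150L, 0L),
                                                c("TAS", "NA", "EU")),
                    fst_drift = stats::setNames(c(0, 0, 0.17),
                                                c("TAS", "NA", "EU")),
                    n_dh_females = 0L, n_artifact_sites = 0L, seed = 6L)
  pop <- simulate_population(cfg)
  vt <- simulate_variant_table(cfg, pop)
  tas <- pop$samples$animal[pop$samples$population == "TAS"]
  na_ <- pop$samples$animal[pop$samples$population == "NA"]
  fst <- wc_fst(vt, tas, na_)
  expect_lt(abs(fst$mean), 0.005)
})

test_that("alignment architecture separates the three sex lineages", {
  cfg <- sim_config(seed = 8L)
  pop <- simulate_population(cfg)
  aln <- simulate_alignments(cfg, pop$truth)
  msr <- cfg$msr_interval
  gsex <- pop$truth$per_sample_gsex
  ids <- unique(aln$records$sample)
  r <- aln$records
  for (id in ids[gsex[ids] == "F"]) {
    rs <- r[r$sample == id & r$contig == "sdY", ]
    both_in <- rs$pos >= msr[1] & (rs$pos + rs$len - 1) <= msr[2] &
      rs$mate_contig == "sdY" & rs$mate_pos >= msr[1] & rs$mate_pos <= msr[2]
    expect_equal(sum(both_in), 0L)
  }
  for (id in ids[gsex[ids] == "M"]) {
    lin <- pop$truth$lineage_by_male[[id]]
    rs <- r[r$sample == id & r$contig == "sdY", ]
    spanning <- rs$strand == "+" & rs$proper & rs$pos <= msr[2] &
      rs$mate_contig == "sdY" & rs$mate_pos > msr[2]
    orph <- rs$mate_contig != "sdY" & rs$pos >= msr[2] - 2000L &
      rs$pos <= msr[2]
    if (lin == "SL-02") {
      expect_gte(sum(spanning), 1L)
    } else {
      expect_equal(sum(spanning), 0L)
      anchor <- pop$truth$true_sd_loci
      lin_chrom <- anchor$chrom[anchor$lineage == lin]
      expect_gte(sum(orph & rs$mate_contig == lin_chrom), 2L)
    }
  }
})

test_that("variant table depth and call structure follow sex and region", {
  cfg <- sim_config(seed = 9L, seq_error_rate = 0)
  pop <- simulate_population(cfg)
  vt <- simulate_variant_table(cfg, pop)
  msr_rows <- which(vt$sites$chrom == "sdY" &
                      vt$sites$pos >= cfg$msr_interval[1] &
                      vt$sites$pos <= cfg$msr_interval[2])
  expect_length(msr_rows, cfg$msr_n_snps)
  females <- pop$samples$animal[pop$samples$GSEX == "F"]
  males <- pop$samples$animal[pop$samples$GSEX == "M"]
  expect_true(all(vt$dp[msr_rows, females] == 0L))
  expect_true(all(is.na(vt$gt[msr_rows, females])))
  # error-free male MSR calls have BAF exactly 0 or 1
  baf <- compute_baf(vt, "sdY")
  msr_baf <- baf$baf[baf$sites$pos >= cfg$msr_interval[1] &
                       baf$sites$pos <= cfg$msr_interval[2], males]
  vals <- msr_baf[!is.na(msr_baf)]
  expect_true(all(vals %in% c(0, 1)))
  # planted artifact sites are heterozygous in the double-haploid females
  dh <- pop$samples$animal[pop$samples$dh]
  art <- pop$truth$artifact_sites
  art_rows <- match(paste(art$chrom, art$pos),
                    paste(vt$sites$chrom, vt$sites$pos))
  het_in_dh <- rowSums(vt$gt[art_rows, dh, drop = FALSE] == 1L,
                       na.rm = TRUE)
  expect_true(all(het_in_dh >= 1L))
})

test_that("array export matches the VCF at zero error and the assays track sex", {
  cfg <- tas_only_config(seed = 10L, n = 30L, array_error_rate = 0)
  pop <- simulate_population(cfg)
  arr <- simulate_array_genotypes(cfg, pop)
  expect_identical(arr$geno, pop$geno)
  gsex <- assign_gsex(arr$assays)
  truth_sex <- ifelse(pop$truth$per_sample_gsex == "M", "male", "female")
  expect_identical(unname(gsex), unname(truth_sex[rownames(arr$assays)]))
  # 1% flips at many genotypes: concordance ~ 99%
  cfg2 <- tas_only_config(seed = 11L, n = 60L, array_error_rate = 0.01,
                          snp_spacing_bp = 250L)
  pop2 <- simulate_population(cfg2)
  arr2 <- simulate_array_genotypes(cfg2, pop2)
  conc <- mean(arr2$geno == pop2$geno)
  expect_equal(conc, 0.99, tolerance = 0.003)
})

test_that("truth record round-trips through JSON and validates its schema", {
  cfg <- tas_only_config(seed = 12L, n = 20L)
  pop <- simulate_population(cfg)
  path <- tempfile(fileext = ".json")
  write_truth(pop$truth, path)
  back <- read_truth(path)
  expect_equal(back$junction_pos, pop$truth$junction_pos)
  expect_equal(back$lineage_by_male, pop$truth$lineage_by_male)
  expect_equal(back$per_sample_gsex, pop$truth$per_sample_gsex)
  expect_equal(back$true_sd_loci$pos, pop$truth$true_sd_loci$pos)
  # missing required field -> schema error
  broken <- jsonlite::read_json(path)
  broken$junction_pos <- NULL
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(broken, path2, auto_unbox = TRUE)
  expect_error(read_truth(path2), "missing fields")
})

test_that("SAM and VCF writers round-trip through their readers", {
  cfg <- sim_config(seed = 13L, n_wgs_males = 2L, n_wgs_females = 1L)
  pop <- simulate_population(cfg)
  aln <- simulate_alignments(cfg, pop$truth)
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, sam)
  back <- read_sam(sam)
  expect_equal(back$contigs, aln$contigs)
  expect_equal(nrow(back$records), nrow(aln$records))
  expect_equal(back$records$pos, aln$records$pos)
  expect_equal(back$records$proper, aln$records$proper)
  expect_equal(back$records$mate_contig, aln$records$mate_contig)
  skip_if_not_installed("vcfR")
  vt <- simulate_variant_table(cfg, pop,
                               samples = pop$samples$animal[1:6])
  vcf <- tempfile(fileext = ".vcf")
  write_variant_vcf(vt, vcf)
  vt2 <- read_variant_vcf(vcf)
  expect_equal(vt2$samples, vt$samples)
  expect_equal(vt2$sites$pos, vt$sites$pos)
  expect_equal(vt2$gt, vt$gt, ignore_attr = TRUE)
  expect_equal(vt2$dp, vt$dp, ignore_attr = TRUE)
  expect_equal(vt2$sites$mq, vt$sites$mq, tolerance = 0.01)
})
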