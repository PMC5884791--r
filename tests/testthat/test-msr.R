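# hand-made alignment set: one helper used across the junction tests
make_aln <- function(records, contigs, read_len = 150L,
                     insert_mean = 400, insert_sd = 50) {
  structure(list(records = records, contigs = contigs, background = NULL,
                 read_len = read_len, insert_mean = insert_mean,
                 insert_sd = insert_sd), class = "alignment_set")
}

rec <- function(sample, contig, pos, len = 150L, mapq = 60L, strand = "+",
                mate_contig = contig, mate_pos = pos, insert = 0L,
                proper = TRUE, qname = "q") {
  data.frame(qname = qname, sample = sample, contig = contig, pos = pos,
             len = len, mapq = mapq, strand = strand,
             mate_contig = mate_contig, mate_pos = mate_pos,
             insert = insert, proper = proper, stringsAsFactors = FALSE)
}

test_that("depth profiles count read spans and respect mapping quality", {
  aln <- make_aln(rbind(rec("s1", "ctg", 1L),
                        rec("s1", "ctg", 300L, mapq = 10L)),
                  c(ctg = 500L))
  prof <- depth_profile(aln, "ctg")
  expect_equal(unname(prof$depth["s1", 1:150]), rep(1L, 150))
  expect_equal(unname(prof$depth["s1", 151:500]), rep(0L, 350))  # mapq 10 dropped
  prof2 <- depth_profile(aln, "ctg", min_mapq = 0)
  expect_equal(unname(prof2$depth["s1", 300]), 1L)
  expect_error(depth_profile(aln, "nope"), "unknown contig")
  # Poisson coverage at 40x: mean within 40 +/- 1 over 20 kb
  cfg <- sim_config(seed = 61L, n_wgs_males = 1L, n_wgs_females = 1L)
  pop <- simulate_population(cfg)
  a2 <- simulate_alignments(cfg, pop$truth)
  bg <- depth_profile(a2, a2$background$contig)
  mu <- mean_depth(bg, a2$background$start, a2$background$end)
  expect_true(all(abs(mu - 40) < 1))
})

test_that("junction detection recovers the boundary and knows when to refuse", {
  cfg <- sim_config(seed = 62L)
  pop <- simulate_population(cfg)
  aln <- simulate_alignments(cfg, pop$truth)
  gsex <- pop$truth$per_sample_gsex
  ids <- unique(aln$records$sample)
  males <- ids[gsex[ids] == "M"]; females <- ids[gsex[ids] == "F"]
  pm <- depth_profile(aln, "sdY", samples = males)
  pf <- depth_profile(aln, "sdY", samples = females)
  j <- detect_junction(pm, pf)
  expect_lt(abs(j$junction - pop$truth$junction_pos), 101)
  # identical full-coverage profiles in both sexes: no junction
  j2 <- detect_junction(pm, pm)
  expect_true(is.na(j2$junction))
  # females with zero coverage everywhere: no high segment, no junction
  pf0 <- pf; pf0$depth[] <- 0L
  j3 <- detect_junction(pm, pf0)
  expect_true(is.na(j3$junction))
})

test_that("junction calls shift with a coordinate translation", {
  cfg <- sim_config(seed = 63L, sdy_contig_length_bp = 18000L,
                    msr_interval = c(2001L, 11000L))
  pop <- simulate_population(cfg)
  aln <- simulate_alignments(cfg, pop$truth)
  gsex <- pop$truth$per_sample_gsex
  ids <- unique(aln$records$sample)
  males <- ids[gsex[ids] == "M"]; females <- ids[gsex[ids] == "F"]
  j1 <- detect_junction(depth_profile(aln, "sdY", samples = males),
                        depth_profile(aln, "sdY", samples = females))
  delta <- 1500L
  shifted <- aln
  on_sdy <- shifted$records$contig == "sdY"
  shifted$records$pos[on_sdy] <- shifted$records$pos[on_sdy] + delta
  shifted$contigs["sdY"] <- shifted$contigs["sdY"] + delta
  j2 <- detect_junction(depth_profile(shifted, "sdY", samples = males),
                        depth_profile(shifted, "sdY", samples = females))
  expect_lt(abs((j2$junction - j1$junction) - delta), 50)
})

test_that("sex-lineage classification reads the mate-pair architecture", {
  # the published example: 6 orphans, 4 mates on the Ssa03 proxy and 2 on
  # the Ssa06 proxy -> translocated with both chromosomes as candidates
  J <- 13333L
  orphans <- do.call(rbind, c(
    lapply(1:4, function(i) rec("m1", "sdY", J - 100L * i,
                                mate_contig = "chr2", mate_pos = 1000L,
                                proper = FALSE, qname = paste0("o", i))),
    lapply(5:6, function(i) rec("m1", "sdY", J - 100L * i,
                                mate_contig = "chr4", mate_pos = 1000L,
                                proper = FALSE, qname = paste0("o", i)))))
  aln <- make_aln(orphans, c(sdY = 20000L, chr2 = 50000L, chr4 = 50000L))
  call <- classify_sex_lineage(aln, "m1", J)
  expect_equal(call$call, "translocated")
  expect_equal(call$candidates, c("chr2", "chr4"))
  expect_equal(unname(call$orphan_tally[c("chr2", "chr4")]), c(4L, 2L))
  # ten correctly spaced FR spanning pairs -> anchored
  spans <- do.call(rbind, lapply(1:10, function(i)
    rec("m2", "sdY", J - 200L, strand = "+", mate_pos = J + 50L,
        insert = 400L, qname = paste0("s", i))))
  aln2 <- make_aln(spans, c(sdY = 20000L))
  call2 <- classify_sex_lineage(aln2, "m2", J)
  expect_equal(call2$call, "anchored")
  expect_equal(call2$n_spanning, 10L)
  # no MSR reads at all -> unassigned with zero evidence
  call3 <- classify_sex_lineage(aln2, "f1", J)
  expect_equal(call3$call, "unassigned")
  expect_equal(call3$n_spanning, 0L)
  # wrongly spaced pairs do not count as spanning
  far <- do.call(rbind, lapply(1:10, function(i)
    rec("m3", "sdY", J - 2000L, strand = "+", mate_pos = J + 3000L,
        insert = 5150L, qname = paste0("w", i))))
  call4 <- classify_sex_lineage(make_aln(far, c(sdY = 20000L)), "m3", J)
  expect_false(call4$call == "anchored")
})

test_that("B-allele frequency is the alt fraction of the read stack", {
  gt <- matrix(c(2L, 1L, 0L), nrow = 3, ncol = 1)
  vt <- toy_table(gt)
  vt$dp[] <- 15L
  vt$ad_alt[, 1] <- c(14L, 7L, 0L)
  vt$ad_ref[, 1] <- vt$dp[, 1] - vt$ad_alt[, 1]
  baf <- compute_baf(vt)
  expect_equal(unname(baf$baf[, 1]), c(14 / 15, 7 / 15, 0))
  expect_equal(round(unname(baf$baf[1, 1]), 3), 0.933)
  vt$dp[3, 1] <- 0L; vt$ad_ref[3, 1] <- 0L; vt$ad_alt[3, 1] <- 0L
  expect_true(is.na(compute_baf(vt)$baf[3, 1]))
  vt$ad_alt[2, 1] <- 99L
  expect_error(compute_baf(vt), "exceeds")
})

test_that("MSR site definition applies the absence/presence boundaries", {
  # 1 female + 100 males; site 1: absent in the female, called in all males
  # site 2: called in the female; site 3: called in 94 of 100 males
  n_m <- 100L
  gt <- matrix(2L, nrow = 3, ncol = n_m + 1L)
  vt <- toy_table(gt)
  females <- vt$samples[1]; males <- vt$samples[-1]
  vt$dp[, females] <- 0L; vt$gt[, females] <- NA_integer_
  vt$ad_ref[, females] <- 0L; vt$ad_alt[, females] <- 0L
  vt$dp[2, females] <- 20L; vt$gt[2, females] <- 0L
  drop_m <- males[1:6]
  vt$dp[3, drop_m] <- 0L; vt$gt[3, drop_m] <- NA_integer_
  vt$ad_ref[3, drop_m] <- 0L; vt$ad_alt[3, drop_m] <- 0L
  sites <- define_msr_sites(vt, males, females)
  expect_equal(sites$pos, vt$sites$pos[1])
  expect_error(define_msr_sites(vt, males, character(0)), "female")
})

test_that("hemizygosity report counts exact 0/1 BAF and depth halving", {
  baf <- matrix(c(0, 1, 1, 0, 0.933, 1), nrow = 3)
  rep <- hemizygosity_report(baf, msr_depth = c(m1 = 20), genome_depth = c(m1 = 40))
  expect_equal(rep$fraction_homozygous, 5 / 6)
  expect_equal(rep$n_deviant, 1L)
  expect_equal(unname(rep$depth_ratio), 0.5)
  # one deviant among 300
  baf2 <- matrix(c(rep(1, 299), 0.95), ncol = 1)
  rep2 <- hemizygosity_report(baf2, 20, 40)
  expect_equal(rep2$fraction_homozygous, 299 / 300)
  expect_error(hemizygosity_report(matrix(NA_real_, 2, 2), 20, 40), "no MSR")
})
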