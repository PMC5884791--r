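#' Simulate population genotypes, sample sheet and ground truth
#'
#' Draws a three-population (TAS / NA / EU) diploid SNP dataset under a
#' Balding-Nichols drift model, plants three sex-determining anchor loci
#' carried by males of three sdY lineages (SL-02, SL-03, SL-06), mirrors
#' genotypes across configured homeolog block pairs to create residually
#' tetrasomic non-syntenic LD, appends double-haploid female genomes and
#' paralog-collapse artifact sites, and generates hemizygous male haplotypes
#' over the male-specific region (MSR) of the sdY contig split into two
#' haplogroups (HG-1 carrying SL-03/SL-06 males, HG-2 carrying SL-02).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sim_population`: a list with
#'   \describe{
#'     \item{geno}{integer matrix (samples x sites) of alt-allele dosages
#'       0/1/2 over chromosome SNPs, anchors and artifact sites}
#'     \item{map}{data.frame describing `geno` columns: chrom, pos, ref,
#'       alt, artifact, sd_lineage}
#'     \item{samples}{sample sheet: animal, population, PSEX, GSEX, sire,
#'       dam, SL_SSR, dh}
#'     \item{msr_sites, msr_hap}{MSR site table and male x site matrix of
#'       hemizygous alt-allele indicators (0/1)}
#'     \item{mfcr_sites, mfcr_geno}{diploid SNPs on the sdY contig outside
#'       the MSR and their dosages (samples x sites)}
#'     \item{truth}{`truth_record` ground truth for recovery tests}
#'   }
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  with_substream(config$seed, 2L, {
    samples <- .sim_sample_sheet(config)
    n <- nrow(samples)
    bases <- c("A", "C", "G", "T")

    ## -- chromosome SNPs -------------------------------------------------
    n_per_chrom <- config$chrom_length_bp %/% config$snp_spacing_bp
    map <- do.call(rbind, lapply(config$chrom_names, function(ch) {
      pos <- sort(sample.int(config$chrom_length_bp, n_per_chrom))
      data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
    }))
    # anchor sites (one per sd locus), dropped from random sites on collision
    anchors <- data.frame(
      chrom = vapply(config$sd_loci, `[[`, "", "chrom"),
      pos = vapply(config$sd_loci, function(l) as.integer(l$pos), 1L),
      stringsAsFactors = FALSE)
    key <- paste(map$chrom, map$pos)
    map <- map[!key %in% paste(anchors$chrom, anchors$pos), ]
    map$sd_lineage <- NA_character_
    anchors$sd_lineage <- vapply(config$sd_loci, `[[`, "", "lineage")
    map <- rbind(map, anchors)
    map$artifact <- FALSE

    ## -- artifact sites (planted paralog collapse) -----------------------
    if (config$n_artifact_sites > 0L) {
      art <- data.frame(
        chrom = sample(config$chrom_names, config$n_artifact_sites,
                       replace = TRUE),
        pos = sample.int(config$chrom_length_bp, config$n_artifact_sites),
        sd_lineage = NA_character_, artifact = TRUE,
        stringsAsFactors = FALSE)
      key <- paste(map$chrom, map$pos)
      art <- art[!paste(art$chrom, art$pos) %in% key, ]
      map <- rbind(map, art)
    }
    ord <- order(match(map$chrom, config$chrom_names), map$pos)
    map <- map[ord, ]
    rownames(map) <- NULL
    m <- nrow(map)
    ra <- .draw_ref_alt(m, bases)
    map$ref <- ra$ref
    map$alt <- ra$alt

    ## -- allele frequencies and genotypes --------------------------------
    p0 <- runif(m, 0.05, 0.95)
    geno <- matrix(0L, nrow = n, ncol = m,
                   dimnames = list(samples$animal, NULL))
    for (popname in names(config$pop_sizes)) {
      rows <- which(samples$population == popname)
      if (!length(rows)) next
      F <- unname(config$fst_drift[popname])
      p_pop <- if (F <= 0) p0 else
        rbeta(m, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
      gmat <- matrix(rbinom(length(rows) * m, 2L, rep(p_pop, each = length(rows))),
                     nrow = length(rows))
      geno[rows, ] <- gmat
    }

    ## -- plant sex-determining anchors and cassette-linked blocks --------
    # carriers (males of the locus' lineage) share one haplotype over the
    # linked window, so nearby sites associate with maleness; planted
    # before homeolog mirroring so the association can leak to partners
    p_link <- runif(m, 0.05, 0.95)        # background freq of linked sites
    h_link <- rbinom(m, 1L, 0.5)          # cassette haplotype allele
    for (l in config$sd_loci) {
      carriers <- samples$GSEX == "M" & !is.na(samples$lineage) &
        samples$lineage == l$lineage
      linked <- which(map$chrom == l$chrom &
                        abs(map$pos - l$pos) <= config$sd_link_window_bp &
                        !map$artifact & is.na(map$sd_lineage))
      if (length(linked) && any(carriers)) {
        nc <- sum(carriers)
        other <- matrix(rbinom(nc * length(linked), 1L,
                               rep(p_link[linked], each = nc)), nrow = nc)
        geno[carriers, linked] <- sweep(other, 2L, h_link[linked], `+`)
      }
      j <- which(map$chrom == l$chrom & map$pos == l$pos)
      geno[, j] <- 0L
      geno[carriers, j] <- 1L     # cassette-linked marker allele, het
    }

    ## -- homeolog mirroring (residual tetrasomy) -------------------------
    mirrored <- list()
    for (hp in config$homeolog_pairs) {
      ia <- which(map$chrom == hp$a$chrom & map$pos >= hp$a$start &
                    map$pos <= hp$a$end & !map$artifact &
                    is.na(map$sd_lineage))
      ib <- which(map$chrom == hp$b$chrom & map$pos >= hp$b$start &
                    map$pos <= hp$b$end & !map$artifact &
                    is.na(map$sd_lineage))
      k <- min(length(ia), length(ib))
      if (k == 0L) next
      k_mirror <- round(hp$fraction * k)
      if (k_mirror == 0L) next
      sel <- sort(sample.int(k, k_mirror))
      sub_a <- geno[, ia[sel], drop = FALSE]
      sub_b <- geno[, ib[sel], drop = FALSE]
      copy <- matrix(runif(n * k_mirror) < hp$rho, n, k_mirror)
      sub_b[copy] <- sub_a[copy]
      geno[, ib[sel]] <- sub_b
      mirrored[[length(mirrored) + 1L]] <-
        data.frame(chrom_a = hp$a$chrom, pos_a = map$pos[ia[sel]],
                   chrom_b = hp$b$chrom, pos_b = map$pos[ib[sel]],
                   stringsAsFactors = FALSE)
    }
    mirrored <- if (length(mirrored)) do.call(rbind, mirrored) else
      data.frame(chrom_a = character(), pos_a = integer(),
                 chrom_b = character(), pos_b = integer())

    ## -- artifact sites: heterozygous in everyone (DH included) ----------
    geno[, map$artifact] <- 1L

    ## -- double haploids: force homozygosity elsewhere -------------------
    dh <- samples$dh
    if (any(dh)) {
      normal <- !map$artifact
      sub <- geno[dh, normal, drop = FALSE]
      sub[sub == 1L] <- ifelse(runif(sum(sub == 1L)) < 0.5, 0L, 2L)
      geno[dh, normal] <- sub
    }

    ## -- sdY contig sites -------------------------------------------------
    msr <- config$msr_interval
    msr_pos <- sort(sample(seq(msr[1], msr[2]), config$msr_n_snps))
    mfcr_ranges <- c(seq_len(msr[1] - 1L),
                     seq(msr[2] + 1L, config$sdy_contig_length_bp))
    n_mfcr <- max(config$sdy_n_snps - config$msr_n_snps, 0L)
    mfcr_pos <- sort(sample(mfcr_ranges, n_mfcr))

    ra <- .draw_ref_alt(length(msr_pos), bases)
    msr_sites <- data.frame(chrom = config$sdy_contig, pos = msr_pos,
                            ref = ra$ref, alt = ra$alt,
                            stringsAsFactors = FALSE)
    males <- samples$animal[samples$GSEX == "M"]
    # haplogroup cores: HG-1 (SL-03 / SL-06) vs HG-2 (SL-02)
    core1 <- rbinom(length(msr_pos), 1L, 0.5)
    flip <- runif(length(msr_pos)) < config$hg_divergence
    core2 <- ifelse(flip, 1L - core1, core1)
    hg_by_male <- ifelse(
      samples$lineage[match(males, samples$animal)] == "SL-02",
      "HG-2", "HG-1")
    msr_hap <- t(vapply(seq_along(males), function(i) {
      core <- if (hg_by_male[i] == "HG-2") core2 else core1
      mut <- runif(length(core)) < config$within_hg_mut
      ifelse(mut, 1L - core, core)
    }, integer(length(msr_pos))))
    dimnames(msr_hap) <- list(males, NULL)

    ra <- .draw_ref_alt(length(mfcr_pos), bases)
    mfcr_sites <- data.frame(chrom = config$sdy_contig, pos = mfcr_pos,
                             ref = ra$ref, alt = ra$alt,
                             stringsAsFactors = FALSE)
    p_mfcr <- runif(length(mfcr_pos), 0.05, 0.95)
    mfcr_geno <- matrix(rbinom(n * length(mfcr_pos), 2L,
                               rep(p_mfcr, each = n)), nrow = n,
                        dimnames = list(samples$animal, NULL))
    if (any(dh) && length(mfcr_pos)) {
      sub <- mfcr_geno[dh, , drop = FALSE]
      sub[sub == 1L] <- ifelse(runif(sum(sub == 1L)) < 0.5, 0L, 2L)
      mfcr_geno[dh, ] <- sub
    }

    truth <- structure(list(
      junction_pos = config$msr_interval[2],
      lineage_by_male = stats::setNames(
        samples$lineage[samples$GSEX == "M"], males),
      haplogroup_by_male = stats::setNames(hg_by_male, males),
      true_sd_loci = data.frame(
        chrom = vapply(config$sd_loci, `[[`, "", "chrom"),
        pos = vapply(config$sd_loci, function(l) as.integer(l$pos), 1L),
        lineage = vapply(config$sd_loci, `[[`, "", "lineage"),
        stringsAsFactors = FALSE),
      artifact_sites = map[map$artifact, c("chrom", "pos")],
      homeolog_pairs = config$homeolog_pairs,
      mirrored_site_pairs = mirrored,
      per_sample_gsex = stats::setNames(samples$GSEX, samples$animal),
      per_sample_psex = stats::setNames(samples$PSEX, samples$animal)
    ), class = "truth_record")

    structure(list(geno = geno, map = map, samples = samples,
                   msr_sites = msr_sites, msr_hap = msr_hap,
                   mfcr_sites = mfcr_sites, mfcr_geno = mfcr_geno,
                   truth = truth, config = config),
              class = "sim_population")
  })
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("sim_population: %d samples (%d DH), %d chromosome sites, %d sdY sites\n",
              nrow(x$samples), sum(x$samples$dh), nrow(x$map),
              nrow(x$msr_sites) + nrow(x$mfcr_sites)))
  invisible(x)
}

.draw_ref_alt <- function(m, bases) {
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  list(ref = unname(ref), alt = unname(alt))
}

# Sample sheet: sexes alternate within population (balanced design); each
# male draws a lineage by the configured proportions; PSEX flips from GSEX
# at the discordance rate; DH females appended as extra TAS samples.
.sim_sample_sheet <- function(config) {
  pops <- rep(names(config$pop_sizes), times = config$pop_sizes)
  n <- length(pops)
  animal <- sprintf("%s_%02d", pops, unlist(lapply(config$pop_sizes, seq_len)))
  gsex <- unlist(lapply(config$pop_sizes, function(k)
    rep_len(c("M", "F"), k)), use.names = FALSE)
  lineage <- rep(NA_character_, n)
  is_m <- gsex == "M"
  lineage[is_m] <- sample(names(config$lineage_proportions), sum(is_m),
                          replace = TRUE, prob = config$lineage_proportions)
  psex <- gsex
  flip <- runif(n) < config$psex_discordance_rate
  psex[flip] <- ifelse(gsex[flip] == "M", "F", "M")
  sheet <- data.frame(animal = animal, population = pops, PSEX = psex,
                      GSEX = gsex, sire = "0", dam = "0",
                      SL_SSR = ifelse(is_m, lineage, "nd"),
                      lineage = lineage, dh = FALSE,
                      stringsAsFactors = FALSE)
  if (config$n_dh_females > 0L) {
    dh <- data.frame(animal = sprintf("DH_%02d", seq_len(config$n_dh_females)),
                     population = "TAS", PSEX = "F", GSEX = "F",
                     sire = "0", dam = "0", SL_SSR = "nd",
                     lineage = NA_character_, dh = TRUE,
                     stringsAsFactors = FALSE)
    sheet <- rbind(sheet, dh)
  }
  rownames(sheet) <- NULL
  sheet
}

#' Write the sample sheet to TSV
#' @param pop a `sim_population` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(pop, path) {
  utils::write.table(
    pop$samples[, c("animal", "population", "PSEX", "GSEX", "sire", "dam",
                    "SL_SSR")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
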