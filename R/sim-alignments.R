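#' Simulate mapped paired-end alignment records around the sdY contig
#'
#' Emits already-mapped SAM-style records reproducing the read architecture
#' the male-specific-region (MSR) analyses consume:
#' \itemize{
#'   \item all fish carry the male-female common region (MFCR) flanks of the
#'     sdY contig at full coverage (half for SL-02 males, whose Y haplotype
#'     also contributes), with reads soft-clipped at the MSR boundary so
#'     female depth stops exactly at the junction;
#'   \item SL-02 males add a contiguous Y-haplotype layer across the whole
#'     contig at half coverage, so proper FR pairs with normal insert sizes
#'     span the MSR-MFCR junction;
#'   \item SL-03 / SL-06 males carry the MSR translocated onto their lineage
#'     chromosome: MSR fragments overhanging the junction yield orphan reads
#'     inside the MSR whose mates map to the lineage chromosome (with a
#'     configurable minority placed on its homeolog partner);
#'   \item females have no MSR reads at all;
#'   \item every sample gets a background window on the last chromosome at
#'     full coverage, used as the genome-wide depth baseline.
#' }
#'
#' @param config a [sim_config()] object.
#' @param truth a `truth_record` (from [simulate_population()]).
#' @param samples character vector of sample ids to simulate; default takes
#'   the first `n_wgs_males` TAS males and `n_wgs_females` TAS (non
#'   double-haploid) females from the truth record.
#' @return an object of class `alignment_set`: list with `records`
#'   (data.frame: qname, sample, contig, pos, len, mapq, strand,
#'   mate_contig, mate_pos, insert, proper), `contigs` (named lengths) and
#'   `background` (contig/start/end of the depth baseline window).
#' @export
simulate_alignments <- function(config, truth, samples = NULL) {
  stopifnot(inherits(truth, "truth_record"))
  gsex <- truth$per_sample_gsex
  if (is.null(samples)) {
    ids <- names(gsex)
    tas <- ids[startsWith(ids, "TAS")]
    males <- tas[gsex[tas] == "M"]
    females <- tas[gsex[tas] == "F"]
    samples <- c(utils::head(males, config$n_wgs_males),
                 utils::head(females, config$n_wgs_females))
  }
  missing <- setdiff(samples, names(gsex))
  if (length(missing))
    stop("samples absent from truth: ", paste(missing, collapse = ", "))

  L <- config$sdy_contig_length_bp
  J <- truth$junction_pos
  s0 <- config$msr_interval[1]
  rl <- config$read_len
  cov <- config$coverage_mean
  bg_contig <- config$chrom_names[config$n_chromosomes]
  bg_end <- min(20000L, config$chrom_length_bp)
  hp_partner <- .homeolog_partner_map(config)

  with_substream(config$seed, 3L, {
    recs <- lapply(samples, function(id) {
      male <- gsex[[id]] == "M"
      lineage <- if (male) truth$lineage_by_male[[id]] else NA_character_
      out <- list()
      # background window (genome-wide depth baseline)
      out$bg <- .clipped_reads(bg_contig, 1L, bg_end, cov, rl, id)
      # MFCR flank layers on the sdY contig
      mfcr_cov <- if (male && identical(lineage, "SL-02")) cov / 2 else cov
      out$m1 <- .clipped_reads(config$sdy_contig, 1L, s0 - 1L, mfcr_cov, rl, id)
      out$m2 <- .clipped_reads(config$sdy_contig, J + 1L, L, mfcr_cov, rl, id)
      if (!male && config$female_msr_noise > 0) {
        out$noise <- .clipped_reads(config$sdy_contig, s0, J,
                                    cov * config$female_msr_noise, rl, id)
      }
      if (male) {
        if (identical(lineage, "SL-02")) {
          out$y <- .proper_pairs(config$sdy_contig, 1L, L, cov / 2,
                                 config, id)
        } else {
          out$y <- .translocated_msr(config, truth, id, lineage,
                                     hp_partner, s0, J)
        }
      }
      do.call(rbind, out)
    })
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    contigs <- c(stats::setNames(rep(config$chrom_length_bp,
                                     config$n_chromosomes),
                 config$chrom_names),
                 stats::setNames(L, config$sdy_contig))
    structure(list(records = records, contigs = contigs,
                   background = list(contig = bg_contig, start = 1L,
                                     end = bg_end),
                   read_len = rl,
                   insert_mean = config$insert_mean,
                   insert_sd = config$insert_sd),
              class = "alignment_set")
  })
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set: %d records, %d samples, %d contigs\n",
              nrow(x$records), length(unique(x$records$sample)),
              length(x$contigs)))
  invisible(x)
}

# Unpaired-style coverage reads over [a, b], soft-clipped at the segment
# boundaries (mate fields degenerate: same contig, insert 0).
.clipped_reads <- function(contig, a, b, cov, rl, sample) {
  seg <- b - a + 1L
  if (seg < 1L || cov <= 0) return(NULL)
  # starts range over seg + rl - 1 positions (clipped at the boundaries),
  # so this rate gives flat per-base coverage `cov` across the segment
  n <- stats::rpois(1L, (seg + rl - 1L) * cov / rl)
  if (n == 0L) return(NULL)
  start <- sample.int(seg + rl - 1L, n, replace = TRUE) + a - rl
  end <- pmin(start + rl - 1L, b)
  start <- pmax(start, a)
  keep <- end >= start
  start <- start[keep]; end <- end[keep]
  if (!length(start)) return(NULL)
  data.frame(qname = sprintf("%s_%s_%d", sample, contig, seq_along(start)),
             sample = sample, contig = contig, pos = start,
             len = end - start + 1L, mapq = 60L,
             strand = sample(c("+", "-"), length(start), replace = TRUE),
             mate_contig = contig, mate_pos = start, insert = 0L,
             proper = TRUE, stringsAsFactors = FALSE)
}

# Proper FR fragment pairs over [a, b] at the given coverage; reads clipped
# at segment ends.
.proper_pairs <- function(contig, a, b, cov, config, sample,
                          qprefix = "Y") {
  rl <- config$read_len
  seg <- b - a + 1L
  n <- stats::rpois(1L, seg * cov / (2 * rl))
  if (n == 0L) return(NULL)
  ins <- pmax(round(stats::rnorm(n, config$insert_mean, config$insert_sd)),
              2L * rl)
  start <- sample.int(seg, n, replace = TRUE) + a - 1L
  r1s <- start
  r2s <- start + ins - rl
  r1e <- pmin(r1s + rl - 1L, b)
  r2e <- pmin(r2s + rl - 1L, b)
  r2s <- pmin(r2s, b)
  keep <- r2s > r1e        # drop degenerate overlapping-into-clip pairs
  if (!any(keep)) return(NULL)
  idx <- which(keep)
  qn <- sprintf("%s_%s%s_%d", sample, qprefix, contig, seq_along(idx))
  rbind(
    data.frame(qname = qn, sample = sample, contig = contig,
               pos = r1s[idx], len = r1e[idx] - r1s[idx] + 1L, mapq = 60L,
               strand = "+", mate_contig = contig, mate_pos = r2s[idx],
               insert = ins[idx], proper = TRUE, stringsAsFactors = FALSE),
    data.frame(qname = qn, sample = sample, contig = contig,
               pos = r2s[idx], len = r2e[idx] - r2s[idx] + 1L, mapq = 60L,
               strand = "-", mate_contig = contig, mate_pos = r1s[idx],
               insert = -ins[idx], proper = TRUE, stringsAsFactors = FALSE))
}

# MSR layer for a translocated (SL-03 / SL-06) male: fragments sampled from
# the [lineage-flank][MSR][lineage-flank] haplotype at half coverage.
# Fragments fully inside the MSR give proper pairs on the sdY contig;
# fragments overhanging the junction give an orphan read inside the MSR
# whose mate maps near the lineage's sd anchor (or its homeolog partner),
# plus the mate record itself.
.translocated_msr <- function(config, truth, sample, lineage, hp_partner,
                              s0, J) {
  rl <- config$read_len
  cov <- config$coverage_mean / 2
  seg <- J - s0 + 1L
  # sample fragment starts over an extended range so MSR edge coverage is
  # flat; starts below s0 are clipped at s0 (lineage flank side), fragments
  # overhanging J become orphans
  n <- stats::rpois(1L, (seg + config$insert_mean) * cov / (2 * rl))
  if (n == 0L) return(NULL)
  ins <- pmax(round(stats::rnorm(n, config$insert_mean, config$insert_sd)),
              2L * rl)
  start <- sample(seq(s0 - config$insert_mean, J), n, replace = TRUE)
  fend <- start + ins - 1L
  anchor <- truth$true_sd_loci
  anchor <- anchor[anchor$lineage == lineage, , drop = FALSE]
  lin_chrom <- anchor$chrom[1]
  lin_pos <- anchor$pos[1]
  partner <- hp_partner[[lin_chrom]]
  out <- list()
  ## fully inside [s0, J] -> proper pairs
  inside <- start >= s0 & fend <= J
  if (any(inside)) {
    idx <- which(inside)
    qn <- sprintf("%s_MSR_%d", sample, seq_along(idx))
    r1s <- start[idx]; r2s <- start[idx] + ins[idx] - rl
    out$pp <- rbind(
      data.frame(qname = qn, sample = sample, contig = config$sdy_contig,
                 pos = r1s, len = rl, mapq = 60L, strand = "+",
                 mate_contig = config$sdy_contig, mate_pos = r2s,
                 insert = ins[idx], proper = TRUE, stringsAsFactors = FALSE),
      data.frame(qname = qn, sample = sample, contig = config$sdy_contig,
                 pos = r2s, len = rl, mapq = 60L, strand = "-",
                 mate_contig = config$sdy_contig, mate_pos = r1s,
                 insert = -ins[idx], proper = TRUE,
                 stringsAsFactors = FALSE))
  }
  ## left overhang (into the lineage flank): clip read1 at s0
  lo <- start < s0 & fend <= J & fend >= s0 + rl
  if (any(lo)) {
    idx <- which(lo)
    r2s <- start[idx] + ins[idx] - rl
    keep <- r2s >= s0
    idx <- idx[keep]
    if (length(idx)) {
      r2s <- start[idx] + ins[idx] - rl
      qn <- sprintf("%s_MSRL_%d", sample, seq_along(idx))
      out$lo <- data.frame(
        qname = qn, sample = sample, contig = config$sdy_contig,
        pos = r2s, len = rl, mapq = 60L, strand = "-",
        mate_contig = lin_chrom, mate_pos = lin_pos, insert = 0L,
        proper = FALSE, stringsAsFactors = FALSE)
    }
  }
  ## right overhang (across the junction): orphan in MSR, mate on the
  ## lineage chromosome (minority on its homeolog partner)
  ro <- start >= s0 & start <= J - rl + 1L & fend > J
  if (any(ro)) {
    idx <- which(ro)
    k <- length(idx)
    if (is.null(partner)) {
      on_partner <- rep(FALSE, k)
      partner_chrom <- lin_chrom
      partner_pos <- lin_pos
    } else {
      on_partner <- stats::runif(k) < config$orphan_mate_homeolog_frac
      partner_chrom <- partner$chrom
      partner_pos <- .clamp(lin_pos - partner$a_start + partner$b_start,
                            1L, config$chrom_length_bp)
    }
    mate_chrom <- ifelse(on_partner, partner_chrom, lin_chrom)
    mate_pos <- ifelse(on_partner, partner_pos, lin_pos) +
      sample.int(2000L, k, replace = TRUE)
    qn <- sprintf("%s_ORPH_%d", sample, seq_len(k))
    out$orph <- data.frame(
      qname = qn, sample = sample, contig = config$sdy_contig,
      pos = start[idx], len = rl, mapq = 60L, strand = "+",
      mate_contig = mate_chrom, mate_pos = as.integer(mate_pos),
      insert = 0L, proper = FALSE, stringsAsFactors = FALSE)
    out$orph_mates <- data.frame(
      qname = qn, sample = sample, contig = mate_chrom,
      pos = as.integer(mate_pos), len = rl, mapq = 60L, strand = "-",
      mate_contig = config$sdy_contig, mate_pos = start[idx],
      insert = 0L, proper = FALSE, stringsAsFactors = FALSE)
  }
  if (!length(out)) NULL else do.call(rbind, out)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# chrom -> partner block info (first pair mentioning the chrom on its a or
# b side); used to place minority orphan mates
.homeolog_partner_map <- function(config) {
  out <- list()
  for (hp in config$homeolog_pairs) {
    if (is.null(out[[hp$a$chrom]]))
      out[[hp$a$chrom]] <- list(chrom = hp$b$chrom, a_start = hp$a$start,
                                b_start = hp$b$start)
    if (is.null(out[[hp$b$chrom]]))
      out[[hp$b$chrom]] <- list(chrom = hp$a$chrom, a_start = hp$b$start,
                                b_start = hp$a$start)
  }
  out
}

#' Write an alignment set as plain-text SAM
#'
#' Emits an @HD/@SQ header and the 11 mandatory columns; the proper-pair,
#' strand and mate-reverse bits of FLAG are set from the record fields.
#'
#' @param aln an `alignment_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(aln$contigs),
                     aln$contigs), con)
  r <- aln$records
  flag <- 1L +                                   # paired
    ifelse(r$proper, 2L, 0L) +
    ifelse(r$strand == "-", 16L, 0L) +
    ifelse(r$strand == "-", 0L, 32L)             # mate reverse for fwd read
  rnext <- ifelse(r$mate_contig == r$contig, "=", r$mate_contig)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t%d\t*\t*\tRG:Z:%s",
                   r$qname, flag, r$contig, r$pos, r$mapq, r$len, rnext,
                   r$mate_pos, r$insert, r$sample)
  writeLines(lines, con)
  invisible(path)
}

#' Read a plain-text SAM file into an alignment set
#'
#' Parses the subset of SAM this package writes (single M-operation CIGAR,
#' RG:Z sample tags); suitable for round-tripping [write_sam()] output and
#' for small hand-made fixtures.
#'
#' @param path SAM file path.
#' @return an `alignment_set`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  contigs <- stats::setNames(
    as.integer(sub(".*\tLN:(\\d+).*", "\\1", sq)),
    sub(".*\tSN:([^\t]+).*", "\\1", sq))
  f <- strsplit(body, "\t", fixed = TRUE)
  getf <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(getf(2))
  contig <- getf(3)
  mate <- getf(7)
  rg <- vapply(f, function(x) {
    tag <- grep("^RG:Z:", x, value = TRUE)
    if (length(tag)) sub("^RG:Z:", "", tag[1]) else NA_character_
  }, "")
  records <- data.frame(
    qname = getf(1), sample = rg, contig = contig,
    pos = as.integer(getf(4)),
    len = as.integer(sub("M$", "", getf(6))),
    mapq = as.integer(getf(5)),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mate_contig = ifelse(mate == "=", contig, mate),
    mate_pos = as.integer(getf(8)),
    insert = as.integer(getf(9)),
    proper = bitwAnd(flag, 2L) > 0L,
    stringsAsFactors = FALSE)
  structure(list(records = records, contigs = contigs,
                 background = NULL,
                 read_len = max(records$len),
                 insert_mean = NA_real_, insert_sd = NA_real_),
            class = "alignment_set")
}
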