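#' Per-base depth profiles over a contig
#'
#' Counts, per sample, the reads with mapping quality at or above
#' `min_mapq` covering each base of the contig.
#'
#' @param aln an `alignment_set`.
#' @param contig contig name (must be in the set's header).
#' @param min_mapq minimum read mapping quality.
#' @param samples sample ids to profile; default all in the records.
#' @return object of class `depth_profile`: list with `contig`, `depth`
#'   (samples x contig-length matrix) and `samples`.
#' @export
depth_profile <- function(aln, contig, min_mapq = 20, samples = NULL) {
  stopifnot(inherits(aln, "alignment_set"))
  if (!contig %in% names(aln$contigs)) stop("unknown contig: ", contig)
  L <- aln$contigs[[contig]]
  r <- aln$records
  r <- r[r$contig == contig & r$mapq >= min_mapq, , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(aln$records$sample))
  depth <- matrix(0L, nrow = length(samples), ncol = L,
                  dimnames = list(samples, NULL))
  for (i in seq_along(samples)) {
    rs <- r[r$sample == samples[i], , drop = FALSE]
    if (!nrow(rs)) next
    # difference-array coverage: +1 at starts, -1 after ends
    d <- integer(L + 1L)
    starts <- pmax(rs$pos, 1L)
    ends <- pmin(rs$pos + rs$len - 1L, L)
    ok <- ends >= starts
    tab_s <- tabulate(starts[ok], nbins = L)
    tab_e <- tabulate(ends[ok] + 1L, nbins = L + 1L)
    depth[i, ] <- cumsum(tab_s - tab_e[seq_len(L)])
  }
  structure(list(contig = contig, depth = depth, samples = samples),
            class = "depth_profile")
}

#' Mean depth per sample over a window
#'
#' @param profile a `depth_profile`.
#' @param start,end 1-based inclusive window; default whole contig.
#' @return named numeric vector of per-sample mean depths.
#' @export
mean_depth <- function(profile, start = 1L, end = ncol(profile$depth)) {
  rowMeans(profile$depth[, start:end, drop = FALSE])
}

#' Detect the MSR-MFCR junction from male and female depth profiles
#'
#' Forms the female/male mean-depth ratio track, smooths it with a centred
#' moving average, and fits a two-segment piecewise-constant model by
#' exhaustive changepoint search; a changepoint is admissible only when it
#' separates a low segment (mean below `low_max`) from a high segment
#' (mean above `high_min`), each at least `min_run_bp` long.  The male
#' specific region is the low segment (females have no reads there), and
#' the returned junction is its last base.
#'
#' @param male_profile,female_profile `depth_profile` objects over the same
#'   contig, containing male and female samples respectively.
#' @param smooth_bp centred moving-average window (odd).
#' @param min_run_bp minimum segment length.
#' @param low_max,high_min segment-mean contracts for the low (MSR) and
#'   high (MFCR) segments.
#' @return list with `junction` (1-based bp, or `NA` if no admissible
#'   changepoint exists), `ratio` (smoothed track) and `segment_means`.
#' @export
detect_junction <- function(male_profile, female_profile, smooth_bp = 201,
                            min_run_bp = 500, low_max = 0.25,
                            high_min = 0.5) {
  stopifnot(inherits(male_profile, "depth_profile"),
            inherits(female_profile, "depth_profile"),
            male_profile$contig == female_profile$contig)
  m <- colMeans(male_profile$depth)
  f <- colMeans(female_profile$depth)
  eps <- 1e-9
  ratio <- f / pmax(m, eps)
  k <- max(1L, as.integer(smooth_bp))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- stats::filter(ratio, rep(1 / k, k), sides = 2L)
  sm <- as.numeric(sm)
  # shrink the moving average at the edges instead of dropping them
  half <- (k - 1L) %/% 2L
  L <- length(ratio)
  for (i in which(is.na(sm))) {
    a <- max(1L, i - half); b <- min(L, i + half)
    sm[i] <- mean(ratio[a:b])
  }
  ## exhaustive two-segment changepoint search on the smoothed track
  cs <- cumsum(sm)
  cs2 <- cumsum(sm^2)
  cuts <- seq(min_run_bp, L - min_run_bp)
  n1 <- cuts
  n2 <- L - cuts
  s1 <- cs[cuts]; s2 <- cs[L] - s1
  q1 <- cs2[cuts]; q2 <- cs2[L] - q1
  m1 <- s1 / n1; m2 <- s2 / n2
  sse <- (q1 - s1^2 / n1) + (q2 - s2^2 / n2)
  valid <- m1 < low_max & m2 > high_min
  if (!any(valid))
    return(list(junction = NA_integer_, ratio = sm,
                segment_means = NULL))
  best <- cuts[valid][which.min(sse[valid])]
  list(junction = as.integer(best), ratio = sm,
       segment_means = c(low = m1[match(best, cuts)],
                         high = m2[match(best, cuts)]))
}

#' Classify a male's sex lineage from mate-pair architecture
#'
#' A male whose sdY cassette sits in its ancestral chromosomal context
#' shows proper FR read pairs spanning the MSR-MFCR junction with normal
#' insert sizes ("anchored", the SL-02 architecture).  A male whose
#' cassette has translocated shows no correctly spaced spanning pairs;
#' instead, reads inside the MSR adjacent to the junction have mates
#' mapping to the cassette's host chromosome ("translocated", with the
#' candidate chromosome set taken from the orphan mate tally).
#'
#' @param aln an `alignment_set`.
#' @param sample the male's sample id.
#' @param junction junction position (bp) on the sdY contig.
#' @param contig sdY contig name.
#' @param insert_mean,insert_sd expected insert distribution; defaults from
#'   the alignment set.
#' @param min_span_pairs spanning pairs needed to call "anchored".
#' @param orphan_window_bp how far inside the MSR to look for orphans.
#' @param min_orphans mates per chromosome needed to enter the candidate
#'   set.
#' @param min_mapq minimum mapping quality on both mates.
#' @return object of class `lineage_call`: list with `animal`, `call`
#'   ("anchored", "translocated" or "unassigned"), `candidates`,
#'   `n_spanning` and `orphan_tally`.
#' @export
classify_sex_lineage <- function(aln, sample, junction,
                                 contig = "sdY",
                                 insert_mean = aln$insert_mean,
                                 insert_sd = aln$insert_sd,
                                 min_span_pairs = 3L,
                                 orphan_window_bp = 2000L,
                                 min_orphans = 2L, min_mapq = 20) {
  stopifnot(inherits(aln, "alignment_set"))
  r <- aln$records
  r <- r[r$sample == sample & r$contig == contig & r$mapq >= min_mapq, ,
         drop = FALSE]
  ## spanning pairs: forward read left of the junction, mate right of it,
  ## FR orientation, insert within +/- 3 sd
  fwd <- r[r$strand == "+" & r$mate_contig == contig, , drop = FALSE]
  span <- fwd$pos <= junction & fwd$mate_pos > junction &
    fwd$mate_pos > fwd$pos &
    abs(fwd$insert - insert_mean) <= 3 * insert_sd
  n_span <- sum(span, na.rm = TRUE)
  if (!is.na(n_span) && n_span >= min_span_pairs) {
    return(structure(list(animal = sample, call = "anchored",
                          candidates = character(0), n_spanning = n_span,
                          orphan_tally = integer(0)),
                     class = "lineage_call"))
  }
  ## orphans: reads inside the MSR within the window of the junction whose
  ## mates map to a different contig
  orph <- r[r$pos >= junction - orphan_window_bp & r$pos <= junction &
              r$mate_contig != contig, , drop = FALSE]
  tally <- if (nrow(orph)) table(orph$mate_contig) else table(character(0))
  tally <- stats::setNames(as.integer(tally), names(tally))
  candidates <- names(tally)[tally >= min_orphans]
  call <- if (length(candidates)) "translocated" else "unassigned"
  structure(list(animal = sample, call = call,
                 candidates = sort(candidates), n_spanning = n_span,
                 orphan_tally = tally),
            class = "lineage_call")
}

#' @export
print.lineage_call <- function(x, ...) {
  cat(sprintf("%s: %s", x$animal, x$call))
  if (x$call == "translocated")
    cat(" {", paste(x$candidates, collapse = ", "), "}", sep = "")
  cat(sprintf("  [spanning pairs: %d; orphan mates: %s]\n", x$n_spanning,
              if (length(x$orphan_tally))
                paste(names(x$orphan_tally), x$orphan_tally, sep = "=",
                      collapse = ", ") else "none"))
  invisible(x)
}

#' B-allele frequency per site and sample
#'
#' BAF is the alternate-allele read count divided by the read depth;
#' undefined (NA) where depth is zero.  Hemizygous regions show only
#' values of zero or one.
#'
#' @param table a [variant_table()].
#' @param contig restrict to this contig; `NULL` for all sites.
#' @return list with `sites` (data.frame chrom, pos) and `baf`
#'   (sites x samples matrix).
#' @export
compute_baf <- function(table, contig = NULL) {
  stopifnot(inherits(table, "variant_table"))
  idx <- if (is.null(contig)) seq_len(nrow(table$sites)) else
    which(table$sites$chrom == contig)
  ad_alt <- table$ad_alt[idx, , drop = FALSE]
  dp <- table$dp[idx, , drop = FALSE]
  if (any(ad_alt > dp)) stop("ad_alt exceeds dp")
  baf <- ifelse(dp > 0, ad_alt / dp, NA_real_)
  list(sites = table$sites[idx, c("chrom", "pos")], baf = baf)
}

#' Define male-specific-region sites
#'
#' A site belongs to the MSR when it is called (depth at least `min_dp`)
#' in no female and in at least `male_presence_min` of the males.
#'
#' @param table a [variant_table()] (typically restricted to the sdY
#'   contig upstream).
#' @param males,females sample id vectors (both non-empty).
#' @param male_presence_min minimum fraction of males with a call.
#' @param min_dp depth at which a genotype counts as called.
#' @return data.frame of qualifying sites (chrom, pos).
#' @export
define_msr_sites <- function(table, males, females,
                             male_presence_min = 0.95, min_dp = 5) {
  stopifnot(inherits(table, "variant_table"))
  if (!length(males) || !length(females))
    stop("need both male and female samples")
  called <- table$dp >= min_dp & !is.na(table$gt)
  in_f <- rowSums(called[, females, drop = FALSE])
  frac_m <- rowMeans(called[, males, drop = FALSE])
  sel <- in_f == 0L & frac_m >= male_presence_min
  out <- table$sites[sel, c("chrom", "pos")]
  rownames(out) <- NULL
  out
}

#' Hemizygosity report over MSR sites in males
#'
#' Counts the fraction of defined male BAF values that are exactly zero or
#' one (no tolerance: a single non-reference read makes a site deviate),
#' and the per-male ratio of mean MSR depth to genome-wide mean depth,
#' expected near 0.5 for a single-copy region.
#'
#' @param baf BAF matrix over MSR sites (sites x males), as from
#'   [compute_baf()] subset to MSR sites and male samples.
#' @param msr_depth named per-male mean depth over the MSR.
#' @param genome_depth named per-male genome-wide mean depth.
#' @return list with `fraction_homozygous`, `n_calls`, `n_deviant` and
#'   `depth_ratio` (named per male).
#' @export
hemizygosity_report <- function(baf, msr_depth, genome_depth) {
  if (!length(baf) || all(is.na(baf))) stop("no MSR BAF values")
  vals <- baf[!is.na(baf)]
  hom <- vals == 0 | vals == 1
  ratio <- msr_depth / genome_depth
  list(fraction_homozygous = mean(hom),
       n_calls = length(vals),
       n_deviant = sum(!hom),
       depth_ratio = ratio)
}
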