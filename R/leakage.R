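#' Scan for non-syntenic linkage disequilibrium between two chromosomes
#'
#' Residual tetrasomy after the salmonid whole-genome duplication leaves
#' homeologous blocks with correlated allele frequencies, visible as
#' elevated LD between sites on different chromosomes.  Reports every
#' inter-chromosomal site pair at or above `r2_min`, plus distinct-site
#' counts per chromosome (both raw pair counts and deduplicated site
#' counts).
#'
#' @param geno samples x sites dosage matrix.
#' @param map data.frame (chrom, pos) for the columns of `geno`.
#' @param chrom_pair length-2 character vector of distinct chromosomes.
#' @param r2_min minimum r-squared to report.
#' @return list with `pairs` (data.frame chrom_a, pos_a, chrom_b, pos_b,
#'   r2), `n_pairs`, `n_distinct_a`, `n_distinct_b`.
#' @export
nonsyntenic_ld_scan <- function(geno, map, chrom_pair, r2_min = 0.2) {
  if (length(chrom_pair) != 2L || chrom_pair[1] == chrom_pair[2])
    stop("chrom_pair must name two different chromosomes")
  ia <- which(map$chrom == chrom_pair[1])
  ib <- which(map$chrom == chrom_pair[2])
  if (!length(ia) || !length(ib))
    stop("both chromosomes must be present in the map")
  ga <- geno[, ia, drop = FALSE]
  gb <- geno[, ib, drop = FALSE]
  sda <- apply(ga, 2L, stats::sd, na.rm = TRUE)
  sdb <- apply(gb, 2L, stats::sd, na.rm = TRUE)
  pa <- which(sda > 0); pb <- which(sdb > 0)
  pairs <- data.frame(chrom_a = character(), pos_a = integer(),
                      chrom_b = character(), pos_b = integer(),
                      r2 = numeric(), stringsAsFactors = FALSE)
  if (length(pa) && length(pb)) {
    r2 <- suppressWarnings(
      stats::cor(ga[, pa, drop = FALSE], gb[, pb, drop = FALSE],
                 use = "pairwise.complete.obs"))^2
    hit <- which(!is.na(r2) & r2 >= r2_min, arr.ind = TRUE)
    if (nrow(hit)) {
      pairs <- data.frame(
        chrom_a = chrom_pair[1], pos_a = map$pos[ia[pa[hit[, 1L]]]],
        chrom_b = chrom_pair[2], pos_b = map$pos[ib[pb[hit[, 2L]]]],
        r2 = r2[hit], stringsAsFactors = FALSE)
      pairs <- pairs[order(pairs$pos_a, pairs$pos_b), ]
      rownames(pairs) <- NULL
    }
  }
  list(pairs = pairs, n_pairs = nrow(pairs),
       n_distinct_a = length(unique(pairs$pos_a)),
       n_distinct_b = length(unique(pairs$pos_b)))
}

# project an interval (chrom, start, stop) through the homeolog map:
# returns data.frame of partner intervals it overlaps
.partner_intervals <- function(interval, homeolog_map) {
  out <- list()
  for (hp in homeolog_map) {
    for (side in list(c("a", "b"), c("b", "a"))) {
      from <- hp[[side[1]]]; to <- hp[[side[2]]]
      if (interval$chrom == from$chrom &&
          interval$start <= from$end && interval$stop >= from$start) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = to$chrom, start = to$start, stop = to$end,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Classify GWAS association peaks as true loci or homeolog leakage
#'
#' Processes critical intervals strongest-peak-first.  An interval is
#' labelled `leakage` when (i) it overlaps the homeolog partner projection
#' of an already-retained interval and (ii) at least `min_pairs` SNP pairs
#' between the two intervals reach `r2_min`; `unresolved` when (i) holds
#' but (ii) fails; `true_locus` otherwise.  Ties in peak significance are
#' broken by chromosome and position, making the labels invariant to input
#' order.
#'
#' @param intervals data.frame from [critical_intervals()] (needs chrom,
#'   start, stop, peak_p).
#' @param homeolog_map list of homeolog block pairs (each with `a` and `b`
#'   interval lists), as in [sim_config()]; or from [read_homeolog_bed()].
#' @param geno samples x sites dosage matrix for the LD evidence.
#' @param map data.frame (chrom, pos) for the columns of `geno`.
#' @param r2_min minimum r-squared counting as elevated inter-region LD.
#' @param min_pairs minimum number of elevated SNP pairs to call leakage.
#' @return the `intervals` data.frame with a `label` column added, in
#'   processing (strongest-first) order.
#' @export
classify_leakage <- function(intervals, homeolog_map, geno, map,
                             r2_min = 0.2, min_pairs = 10L) {
  if (!nrow(intervals)) return(cbind(intervals, label = character(0)))
  if (is.null(intervals$peak_p) || anyNA(intervals$peak_p))
    stop("intervals must carry peak significance (peak_p)")
  ord <- order(intervals$peak_p, intervals$chrom, intervals$start)
  iv <- intervals[ord, ]
  label <- character(nrow(iv))
  retained <- integer(0)
  for (i in seq_len(nrow(iv))) {
    verdict <- "true_locus"
    for (r in retained) {
      partners <- .partner_intervals(iv[r, ], homeolog_map)
      if (is.null(partners)) next
      overlap <- partners$chrom == iv$chrom[i] &
        partners$start <= iv$stop[i] & partners$stop >= iv$start[i]
      if (!any(overlap)) next
      # condition (ii): elevated LD between the two intervals' SNPs
      ii <- which(map$chrom == iv$chrom[i] & map$pos >= iv$start[i] &
                    map$pos <= iv$stop[i])
      ir <- which(map$chrom == iv$chrom[r] & map$pos >= iv$start[r] &
                    map$pos <= iv$stop[r])
      n_hi <- 0L
      if (length(ii) && length(ir)) {
        r2 <- suppressWarnings(
          stats::cor(geno[, ii, drop = FALSE], geno[, ir, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        n_hi <- sum(r2 >= r2_min, na.rm = TRUE)
      }
      verdict <- if (n_hi >= min_pairs) "leakage" else "unresolved"
      if (verdict == "leakage") break
    }
    label[i] <- verdict
    if (verdict == "true_locus") retained <- c(retained, i)
  }
  iv$label <- label
  iv
}

#' Read a homeolog block map from BED pairs
#'
#' The file holds 0-based half-open intervals, two lines per pair in order
#' (partner A then partner B), with a shared pair id in column 4.
#'
#' @param path BED file path.
#' @return list of homeolog pairs in the [sim_config()] format (1-based
#'   inclusive internally).
#' @export
read_homeolog_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name"))
  out <- list()
  for (id in unique(bed$name)) {
    rows <- bed[bed$name == id, ]
    if (nrow(rows) != 2L) stop("pair ", id, " does not have two intervals")
    out[[length(out) + 1L]] <- list(
      a = list(chrom = rows$chrom[1], start = rows$start[1] + 1L,
               end = rows$end[1]),
      b = list(chrom = rows$chrom[2], start = rows$start[2] + 1L,
               end = rows$end[2]))
  }
  out
}

#' Write a homeolog block map as BED pairs
#'
#' @param homeolog_map list of pairs in the [sim_config()] format.
#' @param path output path (0-based half-open coordinates).
#' @return `path`, invisibly.
#' @export
write_homeolog_bed <- function(homeolog_map, path) {
  lines <- character(0)
  for (i in seq_along(homeolog_map)) {
    hp <- homeolog_map[[i]]
    lines <- c(lines,
               sprintf("%s\t%d\t%d\tpair%d", hp$a$chrom, hp$a$start - 1L,
                       hp$a$end, i),
               sprintf("%s\t%d\t%d\tpair%d", hp$b$chrom, hp$b$start - 1L,
                       hp$b$end, i))
  }
  writeLines(lines, path)
  invisible(path)
}
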