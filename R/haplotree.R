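#' Extract hemizygous MSR haplotypes from a variant table
#'
#' Males carry a single copy of the male-specific region, so each called
#' genotype is one allele: hom-ref reads out as the reference base, hom-alt
#' as the alternate.  Heterozygous MSR calls violate the hemizygosity
#' contract; they are flagged, counted and set missing.  Sites with call
#' rate below `site_call_min` across males are dropped first, then males
#' missing more than `max_male_missing` of the surviving sites.
#'
#' @param table a [variant_table()] restricted to MSR sites.
#' @param males male sample ids.
#' @param site_call_min minimum per-site call rate across males.
#' @param max_male_missing maximum per-male missing fraction over
#'   surviving sites.
#' @return object of class `haplotype_matrix`: list with `males`, `sites`
#'   (chrom, pos, ref, alt), `alleles` (males x sites character matrix) and
#'   `n_het_flagged`.
#' @export
extract_haplotypes <- function(table, males, site_call_min = 0.75,
                               max_male_missing = 0.50) {
  stopifnot(inherits(table, "variant_table"))
  gt <- table$gt[, males, drop = FALSE]
  n_het <- sum(gt == 1L, na.rm = TRUE)
  if (n_het > 0L)
    warning(n_het, " heterozygous MSR call(s) set missing ",
            "(hemizygosity contract violation)")
  gt[gt == 1L] <- NA_integer_
  call_rate <- rowMeans(!is.na(gt))
  keep_sites <- call_rate >= site_call_min
  if (!any(keep_sites)) stop("all MSR sites dropped by the call-rate filter")
  gt <- gt[keep_sites, , drop = FALSE]
  sites <- table$sites[keep_sites, c("chrom", "pos", "ref", "alt")]
  miss_male <- colMeans(is.na(gt))
  keep_males <- miss_male <= max_male_missing
  gt <- gt[, keep_males, drop = FALSE]
  males <- males[keep_males]
  alleles <- matrix(NA_character_, nrow = length(males),
                    ncol = nrow(sites), dimnames = list(males, NULL))
  for (j in seq_len(nrow(sites))) {
    g <- gt[j, ]
    alleles[, j] <- ifelse(is.na(g), NA_character_,
                           ifelse(g == 0L, sites$ref[j], sites$alt[j]))
  }
  rownames(sites) <- NULL
  structure(list(males = males, sites = sites, alleles = alleles,
                 n_het_flagged = n_het),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d males x %d MSR sites\n",
              length(x$males), nrow(x$sites)))
  invisible(x)
}

#' Pairwise p-distance between haplotypes
#'
#' `d(i, j)` = differing sites / jointly-called sites (pairwise deletion);
#' zero on the diagonal.  Units are base differences per polymorphic site
#' since every matrix site is polymorphic by construction.
#'
#' @param hm a `haplotype_matrix`, or a character matrix (rows =
#'   sequences).
#' @return symmetric distance matrix; a pair with zero jointly-called
#'   sites gets `NA` with a warning.
#' @export
p_distance_matrix <- function(hm) {
  a <- if (inherits(hm, "haplotype_matrix")) hm$alleles else hm
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 haplotypes")
  d <- matrix(0, n, n, dimnames = list(rownames(a), rownames(a)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      both <- !is.na(a[i, ]) & !is.na(a[j, ])
      nb <- sum(both)
      d[i, j] <- d[j, i] <- if (nb == 0L) NA_real_ else
        sum(a[i, both] != a[j, both]) / nb
    }
  }
  if (anyNA(d)) warning("pair(s) with zero jointly-called sites: ",
                        "undefined distances")
  d
}

#' Neighbor-joining tree (Saitou-Nei agglomeration)
#'
#' At each step joins the pair minimising
#' `Q(i, j) = (n - 2) d(i, j) - R_i - R_j` (with `R_i` the row sum),
#' using the standard branch-length and distance-update formulas; ties are
#' broken towards the pair whose clusters carry the lexicographically
#' lowest taxon labels (so the result is independent of input order).
#' Negative branch lengths are clamped to zero (recorded in the
#' `clamped` attribute).  The result is unrooted (trifurcating root node).
#'
#' @param d symmetric distance matrix with zero diagonal and taxon
#'   dimnames; >= 3 taxa and no undefined entries.
#' @return an [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (anyNA(d)) stop("distance matrix has undefined entries")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  labels <- gsub("[(),:;]", "_", labels)
  sub <- labels                  # newick fragment per active cluster
  rep_lab <- labels              # lowest taxon label per cluster
  clamped <- 0L
  active <- seq_len(n)
  D <- d
  while (length(active) > 3L) {
    m <- length(active)
    Da <- D[active, active]
    R <- rowSums(Da)
    Q <- (m - 2) * Da - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12 & upper.tri(Q), arr.ind = TRUE)
    # tie-break: lexicographically lowest cluster-label pair
    ci <- rep_lab[active[cand[, 1L]]]
    cj <- rep_lab[active[cand[, 2L]]]
    lo <- pmin(ci, cj); hi <- pmax(ci, cj)
    pick <- order(lo, hi)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    ai <- active[i]; aj <- active[j]
    dij <- Da[i, j]
    bi <- dij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { clamped <- clamped + 1L; bi <- 0 }
    if (bj < 0) { clamped <- clamped + 1L; bj <- 0 }
    new_d <- (D[ai, active] + D[aj, active] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, active] <- D[active, u] <- new_d
    D[u, u] <- 0
    sub <- c(sub, sprintf("(%s:%.10g,%s:%.10g)", sub[ai], bi, sub[aj], bj))
    rep_lab <- c(rep_lab, min(rep_lab[ai], rep_lab[aj]))
    active <- c(setdiff(active, c(ai, aj)), u)
  }
  a <- active
  d12 <- D[a[1], a[2]]; d13 <- D[a[1], a[3]]; d23 <- D[a[2], a[3]]
  b1 <- (d12 + d13 - d23) / 2
  b2 <- (d12 + d23 - d13) / 2
  b3 <- (d13 + d23 - d12) / 2
  bl <- c(b1, b2, b3)
  clamped <- clamped + sum(bl < 0)
  bl[bl < 0] <- 0
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", sub[a[1]], bl[1],
                 sub[a[2]], bl[2], sub[a[3]], bl[3])
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

# canonical bipartition keys of a phylo's internal edges: each key is the
# sorted tip set on the side NOT containing the first tip label (so keys
# are rooting-invariant), trivial splits excluded
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1L]
  ntip <- length(tree$tip.label)
  internal_children <- tree$edge[tree$edge[, 2L] > ntip, 2L]
  keys <- character(0)
  for (node in internal_children) {
    clade <- ape::extract.clade(tree, node)$tip.label
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    if (length(side) >= 2L && length(side) <= ntip - 2L)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for the NJ tree of a haplotype matrix
#'
#' Resamples sites with replacement, rebuilds the p-distance matrix and NJ
#' tree per replicate, and reports for each internal bipartition of the
#' full-data tree the percentage of replicates containing it.  Replicates
#' whose resampled matrix has undefined distances are skipped (counted).
#'
#' @param hm a `haplotype_matrix`.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return list with `tree` (full-data NJ tree, node labels carrying the
#'   supports), `supports` (named percentage per bipartition key),
#'   `n_effective` replicates used, and `degenerate` flag (single-site
#'   matrix).
#' @export
bootstrap_support <- function(hm, n_replicates = 1000, seed = 1L) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  m <- ncol(hm$alleles)
  ref_tree <- nj_tree(p_distance_matrix(hm))
  ref_splits <- tree_splits(ref_tree)
  hits <- stats::setNames(numeric(length(ref_splits)), ref_splits)
  used <- 0L
  with_substream(seed, 7L, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(m, m, replace = TRUE)
      a <- hm$alleles[, cols, drop = FALSE]
      dd <- suppressWarnings(p_distance_matrix(a))
      if (anyNA(dd)) next
      bt <- nj_tree(dd)
      used <- used + 1L
      bs <- tree_splits(bt)
      inb <- ref_splits %in% bs
      hits[inb] <- hits[inb] + 1
    }
  })
  supports <- if (used > 0L) 100 * hits / used else hits * NA_real_
  ## write supports onto the reference tree's internal nodes
  ntip <- length(ref_tree$tip.label)
  node_lab <- rep("", ref_tree$Nnode)
  tips <- sort(ref_tree$tip.label)
  ref <- tips[1L]
  for (node in unique(ref_tree$edge[ref_tree$edge[, 2L] > ntip, 2L])) {
    clade <- ape::extract.clade(ref_tree, node)$tip.label
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(supports))
      node_lab[node - ntip] <- sprintf("%.0f", supports[key])
  }
  ref_tree$node.label <- node_lab
  list(tree = ref_tree, supports = supports, n_effective = used,
       degenerate = m < 2L)
}

#' Split tree leaves into two haplogroups at the longest internal edge
#'
#' Removes the internal edge with the greatest length; the two resulting
#' leaf sets are the haplogroups.  Within- and between-group mean pairwise
#' p-distances are computed from the distance matrix (pairwise deletion).
#'
#' @param tree an [ape::phylo] (ignored for 2-taxon input).
#' @param distances the p-distance matrix the tree was built from.
#' @return object of class `haplogroup_partition`: list with `group1`,
#'   `group2`, `within1`, `within2`, `between`.
#' @export
split_haplogroups <- function(tree, distances) {
  d <- as.matrix(distances)
  labs <- rownames(d)
  if (length(labs) == 2L) {
    return(structure(list(group1 = labs[1L], group2 = labs[2L],
                          within1 = NA_real_, within2 = NA_real_,
                          between = d[1L, 2L]),
                     class = "haplogroup_partition"))
  }
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2L] > ntip)
  if (!length(internal)) stop("star tree: no internal edge to split")
  lens <- tree$edge.length[internal]
  e <- internal[which.max(lens)]
  node <- tree$edge[e, 2L]
  g1 <- ape::extract.clade(tree, node)$tip.label
  g2 <- setdiff(tree$tip.label, g1)
  grp_mean <- function(g) {
    if (length(g) < 2L) return(NA_real_)
    sub <- d[g, g]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  }
  structure(list(group1 = sort(g1), group2 = sort(g2),
                 within1 = grp_mean(g1), within2 = grp_mean(g2),
                 between = mean(d[g1, g2, drop = FALSE], na.rm = TRUE)),
            class = "haplogroup_partition")
}

#' @export
print.haplogroup_partition <- function(x, ...) {
  cat(sprintf("haplogroups: %d vs %d leaves\n", length(x$group1),
              length(x$group2)))
  cat(sprintf("  within: %.3f / %.3f; between: %.3f (subs per polymorphic site)\n",
              x$within1, x$within2, x$between))
  invisible(x)
}

#' Assign the ancestral haplogroup from outgroup alleles
#'
#' A site is phylogenetically informative when both haplogroups are fixed
#' (unanimous among called alleles) for different alleles and an outgroup
#' allele is available there.  The ancestral haplogroup is the one matching
#' the outgroup allele at a strict majority of informative sites; a tie or
#' zero informative sites gives "undetermined".  Outgroup positions absent
#' from the haplotype matrix are ignored (listed in the report).
#'
#' @param partition a `haplogroup_partition`.
#' @param hm the `haplotype_matrix`.
#' @param outgroup_alleles data.frame with columns pos and allele.
#' @return list with `ancestral` ("group1", "group2" or "undetermined"),
#'   `report` (per informative site: pos, allele1, allele2, outgroup,
#'   matches), and `ignored_positions`.
#' @export
ancestral_assignment <- function(partition, hm, outgroup_alleles) {
  stopifnot(inherits(partition, "haplogroup_partition"),
            inherits(hm, "haplotype_matrix"))
  pos_in <- outgroup_alleles$pos %in% hm$sites$pos
  ignored <- outgroup_alleles$pos[!pos_in]
  og <- outgroup_alleles[pos_in, , drop = FALSE]
  rows1 <- match(partition$group1, hm$males)
  rows2 <- match(partition$group2, hm$males)
  rep_rows <- list()
  for (k in seq_len(nrow(og))) {
    j <- match(og$pos[k], hm$sites$pos)
    a1 <- unique(stats::na.omit(hm$alleles[rows1, j]))
    a2 <- unique(stats::na.omit(hm$alleles[rows2, j]))
    if (length(a1) != 1L || length(a2) != 1L || a1 == a2) next
    matches <- if (og$allele[k] == a1) "group1" else
      if (og$allele[k] == a2) "group2" else "neither"
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      pos = og$pos[k], allele1 = a1, allele2 = a2,
      outgroup = og$allele[k], matches = matches,
      stringsAsFactors = FALSE)
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(pos = integer(), allele1 = character(),
               allele2 = character(), outgroup = character(),
               matches = character(), stringsAsFactors = FALSE)
  n1 <- sum(report$matches == "group1")
  n2 <- sum(report$matches == "group2")
  ancestral <- if (n1 > n2) "group1" else if (n2 > n1) "group2" else
    "undetermined"
  list(ancestral = ancestral, report = report,
       ignored_positions = ignored)
}
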