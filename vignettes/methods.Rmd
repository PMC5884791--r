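---
title: "Methods: models, parameters and design choices in sexlinkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in sexlinkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexlinkit)
```

# The scientific problem

Salmonids determine sex through *sdY*, a male-specific gene that is
unusual among master sex-determining genes in being mobile: within
Atlantic salmon, different male lineages carry the *sdY* cassette on
different chromosomes (designated SL-02, SL-03 and SL-06 after Ssa02,
Ssa03 and Ssa06). Males are heterogametic (XY-like): they carry a single
copy of a male-specific region (MSR) that is entirely absent from
females, flanked by sequence common to both sexes (the male–female
common region, MFCR). Two further features of the salmon genome shape
any attempt to map these loci:

* the reference assembly derives from a double-haploid female, so the
  MSR is missing from it and a male-derived contig must be appended
  before reads can be mapped to the region;
* a lineage-specific whole-genome duplication left ~25% of the genome
  in large homeologous blocks whose rediploidization is incomplete.
  Residual tetrasomy keeps allele frequencies correlated between block
  partners on *different* chromosomes, so a strong association signal
  can reappear ("leak") on the homeolog partner of the truly associated
  region.

The package implements the full analysis chain for this setting —
variant QC, population divergence, case-control GWAS with leakage
classification, MSR delineation from read architecture, hemizygosity
testing, and MSR haplotype phylogenetics — plus a synthetic-data
generator that reproduces the statistical structure each stage assumes.

# The synthetic-data generator

`sim_config()` fixes the study design; all generator randomness flows
from one seed through fixed per-module substreams, so identical configs
give byte-identical outputs.

**Population model.** Ancestral allele frequencies are Uniform(0.05,
0.95); each population's frequencies are Balding–Nichols Beta draws
with drift parameter F (defaults 0.04 for the Tasmanian and North
American populations, 0.17 for the European one, echoing the ordering
of divergence between farmed strains), and diploid genotypes are
Binomial(2, p). The default sample sizes (TAS 20, NA 7, EU 13, plus 4
double-haploid females) mirror a whole-genome-sequencing study design;
association-scale analyses construct larger single-population configs.

**Sex and lineages.** Sexes alternate within population (a balanced
sampling design). Each male draws one lineage with proportions
0.25/0.25/0.50 for SL-02/SL-03/SL-06 (the observed 2/2/4 split among
eight assigned males). Genotypic sex equals cassette presence; the
recorded phenotypic sex flips with probability 0.02, matching a ~98%
phenotype/genotype concordance.

**Sex-determining anchors and linkage.** Each lineage has one anchor
locus; carrier males are heterozygous for a marker allele there (a
perfect correlate of maleness within the lineage) and share one
haplotype over a ±50 kb linked window, so nearby SNPs associate with
sex. Anchors are planted *before* homeolog mirroring so that linked
associations can leak to partner blocks; the anchors themselves are
excluded from mirroring.

**Homeolog blocks.** The default map pairs the two halves of the Ssa02
proxy with the Ssa05 and Ssa12 proxies and the Ssa03 proxy with the
Ssa06 proxy. For half of the sites in each block (fraction 0.5) the
partner site's genotype is copied per sample with probability rho
(default 0.9), producing non-syntenic LD; rho = 1 with fraction 1 gives
perfectly mirrored blocks (r² = 1), rho = 0 a fully rediploidized
genome.

**Alignments.** Reads are emitted as already-mapped records rather than
through an aligner: the analyses consume mapped architecture only, and
this keeps the package download-free and fast. All fish carry the MFCR
flanks at full coverage with reads soft-clipped at the MSR boundary
(mimicking how an aligner clips reads at a deletion breakpoint, and
making female depth stop exactly at the junction); SL-02 males add a
contiguous Y-haplotype layer across the whole contig at half coverage,
producing proper FR pairs spanning the junction; SL-03/SL-06 males
instead carry the MSR on their lineage chromosome, so MSR fragments
overhanging the junction become orphan reads whose mates map to that
chromosome, with a 1/3 minority on its homeolog partner (reproducing
the observed mixed orphan tally). Per-base depth is Poisson at 40×
(20× over the MSR in males, 0 in females); inserts are Normal(400, 50)
with 150 bp reads. A 20 kb window on the last chromosome provides the
genome-wide depth baseline.

**Variant table.** Depth is Poisson; alt-allele depth is
Binomial(DP, f) with f = 0.5 for heterozygotes and the sequencing error
rate (default 0.003) for homozygotes; genotypes are missing iff depth
is zero; site mapping quality is Normal(58, 3) with a 2% low-MQ
fraction. Double haploids are homozygous everywhere except 50 planted
paralog-collapse artifact sites, which are heterozygous in every
sample. MSR haplotypes split into two haplogroups whose cores differ at
78% of the 22 polymorphic MSR sites, with a 5% within-group per-site
flip rate; SL-03 and SL-06 males draw from the same core, leaving them
nearly indistinguishable.

**What it does not emulate.** No recombination maps, selection, indels,
base-quality strings or sequence-level realism; no local LD outside the
anchor windows; no mismapping of female reads into the MSR (available
as `female_msr_noise`, default 0). Passing tests therefore demonstrate
correctness of the inference machinery under the stated statistical
structure, not robustness to alignment artifacts in real data.

# Analysis models and numerical choices

**QC filters.** Sites with MQ < 50 are removed, genotypes with DP < 5
set missing, non-biallelic/non-SNP records dropped; boundaries keep
exactly-50 and exactly-5. "Presence in a double-haploid genome" is read
as a heterozygous call: a hom-alt DH call is a legitimate allele, while
a het call is impossible in a doubled haploid and marks an artifact.
After binomial depth thinning, genotypes are re-called (missing below
DP 5, hom-ref below alt fraction 0.2, hom-alt above 0.8) — thresholds
chosen to mimic a caller's behaviour at low depth, since no published
rule exists. Loci whose ref/alt pair disagrees between genotype sources
are excluded from concordance rather than recoded (no strand
reconciliation rule is defined).

**Diversity and divergence.** Per-site π uses the unbiased estimator
c(n−c)/(n(n−1)/2); the window denominator is the full window length
even where callability is lower, matching the convention of the
standard windowed-π tools. F_ST is the Weir–Cockerham (1984) per-site
ratio θ̂ = a/(a+b+c); the summary is the unweighted mean of per-site
estimates (the ratio-of-sums variant is also reported). r² is the
squared Pearson correlation of 0/1/2 dosages (composite LD — the input
is unphased); for RAF comparisons both r and r² are reported since
published "correlations" are ambiguous between the two. LD pruning
removes the *later* site of the worst offending pair within sliding
windows. "PCA" is classical MDS of the allele-sharing distance — the
double-centred eigendecomposition — with variance fractions over the
positive eigenvalues.

**GWAS.** Case-control association uses OLS of the 0/1 phenotype on
dosage (the analysis is described as linear regression in this
tradition even when tooling flags say otherwise; logistic regression
offers no benefit for rank/threshold decisions here and OLS p-values
are well calibrated at these sample sizes — type-I error is verified at
0.04–0.06 in the tests). P-values are floored at the smallest positive
double with the corresponding capped −log10 score. Critical intervals
take the top ceil(0.5%) of each chromosome's SNPs; min–max span without
a contiguity requirement. A chromosome is reported only if its peak
passes genome-wide Bonferroni at 0.05 — an explicit gate standing in
for the visual distinction between association peaks and isolated SNPs.
Pedigree checking compares tabular-method A against VanRaden-1 G;
|A−G| > 0.25 (between the unrelated expectation 0 and parent-offspring
0.5) marks a pair, and ≥ 2 such pairs flag an animal ("multiple
inconsistencies").

**Leakage.** Intervals are processed strongest-peak-first (ties broken
by chromosome and position, making labels input-order invariant). An
interval is `leakage` iff it overlaps (≥ 1 bp; no reciprocal-fraction
requirement) the homeolog partner projection of an already-retained
interval *and* ≥ 10 SNP pairs between the two intervals reach
r² ≥ 0.2 — thresholds taken from the r² bands used to report elevated
and extreme non-syntenic LD. Partner overlap without LD support yields
`unresolved` rather than a hard call.

**Junction detection.** The female/male mean-depth ratio
f(x) = meanF/max(meanM, ε) is smoothed by a 201 bp centred moving
average (edge windows shrink rather than drop) and fitted with a
two-segment piecewise-constant model by exhaustive changepoint search;
a cut is admissible only when the left segment mean is below 0.25, the
right above 0.5, and both segments are ≥ 500 bp. The MSR is the low
segment and the junction its last base. The algorithm is this package's
own formalisation of what is otherwise done by eye in a genome browser;
the thresholds are exposed as arguments. The short MFCR stub before the
MSR start is absorbed into the low segment; at the default geometry
(2 kb stub, 11.3 kb MSR) its contribution keeps the low-segment mean
near 0.15, inside the contract. The smoothing window sets the
resolution: detected junctions land within ~½ window of the true
boundary, which motivates the ±100 bp recovery tolerance used in the
tests (20 seeds).

**Lineage calls.** "Correct orientation and spacing" is operationalised
as FR orientation with implied insert within ±3σ; ≥ 3 spanning pairs
are required for an `anchored` call (guarding against chimeric pairs).
Otherwise reads within 2 kb inside the junction whose mates map
elsewhere are tallied per mate chromosome; chromosomes with ≥ 2 mates
form the candidate set (the rule accepts a 2-read minority
chromosome), giving `translocated`, else `unassigned`.

**Hemizygosity.** BAF = AD_alt/DP, undefined at DP 0. The homozygosity
fraction counts *exact* membership in {0, 1} — a single stray read
makes a genotype deviant, matching how a 14/15 site (BAF 0.933) is
treated as a deviation rather than rounded up. MSR sites require a call
(DP ≥ 5) in zero females and ≥ 95% of males.

**Haplotypes and trees.** Haplotype filtering applies two ordered
filters: site call rate ≥ 75% across males first,
then male missingness ≤ 50% over surviving sites. Heterozygous MSR
calls violate hemizygosity; they are flagged and set missing.
p-distance uses pairwise deletion; its denominator is jointly-called
(all polymorphic) sites. NJ is the Saitou–Nei agglomeration with the
standard Q criterion; ties are broken towards the pair whose clusters
carry the lexicographically lowest taxon labels — a deterministic rule
that, unlike an input-index rule, is invariant to input order when
duplicate haplotypes produce genuine ties. Negative branch lengths are
clamped to zero and counted. Bootstrap support resamples sites with
replacement and scores each internal bipartition of the full-data tree
by its replicate frequency. Haplogroups split at the longest internal
edge (formalising "a clear bifurcation"); ancestral assignment requires
a site where both groups are fixed for different alleles and an
outgroup allele exists, and takes a strict majority across informative
sites (a 2–2 split is undetermined; the motivating use case is a
unanimous 4/4 match).

# Problem sizes used in the tests

The suite validates at sizes a laptop handles in about two minutes:
junction recovery over 20 seeds of the default 12-genome design;
lineage calls for 100 males; 100 leakage replicates at 300 samples ×
~6,000 SNPs with fully mirrored blocks (rho = 1, so the planted leak is
deterministic and recall can honestly be required to be 100/100);
100 haplogroup replicates at 12 males × 60 sites with a planted
between/within divergence ratio of ~7.6; and a 10,000-SNP × 500-sample
null for the type-I error check. Oracles are independent: a separate
brute-force transcription of the Weir–Cockerham components, exhaustive
least-squares quartet enumeration for NJ, and hand-evaluated π sums.

# Known limitations

* The junction detector assumes a single MSR interval per contig; a
  fragmented MSR would need a multi-changepoint extension.
* Leakage classification relies on the provided homeolog map; it does
  not infer homeology from sequence.
* Sequence data alone cannot separate SL-03 from SL-06 (their
  haplotypes are nearly identical and each male's orphan mates split
  across both chromosomes); the package reports the candidate set
  rather than forcing a choice.
* VanRaden G with frequencies estimated from few samples is shrunken;
  pedigree checks at small n should pass known base-population
  frequencies.
* The hemizygosity fraction under the default sequencing error rate is
  lower than in published real-data reports, where base-quality
  filtering suppresses most error reads before allele depths are
  computed; error-free configurations recover fraction 1 exactly.
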