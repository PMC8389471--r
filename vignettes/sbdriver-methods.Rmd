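---
title: "Statistical methods behind sbdriver"
author: "sbdriver authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind sbdriver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbdriver)
```

# The problem

Sleeping Beauty (SB) insertional mutagenesis screens mobilize a bifunctional
transposon genome-wide in mice. The transposon reintegrates at TA
dinucleotides; its internal promoter/splice donor can activate a
proto-oncogene, and its bidirectional splice acceptors and polyA can truncate
a tumor suppressor. Sequencing the transposon-genome junctions of each tumor
yields, per specimen, a table of insertion sites with supporting read depths.
Genes that accumulate more insertions across a tumor cohort than a neutral
model predicts are candidate cancer drivers (CCDs).

`sbdriver` implements the full analysis path from those per-specimen
insertion calls to tiered driver lists, together with a synthetic-cohort
generator so that every stage can be validated against planted ground truth.

# The insertion null model

Under neutral transposition, insertions fall uniformly over the genome's TA
sites. A gene's exposure is therefore not its length but the number of TA
dinucleotides in its footprint, $t_g$ (computed from the genome sequence;
overlapping occurrences count, so `TATA` holds two sites). For a cohort with
$N$ qualifying insertions over $T$ TA sites, the background rate is
$\lambda = N/T$ per site and the per-gene insertion count is modeled as

$$k_g \sim \mathrm{Poisson}(\mu_g), \qquad \mu_g = \lambda\, t_g,$$

with a one-sided enrichment p-value $P(X \ge k_g \mid \mu_g)$. A gene with no
TA site cannot be tested under this null and is reported with $p = 1$ and a
warning. The Poisson count model is this package's operationalization of
"more insertions than expected by chance"; it has a single tunable background
(the cohort rate) and is checked in the test suite against term-by-term pmf
summation to $10^{-12}$.

## Driver tiers

Three tiers share the Poisson test and differ in which insertions qualify and
how multiplicity is controlled:

* **discovery** — all insertions, Benjamini–Hochberg FDR, significant at
  $q < 0.5$. A deliberately lenient screening tier.
* **progression** — all insertions, family-wise error control (Holm
  step-down by default, Bonferroni by configuration), adjusted $P < 0.05$.
* **trunk** — only clonal insertions (read depth strictly above the depth
  cutoff, default 300), FWER-controlled at 0.05. Trunk drivers are read as
  early, positively selected events present in the founding clone.

Every tier additionally requires recurrence in at least 3 tumors (a
reporting filter applied after adjustment, configurable via `minTumors`).
Both adjustments are delegated to `stats::p.adjust` and cross-checked in the
tests against independent sorted-scan implementations.

## Donor chromosome and local hopping

SB reintegrates preferentially in *cis* near its donor concatemer, inflating
insertion rates in a window of the donor chromosome. `donorHotspotRegion()`
scans the donor chromosome in fixed bins (default 1 Mb), tests each bin's
count against $\lambda_0 \cdot t_{\text{bin}}$ with $\lambda_0$ estimated
from all non-donor chromosomes, Bonferroni-corrects across bins, and reports
the *maximal contiguous run* of significant bins. The maximal-run rule is
deliberate: at $\alpha = 0.05$ the family of bin tests retains a ~5% chance
of one isolated false-positive bin somewhere, and an isolated bin cannot
displace a longer genuine run.

Driver calling then censors the window (`donorExclusion`): genes overlapping
it are dropped, and its insertions and TA sites are removed from the donor
partition's background rate. Donor and non-donor partitions are tested
separately, each with its own $\lambda$, and merged into one list (smaller
adjusted p wins for duplicated genes; genes lie on one chromosome, so this
matters only for pathological annotations).

## Clonality thresholds

Read depth proxies the cell fraction carrying an insertion. The cutoff is
derived from a reference cohort without clonal expansion (normal tissue) as
the smallest whole number $r$ such that the proportion of cohort insertions
with depth $> r$ is at most $1 - p$ (default $p = 0.95$). Clonality uses the
strict rule `readCount > cutoff` everywhere, including at the multi-region
cutoff of 200 (the top-30% rule for shallower regional libraries). The
package ships 300 and 200 as configured defaults for bulk and regional
analyses respectively; `deriveDepthThreshold()` returns the exact bound for
whatever cohort it is given, with no rounding to convenient numbers.

## Orientation classification

Activating insertions are same-strand (sense) relative to the gene and
positionally clustered (the promoter/splice-donor fuses to a downstream
portion of the transcript); inactivating insertions are strand-indifferent
and dispersed. With at least `minSites = 3` qualifying insertions,
`classifyOrientation()` runs a two-sided exact binomial test of the sense
fraction against 0.5 and measures clustering by the IQR of relative
positions along the gene:

* significant antisense excess → inactivating;
* significant sense excess with IQR < 0.5 → activating;
* dispersed (IQR ≥ 0.5), with or without strand bias → inactivating;
* otherwise indeterminate.

The thresholds are exposed heuristics, not fitted quantities. Note that the
sample IQR of a perfectly uniform positional spread sits slightly *below*
0.5 at small n (type-7 quantiles), so sparse dispersed patterns can land in
"indeterminate"; that conservatism is accepted.

## Mutual exclusivity

Two drivers hitting the same pathway tend to be altered in different tumors.
The test statistic is the number of specimens altered in both genes; the
null preserves *all* row sums (per-specimen alteration burden) and column
sums (per-gene frequency) of the binary specimen × gene matrix via a
sequential checkerboard-swap Markov chain, implemented as a small compiled
kernel that flips 2×2 checkerboards in place and records only the focal-pair
overlap. The one-sided exclusivity p-value is
$(1 + \#\{\text{null} \le \text{obs}\})/(1 + n_{\text{perm}})$.

Numerical choices: burn-in is $10 \times$ (number of 1s) *successful* swaps
— on dense cohort matrices the acceptance rate is a few percent, and an
attempt-counted burn-in leaves the chain measurably autocorrelated with the
observed matrix, which biases the p-value upward; thinning between samples
is $10 \times$ (number of 1s) swap *attempts*, which keeps 10,000 samples
tractable at the cost of some autocorrelation (the estimator remains valid;
its Monte-Carlo error is what the tests budget for). A matrix with only the
two focal columns is degenerate under this null — the overlap is invariant
under swaps — so the test should always be conditioned on the cohort-wide
alteration matrix. Degenerate margins (a gene altered in no or every
specimen) are flagged rather than tested.

## Multi-region heterogeneity

For masses sequenced in several histologically distinct regions,
`buildRegionMatrix()` marks gene × region cells clonal at the regional
cutoff, and `clusterBinaryMatrix()` clusters both axes with the normalized
Hamming distance (fraction of mismatching entries — scale-free across
matrices of different gene counts) under Ward linkage
(`hclust(method = "ward.D2")`, the R equivalent of SciPy's `ward` on a
precomputed distance). Ward linkage formally presumes Euclidean geometry;
applying its update formula to Hamming distances is a documented convention
of this analysis style, not a theoretical claim. Ties in agglomeration
resolve by lowest pair index, so dendrograms are reproducible.
`sharedAddressTrunk()` separates clonal descent (the same TA address in
every region) from independent recurrent targeting (a gene hit in all
regions at different addresses).

## SB fusion reads

Insertion-driven transcripts appear in RNA data as reads chimeric between a
transposon splice-donor/acceptor sequence and an annotated exon.
`detectFusionReads()` is an exact-match detector for desk-scale validation:
a read is called iff it contains a motif exactly (tried as-is and
reverse-complemented) and the $k$ = 20 flanking bases on the fused side map
uniquely to an exon boundary (exon prefix for SD, suffix for SA). Sense SD
fusions are activating truncations; every other element/orientation
combination is inactivating. The motif sequences are configurable inputs —
they are properties of the transposon construct, not constants of the
package — and spliced alignment is out of scope by design: the detector
validates the concept against the simulator's read-level manifest, where it
achieves exact recall and precision by construction of the uniqueness rule.
`expressionContrast()` consumes an already-normalized expression matrix
(normalization is standard upstream tooling) and reports group means and
fold changes by insertion status, with explicit untestable flags.

# The synthetic cohort generator

`simConfig()`/`simulateGenomeModel()`/`simulateCohort()` define the study
conditions the package is tested under:

* **genome** — i.i.d. sequence at GC 0.42 (mouse-like; TA density follows
  from composition: $(L-1) p_T p_A$), non-overlapping genes placed uniformly.
* **burden** — negative binomial per genome, mean 1,320 and size 2, giving
  the long right tail (ranges past 3,800) seen in screen tissue with high
  insertional load.
* **depths** — subclonal depths are geometric with mean 3 (well under 1% of
  normal-tissue insertions exceed a 300-read cutoff); clonal depths are
  log-normal with median 3,000 = 10 × the cutoff and sdlog 0.5. Tumors draw
  a clonally-expanded passenger fraction of 0.085 at clonal depth; normals
  never draw clonal depths.
* **drivers** — activating drivers plant sense-strand clonal sites clustered
  in a relative window (default 0.25–0.45) of the gene; inactivating drivers
  plant clonal sites on either strand across the body; 1–2 sites per
  carrier. Drivers sharing an `exclusiveGroup` receive disjoint carrier
  sets, the mutually-exclusive paralog pattern.
* **local hopping** — a multiplicative rate elevation (default 10×) inside a
  configured donor window, flat outside it.

Every planted site is recorded in a ground-truth manifest, and identical
`(config, seed)` pairs reproduce outputs exactly.

What the simulator does *not* emulate: sequencing error and PCR duplication,
chromatin- or expression-biased insertion preferences, subclonal phylogenies
deeper than shared/private, and — importantly — realistic genic fraction. At
desk scale genes cover ~40% of the simulated genome versus a few percent of
a mammalian genome, so per-gene background collision rates are much higher
than in real cohorts; statistical calibration and recovery results transfer,
absolute per-gene coincidence rates do not. This is why the worked
exclusivity example conditions on sense-strand clonal alterations for an
activating pair.

# Problem sizes and numerical conventions

The shipped tests run at sizes chosen to exercise the statistics while
staying desk-scale: a shared 2 × 3 Mb, 500-gene genome for calibration and
recovery (20 cohorts of 20 tumors for null calibration; 20 seeds with five
planted drivers at carrier fractions 0.35–0.7 for recovery); 40 seeds of
two 3-region masses for clustering; 500 reads with 50 planted fusions for
the detector; 10,000 permutations for exclusivity. The acceptance script
simulates one full-scale cohort (60 tumors, 32 normals) on a 2 × 5 Mb,
400-gene genome.

Conventions worth knowing when extending the package:

* coordinates are 1-based inclusive internally, 0-based half-open in BED;
  the TA position is the first base of the dinucleotide;
* clonality is strictly `readCount > cutoff` at every cutoff;
* `collapseToSites()` sums depths over duplicate `(specimen, chrom, pos)`
  keys and keeps the maximal-depth strand, `+` on ties, warning on
  conflicts;
* multi-gene overlaps credit the insertion to every gene (flagged
  `multiHit`); partition totals count each site once;
* empty and degenerate inputs (no shared replicate sites, constant depth
  vectors, all-zero genes, degenerate exclusivity margins, constant region
  matrices) return flagged results rather than errors wherever a downstream
  decision is still possible.

# Known limitations

* The Poisson null ignores insertion-site autocorrelation within a clone
  (several reads of one expansion are collapsed to one site, but multiple
  nearby sites of one clone are not modeled); FWER control in trunk mode is
  the guard against the resulting optimism.
* The original screen's driver statistic is defined in external software
  that this package does not reproduce verbatim; driver counts on real
  cohorts may differ from published lists even at identical thresholds.
* The fusion detector requires exact motif and flank matches; it is a
  validation instrument, not a replacement for spliced alignment on real
  RNA-seq.
* Ward-on-Hamming is a convention; for large region matrices a binary-aware
  linkage may be preferable.

# A minimal worked run

```{r example, eval = FALSE}
cfg <- simConfig(nChroms = 2L, chromLength = 1e6, nGenes = 100L,
                 nTumors = 20L, nNormals = 10L, burdenMean = 500,
                 drivers = data.frame(gene = "gene010",
                                      mechanism = "activating",
                                      carrierFraction = 0.5))
genome <- simulateGenomeModel(cfg, seed = 1)
cohort <- simulateCohort(cfg, genome, seed = 2)

ann <- annotateInsertions(cohort$tumors, genome$model)
cfgT <- driverConfig("trunk", depthCutoff = 300L)
drivers <- callDrivers(geneInsertionStats(ann, genome$model, cfgT), cfgT,
                       annotated = ann)
significantDrivers(drivers)
```
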