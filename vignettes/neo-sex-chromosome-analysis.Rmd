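---
title: "Methods: detecting and dissecting a young neo-W chromosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and dissecting a young neo-W chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `neosexkit`, the provenance and
meaning of every tunable parameter, what the synthetic-data generator does
and does not emulate, and the numerical choices made where the design was
genuinely open. It states no empirical numbers beyond those the test suite
and `scripts/acceptance.R` themselves compute.

## The system being modelled

A Z-autosome fusion in a species with achiasmatic female meiosis creates a
neo-sex pair: the fused element behaves as a **neo-Z** (recombining in
males), while the unfused homolog cosegregates with the W and becomes a
**neo-W** that never recombines. Consequences exploited by the analysis:

1. In heterogametic females, reads from both neo-W and neo-Z map to the
   same reference, so per-site heterozygous density **H** in females
   measures neo-W/neo-Z divergence; males (two neo-Z copies) stay at the
   autosomal level.
2. The neo-W is inherited as one haplotype, so divergence should be uniform
   along the chromosome — unless a rare historical exchange with the neo-Z
   locally reset it, creating **plateaus** with sharp boundaries, each
   dating a rescue event.
3. Variation among neo-W haplotypes sampled from several females must be
   consistent with a *single genealogy* (perfect phylogeny under infinite
   sites), in contrast to recombining sequence.
4. Without recombination, selection is inefficient: loss-of-function (LoF)
   alleles fix, sequence is lost (reduced read mapping), and expression
   shifts toward the neo-Z — all in proportion to how long a plateau has
   been non-recombining.

## Stage models

### Variant filtering

Hard record-level filters: SNPs need genotype quality ≥ 10 and per-sample
depth between 8 and 3× that sample's mean genome depth in every non-missing
genotype, must pass strand-balance and read-placement flags, and must lie
more than 2 bp from any non-SNP variant. Excluded SNP positions are excised
from the callable mask so that numerators and denominators stay consistent;
indels are optionally retained under the depth/quality rules only. A record
with any failing genotype is dropped entirely (the conservative reading of
a cohort-level filter); the filter is idempotent. Coordinates are VCF
1-based for sites and BED 0-based half-open for all interval arithmetic,
converted only at the boundary.

### Diversity and divergence

π is the mean pairwise difference per callable site (per-site allele counts
adjusted for missingness); H is per-sample heterozygous density; dxy the
between-group mean pairwise difference; FST is Hudson's `1 − π̄/dxy`
(the source analysis does not name its estimator; Hudson's form is the one
consistent with dxy and da already being computed); `da = dxy − π̄`.
Codon degeneracy (0D/2D/3D/4D) is classified per CDS site, strand- and
phase-aware, by counting which of the three possible substitutions preserve
the amino acid under the standard code.

The **moments split time** `T̂ = max(0, (dxy − π̄)/(2μ))` is an explicit,
documented stand-in for composite-likelihood demographic fitting, which is
out of scope. It is unbiased only when the mean of the two derived-population
diversities is a fair proxy for ancestral diversity (`π̄ ≈ 4 μ Ne_anc`);
under strong size asymmetry it inherits the classical net-divergence bias.
The test suite quantifies this by parameter recovery on simulated
strict-divergence data (recovery within 15% under the default generator
conditions); per-plateau `T̂` values on the neo-sex chromosome are
interpretable only as an ordering, because female H contains the full
ancestral coalescent depth that the small within-class diversities cannot
subtract.

### Change-point segmentation

Windowed female H (masked windows removed) is segmented with the
Barry–Hartigan (1993) product-partition model, Gibbs-sampling the change
indicator at every window boundary. Priors are uniform on `[0, p0]` for the
change probability and `[0, w0]` for the signal-to-noise ratio with the
conventional defaults `p0 = w0 = 0.2`, 550 sweeps, 50 burn-in (the
segmentation literature's package defaults; the source analysis names no
settings). The conditional odds combine a truncated-Beta prior ratio with
the marginal-likelihood ratio
`∫₀^{w0} w^{b/2} (W + Bw)^{−(n−1)/2} dw`, evaluated by 64-point
Gauss–Legendre quadrature on the log scale. The posterior mean reported per
window is the average of per-sweep block means (the no-shrinkage `w → 0`
limit of the conditional posterior mean); change probabilities are
visit frequencies after burn-in. Numerical guards: an exactly constant
series returns prior-level probabilities and a flat mean; within-block sums
of squares are floored at `1e-12` of the total to avoid degenerate
likelihoods. The sampler is deterministic given a seed. A deterministic
binary-segmentation fallback with BIC stopping (`binseg_boundaries()`) is
provided for exact-reproducibility checks.

Plateau extraction thresholds boundaries at posterior probability 0.5 and
merges segments shorter than 5 windows into the neighbour with the closer
mean — the analysis expects a few large plateaus, so shorter segments are
treated as noise; both knobs are exposed. Because posterior mass can split
across adjacent boundaries, recovery is assessed within ±2 windows.
The lowest-coverage 20% of windows are excluded *from segmentation only*
(they are poorly mapped on the neo-W and bias H); coverage summaries per
plateau use all windows, since masking by low coverage would bias covW
upward.

### Phasing from diagnostic alleles

A site is neo-W-diagnostic when the alternate allele is heterozygous in
every non-missing female and absent from every male; a missing male
disqualifies the site (absence unverifiable) and missing females are
tolerated up to a configurable count (default 0, the strict reading of
"each female"). The W haplotype takes the diagnostic allele, the female
complement the other; male genotypes are homozygous by construction and
collapse to one Z haplotype each. Missing genotypes stay missing — no
imputation. Consecutive females are paired deterministically into
pseudo-diploids for diploid-based divergence estimators.

Two fidelity gaps are inherent to genotype-level phasing and are stated
rather than hidden. First, the criterion cannot see variation *within* the
neo-W clade (such sites are not heterozygous in every female), so the
single-genealogy test consumes per-female haplotype calls — the product of
read-backed phasing, which the generator emits exactly, and which real
pipelines produce by extracting reads carrying diagnostic alleles and
re-calling variants. Second, a neo-Z variant private to all female
complements satisfies the genotype pattern and produces a rare false
diagnostic site; the generator's truth tables label such confounded sites
so the tests can bound their rate.

### The single-genealogy (tree) test

Each bi-allelic site induces an unordered bipartition of the haplotypes;
the canonical **folded type** is the smaller side (ties at `n/2` resolved
by excluding the lexicographically-first label). A single resolved
genealogy over n haplotypes can generate only the `2n − 3` types matching
its edges, against `2^(n−1) − 1` possible types. (A widely used summation
formula for that count double-counts the balanced class for even n; the
implementation uses `2^(n−1) − 1`, which agrees at every odd n, including
n = 7 where both give 63.)

Types are ranked by count (ties by canonical key, deterministically) and
accepted greedily when pairwise compatible (two splits are compatible iff
one of the four side-intersections is empty); accepted splits assemble
uniquely into an unrooted tree via a laminar-family construction rooted at
the first label. This greedy-by-frequency procedure is the package's
interpretation of "maximum parsimony from type frequencies": with conflicts
rare, the majority tree maximizes the parsimony-consistent variant count.
The consistency statistic is the fraction of variants whose type is
accepted. Inconsistent variants are tested for physical clustering with a
Wald–Wolfowitz runs test on positions (recombination makes conflicts
cluster; back-mutation and genotyping error do not).

Polarization uses outgroup (unfused-homolog) alleles: the derived allele is
the one not matching the outgroup; fixed-derived sites are excluded; types
not on the tree are discarded; a pattern observed as the complement of a
tree split is reassigned to the canonical (smaller) side — the same
orientation convention as the folding, which slightly undercounts genuinely
majority-sized derived sets but is deterministic and matches how
mispolarization presents in practice. The TMRCA estimator — mean
per-individual derived density divided by μ — equals mean tip depth, i.e.
the clade TMRCA exactly only for a star genealogy (the expected shape after
the sweep that fixes a recombinant neo-W); for non-star trees it is a lower
bound, which the tests respect by validating recovery on simulated stars.

The neutral reference for the folded spectrum gives a type with smaller
side i expectation `θ (1/i + 1/(n−i)) / C(n,i)` (balanced class:
`θ (2/n) / (C(n, n/2)/2)`); unnormalized expectations sum to Watterson's
`θ Σ 1/i`, which the tests assert exactly.

### Degeneration

`covW = (covFemale − covMale/2) × 2` with both inputs as focal:autosome
depth ratios normalized per sample; negative estimates are clamped and
flagged. LoF classification is a deterministic CDS-aware re-implementation
of exactly four categories — premature stop, frameshift (indel length not
divisible by 3 wholly inside the CDS), start-loss, stop-loss — with
boundary-spanning variants conservatively excluded and splice effects not
modelled (not in the category set). "Fixed on the neo-W" means carried by
every neo-W haplotype with a non-missing call; the pipeline additionally
requires absence from every neo-Z haplotype, because a variant shared with
the neo-Z is ancestral polymorphism or a reference-derived state, not
W-specific decay. Proportions are reported over genes with nonzero
expression, with exact Clopper–Pearson intervals (also used for the neo-W
carrier frequency; exact inversion reproduces the 0.59 lower bound for
7 of 7 and is the natural reading of "assuming binomial sampling").
For allele-specific expression, genes below a minimum total count are
excluded; genes with zero neo-W counts get fraction 1 but are excluded from
the median fold (undefined ratio) and counted separately.

## The synthetic-data generator

Every block of 64 bp (the block-wise assumption of the target analysis:
no recombination within a block, free recombination between blocks) gets an
independent genealogy from a compiled Hudson-style structured coalescent —
demes with diploid-scale sizes (pairs coalesce at `1/(2Ne)`), scheduled
deme mergers, delayed lineages, Poisson mutations with infinite sites
within a block.

Default conditions (all overridable via `sim_config()`):

* μ = 2.9e-9 /site/generation; generation time 1 year.
* Iberia/Maghreb split `T = 1.5e6` generations; East/West Maghreb split
  7.5e5 (a plausible intermediate; only the Eastern deme is used
  quantitatively); ancestral Ne 1.1e6.
* Derived sizes `Ne_Iberia = 6.47e5`, `Ne_EastMaghreb = 1.724e6`,
  `Ne_WestMaghreb = 1.12e6` — chosen so `4Neμ` matches each population's
  observed 4-fold-degenerate diversity. Realized single-population
  diversity also includes the ancestral-escape term
  `2μ[2Ne(1−e^{−T/2Ne}) + e^{−T/2Ne}·2Ne_anc]`, which the tests assert
  against simulation. With these conditions the moments estimator's
  net-divergence bias stays within its 15% recovery band; the
  jointly-fitted composite-likelihood sizes for the same populations are
  substantially different and would push the moments stand-in far outside
  it, which is a property of the estimator, not of the fit.
* Neo-sex chromosome: per-plateau split times 1.4e6 / 8.6e5 / 5.0e5
  generations with per-plateau ancestral sizes 1.3e6 / 9.8e5 / 5.7e5 and
  `Ne_neoZ = 2.6e5`; the merged population keeps the plateau's ancestral
  size into the deep past, so the expected female H per plateau is exactly
  `2μ(T_k + 2Ne_anc_k)` — ordered and well separated. Plateau widths
  210/30/20 windows mirror the 10.5 : 1.5 : 1 Mb physical proportions.
* The neo-W clade (`Ne_neoW = 2.1e4`) has one chromosome-wide genealogy —
  full linkage — truncated at a TMRCA cap of 5e4 generations (the sweep
  fixing the last recombinant haplotype bounds the clade age); lineages
  uncoalesced at the cap join in a polytomy, and `Ne_neoW → 0` gives the
  star limit. Per-block mutations on this shared tree are independent.
  An optional rescue region redraws the clade topology inside chosen
  windows, creating the clustered tree-conflicts the runs test detects.
* Windows are 12,800 bp with 100 callable 64-bp blocks each (the physical
  window size is a free parameter of the windowed analysis; the callable
  content per window is what controls estimator noise). Chromosome sizes:
  260 windows neo-sex, 60 autosome, 30 Z — sized so the full pipeline,
  the 200-landscape segmentation experiment and the 2,000-gene LoF
  experiment all run in minutes on one CPU; these are the problem sizes the
  tests and acceptance experiments use.
* 120 two-exon genes (300-bp CDS, alternating strands) on the neo-sex
  chromosome; LoF injection per gene with probability
  `1 − exp(−rate·T_k)`, rate 2.25e-7 per generation (calibrated so the
  oldest plateau's injected proportion is near one quarter), category
  uniform over the four classes, placed on the neo-W stem. Note the
  pipeline's *measured* fixed-LoF proportion also contains LoF arising
  from neutral W-lineage divergence since the fusion — the injected rate
  parameterizes degeneration beyond that neutral floor.
* Coverage: male focal:autosome ratio 1; female `(1+m_k)/2` with mapping
  rates 0.8/0.8/1.0 per plateau; gamma noise with CV 0.05; mean depth 20×.
  Expression: per-gene totals NB(mean 200, size 8); neo-Z:neo-W fold
  log-normal with median 1.5 (sdlog 0.4).
* Maghreb demes are simulated without post-split migration (strict
  divergence, the best-supported history for the system the package
  targets); a migration-rate slot is reserved but unused.

What the generator deliberately does **not** emulate: read-level error and
mapping bias (genotypes are clean; strand/placement flags are always true),
linked selection and background selection (degeneration is imposed, not
evolved, so π0/π4 at simulated neutral sites is ~1 and reduced neo-W
diversity is enforced through `Ne_neoW` rather than emerging), transposable
elements and structural variation beyond 1-bp frameshift indels, intra-block
recombination, and female Z hemizygosity is represented as homozygous
genotypes. Passing tests therefore validate the estimators and their
wiring, not robustness to genotyping error or reference bias in real data.

## Known limitations

* The tree test consumes phased haplotype calls; with genotype-only input
  the package phases diagnostic sites but cannot generate within-clade
  variation (see the fidelity gaps above).
* The moments split time is a biased stand-in whenever ancestral and
  derived diversities differ; treat per-plateau values as an ordering.
* The TMRCA estimator assumes a star-like clade genealogy.
* The LoF classifier ignores splice sites and compound effects; a variant
  is classified in isolation against the reference CDS.
* PCA sex-separation uses the best single threshold on PC1 and is
  optimistic for small samples; the test suite bounds, but does not remove,
  that optimism.
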