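---
title: "LD-aware design and analysis of trait-enriched genotyping arrays"
author: "ldarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-aware design and analysis of trait-enriched genotyping arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldarray)
```

# The problem

Custom follow-up genotyping arrays concentrate their content where GWAS
meta-analyses point: a few thousand "replication" SNPs per trait carrying
the top independent association signals, plus dense "fine-mapping" panels
that exhaustively cover LD-defined intervals around genome-wide-significant
index SNPs. Such arrays are cost-efficient, but the same enrichment that
makes them useful breaks the assumptions behind routine analysis steps.
Genomic control, PCA-based stratification correction and kinship estimation
all presume a set of SNPs unrelated to the phenotype and in weak mutual LD;
an enriched array violates both presumptions at once, and naive use
produces grossly inflated inflation factors and artifactual relatedness.

`ldarray` packages both halves of this problem: the *design* machinery
(LD-defined fine-mapping regions, replication-SNP selection, multi-trait
assembly with duplicate collapsing, tagging-coverage evaluation) and the
*analysis* machinery an enriched array requires (null-SNP-set selection,
trend tests and genomic-control lambda, structure-SNP selection,
method-of-moments IBD, a standardized-genotype relationship matrix, and a
permutation test for SNP-set overlap between traits). A seeded
synthetic-data module generates every input with known ground truth, so the
whole pipeline is testable without access to any cohort.

# Linkage disequilibrium core

For phased haplotypes the package uses the classical composite measure

$$ r^2 \;=\; \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}, \qquad D = p_{AB}-p_Ap_B, $$

which for 0/1 allele indicator columns equals the squared Pearson
correlation; the implementation exploits that identity, and the test suite
verifies it against a direct haplotype-contingency computation to 1e-12.

When only unphased genotypes are available, two-locus haplotype frequencies
are estimated by EM over the double-heterozygote phase ambiguity
(initialized at linkage equilibrium, tolerance 1e-8 on the frequency
change, at most 100 iterations; non-convergence returns the last iterate
with a warning). On genotypes collapsed from 1,000 phased haplotypes the EM
estimate tracks the phased truth with a mean absolute error well under
0.02. EM convergence is slow for very tightly linked pairs — the warning,
not a failure, marks those cases.

LD computations are bounded by an `ldHorizonBp` window (default 1 Mb);
cross-chromosome and beyond-horizon r² are treated as zero. Greedy pruning
scans candidates in genomic order and keeps a SNP only if its r² with every
previously kept SNP inside the window is at or below the threshold —
leftmost-wins, deterministic, idempotent, and verifiable by exhaustive
post-scan. Tagging coverage counts a target as covered when it is itself a
tag or reaches the r² threshold (0.8 for "strong LD") with a tag inside the
horizon, reported overall and per MAF bin. The default bin edges
(0, .01, .02, .05, .1, .2, .3, .4, .5, with monomorphic SNPs as their own
bin) cover the design-relevant cut points .02 and .05.

# Fine-mapping regions

A signal-fine-mapping (SFM) region grows from the span of all SNPs with
r² ≥ 0.5 (configurable) to the index SNP. Each boundary is then resolved
independently:

1. **Hotspot rule.** If a recombination hotspot lies outward of the
   boundary with its inner (region-proximal) edge within
   `hotspotSearchCm` (default 0.1 cM), the boundary moves to that inner
   edge. Hotspots delimit LD blocks, and the inner edge is the
   conservative block boundary — preferred over the hotspot midpoint.
2. **Shoulder rule.** Otherwise the boundary extends outward by
   `shoulderCm` (default 0.02 cM — about 20 kb on a 1 cM/Mb background).

The two rules could also be read as cumulative; `shoulderMode = "always"`
applies the shoulder beyond the hotspot edge for that reading, but the
default is hotspot-first with the shoulder as fallback, and the provenance
string on every region records which rule fired per side. Hotspots are
detected as maximal runs of inter-anchor map intervals whose local rate
(ΔcM/Δbp × 10⁶) meets `rateThreshold` (default 10 cM/Mb, the conventional
cutoff; the quantitative definition of "hotspot" is otherwise open, so it
is a parameter).

Locus-fine-mapping (LFM) regions additionally absorb every gene interval
they overlap, iterated to transitive closure, so they always contain their
SFM. Overlapping regions merge on strict bp overlap only (abutting regions
stay separate — the simplest rule consistent with unique-region
accounting); merged kind is LFM when any constituent is.

Genetic positions interpolate piecewise-linearly between map anchors and
are constant beyond them. The *inverse* map (needed to convert the shoulder
to bp) extrapolates beyond the anchored range at the terminal interval's
rate, falling back to 1 cM/Mb when that rate is zero — the conversion a
flat background map implies.

# Array design

Replication SNPs are the top independent association signals: candidates
ranked by ascending p-value (ties broken by genomic order for determinism)
and accepted greedily subject to r² ≤ 0.3 with every already-accepted SNP
within 1 Mb, skipping candidates within 250 kb of supplied known loci. The
independence criterion for "independent signals" is not canonical, so both
the r² threshold and the window are explicit configuration; the defaults
mirror the pruning thresholds used elsewhere in the package for internal
consistency.

Multi-trait submissions assemble into an `ArrayDesign` with one entry per
unique variant, `category:trait` tags merged across submissions, and
distinct ids at an identical (chrom, pos, ref, alt) site — unintended
duplicates — collapsed onto the alphabetically first id with the rest kept
as aliases. The category vocabulary is closed (replication, fine_mapping,
prior_association, cnp_tag, mhc, mitochondrial, sex_check, fingerprint,
wildcard). Manufacturability is modeled only as a per-variant boolean
`designable` flag; assay-chemistry scoring is out of scope.

# Enriched-array statistics

**Null-SNP sets.** For genomic control on trait T, the usable SNPs are
replication SNPs submitted for *other* traits, minus anything within
250 kb of a locus known to associate with T, LD-pruned at r² 0.3. The
returned vector carries a provenance attribute recording all three steps.

**Trend test and lambda.** The association vehicle is the Cochran-Armitage
trend chi-square with scores (0,1,2), vectorized across SNPs and checked
against `stats::prop.trend.test`. The genomic-control factor is
`median(chi-square)/0.4549`, the 1-df chi-square median as fixed by the
genomic-control construction (the literal constant, so a median of exactly
0.4549 gives lambda 1).

**Kinship.** Pairwise IBD is estimated by the method of moments: observed
identity-by-state counts are decomposed into their expected contributions
under IBD states given the supplied allele frequencies, solved
moment-wise, and repaired onto the simplex by truncating negatives and
renormalizing. This is the computation the standard toolkits perform in
practice; full maximum-likelihood estimation is deliberately out of scope.
The genetic relationship matrix standardizes genotypes as
$(g-2p)/\sqrt{2p(1-p)}$ with pairwise-complete averaging. For a
parent-offspring pair the expected GRM off-diagonal equals π̂ = k₂ + k₁/2
(both 0.5), and the two estimators are cross-checked against each other
within ±0.1 in the acceptance suite. Both estimators assume the supplied
frequencies describe the sample; on rare-variant-enriched panels this
fails badly — which is exactly why `selectStructureSnps` (MAF > 0.05,
pruned at r² 0.3) exists and is used upstream of both.

**Overlap test.** The SNP-set overlap between two traits is tested by
simulation: null replicates draw both sets independently and uniformly
without replacement from a caller-supplied universe, and the one-sided
enrichment p-value is `(1 + #{overlap ≥ observed})/(nSim + 1)` — a valid
finite-sample permutation p. The universe is a *required* argument because
the sampling frame changes the p-value; silently defaulting it would bias
results. The null mean matches the hypergeometric value |A||B|/U. Because
the overlap count is a small-support discrete statistic, the test is
conservative at small set sizes: with |A| = |B| = 50 in a universe of
1,000 the largest attainable rejection level at nominal 0.05 is about
0.034.

# The synthetic-data generators

`simulatePanel` emulates a reference haplotype panel: founder haplotypes
drawn site-wise from a 1/x MAF law truncated to [1/(2N), 0.5], descendants
built as founder mosaics with crossovers placed by a Poisson process whose
intensity follows the genetic map. A single meiosis at realistic map
intensities yields essentially no recombination across a sub-cM region, so
the mosaic intensity is the map times `mosaicGenerations` (default 100),
emulating the recombination a real panel accumulates over many meioses;
this is what produces distance-decaying block LD and depressed r² across
hotspots. The model is *not* a coalescent: it has no genealogical depth
structure, no mutation, and long-range background correlation of order
1/nFounders. Tests that need genuinely unlinked loci therefore use many
founders. Passing tests on these panels demonstrate the algorithms' logic
on block-LD data, not population-genetic realism.

Two notes on the 1/x law. First, representable rare frequencies are
limited by founder granularity (1/nFounders), so spectrum studies use
founder counts of several hundred. Second, the law's bin masses are
logarithmic ratios — the (0,.01] bin outweighs (.01,.05] and (.1,.2], but
a strictly decreasing spectrum across coarse bins is not arithmetically
attainable (ln 10 > ln 5); the tests assert the attainable rare-dominance
shape.

`dropPedigree` performs true single-meiosis gamete transmission through a
user pedigree and records *realized* IBD fractions exactly from founder
segment labels, so k₀+k₁+k₂ = 1 holds by construction and parent-offspring
pairs are exactly (0,1,0). Realized sib k₁ has large per-seed variance on
short maps; the sib Monte-Carlo uses a 100 cM simulated chromosome
(20 cM/Mb over 5 Mb) so the 100-seed mean lands within ±0.05 of one half.

`simulateStratifiedCC` draws two subpopulation frequency vectors from the
Balding-Nichols Beta construction (shape p(1−F)/F and (1−p)(1−F)/F, mean p,
variance F·p(1−p)); F = 0 returns the base frequencies exactly. F may be a
per-SNP vector, which is how the package reproduces the enriched-array
inflation phenomenon in one coherent study: differentiated SNPs (F = 0.1)
play the trait-enriched content, undifferentiated SNPs (F = 0) the null
content, with cases sampled 90% from one subpopulation and controls 10%.
Lambda over all SNPs then exceeds 1.2 while lambda over the selected null
set stays at 1 — the qualitative ordering observed on real enriched
arrays. The null-calibration check uses 10,000 SNPs and 500 cases/500
controls per seed over 20 seeds; the chi-square goodness-of-fit check uses
1,000 cases/1,000 controls, the regime where the trend statistic's 1-df
chi-square limit is the appropriate reference (at a few hundred samples the
2×3 table's discreteness is detectable at the 10,000-SNP scale).

`simulateSummaryStats` is analytic rather than phenotype-based: the
marginal effect at SNP j is the causal effect propagated through signed LD,
β_j = Σ_c r_jc β_c, the standard error is 1/√(2n·maf(1−maf)), and
z = β/se + N(0,1). This is orders of magnitude faster than simulating
individual-level phenotypes, and the selection algorithms only consume the
p-value ranking; null SNPs get exactly uniform p-values by construction.

# Numerical choices and degenerate inputs

- Monomorphic columns make r² undefined: pairwise operations raise an
  error, while batch operations (pruning substrate, coverage search,
  summary-stat generation) treat or skip them as zero-information.
- EM: linkage-equilibrium initialization, tol 1e-8, maxIter 100;
  missing dosages excluded pairwise everywhere (`NA` is the missing
  sentinel).
- IBD simplex repair: truncate negative moments to zero, renormalize.
- Permutation p-values use the (1+exceed)/(n+1) convention and can never
  be smaller than 1/(n+1).
- p-values of 0 are rejected on input and never produced (underflow is
  clamped to the smallest positive double).
- All coordinates are 1-based inclusive internally (the VCF convention);
  BED output converts to 0-based half-open on the way out.
- Every generator and permutation routine takes an explicit seed and
  restores the caller's RNG state, so results are bit-reproducible and
  library calls do not perturb user randomness.

# Validation scales

The shipped checks run at desk scale, chosen to finish in minutes on one
CPU while keeping Monte-Carlo error well inside the asserted bands:
1,000 random pairs for the LD oracle; 200 pairs at 1,000 haplotypes for
EM consistency; 500-SNP panels for exhaustive pruning scans; 20 seeds of
10,000-SNP studies for lambda calibration; 8 trios on 5,000 unlinked SNPs
for kinship recovery; 10,000 replicates for the overlap null mean and
1,000 trials of 999 replicates for its type-I level. Headline numbers
reported for the original application-scale arrays (coverage fractions,
inflation factors measured on specific cohorts) depend on external
reference panels and cohort genotypes and are reproduced here only as
qualitative orderings on synthetic data.

# Known limitations

- Only biallelic SNPs carry LD semantics; indels and CNP tags can ride
  along as annotation but never enter r² computations.
- No haplotype phasing, no D′, no imputation: the package consumes phased
  panels or works genotype-wise.
- The founder-mosaic simulator cannot calibrate absolute LD decay rates
  against a real population; it provides structure, not parameters.
- PCA/MDS decompositions themselves are delegated to standard numerics
  (`prcomp`, `cmdscale`) on the `selectStructureSnps` output.
- The alternative null-set recipe based on per-trait association
  p-value filtering is supported only implicitly (filter the design before
  `selectNullSnps`); no default threshold is shipped because none is
  canonical.
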