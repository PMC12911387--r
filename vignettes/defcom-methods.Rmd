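---
title: "Strain-resolved DefCom analysis: models, parameters and design choices"
author: "DefComTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-resolved DefCom analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DefComTools)
```

# The problem

Defined communities (DefComs) are consortia of fully sequenced bacterial
strains inoculated onto plants at equal abundance. Shotgun sequencing of
root compartments — interior root tissue (endosphere) versus the soil
zone around the root (rhizosphere) — then reveals which strains and which
gene functions the plant environment selects for. The statistical
difficulty is that DefCom members are often nearly identical (pairwise
average nucleotide identity, ANI, above 97–99%), so reads cannot always be
attributed to a single strain, near-identical genomes must not be treated
as independent observations, and differential-abundance calls must be
robust to the peculiarities of sparse, compositional microbiome counts.

DefComTools implements the full desk-side chain for such experiments:
ANI-based lineage definition, competitive read assignment with explicit
multi-mapping policies, strain-level compartment contrasts, a
lineage-level KEGG Ortholog (KO) enrichment rule, orthogroup-level
functional profiling with diversity statistics, and a three-method
consensus differential-abundance framework. Because ground truth is never
available for real colonization data, the package ships a synthetic
community generator whose outputs carry complete generative bookkeeping;
every statistical component is validated by recovery experiments against
that truth.

# The synthetic community generator

`buildCommunity()` derives all strains from a single ancestral sequence by
substitutions only. Lineage founders diverge from the ancestor at half the
configured between-lineage divergence and members from their founder at
half the within-lineage divergence, so a within-lineage pair differs by
approximately the within divergence and a between-lineage pair by
approximately the between divergence. Indels are confined to whole-gene
accessory edits: deletions remove complete core genes, insertions append
novel genes (with random 100 bp spacers) after the core. This restriction
is deliberate: with substitutions recorded in ancestor coordinates, the
true ANI of any strain pair over their shared regions is
`100 * (1 - differing/shared)` by integer arithmetic (`truePairANI()`),
which gives every downstream ANI estimate an exact oracle.

Planted endosphere features are novel genes carrying a chosen KO and
orthogroup label, inserted into every member of the designated dominant
lineages. The default ten-strain configuration (`communityConfig()`) uses
seven lineages (sizes 3, 2, 1, 1, 1, 1, 1) on 0.5 Mb genomes; the
28-strain `studyMimicConfig()` reproduces the situation of a community
partitioned into 15 lineages of which 4 — one three-strain lineage plus
three singletons, six strains in total — contain the dominant endosphere
colonizers and 11 do not.

The abundance model (`abundanceModel()`) draws per-sample strain
proportions log-normally (`base_log_sd = 0.35` on the natural-log scale,
about 0.5 log2 units of replicate-to-replicate variability — the order of
variation we consider realistic for replicate microcosms inoculated at
equal abundance), multiplies by `2^compartment_effect` in the endosphere
and `2^host_effect` in the second host, and renormalizes. The default
model encodes the endosphere bottleneck characteristic of colonization
experiments: dominant strains gain 2 log2 units, all others lose 2. Reads
are single-end 150 bp on the forward strand with i.i.d. substitution
errors (0.5% per base) and a configurable fraction of host-decoy reads;
read names carry provenance (strain, position) so assignment accuracy is
measurable. The default design is 7 endosphere and 8 rhizosphere samples
split across two hosts, at 50,000 reads per sample.

What the generator does *not* emulate: realistic error profiles (quality
scores, indel errors), strand sampling, paired-end fragments, plasmids,
horizontal transfer, or genuinely homologous accessory sequence shared
between lineages. Passing recovery tests therefore demonstrates
correctness of the statistical machinery under the stated generative
model, not performance on real Illumina data.

Count-level shortcuts (`simulateStrainCounts()`, `simulateGeneCounts()`,
`simulateOrthogroupCounts()`) share the same abundance model but skip read
strings; the statistical recovery experiments use them because the
quantities under test are functions of counts, while the read-level path
is exercised by the assignment-accuracy and end-to-end analyses. The
problem sizes used throughout (for example 20-seed lineage-recovery
batches on 30 kb genomes, 50-seed enrichment recovery at n = 7/8,
330-orthogroup consensus experiments) were chosen as the smallest sizes at
which the distributional claims are meaningful.

# k-mer ANI and lineages

`kmerANI()` splits the query into non-overlapping 3 kb fragments (the
fragment length used by fragment-mapping ANI tools) and computes, per
fragment, the containment `c` of its k-mer set (k = 16) in the reference's
full k-mer set. Containment is converted to the Jaccard index two
equal-size sets would have, `J = c/(2-c)`, fragments with `J < 0.01` are
discarded as non-orthologous, and each retained fragment is scored through
the Mash distance `d = -(1/k) log(2J/(1+J))`.

Two numerical choices matter here:

* **Identity mapping.** We report `100 * exp(-d)` (equivalently
  `100 * c^(1/k)`) rather than the first-order `100 * (1-d)`. Under an
  i.i.d. substitution model the expected containment is `(1-δ)^k` at true
  divergence δ, so `c^(1/k)` is unbiased across the whole 0–20% range,
  whereas `1-d` is biased by about `d²/2` (half a percentage point at 10%
  divergence).
* **Median aggregation.** A fragment straddling a core/accessory boundary
  passes any usable mapping floor with heavily depressed identity: a
  half-accessory fragment has containment around 0.13, which exceeds the
  0.028 of a fully orthologous fragment at 20% divergence, so no threshold
  separates the two. Each direction's estimate is therefore the *median*
  fragment identity, which is unbiased when fragments are homogeneous and
  robust to the handful of boundary fragments; the two query/reference
  directions are then averaged to enforce symmetry.

`clusterLineages()` forms single-linkage connected components of the
"ANI ≥ τ" graph (τ = 97 by default), computed as single-linkage
hierarchical clustering of `100 - ANI` cut at height `100 - τ`. Single
linkage is the least-assumption reading of "group strains above a
threshold"; the linkage is a property of the implementation users can
replace by supplying their own partition. Lineage identifiers are the
lexicographically smallest member strain id, making partitions comparable
across runs. A lineage is endosphere-associated iff it contains at least
one dominant endosphere colonizer (`labelEndosphereLineages()`).

# Read assignment and counting

Pseudo-mapping by k-mer scoring (k = 31) replaces aligner-based mapping:
a read's score against a genome is its number of shared 31-mers, hits
require at least 25% of the read's k-mers, and the best set is the argmax.
The `unique` policy discards reads whose best set has more than one member
(the conservative default, which avoids double-counting between
near-identical strains); `fractional` assigns `1/|best set|` to each
member. Host reads are removed first when at least half of a read's
k-mers occur in the host decoy. Read positions are inferred from the
leftmost anchoring k-mer, genes receive reads by largest overlap (ties
discard the read at gene level and are logged), and orthogroup counts sum
member-gene counts, optionally divided by the orthogroup's gene-copy
number in the community reference (the `per_copy` interpretation we adopt;
copies among detected strains only is available via `copy_universe`).
Coordinates are 0-based half-open throughout and counting ignores strand,
as appropriate for unstranded metagenomic DNA.

# Strain enrichment

Counts are TMM-normalized (edgeR's trimmed mean of M-values),
log-CPM-transformed with a +0.5 count and +1 library offset, and weighted
by an inverse fourth power of a lowess mean–variance trend (span 0.5, two
robustness iterations, residual-sd floor 1e-4 to protect constant
features) — the voom construction. Per-feature weighted least squares on
the design (rhizosphere and first host as reference levels, so a positive
compartment coefficient always means endosphere enrichment) is followed by
empirical-Bayes variance moderation: the prior (d₀, s₀²) is estimated by
moment matching on the log sample variances and the moderated t has
d₀ + residual degrees of freedom. Benjamini–Hochberg correction is applied
across features. Both the model-fitted log2 fold change (default) and the
plain ratio of compartment mean CPMs are reported, since the two answer
slightly different questions for strongly compositional data.

Colonization strategies are rule-based on the enrichment table:
significant positive fold change with endosphere abundance at or above the
`abundance_quantile` threshold (default 0.5) is a strong colonizer, below
it a niche specialist; non-significant strains abundant in both
compartments are generalists; significant negative fold change is
rhizosphere-associated. The class definitions in the literature are
qualitative, so both α and the abundance quantile are explicit
configuration.

# Lineage-level KO enrichment

`lineagePresence()` scores a KO as present in a lineage if any member
genome carries at least one gene with it (presence, not copy number).
`koEnrichmentRule()` then flags a KO as endosphere-enriched iff it occurs
in at least `min_endo = 2` endosphere-associated lineages and at most
`max_non = 4` non-endosphere lineages, taking the thresholds literally as
"at least"/"no more than". Group sizes are always derived from the lineage
map rather than hard-coded, so the rule applies unchanged to communities
of any composition.

# Diversity statistics

Alpha diversity is orthogroup richness (CPM > 0) and Shannon H in natural
log (the dominant ecology convention; the base is configurable), compared
between groups with a two-sided Wilcoxon rank-sum test (exact below a
combined n of 21 without ties) and one-way ANOVA. Beta diversity is
Bray–Curtis on CPM profiles, ordinated by NMDS (vegan's monotone
regression engine, best of one metric-scaling start plus 19 random starts,
300 iterations, stress tolerance 1e-6).

PERMANOVA partitions the Gower-centered inner-product matrix of squared
distances by sequential (type-I) projection onto nested design subspaces,
with compartment entering before host (the order is explicit
configuration). P-values come from free permutation of sample labels,
`(1 + #{F* ≥ F}) / (n_perm + 1)`, with optional exhaustive enumeration of
all n! permutations for small n, in which case the p-value is the exact
proportion of the permutation distribution at or above the observed F. No
permutation strata are imposed by default; a caller needing
restricted permutations can permute within strata and supply the result.

# Consensus differential abundance

Three deliberately lightweight reimplementations of the standard
modelling families for microbiome counts are run on the same orthogroup
count matrix:

1. **nb_wald** — median-of-ratios size factors (features containing any
   zero are excluded from the median), method-of-moments NB dispersions
   shrunk halfway (configurable) toward a lowess mean–dispersion trend, NB
   log-link GLM by iteratively reweighted least squares with size-factor
   offsets, Wald z test. All-zero features take p = 1 and are flagged.
2. **voom_mod_t** — exactly the strain-enrichment machinery applied to
   orthogroup counts; per-copy-normalized input is rounded to
   pseudo-counts first.
3. **css_zig** — cumulative-sum-scaling normalization (each sample scaled
   by the sum of its counts up to the median of its nonzero counts),
   `log2(count/scale * 1000 + 1)` transform, and a two-component EM
   (point mass at zero with a logistic dependence on log library size
   versus per-feature Gaussians, at most 100 iterations, tolerance 1e-6,
   falling back to unit weights with a warning on non-convergence) whose
   posterior "structural zero" probabilities downweight zeros in a
   weighted moderated-t fit.

The contract of these three methods is distributional — each controls
type-I error near the nominal level and ranks truly enriched features
highly — not numerical identity with any external package. The consensus
set contains the features with q < 0.05 in all three methods, with
sign-consistent fold changes in the requested direction (endosphere =
positive); direction consistency is the default and can be switched off.
Per-host analyses run the voom path within each host and report per-host
significant sets, their intersection, disjoint (UpSet-style)
cardinalities, and presence/absence detection sets. Finally the
cross-framework intersection keeps the KOs that annotate at least one
consensus orthogroup *and* pass the lineage-level rule — the package's
analogue of reconciling read-abundance evidence with gene-content
evidence.

# Degenerate inputs and numerical guards

Constant features are protected by the voom residual-sd floor; zero
library columns, all-zero sample pairs in Bray–Curtis, samples with fewer
than ten nonzero features in CSS, rank-deficient designs, confounded
PERMANOVA terms, and reads shorter than k all raise immediate errors
naming the offending input. The variance-prior moment matching falls back
to an infinite prior (fully pooled variance) when the observed log
variances underdisperse the theoretical χ² spread.

# Reproducibility

Every stochastic routine takes a seed; the C++ error-injection code draws
from R's RNG so that `set.seed()` governs the entire pipeline, and
`runPipeline()` writes a manifest whose hash is the md5 of the sorted
per-file md5 list — identical configuration and seed give an identical
hash. The assignment index holds an external pointer and must be rebuilt
per session rather than serialized.

# Known limitations

The k-mer ANI estimator is designed for desk-scale genomes (it holds full
k-mer hashes in memory; no MinHash sketching) and the exact-alignment
oracle it is tested against requires the generator's bookkeeping. The NB
Wald test uses a normal reference distribution and becomes anticonservative
below roughly five samples per group. The zero-inflation EM assumes zeros
are exchangeable within a feature given library size; structured zero
patterns (batch effects) are not modelled. Multi-copy genes within a
strain are counted once per read by the largest-overlap rule, so tandem
duplications inflate per-copy normalization denominators rather than
counts.
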