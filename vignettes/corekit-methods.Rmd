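---
title: "corekit: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{corekit: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the science inside `corekit`: the statistical models,
the tunable parameters and their defaults, the numerical decisions made where
the design was genuinely open, and what the test suite does and does not
establish. It states no empirical result that the tests or the acceptance
script do not themselves compute.

## The problem

A germplasm collection of inbred lines is to be reduced to a core subset of
fixed size that (a) preserves genetic diversity, (b) stays representative of
the whole collection, and (c) remains useful for QTL discovery. These goals
conflict. `corekit` operationalizes the comparison: construct cores under
many criterion/optimizer combinations, score each core with a common metric
panel, and rank methods by a composite index that balances diversity and
representativeness, including a simulation-based QTL-recovery criterion.

## Genotype model and QC

Genotypes are dosages in {0, 1, 2} counting alternate-allele copies;
heterozygous calls are legal everywhere even though an inbred panel has few.
QC applies, in a fixed order: (1) markers with more than 50% missing calls
are dropped, then (2) accessions with more than 50% missing calls on the
surviving markers. Markers first preserves more accessions, which is what a
curator wants. Missing calls are then imputed by the per-marker modal dosage
(ties toward the lower dosage) — a deliberate, deterministic simplification
relative to haplotype-model imputation; it keeps the package dependency-free
and reproducible, at the cost of attenuating rare-allele dosages in highly
missing markers. Markers with MAF ≤ 1% are removed (strict inequality, so
monomorphic markers always go).

LD pruning slides a 50-marker window in steps of 5 per chromosome; within a
window, while any retained pair has r² > 0.4, the lower-MAF member is removed
(ties: the later position). The step size is not dictated by the pruning
window definition; 5 is the common companion value for windowed r² pruning.
Removing the lower-MAF member (rather than a random one) makes pruning a pure
function of the input.

## Distances, kinship, structure

For biallelic dosage data the per-locus Rogers distance reduces to
`|x_a − x_b| / 2`, averaged over loci — a metric in [0, 1]. Kinship is
VanRaden's `Z Z' / (2 Σ p(1−p))` with `Z` column-centered by `2p`. Note that
this `K` always has the 1-vector in its null space; every consumer treats
near-singularity as the normal case (ridging with a warning where an inverse
is required).

PCA standardizes each column by the binomial scale `sqrt(2p(1−p))` — the
normalization under which the leading eigenvalues of unstructured data follow
Tracy–Widom fluctuations. Axis significance uses the moment-matching
normalization of successive eigenvalues (effective column count estimated
from the first two spectral moments of the remaining eigenvalues) against
tabulated Tracy–Widom GOE quantiles, linearly interpolated in log α; the
default α = 0.05 is exposed because published analyses rarely state it.
Counting stops at the first non-significant axis. Calibration note: the test
suite checks the null behavior on unstructured genotypes with a *spectrum* of
allele frequencies; a null in which every marker shares one frequency is both
unrealistic and slightly anticonservative for any eigenvalue test of this
family.

K-means (10 seeded restarts per K, K = 1..10) is scored by the BIC of a
spherical Gaussian mixture evaluated at the K-means solution (means =
centers, shared variance = WSS/(nd), weights = cluster shares, parameter
count `(K−1) + Kd + 1`). A classification/WSS-based BIC was considered and
rejected: its likelihood term improves by O(n) for every split of a true
cluster, so it decreases monotonically in K on clustered data and cannot
place a minimum at the generating K — the mixture likelihood can, because
splitting a well-fit component barely improves it. Since curators sometimes
overrule any information criterion with domain knowledge, `force_k` is a
first-class argument.

DAPC covariates: linear discriminant axes are fit on the retained PCs with
K-means labels as classes; memberships are LDA posteriors and the GWAS
covariate matrix `Q` holds the `min(k−1, d)` discriminant coordinates,
column-centered. Discriminant coordinates rather than raw memberships avoid
the sum-to-one singularity and are full rank by construction.

Fst is the Weir–Cockerham (1984) estimator, ratio of sums of the three
variance components across loci, for cluster pairs and overall. With heavy
inbreeding the within-individual component collapses toward zero and the
among-individual component absorbs it; the estimator remains consistent for
the divergence parameter, which the generator-recovery test verifies.

## Selection criteria and optimizers

A-NE averages the nearest-entry distance over **all** accessions (selected
entries contribute 0). Definitions differ between published implementations
on whether unselected accessions only should be averaged; the all-accessions
form is used because it makes the criterion a proper coverage radius and is
the form under which "subset = everything" gives exactly 0.

CDmean follows the mixed-model formulation: with `λ = σe²/σg²`,
`CD_i = [K − λ(Z'MZ + λK⁻¹)⁻¹]_ii / K_ii`, averaged over candidates outside
the subset (`Z` the subset incidence, `M` the subset-level projector
orthogonal to the intercept). The n×n inverse is computed once per proposal
via the Woodbury identity from a precomputed `K⁻¹`, turning each evaluation
into a k×k solve. The variance ratio defaults to `λ = 1` (h² = 0.5) because
the trait to be predicted is unknown at design time; it is a config knob.

D-optimality is the log-determinant of the subset's cross-product on the
first `q` PC scores; `q` defaults to the Tracy–Widom-significant axis count
capped at `size − 1` (beyond that the determinant is structurally zero).
Rank-deficient subsets score `−Inf`, which is a legal objective value.

Multi-objective runs use weighted scalarization after mapping each raw
criterion to [0, 1] with bounds estimated from 200 random subsets of the
target size (seeded). Minimization-type criteria (A-NE, Avg_GRM) are flipped.
The exported `combine_objectives` clamps out-of-bounds values with a warning,
as a reporting function should; the optimizer's internal objective applies
the same linear map *without* clamping, because optimized subsets routinely
exceed bounds estimated from random ones and a clamped objective would
plateau exactly where search pressure is needed.

Optimizer budgets: hill climbing runs exactly 3,000 proposals (the published
setting for the CDmean search); annealing defaults to 20,000 proposals with
geometric cooling from T = 0.1 to 1e-4 on the normalized objective scale; the
genetic algorithm defaults to population 40 for 300 generations with uniform
subset crossover repaired to size k and swap mutation. The annealing engine
stands in for a replica-exchange Monte Carlo search: same move set and
acceptance rule, single chain plus restarts — the scientific content of the
package is the criterion comparison, not the search engine. All budgets are
configuration, and the exhaustive-enumeration acceptance test pins every
optimizer to the true optimum on small instances.

## Evaluation metrics

SH uses log base 2 and averages per-locus entropies over loci, which puts a
biallelic panel in [0, 1]. RAR counts whole-collection rare markers
(MAF < 10%) that are *still segregating* (both alleles present) in the core;
for an inbred panel a literal "heterozygous in the core" reading would be
structurally near zero, contradicting the observed behavior of every
published core method, so segregation is the operative sense. KL is the
truncated sum `Σ p log(p/q)` over whole-collection minor alleles (the same
allele tracked in the core), with exact zeros floored at
`ε = 1/(2·n_core + 1)`; the truncated sum is not sign-definite and is exactly
0 at equality. Its absolute scale grows linearly with marker count — across
a pool of cores only its ordering matters, and the composite index z-scores
it, so the scale cancels there. COR correlates same-rank marker-loading
vectors between the core PCA and the whole-collection PCA (loadings, not
scores, because score vectors have different lengths), takes absolute values
(axes are sign-ambiguous), Fisher-z transforms with clipping just below 1,
and averages with whole-collection eigenvalue weights over the significant
axes; only the weighted *mean* of z is taken, so raw eigenvalues and inertia
proportions give identical results. MD preselects traits with a greedy
Cramér's V filter (drop the later of any categorical pair with V > 0.7),
then chi-square (categorical, against whole-collection proportions) or
two-sample Kolmogorov–Smirnov (quantitative) at α = 0.05, uncorrected — MD
counts raw significant traits.

The composite index z-scores SH, He, RAR, CV, COR, KL and QTL across the
supplied report pool and averages them with KL negated. MD is computed but
excluded from the index (passport traits cannot carry the full phenotypic
information). A zero-variance component contributes zero for every report,
which also makes the index invariant to affine rescaling of any component.

## QTL benchmark

Traits are simulated per chromosome (two each by default, 31 causal SNPs per
trait — with 15 chromosomes that is 930 causal slots, matching the published
order of magnitude of ~940 genome-wide simulated QTLs, which this package
reads as the causal count). Causal effects are standard normal; the causal
score, a kinship-distributed polygenic term, and white noise are each
rescaled to their exact target variance shares (defaults 0.4 / 0.2 / 0.4 —
a moderately heritable trait with half its genetic signal in mapped QTLs)
and the trait is standardized. The realized causal share is recorded; it
deviates from the target only through the sampled covariance between the
causal score and the polygenic term.

The association scan is P3D/EMMAX: REML on the eigendecomposition of K
profiles the single variance ratio under the null model (intercept + DAPC
covariates), then every SNP gets a score test with variance components held
at the null estimates. One decomposition and one rotation of the genotype
block serve all SNPs. In the `K = I` limit the scan reduces exactly to the
OLS score test, which the suite verifies in closed form. Significance uses
the simpleM construction: per chromosome, the smallest number of leading
correlation-matrix eigenvalues explaining 99.5% of the trace, summed over
chromosomes, dividing α = 0.05. The per-chromosome blocking is the standard
scaling device; on a single chromosome it equals the full-matrix computation.

The recovery ratio counts, per trait, core-significant markers with a
whole-collection-significant marker within `window_bp` (default 0 = exact
identity, appropriate because cores are scanned on the whole panel's marker
set), pooled as total common hits over total whole-collection hits. Core
scans reuse the whole-panel covariate rows (recomputing structure on a core
would change the correction across methods and sizes); the kinship is the
whole-panel matrix subset to the core. The Gao threshold is recomputed on
each core's genotype block, since the effective test count is a property of
the scanned panel.

## Synthetic panels

The generator is Balding–Nichols: ancestral frequencies uniform on
`maf_range` (default 0.1–0.9), cluster frequencies Beta-distributed with the
divergence parameter as Fst, genotypes drawn with inbreeding coefficient
0.98 by default (inbred lines maintained by selfing with occasional
outcrossing). Within chromosomes an AR(1) Gaussian copula (ρ = 0.6) on the
latent sampling variables induces adjacent-marker LD without touching the
marginals, so LD pruning and effective-test counting have structure to act
on. The standard fixture has 6 clusters of sizes 140/190/45/45/120/60
(n = 600; shares mirroring a worldwide flax germplasm's cluster ratios),
3,000 SNPs on 15 chromosomes, divergence 0.19 (the whole-collection
differentiation reported for that germplasm) and 10 categorical + 2
quantitative passport-style traits with moderate cluster association
(`cluster_effect = 1`).

What the generator does **not** emulate: demographic history (bottlenecks,
admixture gradients, IBD segments), realistic LD decay (the copula gives a
single-scale geometric decay), genotyping error, and any genuine
genotype–phenotype architecture in the passport traits. A green test on this
fixture therefore establishes that the algorithms behave correctly on a
structured panel of the right shape and differentiation — not that any
specific germplasm's published table values are reproduced. Desk-scale cores
(size 100 of 600) recover far fewer whole-panel QTLs than a 350-of-1593 core
would; the benchmark's claims are ordinal (monotone in size, method
rankings), never absolute rates.

## Numerical choices

* Tracy–Widom GOE quantiles are tabulated at seven upper-tail points and
  interpolated linearly in log₁₀ α.
* `rcond < 1e-10` triggers kinship ridging (1e-6 of the mean diagonal).
* Annealing temperatures refer to the normalized objective; single-criterion
  runs skip normalization entirely (it is monotone) and optimize the raw
  (sign-adjusted) criterion.
* p-values from the score test are floored at the smallest positive double;
  λ uses the exact χ²₁ median 0.4549364.
* The frequency criteria (HE, SH, CV) maintain allele-count state updated in
  O(m) per proposed swap; all other criteria are recomputed per proposal
  (distance criteria via C-level row minima, CDmean via Woodbury).
* `run_sweep` recomputes rather than caches stage artifacts: a desk-scale
  sweep reruns in minutes and a content-hash cache would add a binary
  artifact store for no analytical gain. All stage outputs and a manifest
  are written when `out_dir` is given, so interrupted sweeps lose only the
  current stage.

## Known limitations

* Mode imputation biases toward major alleles in high-missingness markers;
  markers above the missingness filter are unaffected by design.
* The annealing engine is a single chain with restarts, not replica
  exchange; with default budgets it reaches enumeration optima on all small
  instances tested, but no guarantee transfers to n ≫ 600.
* MD's chi-square treats whole-collection proportions as fixed, which is
  anticonservative for cores approaching the whole collection's size.
* The scan is single-marker P3D; per-SNP exact REML, binary traits,
  epistasis and G×E are out of scope.
* VCF support is GT-only on plain text; multi-allelic records are skipped,
  not decomposed.
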