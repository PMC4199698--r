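---
title: "Methods: multiallelic LD, diversity, structure and bottleneck inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiallelic LD, diversity, structure and bottleneck inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistical methods it
implements, the choices that were genuinely open, and what the test suite
does and does not demonstrate.

## The data model

Genotypes are diploid, multiallelic microsatellite calls: per locus an
unordered pair of fragment sizes (bp). GenePop is the interchange format
(both the 2-digit and 3-digit allele dialects, auto-detected). The
all-zeros code is missing; a genotype with one missing allele is treated
as fully missing, the simplest defensible contract. Markers carry a
physical position (Mb) on a linkage group through a separate map file;
markers absent from the map simply drop out of syntenic analyses. Repeat
motif lengths (needed only by the M-ratio) ride along in the map's
optional `motif_bp` column, defaulting to 4 bp.

## Haplotype frequencies and LD measures

Pairwise two-locus haplotype frequencies are estimated from unphased
genotypes by EM over the phase ambiguity of double heterozygotes,
initialised at the product of the observed allele margins and stopped
when the largest frequency change falls below `tol = 1e-8` (cap 1000
iterations; non-convergence is flagged on the record, not fatal). Two
properties are useful for testing and hold exactly: the allele margins of
the estimate equal the observed allele frequencies at every iteration,
and the observed-data log-likelihood never decreases. Individuals missing
either locus are excluded pairwise; nothing is imputed. Genome-wide
multi-locus phasing is deliberately out of scope — pairwise LD only needs
pairwise haplotype frequencies, and the composite phase-free measure
(below) bounds the phasing sensitivity empirically.

Multiallelic D′ is the allele-frequency-weighted mean of
|D_ij/D_ij^max| with the standard sign-split D_ij^max. Cells with
D_ij^max = 0 (an allele at frequency 0 or 1 against another) contribute
0, which keeps D′ ≤ 1. Monomorphic loci make the measure undefined and
the pair is excluded from scans.

For multiallelic r² we aggregate per-allele-pair correlations with
p_i p_j weights: `Σ p_i p_j D_ij²/[p_i(1−p_i) p_j(1−p_j)]`. The
unweighted sum that sometimes appears in print counts each biallelic
table four times (every cell of a 2×2 table carries the full classical
r²), so it cannot reduce to the classical `D²/(p_A q_A p_B q_B)`; the
weighted form reduces to it exactly for every biallelic table and stays
in [0, 1] by the per-pair correlation bound |D_ij| ≤
√(p_i(1−p_i)p_j(1−p_j)). The weighted form is what the acceptance oracle
checks.

The composite (phase-free) disequilibrium is estimated on the per-gamete
scale: `Δ_ij = Σ_ind g_i g_j/(4n) − p_i p_j`, where g_i ∈ {0,1,2} counts
the individual's copies of allele i. This combines the within- and
between-gamete association (it is Burrows' Δ divided by two) and has two
properties we rely on: it equals the haplotypic D_ij *exactly* on data
with no double heterozygotes, and it vanishes in expectation under
random pairing of independent haplotypes. Its normalisation is the same
D_ij^max machinery as D′. The choice of the halved scale is ours — the
cited composite-measure literature does not pin the normalisation — and
under random mating with many double heterozygotes it attenuates toward
D/2, so composite values are a conservative phasing-robustness check,
not a drop-in replacement for the EM estimates.

Rare-allele exclusion (<5% within the analysis unit) is implemented by
masking genotypes that carry a rare allele at that locus (consistent
with the missing-data contract) and re-estimating; this can only reduce
the allele count at a locus.

## Scans, bins, decay, comparisons

Scans cover all unordered same-linkage-group marker pairs with both loci
polymorphic in the analysed unit; distance is |Δ position| in Mb. A
habitat unit either pools the member populations' raw genotypes before
estimation ("combined") or averages the member populations' binned
means ("average"); both conventions are provided because they answer
different questions (the pooled estimate includes between-population
allele-frequency contrasts, which depress D′ relative to the
within-population average). Distance bins are right-closed —
[0,5], (5,10], (10,15], (15,20], (20,∞) — matching the convention of
labelling the second bin "5.001–10" at Mb resolution 0.001; a bin's
error is SD/√n_pairs, reported as 0 for a single pair.

LD decay is an ordinary least-squares fit of D′ on ln(distance); the
half-length is exp((0.5 − intercept)/slope) when the slope is negative,
otherwise undefined. A constant response returns slope 0, R² = 0 and no
half-length; equal distances flag a degenerate fit.

Habitat comparisons use the Mann–Whitney U test (exact p for tie-free
samples up to 50 per group, tie-corrected normal approximation
otherwise; U counts first-sample wins and the tie-corrected Z is
reported alongside), Kruskal–Wallis across populations, and an ANCOVA of
D′ on the distance covariate, habitat, and population nested within
habitat. The habitat F uses the population-within-habitat mean square as
its error term — the classical expected-mean-squares treatment of a
random population factor, identical to the mixed-model F in balanced
designs and free of opaque fitting machinery; population and the
covariate are tested against the residual. With a single population per
habitat the habitat effect is aliased and flagged untestable. Raw
distance is the default covariate, ln(distance) by flag. Bonferroni
correction is exposed both as min(1, m·p) and as the α/m threshold form.

## Diversity statistics

Expected heterozygosity uses Nei's unbiased correction
(2n/(2n−1))(1 − Σp²) — at n = 24 the correction is ~2%. Multilocus
values are unweighted means over loci with data, *including* loci
monomorphic in that population (they contribute 0), matching the
"across all loci" convention of standard diversity tables. F_IS is the
Weir–Cockerham single-population f combined over alleles and loci by
ratio of sums, with a percentile bootstrap over loci (default 1000
resamples) for the 95% CI. Rarefied allelic richness and Kalinowski's
private allelic richness work at the gene-copy level with a single
global rarefaction size g (default: the smallest non-missing per-locus
gene count over all populations and loci); the hierarchical
within-region rarefaction of HP-RARE is not replicated.

## Structure

Pairwise F_ST is Weir & Cockerham's θ, ratio-of-sums over alleles and
loci; significance by permuting individuals between the pair
(p = (1 + #{θ* ≥ θ})/(n_perm + 1)). AMOVA is three-level (among groups /
among populations within groups / within populations) on the 0/1
allele-identity distance, locus by locus with summed covariance
components — equivalent to decomposing summed SSDs when gene counts are
complete, and the natural generalisation when they are not. Components
may be negative; percentages always total 100. Permutation schemes:
whole populations among groups for σ²_a, individuals among populations
within groups for σ²_b. Queller–Goodnight relatedness excludes the focal
pair from the reference allele frequencies and averages the two
reference orderings; loci monomorphic after exclusion are skipped.

## Bottleneck tests

**M-ratio.** M = k/r per polymorphic locus with r = (max − min)/motif + 1
lattice states in the observed range, endpoints included (the
Garza–Williamson convention); off-lattice sizes are snapped to the
nearest lattice point with a warning; the multilocus M is the mean over
polymorphic loci. Critical values Mc are the conservative (lower-tie)
5th percentile of multilocus M over equilibrium coalescent replicates at
a stated prebottleneck θ. One caution from our own simulations: the
equilibrium M distribution is not monotone in θ — it falls from θ ≈ 0.6
toward both very low θ (few alleles, noisy M) and high θ (multistep TPM
jumps widen the range faster than the allele count grows) — so Mc
comparisons should use the θ grid appropriate to the population's
prebottleneck size, as the original method prescribes.

**Heterozygosity excess.** Under the TPM (default 90% single-step,
multistep size 1 + Geometric with mean 3.5 repeat units, symmetric
signs), equilibrium samples are simulated by the coalescent. One
population-level θ is tuned by bisection until the mean simulated
polymorphic allele count matches the observed mean; each locus's null
gene-diversity distribution is then the equilibrium draws with exactly
its observed k (rejection conditioning at the common θ; a per-locus
tuned fallback covers allele counts too rare at the common θ). The
reported per-locus statistic is the standardised difference
(H_E − mean H_eq)/SD(H_eq). The one-tailed Wilcoxon signed-rank test for
excess is applied to the per-locus conditional *quantiles* of H_E
(centred at 1/2) rather than to the standardised differences: measured
under the null, the standardised differences are left-skewed (skewness
≈ −1.3, median ≈ +0.27), so a signed-rank test on them is
anticonservative once the locus count is large, while the quantiles are
uniform — hence symmetric — under the null at any locus count. Residual
caveats: the shared θ estimate couples loci weakly (a mild residual
anticonservatism at a hundred-plus loci), and physically linked loci are
not independent in the way the Wilcoxon assumes — in high-LD populations
the test's effective locus count is smaller than its nominal one.

## The synthetic-data generator

`simulate_metapopulation()` is a forward-time diploid Wright–Fisher
simulation: a common ancestral pool, daughter demes founded from it at
stated times with stated founder counts, optional continuing migration
from the pool, TPM mutation, and recombination between adjacent syntenic
markers at min(0.5, rate/Mb × gap) per meiosis (default 0.01/Mb, i.e.
1 cM/Mb — a generator knob, not a claim about any genome). Repeat counts
live in [5, 60] with reflecting boundaries. Allele sizes are emitted as
100 + motif × repeat-count bp.

Initialisation and burn-in: the pool starts at per-locus coalescent
equilibrium under the same TPM (exact marginal equilibrium, linkage
equilibrium across loci — the correct joint equilibrium for a large
panmictic pool at these marker spacings except for residual background
LD at the tightest pairs) and then runs forward for 2 × Ne generations
so multi-locus structure, including that background LD, can settle.
Starting at equilibrium rather than approaching it from a monomorphic
state is what makes the generator usable at the study's effective sizes.
When no deme samples from or migrates with the pool after founding, the
pool is a stationary source and its forward evolution is skipped
entirely: isolated demes are founded directly from the equilibrium pool.

Rescaling: `rescale = f` divides Ne and times by f and multiplies the
mutation, migration and recombination rates by f, preserving θ = 4Neμ,
Nm and 4Ne·c. Founder counts are *not* divided: a founder event is an
instantaneous sample whose severity is its copy number. Scaled deme
sizes are floored at the sample size (24), which slightly slows drift in
the smallest demes at aggressive rescales. Two known discretisation
artifacts bound the useful range of f: sampled genealogies depart from
the Kingman coalescent when the sample is no longer small relative to
the scaled deme (n²/4N no longer ≪ 1), and the Ne floor distorts the
smallest demes; the preset defaults below were chosen inside the range
where the per-locus diversity and allele-count distributions match the
coalescent reference.

**Presets.** All four habitat templates descend from a common ancestral
pool of Ne = 5000 (θ = 3 at μ = 1.5 × 10⁻⁴), reflecting the system's
postglacial common origin:

| preset | demes | founding | founders | Ne | migration | default f |
|---|---|---|---|---|---|---|
| marine | 2 pool samples | — | — | (pool) | — | 20 |
| coastal | lake + river | 500 gen | 200 | 1000 | 0.01 | 20 |
| inland_lake | 2 lakes | 4000 gen | 50 | 500 | 0 | 4 |
| inland_pond | 2 ponds | 2000 gen | 20 | 100 | 0 | 4 |

Founding times sit within the ~10,000-year postglacial window at a
roughly 2-year generation time; Ne values are plausibility choices that
reproduce the observed diversity ordering (marine ≈ coastal ≫ lake >
pond, H_E ≈ 0.63/0.63/0.2/0.05 in our replicates) and the LD ordering
(pond > lake > marine with coastal ≈ marine). They are qualitative-
pattern settings, never asserted to match any real population.

One demographic subtlety the presets encode: a pond isolated for ~20×
its Ne (the default) has re-equilibrated at its own low θ — both
bottleneck signatures have decayed, heterozygosity is low, and the
M-ratio recovers toward its (high) low-θ equilibrium. That is the
profile of the study system's most depauperate pond, which is precisely
where bottleneck tests go quiet. The *detectable* regime is a recent
founder event; the bottleneck power analyses therefore run the pond
template with the founding moved to 20 generations ago, and the
validation report states both settings.

**What the generator does not emulate:** genotyping error and allele
binning noise, selection, sex-biased processes, spatial river/stream
structure, recombination-rate heterogeneity, and mutation-rate variation
across loci. Passing tests on synthetic data therefore demonstrate
estimator and pipeline correctness under the stated demographic model,
not robustness to those real-data complications.

## Validation problem sizes

The acceptance script (`scripts/acceptance.R`) and the acceptance test
file use: 10⁴ random frequency tables for the estimator oracles; 30
random datasets for the EM checks; 100 null replicates each for the
F_ST-permutation (199 permutations, two samples of 24, 8 loci) and
heterozygosity-excess (SMM, θ = 1, 10 loci, 150 conditioned replicates
per locus) calibrations, assessed by a Kolmogorov–Smirnov test at
α = 0.01; 50 recent-founder pond replicates for M-ratio power (Mc at
θ = 0.6, 2000 equilibrium iterations) and 15 for heterozygosity-excess
power; 20 marine replicates for M-ratio false positives (Mc at θ = 3)
and 8 for heterozygosity-excess false positives — these marine runs use
rescale 10 rather than the preset's 20, because at f = 20 the 48-copy
sample is no longer small against the scaled pool (n²/4N ≈ 2.3) and the
shared-pedigree inflation of multilocus-M variance makes the
false-positive rate wander between batches, while at f = 10 the forward
M distribution matches the independent-loci coalescent reference behind
Mc; and 10 replicate sets
of all four presets for the habitat D′ ordering. These sizes keep the
full validation near a quarter hour on one CPU while leaving the checks
clearly powered; the same quantities scale up cleanly if stronger Monte
Carlo precision is wanted.

## Known limitations

- The EM haplotype estimates assume random union of gametes within the
  analysed unit; pooled habitat units violate this by construction
  (that is, in fact, the point of the combined/average contrast).
- Composite LD on random-mating data attenuates toward half the
  haplotypic disequilibrium (normalisation choice above).
- The heterozygosity-excess machinery carries mild residual
  anticonservatism at very high locus counts and assumes unlinked loci.
- Rarefaction uses one global g; populations with heavy missingness drag
  g down for everyone.
- The forward simulator's reflecting allele-size boundaries add a little
  size homoplasy at high θ; at the preset settings the effect on
  diversity and M statistics was not measurable against the coalescent
  reference.
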