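# msatLD

Genome-wide linkage disequilibrium (LD) and population-genetic analysis of
multiallelic microsatellite data, built for the kind of study design used
in wild fish population genomics: a hundred-odd microsatellites mapped to
physical (Mb) positions on ~20 linkage groups, a couple of dozen diploid
individuals per population, and populations spread over contrasting
habitats (open marine, coastal freshwater with gene flow, long-isolated
inland lakes and ponds). The package quantifies how much LD each
population carries, how LD and diversity differ between habitats, and
whether the demographic histories implied by those differences (founder
events, bottlenecks, small effective sizes) are detectable.

## What it computes

**LD for multiallelic markers.** Two-locus haplotype frequencies are
estimated from unphased diploid genotypes by an EM algorithm over the
phase ambiguity of double heterozygotes. From a haplotype table with
margins `p(A_i)`, `p(B_j)` and `D_ij = p(A_iB_j) − p(A_i)p(B_j)`:

- multiallelic `D' = Σ_i Σ_j p(A_i) p(B_j) |D_ij / D_ij^max|`, with the
  usual sign-split normalisation of `D_ij^max`; bounded in [0, 1];
- multiallelic `r² = Σ_i Σ_j p(A_i) p(B_j) D_ij² / [p(A_i)(1−p(A_i))
  p(B_j)(1−p(B_j))]`, which reduces exactly to the classical
  `D²/(p_A q_A p_B q_B)` for biallelic loci;
- a composite (phase-free) counterpart estimated from genotype counts
  alone, `Δ_ij = Σ_ind g_i g_j/(4n) − p_i p_j`, as a phasing-robustness
  check.

Syntenic marker pairs are scanned per population or per habitat (pooled
or averaged), binned by physical distance (0–5, 5–10, … , >20 Mb), fitted
against ln(distance) for decay and half-length, and compared between
units with Mann–Whitney / Kruskal–Wallis / nested-ANCOVA tests under
Bonferroni correction. Rare alleles (<5%) can be excluded for sensitivity
analyses.

**Diversity and structure.** Observed and Nei-unbiased expected
heterozygosity, Weir–Cockerham F_IS with bootstrap CIs, rarefied allelic
and private allelic richness (Kalinowski estimators), rare-allele
proportions; pairwise Weir–Cockerham F_ST with permutation tests,
three-level AMOVA with permutation significance, and Queller–Goodnight
pairwise relatedness.

**Bottleneck tests.** The heterozygosity-excess test (coalescent
simulation under a two-phase mutation model, conditioned on the observed
allele count, one-tailed Wilcoxon across loci) and the Garza–Williamson
M-ratio with critical values Mc simulated at prebottleneck θ settings.

**Synthetic data.** A forward-time Wright–Fisher simulator (TPM mutation,
map-based recombination, coalescent-equilibrium initialisation) generates
the marine / coastal / inland-lake / inland-pond demographic scenarios as
presets, with an Ne-rescaling knob so tests run in seconds, plus truth
records for oracle checks.

## Worked example

```r
library(msatLD)

ps  <- preset_scenarios()            # marine / coastal / lake / pond
sim <- simulate_metapopulation(ps$inland_pond, seed = 7)
expected_heterozygosity(sim$dataset, "P1")$mean
#> [1] 0.08182055

rec <- syntenic_ld_scan(sim$dataset, sim$map, unit = "pond",
                        mode = "habitat")
bin_ld_by_distance(rec)[, 1:4]
#>       bin      mean       error n_pairs
#> 1   [0,5] 0.9805995 0.008422800      74
#> 2  (5,10] 0.9683184 0.014645184      57
#> 3 (10,15] 0.9960397 0.003384836      34
#> 4 (15,20] 0.9828961 0.009811310      19
#> 5     >20 0.9948049 0.004054689      35
#> 6 overall 0.9822697 0.004921692     219
```

A pond founded by 20 individuals and held at Ne = 100 keeps near-maximal
D′ at every distance — few haplotypes survive the founder event, so the
surviving alleles are almost completely associated — while its
heterozygosity collapses to ~0.08. The same scan on the `marine` preset
(seed 7) gives overall D′ ≈ 0.338 at H_E ≈ 0.640: the habitat contrast
the analysis is designed to expose.

The full 13-population study-style workflow lives in `analysis/` (run the
numbered scripts in order; outputs under `results/`):

```sh
Rscript analysis/01_simulate.R    # synthetic study dataset (GenePop + map)
Rscript analysis/02_diversity.R   # diversity table
Rscript analysis/03_ld.R          # LD scans, bins, decay, correlations
Rscript analysis/04_structure.R   # F_ST, AMOVA, relatedness
Rscript analysis/05_bottleneck.R  # heterozygosity excess + M-ratio
Rscript analysis/06_compare.R     # habitat/population comparisons
```

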