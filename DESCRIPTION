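Package: msatLD
Title: Genome-Wide Linkage Disequilibrium and Diversity Analysis for
    Multiallelic Microsatellite Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for genome-wide linkage disequilibrium (LD)
    in multiallelic microsatellite data from wild populations sampled across
    habitat types. Provides GenePop input/output with a physical (Mb) marker
    map, per-population diversity statistics (observed/expected
    heterozygosity, Weir-Cockerham F_IS with bootstrap confidence intervals,
    rarefied allelic and private allelic richness, rare-allele proportions),
    EM estimation of two-locus haplotype frequencies from unphased diploid
    genotypes, multiallelic D' and r2 together with a composite (phase-free)
    LD estimator, syntenic LD scans with distance binning and log-distance
    decay fits, population structure (pairwise Weir-Cockerham F_ST with
    permutation tests, hierarchical AMOVA, Queller-Goodnight relatedness),
    two bottleneck tests (heterozygosity excess under a two-phase mutation
    model and the M-ratio with coalescent-simulated critical values),
    habitat-level comparisons (Mann-Whitney, Kruskal-Wallis, nested ANCOVA,
    Bonferroni), and a forward-time Wright-Fisher simulator of
    marine/coastal/inland demographic scenarios for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
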