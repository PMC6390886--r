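# tetraqtl

Multi-allelic QTL mapping for **autotetraploid bi-parental populations**
(2n = 4x), built around identity-by-descent (IBD) haplotype
probabilities. The package targets the analysis chain used for complex
traits in cultivated tetraploid potato — e.g. tuber protein content
measured in potato fruit juice (PFJ) across replicated multi-year field
trials — where every locus segregates for up to eight parental
homologues and the genetic predictor is the expected homologue dosage
of each F1 clone rather than a single marker genotype.

## What it computes

At every position of a cM grid, the expected dosages
`X1..X4` (parent 1) and `X5..X8` (parent 2) obey
`ΣX_{1..4} = ΣX_{5..8} = 2`. The naive single-locus scan fits
Kempthorne-style additive models:

    model A:  y = μ + α₁X₁ + … + α₈X₈ + ε            (over-parameterized)
    model B:  y = μ′ + α′₂X₂ + α′₃X₃ + α′₄X₄ + α′₆X₆ + α′₇X₇ + α′₈X₈ + ε

with evidence `LOD = (n/2)·log₁₀(RSS₀/RSS₁)` against the intercept-only
null and `R² = 1 − RSS₁/RSS₀`. Genome-wide significance comes from
permutation of the phenotype (Churchill–Doerge; 1000 cycles, α = 0.05
in routine use), peaks are reported with LOD-2 support intervals, and
QTLs masked by larger ones are recovered by cofactor analysis
(residualize on the naive peaks, rescan, re-threshold on the
residuals). For a detected QTL the package estimates per-homologue
effects `h̄ᵢ − ȳ` with `h̄ᵢ = Σπᵢyᵢ/Σπᵢ`, and searches all bi-allelic
Q/q configurations of the 8 homologues (e.g. `QQQQ × QQQq`) by minimum
Schwarz information criterion with additive and additive + dominance
codings.

Around the scan sit the supporting stages: a **tetrasomic meiosis
simulator** (bivalent/quadrivalent pairing, double reduction, Haldane
recombination) that generates F1 populations with known planted QTLs; a
gamete-class → dosage converter with grid interpolation and genotypic
information coefficients (GIC); trait derivation
(`protein = PFJ protein × moisture / 100`), ANOVA variance components,
broad-sense heritability (`H² = σ²_G / (σ²_G + σ²_E/r)` within year)
and REML BLUEs; marker QC (missing-rate and tetrasomic segregation
chi-square filters); and delimited-text IO plus a command-line
dispatcher.

## Worked example

Simulate a 300-clone F1 across two chromosomes with a QTL on
homologue 6 of chromosome 1, derive BLUEs from a two-year trial, and
scan:

```r
library(tetraqtl)

map    <- geneticMap(c(chr1 = 100, chr2 = 90))
pop    <- simulatePopulation(300, map, meiosisConfig(), meiosisConfig(), seed = 11)
qtl    <- plantedQTL("chr1", 40, effects = c("6" = 0.10), mu = 0.93)
pheno  <- simulatePhenotypes(pop, qtl, years = 2, blocksPerYear = 2,
                             varPolygenic = 0.013, varGxY = 0.001,
                             varE = 0.039, seed = 12)

vc <- varianceComponents(anovaMeanSquares(pheno, "between"))
heritability(vc)
#> [1] 0.586  (broad-sense H², between-years model)

blues  <- computeBLUEs(pheno)
y      <- setNames(blues$blue, blues$clone)
dosage <- simulateDosageGrid(pop, lambda = 0.95)
scan   <- runNaiveScan(y, dosage, nPerm = 200, alpha = 0.05, seed = 13)
scan
#> ScanResult: 192 positions on 2 chromosome(s)
#>   max LOD: 5.73 at chr1 : 40 cM
#>   threshold: 4.62 ( 200 permutations, alpha = 0.05 )
#>   peaks: 1 above threshold
scanPeaks(scan)
#>   chrom peakCM  peakLOD         R2 intervalLo intervalHi
#> 1  chr1     40 5.727359 0.08416422         38         41
```

The scan recovers the planted QTL at its true position (40 cM), with a
LOD-2 support interval of 38–41 cM and `R² = 0.084`: the QTL explains
8.4% of the trait variance among clone means. The homologue effects at
the peak single out the planted haplotype — homologue 6 carries the
largest positive deviation:

```r
homologueEffects(y, dosage, "chr1", 40)
#>   homologue  hbar effect weight
#> 1         1 0.955 -0.010   80.2
#> ...
#> 6         6 1.001  0.036   77.4   <- planted carrier homologue
#> ...
```

`biallelicModelSearch(y, dosage, "chr1", 40)` then ranks all 126
segregating Q/q configurations by SIC, and
`cofactorAnalysis(y, dosage, scanPeaks(scan))` rescans after
residualizing on the peak.

A command-line interface wraps the same steps
(`inst/scripts/tetraqtl.R simulate | prep | scan | cofactor | effects | qc`).

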