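---
title: "Methods: IBD-based QTL mapping in autotetraploid F1 populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IBD-based QTL mapping in autotetraploid F1 populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetraqtl)
```

## The problem

Cultivated potato is autotetraploid (2n = 4x = 48): every chromosome is
present in four homologous copies, and during meiosis any two of the
four homologues can pair. A bi-parental F1 cross therefore segregates
for up to eight distinct parental homologues at every locus, and a QTL
can be carried by any of them. The analyses in this package take as
their genetic predictor not a single marker genotype but the
identity-by-descent (IBD) composition of each offspring: at every map
position, the expected number of copies of each parental homologue
(`X1..X4` from parent 1, `X5..X8` from parent 2) inherited by each F1
clone. Such expected dosages are what probabilistic haplotype
reconstruction tools (e.g. TetraOrigin) produce from SNP-array dosage
data; `tetraqtl` both consumes tables of this kind and simulates them.

The worked application the package is organized around is a tuber
protein-content trial: clones of a large F1 population are grown in
replicated multi-year field trials, soluble protein is measured in
potato fruit juice (PFJ, % w/v) and corrected by tuber moisture,

\[
\text{protein content} = \frac{\text{PFJ protein} \times (100 - \text{dry matter})}{100},
\]

and the resulting trait is mapped against the IBD dosages.

## Tetrasomic meiosis simulator

No public data set accompanies the analysis chain, so the package
includes a mechanistic simulator that produces F1 populations with
fully known inheritance. Its defaults are chosen to emulate a
potato-type cross: hundreds of F1 clones, chromosomes of roughly
80–110 cM, a 1 cM evaluation grid with positions rounded to 0.1 cM.

* **Bivalent meiosis.** With probability `1 - quadrivalentRate` the four
  homologues pair into two bivalents; the three possible pairings are
  equiprobable, since no preferential pairing is documented for the
  varieties this emulates. Each bivalent delivers one chromatid, so the
  two transmitted labels are always distinct and every homologue is
  transmitted with probability 1/2.
* **Recombination** follows Haldane's model: crossover counts are
  Poisson with mean (length in Morgan) and positions uniform, i.e. no
  interference. This matches the map function used to build the maps
  the method consumes.
* **Quadrivalents and double reduction.** With probability
  `quadrivalentRate` the chromosome forms a quadrivalent. The gamete is
  then drawn segment-wise between the pooled crossover breakpoints of
  its two chromatids, and at any locus the two chromatids are copies of
  the same homologue with probability `doubleReductionRate`
  (bounded by the theoretical maximum 1/4). Double reduction is
  parameterized as a flat per-locus rate rather than a
  centromere-distance model: the downstream machinery only requires
  that double-reduction classes be representable, not a specific DR
  landscape along the chromosome.
* **Posterior blur.** `inheritanceToProbabilities()` turns the true
  gamete classes into the mixture
  `lambda * truth + (1 - lambda) * uniform` per parent. This one-knob
  emulation of reconstruction uncertainty was chosen so that both ends
  are exact: `lambda = 1` is the truth and `lambda = 0` the uniform
  (completely uninformative) distribution, under which every expected
  dosage is 0.5. Real posteriors have position- and
  individual-dependent uncertainty concentrated near recombination
  breakpoints and in marker-poor regions; the flat blur does not
  reproduce that structure, so passing tests say nothing about
  reconstruction quality on real marker data — only about the QTL
  machinery downstream of it.
* **Phenotypes.** Trait records follow
  `y = mu + sum(alpha_i C_i) + d 1[carrier] + g + year + block(year) +
  (g x year) + e` with Gaussian terms, matching the approximately
  normal trait distributions such trials report. Year and
  block-within-year variances are not part of the reported variance
  components; defaults of 5e-4 were fixed once from the spread of the
  reported year means (0.92 vs 0.95 on a trait mean of ~0.93) and are
  absorbed by the ANOVA design terms in any case.

The gamete-class set is fixed at 6 bivalent classes (unordered pairs of
distinct homologues) plus 4 double-reduction classes per parent; the
joint F1 class is the product of independent parental gametes.

## Phenotype statistics

Variance components come from ANOVA mean squares:
within-year `sigma2_G = (MS_G - MS_E) / r`; between-years
`sigma2_G = (MS_G - MS_GxY) / (r y)`, `sigma2_GxY = (MS_GxY - MS_E) / r`;
`sigma2_E = MS_E`. Mean squares are computed by nested least-squares
model comparisons (type-II sums of squares), which remain well defined
for unbalanced tables — clones missing a cell are retained. Negative
method-of-moments estimates are floored at zero for reporting and kept
raw alongside, the standard convention for this estimator.

Broad-sense heritability is

\[
H^2_{\text{within}} = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_E / r},
\qquad
H^2_{\text{between}} = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{G\times Y}/y + \sigma^2_E/(r y)}.
\]

On the reported components of the motivating trial these give 40%
(sigma2_G = 0.013, sigma2_E = 0.039, r = 2) and 55% (0.021, 0.034).
One documented discrepancy: the between-years formula evaluated on the
reported components (0.042, 0.001, 0.062, r = 2, y = 2) gives 72.4%,
while the trial reports 74%. The formulas as printed are implemented;
the gap is left as-is rather than silently reconciled.

Adjusted clone means (BLUEs) come from the REML fit of
`trait = genotype + year + error` with genotype fixed and year random
(`lme4::lmer`). With a single year the model degenerates to ordinary
clone means, which is what the implementation returns in that case.

## The naive single-locus scan

At a position the full additive model is
`y = mu + alpha_1 X1 + ... + alpha_8 X8 + e` ("model A"). The parental
constraints `X1+X2+X3+X4 = 2` and `X5+X6+X7+X8 = 2` make it
over-parameterized, so one term per parent is eliminated ("model B"):
the package drops `X1` and `X5`. Any one-per-parent choice spans the
same column space and yields identical residual sums of squares and
LOD — this is asserted by test, and the dropped columns are always
recoverable as `2 - sum` of the retained ones.

The evidence measure is
`LOD = (n/2) log10(RSS0 / RSS1)` against the intercept-only null, with
`R2 = 1 - RSS1/RSS0 = 1 - 10^(-2 LOD / n)` as an exact identity. The
degenerate case `RSS0 = RSS1` (including a constant phenotype, 0/0) is
defined as LOD 0; a perfect fit gives `Inf`. Missing phenotypes are
dropped per scan and the `n` actually used enters the formula.

Numerical choices: every position is fitted by minimum-norm least
squares (SVD pseudo-inverse), so rank-deficient designs — uninformative
regions where dosages approach 0.5, or collinear homologues — are
handled without changing the model dimension per position.
Permutation scans use precomputed per-position orthonormal bases (QR),
which reduces each permutation to one matrix product per position.
Ties in peak argmax are broken toward the lower cM position for
determinism.

The genome-wide threshold is the empirical `(1 - alpha)` quantile of
the maximum LOD over phenotype permutations (1000 cycles and
alpha = 0.05 in routine use; the permutation scheme permutes phenotype
labels against intact genotype rows, preserving the dosage LD
structure). Peaks above the threshold are reported with LOD-2 support
intervals: the contiguous run around the peak with `LOD >= peak - 2`,
truncated to positions above the threshold.

## Homologue effects and the bi-allelic model search

For a detected QTL, per-homologue effects are the weighted means
`hbar_i = sum_n pi_in y_n / sum_n pi_in` with `pi_in = X_in / 2`
(the probability of carrying homologue i, up to double-reduction
corrections), reported as deviations from the population mean. Because
the per-individual weights sum to a constant, the weighted effects sum
to zero exactly.

The bi-allelic search asks whether the multi-allelic signal is
explained by a single Q/q allele spread over the 8 homologues. All
2^8 assignments are enumerated, canonicalized under the global Q–q
swap (homologue 1 carries q) and pruned of non-segregating assignments
(both parents homozygous), leaving 126 candidates, each fitted with an
additive coding (expected Q dosage) and an additive + dominance coding
(probability of at least one Q copy). Model fit is ranked by the
Schwarz information criterion in its Gaussian form
`SIC = n ln(RSS/n) + k ln(n)`, k counting fitted parameters including
the intercept; the criterion's source prints no formula, so this
standard form is adopted. Differences `deltaSIC` below 2 between the
best and runner-up model are labelled weak evidence. Two genuine
ambiguities are handled explicitly:

* under the additive coding, complementing the Q/q labels of a single
  parent shifts the predictor by a constant — such models are exactly
  tied, so "recovery" of a planted configuration is always judged up to
  per-parent complementation;
* the dominance predictor requires gamete-class probabilities; when
  only dosages are available, a products-of-marginals approximation is
  used and flagged in the output (`dominanceApprox`).

## Cofactor analysis

To find QTLs masked by larger ones, the naive peak positions are frozen
as cofactors: the phenotype is regressed jointly on the model-B columns
of all cofactor positions, residuals are rescanned, and a fresh
permutation threshold is computed on those residuals with the same
permutation engine and seed discipline. Cofactor design columns are not
refit during permutation — the residuals themselves are permuted. All
non-empty subsets of the naive peaks are analysed (2^k - 1 analyses for
k peaks). A newly significant peak is flagged as a masked QTL unless it
falls inside the LOD-2 interval of a naive peak on the same chromosome
(fallback: within 15 cM when no interval is available); this
interval-based rule was chosen because it reproduces the intended
behaviour on reference cases where a rescan peak 8 cM from a naive peak
is the same QTL while one 50 cM away on the same chromosome is new.

## Marker QC

Upstream of any IBD work, `qcMarkers()` applies the standard dosage
filters: markers with more than 5% missing calls, individuals with more
than 10% missing calls, and markers whose offspring dosage counts
contradict the tetrasomic segregation expectation for their parental
dosage pair (chi-square goodness-of-fit at alpha = 0.001; e.g. 1:1 for
simplex x nulliplex, 1:4:1 for duplex x nulliplex). The segregation
null assumes bivalent-only gametes; double reduction shifts these
ratios by far less than the test's sensitivity at the population sizes
involved, and full segregation-model assignment is out of scope here.

## Problem sizes and what the tests show

The test suite validates the pipeline on simulated populations chosen
to exercise the study-scale behaviour while staying quick to run:
oracle equivalence on 20 individuals; meiosis calibration on 10,000
gametes; type-I error of the permutation threshold on 200 independent
null scans (200 individuals, 3 x 100 cM, 200 permutations each,
expected exceedance within [0.02, 0.10] at alpha 0.05); detection power
for a single-homologue QTL explaining ~8% of variance at n = 496 and
lambda = 0.9 (>= 80% detection, LOD-2 interval covering the truth in
>= 80% of detections over 20 replicates); min-SIC recovery of a planted
`QQQQ x QQQq` configuration (>= 70% over 20 replicates at n = 250);
masked-QTL behaviour in a two-QTL design whose minor effect is
significant only after residualizing the major one; and unbiasedness of
the variance-component estimators at the reported trial scale
(sigma2_G = 0.042, sigma2_GxY = 0.001, sigma2_E = 0.062) over 200
replicates of a 60-clone balanced trial.

These checks establish the statistical machinery on data whose
generating process is exactly the assumed model. They do not establish
robustness to map error, genotyping error, non-Gaussian traits,
position-dependent reconstruction uncertainty, segregation distortion
or spatial field trends — none of which the simulator emulates.

## Known limitations

* The simulator's quadrivalent gametes redraw the homologue pair on
  every pooled breakpoint segment, which slightly inflates effective
  recombination relative to a physical quadrivalent model; bivalent
  mode (the default) matches Haldane expectations exactly.
* The between-years heritability formula reproduces its printed
  definition, including the 72.4% vs 74% discrepancy noted above.
* `deltaSIC` is reported rather than any absolute SIC, since the
  absolute value depends on an arbitrary likelihood constant;
  published absolute "minimum SIC" figures are treated as separation
  statements.
* Conversion of under-water weight to tuber dry matter is out of
  scope; the phenotype reader accepts dry matter directly.
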