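---
title: "Methods: quantitative-genetic analysis and multiple-QTL mapping for intermated RILs"
author: "irilqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative-genetic analysis and multiple-QTL mapping for intermated RILs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irilqtl)
```

## The problem and the population

`irilqtl` analyses replicated phenotype trials of biparental **intermated
recombinant inbred line (IRIL)** populations — the design of the maize IBM
population, in which the F2 of B73 × Mo17 was randomly intermated for
several generations before single-seed-descent selfing.  Intermating
accumulates extra recombination, which expands the genetic map and sharpens
QTL localisation.  The package takes a genetic map, a genotype matrix and a
long-format phenotype table through quality control, per-regime trait
modelling and a composite-interval multiple-QTL scan, and reports
publication-style QTL tables.  A gene-drop simulator with known truth backs
every stage with parameter-recovery tests.

## The phenotype model

Each trait within each treatment regime is modelled as

$$y_{ik} = \mu + g_i + r_k + e_{ik},$$

where $y_{ik}$ is the record of line $i$ in replication $k$ (operationally
the mean of the plants grown in one pot), $g_i$ the genotype effect, $r_k$
the replication effect and $e_{ik}$ the residual.  Regimes are analysed
separately throughout; the regime label is a stratification key, and no
genotype-by-regime interaction model is offered.

Two fits of this model are used:

* **Adjusted entry means (AEM).** With $g_i$ and $r_k$ fixed, the AEM of a
  line is its least-squares mean — the model prediction averaged over the
  replication levels.  For complete balanced data this is the arithmetic
  mean across replications.
* **Variance components.** With $g_i$ random and $r_k$ fixed, REML yields
  $\sigma^2_g$ and $\sigma^2_e$, and the broad-sense heritability on an
  entry-mean basis with $b$ replications is
  $$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_e / b}.$$

For complete balanced data the REML solution is available in closed form
and equals the ANOVA moment estimators $\hat\sigma^2_e = MS_E$ and
$\hat\sigma^2_g = (MS_G - MS_E)/b$; `fit_trait_model()` uses that exact
path, falling back to a numerical one-dimensional REML optimisation (via
lme4's modular interface, tolerance $10^{-12}$ on the variance-ratio
parameter) for unbalanced data.  Negative moment estimates are truncated at
zero and flagged, which keeps $H^2 \in [0, 1]$.  Normality of the AEM is
screened with a Kolmogorov–Smirnov test whose reference normal has mean and
standard deviation estimated from the same sample; the resulting p-value is
conservative in the Lilliefors sense and is reported as a descriptive
check, not a gate.

## Trait networks

Pairwise Pearson correlations are computed on the AEM.  Partial
correlations come from the Gaussian graphical model: the trait correlation
matrix $R$ is (optionally) shrunk toward the identity,
$R_\lambda = (1-\lambda) R + \lambda I$, inverted, and standardised,
$\rho_{ab\cdot rest} = -\Omega_{ab} / \sqrt{\Omega_{aa}\Omega_{bb}}$.  This
equals the correlation of the residuals after regressing each trait on all
remaining traits, which is the oracle the tests check against.  Partial
correlations are computed on AEM (not on raw records), so replication
effects are removed before the network is formed; $\lambda$ defaults to 0,
which is appropriate whenever the number of complete lines exceeds the
number of traits plus one, and a singular matrix raises an error that
suggests shrinkage rather than silently regularising.

## Genotype quality control

* **Segregation distortion.** In a biparental inbred population every
  marker should segregate 1:1.  Each marker's A:B counts (heterozygous and
  missing calls excluded — the lines are near-inbred, so residual
  heterozygotes carry almost no information about transmission bias) are
  tested with a 1-df chi-square goodness-of-fit; markers with
  $p < \alpha$ (default $\alpha = 0.001$, the threshold used on the IBM
  map) are removed.  Markers with no informative calls are excluded with
  an explicit `no_data` status.  The filter is idempotent.
* **Imputation.** Missing calls are replaced by their conditional expected
  dosage $E[x] = 2P(A) - 1$ given the nearest informative flanking markers
  on the chromosome, under a two-state Markov model whose transition
  probability between fixed RIL loci at Haldane distance $d$ is
  $R = 2r/(1+2r)$, $r = (1-e^{-2d})/2$.  A configurable expansion factor
  scales distances for maps whose coordinates do not already reflect
  intermating (for an intermating-expanded map such as IBM2 it stays 1).
  Hard calls are only written where $|E[x]| > 0.98$; otherwise the
  fractional dosage is kept for regression, and observed calls are never
  altered.  Chromosome ends condition on the single available flank, and a
  line with an entirely missing chromosome gets the uninformative dosage 0
  with a warning.

The imputation method of the emulated analysis was cited but not described;
flanking-marker conditional expectation was chosen here as the standard,
testable approach, and simulations confirm it beats marginal-frequency
imputation in mean absolute dosage error.

## The mapping engine

**Genotype probabilities.**  A pseudomarker grid is laid every 2 cM
(configurable), always including the marker positions.  Per line and
position, $P(A)$ is conditioned on the nearest informative flanking
markers under the same two-state RIL model; at observed homozygous markers
it is exactly 0 or 1, at heterozygous calls 0.5.

**Cofactor selection.**  With far more markers than lines, plain stepwise
regression is unstable, so cofactors are chosen by a randomized, bin-based
procedure: (1) draw one random marker per map bin and run forward–backward
stepwise selection minimising $BIC = n\ln(RSS/n) + k\ln(n)$; repeat
(1000 times by default); (2) let $m^*$ be the rounded mean number of
selected cofactors and keep the $m^*$ bins with the highest selection
frequency; (3) draw up to 100 markers from those bins and run one final
stepwise-BIC selection.  The "bins to study in more detail" stage is
interpreted as the top-$m^*$ bins ranked by selection frequency; the
source procedure does not state the ranking rule, so this interpretation
is explicit.  Stepwise ties break toward the lower marker index and
rank-deficient (collinear) additions are skipped, making the whole
procedure deterministic under a seed.

**Scan.**  The composite-interval scan is Haley–Knott regression of the
AEM on the expected dosage at each grid position plus the cofactor
dosages, excluding any cofactor within a 10 cM window (configurable) of
the test position on its chromosome, so a cofactor never absorbs the
signal under test.  With the reduced model keeping the same included
cofactors,
$$LOD = \frac{n}{2}\log_{10}\frac{RSS_{reduced}}{RSS_{full}},$$
which at a fully observed marker equals the exact single-marker regression
LOD (the tests require agreement to ten significant digits).  Internally,
positions sharing an included-cofactor set are processed together by
residualising on the cofactors first (Frisch–Waugh–Lovell), which is
algebraically identical and lets permutation scans run as single matrix
products.  The mixture-likelihood MQM variant cited by the emulated study
is not reproduced exactly — its internal details are unpublished at this
level — so the Haley–Knott approximation with fixed-window cofactor
exclusion is implemented and documented as such; at IRIL levels of
residual heterozygosity the two agree closely.

**Permutation thresholds.**  The genome-wide significance threshold is the
empirical $1-\alpha$ quantile (type-7, linear interpolation, for
cross-language reproducibility) of the maximum LOD over permutations of
the phenotype across lines (1000 by default, $\alpha = 0.05$).  The
cofactor *set* stays fixed at its unpermuted selection; re-running the
randomized cofactor search inside every permutation would multiply the
cost roughly a thousand-fold and the source analysis does not state that
it was done.  Null simulations show the resulting genome-wide type-I error
is compatible with the nominal $\alpha$.

**Peaks, intervals, effects.**  Local maxima at or above the threshold are
peak candidates; candidates on one chromosome closer than 30 cM
(configurable; the published same-chromosome QTL pairs are at least
roughly 14 cM apart) merge to the higher peak, ties toward the lower cM.
Each peak's credible interval treats $10^{LOD}$, normalised over the
chromosome grid, as a posterior and grows the smallest contiguous region
containing the peak to 95% mass, then expands the endpoints outward to the
nearest flanking markers, whose physical coordinates define the physical
interval.  All peaks of a trait enter one simultaneous Haley–Knott
regression: the additive effect is the coefficient on the $\{-1,+1\}$
dosage (positive means the B73 allele increases the trait, so
Mo17-contributed increasing alleles appear negative, matching the
published sign convention), per-QTL $\%r^2$ is the drop-one RSS increase
over the total sum of squares, and the total $\%r^2$ is the model $R^2$.
Genes are counted by closed-interval overlap with a supplied annotation;
without an annotation the count is reported missing, never zero.

## The simulator

`sim_spec()` fixes the study conditions; defaults emulate the trial the
package was built around: 85 lines, 3 replications, a biparental cross
with 4 intermating and 8 selfing generations, and variance components
chosen per trait to land heritabilities in the observed 0.28–0.80 range.
Gametes follow the Haldane model (crossovers without interference), the
only mapping function consistent with a bare cM map; chromosomes assort
independently.  The intermating-generation count of the real population is
not stated in the emulated study, so 4 is a documented default, not an
inference.  Causal QTL are placed at the nearest marker so that the truth
is exactly representable on the scan grid.  Phenotypes follow the analysis
model above with additive QTL dosages, a polygenic line deviation, fixed
replication effects and pot error; the split-plot arrangement of the real
trial is not simulated, matching the analysis model actually fitted.

Useful physics of the gene-drop, verified by the tests: heterozygosity
halves per selfing generation, so after $g$ generations from the F2 the
expected rate is $0.5^{g+1}$; the two-locus recombinant fraction of selfed
RILs equals $2r/(1+2r)$; intermating strictly increases observed
recombinant fractions.  What the simulator does **not** emulate —
genotyping error, segregation distortion of biological origin (the
distortion injector resamples calls, it does not model gametic selection),
epistasis, QTL-by-regime interaction, selective genotyping — bounds what
passing tests can show about real data: they validate the estimation
machinery, not robustness to those artefacts.

## Numerical choices

* BIC is $n\ln(RSS/n) + k\ln(n)$ with $k$ the number of selected markers;
  an exact-fit candidate gives $-\infty$ and is selected, after which no
  move can improve.
* Quantiles for permutation thresholds are type 7; `n_perm < 20` is
  refused outright rather than silently extrapolated.
* $r^2$ in the scan is capped at $1 - 10^{-15}$ so an exact fit yields a
  large finite LOD; positions whose residualised dosage is numerically
  constant get LOD 0.
* The hard-call threshold for imputation is $|E[x]| > 0.98$, i.e. a
  posterior of 0.99 for one homozygote.
* AEM of lines with no observations are `NA` and logged; constant traits
  yield $\sigma^2_g = \sigma^2_e = 0$ and a missing $H^2$.
* All randomized stages take explicit seeds; the pipeline derives one seed
  per trait-by-regime from its master seed, so outputs are a pure function
  of (inputs, configuration, seed).

## Problem sizes used by the checks

The published analysis is not reproducible from raw data (the phenotypes
were never deposited), so the package's checks combine (a) summaries of
the transcribed published tables shipped under `inst/extdata/` and (b)
simulation studies at sizes chosen to give stable statistics at desk
scale: permutation calibration uses 200 null traits with 200 permutations
each on a 2-chromosome genome of 120 lines; single-QTL recovery uses 100
replicates of 200 lines with a QTL heritability of about 0.25; variance
component recovery uses 500 balanced trials of 200 lines; simulator
physics use 2000–5000 lines.  `scripts/acceptance.R` recomputes all of
these from scratch under a caller-supplied seed.

## Known limitations

* Dominance is absent by design (inbred lines), as are multi-trait and
  multi-environment joint QTL models and eQTL/pQTL integration.
* The credible interval is the usual $10^{LOD}$-posterior approximation;
  its empirical coverage at nominal 95% is checked to be at least ~0.88 in
  simulation, not exactly calibrated.
* Additive effects at selected peaks carry a mild winner's-curse inflation
  (median around +9% at QTL $h^2 \approx 0.25$, $n = 200$ in the shipped
  recovery study), inherent to reporting effects at the scan maximum.
* The distortion filter tests each marker marginally; no multiple-testing
  correction is applied, matching the emulated analysis.
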