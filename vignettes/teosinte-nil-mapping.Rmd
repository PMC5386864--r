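---
title: "Joint-linkage QTL mapping in NIL introgression libraries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-linkage QTL mapping in NIL introgression libraries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teonil)
```

`teonil` implements the full analysis chain used to dissect kernel
composition (and other quantitative traits) in multi-parent near-isogenic
line (NIL) libraries: populations built by backcrossing several wild or
exotic donors — e.g. ten geographically diverse accessions of teosinte
(*Zea mays* ssp. *parviglumis*) — into a common recurrent inbred such as
B73, then selfing to fix the introgressions.  Each NIL carries a few donor
segments (about 4% of the genome after four backcrosses and two selfings),
so phenotypic contrasts against the recurrent background isolate the
allelic effects of the introgressed segments.

This vignette documents the models, the tunable parameters, the synthetic
data generator used for validation, and the numerical choices.

## Pedigree simulation

A BC$_n$S$_m$ pedigree is simulated per line as a pair of chromosome
haplotypes.  Crossovers follow the Haldane model — no interference, so the
crossover process along a chromosome is Poisson with rate 1 per 100 cM and
the recombination fraction at distance $d$ cM is
$r = \tfrac12\,(1 - e^{-2d/100})$.  Because the process is Markov, the
donor/recurrent origin of a gamete *at the marker positions* is itself a
Markov chain whose switch probability between adjacent markers is exactly
that $r$; gametes are drawn directly from this chain, which is the exact
marginal of the Poisson-breakpoint process at the markers and vectorises
over whole populations.

Single-locus expectations come from the transition rules (F1 is
heterozygous; a backcross maps H to B or H with probability $\tfrac12$
each; a selfing maps H to B, H, D with probabilities
$\tfrac14, \tfrac12, \tfrac14$):

```{r}
expected_genome_composition(pedigree_spec(n_backcross = 4, n_self = 2))
```

so a BC4S2 library is expected to be 96.1% recurrent homozygote and 3.9%
donor-derived per line.  Simulation is neutral: no selection among
progeny, no forced introgression-bearing gametes, lines with zero donor
segments retained.  Real libraries were built with visual selection and
show slightly more residual heterozygosity than this expectation; the
generator makes no attempt to reproduce that excess.

## Phenotypes, entry means, heritability

Plot values are generated as
$$y_{ijk} = \mu_t + \textstyle\sum_q a_{q,f(i)}\,x_{iq} + g_i + e_j +
(ge)_{ij} + \varepsilon_{ijk},$$
with donor-allele dose $x \in \{0, \tfrac12, 1\}$ for B/H/D (so the
per-family additive effect $a$ is on the homozygous-substitution scale),
polygenic deviate $g_i \sim N(0, \sigma^2_G)$ (optionally correlated
across traits), environment shifts $e_j$, interaction
$(ge)_{ij} \sim N(0, \sigma^2_{GE})$ and plot residual
$\varepsilon \sim N(0, \sigma^2_e)$.  Defaults emulate a two-location,
two-replicate trial with trait intercepts at typical B73-background kernel
composition (starch 71.41, protein 10.77, oil 3.89 % dry matter).

Entry least-squares means come from the fixed-effects model
`value ~ line + env`, evaluated at the average of the environment
effects; replicates are nested in environments and absorb into the error
for entry means, which is why no rep term appears.  On balanced data this
reduces (exactly) to the per-line plot mean and that fast path is used.

Broad-sense heritability on an entry-mean basis uses the random-effects
model `value ~ env + (1|line) + (1|line:env)` (environment fixed) and
$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GE}/e +
\sigma^2_e/(er)},$$
with harmonic-mean environment and replicate counts $e, r$ when the
design is unbalanced and negative component estimates truncated at zero.
Estimation is REML via `lme4` by default; a method-of-moments ANOVA
estimator (`method = "anova"`) is provided as a fast cross-check and
coincides with REML on balanced data with interior estimates.  Phenotypic
correlations are pairwise-complete Pearson correlations of entry means
with $t$-distribution p-values.

## Joint-linkage mapping

Mapping is marker-based (no interval mapping), jointly across families.
The model always carries family main effects; a marker enters as the
*group* of its family-nested dose columns, one per family in which it
segregates (within-family dose variance > 0).  The entry test is the
grouped F-test of those columns.  Against the family-only base model the
nested columns of one marker have disjoint support across families and
are orthogonal to the family indicators after within-family centering, so
the scan reduces to a few `rowsum` operations; against richer base models
the test uses QR projections.  Both paths are verified against a dense
normal-equations implementation in the test suite (to $10^{-8}$ relative
error).

**Permutation thresholds.** Entry means are shuffled across lines
*within* each family, holding genotypes fixed — this preserves family
main effects under the null so the family term cannot inflate the scan —
and the minimum entry p-value over all markers is recorded per
permutation.  The threshold is the `gwer`-quantile (default 0.05, 1000
permutations) of these minima, giving genome-wide error-rate control by
construction.  On the default synthetic library the resulting thresholds
are of order $10^{-6}$, the same scale as published NIL scans.  Whether
to shuffle within or across families is genuinely open in the source
protocols; within-family is the conservative choice and is the default.

**Forward selection** adds the marker with the smallest entry p-value
while it is below the threshold, up to `max_qtl`; ties break to the lower
chromosome and then lower cM; markers whose dose is perfectly correlated
with a selected marker are skipped.  There is no backward elimination —
the protocol is forward-only.  The final model is refit by OLS and each
family's donor allele is tested against the recurrent (0-dose) baseline
by a two-sided t-test; stars mark p < 0.05 (`*`) and p < 0.01 (`**`), raw
p-values with no multiplicity correction, and `-` marks families with no
introgression at the marker (no donor allele to test).  A negative
coefficient means the donor allele lowers the trait.

**Support intervals.** For each QTL, every marker on its chromosome is
swapped into the model in place of the QTL (other QTL stay as covariates,
a composite-interval-style conditional profile) and
$\mathrm{LOD}(m) = \tfrac{n}{2}\log_{10}(\mathrm{RSS}_0 /
\mathrm{RSS}_m)$ with $n$ the complete-case line count for the trait.
The 1-LOD support interval grows outward from the peak while markers stay
within `drop` (default 1) LOD of it; endpoints are those boundary
markers' cM positions (closed interval).  On a flat profile this is the
whole chromosome.

## Chemometric calibration

The NIR stage mirrors bulk whole-grain calibration on a scanning
instrument: absorbance $\log(1/R)$ on a 400–2500 nm grid at 10 nm steps.

* **MSC** regresses each spectrum on a reference ($x \approx a + bm$) and
  rescales to $(x - a)/b$.  The reference defaults to the mean spectrum;
  with a *fixed* reference MSC is exactly idempotent (to machine
  precision), while re-deriving the mean from already-corrected spectra
  perturbs a second pass at about $10^{-5}$ — the package therefore
  stores the training reference in fitted models and reuses it at
  prediction.
* **Savitzky–Golay first derivative** fits a local polynomial (default
  window 11 points, order 2 — conventional for 10 nm grids) and
  differentiates the fit; edges are handled by the asymmetric clipped
  window with no padding, so polynomials up to the fit order are
  differentiated exactly everywhere.  Output units are absorbance per nm.
* **PLS1** is NIPALS on centered data: $w \propto X^\top y$, $t = Xw$,
  $p = X^\top t / t^\top t$, $q = y^\top t / t^\top t$, deflation of both
  $X$ and $y$; coefficients are assembled for raw-scale prediction.  With
  full rank it reproduces OLS (tested to $10^{-6}$).  The component count
  defaults to leave-one-out cross-validation capped at 15; SEC uses
  $n - 1 - k$ denominator degrees of freedom ($k$ components), one common
  chemometrics convention — conventions differ, so it is stated here.
  Preprocessing chains are configuration: the starch chain is SG
  derivative then MSC, protein is MSC only (order of the two is not fixed
  by any source protocol and is exposed as configuration).
* **NMR oil calibration** is a simple least-squares line through the mean
  of triplicate resonance readings, summarised by $r$ and the residual
  standard error.

The synthetic spectra generator composes Beer–Lambert mixtures of three
constituents with Gaussian bands, per-sample additive/multiplicative
scatter, and i.i.d. instrument noise (default 0.02 AU).  Two features are
deliberate: compositions are drawn with the strong negative
starch–protein correlation of real grain (compositional closure) —
without it, starch variation is parallel to the mean spectrum and MSC
removes it, which no real calibration set exhibits — and the oil bands
get a random per-sample attenuation emulating embryo orientation in
intact kernels.  Under defaults the protein model calibrates at
$r \approx 0.98$, starch (SG+MSC) at $r \approx 0.86$, and oil saturates
near $r \approx 0.76$, qualitatively reproducing why intact-kernel NIR
predicts protein and starch but fails for oil, which is why the oil trait
is calibrated by NMR instead.

## Validation design and problem sizes

All validation is against synthetic truth (the test suite) plus printed
structural expectations; the heavy checks and the sizes they run at,
chosen to represent the study design at tractable cost:

* genome composition at the full library scale (961 lines, 10 families of
  58–135, 728 markers, ~1600 cM);
* genome-wide error-rate control on 500 null datasets of 300 lines x 200
  markers with 200 permutations each (entry-mean $H^2 = 0.7$ polygenic
  noise), requiring the false-QTL rate in [2.5%, 7.5%] at gwer 0.05;
* truth recovery over 100 replicates at full scale with one QTL whose ten
  family effects span $-2.56$ to $+0.61$ (the strongest published
  teosinte allelic-effect range), the largest magnitude assigned to the
  largest family.  Residual variance components are
  $\sigma^2_G = 0.3, \sigma^2_{GE} = 0.1, \sigma^2_e = 0.4$, giving
  entry-mean $H^2 = 0.70$ *including* the QTL variance: in a
  near-isogenic background most genetic variance comes from the
  introgressions themselves, so a planted QTL of this size explains
  roughly 10% of entry-mean variance, the scale observed in real NIL
  scans.  (A polygenic-dominated partition at the same $H^2$ would bury
  the QTL and contradict the source study's own detections.)  The entry
  threshold is fixed at $10^{-6}$, the scale of published permutation
  thresholds; coverage of the largest effect is assessed where the family
  actually carries an introgression at the QTL (otherwise it is the `-`
  cell of the effect table, with no t-test defined);
* heritability recovery on a 3x3 grid of variance components at 961
  lines, 20 seeds per cell, using the moment estimator (shown equal to
  the REML default on balanced data within $10^{-4}$).

What passing these checks does **not** show about real data: the
generator has no segregation distortion, no genotyping error, no
selection during line development (real libraries show more residual
heterozygosity than the neutral expectation), Gaussian trait residuals,
and markers at their true map positions.  Estimates on real libraries
inherit none of those guarantees.

## Degenerate inputs and numerical conventions

* Markers segregating in no family get entry p = 1 with a flag; rank
  deficiency in final models drops offending columns with a warning.
* Missing genotype calls are imputed by the family-mean dose (so imputed
  doses may be fractional, e.g. 1/3); missing phenotype plots are
  dropped, never imputed; a line observed in no environment gets a
  missing entry mean with a warning.
* Single-marker chromosomes yield a degenerate one-point LOD profile,
  flagged.
* Coordinates are genetic-map cM, chromosomes 1-based, intervals closed.
* One master seed drives everything; per-stage seeds are derived
  deterministically (`derive_seed`), outputs are bit-identical for a
  fixed seed, and all output files carry version, seed and parameters in
  their headers.

## A small end-to-end run

```{r, eval = FALSE}
map <- synthetic_genetic_map()
pop <- simulate_nil_population(map, seed = 1)
q <- qtl_spec(rep("m0100", 3), "starch", c("F08", "F09", "F10"),
              c(-2.56, -1.8, -1.2))
plots <- simulate_phenotypes(pop, q,
                             env_spec(var_G = 0.3, var_GE = 0.1,
                                      var_E = 0.4),
                             traits = "starch", seed = 2)
y <- lsmeans_vector(compute_lsmeans(plots), "starch")
dos <- encode_dosage(pop)
thr <- permutation_threshold(y, dos, n_perm = 1000, seed = 3)
model <- forward_select(y, dos, thr$threshold)
qtl_report(y, dos, model, pop, trait = "starch")
```

The same chain, driven by a YAML config and writing all artifacts with
headers and a run log, is `run_pipeline()` (see its help page for the
config schema) or the thin wrapper in
`system.file("scripts", "teonil-pipeline.R", package = "teonil")`.
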