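---
title: "Methods: soil microbial energetics and 13C source partitioning with thermosip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil microbial energetics and 13C source partitioning with thermosip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermosip)
```

## What the package models

`thermosip` analyses soil incubation experiments in which a ^13^C-labelled
glucose pulse is added to replicated field soils and three complementary
measurements follow: continuous heat flow in an isothermal calorimeter,
flushed-headspace CO~2~ sampling with ^13^C isotope-ratio analysis, and
density-gradient stable isotope probing (SIP) of 16S rRNA genes to identify
the taxa that assimilated the glucose. The motivating design contrasts two
long-term management systems (conventional, `CON`, and organic, `ORG`) and
two cropping histories (annual, `ANN`, and annual--perennial, `PER`) in a
split-plot layout with four field replicates, glucose added at
500 µg C g^-1^ dry soil, and headspace sampling at 4, 12, 24, 36, and 48 h.

Three quantitative layers are implemented:

1. **Calorimetric energetics.** Power curves are integrated to cumulative
   heats *Q* (J g^-1^ soil) and converted into a thermodynamic efficiency
   index
   $$\eta_{\mathrm{eff}} = 1 - \frac{Q_{\mathrm{glucose}} -
   Q_{\mathrm{control}}}{\Delta H_{\mathrm{glucose}}},$$
   the thermal yield partition
   $$\eta_{\mathrm{CO_2}} = \frac{\Delta H_{\mathrm{CO}}\, n(\mathrm{CO_2\!-\!C})_{\mathrm{glucose}}}
   {\Delta H_{\mathrm{glucose}}}, \qquad \eta_{\mathrm{soil}} = 1 - \eta_{\mathrm{CO_2}},$$
   the calorespirometric ratio (mJ heat per µg CO~2~-C respired) and the
   metabolic quotient *q*CO~2~ (basal respiration per unit microbial
   biomass carbon).
2. **^13^C mass balance.** Total respired CO~2~-C from a glucose-amended
   jar is split by two-source mixing,
   $$R_{\mathrm{glucose}} = R_t\,
   \frac{x_{\mathrm{sample}} - x_{\mathrm{soil}}}{x_{\mathrm{glucose}} - x_{\mathrm{soil}}},
   \qquad R_{\mathrm{SOM}} = R_t - R_{\mathrm{glucose}},
   \qquad R_{\mathrm{primed}} = R_{\mathrm{SOM}} - R_{\mathrm{basal}},$$
   where the *x* are ^13^C atom fractions of the evolved CO~2~, the added
   glucose (19.5 atom%), and the water-only controls.
3. **SIP community analysis.** Rarefaction to equal depth, Bray--Curtis
   dissimilarity on relative abundances, principal coordinate analysis,
   PERMANOVA, a differential-abundance screen contrasting ^13^C-heavy and
   ^13^C-light fractions (and management systems within fractions), and
   Spearman correlation maps between enriched OTUs and soil attributes.

A synthetic-data generator produces complete experiments with known ground
truth so every stage is testable end to end without access to raw
instrument or sequence data.

## Tunable constants

| Constant | Default | Units | Meaning |
|---|---|---|---|
| `dH_glucose` | 18.05 | J g^-1^ soil | energy content of the glucose addition at 500 µg C g^-1^ |
| `dH_CO` | 467 200 | J mol^-1^ C | heat per mole of glucose-derived CO~2~-C (2 803 kJ mol^-1^ glucose combustion enthalpy ÷ 6 C) |
| `x_glucose` | 0.195 | atom fraction | ^13^C abundance of the labelled glucose in respiration jars |
| `kec` | 0.45 | -- | fumigation-extraction efficiency for microbial biomass C |
| VPDB ratio | 0.011 180 2 | -- | standard ^13^C/^12^C ratio for δ conversions |

`dH_CO` deserves a note. Published thermal-yield values of ≈ 0.43--0.45 for
this system are not reproducible from the printed respiration and
partition means with the physically standard 467.2 kJ mol^-1^ C: they are
consistent instead with subtracting only the control (not the primed)
CO~2~-C and an effective enthalpy near 462 kJ mol^-1^ C. Because the
effective constant is not stated anywhere, `thermal_yield()` treats the
enthalpy as configuration and exposes a `mode` label
(`"as_written"` for glucose-derived CO~2~-C only, `"net_of_control"` for
total minus basal) rather than forcing either convention. The package's
guarantees for the thermal yield are therefore structural -- the partition
sums to one exactly, vanishes at zero glucose-derived CO~2~-C, and is
linear in the supplied moles -- and the numeric index values in the
efficiency table are reported as computed, not calibrated to match any
published figure.

## Numerical choices

* **Integration.** Cumulative heat uses the trapezoid rule (composite
  Simpson available behind a flag for uniformly spaced records). At the
  1-min sampling step of the generator, trapezoid error on smooth pulses
  is far below the 0.1% recovery tolerance.
* **Equilibration.** `exclusion_h = 0` by default (all data used). An
  optional exclusion back-fills the initial segment with the first
  retained reading, a conservative way to remove the ampoule-insertion
  artifact without extrapolating a model.
* **Partition granularity.** The mixing model is applied per flush
  interval and summed, which is exact when atom fractions drift in time;
  a single cumulative-abundance partition is available as an option and
  agrees with the interval form when the soil endmember is constant.
* **Soil endmember.** `x_soil` defaults to the time-matched mean of the
  water-control jars within the same treatment; pooling over time is
  optional. Blank correction subtracts the per-time mean of the soil-free
  blank jars; negative corrected masses are clamped to zero with a
  warning. Missing sampling intervals fail loudly -- no imputation.
* **No clamping of indices.** Negative efficiency indices and negative
  priming are diagnostic and are reported as-is (with a warning for the
  former).
* **Aggregation.** Indices are computed per replicate and summarized, and
  contrasts are emitted under both conventions (ratio of means and mean
  of ratios) because published tables in this field demonstrably mix
  them; e.g. a printed metabolic quotient of 0.11 for one treatment comes
  from per-replicate averaging while direct division of the printed means
  gives 0.103. One published partition row (CON-PER) is internally
  inconsistent as printed (SOM-derived minus basal does not equal the
  printed primed value); the package computes identities from its inputs
  and does not attempt to reconcile that row.

## The synthetic generator

The generator is first-class, tested code. Its defaults *are* the study
conditions: treatment-level cumulative heats of 1.18--1.76 J g^-1^
(controls) and 6.86--7.47 J g^-1^ (glucose), 48-h basal respiration of
26.1--37.4 µg CO~2~-C g^-1^, 33.6--34.7% of glucose-C respired in 48 h,
priming coefficients of 1.02--1.33, and soil CO~2~ at 1.08 atom% ^13^C.

* **Heat curves.** Water units dissipate constant basal power; glucose
  units add a gamma-shaped pulse (shape 3, scale 5.5 h, mode near 11 h --
  within the "mode near 12 h" intent while keeping more than 99% of the
  untruncated pulse inside the 48-h window, which the input contract
  requires). The pulse is renormalized over the truncated window so the
  noise-free integral equals the target heat essentially exactly;
  parameters pushing > 1% of pulse mass past the end of the record are
  rejected.
* **Gas series.** Glucose-derived emission follows first-order depletion
  of the respirable pool (half-life 10 h, ≥ 95% emitted in 48 h), with
  interval masses renormalized over the window so that their sum equals
  the true respired fraction exactly before noise -- the mass-balance
  contract the recovery tests rely on. Priming is proportional to basal
  flux and constant in time, reflecting that only cumulative priming is
  observable in a 48-h experiment.
* **Noise.** Gaussian and additive: power (sd 0.1 µW g^-1^),
  interval CO~2~-C mass (sd 1 µg C g^-1^), atom fraction (sd 5 × 10^-4^).
  Between-replicate spread of the true quantities defaults to zero so
  that recovery error isolates measurement noise.
* **OTU tables.** Dirichlet-multinomial counts around a log-normal base
  composition; planted "glucose utilizer" OTUs carry a configurable
  log~2~ fold-change (default 2) in the ^13^C-heavy vs ^13^C-light
  fraction of the designated management system, and column sums equal
  the depth exactly. The overdispersion default θ = 0.001 (Dirichlet
  concentration 1000) was fixed by a design-power simulation before the
  validation suite was written: it is the mild overdispersion expected
  among homogenized laboratory incubations of sieved soil from the same
  plots, and it is the regime in which a 4-vs-4 contrast of taxa planted
  at log~2~FC = 4 and depth 10^4^ is detectable at FDR < 0.01 with
  ≥ 80% median recall while null datasets stay clean. At θ ≥ 0.002 rare
  planted taxa become zero-inflated and that design power is not
  attainable by any of the statistics we examined.
* **Determinism.** All randomness flows from the single design seed
  through named substreams per file type; identical seed and
  configuration give byte-identical bundles and reports (no timestamps
  are written).

What the generator does **not** emulate: sequencing read structure,
gradient-fractionation physics (GC-content density shifts, smearing of
unlabelled DNA into heavy fractions), instrument drift or autocorrelated
noise, diurnal temperature effects, and between-replicate field
heterogeneity (unless configured). Passing recovery tests therefore
demonstrate correctness of the estimators under the stated error model,
not robustness to every artifact of real instruments.

## The differential-abundance screen

The screen is a deliberately transparent stand-in for negative-binomial
Wald machinery, which is out of scope; its OTU lists are not numerically
comparable to those tools. Per OTU it reports the log~2~ fold-change of
mean relative abundance (pseudocount 1 added before conversion) and a
t statistic on log~2~ relative abundances.

The default p-value is an empirical-Bayes **moderated t**: per-OTU
variances are shrunk toward a scaled inverse-chi-square prior fitted by
method of moments on the log sample variances, and the statistic is
referred to a t distribution with correspondingly augmented degrees of
freedom. The reason is arithmetic, not taste: at the SIP design's group
size of four, a label-permutation p-value cannot fall below 1/70 ≈ 0.014,
and pooling permuted statistics across OTUs does not rescue it because
partial-signal permutations of truly enriched OTUs contaminate the pooled
null -- so no permutation variant can reach an FDR threshold of 0.01
regardless of effect size. A permutation mode
(`p_method = "permutation"`, per-OTU or pooled null, exhaustive when
feasible) is retained for users who prefer assumption-free inference at
more permissive thresholds. The validation suite checks the null
calibration of the default: across 50 simulated datasets with no planted
effect, the fraction showing any FDR < 0.01 discovery must stay within
binomial error of the nominal level.

## PERMANOVA and ordination

PERMANOVA uses the hat-matrix trace form on the Gower-centered matrix
with sequential (Type I) term decomposition, so the R² of terms plus
residual is exactly one. p-values use the `(count + 1)/(n_perm + 1)`
convention; exact enumeration of all sample permutations is available for
small problems and is the oracle the test suite checks against (a fully
separated 3 + 3 toy yields p = 1/10 exactly). The split-plot error
structure of the motivating design is approximated, when requested, by
restricting permutations to within-block shuffles (blocks preserve
exchangeability); exact nested-strata semantics are out of scope. PCoA is
classical metric scaling with negative eigenvalues reported but
uncorrected, and a fixed sign convention (largest-magnitude loading
positive) for reproducible axes.

## Problem sizes used in validation

The validation suite simulates full-design experiments (32 calorimetry
units and 34 jars at 1--2 min power resolution) for parameter recovery
over 20 seeds; screen power over 20 seeds (120 OTUs, depth 10^4^) and
null calibration over 50 datasets (100 OTUs, depth 5 × 10^3^); and
PERMANOVA null uniformity over 120 small datasets. These sizes give
stable medians and binomial error bars while keeping the suite quick to
run; all of them are configuration, not limits of the implementation.

## Known limitations

* The thermal-yield enthalpy ambiguity described above means η~CO~2~~
  values are convention-dependent; comparisons across studies should fix
  `dH_CO` and `mode` explicitly.
* The calorespirometric pairing assumes calorimeter ampoules and
  respiration jars of the same treatment × replicate are exchangeable
  subsamples; the two are physically distinct vessels.
* The screen's moderated t assumes approximate log-normality of relative
  abundances given the group; heavily zero-inflated OTUs at low depth
  violate this, and the permutation mode is the safer (if less powerful)
  choice there.
* Mixed-effects inference (random field-replicate terms, multiple-range
  letters) is intentionally out of scope; the report carries means,
  standard errors, and permutation tests only.
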