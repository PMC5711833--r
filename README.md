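# thermosip

Quantifying **soil microbial carbon use** from incubation experiments that
combine **isothermal calorimetry**, **¹³C-glucose tracing**, and **DNA
stable isotope probing (SIP)**.

When a pulse of ¹³C-labelled glucose is added to soil, three measurements
together reveal how the microbial community spends the carbon and energy:
the calorimeter records the heat not conserved during metabolism, the
¹³C signature of respired CO₂ separates glucose-derived from soil organic
matter (SOM)-derived carbon — including SOM decomposition *primed* by the
fresh substrate — and density-gradient SIP of 16S rRNA genes identifies
which taxa assimilated the glucose. `thermosip` is aimed at soil ecologists
and biogeochemists running such assays (typically contrasting management
systems or treatments) who need the full chain from raw power curves and
headspace tables to summary indices, source partitions, and community
statistics.

## The quantities at the core

With cumulative heats *Q* (J g⁻¹ soil) and respired CO₂-C masses *R*
(µg C g⁻¹ soil) over the incubation window:

- **Thermodynamic efficiency index**
  η_eff = 1 − (Q_glucose − Q_control) / ΔH_glucose,
  with ΔH_glucose = 18.05 J g⁻¹ soil for glucose added at 500 µg C g⁻¹.
- **Thermal yield** η_CO₂ = ΔH_CO · n(CO₂-C)_glucose / ΔH_glucose and
  η_soil = 1 − η_CO₂ (energy dissipated via oxidized CO₂ vs retained in
  soil).
- **¹³C mass balance** R_glucose = R_t · (x_sample − x_soil) /
  (x_glucose − x_soil); R_SOM = R_t − R_glucose;
  R_primed = R_SOM − R_basal.
- **Calorespirometric ratio** (mJ µg⁻¹ CO₂-C) and **metabolic quotient**
  qCO₂ = R_basal / MBC, with MBC from chloroform fumigation-extraction
  (k_ec = 0.45).
- **Community stage:** rarefaction to equal depth, Bray–Curtis
  dissimilarity, PCoA, PERMANOVA, a moderated-t differential-abundance
  screen of ¹³C-heavy vs ¹³C-light fractions, and Spearman correlation
  maps of enriched OTUs against soil attributes.

A synthetic-data generator (`simulate_experiment()`) emulates the full
split-plot study design with known ground truth, so the entire pipeline is
testable without instrument or sequence data. See the methods vignette
(`vignettes/thermosip-methods.Rmd`) for models, defaults, and design
choices.

## Worked example

```r
library(thermosip)

design <- experiment_design(seed = 42)           # 2 systems x 2 histories x 4 reps
truth  <- synthetic_truth(design)                # study-condition defaults
simulate_experiment(design, truth, "bundle", dt_min = 2, depth = 10000)

res <- run_pipeline("bundle", n_perm = 999, seed = 42)
subset(res$efficiency_summary, level == "treatment" & variable == "eta_eff")
#>        level management crop variable n  mean       se
#> 7  treatment        CON  ANN  eta_eff 4 0.684 1.21e-05
#> 10 treatment        ORG  ANN  eta_eff 4 0.677 9.96e-06
#> 13 treatment        CON  PER  eta_eff 4 0.675 1.98e-05
#> 16 treatment        ORG  PER  eta_eff 4 0.688 1.96e-05

res$permanova
#> PERMANOVA (999 permutations)
#>        term Df SumOfSqs      R2       F     p
#>  management  1   0.2449 0.57765 19.1035 0.001
#>        crop  1   0.0124 0.02926  0.9676 0.384
#>    Residual 13   0.1666 0.39309      NA    NA
#>       Total 15   0.4239 1.00000      NA    NA
```

The efficiency means say that roughly 68% of the added glucose energy was
*not* dissipated as net heat in any treatment — the communities metabolized
glucose at similar energetic cost. The PERMANOVA (on Bray–Curtis
dissimilarities of the rarefied ¹³C-heavy fraction) attributes 58% of
β-diversity variation to management system (p = 0.001): the planted
glucose-utilizing populations differ between systems, while cropping
history has no detectable effect. In the same run the pooled partition
recovers ~171/167 µg g⁻¹ glucose-derived CO₂-C and priming of ~38/37
µg g⁻¹ (CON/ORG), with 55–60% of SOM-derived CO₂-C primed, and the screen
flags 16 OTUs as organic-system glucose utilizers (20 were planted, at the
default log₂ fold-change of 2).

Desk calculations work directly on published summary statistics shipped
with the package:

```r
thermodynamic_efficiency(7.47, 1.76)   # printed CON-ANN heats -> 0.684
som_and_primed(248.1, 172.5, 37.4)     # rsom 75.6, rprimed 38.2
```

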