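# sbedtcp

Radiobiological outcome modelling for lung SBRT (stereotactic body
radiotherapy): size-adjusted-BED tumor control probability, Lyman-type
normal tissue complication probability from dose-volume histograms, and
Kaplan–Meier validation of predicted against observed 2-year local control —
with a seeded synthetic-cohort generator so the whole analysis runs without
clinical data.

## Who this is for

Medical physicists and outcomes researchers who want a tested, scriptable
version of the standard lung-SBRT TCP/NTCP modelling chain: extract PTV dose
metrics from DVHs, turn them into control probabilities, check those
predictions against actuarial control, and ask which PTV dose
parameterization predicts best.

## The models

**TCP.** For total dose *D* in *n* fractions, the linear-quadratic
biologically effective dose is BED₁₀ = D(1 + (D/n)/10). Tumor size enters
as a linear penalty, sBED = BED₁₀ − c·L (c = 10 Gy/cm, L = diameter in cm),
and 2-year local control is logistic in sBED:

    TCP = exp((sBED − TCD50)/k) / (1 + exp((sBED − TCD50)/k)),
    TCD50 = 0 Gy, k = 31 Gy.

The model can be parameterized by any of seven PTV dose metrics:
prescription, minimum, mean, maximum dose, D95, D98, D99.

**NTCP.** Per DVH bin, the 2-Gy-fraction equivalent dose is
EQDᵢ = Dᵢ(α/β + Dᵢ/n)/(α/β + 2) with α/β = 3 Gy; the distribution is
reduced to a generalized equivalent uniform dose
EUD = (Σ vᵢ·EQDᵢᵃ)^(1/a) (a = 1 for parallel organs) and mapped to

    NTCP = 1 / (1 + (TD50/EUD)^(4·γ50)),  TD50 = 45 Gy, γ50 = 1.2.

**Validation.** Observed control is the Kaplan–Meier product-limit estimate
read at 24 months; tumors are binned into sBED quartiles and each
parameterization is scored by the Pearson correlation between per-bin
observed control and mean predicted TCP.

## Worked example

The `analysis/` scripts run the full workflow on a simulated 109-tumor
cohort (40–60 Gy in 3–5 fractions, lognormal volumes with median 22.4 cc,
outcomes drawn from the D99-based TCP model):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_dose_metrics_tcp.R
Rscript analysis/03_control_validation.R
Rscript analysis/04_toxicity_ntcp.R
```

Step 2 prints the predicted 2-year control under each parameterization —
minimum-dose lowest, maximum-dose highest, with the D95/D98/D99 family in
between:

    predicted 2-year control by parameterization (mean +/- SD, %):
      RX     91.0 +/-  5.5
      DMIN   88.5 +/-  6.5
      DMEAN  93.7 +/-  4.5
      DMAX   95.9 +/-  3.6
      D95    91.0 +/-  5.5
      D98    90.5 +/-  5.7
      D99    89.9 +/-  5.9

Step 3 compares those predictions with the cohort's own actuarial control
(here 83.7% at 2 years) per sBED quartile; all seven metrics correlate
strongly, and at n = 109 the top rank among them is noise-limited — the same
bunching seen in clinical series:

    parameterization ranking (Pearson r, observed vs predicted):
      metric mean_tcp sd_tcp pearson_r p_value n_bins
    1   DMAX    0.959 0.0357     0.967  0.0328      4
    2     RX    0.910 0.0554     0.960  0.0398      4
    3    D99    0.899 0.0587     0.910  0.0897      4
    ...

Step 4 evaluates the NTCP chain on synthetic organ-at-risk DVHs and tests
observed toxicity counts against the predicted incidence:

    grade >=2 pneumonitis: predicted 3.1%, observed 3/109 (2.8%), p = 1.000
    rib fracture: predicted 15.1%, observed 4/21 (19.0%), p = 0.545

Or directly from R:

```r
library(sbedtcp)
spec <- cohort_spec(n_tumors = 109, seed = 42)
cohort <- generate_cohort(spec)
cohort <- add_followup(cohort, simulate_outcomes(cohort, spec))
rank_parameterizations(cohort)          # 7 metrics, ranked by Pearson r
tcp(sbed(bed(50, fractionation_scheme(50, 5)), diameter_from_volume(22.4)))
#> 0.8906698  — 2-year TCP for 50 Gy/5 fx to a median-size (22.4 cc) tumor
```

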