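# cspascore

Toxicological prioritization of chemicals reported under Washington
State's Children's Safe Product Act (CSPA).

CSPA requires manufacturers to report, for 66 chemicals of high concern,
every children's product that contains them: the product segment and brick
(e.g. Clothing, or Baby Care / pacifier), whether the product targets
children under three, and the concentration as one of six ranges (<100 up
to >10,000 ppm). The database is large but unranked. `cspascore` is a
scoring engine for this kind of report stream, aimed at risk assessors and
regulators who need a transparent, high-throughput way to sort it.

Each report receives:

* an **exposure score**
  `(LS + EX + A + Con) + O_MF·(S + Abs_oral)/2 + I_MF·(VP + Abs_inh)/2 + D_MF·(Kp + Abs_derm)/2` —
  lifestage, exposure duration, skin application and concentration, plus
  oral/inhalation/dermal components in which a primary/secondary/tertiary
  route factor (3/2/1) weights the average of a chemical-property score
  (water solubility, vapor pressure, Potts–Guy dermal permeability) and an
  observed absorption score;
* a **toxicity score**
  `Σ_e certainty_e × potency_e` over the four endpoints e ∈ {ED, RD,
  Carc, NT} (endocrine disruption, reproductive/developmental toxicity,
  carcinogenicity, neurotoxicity), with certainty the maximum
  classification across curated databases and potency from
  NOAEL/LOAEL/RfD/TD50 tertiles;
* a **total priority index** `TPI = exposure × toxicity` (a rank, not a
  risk estimate) and endpoint-specific scores such as the endocrine
  disruptor score `exposure × ED_certainty × ED_potency`.

The package bundles the score table for the 21 most frequently reported
CSPA chemicals/groups, aggregation and ranking by chemical / chemical
group / product segment, quadrant classification around the median scores,
a PCA of score drivers, rank-concordance comparison against external
prioritization schemes, and a seeded generator of CSPA-like synthetic
report databases. See the vignette in `vignettes/cspa-prioritization.Rmd`
for the full model description and the design conventions.

## Worked example

```r
library(cspascore)
profiles <- bundled_profiles()

# One report: formaldehyde in an under-3 shirt at 100-500 ppm
report <- validate_report(list(
  chemical_id = "formaldehyde", segment = "Clothing",
  target_age = "under_three", concentration_bin = "100-500"))$report
exposure_score(report, chemical_profile(profiles, "formaldehyde"))
#> <exposure_breakdown> total 22.0 = (LS 3 + EX 3 + A 1 + Con 1) + oral 5.00 + dermal 6.00 + inhalation 3.00

toxicity_score(chemical_profile(profiles, "dibutyl phthalate"))
#> <toxicity_breakdown> total 24 = ED 9 + RD 9 + CARC 0 + NT 6
```

The exposure breakdown reads directly: the shirt targets an under-3 child
(LS 3), clothing is long-term wear (EX 3) but not applied like a cosmetic
(A 1), 100–500 ppm is the second-lowest concentration bin (Con 1). Dermal
is the primary route for clothing (factor 3), oral is secondary because
the child is under three, inhalation floors at tertiary. Dibutyl
phthalate's toxicity of 24 is the highest in the bundled set: a known,
potent endocrine disruptor and reproductive toxicant plus a known
neurotoxicant.

Scoring a synthetic CSPA-like database end to end:

```r
fx <- scenario_fixture("cspa_like", n_reports = 500, seed = 1)
res <- score_dataset(fx$reports, fx$profiles)
head(aggregate_scores(res$scored, "chemical"), 5)
#> # A tibble: 5 × 6
#>   key                    n_reports mean_exposure sd_exposure mean_index sd_index
#> 1 Dibutyl phthalate             12          18.1        1.98       434      47.5
#> 2 Di-2-ethylhexyl phtha…        11          16.8        2.42       353.     50.9
#> 3 Butyl benzyl phthalate        10          19.0        2.18       341.     39.3
#> 4 Formaldehyde                   8          21          2.46       336      39.4
#> 5 Styrene                       35          17.7        1.90       302.     32.3
```

Chemicals rank by mean total priority index; the phthalates, formaldehyde
and styrene lead, driven by multi-endpoint toxicity. Chemicals with no
toxicity classification in any consulted source (methyl and propyl
paraben, phthalic anhydride, molybdenum) have TPI 0 in every report and
are flagged `no_toxicity_data` by `quadrant_classify()` — absence of
evidence, not evidence of safety.

A command-line wrapper is installed as `exec/cspascore` with subcommands
`simulate`, `score`, `aggregate`, `quadrants`, `pca` and `compare`; every
run writes its outputs plus a `manifest.json` audit record.

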