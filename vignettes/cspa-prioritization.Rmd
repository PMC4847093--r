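---
title: "Scoring and prioritizing CSPA product reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and prioritizing CSPA product reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspascore)
```

## The problem and the model

Washington State's Children's Safe Product Act (CSPA) requires manufacturers
of children's products to report, for 66 chemicals of high concern, the
product category (a broad *segment* and a narrow *brick*), whether the
product targets children under age three, and the chemical's concentration
as one of six ranges (<100 up to >10,000 ppm). The database holds tens of
thousands of such reports but no ready way to rank them toxicologically.
`cspascore` implements a multi-attribute utility framework that turns each
report into three numbers:

**Exposure score.** An additive product block plus three route-weighted
toxicokinetic terms:

$$\mathrm{Exposure} = (LS + EX + A + Con) +
  O_{MF}\frac{S + Abs_{oral}}{2} +
  I_{MF}\frac{VP + Abs_{inh}}{2} +
  D_{MF}\frac{K_p + Abs_{derm}}{2}$$

where $LS$ is the lifestage score (under-3 products score 3, ages 3–12
score 1), $EX$ the exposure duration (long-term segments — clothing,
footwear, beauty/personal care/hygiene, camping — score 3, others 1), $A$
whether the product is applied directly to skin (beauty/personal care
scores 3, others 1) and $Con$ the concentration bin on half-point steps
from 0.5 (<100 ppm) to 3 (>10,000 ppm). Each route's modifying factor
$MF \in \{3,2,1\}$ marks it primary/secondary/tertiary, and multiplies the
average of a chemical-property score and an observed absorption score:
water solubility ($S$, mol/L) for oral, vapor pressure ($VP$, mmHg at
25 °C) for inhalation and the dermal permeability coefficient ($K_p$,
cm/h, from the Potts–Guy relation
$\log_{10} K_p = -2.72 + 0.71\,\log K_{ow} - 0.0061\,MW$) for dermal.
Where an absorption observation is missing, the property score stands
alone — the average would otherwise bias data-poor chemicals.

**Toxicity score.** Four endpoints — endocrine disruption (ED),
reproductive/developmental toxicity (RD), carcinogenicity (Carc) and
neurotoxicity (NT) — each contribute certainty × potency:

$$\mathrm{Toxicity} = \sum_{e \in \{ED, RD, Carc, NT\}}
  \mathrm{certainty}_e \times \mathrm{potency}_e$$

Certainty (0–3: none / potential / suspected / known) is harmonized as the
*maximum* classification across curated sources (GHS, Proposition 65, IARC,
IRIS, ECHA lists); the package never queries those databases — their
verdicts arrive pre-digested in the chemical profile. Potency for known
toxicants comes from dose descriptors: NOAEL-equivalent tertiles for RD
(edges 200/397 mg/kg) and ED (336/667 mg/kg), TD50 tertiles for
carcinogens (233/465 mg/kg/day, lower of mouse and rat), and a constant 2
for neurotoxicants, for which no consistent dose source exists. LOAELs
divide by an uncertainty factor of 10; RfDs multiply back by their reported
uncertainty-factor product. Potential/suspected toxicants get potency 1 so
their certainty still counts; certainty 0 contributes nothing regardless
of dose data.

**Total priority index.** $TPI = \mathrm{Exposure} \times
\mathrm{Toxicity}$, and per-endpoint variants such as the endocrine
disruptor score $= \mathrm{Exposure} \times ED_{cert} \times ED_{pot}$.
The TPI is a *rank*, not a risk estimate: an index of 100 is not ten times
more concerning than 10, merely ranked above it.

## Route assignment

Exposure routes follow a deterministic cascade on product metadata, first
match wins:

1. **Bricks:** paints → primary inhalation, secondary dermal, tertiary
   oral; party blowers → dual primary oral + inhalation; fragrances → dual
   primary dermal + inhalation; pacifier / kitchen-toy / feeding-support /
   food-preparation bricks → primary oral.
2. **Segments:** kitchen merchandise → primary oral; clothing, beauty,
   footwear, arts/crafts, household, camping, personal accessories and
   toys/games → primary dermal.
3. Primary-oral products gain secondary dermal (children hold what they
   mouth); under-3 products whose primary is not oral gain secondary oral.
4. If neither oral nor inhalation ended up primary or secondary, both
   become tertiary (products disintegrate into house dust that children
   ingest and inhale); every remaining route floors at tertiary.

Two segments are not named in any published route list (baby care without
a special brick, stationery/office/occasion supplies), and personal
accessories appears only in the segment table; the package defaults all of
these to primary dermal, consistent with the named majority, and treats
them as short-term. Unknown segment strings are never scored silently:
they are flagged at validation, routed as default-dermal and short-term,
and each fallback fires a warning that the I/O layer logs.

With these conventions the exposure score is bounded in $[6.5, 36]$:
minimum $1+1+1+0.5$ plus three tertiary components of 1, maximum $12$ plus
two primary and one secondary component at toxicokinetic average 3.

## Numerical conventions

Choices the published rules left open, fixed once here:

* **Bin boundaries.** Concentration ranges are lower-inclusive,
  upper-exclusive (open top bin). Solubility and vapor-pressure bins
  likewise read their printed ranges with the middle band inclusive of its
  edges; the $K_p$ tertile boundary is half-open upward with the printed
  gap (3.39–3.4 × 10⁻³) closed at 3.395 × 10⁻³ cm/h.
* **Solubility upper cutoff** is 0.01 mol/L: the prose threshold; the
  variant 0.1 would leave [0.01, 0.1] unmapped.
* **Absorption bins** default to ≤5% → 1, 5–10% (or absorbed at an unknown
  rate) → 2, >10% → 3; observations below 1% floor at 1. The alternative
  reading, anything above 5% → 3, is selectable via
  `default_rules(overrides = list(absorption_high_above_5 = TRUE))`.
* **ED potency cutoffs** as printed are self-contradictory; the package
  uses the unique monotone repair (>667 → 1, 336–667 → 2, <336 → 3), and
  the RD middle band is 200–397 mg/kg (the printed upper edge 297 is
  treated as a typo for 397). Both are configurable.
* **NT potency** defaults to 2: it reproduces the derived toxicity totals
  of the neurotoxicants in the bundled set (styrene 17, methyl ethyl
  ketone 9), where the alternative constant 3 would not. It is a single
  rules key (`nt_potency`) for users who prefer the heavier weighting.
* **Applied-to-skin "No"** scores 1, not 0 — consistent with every other
  additive variable's floor.
* **Mixed potency inputs:** a NOAEL wins over a coexisting LOAEL; the
  LOAEL is converted only in its absence. A known toxicant with no dose
  input at all gets potency 1 with a warning.
* **Potency tertiles** default to the fixed cutoffs above. For novel
  chemical sets, `tertile_cutoffs()` recomputes edges from the supplied
  NOAEL-equivalents, to be passed back through the rules.
* **Aggregation** uses the population SD (divisor $n$), stable descending
  sort on mean index, alphabetical tie-break. Quadrant classification
  assigns values exactly at a median to the "high" side.
* **Missing dermal permeability** (one bundled chemical, antimony, has no
  $K_p$) falls back to the observed dermal absorption alone, symmetric to
  the missing-absorption rule.

## The bundled chemical set

`bundled_profiles()` ships scores for the 21 most frequently reported
CSPA chemicals/groups — 9 phthalates (including phthalic anhydride), 4
parabens, ethylene glycol, 3 total-metal groups (cobalt, antimony,
molybdenum, which CSPA reports as elemental totals and cannot be
disaggregated) and 4 singletons. Four chemicals (methyl paraben, propyl
paraben, phthalic anhydride, molybdenum) have no toxicity classification
in any consulted source: their toxicity score is 0 and every report of
them has TPI 0, which the quadrant output flags as `no_toxicity_data` —
absence of evidence, not evidence of safety. Ethylene glycol monoethyl
ester is reported under CSPA but has no separate score row; it shares
ethylene glycol's toxicity profile and is grouped with it.

One documented inconsistency is preserved rather than repaired: the
published narrative assigns formaldehyde a toxicity of 21, but its own
published endpoint scores sum to 16 ($1{\times}1 + 3{\times}3 +
3{\times}2$); the package computes 16 and treats the 21 as the source's
internal conflict.

## The synthetic report generator

The real ~33,000-record database is not redistributable, so
`generate_reports()` draws CSPA-*like* databases from configurable
categorical marginals. Defaults are the study conditions: segment weights
proportional to the published per-segment report counts (clothing ≈ 44%),
chemical weights proportional to the published per-chemical counts, an
under-three fraction of 0.3 (the true fraction is unpublished; 0.3
reflects that most children's products target the wider 3–12 band), and
concentration weights mildly decreasing with the bin, reflecting that low
ranges dominate reporting. Draws are independent: the generator does not
model the real database's correlation structure (one product reported for
several chemicals, segment-specific concentration profiles), so passing
distributional tests says the *marginals* behave, nothing more. Records
are generated with R's Mersenne–Twister under `withr::with_seed`, so a
seed fully determines the dataset without touching the global random
state; cross-language bit-identity is not promised, statistical behaviour
is.

```{r example}
fx <- scenario_fixture("cspa_like", n_reports = 500, seed = 1)
res <- score_dataset(fx$reports, fx$profiles)
head(aggregate_scores(res$scored, "chemical"), 3)
```

## What the checks do and do not show

The test suite verifies the scoring engine against an independent
brute-force evaluation of the exposure equation over the full grid of 11
segments × 2 ages × 6 bins × 21 chemicals (2,772 combinations, exact
equality), transcription of every bundled score cell, the published
toxicity totals (dibutyl phthalate 24, DEHP 21) and the identity between
published mean-index/mean-exposure ratios and the computed toxicity
scores (17 chemicals within ±0.1). Generator calibration uses 10,000
draws (χ² goodness-of-fit at α = 0.01, binomial 99% interval for the
under-3 fraction); pipeline tests use a few hundred draws, enough to
cover all segments and most chemicals.

Published *report-level* statistics — the extreme exposure scores, the
database-wide averages, and the PCA variance percentages (33.6%/23.1%) —
depend on the unpublished report database and on scoring conventions that
the published account leaves internally inconsistent; no single
consistent reading of the route rules reproduces them. The package
therefore does not treat them as targets. The PCA here is a correlation
PCA (centered, unit-scaled; zero-variance columns dropped with a warning)
over a declared variable set — the four endpoint products, the four mean
additive exposure variables and the three mean route components — so any
deviation from the published percentages is attributable to inputs, not
hidden settings.

## Limitations

* The TPI ranks; it does not estimate risk, and it is not weighted by
  reporting frequency or production volume.
* Bioaccumulation is not modelled; no persistent organic pollutants are in
  the bundled set.
* Metal groups are scored as elemental totals; compound-specific
  toxicokinetics are lost.
* External-scheme comparison (`compare_external()`) is rank-only
  (Spearman, tertile discordance): an external mg/kg/day exposure
  prediction and this unitless score share no scale worth regressing on.
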