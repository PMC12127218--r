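---
title: "Converting processed-food consumption to raw-commodity intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting processed-food consumption to raw-commodity intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prcf)
```

## The problem

Dietary exposure to a chemical — a pesticide residue, a contaminant, a
nutrient — is usually assessed by combining *consumption* data with
*occurrence* data. The mismatch is that occurrence data (maximum residue
limits, composition tables) are referenced to raw primary commodities (RPCs),
while people eat flour, cheese, jerky, soy sauce, and tea. A processed-to-raw
food conversion factor (PRCF) is the multiplier that turns the consumed mass
of a processed food into the edible-portion mass of its raw ingredient, so
that

$$\text{exposure} \;=\; \sum_{\text{foods}} \text{amount} \times \text{PRCF}
\times \text{concentration in RPC}.$$

This package implements the three derivations of such factors, ships the
reference table of 120 published factors with integrity validators, and wires
them into a diary-to-exposure pipeline.

## The three derivations

**Reverse percentage yield.** For a food processed *whole* (boiling,
pickling, dehydration, ...) the factor is simply

$$F \;=\; \frac{W_{\text{initial}}}{W_{\text{final}}},$$

the edible-portion weight of the raw ingredient over the weight of the
finished food (`reverse_percentage_yield()`). Inedible parts removed before
processing are never counted, and when a recipe adds water before a
separation step (soy products), the water is part of the initial weight —
both are conventions of the input data, not corrections the engine applies.

**Partition correction.** Many processes split the commodity into
co-products: egg into white (67 %) and yolk (33 %), milk into cream and skim,
grain into bran, germ, and endosperm. Plain reverse yields then double-count:
0.67 g of white converts to ~1 g of egg (yield 1.49) and 0.33 g of yolk
*also* converts to ~1 g (yield 3.03), so one fully consumed egg appears as
two. The corrected factor multiplies the mean reverse yield by the partition
ratio $p$, the mass fraction of the commodity that actually feeds the
product:

$$F \;=\; p \times \overline{Y}.$$

```{r}
naive <- 0.67 * 1.49 + 0.33 * 3.03
corrected <- sum(c(0.67, 0.33) *
                   partitioned_factor(c(0.67, 0.33), c(1.49, 3.03)))
c(naive = naive, corrected = corrected)
```

For a *pure physical separation* (no water gained or lost), each
compartment's reverse yield is exactly $1/p$, so the corrected factor is 1;
the test suite asserts this for random separations with up to six
compartments, and the generalisation of the double-counting example — naive
conversion of a fully consumed $k$-way separation overestimates by exactly
$k$-fold — is a property test. Where downstream steps do change composition
(powdering, churning, pressing curd), the factor moves away from 1
accordingly.

**Migration rates.** Where weight cannot be traced at all — fermentations,
infusions, stocks — a traceable component stands in for the food:
$\alpha$-acids for hop in beer, total solids for broths, total polyphenols
for teas and spice stocks, carbohydrate for alcoholic beverages and
vinegars. The factor is the component's content per 100 g of product over
its content per 100 g of edible raw ingredient (`migration_rate()`). For the
fermented products the denominator is additionally multiplied by the
theoretical fermentation yield — the stoichiometric fraction of carbohydrate
convertible to product, 0.51 for ethanol and 0.67 for acetic acid
(`migration_rate_fermented()`), assuming complete hydrolysis and conversion
of the raw material's carbohydrate.

Per-study values within one (procedure, food type) combination are averaged
(`aggregate_factors()`); the published convention reports mean ± sample SD
and stores no SD when a single study contributed.

## The bundled reference table

`load_reference()` returns the 120 published factors (32 pure yield, 50
partition-corrected, 38 migration) transcribed with their partition ratios,
mean reverse yields, SDs, sample counts, and component/plant-part metadata.
Co-product rows with no finished consumable food (husk, juicing pulps, oil
cakes) are shipped too, flagged `consumable = FALSE`; they carry the
partition ratios that the mass-balance validator needs, and they are not part
of the 120-factor count. A JSON mirror with identical content is bundled for
programmatic use; `write_reference()`/`load_reference()` round-trip both
formats exactly.

`validate_reference()` checks three things and reports violations instead of
raising:

* the 32/50/38 category counts;
* per-commodity mass balance — distinct compartment ratios within each
  (procedure, raw commodity) group must sum to $1 \pm 0.02$, the slack that
  two-decimal printed rounding can introduce;
* partition consistency — each factor must equal
  partition ratio × mean reverse yield within one unit of the factor's last
  printed digit, *widened by the yield's own printed rounding*
  ($+\,p \cdot \tfrac{1}{2}\,\mathrm{ulp}(\overline{Y})$). The widening is
  needed because the published factors were computed from unrounded means:
  with printed values alone, butter is $0.10 \times 22 = 2.2$ against a
  printed 2.1, and skim milk powder $0.90 \times 11 = 9.9$ against 9.7.

```{r}
validate_reference()
```

**A known anomaly.** The printed milling partition ratios for whole grains —
bran 0.18, germ 0.04, endosperm 0.88 — sum to 1.10, and the validator
faithfully reports the group as a mass-balance failure (hence the FAIL
status above and the non-zero exit of `prcf validate-ref` on the bundled
table). The source's own prose quotes bran at 8–15 %, so the printed table is
internally inconsistent; we transcribe what is printed rather than guess a
correction, and leave the flag standing. Every other commodity group
balances within tolerance.

Two smaller conventions: the worked-example prose attaches 1.49 to yolk and
3.03 to white, but the partition ratios (white 0.67, yolk 0.33) and the
printed table imply the reverse assignment, which is what this package uses.
Egg-product reverse yields and milk powder's 5.52 are stored verbatim at
their printed precision.

## Exposure pipeline

`convert_diary()` resolves each diary record (subject, processed food,
procedure, g/day) against the reference by case- and whitespace-insensitive
name matching and multiplies; `estimate_exposure()` joins the result with a
raw-commodity concentration table (µg/g) and sums per subject, chemical, and
commodity. Units are fixed — g/day in, µg/day out — with no unit inference.
Unresolvable foods are skipped and reported by default; `strict = TRUE` (or
`--strict` on the command line) aborts instead. Uncertainty propagation is
first-order only: a factor SD scales with the amount, partition ratios are
treated as fixed constants (factor SD = ratio × SD of reverse yields), and no
covariance across foods is carried. Nested processing (a processed food used
as an ingredient of another) is out of scope: conversion is single-level.

**Chemical-specific correction.** The mass partition ratio answers "how much
of the commodity went this way"; for a specific chemical the right question
is "how much of the *chemical* went this way". `chemical_adjusted_factor()`
substitutes a migration ratio for the mass share in the partition-corrected
factor: cholesterol sits entirely in yolk, so with migration 1 for yolk and
reverse yield 3.0, 1 g of yolk counts as 3 g of egg for cholesterol — and 0 g
of egg white ever matters. With no profile supplied the mass ratio is used
and the ordinary factor is recovered.

## Folin–Ciocalteu quantitation

The polyphenol migration rates were derived from direct measurements; the
package implements the arithmetic of that assay so users can derive rates
from their own plate readings. `fit_standard_curve()` fits absorbance at
765 nm against a gallic acid ladder by ordinary least squares with a free
intercept (reagent blanks give a nonzero baseline; at least three distinct
concentrations are required). `gae_content()` back-calculates

$$\text{content (mg GAE/g)} = \frac{\bar{A} - b}{m} \times \text{dilution}
\times \frac{\text{extract volume}}{\text{sample mass}},$$

with the raw-material convention of 0.2 g extracted into a final 15 mL;
triplicates are averaged before back-calculation and their spread carried as
a content SD. Readings outside the fitted ladder trigger an extrapolation
warning rather than an error. Infusions and stocks are treated per gram at
density 1, so per-mL and per-g contents coincide, and
`polyphenol_migration_rate()` is content ratio of infusion to dry raw
material. The measured rates in the bundled table are *not* recomputable —
the underlying absorbances are unpublished — so they are covered by
transcription-integrity tests, not by re-derivation.

## Synthetic data

All test inputs are generated in code with known ground truth:

* `gen_yield_study()` draws per-study factors lognormally (positivity) with
  the log-scale spread set from the target coefficient of variation and the
  mean offset chosen so the expected factor equals the truth exactly;
  aggregation then recovers the truth within about $3\,cv/\sqrt{n}$ relative
  error. The recovery suite uses $cv = 0.1$, $n = 30$, across 20 seeds.
* `gen_partition_separation()` draws flat-Dirichlet partitions (2–6
  compartments) and exact pure-separation observations, the fixture behind
  the factor-of-1 and $k$-fold double-counting properties.
* `gen_diary()` draws gamma daily amounts (right-skewed, non-negative;
  shape 2, mean 50 g/day by default) per subject-food pair, and
  `gen_assay_plate()` synthesises standard ladders and triplicate readings
  through a known line with optional Gaussian read noise.

Every generator is a pure function of its parameters and seed (the caller's
RNG stream is left untouched). What the generators deliberately do *not*
emulate: correlated food choices within subjects, measurement error in
diaries, inter-laboratory assay bias, or realistic national consumption
surveys — passing tests demonstrate the arithmetic and its invariants, not
survey realism.

## Numerical conventions and problem sizes

Internal arithmetic is full double precision; rounding to printed precision
(2 significant figures unless a table prints otherwise) happens only at
comparison or output time. Degenerate inputs fail loudly with typed
conditions: non-positive weights, partition ratios outside (0, 1], empty
aggregations, zero raw content in a migration denominator, curves with fewer
than three distinct standards or non-positive slope. Zero consumed amounts
and zero migration numerators are legitimate and propagate as zeros.

The test and validation runs use deliberately small problem sizes — diaries
of tens of subjects, yield studies of 30–100 observations, 20-seed recovery
sweeps — chosen because the statistics being checked (means, SDs, OLS
slopes) stabilise well below those sizes; everything completes in seconds.

## Command line

The installed `exec/prcf` script exposes `derive`, `convert`, `expose`,
`validate-ref`, `assay gae`, and `simulate` over the CSV dialects documented
in the function help, with a YAML config file (`--config`) whose values are
overridden by flags. Logs go to standard error, data only to declared output
files. `prcf validate-ref` exits non-zero when validation fails — which, as
noted above, includes the bundled table's one printed anomaly.
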