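# prcf — processed-to-raw food conversion factors

Dietary exposure to food chemicals (pesticide residues, contaminants,
nutrients) is assessed against *raw primary commodities* — that is where
residue limits and composition data live — but consumption surveys record
flour, cheese, jerky, soy sauce, and tea. `prcf` converts processed-food
consumption into raw-commodity intake so the two can be combined:

```
exposure (µg/day) = Σ_foods  amount (g/day) × PRCF × concentration in RPC (µg/g)
```

A **processed-to-raw food conversion factor (PRCF)** is derived one of three
ways, depending on how the food was made:

* **Reverse percentage yield** `F = W_initial / W_final` for foods processed
  whole (boiling, pickling, dehydration, ...), with edible-portion weights
  throughout.
* **Partition-corrected** `F = p × Ȳ` when processing splits the commodity
  into co-products (egg → white/yolk, milk → cream/skim, grain →
  bran/germ/endosperm). The partition ratio `p` — the mass fraction feeding
  the product — prevents double counting: with plain reverse yields a fully
  consumed egg (0.67 g white × 1.49 + 0.33 g yolk × 3.03) converts to ~2 g
  of egg; partition-corrected it converts to the true 1 g. For a pure
  physical separation each reverse yield is `1/p` and the factor is exactly 1.
* **Migration rate** `F = content per 100 g product / content per 100 g raw
  ingredient` of a traceable component where weight cannot be followed:
  α-acids (hop in beer), total solids (broths/stocks), total polyphenols
  (teas, spice stocks), and carbohydrate for alcoholic beverages and
  vinegars — the latter with theoretical fermentation yields 0.51 (ethanol)
  and 0.67 (acetic acid) in the denominator.

The package bundles a machine-readable reference table of the 120 published
factors (32 pure-yield, 50 partitioned, 38 migration, plus the partition-only
co-product rows), with loaders, integrity validators, a diary-to-exposure
pipeline with chemical-specific migration-ratio substitution, the
Folin–Ciocalteu gallic-acid-equivalent arithmetic behind the polyphenol
migration rates, seeded synthetic-data generators, and a command-line
interface.

## Worked example

Look up a published factor, convert the classic egg diary, and estimate an
exposure:

```r
library(prcf)

lookup_factor("Cheese production", "Gouda cheese")
#> PRCF [Gouda cheese]: 1 (partitioned_yield, n = 4)
#>   partition ratio 0.10 × mean reverse yield 10

egg <- data.frame(subject_id = "s1",
                  processed_food = c("Egg white", "Egg yolk"),
                  procedure = "Powdered egg product production",
                  amount_g = c(0.67, 0.33))
convert_diary(egg)
#>   subject_id processed_food                       procedure amount_g
#> 1         s1      Egg white Powdered egg product production     0.67
#> 2         s1       Egg yolk Powdered egg product production     0.33
#>   raw_commodity factor raw_equivalent_g raw_equivalent_sd_g
#> 1          Eggs      1             0.67                  NA
#> 2          Eggs      1             0.33                  NA
```

Both egg fractions carry factor 1 (pure physical separation), so the
converted raw-equivalent masses sum to exactly the 1 g of egg that was
consumed — no double counting.

```r
diary <- data.frame(subject_id = "s1",
                    processed_food = "Broth/stock (beef bones)",
                    procedure = "Broth/stock production", amount_g = 100)
conc <- data.frame(chemical = "lead", raw_commodity = "Beef bones",
                   concentration_ug_per_g = 10)
estimate_exposure(diary, conc)
#>   subject_id chemical raw_commodity raw_equivalent_g exposure_ug
#> 1         s1     lead    Beef bones             1.56        15.6
```

100 g of stock × migration-rate factor 0.0156 = 1.56 g of beef bone
equivalent; at 10 µg/g that is 15.6 µg/day of lead.

For a chemical confined to one compartment, the partition ratio is replaced
by the chemical's migration ratio — cholesterol sits entirely in yolk:

```r
eggs <- reference_partition_scheme("Powdered egg product production", "Eggs")
chemical_adjusted_factor(eggs, "Egg yolk", 3.0, migration_ratio = 1)
#> PRCF: 3 (partitioned_yield, n = 1)
#>   partition ratio 1.00 × mean reverse yield 3
```

so 1 g of egg yolk counts as 3 g of egg for cholesterol.

The same operations are available from the shell via the installed script
(`<library>/prcf/exec/prcf`): `prcf validate-ref`, `prcf derive`,
`prcf convert`, `prcf expose`, `prcf assay gae`, `prcf simulate`, with
`--config cfg.yaml` for defaults. Note that `validate-ref` reports one
printed mass-balance anomaly in the bundled table (the milling partition
ratios as published sum to 1.10) and therefore exits non-zero; see the
methods vignette (`vignettes/prcf-methods.Rmd`) for details.

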