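# compartquant

Compartment-resolved quantification of protein subcellular distribution from
multi-channel fluorescence microscopy.

## The problem

Stress responses redistribute proteins between subcellular compartments.
A classic example is the constitutive hsp70-family chaperone hsc70, which
accumulates in the nucleus during heat shock and concentrates in nucleoli
during recovery, while its nucleotide-exchange co-chaperone HspBP1 stays
largely unchanged and excluded from nucleoli. Measuring this quantitatively
requires, for hundreds of single cells per condition: demarcating nucleus,
nucleolus and cytoplasm from a DNA-stain channel; background-corrected mean
pixel intensities per compartment for each protein channel; and population
statistics comparing conditions.

`compartquant` implements that pipeline end to end for two protein channels
(generically `A` and `B`) plus a DNA-stain channel, and pairs it with a
synthetic image generator whose ground truth (compartment geometry,
per-cell brightness factors, correlation structure, embedded colocalization
fractions) lets every stage be validated by parameter recovery.

## What is computed

For each cell *i* and channel *c*, with background-corrected mean
compartment intensities \(\bar I_{c}\):

- **N/C ratio**: \( \mathrm{NC}_{c,i} = \bar I_{c,i}^{\,\mathrm{nuc}} /
  \bar I_{c,i}^{\,\mathrm{cyt}} \), computed per cell, then averaged.
- **Control normalization**: every channel × compartment quantity divided by
  the mean over control cells *of the same replicate experiment*, so the
  control mean is exactly 1 per replicate.
- **Ascending single-cell profiles**: normalized values sorted ascending —
  the whole-population view of a shift.
- **Percent-area colocalization**: after thresholding each channel once on
  pooled control pixels (threshold frozen across all conditions), within
  each nuclear/cytoplasmic ROI:
  `pct_A_in_B = 100 |A∩B| / |A|` and `pct_B_in_A = 100 |A∩B| / |B|`
  (asymmetric by design; pixel size 0.14 µm²).
- **Statistics**: Pearson `r = cov(A, B) / (σ_A σ_B)` per condition for the
  N/C ratio, nuclear and cytoplasmic intensities; OLS regression with R²;
  one-way ANOVA with Bonferroni post-hoc tests against the unstressed
  control (`p_adj = min(1, m·p)`), reported as means + SEM with
  `*`/`**`/`***` significance at p < 0.05/0.01/0.001.

## Worked example

```r
library(compartquant)

cfg <- sim_config(n_cells = 20L, field_size = c(420L, 420L))
gf  <- generate_field(cfg, "heat_shock", seed = 1)    # field + ground truth
seg <- segment_field(gf$field)                        # background + masks
round(seg$background, 1)
#> dna   A   B
#>  40  40  40

fc <- gf$field; fc$channels <- seg$corrected
m  <- measure_field(fc, seg$masks)
head(m[, c("cell_id", "A_nucleus", "A_cytoplasm", "nc_A", "nc_B")], 3)
#>   cell_id A_nucleus A_cytoplasm  nc_A   nc_B
#> 1       1     154.5       113.1 1.366 0.9155
#> 2       2     128.5       109.0 1.179 0.8609
#> 3       3     113.4       100.8 1.125 1.0993

mean(m$nc_A); mean(m$nc_B)
#> [1] 1.35        # channel A shifted into the nucleus under heat shock
#> [1] 1.06        # channel B essentially unchanged
pearson_r(m$A_nucleus, m$B_nucleus)
#> [1] 0.82        # strong per-cell A-B coupling in this condition
```

The estimated background (40 ADU per channel) matches the generator's
configured camera level; the mean heat-shock N/C ratio of channel A (1.35
vs 1.06 for channel B) reflects the configured nuclear enrichment.

A full five-condition run (control, heat shock, 1/2/3 h recovery; three
replicates of 40 cells) is one call:

```r
res <- run_pipeline(run_config(sim = sim_config(), seed = 2026), "out/")
report("out/", plots = TRUE)
```

which writes per-cell measurement and colocalization tables, condition
summaries (mean + SEM), the correlation and regression grids, ANOVA tables
and a provenance block to `out/`. The same run is available from a shell
via `inst/cli/compartquant.R` (`all`, `simulate`, `report` subcommands).

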