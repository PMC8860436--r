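# ssims

Simulation of genetic biocontrol with **sex-sorting incompatible male
systems** — engineered insect strains that combine *engineered genetic
incompatibility* (EGI) with X-linked, tetracycline-repressible *female
lethality* (FL) — compared against RIDL and FL-only release strategies.

The package is for researchers in genetic biocontrol and pest-population
modelling who want to explore how rearing conditions, release size and
release frequency shape suppression of a wild *Drosophila* population,
at laboratory-cage and field-season scales.

## The model in brief

**Incompatibility.** The engineered line expresses a programmable
transcriptional activator (PTA) targeting the promoter of a developmental
gene and survives only because it is homozygous for a PTA-resistant
promoter allele. With the PTA haplosufficient for lethality and the
resistance allele haploinsufficient, every engineered × wild-type hybrid
dies at egg hatch, while the engineered line breeds true.

**Sex sorting.** An X-linked tTA positive-feedback circuit kills females
unless repressed by dietary tetracycline (Tet). Effective exposure follows

    E_child = food_tet + kappa * E_mother,        kappa = 0.07

(maternal oocyte deposition), and female survival is a floored Hill curve

    S(E) = 0                                for E < 2
    S(E) = 0.85 * E^2 / (6^2 + E^2)         otherwise.

A stock held at food concentration `c` carries the fixed-point exposure
`c / (1 - kappa)`. Rearing at 10 µg/ml therefore gives 100% female
lethality one generation after transfer to Tet-free food, while rearing at
100 µg/ml delays complete lethality to the second generation — which is
what turns one strain into male-only, single-amplification or
double-amplification release programs.

On top of this sit exact Mendelian cross enumeration, a sperm-store model
with last-male precedence (P2 = 0.8), a degree-day agent-based model of a
Spotted Wing Drosophila season driven by daily mean temperature
(synthetic Upper-Midwest climatology or your own CSV), and a
discrete-event simulator of the multi-generation laboratory cage trial.

## Worked example

Cross a wild-type female to an engineered (SSIMS) male — every offspring
inherits one PTA copy and only one resistance copy, so nothing survives:

```r
library(ssims)
cross_distribution(strain_genotype("WT", "female"),
                   strain_genotype("SSIMS", "male"))
#>                  genotype probability egi_viable
#> 1   X+/Y;res,wt;PTA,+;+,+         0.5      FALSE
#> 2 XFL/X+;res,wt;PTA,+;+,+         0.5      FALSE
```

Check the dosimetry calibration against its empirical anchors (adult
female fraction by rearing condition):

```r
check_anchors()
#>                                       condition predicted    target
#> 1                             stock on 10 ug/ml 0.3932702 0.40-0.45
#> 2 mothers @100 steady state, offspring Tet-free 0.3419922      0.35
#> 3  mothers @10 steady state, offspring Tet-free 0.0000000         0
#> 4    second Tet-free generation after 100 ug/ml 0.0000000         0
```

Run an untreated field season and a weekly double-amplification release
of 80 agents on the same synthetic season:

```r
run_season(season_config(), seed = 1)
#> Field season: 2021-03-01 to 2021-09-01 (185 days), strategy none, seed 1
#>   peak population: 16285 on 2021-06-13
#>   cumulative wild-type adults hatched: 5081
#>   wild-type eradication: not reached

cfg <- season_config(strategy = release_strategy("SSIMS_double_amp",
                                                 n = 80, interval = 7))
run_season(cfg, seed = 1)
#> Field season: 2021-03-01 to 2021-09-01 (185 days), strategy SSIMS_double_amp, seed 1
#>   peak population: 21412 on 2021-06-13
#>   cumulative wild-type adults hatched: 771
#>   wild-type eradication: day 178 (2021-08-25)
```

The untreated population expands to tens of thousands by early July and
declines through the hot mid-summer; the weekly release cuts in-season
wild-type recruitment roughly sevenfold (5081 → 771 adults hatched) and
eradicates the wild population before the season ends. `summary()`,
`as.data.frame()` and `plot()` expose the full daily census;
`run_cage()`, `run_sweep()` and `april_limited_run()` drive the cage
protocol, release-grid sweeps and the April-only release scenario.
A thin command-line driver with `season`, `sweep`, `april`, `cage`,
`anchors` and `fit-hill` subcommands is installed at
`inst/cli/ssims.R`.

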