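---
title: "Modelling genetic biocontrol with sex-sorting incompatible male systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling genetic biocontrol with sex-sorting incompatible male systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssims)
```

## The system being modelled

`ssims` simulates population suppression of a pest fly by releases of
engineered strains built from two genetic components.

**Engineered genetic incompatibility (EGI)** is an underdominance-like,
post-zygotic mating barrier.  The engineered line expresses a programmable
transcriptional activator (PTA) that lethally misexpresses a developmental
gene, and survives only because it is homozygous for a refactored
("resistant") promoter the PTA cannot bind.  One PTA copy is lethal
(haplosufficient), and one resistance copy is not enough
(haploinsufficient), so every hybrid of the engineered line and wild type
dies, in both cross directions, while the engineered line itself breeds
true.

**X-linked tetracycline-repressible female lethality (FL)** is a
tTA-positive-feedback circuit with female-specific splicing.  Females die
in the absence of dietary tetracycline (Tet); males are unaffected.
Because Tet is deposited maternally in oocytes, a mother's exposure leaks
into her offspring, which delays lethality by one generation when stocks
are reared at high Tet.

A strain carrying both components — a *sex-sorting incompatible male
system* (SSIMS) — can be tuned at the rearing stage: reared at low Tet and
hatched without it, only males emerge (a self-limiting, SIT-like release);
reared and hatched at low Tet, a bi-sex release produces one extra
male-only field generation ("single amplification"); reared and hatched at
high Tet, two extra field generations are possible ("double
amplification") before the female line collapses.

The package provides, as separately testable layers: exact Mendelian
bookkeeping for the four engineered loci; the Tet dosimetry model; a
synthetic daily-temperature climatology; a degree-day-driven agent-based
model (ABM) of a Spotted Wing Drosophila (*Drosophila suzukii*, SWD)
field season under scheduled releases; a discrete-event laboratory
cage-trial protocol; and sweep/fitting drivers.

## Inheritance and viability rules

Genotypes track the sex-chromosome karyotype, an X-linked FL allele, and
unordered diploid pairs at three autosomal loci (resistant *pyramus*
promoter `res`, PTA cassette, RIDL cassette).  Each engineered element is
collapsed to a single allele: the published two-copy X-linked FL strain is
represented by one `FL` allele because no within-strain copy-number
contrast is exercised anywhere in the modelled experiments.  The loci sit
on different chromosomes and assort independently, so no recombination
model is needed.

Viability is enforced at fixed life-stage boundaries:

* **EGI** (≥1 PTA copy together with ≥1 wild-type promoter copy) kills at
  egg hatch — incompatible zygotes are counted as laid eggs but never
  become larvae and never compete for larval resources.
* **FL** kills females at the larva-to-pupa transition with probability
  `1 - female_survival(E)` (below).  Doomed females therefore *do* occupy
  larval rearing capacity before dying, which matters in the
  resource-capped reproduction bottles of the cage trial.
* **RIDL** (dominant lethal, both sexes) kills carriers at the same
  larva/pupa boundary whenever food Tet is below the repression threshold.
  RIDL is modelled as a fourth, independently assorting locus so that the
  comparison strategy can be expressed in the same genetic machinery.

`cross_distribution()` is exact (the outer product of the parents' gamete
distributions), and the test suite verifies it against an independent
brute-force enumeration over every parental allele choice, together with
the X-linkage law (sons never inherit the paternal X, daughters always
do).  EGI lethality is modelled as fully penetrant: the laboratory crosses
it is based on produced zero adult escapers, and no escape rate is
available to calibrate against.

## Tetracycline dosimetry

Each individual carries a scalar *effective exposure* `E` in ug/ml
equivalents.  Offspring exposure is

    E_child = food_tet + kappa * E_mother,

with maternal carryover fraction `kappa = 0.07`.  Sperm carries no Tet.  A
stock kept at constant food concentration `c` converges geometrically to
the fixed point `c / (1 - kappa)`, which is the exposure released adults
carry.  Female survival through the FL circuit is a floored Hill curve:
zero below `e_floor = 2` ug/ml-equivalents, otherwise
`s_max * E^h / (ec50^h + E^h)` with `ec50 = 6`, `h = 2`, and
`s_max = 0.85`.  `s_max < 1` encodes the residual leak of the circuit even
at saturating Tet (the male-biased sex ratio observed on Tet food); the
hard floor makes the observed *complete* female lethality exact rather
than asymptotic.

These five numbers were calibrated jointly against four anchor
observations: ~40–45% female offspring in stocks kept at 10–100 ug/ml,
~35% females when mothers reared at 100 ug/ml produce offspring on Tet-free
food, zero surviving females one generation after a 10 ug/ml stock comes
off Tet, and zero in the second Tet-free generation after 100 ug/ml
rearing.  The anchors cannot all be met exactly — the recursion assigns
nearly the same exposure (7.5 vs 10.8) to conditions reported as 35% vs
40% — so the defaults aim within a few percentage points of each
(`check_anchors()` reports predicted 39.3%, 34.2%, 0, 0).  The floor also
yields the useful invariant that any lineage whose ancestors never
exceeded ~10 ug/ml has *exactly* zero surviving females in all Tet-free
generations, because exposure decays by `kappa` per generation.

## The synthetic climatology

Daily mean temperature drives every field vital rate; hourly structure is
not modelled because the degree-day formulation only consumes daily means.
The generator is a sinusoid (annual mean 8 °C, amplitude 16 °C, peak July
20) plus AR(1) noise (s.d. 3 °C, lag-1 autocorrelation 0.6), which gives a
continental Upper-Midwest season: March means near −3 °C, July means near
23.5 °C.  Observed series can be supplied as CSV (`date,tmean` or
`date,tmin,tmax`) instead.  What the generator does *not* emulate: real
spring heat waves' covariance structure, humidity, photoperiod, and
microclimate refugia.  Conclusions that depend on fine weather structure
(e.g. exact eradication dates) should be read as qualitative.

## Field agent-based model

Agents progress egg → larva → pupa → adult by accumulating degree-days
above a base of 7.2 °C (per-stage requirements 20/120/130).  Each day the
model applies, in order: development and stage promotion with boundary
lethality; stage- and temperature-dependent mortality; mating; oviposition;
and density-dependent egg survival `1/(1 + L/K)` against the larval census
`L`.  Mated females store sperm as per-sire weights; a new mating takes
weight `P2 = 0.8` and scales previous sires by `1 - P2` (last-male
precedence); each egg's sire is drawn independently from the store.  Males
compete equally for matings regardless of genotype, reflecting the
laboratory competitiveness of the engineered males.

### Vital-rate calibration

No published parameter set accompanies the seasonal dynamics this model
is meant to reproduce, so the vital-rate constants are package defaults
calibrated once against the documented qualitative pattern: an unmanaged
population of a few hundred overwintered adults expands to *tens of
thousands by early July* and then declines through the hot mid-summer,
while weekly releases of only 10–80 engineered agents, started in early
spring, can meaningfully suppress or eradicate the wild population.  Two
features of the calibration deserve explanation:

* **Cold side.**  Overwintered SWD adults are winter morphs that tolerate
  near-freezing temperatures well, so adult mortality at ≤0 °C is 0.03/day
  (not an order of magnitude higher), adults do not age on days below the
  developmental base temperature, and the 350 seeded adults survive March
  and April to found the season in May.
* **Heat side, on the daily-mean scale.**  All heat thresholds are
  expressed against daily *means*: a daily mean of 23–24 °C in continental
  summer implies afternoon maxima near 30 °C, where SWD oviposition stops
  and both adults and the developing stages in sun-exposed fruit suffer.
  Fecundity therefore peaks (12 eggs/female/day) at means of 14–20 °C and
  falls to zero at 23 °C; adult mortality ramps from 0.03 above 20 °C to
  0.28 at 26 °C; juvenile mortality ramps from 0.01 above 20 °C to 0.35 at
  27 °C.  This concentrates reproduction in May–June, makes the
  late-June/early-July juvenile bulge the seasonal peak, and produces the
  mid-summer decline.

Adults have a maximum lifespan of 50 *active* days (days above the
developmental base).  Without such a cap the geometric survival tail lets
occasional adults live many months, which both contradicts fly biology
and qualitatively changes outcomes: a single long-lived high-exposure
female can regenerate the engineered female line long after releases
stop.

All of these constants are exposed in `lifecycle_params()` and in the YAML
config, so published values can be dropped in without code changes.

### Releases and the persistence ladder

Released cohorts are adults of the strategy's strain; females carry the
steady-state exposure of their rearing concentration.  The dosimetry then
*derives* the persistence ladder rather than hard-coding it: male-only
releases leave no hatched engineered descendants (all hybrids die);
single-amplification females (exposure ≈ 10.8) have daughters below the
lethality floor, so field-born engineered survivors are exclusively male;
double-amplification females (exposure ≈ 107.5) have viable daughters
(≈ 52% survival) whose own daughters fall below the floor, so engineered
females beyond the larval stage occur only in the first field generation.
The test suite asserts all three rungs over 10 replicates each.

`days_to_eradication()` reports the first day from which zero wild-type
individuals of any stage remain, using 1-based day indices alongside ISO
dates.

## Cage-trial protocol

The cage simulator reproduces the laboratory protocol at constant 25 °C:
600 wild-type adults seeded; 600 SSIMS (45% female, reared at 100 ug/ml)
added weekly for 8 weeks; a weekly 24-hour reproduction bottle whose
cohort ecloses 10–12 days later, capped at 800 emergers with the cap
applied to *hatched larvae* (so female-lethal-doomed larvae consume
capacity); a weekly removal trap that kills everything it catches
(capture probability 1/3, from the report that the standing population
was about three times the weekly catch); and a separate, non-lethal weekly
fecundity assay of up to 10 wild-type females, returned after 3 days.
The cage default remating probability is 0.15/day — higher than the field
default of 0.03/day — because sperm-displacement experiments in
male-saturated vials show near-complete store turnover within a single
4-day egg-lay window, and a cage with a large excess of engineered males
is exactly that regime.

With these settings the control cages rise to a plateau of roughly 450–530
wild-type flies trapped per week, treated cages lose wild-type females
from the traps within 16 weeks, and after releases stop the engineered
females disappear several weeks before the engineered males (whose final
generation is male-only).  Engineered flies persist somewhat longer here
than in the laboratory report; the likely missing mechanism is an adult
fitness cost of the (partially leaky) female-lethal circuit in surviving
females, which is not modelled for want of quantitative data.  This makes
the simulated engineered persistence conservative (an overestimate).

## Numerical and design choices

* The population is a column-oriented store of atomic vectors; daily
  dynamics are vectorised, and a full default season (peak ~2×10⁴ agents)
  runs in well under a second.
* Degree-day excess above a stage threshold carries into the next stage,
  avoiding systematic phenology lag from discretisation.
* Bi-sex cohorts use an exact `floor(n * female_frac)` split rather than a
  binomial draw, so release composition is not a nuisance source of
  variance.
* Every stochastic entry point takes an integer seed and is bit-exactly
  reproducible; sweep rows record the seed of every run.
* Hill fitting uses Levenberg–Marquardt (`minpack.lm`) with non-negative
  bounds; a constant response is rejected as unfittable rather than
  returning a degenerate curve.
* Problem sizes in the test suite (cohorts of 2,000–4,000 zygotes, 10
  replicates per stochastic property, seasons of 185 days, cages of 16–26
  weeks) were chosen so the whole suite exercises every subsystem at
  realistic scale while remaining quick enough to run routinely.

## Known limitations

* No migration, spatial structure, resistance evolution, or
  fruit-phenology/economics; these are outside the model's scope.
* The four Tet anchors over-determine the three-parameter exposure model;
  residuals of a few percentage points are intrinsic.
* Vital rates are calibrated to qualitative targets, not fitted to field
  census data; absolute abundances should be read as order-of-magnitude.
* Engineered-line persistence in the cage is overestimated (see above).
* Laboratory mating parameters (equal male competitiveness, last-male
  precedence `P2 = 0.8`) are treated as genotype-independent constants.
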