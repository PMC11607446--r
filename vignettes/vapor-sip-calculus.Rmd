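---
title: "The vapor-SIP calculus: from delta values to microbial growth, storage and CUE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vapor-SIP calculus: from delta values to microbial growth, storage and CUE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaporsip)
library(dplyr)
```

## The measurement problem

Quantifying soil microbial growth during drought is hard because the standard
tracer techniques add substrate or liquid water, which themselves trigger
growth in a dry soil. Vapor-equilibration stable isotope probing (vapor-SIP)
sidesteps this: a reservoir of isotopically enriched water sits in the same
closed vial as the soil but never touches it, and the label reaches the soil
water only through the gas phase. Organisms that synthesise biomass during
the incubation draw on that labelled soil water, so the heavy-isotope excess
in their biomolecules measures how much of each pool was newly made.

`vaporsip` implements the complete calculus for the two tracers used with
this design:

* **²H into fatty acids** — phospholipid fatty acids (PLFA) proxy membrane
  growth; neutral-lipid fatty acids (NLFA, mainly triglycerides) proxy
  storage-compound synthesis. Marker fatty acids resolve broad microbial
  groups (fungi, gram-positive and gram-negative bacteria, actinobacteria,
  arbuscular mycorrhizal fungi).
* **¹⁸O into DNA** — bulk DNA production proxies community-level replication.

Both pipelines end in the same physiological quantities: growth rate,
respiration, carbon uptake, carbon use efficiency (CUE) and biomass turnover
time.

## From raw delta values to atom percent

GC-IRMS reports per-mil delta values against a working reference. Bracketing
standards of known isotopic composition (e.g. USGS70/USGS72 fatty-acid
esters) are measured through the sequence; `fit_calibration()` regresses
known on measured delta by ordinary least squares and, when standards were
measured at several run positions, estimates a linear drift term in the same
least-squares problem. Linearity in run position is the minimal drift model
consistent with using standard offsets to correct a sequence; nothing in the
data demands more structure, and the residual standard deviation is reported
so users can judge the fit. Normalized delta values convert to atom percent
with the two-isotope form

$$R = (\delta/1000 + 1)\,R_{std}, \qquad
  \mathrm{at\%} = 100\,\frac{R}{1+R},$$

with $R_{std}$ the VSMOW ratio (0.00015576 for ²H/¹H, 0.0020052 for
¹⁸O/¹⁶O). A triple-isotope (¹⁷O) treatment is deliberately omitted: at
tracer-level enrichments of 10–25 at% the two-isotope approximation errs far
below instrument noise. Fatty-acid carbon amounts come from peak areas scaled
by the co-injected internal standard (19:0), which is excluded from every
downstream sum because it carries no biological signal.

## The equilibration curve and its average

The soil water does not start enriched: label accumulates over the
incubation. Collecting the reservoir water at 0, 3, 6, 16 and 48 h and
converting its label loss to soil-water gain by two-pool mass balance
(`source_loss_to_soil_atpct()`) gives the soil-water trajectory, which is
fitted (`fit_equilibration()`) with the negative exponential

$$X(t) = X_{end} + (X_{start} - X_{end})\,e^{-bt},$$

where $b$ (h⁻¹) is a soil-specific equilibration coefficient. The same
functional form fits either the decaying source series or the rising soil
series; both interpretations are supported because published descriptions of
the method are ambiguous about which pool the fitted symbols refer to, and
the mass-balance-derived soil series is the default input. The tracer
denominator used by all flux equations is the *time-averaged* enrichment

$$\bar X = X_{end} + (X_{start} - X_{end})\,\frac{1 - e^{-bW}}{bW}$$

over the incubation window $W$ (48 h default) — the closed form of the
integral average, cross-checked against adaptive quadrature in the test
suite to $10^{-9}$ relative. Fitting uses Levenberg–Marquardt with $b$
bounded in $[10^{-6}, 10^3]$ h⁻¹ and initialisation from log-linearised
residuals; a flat series is returned as a flagged degenerate fit rather than
an error. Because only a subset of vials (2 per treatment) yields a time
series, replicate fits are averaged to one treatment-level value applied to
all samples of that treatment, and phases without their own series (the
recovery sampling) reuse the matching non-drought climate's value.

```{r equilibration}
tt <- c(0, 3, 6, 16, 48)
series <- tibble::tibble(
  time_h = tt,
  atom_percent = 16.1 + (0.0155 - 16.1) * exp(-0.12 * tt))
fit <- fit_equilibration(series)
fit
generics::glance(fit)
```

## Tracer flux equations

Both tracers share one kernel: the fraction of a pool newly synthesised is
excess enrichment over the (assimilation-scaled) soil-water enrichment.

For each fatty acid,

$$\mathrm{FA\,C_{produced}} =
  \frac{\mathrm{at\%_{labelled}} - \mathrm{at\%_{natural}}}
       {a_w \cdot \mathrm{at\%_{soil\,water}}} \times \mathrm{FA\,C},$$

where $a_w$ is the water hydrogen assimilation constant — the fraction of
fatty-acid hydrogen drawn from ambient water during biosynthesis, net of
fractionation. For mixed heterotrophic communities 0.71 is the accepted
default; the package exposes it in `vs_config()` because every lipid-based
growth estimate scales exactly as $1/a_w$ (a property the test suite asserts:
reanalysing with $a_w = 0.3$ multiplies all lipid growth by 0.71/0.3).
`FA C` is the mean fatty-acid carbon of the labelled and paired
natural-abundance sample. The natural-abundance at% comes from the same
plot's unlabelled incubation.

For DNA,

$$\mathrm{DNA_{produced}} = \mathrm{O_{DNA\,extr}} \times
  \frac{\mathrm{at\%_{labelled}} - \mathrm{at\%_{natural}}}
       {\mathrm{at\%_{soil\,water}}} \times \frac{100}{31.21},$$

with 31.21 % the mean oxygen content of DNA by mass and no assimilation
constant, which is why DNA- and lipid-based absolute rates are not directly
comparable while treatment *ratios* are.

Community growth converts the produced fraction to carbon flux via microbial
biomass C (from chloroform fumigation extraction, an input here):

$$\mathrm{Growth} = \frac{\mathrm{pool\,produced}}{\mathrm{total\,pool}}
  \times \mathrm{Microbial\,BM\,C} \; / \; \mathrm{time}.$$

The division by incubation time is applied on both tracer paths so that
growth is an hourly rate wherever it meets hourly respiration (in uptake and
CUE); printed formulations of the DNA variant sometimes omit the time term,
but a rate is required for the physiological ratios to be dimensionally
consistent, and we document this as a deliberate choice. Group-specific
mass-specific rates divide each group's summed production by the group's
summed fatty-acid carbon and time; the fungi:bacteria ratio uses fungal
markers over gram-positive (including actinobacteria) plus gram-negative
markers, with the AMF marker 16:1ω5 and the general markers excluded from
both sides.

Storage investment is reported as the percentage of newly produced NLFA
relative to newly produced PLFA of the *same* markers, per group — a ratio
robust to necromass-NLFA accumulation because both numerator and denominator
are production terms of the same incubation.

## Respiration, CUE and turnover

Respiration comes from the headspace CO₂ rise by the ideal gas law at the
vial's temperature and pressure (27 mL vial minus a configurable inner-vial
displacement; ppm treated as µmol mol⁻¹). Then

$$\mathrm{CUE} = \frac{\mathrm{Growth}}{\mathrm{Growth} +
  \mathrm{Respiration}}, \qquad
  T = \frac{\mathrm{Microbial\,BM\,C}}{\mathrm{Growth} \times 24},$$

with $T$ in days — the reciprocal of the daily mass-specific growth rate.
Treatment-level turnover tables are computed from treatment-mean growth and
biomass (the convention behind published "rounded values" tables), with the
mean of per-sample turnovers reported alongside since Jensen's inequality
makes the two differ. Respiration in the CUE of a tracer is the one measured
in the same labelled vial over the same window; a paired t-test of labelled
versus natural-abundance respiration (`paired_t()`) checks that the ²H label
itself did not depress activity.

## Numerical and degenerate-input choices

* Negative excess enrichment (labelled below natural abundance, IRMS noise
  around zero growth) clamps production to 0 with a per-record flag rather
  than propagating negative rates; the clamp count is reported and the
  behaviour can be disabled in `vs_config()`.
* Zero total pools (PLFA C, total DNA) are typed errors, not silent zeros;
  groups with no fatty-acid carbon are omitted from rate tables with a
  notice, never reported as rate 0.
* CUE and turnover with zero denominators return `NA` with a warning.
* Marker names are normalised (spacing, ω vs w, cis/trans suffixes) before
  registry lookup; unknown markers fall to the `general` group with a
  notice. The registry ships as data (`inst/extdata/biomarker_groups.csv`)
  so users can extend it.
* The equilibration optimizer tolerance is $10^{-10}$ on the sum of squares.

## What the synthetic generator emulates — and what it does not

`vs_simulate_dataset()` forward-simulates the whole experiment with known
ground truth: 4 treatments × 2 phases × 4 plots, separate ²H (fatty acid)
and ¹⁸O (DNA) incubations per plot, water series for 2 replicates per
treatment at the canonical sampling times, and headspace CO₂ for labelled
and natural vials. The default truth was chosen once to echo the qualitative
biology the method was built to detect: drought roughly halves bacterial
mass-specific growth (gram-negative slightly more than gram-positive,
actinobacteria least) while fungal growth is unchanged; fungal NLFA:PLFA
production investment rises from ~22 % to several-fold; rates return to
ambient-like values in recovery; community turnover is on the order of 100
days. Instrument noise defaults to 4 ‰ on δ²H — applied in delta space,
where IRMS noise is actually stated, then converted — plus smaller at%
noise on ¹⁸O, ppm noise on CO₂, and a lognormal plot-level rate multiplier
(sd 0.15) so plot-keyed mixed-model exports look realistic. Since no
within-treatment variance components are published for this design, the
noise magnitudes beyond the δ²H figure are the package's own synthetic
choices and are labelled as such.

The generator deliberately does **not** simulate mechanistic soil-moisture
or substrate-diffusion dynamics, taxon-resolved (density-gradient) qSIP,
chromatographic artefacts, memory effects, or NLFA degradation. Passing the
recovery tests therefore demonstrates that the calculus is self-consistent
and robust to stated instrument noise — not that field data are free of
those unmodelled processes.

```{r recovery}
ds <- vs_simulate_dataset(vs_truth(), seed = 1)
res <- vs_run_pipeline(ds, quiet = TRUE)
res$physiology |>
  left_join(select(ds$meta, sample_id, treatment, phase), by = "sample_id") |>
  filter(tracer == "plfa_2h", phase == "drought") |>
  group_by(treatment) |>
  summarise(growth = mean(growth), cue = mean(cue),
            turnover = mean(turnover_days))
```

## Problem sizes used in validation

The shipped test suite validates the calculus at the scale of the design it
serves: 16 plots (4 per treatment), 18 markers in two lipid fractions,
5-point water series, 200-seed Monte-Carlo recovery runs for the
noise-robustness checks and 500-seed runs for the equilibration fitter,
1000 random parameter draws for the closed-form/quadrature agreement. These
sizes make the whole suite run in a few minutes while keeping the
Monte-Carlo acceptance fractions statistically meaningful.

## Known limitations

* Absolute lipid-based rates inherit the full uncertainty of $a_w$ (reported
  community values range ~0.1–1); treatment contrasts are invariant to it.
* No assimilation constant exists for the ¹⁸O→DNA path, so cross-tracer
  comparisons of absolute rates conflate methodology with biology.
* NLFA production rates assume no NLFA degradation over 48 h (degradation
  rates in soil are unknown); mass-specific NLFA rates may be slight
  underestimates.
* The pipeline expects raw delta values already corrected for the
  trihydrogen (H₃⁺) factor by the instrument; memory-effect corrections are
  out of scope.
* Statistical modelling beyond cell means, contrasts and the paired t-test
  (mixed models, ordination, PERMANOVA) is intentionally left to dedicated
  packages; the pipeline exports tidy tables shaped for them.
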