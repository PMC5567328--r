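---
title: "Auditing taxonomic bias in occurrence data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing taxonomic bias in occurrence data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occbias)
```

## The problem

Primary biodiversity data — occurrence records of the form *this taxon, at
this place, at this time* — accumulate opportunistically, not by design.
The result is taxonomic bias: recording effort across taxa is far from
proportional to known species richness, with a few charismatic groups
(birds above all) absorbing most of the effort. `occbias` packages the
statistics needed to audit this bias in a GBIF-style snapshot: per-taxon
sampling summaries, a deviation from "ideal" species-proportional sampling
and its evolution over time, a spatial-distinctness criterion on an
equal-area grid, a multiple correspondence analysis (MCA) of record
quality and origin, and negative-binomial models relating per-species
record counts to public interest and research effort.

Because the real inputs are hundreds of millions of records plus web-scale
covariate queries, the package also ships a seeded synthetic generator
(`synth_config()`, `gen_backbone()`, `gen_occurrences()`,
`gen_covariates()`) so that every stage runs, and is tested, at desk scale.

## Record model and quality flags

`normalize_occurrences()` reduces each record to: taxon (class, order,
species name), date (year, month), coordinates, a data-origin category and
three derived flags.

* **Origin** (`classify_basis()`): the Darwin Core `basisOfRecord`
  vocabulary collapses to *Specimen* (preserved/living/fossil specimens,
  material samples), *Observation* (human/machine/unclassified
  observations, literature) or *Unknown* (anything else, including empty).
  Matching ignores case and separators because serializations vary.
* **Temporal issue**: year or month missing. **Spatial issue**: coordinates
  missing or any non-empty GBIF issue flag. These feed the per-taxon
  incompleteness proportions `p_time` and `p_space`.
* **Precision** (`flag_precision()`): identified to species rank or lower
  (species, subspecies, variety, form) with a non-empty name. Imprecise
  records have their name blanked, so "species" always means a precise
  identification downstream.

A deliberate parsing policy: unparseable years, months or coordinates are
treated as *absent* (triggering the issue flag) rather than causing row
rejection, because the audit's accounting counts such records in the
incompleteness tallies instead of discarding them. Only structurally
broken rows are skipped, and always tallied. Longitudes are normalized to
[-180, 180); out-of-range latitudes are demoted to missing coordinates;
(0, 0) is accepted as a valid location (no "null island" rule).

## Per-taxon statistics

For each class (or order), `summarize_taxa()` reports the occurrence total
`nb_occ`, the number of distinct recorded species `n_gt1`, known richness
`N` (distinct backbone names with *accepted* or *doubtful* status —
synonyms excluded), the median and MAD of occurrences per recorded
species, taxonomic precision, the coverage proportions
`p_gt1 = n_gt1/N` and `p_gt20 = n_gt20/N`, and `p_gt20d`, the share of
species with at least 20 *spatially distinct* occurrences.

Two conventions matter and are tested:

* The MAD is the **raw** median of absolute deviations from the median,
  with no 1.4826 consistency scaling — the literal robust-spread
  definition.
* Even-length medians are the mean of the two central order statistics
  (half-integer medians are real and occur in published summaries).

### Ideal sampling and its deviation

Under unbiased sampling each taxon would receive occurrences
proportionally to its known richness:

$$I = NB_{occ} \cdot \frac{N}{N_{tot}}, \qquad D = nb_{occ} - I.$$

Deviations sum to zero over taxa by construction — a conservation law the
tests assert at every checkpoint. `temporal_deviations()` recomputes
$I$ and $D$ at decadal checkpoints (default 1956–2006) from the
*cumulative* record count up to each checkpoint: the statistic describes
the state of the accumulating database, not per-decade flow (the source
is ambiguous; cumulative is declared here). Undated records are excluded,
as are records from the ten years before the snapshot (integration lag),
and $N$ is held at its present-day value because no historical backbone
exists. Both absolute deviations `D` and per-checkpoint normalized
`D_norm = D / NB_occ` are emitted, since either scaling is defensible for
plotting.

### Spatial distinctness

Two occurrences are spatially distinct when they fall in different cells
of a global 10×10 km grid built on the **Eckert IV** equal-area
pseudocylindrical projection. The parallel parameter solves
$\theta + \sin\theta\cos\theta + 2\sin\theta = (2 + \pi/2)\sin\varphi$
by damped Newton iteration. Numerical choices: residual tolerance 1e-14
(1e-12 alone permits metre-scale-irrelevant but test-relevant ~4e-6 m
y-errors near the poles, where the derivative $2\cos\theta(1+\cos\theta)$
vanishes); full-precision bisection fallback above 89° latitude; the
closed form $\theta = \pm\pi/2$ at the poles. The sphere radius defaults
to the authalic Earth radius 6 371 007.181 m — standard for equal-area
work — and the grid is anchored at the equator/central-meridian origin
with strict floor indexing, so boundary points resolve deterministically.
The projection agrees with an independently generated PROJ reference to
better than 1e-6 m, and projected patch areas match exact spherical areas
to 1e-6 relative error. The source specifies none of radius, origin or
boundary convention; these are declared defaults, not inferences.

## MCA of record quality and origin

`fit_mca()` relates four categorical variables — class, record age (eight
calendar bins plus *Unknown Year*), origin, and completeness (*No issue*,
*Temporal issue*, *Spatial issues*, *Both issues*) — as a correspondence
analysis of the complete disjunctive (indicator) table: standardized
residuals of the row/column-mass-centred table, decomposed by SVD.
Indicator coding (rather than the Burt table) is used because row scores
are needed: class positions in the factorial plane are **barycentres**,
the mean row score over each class's occurrences
(`class_barycentres()`). Eigenvalues satisfy the identity
$\sum\lambda = J/Q - 1$; axis signs are fixed by making the
largest-magnitude category loading on each axis positive, so a seeded run
is fully deterministic.

Categories rarer than 0.5% of rows are **ventilated**
(`ventilate()`): their rows are randomly reassigned among the variable's
remaining categories, proportionally to those categories' frequencies,
repeating until no rare category remains; a variable that collapses to a
single category is dropped with a warning. The reassignment law is not
fixed by the methodology this follows; proportional-to-frequency is the
natural choice and is seeded. Both the ventilated and unventilated runs
are written by `run_mca()`, since published figures do not say which was
shown.

## Negative-binomial models

`fit_nb_glm()` regresses occurrences per species on public interest
(web-page counts for the species name plus the keyword "species") and
research effort (order-level publication counts), log link, with their
interaction:

$$\log \mu = \beta_0 + \beta_1\, t(x_I) + \beta_2\, t(x_R) +
\beta_3\, t(x_I)\,t(x_R),$$

negative binomial to absorb overdispersion, dispersion estimated by
maximum likelihood (`MASS::glm.nb`), Wald per-term p-values at the 5%
threshold. The covariate transform $t$ defaults to `log1p`: raw web
counts span 0 to ~1.8 million and destabilize the linear predictor; the
source is silent on any transform, so it is declared and configurable
(`identity` available). The keyword-augmented interest variant is the
default covariate for the same reason.

Species enter per class either as the 1,000 best-represented (ties broken
by name for determinism) or as 1,000 uniform random species — sampled
from all recorded species, overlap with Best allowed, since exclusion is
unstated; classes under 1,000 species get a single model. Before fitting,
a **single-pass** outlier rule drops any species whose occurrence count
*or* interest count exceeds $Q_3 + 4\,\mathrm{IQR}$ of the selected set
(type-7 linear-interpolation quantiles, the default of mainstream
statistical software). `residual_diagnostics()` pairs deviance residuals
with fitted means and reports the slope of |residual| on fitted as a
heterogeneity flag.

## What the synthetic generator emulates — and what it does not

The generator's defaults are a fixed "stated world", chosen once:

* **Classes**: six, mirroring the qualitative regimes of the real
  snapshot — one dominant, precisely identified, observation-based class
  (53% weight, 0.99 precision); a large plant-like class; a hyper-diverse
  under-recorded insect-like class; and smaller classes with
  specimen-heavy origin mixes and high missingness (up to 0.55) as seen
  in molluscs and amphibians.
* **Abundances**: lognormal(0, 2) per species, multinomially allocated so
  class totals stay exactly controllable; this reproduces the qualitative
  heavy tail (singleton species outnumber well-sampled ones). The true
  abundance law of portal data is unpublished; lognormal is a stand-in,
  not a calibration.
* **Years**: 1900–2016 with exponential growth rate 0.03/yr — record
  accumulation accelerates strongly toward the present.
* **Coordinates**: three Gaussian clusters per species (sd 2°), truncated
  to valid ranges, producing the spatial redundancy that makes
  `p_gt20d < p_gt20`.
* **Covariates**: interest ~ lognormal(5, 2) per species, research
  ~ lognormal(5, 1.5) per order; coupled mode draws counts from
  NB(mean $= e^{3 + 0.8 t(x_I)}$, $k = 1$), matching the fitting
  transform so truth and estimate live on one scale.

A green test on synthetic data establishes *internal correctness* —
bookkeeping identities, estimator calibration, parameter recovery — not
agreement with the real portal: the generator has no spatial sampling
bias, no name-matching noise, no duplicate records, and its missingness
is independent across fields, all of which real aggregated data violate.
Portal-scale headline numbers are instead reproduced exactly from the
packaged printed summary table (`gbif2016_snapshot()`), which is an
input, not an output, of this package.

## Degenerate inputs and tie-breaks

Empty classes are excluded but tallied; a backbone class absent from the
occurrence stream yields zero coverage, not an error; `IQR = 0` removes
nothing (the rule is strict inequality); grid-cell boundary points use
strict floor; MCA axis signs and Random-mode species draws are seeded.
Non-converged NB fits are returned flagged, never silently replaced.

## Known limitations

Synonym resolution, fuzzy name matching, Darwin Core Archive (meta.xml)
parsing, richness estimators, spatial bias maps and zero-inflated or
mixed count models are out of scope. Order-level research covariates make
$\beta_2$ partially collinear with $\beta_3$ when few orders exist —
visible in wide interaction intervals on small synthetic classes. The
temporal analysis holds $N$ fixed at present-day richness, which
overstates early-century "ideal" counts for groups described recently.
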