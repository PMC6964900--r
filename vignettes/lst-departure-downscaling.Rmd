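---
title: "Downscaling daily maximum air temperatures with LST departures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Downscaling daily maximum air temperatures with LST departures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lstdown)
```

## The model

Coarse gridded daily maximum air temperatures (1/8-degree, ~12 km, forced
by reanalysis) carry the day-to-day weather but none of the sub-cell
thermal structure — urban heat islands, rivers, coastlines — that drives
intra-urban differences in heat exposure. Clear-sky satellite land surface
temperature (LST) at 1 km carries exactly that structure, with two
caveats: it is a skin temperature whose spatial contrasts are larger than
those of 2 m air temperature, and it is missing wherever there is cloud.

The disaggregation model used here assumes that, under quiescent
warm-season conditions, near-surface air temperature is driven by surface
sensible heating, so the *spatial pattern* of afternoon air temperature
mimics the pattern of LST at a reduced amplitude. Writing `T_H` for the
1 km composite LST and `T_L` for the coarse daily maximum, the downscaled
estimate at fine pixel `x` inside coarse cell `c` is

    T_dis(x) = T_L(c) + Z(x) * sigma_L,      Z(x) = (T_H(x) - mean_c T_H) / sigma_H

which, when the variability ratio `sigma_L / sigma_H` is collapsed into a
constant `R`, reduces to the operational form

    T_dis(x) = T_L(c) + R * (T_H(x) - mean_c T_H).

`mean_c T_H` and `sigma_H` are the mean and *population* standard
deviation of the composite over the fine pixels of the single owning
coarse cell (the cell's pixels are an enumeration, not a sample). `T_L(c)`
is the owning cell's value with no further neighborhood averaging; that
choice is what makes the scheme *conservative*: the departures have zero
mean within each cell by construction, so the unweighted mean of `T_dis`
over any fully valid cell reproduces `T_L` exactly (the tests assert this
at 1e-9 °C). The departure pattern is computed once per warm season and
held fixed; only `T_L` varies day to day, so the fine-scale anomaly is a
seasonal climatological imprint, not a daily retrieval.

Both forms are implemented. `constant_ratio` with `R = 0.5` is the
default: estimating `sigma_L` from a neighborhood of coarse cells makes
the rescaling blow up along strong climatological gradients (coastlines
especially) and, with any neighborhood larger than one cell, breaks
conservation. `sigma_ratio` mode is retained because it is the natural
route to a spatially varying ratio, and `estimate_sigma_ratio()` maps
`sigma_L / sigma_H` per cell to support choosing or auditing `R` for a
region. `R = 0.5` for daily maxima encodes that air-temperature spatial
variability is roughly half that of LST over most mid-latitude land; it is
knowingly too small in coastal and mountainous terrain.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `r_ratio` | 0.5 | — | amplitude of the LST departure imposed on air temperature |
| `mode` | `constant_ratio` | — | constant `R` vs per-cell `sigma_L/sigma_H` |
| `neighborhood_cells` | 1 | coarse cells | window for `sigma_L` in `sigma_ratio` mode; 1 preserves cell means |
| `min_valid_pixels` | 3 | fine pixels | below this, a cell's departures fall back to 0 (`qc = "fallback_zero"`) |
| LST scale / fill | 0.02 K, 0 | raw units | scaled-Kelvin decoding; raw 0 (0 K) doubles as the fill value |

The fallback rule means a heavily clouded cell degrades gracefully to the
coarse product rather than to an artifact; `qc` distinguishes `ok`,
`fallback_zero` and `unassigned` (fine pixel outside the coarse domain),
and wherever `qc != "ok"` the output equals the coarse value exactly.

## Compositing: the upper-half rule

Eight-day clear-sky LST composites still lose large areas to cloud, and
partly cloudy pixels occasionally retrieve erroneously cold values. Rather
than filter on QC flags, the seasonal composite takes, per pixel, the
*mean of the upper half* of the valid values across the season's scenes:
with `n` valid samples, the top `ceil(n/2)` are averaged. Cloud fill
(raw 0) is excluded as invalid, and cold contamination lands in the
discarded lower half. The resulting warm bias is irrelevant because only
within-cell departures are used — adding any constant per cell cancels.

Two numerical conventions are worth stating. For odd `n` the "upper half"
is the top `ceil(n/2)`, biasing toward clear-sky values. A consequence of
the ceiling convention: adding a sample below a pixel's median leaves the
selected set untouched when `n` is odd (the composite is bit-identical),
while at even `n` it admits one additional *genuine* value — the outlier
itself is never averaged, and the composite never falls below the pixel's
median. Second, the cell mean and sigma are taken over the *valid* member
pixels only, which guarantees zero-mean departures (hence conservation)
even under arbitrary missingness; computing the mean over all pixels
would quietly break conservation whenever a cell has dropouts.

## Daily extrema and time

Daily maxima are taken per pixel over the 24 hourly samples of the local
calendar day, midnight to midnight *local standard time*, with the offset
derived from longitude as `round(lon/15)` (ties away from zero). A civil
time-zone database would add an external dependency and politically shaped
boundaries for no benefit: the afternoon peak this pipeline cares about
follows solar time. Pixels missing any hour of their window are flagged
invalid rather than given a partial maximum, which would be silently cold
biased. Because the coarse forcing is itself interpolated from 3-hourly
analyses, its daily maxima sit slightly below continuously observed ones;
the tests demonstrate that bias direction on an interpolated series.

## Validation conventions

Gridded estimates are compared to stations by *containment* — the value of
the pixel whose half-open box contains the station coordinate — not by
interpolation, since the aim is to validate the gridded product as users
would read it. Pixel boxes are `[west, east) x (south, north]`, which
resolves every shared-edge tie deterministically (a point on a shared
horizontal edge belongs to the pixel below; on a vertical edge, to the
pixel on the right). Metrics are `mean_diff = mean(estimate - observation)`
(negative = the product runs cold) and `rmsd`, paired over a month-day
window across years: June 1 – August 31 over three years gives 276
candidate days per station. Multi-city summaries are unweighted means
across cities; reported tables round half away from zero to 2 decimals.

## What the synthetic worlds emulate — and what they do not

`scene_recipe()` encodes the study conditions the pipeline targets: a
1/8-degree coarse grid with 12:1 nesting; a warm season of 19 eight-day
composite scenes; blocky cloud masks (random rectangles, ~30% cover) so
that whole neighborhoods drop out together and the per-cell fallback is
exercised; 0.5 °C scene noise plus a 2% rate of 10 °C cold contamination;
a fixed fine-scale anomaly built from Gaussian urban bumps and a coastal
step that deliberately crosses a coarse cell (the mixed land/water cell is
where coarse products err most); and an anomaly-to-air coupling
`r_true = 0.5` mirroring the operational `R`. The hourly cube is a
sinusoid peaking at 14:00 local standard time whose daily maximum equals
the coarse peak exactly, and the anomaly is re-centered to zero mean per
cell, so the world satisfies the method's conservation premise by
construction. All randomness flows from one seed.

Passing tests on these worlds therefore show that the *machinery* is
correct — compositing, centering, rescaling, conservation, extraction,
pairing — and that the method recovers truth exactly when its assumptions
hold (`R = r_true`, no noise) and beats the upsampled coarse product where
fine-scale signal exists under noisy, cloudy conditions. They do not show
that real air temperature follows LST patterns with a constant ratio;
advection, elevation gradients and day-to-day pattern variability are
real-world failure modes that the generator intentionally omits, and no
synthetic experiment can validate the 0.5 itself.

## Numerical and design choices

* Problem sizes: unit tests run on 24x24 to 96x96 fine grids with 1–19
  scenes and 2–276 days; the identity and oracle suites use 100 random
  field pairs and 1,000 random pixel histories. These sizes make every
  property checkable exhaustively while keeping the default suite fast.
* Degenerate cells: `sigma_H = 0` (a perfectly uniform composite cell)
  gives `Z = 0` and `T_dis = T_L` — the only defensible value when the
  pattern carries no information. Cells with invalid `T_L` produce invalid
  fine pixels; nothing is extrapolated.
* `estimate_sigma_ratio()` compares the sd of coarse values over a
  `window x window` cell neighborhood with the sd of the fine composite
  over the same neighborhood's pixels. Because a handful of coarse samples
  under-disperses relative to the pixel population, small windows bias the
  ratio low on smooth fields (~8% at window 3, ~2% at window 5); the
  diagnostic defaults to window 3 for locality, and the recovery
  experiment uses window 5, where the discretization bias is small
  against the ±0.05 assessment band. The domain summary is a median, so
  isolated near-zero-`sigma_H` cells cannot dominate.
* Raster formats: ESRI ASCII grid (text, full double precision,
  bit-identical round trips, square pixels only) and two-channel 32-bit
  float TIFF with an ESRI world file and a JSON sidecar holding the affine
  value scaling (round trips exact to float precision, rectangular pixels
  allowed). Hourly cubes use a one-line-per-hour text serialization.
  Station tables are plain CSV with ISO dates.
* The bundled `five_city_tmax_validation.csv` is an example multi-city
  validation summary (five U.S. cities, coarse vs downscaled, June–August
  over three years) used to exercise and document the aggregation
  conventions; the package does not recompute its per-city rows, which
  derive from observational archives outside desk scope.
* The pipeline applies one seasonal departure field to every day of that
  season. Minimum-temperature fields can be fed through the identical
  machinery (the extrema stage computes `tmin` too), but no
  nighttime-specific compositing logic is claimed: for daily minima the
  departure-imposition approach adds little skill, so the package's
  defaults and documentation target daily maxima.

## Known limitations

Strong temperature advection decouples air temperature from local surface
heating; large within-cell elevation ranges make a constant `R` wrong even
in sign of magnitude; and the seasonal-composite assumption suppresses
genuine day-to-day changes in the fine-scale pattern (irrigation, rain
footprints, phenology). In such regions the honest expectation is that
the downscaled product inherits, not fixes, the coarse product's errors —
the rural control in the README's worked example shows the neutral case.
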