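---
title: "Methods: categorical sensitivity mapping of heatwave impacts on seagrass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: categorical sensitivity mapping of heatwave impacts on seagrass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesamhw)
```

## The model

`mesamhw` maps the *environmental sensitivity* of Mediterranean *Posidonia
oceanica* meadows to marine heatwaves (MHWs) as the combination of two
categorical layers:

* **Susceptibility** — how badly a seagrass pixel is expected to be affected
  by mid-century heatwave conditions, scored 1 (very low) to 5 (very high);
* **Importance** — how much a country's coastal communities rely on the
  ecosystem services the meadows provide, scored 1, 3 or 5 per exclusive
  economic zone (EEZ) for two criteria: coastal-hazard mitigation and
  seagrass-dependent fisheries.

Sensitivity is the product of the two scores, binned into five classes from
Very Low to Very High. The unit of mapping is the quarter-degree grid-cell
(QDGC) lattice at level 3 (0.125° cells), anchored at integer degrees so
cell identities never depend on the analysis extent.

### Heatwave detection and the four drivers

*P. oceanica* shows no heat stress below about 24 °C, while a yearly maximum
of 32 °C implies roughly 20 % shoot mortality per year; recovery is slow
(about 7 %/yr under partial mortality). The event definition is therefore a
regional fixed-threshold one: a MHW is a run of **at least 5 consecutive
days strictly above 24 °C**, evaluated inside the May 1 – September 30 warm
season (153 days). A day at exactly 24.0 °C is *not* an exceedance; the
max-SST class table, by contrast, assigns class 2 from 24 °C inclusive —
both conventions are kept exactly as stated in their respective stages.

Four drivers are extracted per 0.1° pixel and season:

| driver | impact side | definition |
|---|---|---|
| `max_sst_c` | severity | maximum daily temperature |
| `max_run_days` | severity | longest strict-exceedance run (counted even below the 5-day event minimum) |
| `n_events` | recovery | number of qualifying events |
| `max_gap_days` | recovery | longest at-or-below-threshold run strictly between two events |

With fewer than two events the between-events gap is undefined; this package
uses the longest sub-threshold run anywhere in the season, so a season with
no exceedance at all yields the full season length (and hence the best
recovery class), consistent with zero events receiving the best frequency
class. Whether gaps should instead straddle year boundaries is unknowable
from the protocol; all metrics here are confined to one season.

Masked (missing) days break runs and count as below threshold; a pixel with
more than 10 % missing season days is flagged unreliable in the metrics
output.

### Scoring

Each driver is mapped to a 1–5 class through a threshold table
(`default_thresholds()`). The printed duration classes overlap at 20 days
("11–20", "20–30"); the package resolves this to disjoint bins ≤4, 5–10,
11–20, 21–30, ≥31, i.e. 20 days scores 3, preserving the printed lower bound
of the next row. Impact severity is the equal-weight mean of the SST and
duration classes; potential for recovery the mean of the frequency and gap
classes. The two means (values on a 0.5 grid) are combined through the 5×5
susceptibility matrix, which equals `ceiling((is + pr) / 2)` on every cell.

Two rounding conventions are needed where the protocol is silent:

* metrics averaged over the study years can be fractional, while the
  day/count class tables are defined on integers — fractional values are
  rounded **half-up** before lookup (3.4 events → 3; 3.5 → 4);
* half-valued severity/recovery means are likewise rounded half-up before
  the matrix lookup, matching the matrix's own ceil-mean structure.

### Study period aggregation

Daily projections for 2046–2055 stand in for "around 2050". The aggregation
across years is not prescribed; the default (`mean_metrics`) averages each
metric over the ten years and scores once, which yields the single
susceptibility value per pixel that a map displays. The alternative
(`mean_scores`: score each year, average severity/recovery, combine once) is
available via `period$aggregation`.

### Importance

Fisheries importance pools the catch of the six commercial taxa with the
highest seagrass residency (two *Pagellus* species, *Trisopterus minutus*,
*Melicertus kerathurus*, *Pecten maximus*, and *Scorpaena* represented by
three species, summed): per-country mean annual tonnage over 2014–2018,
summed over taxa, as a percentage of the regional total. Pooling the taxa
into a single share (rather than averaging per-taxon shares) is the simpler
reading of the protocol and is the default. Coastal-hazard importance is the
percentage of a country's coastline assessed at very-high risk, consumed as
given (the 13-variable risk index behind it is out of scope).

Percentages map to scores as <5 % → 1, 5–20 % → 3, ≥20 % → 5. The printed
bounds leave exactly 5 % and 20 % unclassified; boundaries here fall in the
**higher** class, the precautionary reading. Countries missing from one
input get score 1 for that criterion, with a warning.

### Sensitivity combination

The reference protocol multiplies the two scores through a sensitivity
matrix whose numeric cells are not published. The package therefore bins the
product (1–25): 1–2 Very Low, 3–5 Low, 6–10 Moderate, 11–15 High, 16–25 Very
High. These defaults are a *reconstruction*, chosen so that the published
qualitative pattern is reproduced — a 3 × 3 product is Moderate, 4 × 5 and
above is Very High, susceptibility 3–4 with importance 1 stays Low — and
they are fully configurable (`sensitivity_bins()`).

### Spatial conventions

* All geometry is plain lon/lat (WGS84); at Mediterranean latitudes this is
  adequate for the membership and overlap decisions made here (no distances
  or true areas are reported). There is no reprojection engine.
* A pixel is a seagrass pixel iff it overlaps a seagrass polygon with
  positive area — regardless of coverage fraction, with no buffer.
* Cells join to EEZs by centroid containment (boundary inclusive); a
  centroid claimed by two countries resolves to the lexicographically
  smaller code, deterministically, with a warning.
* Pixels aggregate to cells by the **maximum** susceptibility of the cell's
  seagrass pixels — the precautionary choice, since the protocol scores
  patches but maps cells; `cell_aggregation = "mean"` (half-up rounded) is
  available.
* Temperature cubes are ingested from CF-style NetCDF in Kelvin and
  converted exactly (x − 273.15). The temperature variable spans the water
  column; the surface (shallowest) level is the intended input, consistent
  with the surface-based MHW literature.

## The synthetic-data generator

`synth_config()` and friends generate every pipeline input with known ground
truth: a daily cube over the full study years with planted events (a tent
shape rising from threshold + guard to the peak at the event midpoint, over
an annual sinusoidal baseline peaking in mid-August at 23.5 °C — below
threshold, so zero-event pixels are constructible); longitudinal EEZ bands
with one patch per country wholly inside a known pixel; catch tables whose
per-year deviations are mean-zero by construction so pooled means reproduce
the requested shares exactly; and coastline-risk tables.

In the default exact-recovery mode (noise SD 0, or noise clipped outside a
±0.5 °C guard band around the threshold) every planted metric is recovered
exactly, which is what the planted-parameter tests assert. What passing
those tests shows is that the detection/scoring machinery is correct — not
that real projection data behave like the generator: real cubes have
spatially correlated anomalies, events that straddle the season boundary,
sub-threshold near-misses, and missing data, of which only the last is
emulated (masked days). The end-to-end test geography (a 1° box, three
EEZ bands, designed susceptibility gradient 2/4/5, catch shares 50/30/20 %,
risk percentages 30/10/1 %) exercises every stage at desk scale: test
problem sizes (10×10 pixels or smaller, 1–10 years, hundreds of random
series for the detector-oracle equivalence) are desk scale by design: small
enough to iterate on freely, large enough to cover every branch and
boundary.

## Numerical choices and degenerate inputs

* Half-up rounding (`round_half_up()`) everywhere an integer class is looked
  up from a fractional value; base `round()` would round halves to even.
* The QDGC lattice snaps to integer-degree anchors with a 1e-9 tolerance so
  boxes that land exactly on lattice lines do not gain phantom cells.
* Degenerate polygons (fewer than three distinct vertices, zero area) are
  rejected at construction; explicit closing vertices and duplicated
  vertices are dropped.
* Zero-area bounding boxes yield empty grids; empty patch sets yield an
  empty selection with a warning rather than an error.
* Event runs are never merged or split across the season boundary.

## Limitations

* The fixed 24 °C threshold is a western-basin, precautionary choice; the
  tolerance of eastern and southern Mediterranean populations is likely
  higher. All thresholds are configuration, not code, for exactly this
  reason.
* The sensitivity bins are a reconstruction (see above), not the protocol's
  printed matrix.
* Only the surface temperature level is read; no depth averaging.
* GeoJSON is the only polygon format read or written (no shapefile driver).
* No cartography: outputs are data surfaces (CSV/GeoJSON), not styled maps.
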