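---
title: "Assessing complementarity of two freshwater monitoring networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing complementarity of two freshwater monitoring networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwcomplement)
```

## The question

Regulatory agencies monitor water quality on predefined station networks,
sampling on a fixed schedule; citizen-science programmes monitor wherever
volunteers choose to go, whenever they go there. `fwcomplement` quantifies
how the two efforts relate over a river catchment for a single determinand
(nitrate-N, mg/L as N):

* **Where and when do they sample?** Seasonal coverage scores on a hexagonal
  grid, per-cell overlap classes, and gap-fill cells where only the citizen
  programme achieved all-season coverage.
* **What do they sample?** Strahler stream order for running-water sites and
  the Ramsar pond/lake size split (8 ha) for still waters.
* **What do they measure?** Nitrate readings harmonized onto a seven-bin
  category scheme, compared between actors.
* **Are the differences real?** Pearson chi-squared association tests with
  Cramér's V effect sizes, adjusted-residual post-hoc comparisons with
  Bonferroni correction, and a Mann–Whitney rank test on still-water areas.

Throughout, the two actors are labelled `EA` (the agency) and `FWW` (the
citizen programme), but the labels are configurable.

## Coverage model

The catchment boundary is tessellated with regular flat-top hexagons of
edge length $s$ (default $s = 5$ km, cell area
$\tfrac{3\sqrt3}{2}s^2 \approx 65$ km²) on an axial $(q, r)$ lattice
anchored at the boundary's bounding-box corner. Cells intersecting the
boundary with positive area are kept whole — a cell straddling the boundary
still receives the points that fall in it. Point location is
nearest-centre search (the tessellation is the Voronoi diagram of its
centres); a point on a shared edge deterministically belongs to the cell
with the lexicographically smallest $(q, r)$.

A cell's **coverage score** for an actor is the number of distinct
seasons-of-year (meteorological convention: Mar–May, Jun–Aug, Sep–Nov,
Dec–Feb) represented by that actor's samples in the cell, 0–4. Counting
season-by-year combinations (0–12) is available via `by_year = TRUE` but is
not the default, because the score scale of interest runs 0 to 4. Winter is
labelled by the year of its December, so a window ending 31 December
truncates that winter exactly. Overlap per cell is **complete** (both
actors scored 4), **none** (season sets disjoint, including empty), else
**partial**; a **gap-fill** cell is one where the citizen actor scored 4
and the agency did not. Cells where both actors are absent are "none"
rather than a separate class. Percentages are reported at full precision
and rounded half-up, with all grid cells as denominator.

## Drainage model

Running-water sites are characterized by Strahler order derived from a D8
flow-direction raster (ESRI codes, 1 = E clockwise to 128 = NE). Flow
accumulation counts upstream cells *excluding* the cell itself, so
headwaters are 0, and the stream network is the cells at or above a
minimum-accumulation condition (default 50 cells). The convention is
configurable; the threshold applies to whichever count is chosen. Stream
cells are chained into segments broken at confluences and ordered by the
generalized Strahler rule (max of inflow orders, +1 when the max is shared
by two or more inflows).

Sites are snapped to the nearest stream-cell centre within `max_snap`
(default 200 m — rasters place channels only to cell precision, so a
generous snap radius is needed; ties break to the smallest segment id).
Points on the same segment within 50 m of each other (between snapped
points, planar distance) are pooled into one standardized site by
single-linkage clustering — chains are allowed, pooling is
order-independent, and names (`seg<id>-<k>`) run upstream to downstream.
Complete linkage is available via a flag for users who read "within 50 m of
each other" pairwise. Unsnappable points become flagged off-network
singleton sites and are excluded from the order table (logged, not
dropped silently).

## Nitrate harmonization

The field-kit scheme has bin edges 0.2, 0.5, 1, 2, 5, 10 mg/L (seven bins).
Bins are right-closed — a value equal to an interior edge falls in the
lower bin — consistent with the first label "<=0.2"; the convention at
interior edges is otherwise arbitrary and is documented rather than
configurable. Laboratory (continuous) records at a site are summarized by
the median (per site over the window, and per season and per grid cell ×
season-year, since both groupings are useful) and then categorized.
Below-detection-limit flags `"<x"` are read as the limit value `x` — a
conservative upper-bound convention, documented because the correct
treatment depends on the laboratory's reporting rules.

When one site mixes categorical and continuous records (the two actors here
never do; the path exists for pooled-network use), categorical readings
enter the median as their bin midpoints, with the open top bin represented
by a sentinel at 1.5× the last edge, which is above the last edge by
construction; mixed sites are flagged in the output.

## Association statistics

All contingency statistics are computed from their formulas. For an
$r \times c$ table of observed counts $O_{ij}$ with total $N$:
$E_{ij} = \text{row}_i \text{col}_j / N$,
$X^2 = \sum (O-E)^2/E$ with $(r-1)(c-1)$ degrees of freedom and no
continuity correction; Cramér's $V = \sqrt{X^2 / (N(\min(r,c)-1))}$;
adjusted residuals
$z_{ij} = (O_{ij}-E_{ij}) / \sqrt{E_{ij}(1-p_{i\cdot})(1-p_{\cdot j})}$
with two-sided normal p-values, Bonferroni-corrected by the number of
cells $r c$ (configurable to other comparison counts). Zero row/column
marginals are dropped with a warning and degrees of freedom recomputed.

The Mann–Whitney test uses midranks, $U_1 = n_1 n_2 + n_1(n_1+1)/2 - R_1$,
reports $U = \min(U_1, U_2)$, and takes p from exact enumeration when
$n_1 + n_2 \le 12$ with no ties, otherwise from the normal approximation
with tie-corrected variance and a 0.5 continuity correction. The
continuity-corrected approximation stays within 0.016 of the exact p over
every achievable $U$ at $n_1 = n_2 = 6$ (median deviation well under
0.01); the uncorrected approximation would deviate up to 0.07, which is
why the correction is on.

## The synthetic catchment generator

The generator exists so the full pipeline runs, and its statistical
behaviour can be tested, with no external data. It emulates the structure
the analysis assumes, not any particular river basin:

* **Terrain** is a random spanning-tree drainage over the raster grown by
  randomized Prim expansion from a single outlet. This guarantees an
  acyclic D8 field with one outlet and produces a dendritic network —
  many short branches feeding a backbone, Strahler orders typically 1–6 at
  the default scale — without any DEM processing. The boundary is the
  convex hull of the drained cells.
* **Scale**: the default raster is 200 × 200 cells of 500 m (a 100 km ×
  100 km catchment, about 10,000 km²), so the default 5 km grid yields
  roughly 150–250 hexagon cells and the 50-cell accumulation condition
  means 12.5 km² of drainage area, both comparable to a large lowland
  catchment monitored at national-agency density. At this scale sites are
  sparse relative to stream cells, which keeps site counts effectively
  multinomial — the regime the association tests assume.
* **Waterbodies**: non-overlapping regular polygons with log-normal areas
  (default meanlog −0.5, sdlog 2 on hectares: a median of ~0.6 ha and
  roughly one large (>8 ha) waterbody in ten, reflecting that ponds vastly
  outnumber lakes).
* **Actors**: site totals default to 691 agency and 870 citizen sites with
  3.6% and 17.9% on still waters respectively — the documented scale of
  the two campaigns. The agency places running-water sites uniformly over
  stream cells and prefers large still waters (weight 10:1); the citizen
  actor weights order-1 stream cells 5:1, small still waters 8:1, and its
  placement probability decays as $e^{-d/10\text{km}}$ with distance $d$
  to the nearest of four urban centres.
* **Season behaviour**: each site is visited in each season-year period
  with the actor's seasonal probability (agency 0.95 every season; citizen
  0.9/0.9/0.2/0.2 for spring/summer/autumn/winter). Citizen sites are
  additionally active only for a contiguous window of 4 season-year
  periods (about one year) with a uniform start — volunteers monitor a
  site for a limited spell, and single-day blitz events shorter still —
  while agency stations are permanent. Without this, three years of
  repeated 0.2-probability autumns would accumulate to near-certain
  autumn coverage in any cell with several citizen sites, and the
  all-season coverage contrast between the actors would vanish.
* **Nitrate**: log-scale linear model
  $\mu = \beta_0 + \beta_{\text{order}}(o-1) + \beta_{\text{small still}}
  \mathbb{1}[\text{small still}] + \delta_{\text{season}}$, value
  $= e^{\mu + \sigma\varepsilon}$. Defaults
  ($\beta_0 = \log 2$, $\beta_{\text{order}} = 0.15$,
  $\beta_{\text{small still}} = -1.5$, winter high / summer low offsets,
  $\sigma = 0.5$) encode concentrations that rise with stream order, drop
  in small still waters, and are positive and right-skewed. The model is
  structural — it is not calibrated to any real basin's values.

The agency actor emits continuous values; the citizen actor's values pass
through the category scheme, exactly as a colorimetric kit reports. A fixed
seed makes every draw reproducible; the emitted files (sample CSV, GeoJSON
boundary/waterbodies, ESRI ASCII D8, JSON manifest) are exactly the formats
the pipeline reads.

**What the generator does not emulate:** measurement error and kit/lab
disagreement, detection limits, spatial autocorrelation of nitrate beyond
the order/size/season structure, seasonal ponds drying out, volunteer
drop-out mid-window, and real road/population accessibility. Passing tests
therefore demonstrate that the pipeline recovers the biases the generator
encodes, not that any particular real-world dataset has them.

## What the tests establish

* **Oracle equivalence**: flow accumulation matches a graph-reachability
  oracle on random 20 × 20 rasters; Strahler orders match a recursive
  evaluation; chi-squared, adjusted residuals and U match direct formula
  evaluation and pair counting (1,000 and 200 random cases); hexagon
  location matches brute-force point-in-polygon over 1,000 points; clipped
  cell areas sum to the boundary area to 1e-6 relative.
* **Calibration**: the chi-squared test rejects at 5% ± 2% under simulated
  multinomial independence (1,000 tables of N = 500), and the end-to-end
  stream-order test — generator with *identical* actor configurations (400
  sites each), pooling, association — rejects at 5% ± 3% over 200 sampling
  replicates on a fixed catchment. Replicates re-draw the sampling layer
  rather than the terrain because the null concerns the sampling and
  testing chain; terrain regeneration would only add runtime.
* **Bias recovery**: with the default biased configuration, 50 seeded
  pipeline replicates flag citizen enrichment at order 1 and among small
  still waters (positive significant adjusted residuals after Bonferroni)
  in ≥ 90% of replicates, and the citizen actor's share of all-season
  cells sits far below the agency's in every replicate.

Problem sizes in the tests (20 × 20 oracle rasters, 200 null replicates on
one catchment, 50 bias replicates at the default scale) were chosen as the
smallest sizes at which the Monte-Carlo bands above are stable.

## Numerical and degenerate-input choices

* Geometry is planar throughout; coordinates must arrive in a projected,
  metre-unit CRS, whose identifier travels as sidecar metadata (GeoJSON
  itself mandates WGS84, which planar projected data cannot honour).
  Reprojection is deliberately out of scope.
* A hexagon cell belongs to the grid when its clipped area exceeds
  1e-12 s² — an area-based test, so boundary-touching cells with zero
  overlap are excluded deterministically.
* Exactly-8-ha still waters classify as small (ties-to-small; the
  published convention leaves the boundary unassigned), configurable.
* A value exactly on an interior nitrate bin edge falls in the lower bin.
* Degenerate association inputs (all-zero marginals, one surviving
  row/column) error after the documented drop-with-warning; an empty
  stream network warns and returns an empty forest; a cyclic D8 field
  errors naming a cell on the cycle.
* `sample.int` with weights performs sequential weighted draws; still-water
  site selection switches to replacement only when more sites are requested
  than positively-weighted waterbodies exist.

## Limitations

* Pooling distance is measured between snapped points, so on coarse
  rasters (cell size ≫ 50 m) pooling reduces to same-cell grouping; on
  fine rasters it approximates true along-bank pooling. This matches the
  raster-limited precision of site locations themselves.
* The 12-season (season × year) coverage variant is computed but none of
  the overlap classes use it.
* The generator's urban centres are points; real accessibility follows
  road networks.
* Exact (permutation/Fisher) tests are not provided for large tables;
  the chi-squared approximation is relied on at the table sizes the
  pipeline produces.
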