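---
title: "Climate-envelope screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-envelope screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climscreen)
```

## The screening problem

Collecting and physiologically testing wild provenances of woody plants is
slow, so a preliminary, desk-based screen is valuable: if a species'
occurrence records concentrate in the dry or cold margin of a genus' overall
climate space, that species is a candidate for drought or cold tolerance and
worth prioritising for controlled experiments. `climscreen` implements this
climate-envelope screen end to end. Two bioclimatic variables act as the
stress proxies:

* **PDQ** — precipitation of the driest quarter (mm), a drought-exposure
  proxy (WorldClim bioclim `bio17`);
* **MTCM** — minimum temperature of the coldest month (°C), a cold-exposure
  proxy (`bio6`).

The pipeline runs: occurrence cleaning → spatial thinning → raster
extraction → minimum-sample filter → Moran's I diagnostics → interspecific
nonparametric statistics → per-species profiles → hierarchical clustering →
percentile thresholds → strict classification → multi-percentile
sensitivity analysis → Mann–Whitney validation of the tolerant/nontolerant
split.

## The procedure, stage by stage

**Cleaning** (`read_occurrences`). Rows with blank species labels or
missing, unparseable or out-of-range coordinates are dropped and counted.
Coordinates exactly (0, 0) are kept by default (no zero-coordinate
heuristic); a strict mode drops them. No taxonomic synonym resolution is
attempted: labels are matched exactly after whitespace trimming.

**Thinning** (`thin_to_grid`). To damp uneven collection intensity, at most
one record per species is retained per 0.1° grid cell, chosen uniformly at
random within each occupied cell. Cells are half-open,
$[k\,c, (k+1)\,c)$ in each axis, with cell index $\lfloor x / c \rfloor$; a
boundary point belongs to the higher-index cell. Some convention is
mandatory here; this one is fixed and documented. Thinning is idempotent
and, because each species draws from its own derived random stream,
deterministic given the seed and unaffected by which other species are
present.

**Extraction** (`extract_at_points`, `link_climate`). Values are read from
the containing raster cell — no interpolation — matching the default
point-extraction behaviour of desktop GIS toolboxes. Records falling outside
the extent or on nodata cells are dropped and counted. Rasters are ESRI
ASCII grids; coordinates and rasters are assumed to share WGS84 and no
reprojection is performed.

**Minimum-sample filter** (`filter_min_specimens`). Species with fewer than
10 linked records after thinning are excluded (a species with exactly 10 is
kept). The order — clean, thin, link, drop missing climate, then filter —
matters, because climate-missing records can push a species below the
minimum.

**Spatial-bias diagnostics** (`morans_i`, `moran_qc`). Moran's I is computed
per species at 10, 20 and 50 km lag distances with binary distance-band
weights $w_{ij} = 1$ iff $0 < d_{ij} \le \text{lag}$ (great-circle,
haversine, Earth radius 6371.0088 km), no row standardisation:

$$I = \frac{n}{W} \frac{\sum_{ij} w_{ij}(x_i - \bar x)(x_j - \bar x)}
{\sum_i (x_i - \bar x)^2},\qquad E[I] = \frac{-1}{n-1},$$

with the variance under the normality assumption and a two-sided normal
p-value. Moran's I needs a variable, not just coordinates; this package
computes it on the extracted PDQ and MTCM values at the occurrence points,
an interpretation choice flagged here deliberately. Inverse-distance weights
and row standardisation are available behind arguments for comparison with
other tooling. QC failures (no pairs within a lag, constant values) are
reported in the table, not fatal: spatial autocorrelation here is a
reported check, not a gate.

**Interspecific statistics** (`shapiro_wilk`, `kruskal_wallis`,
`linear_fit_r2`). Pooled PDQ and MTCM values are tested for normality
(Shapiro–Wilk, valid for $3 \le n \le 5000$; larger pools are subsampled
reproducibly and the report notes it); being non-normal in practice, the
interspecific comparison uses the Kruskal–Wallis rank test with mid-ranks
and the standard tie correction, df = (number of species) − 1, chi-squared
upper-tail p. An ordinary least-squares fit of MTCM on PDQ across specimens
summarises how weakly the two stress axes are coupled (a poor linear fit
supports treating drought and cold screening as separate axes).

**Profiles and niche widths** (`build_profiles`). The species-level
indicator of tolerance is the **median** PDQ/MTCM across its records —
robust against the remaining sampling unevenness. Niche width is the range,
maximum − minimum of each variable per species; it is reported
descriptively alongside the candidate lists and plays no role in
classification.

**Clustering** (`cluster_species`). Species are clustered
agglomeratively on (median PDQ, median MTCM) with squared Euclidean
distance and the tree is cut into k = 5 groups. Two open choices are fixed
as follows and exposed as arguments:

* *Standardisation* defaults to ON: mm and °C are incommensurable, and
  raw-scale distances would be dominated by the precipitation axis
  (its numeric spread is an order of magnitude larger). Raw-scale
  clustering is available and can genuinely differ.
* *Linkage* defaults to between-groups average (a common statistics-package
  default for hierarchical clustering); Ward is available. Only the
  distance, not the linkage, is pinned by the method description this
  implements.

Profiles are sorted by species label before clustering, which makes the
result independent of input order; remaining equal-height merge ties follow
that label order. Clustering is descriptive context for the thresholds — it
groups species with similar water–heat conditions — and does not alter the
thresholds themselves.

**Thresholds and classification** (`derive_thresholds`,
`classify_species`). The drought threshold is the 25th percentile of the
species median-PDQ values; the cold threshold likewise for MTCM. The
quantile rule is linear interpolation at position $h = (n-1)q$ on the
sorted sample (`stats::quantile` type 7): an interpolating rule is what
produces sub-unit thresholds such as 0.925 °C from a set of species
medians; alternative rules are available via `quantile_type`.
Classification is **strict**: tolerant iff the species median is strictly
below the threshold, so a boundary species is nontolerant. Candidates are
ranked strongest → weakest by ascending median (driest/coldest first), ties
broken by species label — the ranking key is made explicit here because
"strongest to weakest" alone does not define one.

**Sensitivity and consistency** (`sensitivity_analysis`). Classification is
repeated at the 5th, 10th, 15th, 20th, 25th, 30th and 35th percentiles.
Because quantiles are monotone in the percentile and the comparison is
strict, tolerant sets **nest**: the set at percentile p is a subset of the
set at p′ > p. The consistency score of a species is the number of
scenarios in which it is tolerant (0–7); species with score ≥ 5 are "core"
candidates. Both the scenario list and the core rule are configurable
together. More stringent percentiles risk excluding genuinely tolerant
species; more inclusive ones admit marginal species — the reference
percentile trades those errors off, and the consistency score shows how
stable each candidate is against that choice.

**Validation** (`validate_separation`). The specimen-level values of the
relevant variable are compared between tolerant-species specimens and all
others with the two-sided Mann–Whitney U test: exact p by enumeration when
both groups have ≤ 50 observations and no ties, otherwise the normal
approximation with tie-corrected variance and continuity correction. A
fully tied pooled sample is treated as perfectly symmetric (U = n₁n₂/2,
p = 1) rather than undefined. No multiple-testing correction is applied
across scenarios (none is part of the procedure this implements).

## The synthetic-data module

`surface_config` / `gen_climate_grid` / `gen_species_pool` /
`gen_occurrences` / `simulate_study` generate a fully known study: smooth
climate surfaces, virtual species with bivariate Gaussian niches, and
occurrence records sampled from suitability. Every generator is a pure
function of (config, seed), with per-stage derived streams.

**Surfaces.** Each surface is `base + gradient × latitude + noise`, the
noise being white noise smoothed by a Gaussian kernel (correlation length 3
cells) and scaled to a target standard deviation — the simplest
controllable random field. Defaults emulate a subtropical study region on a
12° × 15° extent at 0.25° cells: MTCM runs ~ −4…11 °C along a latitudinal
gradient (1.2 °C per degree), PDQ has a 45–135 mm latitudinal trend with a
30 mm noise field. The PDQ noise amplitude is deliberately comparable to
its gradient span: dry patches then occur at many latitudes, the two
variables stay only weakly coupled at the specimen level (consistent with
the weak PDQ–MTCM linear fit expected of such data), and — critically — a
dry niche and a cold niche are distinct spatial targets. If both surfaces
were near-parallel latitudinal ramps, a species planted for drought but not
cold would face contradictory demands and its realised climate would drift
off its niche centre, making the planted labels unrecoverable in principle.
A configurable fraction of cells (2% by default) is nodata, exercising the
missing-climate path.

**Species.** A pool has 35 species; 9 are planted drought-tolerant and 9
planted cold-tolerant (the two subsets drawn independently, so overlap is
possible, as with real dual-tolerant species). Planted niche centres are
drawn uniformly on the landscape's 5th–20th percentile band of the matching
variable — strictly below the 25th percentile, with a deliberate margin so
that the planted label is well-defined ground truth rather than a coin flip
at the band boundary; non-planted centres are drawn from the landscape
interquartile range. Niche breadths default to σ_P = 8 mm and σ_T = 1.0 °C,
moderate relative to the landscape spread. Each species gets 30 occurrence
records by default; uneven sampling intensity is expressed through
`n_occurrences` only — no spatial collection bias is injected, mirroring a
dataset whose Moran diagnostics are unremarkable.

**Occurrences.** Valid cells are sampled with probability proportional to
$\exp\!\big(-\tfrac{(v_P-\mu_P)^2}{2\sigma_P^2}
 -\tfrac{(v_T-\mu_T)^2}{2\sigma_T^2}\big)$
and the record is placed uniformly inside the chosen cell.
`occurrence_cell_distribution` enumerates this discrete mixture exactly and
serves as the generator's analytic oracle in the tests.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: taxonomic misidentification and synonymy,
spatially biased collection effort (roads, herbaria catchments),
historical-biogeographic and dispersal constraints that decouple realised
from potential niches, non-climatic habitat loss, coordinate imprecision,
and elevational microclimate unresolved at the grid scale. Recovery of
planted species on synthetic pools demonstrates that the pipeline's
statistics and bookkeeping are correct, not that a 25th-percentile envelope
screen identifies physiologically tolerant species in nature.

## Numerical choices and degenerate inputs

* Quantiles: type 7 (linear interpolation) everywhere, configurable.
* Strict `<` at every threshold; boundary medians are nontolerant.
* Half-open raster cells and thinning cells; boundary points go to the
  higher-index cell.
* Ties: mid-ranks; Kruskal–Wallis H divided by the standard tie-correction
  factor; Mann–Whitney normal path uses tie-adjusted variance plus
  continuity correction.
* Degenerate inputs fail loudly with stage-named errors: constant samples
  (Shapiro–Wilk, Moran's I), empty groups, no pairs within a lag, zero
  total suitability, malformed raster headers.
* ASCII grids and occurrence CSVs are written at full double precision, so
  write-then-read round-trips are exact and re-running from intermediate
  files reproduces downstream results bit-for-bit.
* One master seed drives all stochastic stages through independent derived
  streams (per species, per surface, per stage), so changing one stage
  never perturbs another's draws.

## Problem sizes used in the test suite

The packaged checks run synthetic studies at the scale of the motivating
use case — 35 species, 9 + 9 planted, 30 records per species on a
48 × 60-cell landscape — with 20 replicate pools for recovery rates, 2000
replicates for null-calibration and Moran-expectation simulations, and
brute-force enumeration oracles up to pooled N = 8 (rank tests) and 42,525
set partitions (clustering). These sizes give Monte-Carlo errors a few
times smaller than the effects being checked while keeping a full run in
well under a minute.

## Known limitations

* Only two climate axes; no evapotranspiration, soil moisture or other
  ecologically relevant covariates.
* Presence-only reasoning: realised niches bound, but do not measure,
  physiological tolerance; candidates require experimental validation.
* The ESRI ASCII grid is the only raster format read natively; convert
  GeoTIFF layers upstream (e.g. `gdal_translate -of AAIGrid`).
* Species labels are taken at face value; apply taxonomic harmonisation
  before screening if the source mixes synonyms.
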