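---
title: "Methods: hotspot analysis of opioid-related EMS runs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hotspot analysis of opioid-related EMS runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Bystander naloxone reverses opioid overdoses, but only if a kit is at hand.
One community-level answer is publicly deployed naloxone (PDN): fixed kits
placed like AEDs at sites chosen from where overdoses actually occur. That
turns a public-health question into a spatial-statistics one, answered in
two stages on a city's opioid-related EMS run records:

1. **Do runs cluster at all?** A global test of the point pattern against
   complete spatial randomness (CSR).
2. **Where?** Local, density-based hotspot discovery, per-hotspot
   characterisation, and a coverage model for kits placed at hotspot
   centres.

`emsclust` implements the full chain — ingestion, deduplication, boundary
clipping, Ripley's K with Monte-Carlo envelopes, DBSCAN, cluster summaries,
and PDN coverage — plus a synthetic city generator, because real EMS
records are confidential and cannot ship with a package.

# Coordinates and geometry

Run coordinates arrive as WGS84/NAD83 longitude-latitude and are projected
onto a local planar system by a single equirectangular projection about the
window's reference point (sphere radius 6,371,000 m, configurable). Over a
city-scale extent (≤ 10 km) planar distances agree with great-circle
distances to within about 2 m — the same tolerance under which NAD83 and
WGS84 are interchangeable — so a full geodesy stack would add machinery
without adding accuracy. The projection validity window is ±0.5° around the
reference; points beyond it are rejected rather than silently distorted.

Membership of the city polygon uses even-odd ray crossing with one
documented convention: **points on the boundary count as inside** (within
10⁻⁶ m, absorbing projection round-trip float error). This makes clipping
stable for locations digitised exactly on the city line.

The edge-correction primitive — the fraction of a circle's circumference
inside the window — is computed numerically by testing equally spaced
angles (default resolution 720, i.e. 0.5° steps; error at most ~1/resolution
for windows whose edges are long relative to the arc step). An exact
arc-clipping alternative exists only for special windows; the numeric
version works for any polygon and is certified in the test suite against a
closed-form rectangle solution. Circles wholly in the interior short-circuit
to 1, which is also what makes the K estimator affordable: most pairs in a
city-interior pattern never touch the sampler.

# Global clustering: Ripley's K with envelopes

The K-function estimate uses the isotropic edge correction:

$$\hat K(r) = \frac{|W|}{n(n-1)} \sum_{i \neq j}
  \frac{\mathbf 1\{d_{ij} \le r\}}{e_{ij}},$$

where $e_{ij}$ is the fraction of the circle centred at point $i$ through
point $j$ lying inside $W$. Under CSR, $K(r) = \pi r^2$. Choices worth
stating:

* **Radius grid**: 128 equally spaced radii from 0 to $0.25\sqrt{|W|}$
  (~1,030 m for a 17 km² city). The upper bound is conventional and keeps
  correction weights stable; larger radii are refused with an error naming
  the bound.
* **Coincident points** (multiple runs at one address) contribute weight 1
  at every $r \ge 0$. The run-level pattern is the analysis target — demand,
  not geography — so duplicates are genuine signal. Passing unique
  locations instead gives the location-level pattern.
* **Weight cap**: a sampled arc fraction can be 0 only by numeric accident;
  it is floored at 1/resolution so no pair gets infinite weight.

Significance comes from a Monte-Carlo envelope: `nsim` CSR patterns of the
same $n$ in the same window, the pointwise min/max band for display, and a
global rank test on the variance-stabilised L-function,
$T = \max_r |\sqrt{\hat K(r)/\pi} - r|$, with
$p = (1 + \#\{T_{sim} \ge T_{obs}\})/(nsim + 1)$. With the shipped
`nsim = 999` the smallest attainable p is 0.001. The deviation statistic is
two-sided by default (a pattern can also be *too regular*); a one-sided
clustering-only variant and a raw-K variant are available by argument. The
test is exactly calibrated because observed and simulated curves use the
identical estimator, grid, and resolution — this exchangeability is checked
empirically in the acceptance suite (type-I error at $\alpha = 0.05$ over
200 CSR replicates).

**Numerical economy.** Envelope computations default to edge-correction
resolution 256 rather than 720: the resulting ≤ 0.4% weight error is far
below Monte-Carlo noise at any feasible `nsim`, and both sides of the test
use the same resolution, so calibration is unaffected while 999 simulations
at $n = 690$ finish in a few minutes on one core.

# Local clustering: DBSCAN

DBSCAN runs on run-level planar points with the inclusive neighbour
predicate $d \le \varepsilon$ and the **self-inclusive** `min_pts`
convention (a point counts in its own neighbourhood) — the convention of
the reference implementations; the two conventions differ by one and are
easy to conflate. Defaults are $\varepsilon = 200$ m and `min_pts = 3`.
Epsilon selection remains a judgement call on the sorted k-nearest-neighbour
distance plot (`knn_distances`); a maximum-curvature knee heuristic
(`knee_eps`) is offered but never applied automatically.

Because runs participate with multiplicity, a building with 76 runs is a
high-density core all by itself — exactly the behaviour needed for
single-address spikes. Clusters below `ceiling(min_fraction × total runs)`
runs (default 10%, giving 69 at 690 runs) are demoted to noise: a kit
serving a handful of runs is not worth a site.

Each kept cluster is classified **single-location** if its modal location
holds ≥ half the runs (ties between modal locations fall to
multi-location), else **multi-location**. Border points attach to the first
core cluster reaching them in input order; the core partition itself is
order-invariant (property-tested).

# Cluster characterisation

Per-cluster statistics follow fixed conventions:

* **Centroid and median centroid distance** use run-level points — they
  describe where demand concentrates, so multiplicity must count.
* **Convex-hull area** uses unique locations — geometry should not grow
  because one address got busier. (A single-location cluster yields a
  degenerate hull with area 0 rather than an error.) Both choices are
  switchable (`hull_on`, `centroid_on`).
* **Quantiles** are linear-interpolation (type 7) throughout; reported
  areas/distances round to 0.1 m²/0.1 m and percentages to 0.1.
* Demographic summaries exclude missing values; missingness is never
  imputed.

# PDN coverage model

One site per kept cluster: at the centroid for multi-location clusters
(covering the cluster's runs within a straight-line accessibility radius,
default 200 m — deliberately matched to $\varepsilon$), or inside the modal
building for single-location clusters (covering exactly the co-located
runs). The modal-location rule is the deliberate default because a kit
inside a building serves that building; a disc interpretation
(`modal_disc = TRUE`) is available for sensitivity analysis, and the two
can legitimately differ — a single-location cluster's centroid disc may
catch nearby non-modal runs that the in-building kit would not. Sites never
claim noise runs or other clusters' runs, so per-site counts sum to the
total without double counting. The model is intentionally naïve: no street
network, no travel-time, no optimal facility location — it estimates the
*potentially modifiable* run count, nothing more.

# The synthetic city

The generator states a world and sticks to it:

* an irregular 12-vertex polygon of exactly 17 km² (small-city footprint);
* a uniform (CSR) background of independent runs;
* Gaussian **two-level** clusters: `n_locations` location coordinates drawn
  from an isotropic normal (sd `sigma`, truncated to the window by
  resampling so counts stay exact), then `n_runs` assigned multinomially
  with every location getting at least one run. Two-level, because real
  hotspots mix few addresses with many runs — a one-level Gaussian cannot
  produce an 85-run cluster on 8 addresses;
* optionally a **spike**: many records at one exact coordinate;
* ages from a three-parameter shifted log-normal solved in closed form from
  a target median and IQR ($\gamma = (q_{25}q_{75} - m^2)/(q_{25} + q_{75}
  - 2m)$, falling back to $\gamma = 0$ when the solution is infeasible);
  sex as Bernoulli; independent missingness.

The shipped preset (`preset_paper_like()`) encodes the study-scale world:
690 runs = 328 background + clusters of 86/42, 191/81 and 9/7
(runs/locations) + a 76-run spike co-located with the third cluster; 61.8%
male; median age 36 (IQR 29–49) with the spike population older (median 43,
IQR 36.5–58.5); 7/690 missing sex and 13/690 missing age. Cluster sigmas
(82, 146, 40 m) were chosen once so median run-to-centroid distances land
near 100/170/20 m and are not tuned thereafter.

What the generator does **not** emulate: street networks and address text,
temporal dynamics, multi-run background locations (background runs are
i.i.d., so each occupies its own location — the synthetic city therefore has
more unique locations than a real one with the same run count), and any
spatial correlation in demographics beyond the spike override. A green
pipeline test on this world shows the machinery is correct, not that any
particular real city clusters.

**A background-absorption caveat.** A *uniform* background of 328 runs over
17 km² (~19 runs/km²) has a mean 3rd-nearest-neighbour distance around
230 m, uncomfortably close to ε = 200 m. DBSCAN on the preset therefore
still finds the three planted hotspots as the three filtered clusters, but
each absorbs a few dozen background runs as border points and short chains,
inflating cluster areas and dragging the adjusted Rand index against the
planted partition to ~0.75 — well below the ≥ 0.9 recovery that holds when
the background is ≤ 10% of runs (where it stays clearly subcritical). A
real city's off-hotspot demand clumps on streets and repeated addresses
with larger empty gaps, so the idealised uniform background is the
pessimistic case here. This is a property of the stated world, not of the
clustering code (DBSCAN is verified against a density-reachability oracle
independently), which is why the planted-partition recovery property is
stated, and tested, for low-background worlds only.

# Reproducibility

A single master seed fans out to fixed per-stage seeds
(`derive_seed(seed, stage)`), so the envelope simulation can be re-run
without re-running the generator. All artifacts are written with fixed
numeric formatting; re-running a config byte-reproduces them (tested).
Display jitter (Gaussian, default sd 5 m) exists only at the plotting
boundary and cannot leak into analysis artifacts (also tested).

# Known limitations

* The equirectangular projection is city-scale only; continental inputs are
  rejected, not handled.
* The numeric arc fraction costs O(resolution × edges) per boundary-touching
  pair; for windows with thousands of vertices, simplify the polygon first.
* DBSCAN is O(n²) in memory and time (distance matrix); fine for 10³–10⁴
  runs, wrong tool for 10⁶.
* Greedy in-order location merging can, in principle, split a chain of
  points spaced just under the tolerance; real coincidences are
  exact-coordinate duplicates, so this is theoretical (order-independence
  holds whenever pairwise distances avoid the tolerance boundary, which is
  property-tested).
* The coverage model's 200 m straight-line radius is an assumption about
  bystander behaviour, not a measurement; vary it and re-run.
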