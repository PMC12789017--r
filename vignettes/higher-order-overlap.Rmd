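---
title: "Higher-order spatial overlap: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher-order spatial overlap: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangecomplex)
```

## The problem

In animal groups with pronounced fission-fusion dynamics — spider monkeys are
the motivating case — individuals forage over partially overlapping seasonal
core ranges.  If a core range is read as the area an individual knows well,
then the overlap pattern of a *set* of ranges encodes how redundantly or
uniquely that set holds foraging knowledge, and where its members can meet to
share it.  Pairwise association networks cannot express this: the relevant
interactions are intrinsically multi-way.  `rangecomplex` represents them as
a filtered simplicial complex and summarises the structure with persistent
homology.

## The model

**Overlap ratio.** For a set $C = \{C_1,\dots,C_n\}$ of core-range polygons,
the spatial interaction strength is the multi-way Jaccard ratio

$$w \;=\; \frac{\mathrm{Area}\!\left(\bigcap_i C_i\right)}
              {\mathrm{Area}\!\left(\bigcup_i C_i\right)} \in [0,1].$$

$w$ is monotone under set inclusion ($S \subset T \Rightarrow w(T) \le
w(S)$), which both justifies apriori-style pruning during enumeration and
makes the downward-closure step below natural.

**Optimal overlap.** A set that shares information must balance redundancy
(a common area in which to meet) against uniqueness (areas worth telling the
others about).  Under the idealised assumptions of equal-sized ranges and
uniform, independent space use, the optimal ratio for $n$ individuals is

$$w^*_n = \frac{1}{n+1}.$$

The package carries a *candidate* objective realising this optimum,
$g_n(w) = w\,(1-w)^n$: meeting opportunity proportional to the redundant
fraction, shareable knowledge proportional to each member's unique fraction.
Its interior maximum is exactly $1/(n+1)$.  We state plainly that this
closed form is a stand-in chosen as the simplest function matching the
verbal argument; only the optimum itself is treated as authoritative, and
the tests verify the argmax numerically rather than the shape of $g$.

**Filtration index.** Each observed subset is scored by how far its $w$ sits
from the optimum for its size, via $w = f(\alpha)\, w^*_n$ with the linear
choice $f(\alpha) = 5 - \alpha$, i.e.

$$\alpha = 5 - w\,(n+1), \qquad \alpha \in [0, 5).$$

Consequences used throughout: a subset sitting exactly at its optimum maps
to $\alpha = 4$ for every $n$; $w = 0$ maps to $\alpha = 5$, outside the
filtration interval, so the filtration starts from isolated vertices; and
any $w > 0$ gives $\alpha \in (0,5)$.  The `alpha_mapping` object carries
$f$ explicitly so the sensitivity of the $\alpha$-axis to the choice of $f$
can be probed by swapping it — a different decreasing $f$ rescales the axis
but passes through the same nested family of complexes.  Note that at fixed
$w > 0$, $\alpha$ is strictly *decreasing* in $n$: the same ratio is more
redundant relative to $w^*_n$ when more individuals share it.

**Filtration and persistence.** Subsets with $w > 0$ and size at most
$n_{\max}$ become simplices entering at their $\alpha$; every face is pulled
down to the earliest entry of any recorded coface (downward closure), and
all vertices enter at $\alpha = 0$.  Persistent homology over GF(2) is
computed by column reduction of the boundary matrix in filtration order.
Each feature is a bar $[\alpha_{\mathrm{birth}}, \alpha_{\mathrm{death}})$;
$\beta_d(\alpha)$ counts bars alive at $\alpha$.  Holes of dimension $d$
read as pockets of uniquely held knowledge among subsets that nonetheless
retain meeting redundancy.

**Complementarity score.** The filtration complementarity index averages
weighted Betti numbers over the filtration interval:

$$\mathrm{FCI} = \left\langle \frac{\beta_0(\alpha)}{n_i}
  + \sum_{d \ge 1} (d+1)\,\beta_d(\alpha) \right\rangle_{[0,5)}.$$

Components are scaled by group size $n_i$ so larger samples do not score
higher automatically; higher-dimensional holes are up-weighted by $d+1$.
The upper limit of the sum is taken as $n_{\max}-1$, the largest dimension
the complex can contain.

**Centrality.** The maximal simplicial degree of a simplex is the number of
facets (maximal simplices) of the complex at $\alpha = 4$ that contain it,
a facet counting as containing itself.  The self-inclusive convention is a
deliberate choice: it keeps every degree at least 1 and makes a single-facet
complex perfectly flat (all degrees 1), so the nesting forced by downward
closure cannot by itself rank simplices — the no-bias property the measure
is meant to have.  A variant counting only strictly-larger facets would
instead assign facets degree 0 and is not what the package implements.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_max` | 6 | individuals | largest subset size admitted; beyond it, an always-shared central area would make every subset a simplex and the structure trivial |
| `eps_area` | 1e-4 | ha (= 1 m²) | boolean-op slivers below this are treated as empty so they cannot create spurious simplices |
| `centrality_alpha` | 4 | — | evaluate centrality among subsets at least as redundant as the optimum |
| `max_dim` | `n_max - 1` | — | highest homology dimension the complex supports |
| `hub_radius_m` | 100 | m | generator: radius of the central area shared by all |
| `lobe_offset_m` | 600 | m | generator: distance of each private lobe from the centre |
| `range_radius_mean_m` | 400 | m | generator: wet-season lobe radius; ×1.5 in the dry season |
| `jitter_sd_m` | 25 | m | generator: SD of lobe-centre and radius jitter |

## What the synthetic generator does and does not emulate

Each synthetic core range is the union of a hub disc at a common centre and
an individual disc offset on a ring, discretised as regular polygons.  This
reproduces, by construction, the two features the downstream mathematics
depends on: an all-way overlap (the hub — in the field data all core ranges
coincided in a small common area, which is exactly why $n_{\max}$ exists)
and a private lobe per individual (so unions strictly grow with every
member).  The dry/wet contrast is a single multiplicative factor 1.5 on the
lobe radius; the field data shows larger, less-overlapping dry-season
ranges, but no ratio is printed anywhere, so the factor is a free parameter
of the stated world, not an estimate.  Defaults (9–17 individuals per
season, ~1 km spatial scale, range areas of tens of hectares) were chosen
once to sit in the regime the field system occupies and are not tuned
against any test outcome.

What the generator does **not** emulate: movement, GPS sampling, or
utilisation-distribution estimation (ranges are taken as given polygons);
irregular range shapes, seasonal site fidelity, or the multimodality of
observed $w$ at fixed $n$.  A green test therefore establishes that the
*machinery* — areas, ratios, filtration, persistence, indices — is correct
on worlds with known answers; it does not establish any empirical claim
about real foraging systems.

## Numerical choices

* **Exact areas.** Intersection and union areas are computed by a vertical
  slab sweep (C++): between consecutive event abscissae (polygon vertices
  and proper pairwise segment crossings) every boolean combination of the
  polygons has a cross-section measure linear in $x$, so midpoint evaluation
  times slab width integrates exactly.  Events closer than $10^{-12}$
  (relative) are merged, and if a slab midpoint lands numerically on a
  vertex (odd crossing parity) the cross-section is re-evaluated at other
  interior fractions of the slab.  Axis-aligned test rectangles come out
  exact to the last bit.
* **Part semantics.** A geometry is a list of parts, each a list of rings
  under the even-odd rule (holes need no orientation convention); a point is
  inside the geometry if inside any part.  Parts may overlap — the generator
  relies on this for hub ∪ lobe.
* **Tie-breaking.** Simplices are ordered by (entry $\alpha$, dimension
  ascending, lexicographic vertex tuple), which guarantees faces precede
  cofaces at equal $\alpha$.
* **Zero-persistence pairs** (birth = death) are dropped.  This matters for
  the four-area worked example: the fourth area's interactions all enter in
  one final step, and the loops momentarily created by its edges are filled
  at the same $\alpha$, leaving exactly one persistent loop.
* **Censoring.** Features alive at the end are reported with death 5 and a
  `censored` flag; $\alpha$ ranges over $[0,5)$ only.
* **Inclusion at a query value is closed** (entry $\le \alpha$); whether the
  original analysis used closed or open inclusion at thresholds is unstated,
  and the choice only matters exactly at breakpoints.
* **FCI** is the exact integral of the Betti step functions divided by 5 —
  no quadrature.  The test-suite oracle is a fine-grid Riemann sum, which
  itself carries $O(\text{step})$ error at off-grid endpoints; tolerances
  reflect the oracle's error, not the implementation's.
* **cv** uses the sample (n−1) standard deviation; unspecified in the
  source, stated here once.

## Design decisions where the design was open

* **Single-individual records** are not emitted by the overlap enumeration;
  vertices are handled by the filtration at $\alpha = 0$.
* **Ring fixtures reject k = 3**: a 3-cycle's loop survives only if the one
  triangle happens to be absent, which is too fragile a contract for an
  oracle fixture; k ≥ 4 keeps the promise unconditional.
* **The four-area fixture** is engineered (exact rectangle arithmetic) so
  the fourth area's four-way simplex has the *smallest* $\alpha$ among its
  own interactions; downward closure then pulls all of them to one entry
  value, reproducing the intended "everything with D enters last, at once"
  behaviour without spawning extra loops.
* **Betti numbers have two independent routes** — reduction-based
  persistence and rank-based computation on the subcomplex
  ($\beta_d = \dim C_d - \mathrm{rank}\,\partial_d -
  \mathrm{rank}\,\partial_{d+1}$) — cross-checked at every breakpoint in the
  tests, plus the Euler-characteristic identity.
* **Geometry and TDA are implemented in-package** rather than delegated:
  no polygon-clipping or persistence library is available in the target
  environment, and the filtration machinery is the analytical core of the
  method in any case.  File formats use `jsonlite` (GeoJSON) and base CSV.

## Known limitations

* Coordinates must be planar/projected metres; no CRS handling or geodesic
  areas (the motivating system spans ~1 km).
* The boundary-matrix reduction is dense-column and pure R; complexes up to
  a few thousand simplices are comfortable, far beyond that is not the
  design point.
* `fit_sigmoid` is descriptive; with few distinct sizes or flat data it
  reports non-convergence rather than inventing parameters.
* The information-transfer objective is a labelled stand-in (see above);
  conclusions should rest on $w^*_n$ only.
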