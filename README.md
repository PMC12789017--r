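# rangecomplex

Higher-order spatial overlap analysis for seasonal core ranges.

Movement and behavioural ecologists studying fission-fusion societies (the
motivating system is a group of spider monkeys tracked across dry and wet
seasons) often have, per season, one core-range polygon per adult — the area
that individual knows well.  Pairwise overlap networks miss the essential
structure: knowledge is shared in subsets of two, three, four or more
individuals whose ranges jointly intersect.  `rangecomplex` treats those
subsets as the objects of interest:

1. **Overlap ratios.** For every subset of up to `n_max` ranges with a
   common intersection, the multi-way Jaccard ratio
   `w = Area(∩ C_i) / Area(∪ C_i)` is computed with exact planar boolean
   areas (a slab-sweep in C++; no geometry library required).
2. **Optimality scaling.** The theoretical optimum for an
   information-sharing set of `n` individuals is `w* = 1/(n+1)` — balancing
   redundant meeting area against uniquely known area.  Each subset's `w`
   is converted to a filtration index `α = 5 − w(n+1) ∈ [0, 5)`; subsets
   sitting exactly at their optimum land at `α = 4` for every `n`.
3. **Topology.** Subsets become simplices of a downward-closed filtered
   simplicial complex; persistent homology over GF(2) yields barcodes and
   Betti curves (`β₀` components, `β₁` loops, `β₂` voids, ...).  Holes are
   read as pockets of complementary — uniquely held but shareable —
   foraging knowledge.
4. **Summaries.** The filtration complementarity index
   `FCI = ⟨β₀(α)/nᵢ + Σ_{d≥1}(d+1)β_d(α)⟩_[0,5)` (exact step-function
   integral) and maximal simplicial degree centrality at `α = 4`, with a
   centrality-vs-size sigmoid fit.
5. **Synthetic data.** A generator producing hub-plus-lobe seasonal range
   sets (all-way shared hub, private lobes, dry ranges 1.5× wet), ring
   fixtures with prescribed topology, a four-rectangle worked example, and
   phenology tables for the fruit-abundance index
   `IFA_f = Σ_i Tf_i·DBH_i·Den_i`.

## Worked example

The four-rectangle fixture (`gen_four_area_example()`) is constructed so that A
and B overlap most, then B–C, then A–C — closing a loop that the triangle
ABC later fills — while D's small overlaps with everyone enter in a single
final step, completing the tetrahedron:

```r
library(rangecomplex)
fx <- gen_four_area_example()
tb <- enumerate_overlaps(fx, n_max = 4)
print(tb, digits = 4)
#> Overlap table: 11 subset(s), n_max = 4, eps_area = 0.0001 ha
#>    members n intersection_ha union_ha        w alpha
#> 1      A;B 2            0.60     2.40 0.250000 4.250
#> 2      A;C 2            0.15     1.87 0.080214 4.759
#> 3      A;D 2            0.04     3.36 0.011905 4.964
#> 4      B;C 2            0.55     2.47 0.222672 4.332
#> ...
#> 11 A;B;C;D 4            0.04     5.23 0.007648 4.962

bars <- compute_persistence(assign_entry_values(tb))
print(bars, digits = 4)
#> Persistence barcode: 5 bar(s), 1 connected component(s) at the end
#>   dimension birth death censored
#> 1         0 0.000 4.250    FALSE
#> 2         0 0.000 4.332    FALSE
#> 3         0 0.000 4.962    FALSE
#> 4         0 0.000 5.000     TRUE
#> 5         1 4.759 4.791    FALSE
```

Reading it: four components at `α = 0` (one per individual); B joins A at
`α = 4.25` (their edge enters), C at 4.33, D at 4.96; one component
persists.  The single dimension-1 bar is the A–B–C loop, born when the A–C
edge closes the cycle at 4.759 and filled by the triangle at 4.791.

```r
fci(lapply(0:3, function(d) betti_curve(bars, d)), n_individuals = 4,
    season = "dry")
#> FCI = 0.93982 (n = 4, dry)
```

The full pipeline (generate/read → overlaps → filtration → persistence →
FCI + centrality, with CSV/GeoJSON outputs and a checksummed JSON run
report) is one call:

```r
report <- run_pipeline(pipeline_config(
  generator = generator_config(n_individuals = 12, seed = 1,
                               season_label = "dry"),
  out_dir = "runs/dry2017"))
```

A command-line launcher with subcommands `generate`, `overlaps`,
`filtrate`, `persistence`, `metrics`, `phenology` and `run-all` is installed
at `inst/cli/rangecomplex`.

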