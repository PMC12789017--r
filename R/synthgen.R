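#' Configuration for the synthetic core-range generator
#'
#' The generator emulates the qualitative geometry of seasonal core ranges in
#' a fission-fusion group: every individual's range contains a small common
#' central area (the hub, e.g. shared sleeping sites near the centre of the
#' group range), plus an individual lobe pointing outward, so each individual
#' also holds a region no one else uses.  Dry-season ranges are larger than
#' wet-season ones by a fixed factor of 1.5 (the motivating data shows larger
#' dry-season ranges but prints no ratio).
#'
#' @param n_individuals number of ranges (>= 1; field seasons had 9-17).
#' @param seed integer seed; identical configs give identical output.
#' @param season_label `"dry"` or `"wet"`.
#' @param hub_radius_m radius of the shared central disc (m, > 0).
#' @param lobe_offset_m distance from the centre to each individual lobe
#'   centre (m, >= 0); 0 stacks all lobes on the hub centre.
#' @param range_radius_mean_m mean lobe radius in the wet season (m, > 0);
#'   multiplied by 1.5 for `season_label = "dry"`.
#' @param polygon_vertices vertices per disc (>= 8).
#' @param jitter_sd_m SD (m, >= 0) of Gaussian jitter applied to each lobe
#'   centre and radius; 0 gives perfectly regular geometry.
#' @param year integer year carried as metadata.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_individuals = 12L, seed = 1L,
                             season_label = c("dry", "wet"),
                             hub_radius_m = 100, lobe_offset_m = 600,
                             range_radius_mean_m = 400,
                             polygon_vertices = 64L, jitter_sd_m = 25,
                             year = 2017L) {
  season_label <- match.arg(season_label)
  stopifnot(n_individuals >= 1, n_individuals == floor(n_individuals),
            hub_radius_m > 0, lobe_offset_m >= 0, range_radius_mean_m > 0,
            polygon_vertices >= 8, jitter_sd_m >= 0)
  structure(list(n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed), season_label = season_label,
                 hub_radius_m = hub_radius_m, lobe_offset_m = lobe_offset_m,
                 range_radius_mean_m = range_radius_mean_m,
                 polygon_vertices = as.integer(polygon_vertices),
                 jitter_sd_m = jitter_sd_m, year = as.integer(year)),
            class = "generator_config")
}

DRY_SEASON_RADIUS_FACTOR <- 1.5

#' Generate synthetic seasonal core ranges
#'
#' Each range is the union of the common hub disc and an individual disc
#' offset from the centre at a per-individual angle, discretised as regular
#' polygons.  Consequences relied on downstream: the intersection of all
#' ranges contains the hub disc (an all-way overlap always exists), and for
#' `lobe_offset_m > 0` each range has a far lobe tip covered by no other.
#'
#' @param config a [generator_config()].
#' @return list of `n_individuals` [core_range()] objects.
#' @export
gen_core_ranges <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  radius <- config$range_radius_mean_m *
    if (config$season_label == "dry") DRY_SEASON_RADIUS_FACTOR else 1
  n <- config$n_individuals
  withr::with_seed(config$seed, {
    angles <- 2 * pi * (seq_len(n) - 1L) / n
    jx <- stats::rnorm(n, 0, config$jitter_sd_m)
    jy <- stats::rnorm(n, 0, config$jitter_sd_m)
    jr <- stats::rnorm(n, 0, config$jitter_sd_m)
    radii <- radius + jr
    if (any(radii <= 0))
      stop("degenerate config: jitter drove a lobe radius to <= 0")
    hub <- disc_ring(0, 0, config$hub_radius_m, config$polygon_vertices)
    lapply(seq_len(n), function(i) {
      cx <- config$lobe_offset_m * cos(angles[i]) + jx[i]
      cy <- config$lobe_offset_m * sin(angles[i]) + jy[i]
      lobe <- disc_ring(cx, cy, radii[i], config$polygon_vertices)
      core_range(sprintf("ind%02d", i),
                 mp_geom(list(list(hub), list(lobe))),
                 season = config$season_label, year = config$year)
    })
  })
}

#' Ring fixture: a k-cycle of pairwise overlaps with prescribed w
#'
#' Geometry-free fixture with known topology: exactly the k cyclic pairs
#' {i, i+1 mod k} overlap, each with ratio `w_pair`, and no subset of
#' size 3 or more is present.  Run through the filtration, persistence must report k
#' dimension-0 bars (k - 1 dying when the cycle edges enter) and exactly one
#' dimension-1 bar, censored (the loop is never filled).
#'
#' @param k cycle length, integer >= 4.  k = 3 is rejected: the fixture's
#'   contract (a never-filled loop) would hinge on the absence of one
#'   triangle, which is too fragile to serve as a test oracle.
#' @param w_pair common pairwise ratio, in (0, 1).
#' @return object of class `fixture_spec`: list with `members` (list of id
#'   pairs), `w` (per-subset ratios) and `universe` (vertex ids).
#' @export
gen_ring_fixture <- function(k, w_pair) {
  if (k < 4 || k != floor(k)) stop("k must be an integer >= 4")
  if (w_pair <= 0 || w_pair >= 1) stop("w_pair must lie in (0, 1)")
  ids <- sprintf("v%02d", seq_len(k))
  members <- lapply(seq_len(k), function(i) c(ids[i], ids[i %% k + 1L]))
  structure(list(members = members, w = rep(w_pair, k), universe = ids),
            class = "fixture_spec")
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf("Fixture spec: %d subset(s) over %d vertices\n",
              length(x$members), length(x$universe)))
  invisible(x)
}

#' Convert a fixture spec to an overlap table
#'
#' @param fixture a `fixture_spec`.
#' @param ... passed to [overlap_table_from_w()].
#' @return an `overlap_table`.
#' @export
fixture_table <- function(fixture, ...) {
  stopifnot(inherits(fixture, "fixture_spec"))
  overlap_table_from_w(fixture$members, fixture$w, ...)
}

#' The four-rectangle worked example
#'
#' Four core ranges A-D, exactly constructed so that
#' \eqn{w(AB) > w(BC) > w(AC) > w(ABC) >} every w involving D \eqn{> 0}:
#' the filtration adds the A-B edge first, then B-C, then A-C (closing a
#' 1-dimensional hole), then the triangle ABC (filling it).  D's overlaps
#' are tuned so the four-way simplex's alpha is below the alpha of every
#' D-involving edge and triangle; downward closure then pulls all of D's
#' simplices to a single entry value, so the complex finishes as the full
#' tetrahedron in one final step and no further persistent loop appears.
#'
#' @param season,year metadata for the generated ranges.
#' @return list of four [core_range()] objects with ids A, B, C, D.
#' @export
gen_four_area_example <- function(season = "dry", year = 2017L) {
  mk <- function(id, x1, x2, y1, y2)
    core_range(id, mp_geom(rect_ring(x1, x2, y1, y2)),
               season = season, year = year)
  list(mk("A",  0, 100,     0, 100),
       mk("B", 40, 140,     0, 200),
       mk("C", 85, 187,     0, 100),
       mk("D", 90,  98, -2950,  50))
}

#' Generate a synthetic phenology table
#'
#' Per-species, per-fortnight fruiting records: `Tf` (proportion of monitored
#' trees with fruit, Beta-distributed), `DBH` (summed diameter at breast
#' height of fruiting trees, cm, gamma) and `Den` (species density, trees per
#' ha, gamma, constant across periods for a species).
#'
#' @param n_species number of species (>= 1; the field protocol tracked 16).
#' @param n_periods number of fortnights (>= 1).
#' @param seed integer seed.
#' @return data frame with `n_species * n_periods` rows and columns
#'   `species`, `period`, `Tf`, `DBH`, `Den`.
#' @export
gen_phenology <- function(n_species = 16L, n_periods = 12L, seed = 1L) {
  stopifnot(n_species >= 1, n_periods >= 1)
  withr::with_seed(as.integer(seed), {
    species <- sprintf("sp%02d", seq_len(n_species))
    den <- stats::rgamma(n_species, shape = 2, scale = 2)
    df <- expand.grid(species = species, period = seq_len(n_periods),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df <- df[order(df$period, df$species), ]
    nrec <- nrow(df)
    df$Tf <- stats::rbeta(nrec, 1.5, 3)
    df$DBH <- stats::rgamma(nrec, shape = 2, scale = 30)
    df$Den <- den[match(df$species, species)]
    rownames(df) <- NULL
    df
  })
}
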