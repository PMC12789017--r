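test_that("gen_core_ranges is deterministic and validates its config", {
  cfg <- generator_config(n_individuals = 5, seed = 11)
  a <- gen_core_ranges(cfg)
  b <- gen_core_ranges(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_length(a, 5)
  expect_false(identical(
    serialize(gen_core_ranges(generator_config(n_individuals = 5, seed = 12)),
              NULL),
    serialize(a, NULL)))
  expect_error(generator_config(hub_radius_m = 0))
  expect_error(generator_config(range_radius_mean_m = -1))
  expect_error(generator_config(polygon_vertices = 4))
  # degenerate: jitter overwhelming the radius must fail, not return junk
  expect_error(gen_core_ranges(generator_config(
    n_individuals = 8, seed = 1, range_radius_mean_m = 1, jitter_sd_m = 50)),
    "degenerate")
})

test_that("identical-config individuals coincide exactly (w = 1)", {
  cfg <- generator_config(n_individuals = 2, seed = 3, lobe_offset_m = 0,
                          jitter_sd_m = 0)
  rg <- gen_core_ranges(cfg)
  iu <- intersection_union_ratio(lapply(rg, function(r) r$geometry))
  expect_equal(iu$w, 1)
})

test_that("all generated ranges share the hub; lobes give unique regions", {
  cfg <- generator_config(n_individuals = 4, seed = 5, hub_radius_m = 100,
                          lobe_offset_m = 600, range_radius_mean_m = 400)
  rg <- gen_core_ranges(cfg)
  geoms <- lapply(rg, function(r) r$geometry)
  iu <- intersection_union_ratio(geoms)
  expect_gt(iu$intersection_ha, 0)
  # cross-check the 4-way intersection against the rasterised oracle;
  # it must be close to the hub disc area (pi * 100^2 / 1e4 ha)
  grid <- oracle_grid_intersection_ha(geoms, res_m = 4)
  expect_equal(iu$intersection_ha, grid, tolerance = 0.02)
  expect_gt(iu$intersection_ha, 0.95 * pi * 100^2 / 1e4)
  # every individual keeps a private lobe tip: dropping it shrinks the union
  u_all <- intersection_union_ratio(geoms)$union_ha
  for (i in seq_along(geoms))
    expect_gt(u_all, intersection_union_ratio(geoms[-i])$union_ha)
})

test_that("dry-season ranges are 1.5x the wet radius", {
  dry <- gen_core_ranges(generator_config(n_individuals = 1, seed = 2,
                                          season_label = "dry",
                                          jitter_sd_m = 0,
                                          lobe_offset_m = 1e4))
  wet <- gen_core_ranges(generator_config(n_individuals = 1, seed = 2,
                                          season_label = "wet",
                                          jitter_sd_m = 0,
                                          lobe_offset_m = 1e4))
  # lobe far from hub: areas are hub + disc; subtract hub to compare radii
  hub_ha <- polygon_area(mp_geom(disc_ring(0, 0, 100, 64)))
  a_dry <- polygon_area(dry[[1]]$geometry) - hub_ha
  a_wet <- polygon_area(wet[[1]]$geometry) - hub_ha
  expect_equal(a_dry / a_wet, 1.5^2, tolerance = 1e-9)
})

test_that("gen_ring_fixture has the promised shape and rejects k < 4", {
  fx <- gen_ring_fixture(4, 0.3)
  expect_length(fx$members, 4)
  expect_true(all(lengths(fx$members) == 2))
  expect_equal(fx$w, rep(0.3, 4))
  expect_length(gen_ring_fixture(6, 0.2)$members, 6)
  expect_error(gen_ring_fixture(3, 0.3))
  expect_error(gen_ring_fixture(5, 0))
  expect_error(gen_ring_fixture(5, 1))
})

test_that("ring fixture persistence: one censored loop, k-1 merging components", {
  for (k in c(4L, 6L)) {
    w_pair <- if (k == 4L) 0.3 else 0.2
    cx <- assign_entry_values(fixture_table(gen_ring_fixture(k, w_pair)))
    bars <- compute_persistence(cx)
    d0 <- bars[bars$dimension == 0, ]
    d1 <- bars[bars$dimension == 1, ]
    expect_equal(nrow(d0), k)
    expect_equal(sum(!d0$censored), k - 1L)
    expect_equal(nrow(d1), 1L)
    expect_true(d1$censored)
    expect_equal(d1$birth, 5 - 3 * w_pair)
    # oracle: once all pairs entered, the k-cycle has beta1 = 1
    keys <- names(cx$entries)
    expect_equal(oracle_betti(keys, 1L), 1L)
    expect_equal(oracle_betti(keys, 0L), 1L)
  }
})

test_that("four-area fixture reproduces the worked example's entry order", {
  fx <- gen_four_area_example()
  expect_equal(vapply(fx, function(r) r$individual_id, ""),
               c("A", "B", "C", "D"))
  g <- four_area_geoms()
  w_of <- function(ids) intersection_union_ratio(g[ids])$w
  w_ab <- w_of(c("A", "B")); w_bc <- w_of(c("B", "C"))
  w_ac <- w_of(c("A", "C")); w_abc <- w_of(c("A", "B", "C"))
  expect_gt(w_ab, w_bc)
  expect_gt(w_bc, w_ac)
  expect_gt(w_ac, w_abc)
  d_subsets <- list(c("A","D"), c("B","D"), c("C","D"), c("A","B","D"),
                    c("A","C","D"), c("B","C","D"), c("A","B","C","D"))
  for (s in d_subsets) {
    ws <- w_of(s)
    expect_gt(ws, 0)
    expect_lt(ws, w_abc)
  }
  # every area intersects at least one other
  for (id in names(g))
    expect_true(any(vapply(setdiff(names(g), id), function(o)
      intersection_union_ratio(g[c(id, o)])$intersection_ha > 0, TRUE)))
  # the 4-way intersection is nonzero: final complex is the full tetrahedron
  expect_gt(w_of(c("A", "B", "C", "D")), 0)
})

test_that("gen_phenology: cardinality, ranges, determinism", {
  ph <- gen_phenology(16, 12, seed = 9)
  expect_equal(nrow(ph), 192)
  expect_true(all(ph$Tf >= 0 & ph$Tf <= 1))
  expect_true(all(ph$DBH > 0))
  expect_true(all(ph$Den > 0))
  expect_identical(ph, gen_phenology(16, 12, seed = 9))
  expect_false(identical(ph, gen_phenology(16, 12, seed = 10)))
  expect_false(anyDuplicated(ph[c("species", "period")]) > 0)
})
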