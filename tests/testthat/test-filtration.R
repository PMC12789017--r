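test_that("assign_entry_values pulls faces down to satisfy closure", {
  tb <- overlap_table_from_w(
    list(c("A", "B"), c("A", "B", "C")),
    # w chosen so alpha(ABC) < alpha(AB): alpha = 5 - w(n+1)
    c(2 / 3, 0.625), n_max = 3)
  expect_equal(stats::setNames(tb$alpha, tb$members),
               c("A;B" = 3.0, "A;B;C" = 2.5))
  cx <- assign_entry_values(tb)
  e <- cx$entries
  expect_equal(e[["A;B"]], 2.5)   # pulled down by its coface
  expect_equal(e[["A;C"]], 2.5)
  expect_equal(e[["B;C"]], 2.5)
  expect_equal(e[["A;B;C"]], 2.5)
  expect_equal(unname(e[c("A", "B", "C")]), c(0, 0, 0))

  tb2 <- overlap_table_from_w(list(c("A", "B")), w = 0.4, n_max = 2)
  cx2 <- assign_entry_values(tb2, vertex_universe = c("A", "B", "Z"))
  expect_equal(cx2$entries[["A;B"]], 5 - 0.4 * 3)
  expect_equal(unname(cx2$entries[c("A", "B", "Z")]), c(0, 0, 0))
  expect_error(assign_entry_values(tb, vertex_universe = c("A", "B")),
               "missing ids")
  expect_error(assign_entry_values(tb, n_max = 2), "n_max")
})

test_that("closure invariant holds on random tables (exhaustive face check)", {
  for (seed in 1:25) {
    cx <- assign_entry_values(random_overlap_table(seed))
    e <- cx$entries
    for (key in names(e)) {
      v <- strsplit(key, ";")[[1]]
      if (length(v) == 1L) next
      for (i in seq_along(v)) {
        fkey <- paste(v[-i], collapse = ";")
        expect_false(is.na(e[fkey]))
        expect_lte(e[[fkey]], e[[key]] + 1e-12)
      }
    }
  }
})

test_that("persistence of the hand-reduced triangle example", {
  # entry values set directly (outside the w-image of pairs, which is [2, 5))
  cx <- rangecomplex:::new_filtered_complex(
    c(a = 0, b = 0, c = 0, "a;b" = 1, "b;c" = 2, "a;c" = 3, "a;b;c" = 4),
    vertices = c("a", "b", "c"), n_max = 3)
  bars <- compute_persistence(cx)
  d0 <- bars[bars$dimension == 0, ]
  expect_equal(nrow(d0), 3)
  expect_equal(sort(d0$death[!d0$censored]), c(1, 2))
  expect_equal(sum(d0$censored), 1)
  d1 <- bars[bars$dimension == 1, ]
  expect_equal(nrow(d1), 1)
  expect_equal(c(d1$birth, d1$death), c(3, 4))
  expect_false(d1$censored)
})

test_that("compute_persistence rejects a closure-violating complex", {
  cx <- assign_entry_values(random_overlap_table(3))
  broken <- cx
  k2 <- names(broken$entries)[vapply(names(broken$entries), function(k)
    length(strsplit(k, ";")[[1]]), 0L) == 2L][1]
  broken$entries[[k2]] <- 6   # edge now enters after its cofaces
  expect_error(compute_persistence(broken), "closure")
})

test_that("betti_at on the solid and hollow tetrahedron", {
  ids <- c("p", "q", "r", "s")
  subsets <- unlist(lapply(2:4, function(k)
    utils::combn(ids, k, simplify = FALSE)), recursive = FALSE)
  solid <- assign_entry_values(
    overlap_table_from_w(subsets, rep(0.1, length(subsets)), n_max = 4))
  expect_equal(betti_at(solid, 5, 0), 1)
  expect_equal(betti_at(solid, 5, 1), 0)
  expect_equal(betti_at(solid, 5, 2), 0)
  hollow_sets <- subsets[lengths(subsets) <= 3]
  hollow <- assign_entry_values(
    overlap_table_from_w(hollow_sets, rep(0.1, length(hollow_sets)),
                         n_max = 3))
  expect_equal(betti_at(hollow, 5, 2), 1)   # boundary of a 3-ball: S^2
  expect_equal(betti_at(hollow, 5, 1), 0)
  expect_equal(betti_at(hollow, 5, 0), 1)
})

test_that("betti_curve agrees with direct recounts and with betti_at", {
  bars <- data.frame(dimension = c(0, 0), birth = c(0, 0), death = c(1, 5),
                     censored = c(FALSE, TRUE))
  cv <- betti_curve(bars, 0)
  expect_equal(cv$alpha, c(0, 1))
  expect_equal(cv$value, c(2, 1))
  single <- data.frame(dimension = 0, birth = 0, death = 5, censored = TRUE)
  cv1 <- betti_curve(single, 0)
  expect_equal(cv1$value, 1)
  expect_equal(betti_curve(single, 1)$value, 0)
})

test_that("reduction persistence matches rank-based Betti at all breakpoints", {
  for (seed in 1:30) {
    cx <- assign_entry_values(random_overlap_table(seed))
    bars <- compute_persistence(cx)
    breaks <- sort(unique(unname(cx$entries)))
    max_d <- cx$n_max - 1L
    curves <- lapply(0:max_d, function(d) betti_curve(bars, d))
    for (a in breaks) {
      for (d in 0:max_d) {
        from_bars <- rangecomplex:::betti_curve_at(curves[[d + 1L]], a)
        expect_equal(from_bars, betti_at(cx, a, d),
                     info = sprintf("seed %d, alpha %.4f, dim %d", seed, a, d))
        # fully independent oracle on the subcomplex
        keys <- names(cx$entries)[unname(cx$entries) <= a]
        expect_equal(from_bars, oracle_betti(keys, d),
                     info = sprintf("oracle seed %d, alpha %.4f, dim %d",
                                    seed, a, d))
      }
    }
  }
})

test_that("Euler characteristic identity holds at every filtration step", {
  for (seed in c(2, 8, 14)) {
    cx <- assign_entry_values(random_overlap_table(seed))
    bars <- compute_persistence(cx)
    dims_all <- vapply(names(cx$entries), function(k)
      length(strsplit(k, ";")[[1]]) - 1L, 0L)
    curves <- lapply(0:(cx$n_max - 1L), function(d) betti_curve(bars, d))
    for (a in sort(unique(unname(cx$entries)))) {
      entered <- unname(cx$entries) <= a
      chi_simplices <- sum((-1)^dims_all[entered])
      chi_betti <- sum(vapply(seq_along(curves), function(i)
        (-1)^(i - 1) * rangecomplex:::betti_curve_at(curves[[i]], a), 0))
      expect_equal(chi_simplices, chi_betti)
    }
  }
})

test_that("a disconnected final complex keeps several censored dim-0 bars", {
  tb <- overlap_table_from_w(list(c("a", "b"), c("c", "d")), c(0.3, 0.2),
                             n_max = 2)
  cx <- assign_entry_values(tb, vertex_universe = c("a", "b", "c", "d", "e"))
  bars <- compute_persistence(cx)
  expect_equal(attr(bars, "n_components"), 3)
})
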