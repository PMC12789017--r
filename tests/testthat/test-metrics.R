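curve0 <- function(alpha, value, dim = 0)
  structure(list(dimension = dim, alpha = alpha, value = value),
            class = "betti_curve")

test_that("FCI closed-form examples", {
  # beta0 constant 1, n = 1: FCI = 1
  r <- fci(list(curve0(0, 1L)), n_individuals = 1)
  expect_equal(r$value, 1)
  # beta0 constant 1, one dim-1 bar on [2, 4), n = 4: 1/4 + 2 * (2/5)
  r2 <- fci(list(curve0(0, 1L),
                 curve0(c(0, 2, 4), c(0L, 1L, 0L), dim = 1)),
            n_individuals = 4)
  expect_equal(r2$value, 1.05)
  expect_error(fci(list(curve0(0, 1L, dim = 1)), 4), "dimension-0")
})

test_that("FCI matches the fine-grid Riemann oracle on random barcodes", {
  for (seed in c(4, 9, 17)) {
    cx <- assign_entry_values(random_overlap_table(seed))
    bars <- compute_persistence(cx)
    curves <- lapply(0:(cx$n_max - 1L), function(d) betti_curve(bars, d))
    r <- fci(curves, length(cx$vertices))
    # the left-Riemann oracle itself has O(step) error at bar endpoints not
    # on the grid, so allow that here; exact agreement to 1e-6 is asserted
    # on grid-aligned barcodes in test-acceptance.R
    expect_lt(abs(r$value - oracle_riemann_fci(bars, length(cx$vertices))),
              1e-4)
  }
})

test_that("FCI monotonicity: dropping or shortening bars never raises it", {
  cx <- assign_entry_values(random_overlap_table(6))
  bars <- compute_persistence(cx)
  n_i <- length(cx$vertices)
  val <- function(b) fci(lapply(0:(cx$n_max - 1L), function(d)
    betti_curve(b, d)), n_i)$value
  base <- val(bars)
  hi <- which(bars$dimension >= 1)
  if (length(hi)) {
    expect_lte(val(bars[-hi[1], ]), base)
    shorter <- bars
    shorter$death[hi[1]] <- (shorter$birth[hi[1]] + shorter$death[hi[1]]) / 2
    shorter$censored[hi[1]] <- FALSE
    expect_lte(val(shorter), base)
  }
  # invariance under bar reordering
  expect_equal(val(bars[sample(nrow(bars)), ]), base)
})

test_that("maximal_simplices finds facets", {
  abc <- assign_entry_values(overlap_table_from_w(
    list(c("A", "B"), c("A", "C"), c("B", "C"), c("A", "B", "C")),
    c(0.5, 0.5, 0.5, 0.4), n_max = 3))
  expect_equal(maximal_simplices(abc, 5), "A;B;C")
  abc_cd <- assign_entry_values(overlap_table_from_w(
    list(c("A", "B"), c("A", "C"), c("B", "C"), c("A", "B", "C"),
         c("C", "D")),
    c(0.5, 0.5, 0.5, 0.4, 0.3), n_max = 3))
  expect_equal(maximal_simplices(abc_cd, 5), c("A;B;C", "C;D"))
  # brute-force pairwise-containment oracle on random complexes
  for (seed in c(5, 11)) {
    cx <- assign_entry_values(random_overlap_table(seed))
    keys <- names(cx$entries)
    vs <- strsplit(keys, ";")
    brute <- keys[vapply(seq_along(keys), function(i)
      !any(vapply(seq_along(keys), function(j)
        i != j && length(vs[[j]]) > length(vs[[i]]) &&
          all(vs[[i]] %in% vs[[j]]), TRUE)), TRUE)]
    expect_equal(maximal_simplices(cx, 5), sort(brute))
  }
})

test_that("maximal simplicial degree centrality on the worked examples", {
  abc_cd <- assign_entry_values(overlap_table_from_w(
    list(c("A", "B"), c("A", "C"), c("B", "C"), c("A", "B", "C"),
         c("C", "D")),
    c(0.5, 0.5, 0.5, 0.4, 0.3), n_max = 3))
  rec <- maximal_degree_centrality(abc_cd, alpha = 5)
  deg <- stats::setNames(rec$degree, rec$simplex)
  expect_equal(deg[["C"]], 2)       # in facets ABC and CD
  expect_equal(deg[["A;B"]], 1)
  expect_equal(deg[["C;D"]], 1)
  expect_equal(deg[["A"]], 1)

  # single facet ABCD: all 15 faces have degree exactly 1 (no closure bias)
  sets <- unlist(lapply(2:4, function(k)
    utils::combn(c("A", "B", "C", "D"), k, simplify = FALSE)),
    recursive = FALSE)
  solid <- assign_entry_values(
    overlap_table_from_w(sets, rep(0.15, length(sets)), n_max = 4))
  rec2 <- maximal_degree_centrality(solid, alpha = 5)
  expect_equal(nrow(rec2), 15)
  expect_true(all(rec2$degree == 1))

  # disjoint edges: every vertex and edge has degree 1
  disj <- assign_entry_values(overlap_table_from_w(
    list(c("A", "B"), c("C", "D")), c(0.3, 0.3), n_max = 2))
  rec3 <- maximal_degree_centrality(disj, alpha = 5)
  expect_true(all(rec3$degree == 1))

  # empty subcomplex warns
  empty <- rangecomplex:::new_filtered_complex(
    c(x = 3), vertices = "x", n_max = 2)
  expect_warning(out <- maximal_degree_centrality(empty, alpha = 1), "empty")
  expect_equal(nrow(out), 0)
})

test_that("centrality is invariant under vertex relabelling", {
  tb <- random_overlap_table(13)
  cx <- assign_entry_values(tb)
  rec <- maximal_degree_centrality(cx, alpha = 5)
  # permute labels
  ids <- cx$vertices
  withr::with_seed(1, perm <- stats::setNames(sample(ids), ids))
  mem <- lapply(strsplit(tb$members, ";"), function(v) unname(perm[v]))
  cx2 <- assign_entry_values(
    overlap_table_from_w(mem, tb$w, n_max = attr(tb, "n_max")))
  rec2 <- maximal_degree_centrality(cx2, alpha = 5)
  relabel <- vapply(strsplit(rec$simplex, ";"), function(v)
    paste(sort(unname(perm[v])), collapse = ";"), "")
  expect_equal(stats::setNames(rec2$degree, rec2$simplex)[sort(relabel)],
               stats::setNames(rec$degree, relabel)[sort(relabel)])
})

test_that("centrality_by_size groups and conserves records", {
  sets <- unlist(lapply(2:4, function(k)
    utils::combn(c("A", "B", "C", "D"), k, simplify = FALSE)),
    recursive = FALSE)
  solid <- assign_entry_values(
    overlap_table_from_w(sets, rep(0.15, length(sets)), n_max = 4))
  rec <- maximal_degree_centrality(solid, alpha = 5)
  s <- centrality_by_size(rec)
  expect_equal(s$size, 1:4)
  expect_true(all(s$mean == 1))
  expect_equal(sum(s$count), nrow(rec))
  # ring: all 4 edges are facets (degree 1), vertices lie in 2 facets
  ring <- assign_entry_values(fixture_table(gen_ring_fixture(4, 0.3)))
  rrec <- maximal_degree_centrality(ring, alpha = 5)
  rs <- centrality_by_size(rrec)
  expect_equal(rs$mean[rs$size == 1], 2)
  expect_equal(rs$mean[rs$size == 2], 1)
})

test_that("fit_sigmoid recovers known parameters and degrades gracefully", {
  withr::with_seed(7, {
    s <- rep(1:9, each = 8)
    c_true <- 30 / (1 + exp(-1.2 * (s - 4)))
    obs <- c_true + stats::rnorm(length(s), 0, 0.5)
  })
  fit <- fit_sigmoid(s, obs)
  expect_true(fit$converged)
  expect_equal(fit$L, 30, tolerance = 0.1)
  expect_equal(fit$k, 1.2, tolerance = 0.1)
  expect_equal(fit$s0, 4, tolerance = 0.1)
  expect_lte(fit$rss, fit$rss_constant)
  # constant data: either flagged as non-converged or k ~ 0
  flat <- fit_sigmoid(1:6, rep(5, 6))
  expect_true(!flat$converged || abs(flat$k) < 1e-3)
  expect_error(fit_sigmoid(c(1, 1, 2, 2), c(1, 2, 3, 4)), "distinct")
})
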