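# Independent oracles; deliberately avoid the package's own code paths.

# even-odd point-in-geometry test (ray casting), vectorised over points
oracle_inside <- function(px, py, geom) {
  inside <- rep(FALSE, length(px))
  for (part in geom$parts) {
    part_in <- rep(FALSE, length(px))
    for (ring in part) {
      n <- nrow(ring)
      x <- ring[, 1]; y <- ring[, 2]
      j <- c(n, seq_len(n - 1L))
      for (i in seq_len(n)) {
        xi <- x[i]; yi <- y[i]; xj <- x[j[i]]; yj <- y[j[i]]
        cross <- ((yi > py) != (yj > py)) &
          (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
        part_in <- xor(part_in, cross)
      }
    }
    inside <- inside | part_in
  }
  inside
}

# Monte-Carlo area of a geometry (hectares)
oracle_mc_area_ha <- function(geom, n = 1e6, seed = 42) {
  allv <- do.call(rbind, unlist(geom$parts, recursive = FALSE))
  xr <- range(allv[, 1]); yr <- range(allv[, 2])
  withr::with_seed(seed, {
    px <- stats::runif(n, xr[1], xr[2])
    py <- stats::runif(n, yr[1], yr[2])
  })
  mean(oracle_inside(px, py, geom)) * diff(xr) * diff(yr) / 1e4
}

# rasterised area (hectares) of the common intersection of geometries
oracle_grid_intersection_ha <- function(geoms, res_m = 5) {
  allv <- do.call(rbind, unlist(lapply(geoms, function(g)
    unlist(g$parts, recursive = FALSE)), recursive = FALSE))
  xs <- seq(min(allv[, 1]) + res_m / 2, max(allv[, 1]), by = res_m)
  ys <- seq(min(allv[, 2]) + res_m / 2, max(allv[, 2]), by = res_m)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inside <- rep(TRUE, length(gx))
  for (g in geoms) {
    inside <- inside & oracle_inside(gx, gy, g)
    if (!any(inside)) break
  }
  sum(inside) * res_m^2 / 1e4
}

# GF(2) matrix rank by plain elimination (independent of the package's)
oracle_gf2_rank <- function(m) {
  if (length(m) == 0L || nrow(m) == 0L || ncol(m) == 0L) return(0L)
  m <- m %% 2L
  r <- 0L
  for (col in seq_len(ncol(m))) {
    if (r >= nrow(m)) break
    piv <- which(m[(r + 1L):nrow(m), col] == 1L)
    if (!length(piv)) next
    piv <- piv[1L] + r
    tmp <- m[r + 1L, ]; m[r + 1L, ] <- m[piv, ]; m[piv, ] <- tmp
    for (i in seq_len(nrow(m))) {
      if (i != r + 1L && m[i, col] == 1L)
        m[i, ] <- (m[i, ] + m[r + 1L, ]) %% 2L
    }
    r <- r + 1L
  }
  r
}

# Betti number of an explicit simplex list (character keys "a;b;c"), by
# dim C_d - rank d_d - rank d_{d+1}
oracle_betti <- function(keys, d) {
  vs <- strsplit(keys, ";", fixed = TRUE)
  dims <- lengths(vs) - 1L
  kd <- keys[dims == d]
  if (!length(kd)) return(0L)
  boundary <- function(dd) {
    lo <- keys[dims == dd - 1L]; hi <- keys[dims == dd]
    if (!length(lo) || !length(hi)) return(NULL)
    m <- matrix(0L, length(lo), length(hi), dimnames = list(lo, hi))
    for (h in hi) {
      v <- strsplit(h, ";", fixed = TRUE)[[1]]
      for (i in seq_along(v))
        m[paste(v[-i], collapse = ";"), h] <- 1L
    }
    m
  }
  rk1 <- if (d == 0L) 0L else oracle_gf2_rank(boundary(d))
  b2 <- boundary(d + 1L)
  rk2 <- if (is.null(b2)) 0L else oracle_gf2_rank(b2)
  length(kd) - rk1 - rk2
}

# random but valid overlap table (monotone w) on a small vertex set
random_overlap_table <- function(seed, n_vertices = NULL, n_subsets = NULL,
                                 n_max = 5L) {
  withr::with_seed(seed, {
    if (is.null(n_vertices)) n_vertices <- sample(4:8, 1)
    if (is.null(n_subsets)) n_subsets <- sample(5:15, 1)
    ids <- letters[seq_len(n_vertices)]
    subs <- list(); ws <- numeric()
    for (i in seq_len(n_subsets)) {
      k <- sample(2:min(n_max, n_vertices), 1)
      s <- sort(sample(ids, k))
      key <- paste(s, collapse = ";")
      if (key %in% vapply(subs, paste, "", collapse = ";")) next
      subs[[length(subs) + 1L]] <- s
      # keep alpha strictly positive: w < 5/(k+1)
      ws <- c(ws, stats::runif(1, 0.02, min(0.9, 4.9 / (k + 1))))
    }
    # enforce w-monotonicity: w(T) <= w(S) for S subset of T
    repeat {
      changed <- FALSE
      for (i in seq_along(subs)) for (j in seq_along(subs)) {
        if (i != j && all(subs[[i]] %in% subs[[j]]) && ws[j] > ws[i]) {
          ws[j] <- ws[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    overlap_table_from_w(subs, ws, n_max = n_max)
  })
}

# fine-grid Riemann average of the weighted Betti integrand, from bars alone
oracle_riemann_fci <- function(bars, n_individuals, step = 1e-4) {
  alphas <- seq(0, 5 - step, by = step)
  total <- 0
  for (d in sort(unique(bars$dimension))) {
    b <- bars[bars$dimension == d, , drop = FALSE]
    alive <- vapply(alphas, function(a)
      sum(b$birth <= a & (b$censored | b$death > a)), 0L)
    wgt <- if (d == 0) 1 / n_individuals else d + 1
    total <- total + wgt * sum(alive) * step
  }
  total / 5
}

four_area_geoms <- function() {
  fx <- gen_four_area_example()
  stats::setNames(lapply(fx, function(r) r$geometry),
                  vapply(fx, function(r) r$individual_id, ""))
}
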