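new_filtered_complex <- function(entries, vertices, n_max) {
  entries <- entries[order(vapply(names(entries), function(k)
    length(split_key(k)), 0L), names(entries))]
  structure(list(vertices = sort(vertices), entries = entries,
                 n_max = as.integer(n_max)),
            class = "filtered_complex")
}

#' @export
print.filtered_complex <- function(x, ...) {
  d <- vapply(names(x$entries), function(k) length(split_key(k)) - 1L, 0L)
  cat(sprintf("Filtered complex: %d vertices, %d simplices (max dim %d), n_max = %d\n",
              length(x$vertices), length(x$entries), max(d), x$n_max))
  invisible(x)
}

#' @export
as.data.frame.filtered_complex <- function(x, ...) {
  data.frame(simplex = names(x$entries),
             dimension = vapply(names(x$entries),
                                function(k) length(split_key(k)) - 1L, 0L),
             entry = unname(x$entries), stringsAsFactors = FALSE)
}

#' Build a downward-closed filtered simplicial complex from an overlap table
#'
#' Each recorded subset becomes a simplex entering the filtration at its alpha
#' value.  Downward closure is enforced by pulling every face down to the
#' earliest entry of any recorded simplex containing it:
#' entry(face) = min(own alpha if recorded, min over recorded supersets).
#' All vertices enter at alpha = 0, so the filtration starts from isolated
#' individuals.
#'
#' @param table an `overlap_table` (see [enumerate_overlaps()],
#'   [overlap_table_from_w()]).
#' @param vertex_universe character vector of all individual ids; must contain
#'   every id appearing in the table.  Defaults to the ids in the table.
#' @param n_max maximal simplex size; defaults to the table's.
#' @return a `filtered_complex`.
#' @export
assign_entry_values <- function(table, vertex_universe = NULL, n_max = NULL) {
  stopifnot(inherits(table, "overlap_table"))
  if (is.null(n_max)) n_max <- attr(table, "n_max")
  member_sets <- lapply(table$members, split_key)
  if (any(lengths(member_sets) > n_max))
    stop("record with more members than n_max")
  ids <- unique(unlist(member_sets))
  if (is.null(vertex_universe)) vertex_universe <- ids
  if (!all(ids %in% vertex_universe))
    stop("vertex_universe missing ids: ",
         paste(setdiff(ids, vertex_universe), collapse = ", "))

  entries <- stats::setNames(table$alpha, table$members)
  entries <- tapply(entries, names(entries), min)   # defensive dedupe
  entries <- stats::setNames(as.numeric(entries), names(entries))
  # propagate min entry to faces, from large simplices down; iterate over
  # every size level because propagation itself creates new faces
  max_size <- max(vapply(names(entries), function(k) length(split_key(k)), 0L))
  for (k in seq(max_size, 2L)) {
    for (key in names(entries)[vapply(names(entries), function(kk)
      length(split_key(kk)), 0L) == k]) {
      v <- split_key(key)
      a <- entries[[key]]
      for (drop in seq_along(v)) {
        fkey <- paste(v[-drop], collapse = ";")
        cur <- entries[fkey]
        if (is.na(cur) || cur > a) entries[fkey] <- a
      }
    }
  }
  entries[vertex_universe] <- 0
  new_filtered_complex(entries, vertex_universe, n_max)
}

check_closure <- function(complex) {
  e <- complex$entries
  for (key in names(e)) {
    v <- split_key(key)
    if (length(v) == 1L) next
    for (drop in seq_along(v)) {
      fkey <- paste(v[-drop], collapse = ";")
      if (is.na(e[fkey]))
        stop(sprintf("downward closure violated: face %s of %s missing",
                     fkey, key))
      if (e[[fkey]] > e[[key]] + 1e-12)
        stop(sprintf("downward closure violated: face %s enters after %s",
                     fkey, key))
    }
  }
  invisible(TRUE)
}

# filtration order: (entry, dimension, lexicographic key)
simplex_order <- function(complex) {
  keys <- names(complex$entries)
  d <- vapply(keys, function(k) length(split_key(k)), 0L)
  order(unname(complex$entries), d, keys)
}

sym_diff <- function(a, b) {
  u <- c(a, b)
  u <- sort(u)
  u[!(u %in% u[duplicated(u)])]
}

#' Persistent homology of a filtered complex
#'
#' Standard persistence over GF(2) by column reduction of the boundary matrix
#' in filtration order, with ties broken by (entry alpha, dimension ascending,
#' lexicographic vertex tuple) so faces always precede cofaces.  Bars of zero
#' persistence (birth = death) are dropped.  Features still alive at the end
#' of the filtration are censored: reported with death = 5 and
#' `censored = TRUE` (the filtration parameter ranges over [0, 5)).
#'
#' @param complex a `filtered_complex`.
#' @param max_dim report bars up to this dimension (default `n_max - 1`).
#' @return data frame of class `persistence_bars` with columns `dimension`,
#'   `birth`, `death`, `censored`, plus attribute `n_components` (number of
#'   never-dying dimension-0 bars).
#' @export
compute_persistence <- function(complex, max_dim = complex$n_max - 1L) {
  stopifnot(inherits(complex, "filtered_complex"))
  if (max_dim > complex$n_max - 1L)
    stop("max_dim exceeds n_max - 1")
  check_closure(complex)

  ord <- simplex_order(complex)
  keys <- names(complex$entries)[ord]
  alphas <- unname(complex$entries)[ord]
  nsimp <- length(keys)
  pos <- stats::setNames(seq_len(nsimp), keys)
  dims <- vapply(keys, function(k) length(split_key(k)) - 1L, 0L)

  # sparse GF(2) boundary columns: sorted indices of facets
  cols <- vector("list", nsimp)
  for (j in seq_len(nsimp)) {
    v <- split_key(keys[j])
    if (length(v) == 1L) { cols[[j]] <- integer(0); next }
    f <- vapply(seq_along(v), function(drop)
      pos[[paste(v[-drop], collapse = ";")]], 0L)
    cols[[j]] <- sort(f)
  }

  low_to_col <- integer(nsimp)      # 0 = no column has this low
  paired <- logical(nsimp)
  bars <- list()
  for (j in seq_len(nsimp)) {
    col <- cols[[j]]
    while (length(col) > 0L) {
      lo <- col[length(col)]
      k <- low_to_col[lo]
      if (k == 0L) break
      col <- sym_diff(col, cols[[k]])
    }
    cols[[j]] <- col
    if (length(col) > 0L) {
      lo <- col[length(col)]
      low_to_col[lo] <- j
      paired[lo] <- TRUE
      paired[j] <- TRUE             # negative simplex: not a creator
      d <- dims[lo]
      if (d <= max_dim && alphas[lo] < alphas[j])
        bars[[length(bars) + 1L]] <-
          list(dimension = d, birth = alphas[lo], death = alphas[j],
               censored = FALSE)
    }
  }
  for (i in seq_len(nsimp)) {
    if (length(cols[[i]]) == 0L && !paired[i] && dims[i] <= max_dim)
      bars[[length(bars) + 1L]] <-
        list(dimension = dims[i], birth = alphas[i], death = 5,
             censored = TRUE)
  }
  df <- if (length(bars))
    do.call(rbind, lapply(bars, as.data.frame))
  else
    data.frame(dimension = integer(), birth = numeric(), death = numeric(),
               censored = logical())
  df <- df[order(df$dimension, df$birth, df$death), ]
  rownames(df) <- NULL
  structure(df, class = c("persistence_bars", "data.frame"),
            n_components = sum(df$dimension == 0 & df$censored))
}

#' @export
print.persistence_bars <- function(x, ...) {
  cat(sprintf("Persistence barcode: %d bar(s), %d connected component(s) at the end\n",
              nrow(x), attr(x, "n_components")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Betti curve of a barcode
#'
#' The d-th Betti number as a right-continuous step function of alpha:
#' \eqn{\beta_d(\alpha)} = number of bars of dimension d with
#' birth <= alpha < death.
#'
#' @param bars a `persistence_bars` data frame.
#' @param dimension homology dimension d >= 0.
#' @return object of class `betti_curve`: list with `dimension`,
#'   `alpha` (breakpoints, starting at 0) and `value` (curve value on
#'   `[alpha[i], alpha[i+1])`).
#' @export
betti_curve <- function(bars, dimension) {
  stopifnot(is.data.frame(bars), dimension >= 0)
  b <- bars[bars$dimension == dimension, , drop = FALSE]
  brk <- sort(unique(c(0, b$birth, b$death[!b$censored])))
  brk <- brk[brk < 5]
  val <- vapply(brk, function(a)
    sum(b$birth <= a & (b$censored | b$death > a)), 0L)
  structure(list(dimension = dimension, alpha = brk, value = val),
            class = "betti_curve")
}

#' @export
print.betti_curve <- function(x, ...) {
  cat(sprintf("Betti curve (dim %d): ", x$dimension))
  cat(paste(sprintf("[%.3g: %d]", x$alpha, x$value), collapse = " "), "\n")
  invisible(x)
}

# value of a betti_curve at alpha (right-continuous)
betti_curve_at <- function(curve, alpha) {
  i <- findInterval(alpha, curve$alpha)
  ifelse(i < 1L, 0L, curve$value[pmax(i, 1L)])
}

gf2_rank <- function(m) {
  if (is.null(dim(m)) || nrow(m) == 0L || ncol(m) == 0L) return(0L)
  m <- m %% 2L
  rank <- 0L
  nr <- nrow(m); nc <- ncol(m)
  row <- 1L
  for (col in seq_len(nc)) {
    piv <- which(m[row:nr, col] == 1L)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) m[c(row, piv), ] <- m[c(piv, row), ]
    hit <- which(m[, col] == 1L)
    hit <- hit[hit != row]
    if (length(hit))
      m[hit, ] <- (m[hit, , drop = FALSE] +
                     matrix(m[row, ], length(hit), nc, byrow = TRUE)) %% 2L
    rank <- rank + 1L
    row <- row + 1L
    if (row > nr) break
  }
  rank
}

#' Betti number of the subcomplex at a filtration value, by rank computation
#'
#' Independent of the persistence pairing: restricts the complex to simplices
#' with entry <= alpha (closed inclusion) and computes
#' \eqn{\beta_d = \dim C_d - \mathrm{rank}\,\partial_d -
#' \mathrm{rank}\,\partial_{d+1}} over GF(2) by Gaussian elimination.
#'
#' @param complex a `filtered_complex`.
#' @param alpha filtration value in [0, 5].
#' @param dimension homology dimension d >= 0.
#' @return non-negative integer.
#' @export
betti_at <- function(complex, alpha, dimension) {
  stopifnot(inherits(complex, "filtered_complex"),
            alpha >= 0, alpha <= 5, dimension >= 0)
  keys <- names(complex$entries)[unname(complex$entries) <= alpha]
  if (length(keys) == 0L) return(0L)
  dims <- vapply(keys, function(k) length(split_key(k)) - 1L, 0L)
  kd <- keys[dims == dimension]
  if (length(kd) == 0L) return(0L)
  bmat <- function(d) { # rows: (d-1)-simplices, cols: d-simplices
    lo <- keys[dims == d - 1L]; hi <- keys[dims == d]
    if (length(lo) == 0L || length(hi) == 0L) return(NULL)
    m <- matrix(0L, length(lo), length(hi),
                dimnames = list(lo, hi))
    for (h in hi) {
      v <- split_key(h)
      for (drop in seq_along(v))
        m[paste(v[-drop], collapse = ";"), h] <- 1L
    }
    m
  }
  rk_d  <- if (dimension == 0L) 0L else gf2_rank(bmat(dimension))
  bd1 <- bmat(dimension + 1L)
  rk_d1 <- if (is.null(bd1)) 0L else gf2_rank(bd1)
  length(kd) - rk_d - rk_d1
}
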