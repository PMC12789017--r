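integrate_step <- function(curve, upper = 5) {
  # exact integral of a right-continuous step function on [0, upper)
  brk <- c(curve$alpha, upper)
  sum(curve$value * diff(brk))
}

#' Filtration complementarity index
#'
#' Scores the complementarity evident in a barcode as the average over the
#' filtration interval [0, 5) of the weighted Betti numbers:
#' \deqn{FCI = \langle \beta_0(\alpha)/n_i + \sum_{d \ge 1} (d+1)
#'   \beta_d(\alpha) \rangle_{[0,5)}}
#' The component count is scaled by the number of individuals \eqn{n_i} so
#' larger samples do not score higher automatically; higher-dimensional holes
#' are up-weighted by d + 1.  The average is the exact integral of the step
#' functions divided by 5 — no quadrature error.
#'
#' @param betti_curves list of [betti_curve()] objects; the dimension-0 curve
#'   must be present.
#' @param n_individuals \eqn{n_i}, positive integer.
#' @param season optional season label carried through.
#' @return object of class `fci_result`: list with `value`, `n_individuals`,
#'   `season`.
#' @export
fci <- function(betti_curves, n_individuals, season = NA_character_) {
  stopifnot(is.list(betti_curves), n_individuals >= 1)
  dims <- vapply(betti_curves, function(c) c$dimension, 0)
  if (anyDuplicated(dims)) stop("duplicate dimensions in betti_curves")
  if (!0 %in% dims) stop("dimension-0 Betti curve is required")
  total <- 0
  for (cv in betti_curves) {
    wgt <- if (cv$dimension == 0) 1 / n_individuals else cv$dimension + 1
    total <- total + wgt * integrate_step(cv)
  }
  structure(list(value = total / 5, n_individuals = as.integer(n_individuals),
                 season = season),
            class = "fci_result")
}

#' @export
print.fci_result <- function(x, ...) {
  cat(sprintf("FCI = %.6g (n = %d%s)\n", x$value, x$n_individuals,
              if (is.na(x$season)) "" else paste0(", ", x$season)))
  invisible(x)
}

subcomplex_keys <- function(complex, alpha) {
  names(complex$entries)[unname(complex$entries) <= alpha]
}

#' Facets (maximal simplices) of the subcomplex at a filtration value
#'
#' A facet is a simplex not properly contained in any other simplex of the
#' subcomplex.  Downward closure lets this be decided locally: a simplex is
#' maximal iff none of its one-vertex extensions is present.
#'
#' @param complex a `filtered_complex`.
#' @param alpha filtration value in [0, 5].
#' @return character vector of canonical simplex keys.
#' @export
maximal_simplices <- function(complex, alpha = 4) {
  stopifnot(inherits(complex, "filtered_complex"), alpha >= 0, alpha <= 5)
  keys <- subcomplex_keys(complex, alpha)
  if (length(keys) == 0L) return(character())
  present <- new.env(parent = emptyenv())
  for (k in keys) assign(k, TRUE, envir = present)
  verts <- complex$vertices
  is_facet <- vapply(keys, function(k) {
    v <- split_key(k)
    for (u in setdiff(verts, v))
      if (!is.null(present[[canonical_key(c(v, u))]])) return(FALSE)
    TRUE
  }, TRUE)
  sort(keys[is_facet])
}

#' Maximal simplicial degree centrality
#'
#' Generalises degree centrality to simplicial complexes: the degree of a
#' simplex is the number of facets of the subcomplex at `alpha` that contain
#' it, a facet counting as containing itself.  By construction the nested
#' structure induced by downward closure does not bias degrees towards high
#' or low order: in a complex with a single facet every simplex has degree 1.
#'
#' @param complex a `filtered_complex`.
#' @param alpha filtration value; default 4 (subsets at least as redundant as
#'   the theoretical optimum).
#' @return data frame of class `centrality_records` with columns `simplex`,
#'   `size`, `degree`, one row per simplex of the subcomplex; empty (with a
#'   warning) if the subcomplex is empty.
#' @export
maximal_degree_centrality <- function(complex, alpha = 4) {
  keys <- subcomplex_keys(complex, alpha)
  if (length(keys) == 0L) {
    warning("empty subcomplex at alpha = ", alpha)
    df <- data.frame(simplex = character(), size = integer(),
                     degree = integer(), stringsAsFactors = FALSE)
    return(structure(df, class = c("centrality_records", "data.frame")))
  }
  facets <- maximal_simplices(complex, alpha)
  deg <- new.env(parent = emptyenv())
  for (f in facets) {
    v <- split_key(f)
    for (k in seq_along(v)) {
      for (sub in utils::combn(v, k, simplify = FALSE)) {
        key <- paste(sub, collapse = ";")  # already sorted within sorted v
        deg[[key]] <- (if (is.null(deg[[key]])) 0L else deg[[key]]) + 1L
      }
    }
  }
  df <- data.frame(simplex = keys,
                   size = vapply(keys, function(k) length(split_key(k)), 0L),
                   degree = vapply(keys, function(k)
                     if (is.null(deg[[k]])) 0L else deg[[k]], 0L),
                   stringsAsFactors = FALSE)
  df <- df[order(df$size, df$simplex), ]
  rownames(df) <- NULL
  structure(df, class = c("centrality_records", "data.frame"))
}

#' Summarise centrality by simplex size
#'
#' @param records a `centrality_records` data frame.
#' @return data frame with one row per size (ascending): `size`, `count`,
#'   `mean`, `sd`, `min`, `max` of degree.
#' @export
centrality_by_size <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  sizes <- sort(unique(records$size))
  do.call(rbind, lapply(sizes, function(s) {
    d <- records$degree[records$size == s]
    data.frame(size = s, count = length(d), mean = mean(d),
               sd = if (length(d) > 1) stats::sd(d) else NA_real_,
               min = min(d), max = max(d))
  }))
}

#' Fit a sigmoid to centrality-vs-size data
#'
#' Descriptive non-linear least-squares fit of
#' \eqn{c(s) = L / (1 + e^{-k (s - s_0)})} to (size, degree) pairs.
#' Non-convergence is reported, never raised.
#'
#' @param size,degree numeric vectors of equal length (>= 4 distinct sizes).
#' @return list with `L`, `k`, `s0`, `converged`, `rss` (residual sum of
#'   squares; `NA` when not converged) and `rss_constant` (best constant
#'   model, for reference).
#' @export
fit_sigmoid <- function(size, degree) {
  stopifnot(length(size) == length(degree))
  if (length(unique(size)) < 4L) stop("need >= 4 distinct sizes")
  df <- data.frame(s = as.numeric(size), c = as.numeric(degree))
  rss_const <- sum((df$c - mean(df$c))^2)
  start <- list(L = max(df$c), k = 1, s0 = stats::median(df$s))
  fit <- tryCatch(
    stats::nls(c ~ L / (1 + exp(-k * (s - s0))), data = df, start = start,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(L = NA_real_, k = NA_real_, s0 = NA_real_,
                converged = FALSE, rss = NA_real_, rss_constant = rss_const))
  }
  p <- stats::coef(fit)
  list(L = unname(p["L"]), k = unname(p["k"]), s0 = unname(p["s0"]),
       converged = fit$convInfo$isConv,
       rss = sum(stats::resid(fit)^2), rss_constant = rss_const)
}
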