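canonical_key <- function(ids) paste(sort(ids), collapse = ";")
split_key <- function(key) strsplit(key, ";", fixed = TRUE)[[1]]

new_overlap_table <- function(df, n_max, eps_area, season = NA_character_) {
  rownames(df) <- NULL
  structure(df, class = c("overlap_table", "data.frame"),
            n_max = as.integer(n_max), eps_area = eps_area, season = season)
}

#' @export
print.overlap_table <- function(x, ...) {
  cat(sprintf("Overlap table: %d subset(s), n_max = %d, eps_area = %g ha\n",
              nrow(x), attr(x, "n_max"), attr(x, "eps_area")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Enumerate subset overlaps of a collection of core ranges
#'
#' Computes, for every subset of 2..`n_max` core ranges whose common
#' intersection area exceeds `eps_area`, the intersection and union areas and
#' the ratio \eqn{w} together with the filtration index alpha.  Enumeration
#' uses apriori-style pruning: because intersection area is monotonically
#' non-increasing under subset inclusion, a subset with (effectively) empty
#' intersection is never extended.
#'
#' @param ranges list of [core_range()] objects (>= 2) with distinct ids.
#' @param n_max largest subset size to consider (default 6, the largest size
#'   that consistently yields non-trivial structure in the motivating data);
#'   capped at `length(ranges)` with a warning.
#' @param eps_area sliver threshold in hectares: intersections at or below
#'   this are treated as empty (default 1e-4 ha = 1 m^2).
#' @param mapping an [alpha_mapping()].
#' @return an `overlap_table`: a data frame with columns `members`
#'   (semicolon-joined sorted ids), `n`, `intersection_ha`, `union_ha`, `w`,
#'   `alpha`, ordered by (n, members).
#' @export
enumerate_overlaps <- function(ranges, n_max = 6L, eps_area = 1e-4,
                               mapping = alpha_mapping()) {
  if (!is.list(ranges) || length(ranges) < 2L)
    stop("need at least 2 core ranges")
  if (!all(vapply(ranges, inherits, TRUE, "core_range")))
    stop("all elements must be core_range objects")
  ids <- vapply(ranges, function(r) r$individual_id, "")
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  if (n_max < 2L) stop("n_max must be >= 2")
  if (n_max > length(ranges)) {
    warning(sprintf("n_max = %d exceeds number of ranges (%d); capped",
                    n_max, length(ranges)))
    n_max <- length(ranges)
  }
  ord <- order(ids)
  ranges <- ranges[ord]; ids <- ids[ord]
  season <- ranges[[1]]$season
  geoms <- lapply(ranges, as_cpp_poly)

  measure_subset <- function(idx) .region_measures(geoms[idx])

  rows <- list()
  # level 2 seeds
  frontier <- list()   # each element: integer index vector, sorted
  m <- length(ids)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    res <- measure_subset(c(i, j))
    if (res$intersection / SQM_PER_HA > eps_area) {
      frontier[[length(frontier) + 1L]] <- c(i, j)
      rows[[length(rows) + 1L]] <- list(idx = c(i, j), res = res)
    }
  }
  k <- 2L
  while (k < n_max && length(frontier) > 0L) {
    keys <- vapply(frontier, paste, "", collapse = ",")
    nxt <- list()
    # join step: extend each surviving k-set by a larger index whose
    # (k)-subsets all survived
    surviving <- new.env(parent = emptyenv())
    for (kk in keys) assign(kk, TRUE, envir = surviving)
    seen <- new.env(parent = emptyenv())
    for (s in frontier) {
      for (j in seq_len(m)) {
        if (j <= max(s)) next
        cand <- c(s, j)
        ckey <- paste(cand, collapse = ",")
        if (!is.null(seen[[ckey]])) next
        assign(ckey, TRUE, envir = seen)
        # all k-subsets must be in the frontier
        ok <- TRUE
        for (drop in seq_along(cand)) {
          sub <- cand[-drop]
          if (is.null(surviving[[paste(sub, collapse = ",")]])) { ok <- FALSE; break }
        }
        if (!ok) next
        res <- measure_subset(cand)
        if (res$intersection / SQM_PER_HA > eps_area) {
          nxt[[length(nxt) + 1L]] <- cand
          rows[[length(rows) + 1L]] <- list(idx = cand, res = res)
        }
      }
    }
    frontier <- nxt
    k <- k + 1L
  }
  overlap_rows_to_table(rows, ids, n_max, eps_area, season, mapping)
}

overlap_rows_to_table <- function(rows, ids, n_max, eps_area, season,
                                  mapping) {
  if (length(rows) == 0L) {
    df <- data.frame(members = character(), n = integer(),
                     intersection_ha = numeric(), union_ha = numeric(),
                     w = numeric(), alpha = numeric(),
                     stringsAsFactors = FALSE)
    return(new_overlap_table(df, n_max, eps_area, season))
  }
  members <- vapply(rows, function(r) canonical_key(ids[r$idx]), "")
  n <- vapply(rows, function(r) length(r$idx), 0L)
  ia <- vapply(rows, function(r) r$res$intersection / SQM_PER_HA, 0)
  ua <- vapply(rows, function(r) r$res$union / SQM_PER_HA, 0)
  w <- ia / ua
  df <- data.frame(members = members, n = n, intersection_ha = ia,
                   union_ha = ua, w = w,
                   alpha = alpha_from_w(w, n, mapping),
                   stringsAsFactors = FALSE)
  df <- df[order(df$n, df$members), ]
  new_overlap_table(df, n_max, eps_area, season)
}

# Unpruned reference enumeration; oracle for enumerate_overlaps.
enumerate_overlaps_bruteforce <- function(ranges, n_max = 6L, eps_area = 1e-4,
                                          mapping = alpha_mapping()) {
  ids <- vapply(ranges, function(r) r$individual_id, "")
  ord <- order(ids)
  ranges <- ranges[ord]; ids <- ids[ord]
  n_max <- min(n_max, length(ranges))
  geoms <- lapply(ranges, as_cpp_poly)
  rows <- list()
  m <- length(ids)
  for (k in 2:n_max) {
    for (idx in utils::combn(m, k, simplify = FALSE)) {
      res <- .region_measures(geoms[idx])
      if (res$intersection / SQM_PER_HA > eps_area)
        rows[[length(rows) + 1L]] <- list(idx = idx, res = res)
    }
  }
  overlap_rows_to_table(rows, ids, n_max, eps_area, ranges[[1]]$season,
                        mapping)
}

#' Build an overlap table directly from prescribed subset ratios
#'
#' Geometry-free route: takes subsets and target w values (e.g. from
#' [gen_ring_fixture()]) and emits the same `overlap_table` structure that
#' [enumerate_overlaps()] produces, with `NA` areas.
#'
#' @param members list of character vectors of individual ids.
#' @param w numeric vector of ratios in (0, 1], one per subset.
#' @param n_max maximal subset size (default max subset size present).
#' @param mapping an [alpha_mapping()].
#' @return an `overlap_table`.
#' @export
overlap_table_from_w <- function(members, w,
                                 n_max = max(lengths(members)),
                                 mapping = alpha_mapping()) {
  stopifnot(is.list(members), length(members) == length(w))
  if (any(w <= 0) || any(w > 1)) stop("w must lie in (0, 1]")
  n <- lengths(members)
  if (any(n < 2L)) stop("subsets must have >= 2 members")
  if (any(n > n_max)) stop("subset larger than n_max")
  keys <- vapply(members, canonical_key, "")
  if (anyDuplicated(keys)) stop("duplicate subsets")
  # monotonicity check: supersets must not have larger w
  for (i in seq_along(keys)) for (j in seq_along(keys)) {
    if (i != j && all(split_key(keys[[i]]) %in% split_key(keys[[j]])) &&
        w[j] > w[i] + 1e-9)
      stop(sprintf("w-monotonicity violated: w(%s) > w(%s)",
                   keys[[j]], keys[[i]]))
  }
  df <- data.frame(members = keys, n = as.integer(n),
                   intersection_ha = NA_real_, union_ha = NA_real_, w = w,
                   alpha = alpha_from_w(w, n, mapping),
                   stringsAsFactors = FALSE)
  df <- df[order(df$n, df$members), ]
  new_overlap_table(df, n_max, eps_area = 0)
}

#' Write / read an overlap table as CSV
#'
#' @param table an `overlap_table`.
#' @param path file path.
#' @return `read_overlap_table` returns an `overlap_table` (with metadata
#'   restored from the table contents where possible).
#' @export
write_overlap_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_overlap_table
#' @param n_max,eps_area metadata for the restored table.
#' @export
read_overlap_table <- function(path, n_max = NULL, eps_area = 1e-4) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("members", "n", "intersection_ha", "union_ha", "w", "alpha")
  if (!all(need %in% names(df))) stop("missing overlap-table columns")
  if (is.null(n_max)) n_max <- if (nrow(df)) max(df$n) else 2L
  new_overlap_table(df[, need], n_max, eps_area)
}
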