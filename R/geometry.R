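#' @useDynLib rangecomplex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

SQM_PER_HA <- 1e4

#' Construct a planar multi-polygon geometry
#'
#' Geometries are lists of \emph{parts}; each part is a list of rings (2-column
#' numeric matrices of x/y vertices in metres, closed implicitly).  Within a
#' part, membership follows the even-odd rule, so any ring after the first acts
#' as a hole; a point belongs to the geometry if it belongs to at least one
#' part (parts may overlap, e.g. a shared hub disc plus an individual lobe).
#'
#' @param parts list of parts, each a list of 2-column numeric matrices, or a
#'   single matrix (one ring, one part).
#' @return an object of class \code{mp_geom}.
#' @export
mp_geom <- function(parts) {
  if (is.matrix(parts)) parts <- list(list(parts))
  if (length(parts) > 0 && is.matrix(parts[[1]])) parts <- list(parts)
  for (part in parts) {
    for (ring in part) {
      if (!is.matrix(ring) || ncol(ring) != 2 || !is.numeric(ring))
        stop("each ring must be a 2-column numeric matrix")
      if (nrow(ring) < 3) stop("ring with fewer than 3 vertices")
      if (any(!is.finite(ring))) stop("non-finite ring coordinate")
    }
  }
  structure(list(parts = parts), class = "mp_geom")
}

#' @export
print.mp_geom <- function(x, ...) {
  nr <- sum(vapply(x$parts, length, 0L))
  cat(sprintf("<mp_geom: %d part(s), %d ring(s), area %.4f ha>\n",
              length(x$parts), nr, polygon_area(x)))
  invisible(x)
}

#' A regular polygon approximating a disc
#'
#' @param cx,cy centre (metres).
#' @param r radius (metres), > 0.
#' @param n_vertices number of vertices (>= 8).
#' @return a ring matrix usable in [mp_geom()].
#' @export
disc_ring <- function(cx, cy, r, n_vertices = 64L) {
  stopifnot(r > 0, n_vertices >= 8)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

rect_ring <- function(x1, x2, y1, y2) {
  cbind(c(x1, x2, x2, x1), c(y1, y1, y2, y2))
}

#' Construct a seasonal core range
#'
#' A core range is the concentrated-use portion of one individual's home range
#' for one season (here taken as given, e.g. a 60% utilisation isopleth),
#' carried as a planar multi-polygon in metric coordinates.
#'
#' @param individual_id character scalar identifier.
#' @param geometry an [mp_geom()] (or matrix / list coercible to one).
#' @param season `"dry"` or `"wet"`.
#' @param year integer year.
#' @return an object of class \code{core_range}.
#' @export
core_range <- function(individual_id, geometry, season = "dry", year = 2017L) {
  if (!is.character(individual_id) || length(individual_id) != 1L ||
      is.na(individual_id) || !nzchar(individual_id))
    stop("individual_id must be a non-empty character scalar")
  season <- match.arg(season, c("dry", "wet"))
  if (!inherits(geometry, "mp_geom")) geometry <- mp_geom(geometry)
  a <- polygon_area(geometry)
  if (!is.finite(a) || a <= 0)
    stop(sprintf("core range '%s' has zero or invalid area", individual_id))
  structure(list(individual_id = individual_id, season = season,
                 year = as.integer(year), geometry = geometry),
            class = "core_range")
}

#' @export
print.core_range <- function(x, ...) {
  cat(sprintf("<core_range %s (%s %d): %.4f ha>\n", x$individual_id,
              x$season, x$year, polygon_area(x$geometry)))
  invisible(x)
}

as_cpp_poly <- function(g) {
  if (inherits(g, "core_range")) g <- g$geometry
  if (!inherits(g, "mp_geom")) g <- mp_geom(g)
  g$parts
}

#' Exact area of a polygon, in hectares
#'
#' Holes are subtracted (even-odd rule); overlapping parts are not
#' double-counted.  Coordinates are metres; 1 ha = 10,000 m^2.
#'
#' @param geometry an [mp_geom()] or [core_range()].
#' @return non-negative area in hectares.
#' @export
polygon_area <- function(geometry) {
  res <- .region_measures(list(as_cpp_poly(geometry)))
  res$union / SQM_PER_HA
}

#' Intersection and union areas of a set of geometries, and their ratio
#'
#' For core ranges \eqn{C_1, \dots, C_n} computes
#' \eqn{w = \mathrm{Area}(\cap_i C_i) / \mathrm{Area}(\cup_i C_i)}, the
#' multi-way intersection/union ratio (a Jaccard index for n sets).
#'
#' @param geometries list of [mp_geom()] / [core_range()] objects (>= 1).
#' @return list with `intersection_ha`, `union_ha`, `w`.
#' @export
intersection_union_ratio <- function(geometries) {
  if (!is.list(geometries) || length(geometries) < 1L)
    stop("need at least one geometry")
  if (inherits(geometries, c("mp_geom", "core_range")))
    geometries <- list(geometries)
  res <- .region_measures(lapply(geometries, as_cpp_poly))
  if (res$union <= 0) stop("union has zero area")
  list(intersection_ha = res$intersection / SQM_PER_HA,
       union_ha = res$union / SQM_PER_HA,
       w = res$intersection / res$union)
}
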