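#' Optimal intersection/union ratio for n individuals
#'
#' Under the idealised model — individuals with equal-sized ranges distributed
#' uniformly and independently, balancing the area each knows uniquely against
#' the opportunity to coincide in the common overlap — the information
#' transfer of a set of n individuals is maximised at
#' \eqn{w^* = 1/(n+1)}.
#'
#' @param n number of individuals, integer >= 1 (vectorised).
#' @return the optimal ratio \eqn{1/(n+1)}, strictly decreasing and convex
#'   in n.
#' @export
optimal_overlap <- function(n) {
  if (length(n) < 1L || any(!is.finite(n)) || any(n < 1) || any(n != floor(n)))
    stop("n must be integer(s) >= 1")
  1 / (n + 1)
}

#' Candidate information-transfer objective
#'
#' A stand-in objective capturing the verbal argument behind the optimum:
#' the opportunity for a set of n individuals to meet is proportional to the
#' redundant fraction w of their union, and the knowledge each can share is
#' proportional to its unique fraction (1 - w), giving
#' \eqn{g_n(w) = w (1-w)^n}.  Its unique interior maximiser is
#' \eqn{w = 1/(n+1)}, matching [optimal_overlap()].  The exact derivation in
#' the source material's supplement is not reproduced here; this form is
#' descriptive.
#'
#' @param w intersection/union ratio in [0, 1] (vectorised).
#' @param n number of individuals, integer >= 1.
#' @return non-negative score, zero at w = 0 and w = 1.
#' @export
transfer_objective <- function(w, n) {
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("w must lie in [0, 1]")
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != floor(n))
    stop("n must be a single integer >= 1")
  w * (1 - w)^n
}

#' The filtration scaling function and its domain
#'
#' The filtration index alpha rescales w by the size-dependent optimum:
#' \eqn{w = f(\alpha) w^*_n} with \eqn{f(\alpha) = 5 - \alpha}, positive and
#' strictly decreasing on the filtration interval [0, 5).  A subset sitting
#' exactly at its optimum \eqn{w = 1/(n+1)} therefore always maps to
#' \eqn{\alpha = 4}, regardless of n.  The mapping object carries f explicitly
#' so that sensitivity to the choice of f can be probed by swapping it;
#' changing f rescales the alpha axis but not the topology encountered.
#'
#' @param f the scaling function, positive and strictly decreasing on
#'   `alpha_max` at 0; default `function(a) 5 - a`.
#' @param f_inverse its inverse; default `function(y) 5 - y`.
#' @param alpha_max right end of the (half-open) filtration interval.
#' @return an object of class \code{alpha_mapping}.
#' @export
alpha_mapping <- function(f = function(a) 5 - a,
                          f_inverse = function(y) 5 - y,
                          alpha_max = 5) {
  stopifnot(is.function(f), is.function(f_inverse), alpha_max > 0)
  if (abs(f(f_inverse(1.23)) - 1.23) > 1e-9)
    stop("f_inverse is not the inverse of f")
  if (f(alpha_max / 2) <= f(alpha_max))
    stop("f must be strictly decreasing on [0, alpha_max]")
  structure(list(f = f, f_inverse = f_inverse, alpha_max = alpha_max),
            class = "alpha_mapping")
}

#' Map an overlap ratio to its filtration index
#'
#' Solves \eqn{w = f(\alpha)/(n+1)} for alpha, i.e. with the default linear f,
#' \eqn{\alpha = 5 - w (n + 1)}.  Simplices with any overlap (w > 0) get
#' alpha < 5; zero overlap maps to alpha = 5, outside the filtration
#' interval [0, 5), so the filtration starts from isolated vertices.
#'
#' @param w ratio in [0, 1] (vectorised).
#' @param n subset size, integer >= 1.
#' @param mapping an [alpha_mapping()].
#' @return alpha in (0, 5]; errors if the implied alpha would be <= 0
#'   (w > 5/(n+1), only possible for n <= 3).
#' @export
alpha_from_w <- function(w, n, mapping = alpha_mapping()) {
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("w must lie in [0, 1]")
  if (any(n < 1) || any(n != floor(n))) stop("n must be integer(s) >= 1")
  a <- mapping$f_inverse(w * (n + 1))
  if (any(a <= 0))
    stop("w implies alpha <= 0; each simplex must have alpha > 0 ",
         "(w exceeds f(0) * w*_n)")
  a
}

#' Inverse of [alpha_from_w()]
#'
#' @param alpha filtration index in [0, 5] (vectorised).
#' @param n subset size, integer >= 1.
#' @param mapping an [alpha_mapping()].
#' @return ratio \eqn{f(\alpha)/(n+1)}, clamped to [0, 1].
#' @export
w_from_alpha <- function(alpha, n, mapping = alpha_mapping()) {
  if (any(!is.finite(alpha)) || any(alpha < 0) ||
      any(alpha > mapping$alpha_max))
    stop("alpha must lie in [0, ", mapping$alpha_max, "]")
  if (any(n < 1) || any(n != floor(n))) stop("n must be integer(s) >= 1")
  pmin(1, pmax(0, mapping$f(alpha) / (n + 1)))
}
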