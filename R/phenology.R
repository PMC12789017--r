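#' Index of fruit abundance for one monitoring period
#'
#' For the species monitored in one fortnight,
#' \deqn{IFA_f = \sum_i Tf_i \, DBH_i \, Den_i}
#' where \eqn{Tf_i} is the proportion of trees of species i with fruit,
#' \eqn{DBH_i} the summed diameter at breast height (cm) of the fruiting
#' trees of that species and \eqn{Den_i} its tree density (trees per ha).
#' Species absent from a period contribute 0.
#'
#' @param records data frame for a single period with columns `species`,
#'   `Tf` (in [0, 1]), `DBH` (>= 0), `Den` (>= 0).
#' @return non-negative scalar.
#' @export
ifa <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("species", "Tf", "DBH", "Den") %in% names(records)))
  if (anyDuplicated(records$species)) stop("duplicate species in one period")
  if (any(records$Tf < 0 | records$Tf > 1)) stop("Tf must lie in [0, 1]")
  if (any(records$DBH < 0) || any(records$Den < 0))
    stop("DBH and Den must be non-negative")
  sum(records$Tf * records$DBH * records$Den)
}

#' Per-period IFA series from a phenology table
#'
#' @param records data frame with columns `species`, `period`, `Tf`, `DBH`,
#'   `Den`; (species, period) pairs must be unique.
#' @return data frame with columns `period`, `IFA`, periods ascending.
#' @export
ifa_series <- function(records) {
  stopifnot(is.data.frame(records), "period" %in% names(records))
  if (anyDuplicated(records[c("species", "period")]))
    stop("duplicate (species, period) pair")
  periods <- sort(unique(records$period))
  data.frame(period = periods,
             IFA = vapply(periods, function(p)
               ifa(records[records$period == p, , drop = FALSE]), 0))
}

#' Seasonal mean and coefficient of variation of an IFA series
#'
#' @param values numeric vector of per-period IFA values (>= 2 periods).
#' @return list with `mean` and `cv` (sample standard deviation over mean;
#'   `NA` with a warning when the mean is zero).
#' @export
season_summary <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("need at least 2 periods")
  m <- mean(values)
  if (m == 0) {
    warning("mean IFA is zero; cv undefined")
    return(list(mean = 0, cv = NA_real_))
  }
  list(mean = m, cv = stats::sd(values) / m)
}
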