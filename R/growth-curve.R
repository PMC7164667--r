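#' Construct a spheroid growth curve
#'
#' A growth curve is a data frame of estimated cell counts over time for one
#' spheroid, the central exchange object between the imaging, curve-fitting,
#' simulation and bridging steps.
#'
#' @param day Numeric vector of times in days since seeding, strictly
#'   increasing.
#' @param cell_count Estimated cell counts, same length, all >= 1.
#' @param equiv_diameter_um Optional equivalent-circle diameters (um).
#' @param cell_diameter_um Single-cell diameter (um) used for the packing
#'   estimate; stored as an attribute.
#' @return A data frame of class `growth_curve` with columns `day`,
#'   `cell_count` and optionally `equiv_diameter_um`.
#' @export
growth_curve <- function(day, cell_count, equiv_diameter_um = NULL,
                         cell_diameter_um = NA_real_) {
  stopifnot(length(day) == length(cell_count))
  if (length(day) && any(diff(day) <= 0)) stop("day must be strictly increasing")
  if (any(cell_count < 1)) stop("cell_count must be >= 1")
  df <- data.frame(day = as.numeric(day), cell_count = as.numeric(cell_count))
  if (!is.null(equiv_diameter_um)) df$equiv_diameter_um <- equiv_diameter_um
  structure(df,
    cell_diameter_um = cell_diameter_um,
    class = c("growth_curve", "data.frame")
  )
}

#' Day a growth curve reaches its plateau phase
#'
#' The plateau onset is the first time point at which the forward relative
#' increase of the curve over a one-day window drops below `threshold`
#' (default 1 percent per day). The day is reported on the curve's native
#' grid, so 3-hour sampling yields fractional days such as 10.875.
#'
#' @param curve A [growth_curve()].
#' @param threshold Relative one-day increase below which growth counts as
#'   flat (dimensionless, default 0.01).
#' @param window_days Width of the forward window in days (default 1).
#' @return The plateau day, or `NA_real_` if the curve never flattens within
#'   the observed range.
#' @export
plateau_day <- function(curve, threshold = 0.01, window_days = 1) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 2)
  day <- curve$day
  n <- curve$cell_count
  for (i in seq_along(day)) {
    if (day[i] + window_days > day[length(day)] + 1e-9) break
    n_ahead <- stats::approx(day, n, xout = day[i] + window_days)$y
    if ((n_ahead - n[i]) / n[i] < threshold) {
      return(day[i])
    }
  }
  NA_real_
}
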