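# Leaf-habit classification from annual canopy-foliage series.

#' Leaf-habit classification thresholds
#'
#' The field definitions (deciduous: leaves absent for a significant part of
#' the year; brevideciduous: a brief leafless period; evergreen: canopy
#' present year-round) are made operational with configurable day counts.
#'
#' @param foliage_threshold fraction of the series maximum above which a day
#'   counts as foliated (default 0.5, the 50% rule).
#' @param evergreen_days minimum foliated days per year for the evergreen
#'   class (default 360).
#' @param deciduous_spell minimum length, in consecutive days, of the
#'   longest leafless (< threshold) spell for the deciduous class
#'   (default 60).
#' @return list of thresholds, to pass to [classify_leaf_habit()].
#' @export
habit_thresholds <- function(foliage_threshold = 0.5, evergreen_days = 360,
                             deciduous_spell = 60) {
  stopifnot(foliage_threshold > 0, foliage_threshold <= 1,
            evergreen_days > 0, evergreen_days <= 365, deciduous_spell > 0)
  list(foliage_threshold = foliage_threshold,
       evergreen_days = evergreen_days,
       deciduous_spell = deciduous_spell)
}

#' Classify leaf habit from a canopy-foliage series
#'
#' Counts the number of days per year on which canopy foliage is at or above
#' a threshold fraction (default 50%) of the series maximum, interpolating
#' linearly between observations on a daily grid with circular wrap-around
#' (December connects to January). Classification: evergreen when foliated
#' days reach `evergreen_days`; deciduous when the longest consecutive
#' sub-threshold spell reaches `deciduous_spell`; brevideciduous otherwise.
#' The rule is relative to the series maximum, so it is invariant to uniform
#' rescaling of the foliage values.
#'
#' @param doy day of year of each observation (1-365).
#' @param fraction canopy foliage fraction at each observation, in `[0, 1]`.
#' @param thresholds see [habit_thresholds()].
#' @return list with `habit` (`"deciduous"`, `"brevideciduous"` or
#'   `"evergreen"`), `foliated_days`, `leafless_spell` (longest consecutive
#'   run of sub-threshold days) and `extrapolated` (TRUE when the
#'   observations span less than ~10 months and the gap was bridged by the
#'   circular interpolation).
#' @examples
#' classify_leaf_habit(doy = c(15, 105, 195, 285), fraction = c(1, 1, 1, 1))
#' @export
classify_leaf_habit <- function(doy, fraction, thresholds = habit_thresholds()) {
  if (length(doy) != length(fraction) || length(doy) < 2L)
    stop("need at least two (doy, fraction) observations", call. = FALSE)
  if (any(is.na(doy)) || any(is.na(fraction)))
    stop("missing values in the foliage series", call. = FALSE)
  if (any(fraction < 0 | fraction > 1))
    stop("foliage fractions must lie in [0, 1]", call. = FALSE)
  if (any(doy < 1 | doy > 365))
    stop("'doy' must lie in 1..365", call. = FALSE)
  if (max(fraction) == 0)
    stop("all-zero foliage series: maximum foliage must be positive",
         call. = FALSE)

  ord <- order(doy)
  doy <- doy[ord]
  fraction <- fraction[ord]
  if (anyDuplicated(doy))
    stop("duplicated observation days", call. = FALSE)

  covered <- max(doy) - min(doy)
  extrapolated <- covered < 300
  if (extrapolated)
    warning("foliage series covers only ", covered,
            " days; circular interpolation extrapolates across the gap",
            call. = FALSE)

  # circular daily grid: pad with the last point shifted back one year and
  # the first shifted forward, then interpolate days 1..365
  x <- c(doy[length(doy)] - 365, doy, doy[1] + 365)
  y <- c(fraction[length(fraction)], fraction, fraction[1])
  daily <- stats::approx(x, y, xout = seq_len(365))$y

  thr <- thresholds$foliage_threshold * max(daily)
  foliated <- daily >= thr
  foliated_days <- sum(foliated)

  # longest sub-threshold run on the circle: double the sequence, cap at 365
  if (all(foliated)) {
    spell <- 0L
  } else {
    r <- rle(rep(!foliated, 2L))
    spell <- min(365L, max(r$lengths[r$values]))
  }

  habit <- if (foliated_days >= thresholds$evergreen_days) {
    "evergreen"
  } else if (spell >= thresholds$deciduous_spell) {
    "deciduous"
  } else {
    "brevideciduous"
  }
  list(habit = habit, foliated_days = foliated_days,
       leafless_spell = spell, extrapolated = extrapolated)
}
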