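#' Winter climate moisture deficit over a season window
#'
#' Hargreaves-style climate moisture deficit (CMD): the summed monthly excess
#' of atmospheric evaporative demand over precipitation, in mm. By convention
#' a deficit cannot be negative, so months where precipitation meets or
#' exceeds demand contribute zero; set `clamp = FALSE` for the raw signed sum.
#'
#' @param eref Numeric vector of monthly reference evaporative demand (mm),
#'   one element per month of the season window (e.g. Dec-Feb).
#' @param precip Numeric vector of monthly precipitation (mm), same length.
#' @param clamp If `TRUE` (default), negative monthly deficits are clamped to
#'   zero before summing.
#' @return A single non-negative number (mm) when `clamp = TRUE`.
#' @examples
#' compute_cmd(c(50, 60), c(30, 100)) # 20
#' @export
compute_cmd <- function(eref, precip, clamp = TRUE) {
  if (length(eref) != length(precip)) {
    stop("`eref` and `precip` must have the same length (one value per month)")
  }
  if (any(!is.finite(eref)) || any(!is.finite(precip))) {
    stop("non-finite values in monthly climate inputs")
  }
  if (any(precip < 0)) {
    stop("negative precipitation values: ", paste(which(precip < 0), collapse = ", "))
  }
  d <- eref - precip
  if (clamp) d <- pmax(d, 0)
  sum(d)
}

#' Annual anomaly of a seasonal climate variable relative to a normal
#'
#' Computes, for each year, the mean over sample points of the deviation of
#' the annual value from that point's long-term normal. For a fixed point set
#' this equals the difference of spatial means.
#'
#' @param annual Data frame with columns `point`, `year`, `value`.
#' @param normal Data frame with columns `point`, `value` (the 1961-1990-style
#'   normal for each point).
#' @return Data frame with columns `year`, `anomaly`, one row per year.
#' @export
seasonal_anomaly <- function(annual, normal) {
  req_a <- c("point", "year", "value")
  req_n <- c("point", "value")
  if (!all(req_a %in% names(annual))) stop("`annual` needs columns point, year, value")
  if (!all(req_n %in% names(normal))) stop("`normal` needs columns point, value")
  if (anyDuplicated(normal$point)) stop("duplicate points in `normal`")
  missing_pts <- setdiff(unique(annual$point), normal$point)
  if (length(missing_pts) > 0) {
    stop("points present in `annual` but missing from `normal`: ",
         paste(utils::head(missing_pts, 5), collapse = ", "))
  }
  dev <- annual$value - normal$value[match(annual$point, normal$point)]
  agg <- tapply(dev, annual$year, mean)
  data.frame(year = as.integer(names(agg)), anomaly = as.numeric(agg),
             row.names = NULL)
}

#' Tailwind component of a wind vector along a migration bearing
#'
#' Projects the horizontal wind vector (u eastward, v northward, m/s) onto a
#' bearing measured in degrees clockwise from north. Positive values push a
#' migrant along the bearing; negative values are headwinds.
#'
#' @param u East-west wind component (m/s, positive eastward).
#' @param v North-south wind component (m/s, positive northward).
#' @param bearing Migration bearing in degrees clockwise from north,
#'   in `[0, 360)`.
#' @return Tailwind component in m/s. Vectorized over all arguments.
#' @export
tailwind_component <- function(u, v, bearing) {
  if (any(bearing < 0 | bearing >= 360)) stop("`bearing` must lie in [0, 360)")
  th <- bearing * pi / 180
  u * sin(th) + v * cos(th)
}

#' Mean spring-migration tailwind per year
#'
#' Averages the tailwind component over all grid points, both pressure levels,
#' and all 6-hourly timestamps inside the migration window, excluding the
#' 12:00 observations (midday, when migrating songbirds are normally
#' sedentary).
#'
#' @param winds Data frame with columns `point`, `datetime` (POSIXct or ISO
#'   string), `level` (mb), `u`, `v`.
#' @param window Character vector `c(start, end)` of month-day strings
#'   (`"mm-dd"`), e.g. `c("04-01", "05-31")`; the window is applied within
#'   each calendar year.
#' @param bearing Migration bearing (degrees clockwise from north).
#' @param exclude_hour Hour-of-day to drop (default 12).
#' @return Data frame with columns `year`, `tw` (mean tailwind, m/s).
#' @export
migration_tailwind <- function(winds, window, bearing, exclude_hour = 12) {
  req <- c("point", "datetime", "u", "v")
  if (!all(req %in% names(winds))) {
    stop("`winds` needs columns point, datetime, u, v (and optionally level)")
  }
  dt <- winds$datetime
  if (!inherits(dt, "POSIXct")) {
    dt <- as.POSIXct(sub("T", " ", as.character(dt)), tz = "UTC")
    if (anyNA(dt)) stop("unparseable datetime values in wind samples")
  }
  hour <- as.integer(format(dt, "%H"))
  md <- format(dt, "%m-%d")
  keep <- md >= window[1] & md <= window[2] & hour != exclude_hour
  if (!any(keep)) stop("no wind samples fall inside the migration window")
  yr <- as.integer(format(dt, "%Y"))[keep]
  tw <- tailwind_component(winds$u[keep], winds$v[keep], bearing)
  years <- sort(unique(as.integer(format(dt, "%Y"))))
  missing_years <- setdiff(years, unique(yr))
  if (length(missing_years) > 0) {
    stop("no in-window samples for year(s): ", paste(missing_years, collapse = ", "))
  }
  agg <- tapply(tw, yr, mean)
  data.frame(year = as.integer(names(agg)), tw = as.numeric(agg),
             row.names = NULL)
}

#' Z-score climate covariates within stratum
#'
#' Standardizes each covariate column to mean 0, sd 1 within each stratum over
#' years (population-sd convention). The original scale is retained: the returned data frame
#' keeps the raw columns and adds `*_z` columns, and the per-stratum means and
#' sds are stored in the `"standardization"` attribute so fitted coefficients
#' can be reported per anomaly unit.
#'
#' @param series Data frame with columns `stratum`, `year` and one or more of
#'   `cmd`, `tw`, `temp`.
#' @param vars Covariate columns to standardize.
#' @return The input with appended `<var>_z` columns and a `standardization`
#'   attribute (data frame: stratum, var, mean, sd).
#' @export
standardize_covariates <- function(series, vars = intersect(c("cmd", "tw", "temp"), names(series))) {
  if (!all(c("stratum", "year") %in% names(series))) {
    stop("`series` needs columns stratum, year")
  }
  if (length(vars) == 0) stop("no covariate columns to standardize")
  rec <- list()
  for (v in vars) {
    zcol <- paste0(v, "_z")
    series[[zcol]] <- NA_real_
    for (m in unique(series$stratum)) {
      idx <- series$stratum == m
      if (sum(idx) < 2) stop("need >= 2 years per stratum to standardize (stratum ", m, ")")
      mu <- mean(series[[v]][idx])
      sdv <- sqrt(mean((series[[v]][idx] - mu)^2))
      if (!is.finite(sdv) || sdv == 0) {
        stop("zero variance in covariate '", v, "' for stratum ", m)
      }
      series[[zcol]][idx] <- (series[[v]][idx] - mu) / sdv
      rec[[length(rec) + 1]] <- data.frame(stratum = m, var = v, mean = mu, sd = sdv)
    }
  }
  attr(series, "standardization") <- do.call(rbind, rec)
  series
}

#' Undo covariate standardization
#'
#' @param z Standardized values.
#' @param stratum,var Which stratum/covariate the values belong to.
#' @param record A `standardization` attribute as produced by
#'   [standardize_covariates()].
#' @return Values on the original anomaly scale.
#' @export
destandardize <- function(z, stratum, var, record) {
  row <- record[record$stratum == stratum & record$var == var, ]
  if (nrow(row) != 1) stop("no standardization record for ", var, " in stratum ", stratum)
  z * row$sd + row$mean
}
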