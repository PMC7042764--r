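# Readers, writers and validators for the four tabular inputs, plus assembly
# of the joint-model dataset with consistent dense indexing.
#
# Year handling: calendar years appear in all files and outputs; internally
# every component stores `year0` (the first calendar year) and uses 1..T
# indices, which avoids off-by-one drift between the T-year data span and the
# (T-1)-interval trend span.

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
}

#' Build a validated count dataset
#'
#' @param records Data frame with columns `route_observer`, `route`,
#'   `stratum`, `year`, `count` and optionally `novice`. Each
#'   (route_observer, year) may appear at most once; missing combinations are
#'   allowed (routes are not surveyed every year). If `novice` is absent it
#'   is recomputed as 1 in the first year each route-observer unit appears.
#' @return A `count_dataset`: list with `records`, `M` (strata), `T` (years),
#'   `Nro` (route-observer units), `year0`, `strata` (ids in index order).
#' @export
count_dataset <- function(records) {
  check_columns(records, c("route_observer", "route", "stratum", "year", "count"),
                "counts")
  bad <- which(records$count < 0 | records$count != round(records$count) |
                 !is.finite(records$count))
  if (length(bad) > 0) {
    stop("validation error: non-negative-integer counts required at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  dup <- duplicated(records[, c("route_observer", "year")])
  if (any(dup)) {
    stop("validation error: duplicated (route_observer, year) at row(s) ",
         paste(utils::head(which(dup), 10), collapse = ", "))
  }
  records <- records[order(records$route_observer, records$year), , drop = FALSE]
  first_year <- tapply(records$year, records$route_observer, min)
  recomputed <- as.integer(records$year == first_year[as.character(records$route_observer)])
  if (is.null(records$novice)) {
    records$novice <- recomputed
  } else {
    if (any(records$novice == 1 & recomputed == 0)) {
      stop("validation error: novice flag set outside a route-observer's first year")
    }
  }
  strata <- sort(unique(as.character(records$stratum)))
  year0 <- min(records$year)
  structure(list(records = records, M = length(strata),
                 T = max(records$year) - year0 + 1L,
                 Nro = length(unique(records$route_observer)),
                 year0 = as.integer(year0), strata = strata),
            class = "count_dataset")
}

#' Read a counts CSV
#'
#' Expected header: `route_observer,route,stratum,year,count,novice`
#' (`novice` optional).
#'
#' @param path CSV file path.
#' @return A `count_dataset`.
#' @export
load_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  count_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a counts CSV
#' @param counts A `count_dataset`.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(counts$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a validated capture-history dataset
#'
#' @param individuals Data frame with columns `individual`, `station`,
#'   `stratum`, `resident_observed`.
#' @param detections 0/1 matrix, one row per individual, one column per year.
#' @param station_years Data frame with columns `station`, `stratum`,
#'   `first_year_operated`, `last_year_operated`, `years_operated`.
#' @param year0 Calendar year of the first detection column.
#' @return A `capture_data` object.
#' @export
capture_data <- function(individuals, detections, station_years, year0) {
  check_columns(individuals, c("individual", "station", "stratum", "resident_observed"),
                "captures")
  check_columns(station_years, c("station", "stratum", "first_year_operated",
                                 "last_year_operated", "years_operated"),
                "station years")
  detections <- as.matrix(detections)
  if (nrow(detections) != nrow(individuals)) {
    stop("one detection row per individual required")
  }
  if (!all(detections %in% c(0, 1))) stop("detections must be 0/1")
  first <- apply(detections, 1, function(h) which(h == 1)[1])
  if (any(is.na(first))) stop("individual(s) with all-zero detection history")
  if (any(!individuals$resident_observed %in% c(0, 1))) {
    stop("`resident_observed` must be 0/1 for every individual")
  }
  unknown <- setdiff(unique(individuals$station), station_years$station)
  if (length(unknown) > 0) {
    stop("station(s) in capture data missing from station table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  individuals$first <- as.integer(first)
  structure(list(individuals = individuals, detections = detections,
                 station_years = station_years, year0 = as.integer(year0),
                 T = ncol(detections)),
            class = "capture_data")
}

#' Read capture histories and the companion station table
#'
#' The captures CSV is wide: `individual,station,stratum`, one 0/1 column per
#' year named `y<calendar year>`, then `resident_observed`. The station CSV
#' has `station,stratum,first_year_operated,last_year_operated,years_operated`.
#'
#' @param path Captures CSV path.
#' @param station_path Station CSV path.
#' @return A `capture_data` object.
#' @export
load_captures <- function(path, station_path) {
  for (p in c(path, station_path)) if (!file.exists(p)) stop("file not found: ", p)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ycols <- grep("^y[0-9]{4}$", names(df), value = TRUE)
  if (length(ycols) == 0) stop("schema error: no per-year columns (y<year>) in ", path)
  years <- as.integer(sub("^y", "", ycols))
  ycols <- ycols[order(years)]
  years <- sort(years)
  if (!all(diff(years) == 1)) stop("per-year columns must cover consecutive years")
  st <- utils::read.csv(station_path, stringsAsFactors = FALSE)
  capture_data(df[, setdiff(names(df), ycols), drop = FALSE],
               as.matrix(df[, ycols, drop = FALSE]), st, min(years))
}

#' Write capture histories and the station table
#' @param captures A `capture_data` object.
#' @param path,station_path Output paths.
#' @export
write_captures <- function(captures, path, station_path) {
  det <- as.data.frame(captures$detections)
  names(det) <- paste0("y", captures$year0 + seq_len(captures$T) - 1L)
  out <- cbind(captures$individuals[, c("individual", "station", "stratum")],
               det, resident_observed = captures$individuals$resident_observed)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(captures$station_years, station_path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Restrict capture data to stations operated a minimum number of years
#'
#' Drops individuals captured at stations operated fewer than `min_years`
#' years and updates the station table. Idempotent.
#'
#' @param captures A `capture_data` object.
#' @param min_years Minimum years of station operation (default 4).
#' @return Filtered `capture_data`.
#' @export
filter_min_station_years <- function(captures, min_years = 4) {
  if (min_years < 1) stop("`min_years` must be >= 1")
  keep_st <- captures$station_years$years_operated >= min_years
  stations <- captures$station_years$station[keep_st]
  keep_ind <- captures$individuals$station %in% stations
  capture_data(captures$individuals[keep_ind, setdiff(names(captures$individuals), "first"),
                                    drop = FALSE],
               captures$detections[keep_ind, , drop = FALSE],
               captures$station_years[keep_st, , drop = FALSE],
               captures$year0)
}

#' Validate an age-specific capture table
#'
#' @param df Data frame with columns `station`, `stratum`, `year`, `n_hy`,
#'   `n_adult`, `effort_net_hours`.
#' @return The validated data frame (class `age_capture_table`).
#' @export
age_capture_table <- function(df) {
  check_columns(df, c("station", "stratum", "year", "n_hy", "n_adult",
                      "effort_net_hours"), "age captures")
  if (any(df$n_hy < 0) || any(df$n_adult < 0)) stop("age-capture counts must be >= 0")
  if (any(df$n_hy + df$n_adult > 0 & df$effort_net_hours <= 0)) {
    stop("rows with captures must have positive effort")
  }
  class(df) <- c("age_capture_table", "data.frame")
  df
}

#' Read an age-specific capture CSV
#' @param path CSV with header `station,stratum,year,n_hy,n_adult,effort_net_hours`.
#' @return An `age_capture_table`.
#' @export
load_ages <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  age_capture_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a per-stratum annual covariate CSV
#' @param path CSV with header `stratum,year,cmd,tw,temp`.
#' @return Validated data frame.
#' @export
load_covariate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("stratum", "year", "cmd", "tw", "temp"), "covariates")
  if (anyDuplicated(df[, c("stratum", "year")])) {
    stop("validation error: duplicated (stratum, year) in covariates")
  }
  df
}

#' Validate stratum metadata
#'
#' @param df Data frame with columns `stratum`, `name`, `area_weight`
#'   (proportions of total area, summing to 1) and optionally `route_weight`.
#' @return Validated data frame.
#' @export
stratum_meta <- function(df) {
  check_columns(df, c("stratum", "name", "area_weight"), "stratum metadata")
  if (abs(sum(df$area_weight) - 1) > 1e-8) stop("area weights must sum to 1")
  if (any(df$area_weight <= 0)) stop("area weights must be positive")
  if (!is.null(df$route_weight) &&
      any(df$route_weight <= 0 | df$route_weight > 1)) {
    stop("route weights must lie in (0, 1]")
  }
  df
}

#' Per-stratum route weights from count data
#'
#' `w_m` = proportion of distinct physical routes in stratum m on which the
#' species was encountered (any year with count > 0), among routes surveyed
#' at least once. A route surveyed by several observers counts once.
#'
#' @param counts A `count_dataset`.
#' @return Named numeric vector of weights in `[0, 1]` by stratum.
#' @export
compute_route_weights <- function(counts) {
  rec <- counts$records
  w <- vapply(counts$strata, function(m) {
    rr <- rec[rec$stratum == m, , drop = FALSE]
    routes <- unique(rr$route)
    if (length(routes) == 0) stop("no routes surveyed in stratum ", m)
    pos <- unique(rr$route[rr$count > 0])
    length(pos) / length(routes)
  }, numeric(1))
  names(w) <- counts$strata
  w
}

#' Assemble the joint-model dataset
#'
#' Aligns the four inputs on a shared stratum set and year range, builds
#' dense index maps (strata, route-observer units, stations), applies route
#' weights, and records a per-stratum summary (routes, stations, individuals,
#' recaptures) of the kind monitoring-program reports tabulate.
#'
#' @param counts A `count_dataset`.
#' @param captures A `capture_data` (already filtered to the minimum
#'   station-years rule if desired).
#' @param ages An `age_capture_table`.
#' @param covariates Covariate data frame (`stratum,year,cmd,tw,temp`),
#'   raw anomaly scale; standardized internally.
#' @param meta Stratum metadata (see [stratum_meta()]).
#' @return A `model_dataset` list used by [build_joint_model()] and
#'   [sample_posterior()].
#' @export
assemble_dataset <- function(counts, captures, ages, covariates, meta) {
  strata <- counts$strata
  for (src in list(unique(captures$individuals$stratum), unique(ages$stratum),
                   unique(covariates$stratum), meta$stratum)) {
    if (!setequal(as.character(src), strata)) {
      stop("alignment error: stratum sets differ across data sources")
    }
  }
  year0 <- counts$year0
  T <- counts$T
  if (captures$year0 != year0 || captures$T != T) {
    stop("alignment error: capture-history year range differs from counts")
  }
  cov_years <- sort(unique(covariates$year))
  if (min(cov_years) > year0 || max(cov_years) < year0 + T - 1) {
    stop("alignment error: covariate years do not span the count years")
  }
  if (any(ages$year < year0 | ages$year > year0 + T - 1)) {
    stop("alignment error: age-capture years outside the count year range")
  }
  covariates <- covariates[covariates$year >= year0 &
                             covariates$year <= year0 + T - 1, , drop = FALSE]
  covz <- standardize_covariates(covariates)
  m_index <- stats::setNames(seq_along(strata), strata)
  rw <- compute_route_weights(counts)
  meta <- meta[order(m_index[as.character(meta$stratum)]), , drop = FALSE]
  meta$route_weight <- as.numeric(rw[as.character(meta$stratum)])

  rec <- counts$records
  ro_ids <- sort(unique(rec$route_observer))
  ro_index <- stats::setNames(seq_along(ro_ids), ro_ids)
  sta_ids <- sort(unique(c(captures$individuals$station, ages$station)))
  sta_index <- stats::setNames(seq_along(sta_ids), sta_ids)

  groups <- collapse_histories(captures)
  ind <- captures$individuals
  recaps <- rowSums(captures$detections) - 1
  summary <- do.call(rbind, lapply(strata, function(m) {
    data.frame(stratum = m,
               n_routes = length(unique(rec$route[rec$stratum == m])),
               n_route_observers = length(unique(rec$route_observer[rec$stratum == m])),
               mean_count = mean(rec$count[rec$stratum == m]),
               n_cmr_stations = length(unique(ind$station[ind$stratum == m])),
               n_individuals = sum(ind$stratum == m),
               n_recaptures = sum(recaps[ind$stratum == m]),
               n_age_stations = length(unique(ages$station[ages$stratum == m])),
               n_hy = sum(ages$n_hy[ages$stratum == m]),
               n_adult = sum(ages$n_adult[ages$stratum == m]))
  }))

  structure(list(counts = counts, captures = captures, ages = ages,
                 covariates = covz, meta = meta, groups = groups,
                 strata = strata, m_index = m_index, ro_index = ro_index,
                 sta_index = sta_index, year0 = year0, T = T,
                 summary = summary),
            class = "model_dataset")
}

#' @export
print.model_dataset <- function(x, ...) {
  cat("Joint IPM dataset:", x$counts$M, "strata x", x$T, "years (",
      x$year0, "-", x$year0 + x$T - 1, ")\n", sep = " ")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Read a YAML run configuration
#'
#' A single YAML file naming the four input CSVs, the year range, stratum
#' metadata, MCMC settings and the seed.
#'
#' @param path YAML path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  yaml::read_yaml(path)
}
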