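make_counts_df <- function() {
  data.frame(route_observer = c("r1_o1", "r1_o1", "r1_o1"),
             route = "r1", stratum = "s1", year = 1992:1994,
             count = c(3L, 0L, 5L))
}

test_that("count loading validates and recomputes novice flags", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(make_counts_df(), f, row.names = FALSE)
  cd <- load_counts(f)
  expect_s3_class(cd, "count_dataset")
  expect_equal(cd$Nro, 1)
  expect_equal(cd$T, 3)
  expect_equal(cd$records$novice, c(1L, 0L, 0L))

  # observer first appearing in year 2 is novice then and only then
  df <- rbind(make_counts_df(),
              data.frame(route_observer = "r2_o9", route = "r2", stratum = "s1",
                         year = 1993:1994, count = c(2L, 2L)))
  cd2 <- count_dataset(df)
  r2 <- cd2$records[cd2$records$route_observer == "r2_o9", ]
  expect_equal(r2$novice[order(r2$year)], c(1L, 0L))

  dup <- rbind(df, df[1, ])
  expect_error(count_dataset(dup), "duplicated")
  neg <- df; neg$count[2] <- -1L
  expect_error(count_dataset(neg), "non-negative-integer")
  bad <- df; bad$novice <- 1L
  expect_error(count_dataset(bad), "novice")
  expect_error(count_dataset(df[, -5]), "schema error")
})

test_that("datasets round-trip through their CSV dialects", {
  sim <- micro_dataset(seed = 9)
  td <- withr::local_tempdir()
  write_counts(sim$tables$counts, file.path(td, "counts.csv"))
  back <- load_counts(file.path(td, "counts.csv"))
  expect_equal(back$records$count, sim$tables$counts$records$count)
  expect_equal(back$Nro, sim$tables$counts$Nro)

  write_captures(sim$tables$captures, file.path(td, "caps.csv"),
                 file.path(td, "stations.csv"))
  cback <- load_captures(file.path(td, "caps.csv"), file.path(td, "stations.csv"))
  expect_equal(unname(cback$detections), unname(sim$tables$captures$detections))
  expect_equal(cback$individuals$resident_observed,
               sim$tables$captures$individuals$resident_observed)
  expect_equal(cback$year0, sim$tables$captures$year0)
})

test_that("station-years filter drops short-lived stations and is idempotent", {
  ind <- data.frame(individual = paste0("i", 1:6),
                    station = c("a", "a", "b", "b", "c", "c"),
                    stratum = "s1", resident_observed = c(1, 0, 0, 1, 0, 0))
  det <- matrix(0L, 6, 5); det[cbind(1:6, c(1, 2, 1, 3, 2, 4))] <- 1L
  st <- data.frame(station = c("a", "b", "c"), stratum = "s1",
                   first_year_operated = 1992,
                   last_year_operated = c(1994, 1995, 1996),
                   years_operated = c(3, 4, 5))
  cd <- capture_data(ind, det, st, 1992)

  f4 <- filter_min_station_years(cd, 4)
  expect_setequal(unique(f4$individuals$station), c("b", "c"))
  expect_equal(nrow(f4$individuals), 4)
  f1 <- filter_min_station_years(cd, 1)
  expect_equal(nrow(f1$individuals), 6)
  again <- filter_min_station_years(f4, 4)
  expect_equal(again$individuals$individual, f4$individuals$individual)
  expect_error(filter_min_station_years(cd, 0), "min_years")

  # brute-force recount on simulated per-station operation years
  set.seed(21)
  ops <- sample(2:8, 10, replace = TRUE)
  st2 <- data.frame(station = paste0("s", 1:10), stratum = "s1",
                    first_year_operated = 1992,
                    last_year_operated = 1991 + ops, years_operated = ops)
  ind2 <- data.frame(individual = paste0("j", 1:200),
                     station = sample(st2$station, 200, replace = TRUE),
                     stratum = "s1", resident_observed = 0)
  det2 <- matrix(0L, 200, 8); det2[cbind(1:200, sample(1:8, 200, TRUE))] <- 1L
  cd2 <- capture_data(ind2, det2, st2, 1992)
  f <- filter_min_station_years(cd2, 5)
  keep <- st2$station[st2$years_operated >= 5]
  expect_equal(nrow(f$individuals), sum(ind2$station %in% keep))
})

test_that("route weights are the encountered-route proportions", {
  df <- data.frame(route_observer = paste0("r", 1:4, "_o1"),
                   route = paste0("r", 1:4), stratum = "s1",
                   year = 2000, count = c(2L, 1L, 4L, 0L))
  expect_equal(unname(compute_route_weights(count_dataset(df))), 0.75)
  df$count <- c(1L, 1L, 2L, 9L)
  expect_equal(unname(compute_route_weights(count_dataset(df))), 1.0)

  set.seed(31)
  big <- expand.grid(route = paste0("r", 1:30), year = 2000:2004)
  big$route_observer <- paste0(big$route, "_o1")
  big$stratum <- ifelse(as.integer(sub("r", "", big$route)) <= 15, "m1", "m2")
  big$count <- rbinom(nrow(big), 1, 0.2) * rpois(nrow(big), 3)
  cd <- count_dataset(big)
  w <- compute_route_weights(cd)
  for (m in c("m1", "m2")) {
    sub <- big[big$stratum == m, ]
    pos <- unique(sub$route[sub$count > 0])
    expect_equal(unname(w[m]), length(pos) / length(unique(sub$route)))
  }
})

test_that("assembly aligns sources, spans 17 years, and logs true totals", {
  sc <- simulation_scenario(strata = c("x", "y"), T = 17, n_routes = c(10, 6),
                            n_stations = c(4, 3), n0 = c(800, 500))
  sim <- simulate_dataset(sc, seed = 13)
  ds <- sim$dataset
  expect_equal(ds$T, 17)
  expect_equal(ds$year0, 1992)

  # logged per-stratum totals equal independent recounts on the raw tables
  rec <- sim$tables$counts$records
  ind <- sim$tables$captures$individuals
  for (m in c("x", "y")) {
    srow <- ds$summary[ds$summary$stratum == m, ]
    expect_equal(srow$n_routes, length(unique(rec$route[rec$stratum == m])))
    expect_equal(srow$n_individuals, sum(ind$stratum == m))
    expect_equal(srow$n_recaptures,
                 sum(sim$tables$captures$detections[ind$stratum == m, ]) -
                   sum(ind$stratum == m))
    expect_equal(srow$n_hy, sum(sim$tables$ages$n_hy[sim$tables$ages$stratum == m]))
  }

  # referential integrity: capture station absent from the station table
  broken <- sim$tables$captures
  expect_error(capture_data(transform(broken$individuals, station = "ghost"),
                            broken$detections,
                            broken$station_years, broken$year0),
               "missing from station table")

  # stratum present in one source only
  cov2 <- sim$tables$covariates
  cov2$stratum[cov2$stratum == "y"] <- "z"
  expect_error(assemble_dataset(sim$tables$counts, sim$tables$captures,
                                sim$tables$ages, cov2, sim$tables$meta),
               "stratum sets differ")

  # year-range mismatch
  cov3 <- sim$tables$covariates
  cov3 <- cov3[cov3$year > 1992, ]
  expect_error(assemble_dataset(sim$tables$counts, sim$tables$captures,
                                sim$tables$ages, cov3, sim$tables$meta),
               "alignment error")
})

test_that("stratum metadata validation enforces weight constraints", {
  ok <- stratum_meta(data.frame(stratum = c("a", "b"), name = c("A", "B"),
                                area_weight = c(0.4, 0.6)))
  expect_equal(sum(ok$area_weight), 1)
  expect_error(stratum_meta(data.frame(stratum = "a", name = "A",
                                       area_weight = 0.7)),
               "sum to 1")
})
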