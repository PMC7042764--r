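test_that("compute_cmd clamps monthly deficits at zero and sums", {
  expect_equal(compute_cmd(c(50, 60), c(30, 100)), 20)
  expect_equal(compute_cmd(c(10, 20, 30), c(50, 60, 70)), 0)
  expect_equal(compute_cmd(c(50, 60), c(30, 100), clamp = FALSE), -20)
  expect_error(compute_cmd(c(1, 2), 1), "same length")
  expect_error(compute_cmd(c(1, 2), c(1, -3)), "negative precipitation")

  set.seed(101)
  for (i in 1:25) {
    eref <- runif(3, 0, 120)
    precip <- runif(3, 0, 120)
    loop <- 0
    for (mth in 1:3) loop <- loop + max(0, eref[mth] - precip[mth])
    expect_equal(compute_cmd(eref, precip), loop)
  }
})

test_that("compute_cmd is monotone in precipitation and demand", {
  eref <- c(80, 90, 70)
  precip <- c(40, 95, 60)
  base <- compute_cmd(eref, precip)
  for (mth in 1:3) {
    wetter <- precip; wetter[mth] <- wetter[mth] + 10
    drier <- eref; drier[mth] <- drier[mth] + 10
    expect_lte(compute_cmd(eref, wetter), base)
    expect_gte(compute_cmd(drier, precip), base)
  }
})

test_that("seasonal_anomaly is the mean point-wise deviation from normals", {
  ann <- data.frame(point = c("a", "b"), year = 2000, value = c(5, 7))
  nrm <- data.frame(point = c("a", "b"), value = c(4, 4))
  expect_equal(seasonal_anomaly(ann, nrm)$anomaly, 2)

  ann0 <- data.frame(point = rep(c("a", "b"), 3),
                     year = rep(2000:2002, each = 2), value = rep(c(4, 4), 3))
  expect_equal(seasonal_anomaly(ann0, nrm)$anomaly, rep(0, 3))

  set.seed(7)
  pts <- paste0("p", 1:100)
  ann <- expand.grid(point = pts, year = 1991:1995)
  ann$value <- rnorm(nrow(ann), 10, 3)
  nrm <- data.frame(point = pts, value = rnorm(100, 10, 1))
  got <- seasonal_anomaly(ann, nrm)
  for (yy in 1991:1995) {
    sub <- ann[ann$year == yy, ]
    direct <- mean(sub$value - nrm$value[match(sub$point, nrm$point)])
    expect_equal(got$anomaly[got$year == yy], direct)
  }
  # invariant to adding a constant to both annual and normal values
  ann2 <- ann; ann2$value <- ann2$value + 3.7
  nrm2 <- nrm; nrm2$value <- nrm2$value + 3.7
  expect_equal(seasonal_anomaly(ann2, nrm2)$anomaly, got$anomaly)

  expect_error(seasonal_anomaly(data.frame(point = "zz", year = 2000, value = 1), nrm),
               "missing from")
})

test_that("tailwind_component projects wind onto the bearing", {
  expect_equal(tailwind_component(0, 5, 0), 5)
  expect_equal(tailwind_component(3, 0, 90), 3)
  expect_equal(tailwind_component(0, 5, 90), 0, tolerance = 1e-12)
  expect_error(tailwind_component(1, 1, 360), "0, 360")

  # rotation oracle: |w| * cos(angle between wind vector and bearing)
  set.seed(11)
  for (i in 1:1000) {
    u <- rnorm(1, 0, 6); v <- rnorm(1, 0, 6)
    b <- runif(1, 0, 360)
    speed <- sqrt(u^2 + v^2)
    wind_dir <- atan2(u, v)                   # direction wind blows toward
    oracle <- speed * cos(wind_dir - b * pi / 180)
    expect_equal(tailwind_component(u, v, b), oracle, tolerance = 1e-10)
  }
})

test_that("migration_tailwind averages in-window samples excluding midday", {
  grid <- expand.grid(point = c("g1", "g2"), level = c(800, 950),
                      day = c("2001-04-05", "2001-04-20", "2002-05-10"),
                      hour = c(0, 6, 12, 18), stringsAsFactors = FALSE)
  grid$datetime <- paste0(grid$day, "T", sprintf("%02d:00:00", grid$hour))
  winds <- data.frame(point = grid$point, datetime = grid$datetime,
                      level = grid$level, u = 0, v = 0)
  got <- migration_tailwind(winds, c("04-01", "05-31"), bearing = 20)
  expect_equal(got$tw, c(0, 0))

  winds$u <- 2; winds$v <- -1
  got <- migration_tailwind(winds, c("04-01", "05-31"), bearing = 35)
  expect_equal(got$tw, rep(tailwind_component(2, -1, 35), 2))

  # enumeration oracle over the (point, level, timestamp) set, hour 12 dropped
  set.seed(3)
  winds$u <- rnorm(nrow(winds)); winds$v <- rnorm(nrow(winds))
  keep <- grid$hour != 12
  for (yy in c(2001, 2002)) {
    sel <- keep & startsWith(grid$day, as.character(yy))
    oracle <- mean(tailwind_component(winds$u[sel], winds$v[sel], 35))
    got <- migration_tailwind(winds, c("04-01", "05-31"), bearing = 35)
    expect_equal(got$tw[got$year == yy], oracle)
  }

  expect_error(migration_tailwind(winds, c("01-01", "01-31"), 35), "window")
})

test_that("covariate standardization uses population sd and round-trips", {
  df <- data.frame(stratum = "s1", year = 2000:2002, cmd = c(-1, 0, 1),
                   tw = c(2, 4, 9), temp = c(0.1, 0.5, 0.2))
  z <- standardize_covariates(df)
  expect_equal(z$cmd_z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(z$cmd_z[3], 1.224744871, tolerance = 1e-8)
  rec <- attr(z, "standardization")
  expect_equal(destandardize(z$tw_z, "s1", "tw", rec), df$tw, tolerance = 1e-12)
  expect_true(all(abs(tapply(z$temp_z, z$stratum, mean)) < 1e-12))

  cst <- df; cst$cmd <- 5
  expect_error(standardize_covariates(cst), "zero variance")
})
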