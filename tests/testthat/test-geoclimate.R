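test_that("haversine distances match spherical closed forms", {
  expect_equal(great_circle_km(48, 10, 48, 10), 0)
  expect_equal(great_circle_km(0, 0, 0, 180), pi * 6371.0088,
               tolerance = 1e-9)                       # 20015.1 km antipodal
  expect_equal(great_circle_km(0, 0, 0, 1), 2 * pi * 6371.0088 / 360,
               tolerance = 1e-9)                       # 111.195 km per degree
})

test_that("great-circle distance is a metric on random triples", {
  set.seed(91)
  if (requireNamespace("geosphere", quietly = TRUE)) {
    lat <- runif(20, -80, 80); lon <- runif(20, -179, 179)
    lat2 <- runif(20, -80, 80); lon2 <- runif(20, -179, 179)
    ours <- great_circle_km(lat, lon, lat2, lon2)
    ref <- geosphere::distHaversine(cbind(lon, lat), cbind(lon2, lat2),
                                    r = 6371.0088)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
  for (rep in 1:20) {
    p <- cbind(runif(3, -80, 80), runif(3, -179, 179))
    ab <- great_circle_km(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    bc <- great_circle_km(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    ac <- great_circle_km(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    expect_lte(ac, ab + bc + 1e-9)
    expect_equal(ab, great_circle_km(p[2, 1], p[2, 2], p[1, 1], p[1, 2]))
    expect_gte(ab, 0)
  }
})

test_that("geographic summaries handle degenerate and symmetric cases", {
  one <- data.frame(latitude = 47.3, longitude = 8.5)
  s <- population_geo_summary(one)
  expect_equal(s$centre_lat, 47.3)
  expect_equal(s$standard_distance_km, 0)
  expect_true(is.na(s$ellipse_major_km))

  two <- data.frame(latitude = c(50, 50), longitude = c(-3, 3))
  s2 <- population_geo_summary(two)
  expect_equal(s2$centre_lat, 50)
  expect_equal(s2$centre_lon, 0)
  expect_equal(s2$mean_pairwise_km,
               great_circle_km(50, -3, 50, 3))
})

test_that("ellipse parameters are recovered from generated offsets within 10%", {
  set.seed(92)
  n <- 2000
  major <- 300; minor <- 100; rot <- 30 * pi / 180
  u <- rnorm(n, 0, major); v <- rnorm(n, 0, minor)
  x <- u * cos(rot) - v * sin(rot)
  y <- u * sin(rot) + v * cos(rot)
  clat <- 48; clon <- 10
  pts <- data.frame(
    latitude = clat + y / (pi * 6371.0088 / 180),
    longitude = clon + x / ((pi * 6371.0088 / 180) * cos(clat * pi / 180))
  )
  s <- population_geo_summary(pts)
  expect_lt(abs(s$ellipse_major_km - major) / major, 0.1)
  expect_lt(abs(s$ellipse_minor_km - minor) / minor, 0.1)
  expect_lt(abs(s$ellipse_rotation_deg - 30), 5)
})

test_that("centre separation testing behaves at the null and with real separation", {
  set.seed(93)
  pts <- data.frame(latitude = rnorm(30, 50, 0.5),
                    longitude = rnorm(30, 10, 0.5))
  null <- centre_separation_test(pts, pts)
  expect_equal(null$distance_km, 0)
  expect_equal(null$t, 0)
  expect_equal(null$p_value, 0.5)

  a <- data.frame(latitude = rnorm(30, 50, 0.09),
                  longitude = rnorm(30, 10, 0.14))   # ~10 km SDs
  b <- data.frame(latitude = a$latitude - 9, longitude = a$longitude)
  sep <- centre_separation_test(a, b)
  expect_gt(sep$distance_km, 900)
  expect_lt(sep$p_value, 0.01)
  expect_equal(sep$df, 58L)

  expect_error(centre_separation_test(a[1, , drop = FALSE], b), "at least 2")
})

test_that("nine populations give 36 pairwise separation tests", {
  set.seed(94)
  k <- 9
  centres <- cbind(lat = seq(38, 62, length.out = k),
                   lon = seq(-5, 25, length.out = k))
  n_per <- 12
  coords <- tibble::tibble(
    accession_id = sprintf("g%03d", seq_len(k * n_per)),
    latitude = rep(centres[, 1], each = n_per) + rnorm(k * n_per, 0, 0.8),
    longitude = rep(centres[, 2], each = n_per) + rnorm(k * n_per, 0, 0.8)
  )
  assignments <- tibble::tibble(
    accession_id = coords$accession_id,
    primary_pop = rep(seq_len(k), each = n_per)
  )
  tests <- centre_separation_tests(coords, assignments)
  expect_equal(nrow(tests), choose(9, 2))
  expect_equal(nrow(tests), 36L)
  n_sig <- attr(tests, "n_significant")
  expect_gt(n_sig[["p<0.01"]], 20)   # widely separated chain of centres
})

test_that("climate summaries reduce a complete grid correctly", {
  ids <- c("a1", "a2")
  grid <- tidyr::expand_grid(accession_id = ids,
                             variable = c("v1", "v2"), month = 1:12)
  const <- grid
  const$value <- 3.5
  cs <- climate_summaries(const)
  expect_true(all(cs$accession_means$mean_value == 3.5))
  expect_true(all(cs$monthly_means$mean_value == 3.5))
  expect_true(all(cs$variable_means$mean_value == 3.5))

  lin <- grid
  lin$value <- ifelse(lin$variable == "v1", 2 * lin$month + 1, 0)
  cs <- climate_summaries(lin)
  v1 <- cs$variable_means[cs$variable_means$variable == "v1", ]
  expect_true(all(v1$mean_value == 2 * 6.5 + 1))

  shuffled <- lin[sample(nrow(lin)), ]
  cs2 <- climate_summaries(shuffled)
  expect_equal(dplyr::arrange(cs2$accession_means, accession_id),
               dplyr::arrange(cs$accession_means, accession_id))
})

test_that("permuted population labels give climate F near one", {
  sim <- small_sim(n = 150, k = 3, seed = 95)
  assignments <- tibble::tibble(
    accession_id = sim$coordinates$accession_id,
    primary_pop = max.col(sim$truth$true_Q)
  )
  set.seed(96)
  perms <- climate_anova_permuted(sim$climate, assignments, month = 7,
                                  n_perm = 200, variables = "temp_mean")
  expect_gt(mean(perms$F), 0.8)
  expect_lt(mean(perms$F), 1.2)
})

test_that("latitude-structured populations give F far above one", {
  sim <- small_sim(n = 150, k = 3, seed = 95)
  assignments <- tibble::tibble(
    accession_id = sim$coordinates$accession_id,
    primary_pop = max.col(sim$truth$true_Q)
  )
  res <- climate_anova(sim$climate, assignments, month = 7)
  expect_gt(res$F, 5)
  expect_gt(res$neg_log10_p, 3)

  by_month <- climate_anova_by_month(sim$climate, assignments)
  expect_equal(nrow(by_month), 12)
  expect_true(all(by_month$F > 1))
})

test_that("identical climate distributions give F near one and single population errors", {
  cfg <- sim_config(n_accessions = 120, n_loci = 4, k_true = 3,
                    admixture_alpha = 0, missing_rate = 0,
                    phenotype_probs = matrix(0.5, 3, 1),
                    geo_centres = cbind(rep(48, 3), rep(10, 3)),
                    geo_sd_km = cbind(rep(0, 3), rep(0, 3), rep(0, 3)),
                    seed = 97)
  sim <- simulate_landraces(cfg)
  assignments <- tibble::tibble(
    accession_id = sim$coordinates$accession_id,
    primary_pop = max.col(sim$truth$true_Q)
  )
  res <- climate_anova(sim$climate, assignments, month = 1)
  expect_lt(res$F, 3)   # no structure beyond noise

  solo <- assignments
  solo$primary_pop <- 1
  expect_error(climate_anova(sim$climate, solo, month = 1), "2 populations")
})

test_that("membership-climate regression recovers slope signs and nulls", {
  # constant membership -> zero slopes
  set.seed(98)
  covs <- data.frame(temp = rnorm(80), precip = rnorm(80))
  fit <- membership_climate_regression(rep(0.5, 80), covs)
  slopes <- fit$coefficients$estimate[-1]
  expect_lt(max(abs(slopes)), 1e-8)

  # membership logistic in temperature -> positive recovered slope
  temp <- rnorm(200)
  memb <- 1 / (1 + exp(-(0.2 + 2 * temp)))
  fit <- membership_climate_regression(memb, data.frame(temp = temp))
  expect_gt(fit$coefficients$estimate[2], 0)
  expect_gt(1 - fit$residual_deviance / fit$null_deviance, 0.5)

  # pure-noise covariates explain almost nothing
  memb2 <- pmin(pmax(rbeta(200, 2, 2), 0), 1)
  fit0 <- membership_climate_regression(memb2,
                                        data.frame(x1 = rnorm(200),
                                                   x2 = rnorm(200)))
  expect_lt(1 - fit0$residual_deviance / fit0$null_deviance, 0.08)

  # collinear covariates are dropped with a warning
  expect_warning(
    membership_climate_regression(memb, data.frame(a = temp, b = temp)),
    "collinear"
  )
})
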