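#' Great-circle distance in kilometres
#'
#' Haversine formula on a sphere of radius 6371.0088 km (IUGG mean
#' Earth radius). Vectorized over points.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

# km offsets of points about a centre on the local tangent plane
# (equirectangular: x east, y north)
km_offsets <- function(lat, lon, centre_lat, centre_lon) {
  cbind(
    x = (lon - centre_lon) * KM_PER_DEG * cos(centre_lat * pi / 180),
    y = (lat - centre_lat) * KM_PER_DEG
  )
}

#' Geographic summary of one population
#'
#' Mean centre (planar arithmetic mean of latitude and longitude, the
#' ArcGIS Mean Center convention), standard distance (root mean squared
#' great-circle distance of members to the centre), the standard-
#' deviation ellipse (eigen-decomposition of the 2x2 covariance of
#' km-projected offsets about the centre; axes are the square roots of
#' the eigenvalues, rotation is the major-axis bearing in degrees
#' counter-clockwise from east, reported in [0, 180)), and the mean
#' pairwise great-circle distance between members. The ellipse needs at
#' least 3 members and is `NA` otherwise.
#'
#' @param points Data frame with `latitude` and `longitude` columns (one
#'   row per member).
#' @return One-row tibble: `n`, `centre_lat`, `centre_lon`,
#'   `standard_distance_km`, `ellipse_major_km`, `ellipse_minor_km`,
#'   `ellipse_rotation_deg`, `mean_pairwise_km`.
#' @export
population_geo_summary <- function(points) {
  lat <- points$latitude
  lon <- points$longitude
  n <- length(lat)
  if (n < 1) stop("empty population")
  clat <- mean(lat)
  clon <- mean(lon)
  sdist <- sqrt(mean(great_circle_km(lat, lon, clat, clon)^2))
  if (n >= 3) {
    off <- km_offsets(lat, lon, clat, clon)
    ev <- eigen(cov(off), symmetric = TRUE)
    major <- sqrt(max(ev$values[1], 0))
    minor <- sqrt(max(ev$values[2], 0))
    rot <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
    rot <- rot %% 180
  } else {
    major <- minor <- rot <- NA_real_
  }
  mp <- if (n >= 2) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    mean(great_circle_km(lat[pairs[, 1]], lon[pairs[, 1]],
                         lat[pairs[, 2]], lon[pairs[, 2]]))
  } else {
    0
  }
  tibble::tibble(
    n = n, centre_lat = clat, centre_lon = clon,
    standard_distance_km = sdist,
    ellipse_major_km = major, ellipse_minor_km = minor,
    ellipse_rotation_deg = rot,
    mean_pairwise_km = mp
  )
}

#' Geographic summaries for every population
#'
#' @param coordinates Tibble `(accession_id, latitude, longitude)`.
#' @param assignments Tibble with `accession_id` and `primary_pop`.
#' @param strong_only Restrict to strong assignments?
#' @return Tibble with one [population_geo_summary()] row per
#'   population.
#' @export
population_geo_summaries <- function(coordinates, assignments,
                                     strong_only = FALSE) {
  if (strong_only) assignments <- assignments[assignments$strong, ]
  merged <- dplyr::inner_join(coordinates, assignments, by = "accession_id")
  merged |>
    dplyr::group_by(population = .data$primary_pop) |>
    dplyr::group_modify(~ population_geo_summary(.x)) |>
    dplyr::ungroup()
}

#' Test the separation of two population mean centres
#'
#' One-tailed Student's t-test of the great-circle distance between the
#' two mean centres against the null that the centres coincide. The
#' standard error combines the populations' standard distances as
#' `sqrt(SD_A^2 / n_A + SD_B^2 / n_B)`, with n_A + n_B - 2 degrees of
#' freedom. A zero standard error with a positive distance is reported
#' as p = 0 with a flag.
#'
#' @param points_a,points_b Member coordinates (data frames with
#'   `latitude`, `longitude`), both with n >= 2.
#' @return One-row tibble `(distance_km, t, df, p_value, degenerate)`.
#' @export
centre_separation_test <- function(points_a, points_b) {
  if (nrow(points_a) < 2 || nrow(points_b) < 2) {
    stop("both populations need at least 2 members")
  }
  sa <- population_geo_summary(points_a)
  sb <- population_geo_summary(points_b)
  d <- great_circle_km(sa$centre_lat, sa$centre_lon, sb$centre_lat, sb$centre_lon)
  se <- sqrt(sa$standard_distance_km^2 / sa$n + sb$standard_distance_km^2 / sb$n)
  df <- sa$n + sb$n - 2L
  degenerate <- se == 0 && d > 0
  t_stat <- if (se == 0) {
    if (d > 0) Inf else 0
  } else {
    d / se
  }
  p <- if (degenerate) 0 else pt(t_stat, df, lower.tail = FALSE)
  tibble::tibble(distance_km = d, t = t_stat, df = df, p_value = p,
                 degenerate = degenerate)
}

#' All pairwise mean-centre separation tests
#'
#' @inheritParams population_geo_summaries
#' @param alpha Significance levels reported as counts.
#' @return Tibble `(pop_a, pop_b, distance_km, t, df, p_value)` over all
#'   unordered population pairs, with attribute `n_significant` =
#'   counts at each `alpha`.
#' @export
centre_separation_tests <- function(coordinates, assignments,
                                    alpha = c(0.05, 0.01)) {
  merged <- dplyr::inner_join(coordinates, assignments, by = "accession_id")
  pops <- sort(unique(merged$primary_pop))
  out <- NULL
  for (i in seq_along(pops)) {
    for (j in seq_along(pops)) {
      if (j <= i) next
      res <- centre_separation_test(
        merged[merged$primary_pop == pops[i], ],
        merged[merged$primary_pop == pops[j], ]
      )
      out <- dplyr::bind_rows(out, dplyr::bind_cols(
        tibble::tibble(pop_a = pops[i], pop_b = pops[j]), res
      ))
    }
  }
  attr(out, "n_significant") <- setNames(
    vapply(alpha, function(a) sum(out$p_value < a), numeric(1)),
    paste0("p<", alpha)
  )
  out
}

#' Accession, month and variable climate means
#'
#' @param climate Long tibble `(accession_id, variable, month, value)`
#'   with a complete 12-month grid per variable.
#' @return List of tibbles: `accession_means` (overall mean per
#'   accession), `monthly_means` (per month across variables),
#'   `variable_means` (per variable across months), and `n_missing`.
#' @export
climate_summaries <- function(climate) {
  n_missing <- sum(is.na(climate$value))
  list(
    accession_means = climate |>
      dplyr::group_by(.data$accession_id) |>
      dplyr::summarise(mean_value = mean(.data$value), .groups = "drop"),
    monthly_means = climate |>
      dplyr::group_by(.data$accession_id, .data$month) |>
      dplyr::summarise(mean_value = mean(.data$value), .groups = "drop"),
    variable_means = climate |>
      dplyr::group_by(.data$accession_id, .data$variable) |>
      dplyr::summarise(mean_value = mean(.data$value), .groups = "drop"),
    n_missing = n_missing
  )
}

#' Between- versus within-population climate variance
#'
#' For one month and a set of climate variables, each variable is
#' z-scored across the included accessions and the standardized
#' (accession, variable) values pooled as observations of a one-way
#' ANOVA on population: `F = MS_between / MS_within`, with
#' `-log10 p` from the F distribution. Constant variables are excluded
#' with a warning. Restricting `accession_ids` to, say, the spring or
#' winter accessions reproduces a habit-split analysis.
#'
#' @param climate Long climate tibble.
#' @param assignments Tibble with `accession_id`, `primary_pop`.
#' @param month Month 1-12.
#' @param variables Variables to pool (default: all present).
#' @param accession_ids Optional subset of accessions (e.g. one growth
#'   habit).
#' @return One-row tibble `(month, n_variables, F, df_between,
#'   df_within, p_value, neg_log10_p)`.
#' @export
climate_anova <- function(climate, assignments, month,
                          variables = NULL, accession_ids = NULL) {
  sub <- climate[climate$month == month, ]
  if (!is.null(variables)) sub <- sub[sub$variable %in% variables, ]
  if (!is.null(accession_ids)) {
    sub <- sub[sub$accession_id %in% accession_ids, ]
    assignments <- assignments[assignments$accession_id %in% accession_ids, ]
  }
  sub <- dplyr::inner_join(
    sub, assignments[, c("accession_id", "primary_pop")], by = "accession_id"
  )
  pops_present <- unique(sub$primary_pop)
  if (length(pops_present) < 2) stop("need at least 2 populations")
  sub <- sub |>
    dplyr::group_by(.data$variable) |>
    dplyr::mutate(v_sd = sd(.data$value),
                  z = (.data$value - mean(.data$value)) / .data$v_sd) |>
    dplyr::ungroup()
  if (any(sub$v_sd == 0)) {
    dropped <- unique(sub$variable[sub$v_sd == 0])
    warning("constant climate variable(s) excluded: ",
            paste(dropped, collapse = ", "))
    sub <- sub[sub$v_sd > 0, ]
  }
  if (nrow(sub) == 0) stop("no non-constant variables left")
  fit <- stats::lm(z ~ factor(primary_pop), data = sub)
  an <- anova(fit)
  f_val <- an$`F value`[1]
  p <- an$`Pr(>F)`[1]
  tibble::tibble(
    month = month,
    n_variables = dplyr::n_distinct(sub$variable),
    F = f_val,
    df_between = an$Df[1],
    df_within = an$Df[2],
    p_value = p,
    neg_log10_p = -log10(pmax(p, .Machine$double.xmin))
  )
}

#' Monthly climate F-ratio table
#'
#' [climate_anova()] applied month by month, optionally within an
#' accession subset (growth-habit split).
#'
#' @inheritParams climate_anova
#' @return Tibble with one row per month.
#' @export
climate_anova_by_month <- function(climate, assignments,
                                   variables = NULL, accession_ids = NULL) {
  purrr::map_dfr(sort(unique(climate$month)), function(m) {
    climate_anova(climate, assignments, month = m,
                  variables = variables, accession_ids = accession_ids)
  })
}

#' Permutation control for the climate F-ratio
#'
#' Recomputes the climate F after randomly permuting population labels.
#' For a single variable (one observation per accession) the permuted F
#' has mean close to 1, the standard randomization control. When
#' variables are pooled the per-accession values are correlated across
#' variables, so the pooled permuted F is not exactly calibrated; run
#' the control per variable.
#'
#' @inheritParams climate_anova
#' @param n_perm Number of permutations.
#' @return Tibble `(perm, F)`.
#' @export
climate_anova_permuted <- function(climate, assignments, month,
                                   n_perm = 200, variables = NULL,
                                   accession_ids = NULL) {
  purrr::map_dfr(seq_len(n_perm), function(i) {
    shuffled <- assignments
    shuffled$primary_pop <- sample(shuffled$primary_pop)
    res <- climate_anova(climate, shuffled, month = month,
                         variables = variables, accession_ids = accession_ids)
    tibble::tibble(perm = i, F = res$F)
  })
}

#' Fractional-membership climate regression
#'
#' Quasi-binomial logistic fit (logit link) of a proportional-
#' membership column on climate covariates, with the sequential
#' deviance partition of the covariates. Collinear covariates are
#' dropped with a warning (the partition is order-dependent, in the
#' order given).
#'
#' @param membership Numeric vector in \[0, 1\] (one accession each).
#' @param covariates Data frame of climate summary covariates, rows
#'   matching `membership`.
#' @return List of class `membership_climate_fit`: `coefficients`
#'   tibble, `deviance_partition` tibble (sequential), `null_deviance`,
#'   `residual_deviance`, `dropped` (collinear covariates removed).
#' @export
membership_climate_regression <- function(membership, covariates) {
  if (any(membership < 0 | membership > 1)) {
    stop("membership fractions must lie in [0, 1]")
  }
  covariates <- as.data.frame(covariates)
  X <- stats::model.matrix(~ ., data = covariates)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep_cols <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(colnames(X), colnames(X)[keep_cols])
    dropped <- setdiff(dropped, "(Intercept)")
    warning("collinear covariate(s) dropped: ", paste(dropped, collapse = ", "))
    covariates <- covariates[, setdiff(names(covariates), dropped), drop = FALSE]
  }
  dat <- data.frame(.y = membership, covariates)
  fit <- glm(.y ~ ., data = dat, family = quasibinomial(),
             control = list(epsilon = 1e-8, maxit = 100))
  an <- anova(fit)
  part <- tibble::tibble(
    term = rownames(an)[-1],
    deviance = an$Deviance[-1],
    df = an$Df[-1]
  )
  structure(
    list(
      coefficients = tibble::tibble(term = names(coef(fit)),
                                    estimate = unname(coef(fit))),
      deviance_partition = part,
      null_deviance = fit$null.deviance,
      residual_deviance = fit$deviance,
      dropped = dropped
    ),
    class = "membership_climate_fit"
  )
}

#' @export
print.membership_climate_fit <- function(x, ...) {
  cat(sprintf(
    "Membership ~ climate (quasi-binomial): deviance %.3f -> %.3f (%.1f%% explained)\n",
    x$null_deviance, x$residual_deviance,
    100 * (1 - x$residual_deviance / x$null_deviance)
  ))
  invisible(x)
}
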