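#' Configuration for the landrace simulator
#'
#' Builds and validates the parameter set consumed by
#' [simulate_landraces()] and the individual `simulate_*()` steps. The
#' defaults emulate a European barley landrace collection: 651
#' accessions typed at 24 multi-allelic microsatellite loci, nine
#' divergent source populations with limited admixture, roughly 10%
#' missing calls, population-biased binary phenotypes, population-
#' specific geographic ellipses and a latitude/season-driven climate
#' surface.
#'
#' @param n_accessions Number of accessions (haploid individuals).
#' @param n_loci Number of loci.
#' @param n_alleles Number of alleles per locus; scalar or length
#'   `n_loci` vector. Microsatellite panels typically span 2-26 alleles
#'   per locus; the default uses the panel mean of 9 throughout.
#' @param k_true Number of source populations.
#' @param drift Per-population divergence from the ancestral allele
#'   pool, the F of the Balding-Nichols model; in (0, 1). Larger values
#'   give more differentiated populations.
#' @param admixture_alpha Symmetric Dirichlet concentration for the
#'   membership rows. `0` assigns each accession wholly to one
#'   population (near-equal population sizes); small positive values
#'   give mostly-pure accessions with some admixture.
#' @param missing_rate Probability that any single call is missing
#'   (missing completely at random).
#' @param phenotype_probs `k_true` x n_traits matrix of Bernoulli
#'   success probabilities, columns named by trait. The default mirrors
#'   the strong population bias seen in landrace panels (e.g. two-rowed
#'   ears predominating in some populations, naked caryopses in one).
#' @param geo_centres `k_true` x 2 matrix (lat, lon in degrees) of
#'   population mean centres.
#' @param geo_sd_km `k_true` x 3 matrix: ellipse semi-major SD (km),
#'   semi-minor SD (km), rotation (degrees counter-clockwise from east).
#' @param climate_params Tibble with one row per climate variable and
#'   columns `variable`, `base`, `lat_slope`, `seasonal_amp`,
#'   `peak_month`, `noise_sd`. Monthly value = base + lat_slope * lat +
#'   seasonal_amp * cos(2 * pi * (month - peak_month) / 12) + noise.
#' @param climate_noise_sd Optional scalar overriding every variable's
#'   `noise_sd`.
#' @param seed Integer RNG seed used by [simulate_landraces()].
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 651,
                       n_loci = 24,
                       n_alleles = 9,
                       k_true = 9,
                       drift = 0.3,
                       admixture_alpha = 0.05,
                       missing_rate = 0.096,
                       phenotype_probs = NULL,
                       geo_centres = NULL,
                       geo_sd_km = NULL,
                       climate_params = NULL,
                       climate_noise_sd = NULL,
                       seed = 1L) {
  stopifnot(n_accessions >= 2, n_loci >= 1, k_true >= 1)
  if (!(drift > 0 && drift < 1)) stop("`drift` must lie in (0, 1)")
  if (admixture_alpha < 0) stop("`admixture_alpha` must be >= 0")
  if (!(missing_rate >= 0 && missing_rate < 1)) {
    stop("`missing_rate` must lie in [0, 1)")
  }
  n_alleles <- as.integer(rep_len(n_alleles, n_loci))
  if (any(n_alleles < 2)) stop("every locus needs at least 2 alleles")

  phenotype_probs <- phenotype_probs %||% default_phenotype_probs(k_true)
  phenotype_probs <- as.matrix(phenotype_probs)
  if (nrow(phenotype_probs) != k_true) {
    stop("`phenotype_probs` must have `k_true` rows")
  }
  if (any(phenotype_probs < 0 | phenotype_probs > 1)) {
    stop("phenotype probabilities must lie in [0, 1]")
  }
  if (is.null(colnames(phenotype_probs))) {
    colnames(phenotype_probs) <- paste0("trait", seq_len(ncol(phenotype_probs)))
  }

  geo_centres <- as.matrix(geo_centres %||% default_geo_centres(k_true))
  geo_sd_km <- as.matrix(geo_sd_km %||% default_geo_sd(k_true))
  if (nrow(geo_centres) != k_true || ncol(geo_centres) != 2) {
    stop("`geo_centres` must be k_true x 2 (lat, lon)")
  }
  if (any(geo_centres[, 1] < -90 | geo_centres[, 1] > 90) ||
      any(geo_centres[, 2] < -180 | geo_centres[, 2] > 180)) {
    stop("geographic centres out of range")
  }
  if (nrow(geo_sd_km) != k_true || ncol(geo_sd_km) != 3) {
    stop("`geo_sd_km` must be k_true x 3 (major, minor, rotation)")
  }
  if (any(geo_sd_km[, 1:2] < 0)) stop("ellipse SDs must be non-negative")

  climate_params <- climate_params %||% default_climate_params()
  if (!is.null(climate_noise_sd)) climate_params$noise_sd <- climate_noise_sd
  if (any(climate_params$noise_sd < 0)) stop("climate noise SD must be >= 0")

  structure(
    list(
      n_accessions = as.integer(n_accessions),
      n_loci = as.integer(n_loci),
      n_alleles = n_alleles,
      k_true = as.integer(k_true),
      drift = drift,
      admixture_alpha = admixture_alpha,
      missing_rate = missing_rate,
      phenotype_probs = phenotype_probs,
      geo_centres = geo_centres,
      geo_sd_km = geo_sd_km,
      climate_params = climate_params,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Table-1-style bias pattern: traits are coded 1 = two-rowed ear,
# 1 = naked caryopsis, 1 = winter growth habit, 1 = daylength
# nonresponsive. Probabilities avoid exact 0/1 so crosstabs stay
# non-degenerate while keeping > 90% biases.
default_phenotype_probs <- function(k) {
  full <- cbind(
    two_row       = c(0.98, 0.98, 0.94, 0.71, 0.36, 0.13, 0.22, 0.14, 0.06),
    naked         = c(0.03, 0.01, 0.03, 0.75, 0.28, 0.01, 0.01, 0.01, 0.01),
    winter        = c(0.01, 0.07, 0.01, 0.01, 0.31, 0.35, 0.08, 0.65, 0.32),
    nonresponsive = c(0.99, 0.95, 0.99, 0.99, 0.67, 0.36, 0.61, 0.01, 0.08)
  )
  full[rep_len(seq_len(9), k), , drop = FALSE]
}

# Nine European mean centres: central Europe, Britain, the Swiss Alps,
# the Carpathians, a broad west-central band, the Balkans, Scandinavia/
# Baltic, a second central band, and the Mediterranean.
default_geo_centres <- function(k) {
  full <- cbind(
    lat = c(48.0, 53.0, 46.8, 47.5, 49.0, 43.0, 60.0, 50.0, 39.0),
    lon = c(10.0, -2.0,  7.5, 24.5,  5.0, 23.0, 20.0, 12.0, 10.0)
  )
  full[rep_len(seq_len(9), k), , drop = FALSE]
}

default_geo_sd <- function(k) {
  full <- cbind(
    major    = c(600, 400,  60, 250, 700, 350, 600, 650, 500),
    minor    = c(400, 300,  40, 150, 500, 250, 350, 450, 300),
    rotation = c(20,    0,   0,  30,  10, -20,  30,   0,   0)
  )
  full[rep_len(seq_len(9), k), , drop = FALSE]
}

# Nine monthly near-surface climate variables on a latitude + season
# surface. Units are the usual station units (degC, mm, days, hPa,
# fraction); slopes give cooler, wetter, cloudier conditions northwards
# and summer-peaked temperature seasonality.
default_climate_params <- function() {
  tibble::tibble(
    variable = c("temp_mean", "temp_min", "temp_max", "diurnal_range",
                 "precipitation", "wet_days", "frost_days",
                 "vapour_pressure", "cloud_cover"),
    base = c(34, 28, 40, 12, 20, 2, -14, 22, 0.20),
    lat_slope = c(-0.45, -0.45, -0.45, -0.05, 0.6, 0.18, 0.4, -0.2, 0.006),
    seasonal_amp = c(9, 8, 10, 2, 15, 3, 8, 4, 0.10),
    peak_month = c(7, 7, 7, 7, 11, 12, 1, 7, 12),
    noise_sd = c(1, 1, 1, 0.5, 5, 1, 2, 1, 0.03)
  )
}

# Dirichlet draws via normalized gammas; rows that underflow to zero
# (possible at very small concentrations) collapse to a vertex.
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = alpha, rate = 1), nrow = n, byrow = TRUE)
  s <- rowSums(g)
  zero <- s == 0
  if (any(zero)) {
    for (i in which(zero)) {
      g[i, ] <- 0
      g[i, sample.int(k, 1)] <- 1
    }
    s <- rowSums(g)
  }
  g / s
}

#' Draw ancestral and population allele frequencies
#'
#' Ancestral per-locus frequencies come from a flat Dirichlet; each
#' population's frequencies diverge from them under the Balding-Nichols
#' F-model, i.e. Dirichlet(ancestral * (1 - F) / F) with F = `drift`.
#' For a biallelic locus this gives Var(p_pop) = p (1 - p) F around the
#' ancestral p.
#'
#' @param config A [sim_config()].
#' @return List with `ancestral` (list of per-locus frequency vectors)
#'   and `P` (list of per-locus k x alleles frequency matrices).
#' @export
simulate_allele_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  scale <- (1 - config$drift) / config$drift
  ancestral <- vector("list", config$n_loci)
  P <- vector("list", config$n_loci)
  for (l in seq_len(config$n_loci)) {
    a <- config$n_alleles[l]
    anc <- as.numeric(rdirichlet_mat(1, rep(1, a)))
    pop <- rdirichlet_mat(config$k_true, anc * scale)
    if (any(!is.finite(anc)) || any(!is.finite(pop))) {
      stop("internal error: non-finite simulated frequencies")
    }
    ancestral[[l]] <- anc
    P[[l]] <- pop
  }
  list(ancestral = ancestral, P = P)
}

#' Draw membership (Q) rows for every accession
#'
#' With `admixture_alpha = 0` each accession belongs wholly to one
#' population and population sizes are as equal as `n_accessions`
#' allows; otherwise rows are symmetric-Dirichlet distributed.
#'
#' @param config A [sim_config()].
#' @return n_accessions x k_true matrix with unit row sums.
#' @export
simulate_memberships <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_accessions
  k <- config$k_true
  if (config$admixture_alpha == 0) {
    pop <- sample(rep_len(seq_len(k), n))
    q <- matrix(0, n, k)
    q[cbind(seq_len(n), pop)] <- 1
    q
  } else {
    rdirichlet_mat(n, rep(config$admixture_alpha, k))
  }
}

#' Simulate a haploid genotype matrix from known truth
#'
#' For each accession and locus the allele's population of origin is
#' drawn from the accession's membership row and the allele from that
#' population's locus frequencies; calls are then masked missing
#' completely at random at `missing_rate`.
#'
#' @param truth A `synthetic_truth` (or the list returned by
#'   [simulate_allele_frequencies()] together with a Q matrix).
#' @param config A [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  q <- truth$true_Q
  P <- truth$true_P
  n <- nrow(q)
  calls <- matrix(NA_integer_, n, config$n_loci)
  for (l in seq_len(config$n_loci)) {
    pl <- P[[l]]
    origin <- sample_categorical_rows(q[rep(seq_len(n), 1), , drop = FALSE])
    calls[, l] <- sample_categorical_rows(pl[origin, , drop = FALSE])
  }
  if (config$missing_rate > 0) {
    miss <- matrix(runif(n * config$n_loci) < config$missing_rate,
                   n, config$n_loci)
    calls[miss] <- NA_integer_
  }
  genotype_matrix(
    calls,
    accession_ids = sprintf("acc%03d", seq_len(n)),
    locus_ids = sprintf("ssr%02d", seq_len(config$n_loci))
  )
}

# one categorical draw per row of a probability matrix (rows sum to 1)
sample_categorical_rows <- function(prob) {
  prob <- as.matrix(prob)
  n <- nrow(prob)
  k <- ncol(prob)
  if (k == 1) return(rep(1L, n))
  cum <- prob
  for (j in 2:k) cum[, j] <- cum[, j - 1] + prob[, j]
  u <- runif(n) * cum[, k]
  as.integer(rowSums(u > cum) + 1L)
}

#' Simulate binary phenotypes driven by the primary population
#'
#' Each trait of each accession is Bernoulli with the success
#' probability of the accession's primary (argmax-membership)
#' population; admixed fractions do not modulate the probability.
#'
#' @inheritParams simulate_genotypes
#' @return Tibble: `accession_id` plus one 0/1 column per trait.
#' @export
simulate_phenotypes <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  probs <- config$phenotype_probs
  primary <- max.col(truth$true_Q, ties.method = "first")
  n <- length(primary)
  out <- tibble::tibble(accession_id = sprintf("acc%03d", seq_len(n)))
  for (trait in colnames(probs)) {
    out[[trait]] <- rbinom(n, 1L, probs[primary, trait])
  }
  out
}

#' Simulate coordinates and monthly climate values
#'
#' Coordinates are drawn from the primary population's standard-
#' deviation ellipse (km offsets rotated then converted to degrees at
#' the centre latitude). Climate values follow the deterministic
#' latitude + season surface in `config$climate_params` plus iid
#' Gaussian noise, 12 monthly values per variable per accession.
#'
#' @inheritParams simulate_genotypes
#' @return List with `coordinates` (tibble: accession_id, latitude,
#'   longitude) and `climate` (long tibble: accession_id, variable,
#'   month, value).
#' @export
simulate_geography_climate <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  primary <- max.col(truth$true_Q, ties.method = "first")
  n <- length(primary)
  cen <- config$geo_centres[primary, , drop = FALSE]
  sds <- config$geo_sd_km[primary, , drop = FALSE]
  u <- rnorm(n, 0, sds[, 1])
  v <- rnorm(n, 0, sds[, 2])
  th <- sds[, 3] * pi / 180
  x_km <- u * cos(th) - v * sin(th)   # east
  y_km <- u * sin(th) + v * cos(th)   # north
  lat <- cen[, 1] + y_km / KM_PER_DEG
  lon <- cen[, 2] + x_km / (KM_PER_DEG * cos(cen[, 1] * pi / 180))
  coordinates <- tibble::tibble(
    accession_id = sprintf("acc%03d", seq_len(n)),
    latitude = lat, longitude = lon
  )

  cp <- config$climate_params
  climate <- tidyr::expand_grid(
    accession_id = coordinates$accession_id,
    variable = cp$variable,
    month = 1:12
  )
  idx <- match(climate$variable, cp$variable)
  acc_lat <- lat[match(climate$accession_id, coordinates$accession_id)]
  det <- cp$base[idx] + cp$lat_slope[idx] * acc_lat +
    cp$seasonal_amp[idx] * cos(2 * pi * (climate$month - cp$peak_month[idx]) / 12)
  climate$value <- det + rnorm(nrow(climate), 0, cp$noise_sd[idx])
  list(coordinates = coordinates, climate = climate)
}

#' Simulate a full landrace study with ground truth
#'
#' Runs the four simulation stages under one seed and returns all data
#' tables plus a `synthetic_truth` object for parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @return List of class `landrace_sim`: `genotypes`
#'   ([genotype_matrix()]), `phenotypes`, `coordinates`, `climate`
#'   (tibbles) and `truth` (`synthetic_truth`: `true_Q`, `true_P`,
#'   `ancestral_freqs`, `config`).
#' @export
simulate_landraces <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  freqs <- simulate_allele_frequencies(config)
  truth <- structure(
    list(
      true_Q = simulate_memberships(config),
      true_P = freqs$P,
      ancestral_freqs = freqs$ancestral,
      config = config
    ),
    class = "synthetic_truth"
  )
  genotypes <- simulate_genotypes(truth, config)
  phenotypes <- simulate_phenotypes(truth, config)
  geo <- simulate_geography_climate(truth, config)
  structure(
    list(
      genotypes = genotypes,
      phenotypes = phenotypes,
      coordinates = geo$coordinates,
      climate = geo$climate,
      truth = truth
    ),
    class = "landrace_sim"
  )
}

#' @export
print.landrace_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(
    "Synthetic landrace study: %d accessions, %d loci, %d populations (drift %.2f)\n",
    cfg$n_accessions, cfg$n_loci, cfg$k_true, cfg$drift
  ))
  invisible(x)
}
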