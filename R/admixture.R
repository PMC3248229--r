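#' Fit the haploid admixture model by Gibbs sampling
#'
#' Re-implements the admixture model for haploid multi-allelic data:
#' each accession i has a membership row q_i over k populations, each
#' population k a frequency vector per locus, and each non-missing call
#' a latent population of origin. One sweep samples (i) the origins
#' given q and P, (ii) P from its Dirichlet full conditional, (iii) q
#' from its Dirichlet full conditional and (iv) the symmetric admixture
#' parameter alpha by a Metropolis step with a reflecting normal
#' proposal and a uniform prior on (0, `alpha_max`). Missing calls
#' contribute nothing to any conditional. Posterior means of Q and P
#' over the thinned post-burn-in samples are returned, together with
#' the data log-likelihood trace and the model-evidence approximation
#' from [estimate_lnP()].
#'
#' Defaults are desk-scale (5,000 burn-in, 20,000 iterations thinned by
#' 10); production-scale settings such as 200,000 / 1,500,000 are
#' available through the same arguments.
#'
#' @param g A [genotype_matrix()].
#' @param k Number of populations (>= 1, <= number of accessions).
#' @param burnin,iters,thin MCMC schedule (sweeps).
#' @param seed Integer seed; fixes the run bit-reproducibly.
#' @param lambda_prior Symmetric Dirichlet prior mass on allele
#'   frequencies.
#' @param alpha_init,alpha_sd,alpha_max Initial value, proposal SD and
#'   prior upper bound for the admixture parameter.
#' @return Object of class `structure_fit`: `Q` (posterior-mean
#'   membership matrix), `P` (list of per-locus k x alleles posterior-
#'   mean frequency matrices, columns named by allele code),
#'   `loglik_trace`, `alpha_trace`, `lnP_est`, `alpha_accept`,
#'   `max_simplex_dev`, plus the run settings.
#' @export
gibbs_run <- function(g, k, burnin = 5000, iters = 20000, thin = 10,
                      seed = 1L, lambda_prior = 1.0,
                      alpha_init = 1.0, alpha_sd = 0.025, alpha_max = 10.0) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$calls)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k larger than the number of accessions")
  if (iters <= 0 || burnin < 0 || thin < 1) stop("invalid MCMC schedule")
  if (lambda_prior <= 0 || alpha_max <= 0 || alpha_sd <= 0) {
    stop("priors and proposal SD must be positive")
  }

  enc <- encode_alleles(g)
  set.seed(seed)
  raw <- gibbs_cpp(enc$calls, enc$n_alleles, as.integer(k),
                   as.integer(burnin), as.integer(iters), as.integer(thin),
                   lambda_prior, alpha_init, alpha_sd, alpha_max)
  P <- decode_P(raw$P, enc, k)
  q <- raw$Q
  dimnames(q) <- list(g$accession_ids, paste0("pop", seq_len(k)))
  structure(
    list(
      Q = q, P = P,
      loglik_trace = raw$loglik_trace,
      alpha_trace = raw$alpha_trace,
      lnP_est = estimate_lnP(raw$loglik_trace),
      alpha_accept = raw$alpha_accept,
      max_simplex_dev = raw$max_simplex_dev,
      k = as.integer(k), seed = as.integer(seed),
      burnin = burnin, iters = iters, thin = thin,
      lambda_prior = lambda_prior
    ),
    class = "structure_fit"
  )
}

# map arbitrary allele codes to 1..A_l per locus (0 = missing)
encode_alleles <- function(g) {
  L <- ncol(g$calls)
  codes <- vector("list", L)
  calls <- matrix(0L, nrow(g$calls), L)
  for (l in seq_len(L)) {
    col <- g$calls[, l]
    codes[[l]] <- sort(unique(col[!is.na(col)]))
    if (length(codes[[l]]) == 0) {
      codes[[l]] <- integer(0)
    } else {
      calls[, l] <- ifelse(is.na(col), 0L, match(col, codes[[l]]))
    }
  }
  n_alleles <- pmax(1L, lengths(codes))
  list(calls = calls, n_alleles = as.integer(n_alleles), codes = codes,
       locus_ids = g$locus_ids)
}

decode_P <- function(Pflat, enc, k) {
  d <- dim(Pflat)
  amax <- d[2]
  purrr::map(seq_along(enc$codes), function(l) {
    a <- length(enc$codes[[l]])
    if (a == 0) a <- 1
    m <- matrix(Pflat[seq_len(k) + rep((seq_len(a) - 1) * k, each = k) +
                        (l - 1) * k * amax], nrow = k)
    rownames(m) <- paste0("pop", seq_len(k))
    colnames(m) <- if (length(enc$codes[[l]])) as.character(enc$codes[[l]]) else "1"
    m
  }) |> setNames(enc$locus_ids)
}

#' @export
print.structure_fit <- function(x, ...) {
  cat(sprintf(
    "Haploid admixture fit: %d accessions, k = %d, lnP(X|K) = %.1f (seed %d)\n",
    nrow(x$Q), x$k, x$lnP_est, x$seed
  ))
  invisible(x)
}

#' Model-evidence approximation from a log-likelihood trace
#'
#' The harmonic-style approximation used for K selection:
#' `mean(trace) - var(trace) / 2`, with the variance taken over the
#' recorded samples (denominator n, not n - 1).
#'
#' @param loglik_trace Numeric vector of recorded data log-likelihoods
#'   (length >= 2, all finite).
#' @return Scalar estimate of ln Pr(X | K).
#' @export
estimate_lnP <- function(loglik_trace) {
  if (length(loglik_trace) < 2) stop("need at least 2 recorded log-likelihoods")
  if (any(!is.finite(loglik_trace))) stop("non-finite log-likelihood in trace")
  m <- mean(loglik_trace)
  v <- mean((loglik_trace - m)^2)
  m - v / 2
}

#' Data log-likelihood of a genotype matrix under (Q, P)
#'
#' Sums `log sum_k q_ik p_k,l,a` over the non-missing calls; missing
#' cells are skipped entirely (the admixture model needs no imputation
#' for gaps). An allele with zero probability under every population
#' yields `-Inf` with a warning.
#'
#' @param g A [genotype_matrix()].
#' @param Q Accessions x k membership matrix.
#' @param P List of per-locus k x alleles frequency matrices with
#'   allele codes as column names (as in a `structure_fit`).
#' @return Scalar log-likelihood (0 for an all-missing matrix).
#' @export
data_loglik <- function(g, Q, P) {
  stopifnot(inherits(g, "genotype_matrix"))
  Q <- as.matrix(Q)
  if (nrow(Q) != nrow(g$calls)) stop("Q rows must match accessions")
  if (length(P) != ncol(g$calls)) stop("P must have one matrix per locus")
  total <- 0
  hit_zero <- FALSE
  for (l in seq_len(ncol(g$calls))) {
    col <- g$calls[, l]
    obs <- which(!is.na(col))
    if (length(obs) == 0) next
    pl <- P[[l]]
    if (ncol(Q) != nrow(pl)) stop("Q and P disagree on k")
    a_idx <- match(as.character(col[obs]), colnames(pl))
    if (anyNA(a_idx)) stop("allele code absent from P at locus ", l)
    mix <- Q[obs, , drop = FALSE] %*% pl
    vals <- mix[cbind(seq_along(obs), a_idx)]
    if (any(vals == 0)) hit_zero <- TRUE
    total <- total + sum(log(vals))
  }
  if (hit_zero) warning("allele with zero probability under all populations; -Inf log-likelihood")
  total
}

#' @rdname gibbs_run
#' @param x A `structure_fit`.
#' @param ... Unused.
#' @export
tidy.structure_fit <- function(x, ...) {
  tibble::as_tibble(x$Q, rownames = "accession_id") |>
    tidyr::pivot_longer(-"accession_id",
                        names_to = "population", values_to = "membership")
}

#' @rdname gibbs_run
#' @export
glance.structure_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, lnP_est = x$lnP_est,
    mean_alpha = mean(x$alpha_trace),
    alpha_accept = x$alpha_accept,
    burnin = x$burnin, iters = x$iters, thin = x$thin, seed = x$seed
  )
}
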