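# Hungarian algorithm (potentials formulation), O(n^3). Minimizes
# sum(cost[i, p[i]]). No LSAP solver ships with the installed stack, so
# this is written out and verified against brute force in the tests.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  a <- matrix(0, n + 1, n + 1)
  a[2:(n + 1), 2:(n + 1)] <- cost
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j]: row matched to column j (index 1 = virtual)
  way <- integer(n + 1)
  for (i in 2:(n + 1)) {
    p[1] <- i
    j0 <- 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- a[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  perm <- integer(n)
  for (j in 2:(n + 1)) perm[p[j] - 1] <- j - 1
  as.integer(perm)
}

#' Align two Q-matrices across the label-switching ambiguity
#'
#' Independent MCMC runs label populations arbitrarily. This finds the
#' column permutation of `Qb` maximizing the sum of per-matched-column
#' Pearson correlations with `Qa` (optimal assignment on the k x k
#' correlation matrix), and applies the replicate-reproducibility rule:
#' runs agree when every matched correlation exceeds `threshold`.
#'
#' @param Qa,Qb Membership matrices over the same accessions, same k.
#' @param threshold Reproducibility cutoff on the matched correlations.
#' @return Object of class `q_alignment`: `permutation` (column of `Qb`
#'   matched to each column of `Qa`), `r` (matched correlations),
#'   `reproducible`, `undefined` (columns with zero variance, if any)
#'   and `Qb_aligned`.
#' @export
align_q <- function(Qa, Qb, threshold = 0.999) {
  Qa <- as.matrix(Qa)
  Qb <- as.matrix(Qb)
  if (!all(dim(Qa) == dim(Qb))) stop("Q-matrices differ in shape (k or accessions)")
  k <- ncol(Qa)
  sd_a <- apply(Qa, 2, sd)
  sd_b <- apply(Qb, 2, sd)
  undefined <- sd_a == 0 | sd_b == 0
  C <- suppressWarnings(cor(Qa, Qb))
  C[!is.finite(C)] <- -1   # zero-variance columns can never certify a match
  perm <- hungarian_min(-C)
  r <- C[cbind(seq_len(k), perm)]
  r[sd_a == 0 | sd_b[perm] == 0] <- NA_real_
  structure(
    list(
      permutation = perm,
      r = r,
      reproducible = !anyNA(r) && all(r > threshold),
      threshold = threshold,
      undefined = which(undefined),
      Qb_aligned = Qb[, perm, drop = FALSE]
    ),
    class = "q_alignment"
  )
}

#' @export
print.q_alignment <- function(x, ...) {
  cat(sprintf("Q alignment: min matched r = %.6f -> %s (threshold %g)\n",
              suppressWarnings(min(x$r)),
              if (isTRUE(x$reproducible)) "reproducible" else "NOT reproducible",
              x$threshold))
  invisible(x)
}

#' Detect a symmetric (uninformative) admixture solution
#'
#' Above the supported number of populations the sampler can collapse
#' to the symmetric solution in which every accession receives an equal
#' allocation 1/k to every population. Returns `TRUE` iff
#' `max |q_ik - 1/k| < tol` over all cells.
#'
#' @param Q Membership matrix.
#' @param tol Absolute tolerance on the deviation from 1/k.
#' @export
detect_symmetric <- function(Q, tol = 0.02) {
  Q <- as.matrix(Q)
  max(abs(Q - 1 / ncol(Q))) < tol
}

#' Run replicate admixture fits with the third-run rule
#'
#' Fits the model `n_runs` times from different seeds and tests each
#' pair with [align_q()]. If no pair is reproducible, additional runs
#' (up to `max_runs`) are added, mirroring the practice of accepting K
#' once two runs agree and trying a third when the first two disagree.
#'
#' @inheritParams gibbs_run
#' @param n_runs Initial number of replicate runs.
#' @param max_runs Upper bound on total runs.
#' @param threshold Reproducibility correlation threshold.
#' @param ... Passed on to [gibbs_run()].
#' @return List of class `replicate_runs`: `fits`, `alignment` (the
#'   best pairwise alignment), `reproducible`, `symmetric` (symmetric-
#'   solution flag on the first fit), `lnP_est` (mean over the agreeing
#'   pair, or over all runs when none agree), `n_runs`.
#' @export
replicate_structure_runs <- function(g, k, seed = 1L, n_runs = 2,
                                     max_runs = 3, threshold = 0.999, ...) {
  seeds <- seed + seq_len(max_runs) - 1L
  fits <- lapply(seeds[seq_len(n_runs)], function(s) gibbs_run(g, k, seed = s, ...))
  best <- NULL
  pick_best <- function(fits) {
    best <- NULL
    pair <- NULL
    for (i in seq_len(length(fits) - 1)) {
      for (j in (i + 1):length(fits)) {
        al <- align_q(fits[[i]]$Q, fits[[j]]$Q, threshold = threshold)
        score <- suppressWarnings(min(al$r))
        if (is.null(best) || (is.finite(score) && score > attr(best, "score"))) {
          attr(al, "score") <- if (is.finite(score)) score else -Inf
          best <- al
          pair <- c(i, j)
        }
      }
    }
    attr(best, "pair") <- pair
    best
  }
  best <- pick_best(fits)
  while (!isTRUE(best$reproducible) && length(fits) < max_runs) {
    fits <- c(fits, list(gibbs_run(g, k, seed = seeds[length(fits) + 1L], ...)))
    best <- pick_best(fits)
  }
  pair <- attr(best, "pair")
  lnP <- if (isTRUE(best$reproducible)) {
    mean(vapply(fits[pair], function(f) f$lnP_est, numeric(1)))
  } else {
    mean(vapply(fits, function(f) f$lnP_est, numeric(1)))
  }
  structure(
    list(
      fits = fits,
      alignment = best,
      reproducible = isTRUE(best$reproducible),
      symmetric = detect_symmetric(fits[[1]]$Q),
      lnP_est = lnP,
      n_runs = length(fits),
      k = k
    ),
    class = "replicate_runs"
  )
}

#' Rate of change of the log evidence across K
#'
#' First differences `L(K) - L(K-1)` keyed by the larger K, with a
#' plateau report: the smallest K whose difference has fallen to at
#' most `plateau_frac` of the maximum difference (the point where
#' adding populations stops improving the evidence).
#'
#' @param lnP_by_K Named numeric vector (names = K) or two-column data
#'   frame `(K, lnP)` over consecutive K values.
#' @param plateau_frac Plateau threshold as a fraction of the largest
#'   difference.
#' @return List of class `k_rate_of_change`: `differences` tibble
#'   `(K, lnP, delta)`, `plateau_k`, `threshold`.
#' @export
rate_of_change <- function(lnP_by_K, plateau_frac = 0.1) {
  if (is.data.frame(lnP_by_K)) {
    ks <- as.integer(lnP_by_K[[1]])
    vals <- as.numeric(lnP_by_K[[2]])
  } else {
    ks <- as.integer(names(lnP_by_K))
    vals <- as.numeric(lnP_by_K)
  }
  if (length(ks) < 2 || anyNA(ks)) stop("need lnP at >= 2 consecutive K values")
  ord <- order(ks)
  ks <- ks[ord]
  vals <- vals[ord]
  if (any(diff(ks) != 1L)) stop("K sequence has gaps; differences undefined")
  delta <- diff(vals)
  dk <- ks[-1]
  mx <- max(delta)
  threshold <- if (mx > 0) plateau_frac * mx else 0
  plat <- dk[delta <= threshold]
  list(
    differences = tibble::tibble(K = dk, lnP = vals[-1], delta = delta),
    plateau_k = if (length(plat)) min(plat) else NA_integer_,
    threshold = threshold
  )
}

# logistic regression of a binary trait on a Q-matrix; the last Q
# column is dropped (rows sum to 1, so it is collinear with the
# intercept). Falls back to a lightly ridged IRLS fit under complete
# separation.
logistic_q_aic <- function(Q, trait, ridge = 1e-6) {
  Q <- as.matrix(Q)
  keep <- !is.na(trait)
  y <- trait[keep]
  if (length(unique(y)) < 2) stop("trait must carry both classes")
  X <- Q[keep, -ncol(Q), drop = FALSE]
  df <- data.frame(y = y, X)
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  mu <- fitted(fit)
  separated <- any(mu < 1e-8 | mu > 1 - 1e-8)
  if (!separated) {
    return(list(aic = fit$aic, loglik = as.numeric(logLik(fit)),
                n_params = length(coef(fit)), separated = FALSE))
  }
  warning("complete separation; reporting AIC from a ridge-penalized refit")
  Xd <- cbind(1, X)
  pvec <- c(0, rep(ridge, ncol(X)))
  beta <- numeric(ncol(Xd))
  for (it in seq_len(200)) {
    eta <- drop(Xd %*% beta)
    m <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(Xd, y - m)) - pvec * beta
    if (max(abs(g)) < 1e-8) break
    w <- pmax(m * (1 - m), 1e-10)
    H <- crossprod(Xd * w, Xd) + diag(pvec, ncol(Xd))
    beta <- beta + solve(H, g)
  }
  eta <- drop(Xd %*% beta)
  m <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  ll <- sum(y * log(m) + (1 - y) * log(1 - m))
  list(aic = 2 * length(beta) - 2 * ll, loglik = ll,
       n_params = length(beta), separated = TRUE)
}

#' Phenotype-based K selection by logistic AIC
#'
#' For each candidate K, regresses a binary trait on the Q-matrix
#' columns (intercept plus k - 1 columns; the last is dropped because
#' rows sum to one) and reports Akaike's information criterion. The
#' range of K minimizing the AIC marks where population structure best
#' predicts the phenotype.
#'
#' @param Q_by_K Named list of Q-matrices, names = K.
#' @param trait Binary 0/1 vector over the same accessions (NA
#'   allowed; such accessions are dropped).
#' @return Tibble `(K, aic, loglik, n_params, separated)`.
#' @export
phenotype_aic <- function(Q_by_K, trait) {
  purrr::map_dfr(names(Q_by_K), function(kname) {
    Q <- Q_by_K[[kname]]
    if (nrow(as.matrix(Q)) != length(trait)) {
      stop("trait length must equal the accession count")
    }
    res <- logistic_q_aic(Q, trait)
    tibble::tibble(K = as.integer(kname), aic = res$aic, loglik = res$loglik,
                   n_params = res$n_params, separated = res$separated)
  })
}

#' Assign accessions to their primary population
#'
#' Argmax membership per accession, ties broken deterministically
#' towards the lowest population index. An accession is `strong` when
#' its primary membership is at least `strong_threshold`; a primary
#' membership strictly below 0.5 is counted separately as weakly
#' assigned.
#'
#' @param Q Membership matrix (rownames used as accession ids).
#' @param strong_threshold Membership needed for a strong assignment.
#' @return Tibble `(accession_id, primary_pop, membership, strong)`
#'   with attribute `counts` = list(n, n_strong, n_below_half).
#' @export
assign_populations <- function(Q, strong_threshold = 0.9) {
  Q <- as.matrix(Q)
  ids <- rownames(Q) %||% sprintf("acc%03d", seq_len(nrow(Q)))
  primary <- max.col(Q, ties.method = "first")
  memb <- Q[cbind(seq_len(nrow(Q)), primary)]
  out <- tibble::tibble(
    accession_id = ids,
    primary_pop = primary,
    membership = memb,
    strong = memb >= strong_threshold
  )
  attr(out, "counts") <- list(
    n = nrow(out),
    n_strong = sum(out$strong),
    n_below_half = sum(out$membership < 0.5)
  )
  out
}

#' Trace hierarchical population structure across K
#'
#' Takes strong-accession population labels at each K of a consecutive
#' range and, for each consecutive pair (K, K+1), tabulates labels
#' against each other. Each K+1 population is mapped to its majority
#' parent at K; the hierarchy score is the fraction of accessions
#' (present and strong at both K) whose K label equals the majority
#' parent of their K+1 label — 1 when increasing K only ever splits
#' existing populations.
#'
#' @param assignments_by_K Named list (names = K, consecutive) of
#'   tibbles/data frames with columns `accession_id` and a population
#'   label column (`primary_pop` or the second column).
#' @return List of class `hierarchy_trace`: `parent_map` tibble
#'   `(K_child, child_pop, parent_pop, n, agreement)`, `pair_scores`
#'   tibble `(K_child, score, n_shared)` and `score` (accession-
#'   weighted overall fraction).
#' @export
trace_hierarchy <- function(assignments_by_K) {
  ks <- as.integer(names(assignments_by_K))
  if (anyNA(ks) || length(ks) < 2) stop("need labelled assignments for >= 2 K values")
  ord <- order(ks)
  ks <- ks[ord]
  assignments_by_K <- assignments_by_K[ord]
  if (any(diff(ks) != 1L)) stop("K range must be consecutive")
  get_labels <- function(df, K) {
    pop <- if ("primary_pop" %in% names(df)) df$primary_pop else df[[2]]
    if (nrow(df) == 0) stop("empty strong-accession set at K = ", K)
    setNames(pop, df$accession_id)
  }
  parent_map <- NULL
  pair_scores <- NULL
  hits <- 0
  total <- 0
  for (idx in seq_len(length(ks) - 1)) {
    la <- get_labels(assignments_by_K[[idx]], ks[idx])
    lb <- get_labels(assignments_by_K[[idx + 1]], ks[idx + 1])
    shared <- intersect(names(la), names(lb))
    if (length(shared) == 0) stop("no shared strong accessions between K = ",
                                  ks[idx], " and K = ", ks[idx + 1])
    tab <- table(parent = la[shared], child = lb[shared])
    for (child in colnames(tab)) {
      col <- tab[, child]
      parent <- rownames(tab)[which.max(col)]
      parent_map <- dplyr::bind_rows(parent_map, tibble::tibble(
        K_child = ks[idx + 1],
        child_pop = child,
        parent_pop = parent,
        n = sum(col),
        agreement = max(col) / sum(col)
      ))
    }
    majority_parent <- parent_map$parent_pop[parent_map$K_child == ks[idx + 1]]
    names(majority_parent) <- parent_map$child_pop[parent_map$K_child == ks[idx + 1]]
    ok <- la[shared] == majority_parent[as.character(lb[shared])]
    pair_scores <- dplyr::bind_rows(pair_scores, tibble::tibble(
      K_child = ks[idx + 1], score = mean(ok), n_shared = length(shared)
    ))
    hits <- hits + sum(ok)
    total <- total + length(ok)
  }
  structure(
    list(parent_map = parent_map, pair_scores = pair_scores,
         score = hits / total),
    class = "hierarchy_trace"
  )
}

#' @export
print.hierarchy_trace <- function(x, ...) {
  cat(sprintf("Hierarchy trace over K = %s: score %.3f\n",
              paste(range(x$parent_map$K_child), collapse = "-"), x$score))
  invisible(x)
}

#' Population-by-phenotype cross-tabulation with chi-squared tests
#'
#' Builds per-population counts, denominators and integer percentages
#' for each trait, and tests population x trait-level association with
#' Pearson's chi-squared statistic (no continuity correction) on the
#' count table, accessions with a missing trait value excluded.
#'
#' @param assignments Tibble from [assign_populations()] (or any table
#'   with `accession_id` and `primary_pop`).
#' @param phenotypes Tibble with `accession_id` and one column per
#'   trait (binary or factor; NA = not scored).
#' @return List of class `phenotype_crosstab`: `table` tibble
#'   `(trait, population, level, count, denominator, percent)` and
#'   `tests` tibble `(trait, statistic, df, p_value, note)`.
#' @export
phenotype_crosstab <- function(assignments, phenotypes) {
  traits <- setdiff(names(phenotypes), "accession_id")
  merged <- dplyr::inner_join(
    assignments[, c("accession_id", "primary_pop")],
    phenotypes, by = "accession_id"
  )
  if (dplyr::n_distinct(merged$primary_pop) < 2) {
    stop("need at least 2 populations with data")
  }
  tab_rows <- NULL
  test_rows <- NULL
  for (trait in traits) {
    sub <- merged[!is.na(merged[[trait]]), c("primary_pop", trait)]
    counts <- table(factor(sub$primary_pop), factor(sub[[trait]]))
    den <- rowSums(counts)
    for (pop in rownames(counts)) {
      for (lev in colnames(counts)) {
        tab_rows <- dplyr::bind_rows(tab_rows, tibble::tibble(
          trait = trait,
          population = pop,
          level = lev,
          count = as.integer(counts[pop, lev]),
          denominator = as.integer(den[pop]),
          percent = as.integer(round(100 * counts[pop, lev] / den[pop]))
        ))
      }
    }
    if (ncol(counts) < 2) {
      test_rows <- dplyr::bind_rows(test_rows, tibble::tibble(
        trait = trait, statistic = NA_real_, df = NA_integer_,
        p_value = NA_real_, note = "single trait level; chi-squared undefined"
      ))
    } else {
      ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
      test_rows <- dplyr::bind_rows(test_rows, tibble::tibble(
        trait = trait, statistic = unname(ct$statistic),
        df = as.integer(ct$parameter), p_value = unname(ct$p.value),
        note = NA_character_
      ))
    }
  }
  structure(list(table = tab_rows, tests = test_rows),
            class = "phenotype_crosstab")
}

#' @export
print.phenotype_crosstab <- function(x, ...) {
  print(x$tests)
  invisible(x)
}
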