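test_that("hungarian assignment matches brute force on random matrices", {
  set.seed(71)
  for (n in c(2, 4, 6, 7)) {
    for (rep in 1:4) {
      cost <- matrix(rnorm(n * n), n, n)
      perm <- landpop:::hungarian_min(cost)
      bf <- brute_force_assignment(cost)
      expect_equal(sum(cost[cbind(seq_len(n), perm)]), bf$value,
                   tolerance = 1e-12)
    }
  }
})

test_that("alignment recovers identity and arbitrary column shuffles", {
  set.seed(72)
  Q <- matrix(rgamma(200 * 4, 0.2), 200, 4)
  Q <- Q / rowSums(Q)
  self <- align_q(Q, Q)
  expect_identical(self$permutation, 1:4)
  expect_equal(self$r, rep(1, 4))
  expect_true(self$reproducible)

  shuffle <- c(3L, 1L, 4L, 2L)
  al <- align_q(Q, Q[, shuffle])
  expect_identical(shuffle[al$permutation], 1:4)
  expect_equal(al$r, rep(1, 4))
})

test_that("alignment is symmetric: inverse permutations, same correlations", {
  set.seed(73)
  A <- matrix(rgamma(150 * 5, 0.3), 150, 5); A <- A / rowSums(A)
  B <- A[, c(2, 5, 1, 4, 3)] + matrix(rnorm(750, 0, 0.01), 150, 5)
  ab <- align_q(A, B)
  ba <- align_q(B, A)
  expect_identical(order(ab$permutation), ba$permutation)
  expect_equal(sort(ab$r), sort(ba$r), tolerance = 1e-12)
})

test_that("zero-variance membership columns are flagged, never reproducible", {
  Q <- cbind(rep(0.5, 10), rep(0.5, 10))
  al <- align_q(Q, Q)
  expect_false(al$reproducible)
  expect_true(length(al$undefined) > 0)
  expect_true(anyNA(al$r))
  expect_error(align_q(Q, Q[, 1, drop = FALSE]), "shape")
})

test_that("symmetric-solution detection fires at the uniform allocation", {
  k <- 16
  uniform <- matrix(1 / k, 30, k)
  expect_true(detect_symmetric(uniform))
  expect_equal(unique(as.numeric(uniform)), 0.0625)

  unit <- diag(4)[rep(1:4, 5), ]
  expect_false(detect_symmetric(unit))

  tol <- 0.02
  noisy <- matrix(1 / k + 2 * tol * rep(c(1, -1), length.out = 30 * k), 30, k)
  expect_false(detect_symmetric(noisy, tol = tol))
})

test_that("rate of change produces keyed differences and a plateau", {
  roc <- rate_of_change(c("2" = -100, "3" = -50, "4" = -40, "5" = -39))
  expect_equal(roc$differences$K, 3:5)
  expect_equal(roc$differences$delta, c(50, 10, 1))
  expect_equal(roc$plateau_k, 5L)   # first K at <= 10% of the max gain

  flat <- rate_of_change(c("2" = -7, "3" = -7, "4" = -7))
  expect_true(all(flat$differences$delta == 0))
  expect_equal(flat$plateau_k, 3L)  # smallest K in the difference series

  expect_error(rate_of_change(c("2" = -10, "4" = -5)), "gaps")
})

test_that("uniform memberships collapse the phenotype regression to intercept-only", {
  n <- 40
  Q <- matrix(1 / 3, n, 3)
  trait <- rep(c(0, 1), n / 2)
  res <- landpop:::logistic_q_aic(Q, trait)
  expect_equal(res$aic, 2 + 2 * n * log(2), tolerance = 1e-6)
})

test_that("phenotype AIC matches a brute-force likelihood maximization oracle", {
  set.seed(74)
  n <- 20
  Q <- matrix(rgamma(n * 3, 0.5), n, 3); Q <- Q / rowSums(Q)
  lin <- 1.5 * Q[, 1] - 0.5
  trait <- rbinom(n, 1, 1 / (1 + exp(-lin)))
  if (length(unique(trait)) < 2) trait[1] <- 1 - trait[1]
  res <- landpop:::logistic_q_aic(Q, trait)
  # independent oracle: direct numerical maximization of the binomial
  # log-likelihood over (intercept, 2 slopes)
  X <- cbind(1, Q[, 1:2])
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(trait * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, 3), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(res$loglik, -opt$value, tolerance = 1e-5)
  expect_equal(res$aic, 2 * 3 + 2 * opt$value, tolerance = 1e-4)
})

test_that("an uninformative trait gains no more than the parameter penalty", {
  set.seed(75)
  n <- 300
  Q <- matrix(rgamma(n * 4, 0.3), n, 4); Q <- Q / rowSums(Q)
  trait <- rbinom(n, 1, 0.5)
  res <- phenotype_aic(list("4" = Q), trait)
  ll0 <- sum(trait) * log(mean(trait)) + sum(1 - trait) * log(1 - mean(trait))
  aic0 <- 2 - 2 * ll0
  # random slopes buy at most a chi-squared(3)'s worth of likelihood
  expect_gt(res$aic, aic0 - 10)
  expect_lt(res$aic, aic0 + 2 * 3 + 1)
})

test_that("permuting a real trait association never improves expected AIC", {
  sim <- small_sim(n = 90, k = 3, seed = 76)
  primary <- max.col(sim$truth$true_Q)
  set.seed(77)
  trait <- rbinom(90, 1, c(0.9, 0.1, 0.1)[primary])
  fit <- gibbs_run(sim$genotypes, 3, burnin = 500, iters = 2000, seed = 8)
  aic_true <- phenotype_aic(list("3" = fit$Q), trait)$aic
  perm_aics <- vapply(1:20, function(i) {
    phenotype_aic(list("3" = fit$Q), sample(trait))$aic
  }, numeric(1))
  expect_gt(mean(perm_aics), aic_true)
})

test_that("complete separation is flagged and refit with a ridge", {
  Q <- cbind(c(rep(0.99, 10), rep(0.01, 10)))
  Q <- cbind(Q, 1 - Q)
  trait <- c(rep(1, 10), rep(0, 10))
  expect_warning(res <- landpop:::logistic_q_aic(Q, trait), "separation")
  expect_true(res$separated)
  expect_true(is.finite(res$aic))
})

test_that("primary assignment applies deterministic tie-breaks and thresholds", {
  Q <- rbind(c(0.95, 0.03, 0.02),
             c(0.50, 0.50, 0.00),
             rep(1 / 3, 3))
  rownames(Q) <- c("a", "b", "c")
  a <- assign_populations(Q)
  expect_equal(a$primary_pop, c(1, 1, 1))
  expect_true(a$strong[1])
  expect_false(a$strong[2])
  expect_equal(a$membership[2], 0.5)
  counts <- attr(a, "counts")
  expect_equal(counts$n_strong, 1)
  expect_equal(counts$n_below_half, 1)   # 0.5 is not < 0.5; only the uniform row
  expect_true(all(!(a$strong & a$membership < 0.5)))
})

test_that("perfectly nested labels trace a hierarchy with score 1", {
  ids <- sprintf("s%02d", 1:40)
  k3 <- tibble::tibble(accession_id = ids,
                       primary_pop = rep(1:2, each = 20))
  # population 1 splits into 1a (1) and 1b (3) at K = 4 (labels arbitrary)
  k4 <- tibble::tibble(accession_id = ids,
                       primary_pop = c(rep(1, 10), rep(3, 10), rep(2, 20)))
  tr <- trace_hierarchy(list("3" = k3, "4" = k4))
  expect_equal(tr$score, 1)
  pm <- tr$parent_map
  expect_equal(pm$parent_pop[pm$child_pop == "1"], "1")
  expect_equal(pm$parent_pop[pm$child_pop == "3"], "1")
  expect_equal(pm$parent_pop[pm$child_pop == "2"], "2")
})

test_that("random labels score near chance, and empty strong sets fail loudly", {
  set.seed(78)
  ids <- sprintf("s%03d", 1:600)
  k4 <- tibble::tibble(accession_id = ids,
                       primary_pop = sample(1:4, 600, TRUE))
  k5 <- tibble::tibble(accession_id = ids,
                       primary_pop = sample(1:5, 600, TRUE))
  tr <- trace_hierarchy(list("4" = k4, "5" = k5))
  expect_lt(tr$score, 0.45)   # chance is ~ 1/4 with majority-parent slack

  expect_error(
    trace_hierarchy(list("4" = k4, "5" = k5[0, ])),
    "K = 5"
  )
})

test_that("crosstab reproduces printed-count percentages and chi-squared oracles", {
  # population with 7 hulled : 21 naked -> 25% : 75%
  tabs <- counts_to_tables(rbind(c(129, 4), c(7, 21)), trait = "naked")
  ct <- phenotype_crosstab(tabs$assignments, tabs$phenotypes)
  pop2 <- ct$table[ct$table$population == "2", ]
  expect_equal(pop2$percent[pop2$level == "0"], 25L)
  expect_equal(pop2$percent[pop2$level == "1"], 75L)
  expect_equal(pop2$denominator[1], 28L)

  # independence: all cells equal -> chi-squared 0, p = 1
  tabs <- counts_to_tables(rbind(c(10, 10), c(10, 10)))
  ct <- phenotype_crosstab(tabs$assignments, tabs$phenotypes)
  expect_equal(ct$tests$statistic, 0)
  expect_equal(ct$tests$p_value, 1)

  # perfect association 10,0 / 0,10: chi-squared = 20 = sum (O-E)^2 / E
  tabs <- counts_to_tables(rbind(c(10, 0), c(0, 10)))
  ct <- phenotype_crosstab(tabs$assignments, tabs$phenotypes)
  O <- rbind(c(10, 0), c(0, 10))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(ct$tests$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(ct$tests$statistic, 20)

  # single-level trait is reported as undefined, not an error
  tabs <- counts_to_tables(rbind(c(10, 0), c(10, 0)))
  ct <- phenotype_crosstab(tabs$assignments, tabs$phenotypes)
  expect_true(is.na(ct$tests$statistic))
  expect_match(ct$tests$note, "single")
})
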