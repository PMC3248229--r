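# shared fixtures, all generated in code

# a small, well-separated, unadmixed study used across modules
small_sim <- function(n = 120, k = 3, drift = 0.3, alpha = 0,
                      missing = 0.05, seed = 101, n_loci = 24) {
  simulate_landraces(sim_config(
    n_accessions = n, n_loci = n_loci, k_true = k, drift = drift,
    admixture_alpha = alpha, missing_rate = missing, seed = seed
  ))
}

# genotype_matrix straight from an integer matrix (NA = missing)
gm <- function(m, ids = NULL) {
  genotype_matrix(
    m,
    accession_ids = ids %||% sprintf("a%02d", seq_len(nrow(m))),
    locus_ids = sprintf("L%02d", seq_len(ncol(m)))
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# expand per-population (level0, level1) counts into accession rows;
# returns list(assignments, phenotypes) for phenotype_crosstab
counts_to_tables <- function(counts, trait = "trait") {
  pops <- integer(0)
  vals <- integer(0)
  for (p in seq_len(nrow(counts))) {
    pops <- c(pops, rep(p, counts[p, 1] + counts[p, 2]))
    vals <- c(vals, rep(0L, counts[p, 1]), rep(1L, counts[p, 2]))
  }
  ids <- sprintf("x%04d", seq_along(pops))
  assignments <- tibble::tibble(accession_id = ids, primary_pop = pops)
  phenotypes <- tibble::tibble(accession_id = ids)
  phenotypes[[trait]] <- vals
  list(assignments = assignments, phenotypes = phenotypes)
}

# brute-force assignment solver for validating the Hungarian routine
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- gtools_permutations(n)
  best <- NULL
  best_val <- Inf
  for (i in seq_len(nrow(perms))) {
    v <- sum(cost[cbind(seq_len(n), perms[i, ])])
    if (v < best_val) {
      best_val <- v
      best <- perms[i, ]
    }
  }
  list(perm = best, value = best_val)
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
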