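#' Configuration for the end-to-end pipeline
#'
#' @param sim A [sim_config()] describing the synthetic study to
#'   generate, or `NULL` to read data from `paths`.
#' @param paths Named list of input files when `sim` is `NULL`:
#'   `genotypes` (STRUCTURE one-row format), and optionally
#'   `phenotypes`, `coordinates`, `climate` (headered CSV, formats as
#'   written by the pipeline itself).
#' @param k_range Candidate numbers of populations (consecutive).
#' @param k_focus K used for assignments, tree annotation and the
#'   geographic/climate stages; default: the rate-of-change plateau,
#'   falling back to the K with the largest evidence.
#' @param n_runs,max_runs Replicate runs per K; a further run (up to
#'   `max_runs`) is triggered whenever the first two disagree.
#' @param membership_threshold Strong-assignment cutoff on membership.
#' @param correlation_threshold Replicate reproducibility cutoff.
#' @param burnin,iters,thin MCMC schedule per run.
#' @param seed Master seed; all stage randomness derives from it.
#' @param out_dir Output directory (created if needed).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            paths = NULL,
                            k_range = 2:16,
                            k_focus = NULL,
                            n_runs = 2,
                            max_runs = 3,
                            membership_threshold = 0.9,
                            correlation_threshold = 0.999,
                            burnin = 5000,
                            iters = 20000,
                            thin = 10,
                            seed = 1L,
                            out_dir = tempfile("landpop_run_")) {
  if (length(k_range) == 0) stop("K range must be non-empty")
  if (any(diff(sort(k_range)) != 1)) stop("K range must be consecutive")
  stopifnot(membership_threshold > 0, membership_threshold < 1,
            correlation_threshold > 0, correlation_threshold < 1)
  structure(
    list(sim = sim, paths = paths, k_range = sort(as.integer(k_range)),
         k_focus = k_focus, n_runs = n_runs, max_runs = max_runs,
         membership_threshold = membership_threshold,
         correlation_threshold = correlation_threshold,
         burnin = burnin, iters = iters, thin = thin,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full landrace population-structure pipeline
#'
#' Executes: data simulation (or loading) -> per-locus summaries ->
#' replicate admixture runs over the K range with the reproducibility
#' rule -> K selection (evidence, rate of change, phenotype AIC) ->
#' population assignments -> hierarchy tracing -> allele-sharing
#' distances and an annotated neighbour-joining tree -> geographic
#' summaries with pairwise separation tests -> monthly climate variance
#' analysis and the membership-climate regression. Every artifact is
#' written under `config$out_dir` along with a JSON manifest of the
#' settings; a stage failure aborts with the stage named, retaining the
#' artifacts already written.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with the in-memory results (`data`, `runs`,
#'   `k_selection`, `assignments`, `hierarchy`, `tree`, `geo`,
#'   `climate`, `files`, `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  dat <- stage("data", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- config$seed
      out <- simulate_landraces(sim)
      path <- file.path(config$out_dir, "genotypes.txt")
      write_structure_genotypes(out$genotypes, path)
      emit(out$phenotypes, "phenotypes.csv")
      emit(out$coordinates, "coordinates.csv")
      emit(out$climate, "climate.csv")
      truth_path <- file.path(config$out_dir, "truth.json")
      jsonlite::write_json(
        list(true_Q = out$truth$true_Q,
             ancestral_freqs = out$truth$ancestral_freqs,
             drift = sim$drift, k_true = sim$k_true, seed = config$seed),
        truth_path, digits = NA
      )
      files <- c(files, path, truth_path)
      out
    } else {
      p <- config$paths
      if (is.null(p$genotypes)) stop("paths$genotypes is required")
      list(
        genotypes = read_structure_genotypes(p$genotypes),
        phenotypes = if (!is.null(p$phenotypes)) {
          tibble::as_tibble(read.csv(p$phenotypes))
        },
        coordinates = if (!is.null(p$coordinates)) {
          tibble::as_tibble(read.csv(p$coordinates))
        },
        climate = if (!is.null(p$climate)) {
          tibble::as_tibble(read.csv(p$climate))
        },
        truth = NULL
      )
    }
  })

  stage("summaries", {
    emit(locus_summaries(dat$genotypes), "locus_summaries.csv")
  })

  runs <- stage("structure", {
    res <- list()
    for (k in config$k_range) {
      res[[as.character(k)]] <- replicate_structure_runs(
        dat$genotypes, k,
        seed = config$seed + 1000L * k,
        n_runs = config$n_runs, max_runs = config$max_runs,
        threshold = config$correlation_threshold,
        burnin = config$burnin, iters = config$iters, thin = config$thin
      )
      emit(
        tibble::as_tibble(res[[as.character(k)]]$fits[[1]]$Q,
                          rownames = "accession_id"),
        sprintf("qmatrix_K%02d.csv", k)
      )
    }
    res
  })

  ksel <- stage("k_selection", {
    lnP <- vapply(runs, function(r) r$lnP_est, numeric(1))
    roc <- rate_of_change(setNames(lnP, names(runs)))
    report <- tibble::tibble(
      K = config$k_range,
      lnP_est = unname(lnP),
      reproducible = vapply(runs, function(r) r$reproducible, logical(1)),
      symmetric = vapply(runs, function(r) r$symmetric, logical(1)),
      n_runs = vapply(runs, function(r) r$n_runs, numeric(1)),
      delta = c(NA, roc$differences$delta)
    )
    aic <- NULL
    if (!is.null(dat$phenotypes)) {
      Q_by_K <- lapply(runs, function(r) r$fits[[1]]$Q)
      for (trait in setdiff(names(dat$phenotypes), "accession_id")) {
        tr <- dat$phenotypes[[trait]]
        if (length(unique(tr[!is.na(tr)])) < 2) next
        a <- phenotype_aic(Q_by_K, tr)
        a$trait <- trait
        aic <- dplyr::bind_rows(aic, a)
      }
    }
    emit(report, "kselection.csv")
    if (!is.null(aic)) emit(aic, "phenotype_aic.csv")
    list(report = report, plateau_k = roc$plateau_k, aic = aic)
  })

  # the plateau key marks the first K whose evidence gain has collapsed,
  # so the last K with a substantial gain is one below it
  k_focus <- config$k_focus %||% (ksel$plateau_k - 1L)
  if (is.na(k_focus %||% NA) || !(k_focus %in% config$k_range)) {
    k_focus <- ksel$report$K[which.max(ksel$report$lnP_est)]
  }

  assignments <- stage("assignments", {
    a <- assign_populations(runs[[as.character(k_focus)]]$fits[[1]]$Q,
                            strong_threshold = config$membership_threshold)
    emit(a, "assignments.csv")
    a
  })

  hierarchy <- stage("hierarchy", {
    by_k <- lapply(runs, function(r) {
      a <- assign_populations(r$fits[[1]]$Q,
                              strong_threshold = config$membership_threshold)
      a[a$strong, c("accession_id", "primary_pop")]
    })
    h <- tryCatch(trace_hierarchy(by_k), error = function(e) NULL)
    if (!is.null(h)) emit(h$parent_map, "hierarchy.csv")
    h
  })

  tree <- stage("tree", {
    dm <- allele_sharing_distance(dat$genotypes)
    emit(tibble::as_tibble(dm$d, rownames = "accession_id"), "distances.csv")
    tr <- neighbor_joining(dm)
    nwk_path <- file.path(config$out_dir, "tree.nwk")
    annotate_and_export(tr, assignments, path = nwk_path)
    files <- c(files, nwk_path)
    tr
  })

  geo <- stage("geo", {
    if (is.null(dat$coordinates)) return(NULL)
    summ <- population_geo_summaries(dat$coordinates, assignments)
    tests <- centre_separation_tests(dat$coordinates, assignments)
    emit(summ, "geo_summary.csv")
    emit(tests, "geo_pairs.csv")
    list(summaries = summ, tests = tests)
  })

  climate <- stage("climate", {
    if (is.null(dat$climate)) return(NULL)
    subsets <- list(all = unique(dat$climate$accession_id))
    if (!is.null(dat$phenotypes) && "winter" %in% names(dat$phenotypes)) {
      subsets <- list(
        spring = dat$phenotypes$accession_id[dat$phenotypes$winter == 0],
        winter = dat$phenotypes$accession_id[dat$phenotypes$winter == 1]
      )
    }
    res <- purrr::imap_dfr(subsets, function(ids, habit) {
      ok <- tryCatch(
        climate_anova_by_month(dat$climate, assignments, accession_ids = ids),
        error = function(e) NULL
      )
      if (is.null(ok)) return(NULL)
      ok$habit <- habit
      ok
    })
    emit(res, "climate_anova.csv")
    res
  })

  stage("manifest", {
    manifest_path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(
      list(
        seed = config$seed, k_range = config$k_range, k_focus = k_focus,
        n_runs = config$n_runs, max_runs = config$max_runs,
        burnin = config$burnin, iters = config$iters, thin = config$thin,
        membership_threshold = config$membership_threshold,
        correlation_threshold = config$correlation_threshold,
        files = basename(files)
      ),
      manifest_path, auto_unbox = TRUE, digits = NA
    )
    files <- c(files, manifest_path)
  })

  invisible(list(
    data = dat, runs = runs, k_selection = ksel, k_focus = k_focus,
    assignments = assignments, hierarchy = hierarchy, tree = tree,
    geo = geo, climate = climate,
    files = files, out_dir = config$out_dir
  ))
}
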