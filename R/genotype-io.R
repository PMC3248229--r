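#' Construct a haploid genotype matrix
#'
#' Container for one allele call per accession per locus. Calls are
#' arbitrary non-negative integer allele codes; missing calls are `NA`
#' internally and written with the conventional `-9` sentinel on disk.
#'
#' @param calls Integer matrix, accessions x loci; `NA` = missing.
#' @param accession_ids,locus_ids Row/column labels.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls,
                            accession_ids = rownames(calls),
                            locus_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) < 2 || ncol(calls) < 1) {
    stop("need at least 2 accessions and 1 locus")
  }
  if (any(calls < 0, na.rm = TRUE)) {
    stop("allele codes must be non-negative (missing is NA / -9 on disk)")
  }
  accession_ids <- accession_ids %||% sprintf("acc%03d", seq_len(nrow(calls)))
  locus_ids <- locus_ids %||% sprintf("locus%02d", seq_len(ncol(calls)))
  stopifnot(length(accession_ids) == nrow(calls),
            length(locus_ids) == ncol(calls))
  dimnames(calls) <- list(accession_ids, locus_ids)
  structure(list(calls = calls,
                 accession_ids = as.character(accession_ids),
                 locus_ids = as.character(locus_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d loci (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Read haploid genotypes in STRUCTURE one-row text format
#'
#' Expects a whitespace-delimited file with one row per accession:
#' first column the accession label, remaining columns one integer
#' allele call per locus. An optional first header row carries locus
#' labels (one fewer field than data rows, or non-integer fields).
#'
#' @param path File path.
#' @param missing_code Integer code denoting a missing call.
#' @return A [genotype_matrix()].
#' @export
read_structure_genotypes <- function(path, missing_code = -9L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty genotype file: ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  first <- fields[[1]]
  rest_widths <- lengths(fields[-1])
  header <- NULL
  is_int <- function(x) grepl("^-?[0-9]+$", x)
  if (length(fields) > 1 &&
      (length(first) == unique(rest_widths)[1] - 1 || !all(is_int(first[-1])))) {
    header <- first
    fields <- fields[-1]
    lines <- lines[-1]
  }
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    bad_line <- bad + if (is.null(header)) 0L else 1L
    stop(sprintf("ragged genotype file: line %d has %d fields, expected %d",
                 bad_line, widths[bad], widths[1]))
  }
  n_loci <- widths[1] - 1L
  if (n_loci < 1) stop("genotype rows must carry at least one locus")
  ids <- vapply(fields, `[`, character(1), 1L)
  body <- lapply(fields, `[`, -1L)
  bad_cell <- which(!vapply(body, function(r) all(is_int(r)), logical(1)))
  if (length(bad_cell) > 0) {
    stop(sprintf("non-integer allele call on data line %d", bad_cell[1]))
  }
  calls <- matrix(as.integer(unlist(body)), ncol = n_loci, byrow = TRUE)
  calls[calls == missing_code] <- NA_integer_
  locus_ids <- if (!is.null(header)) {
    utils::tail(header, n_loci)
  } else {
    sprintf("locus%02d", seq_len(n_loci))
  }
  genotype_matrix(calls, accession_ids = ids, locus_ids = locus_ids)
}

#' Write haploid genotypes in STRUCTURE one-row text format
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @param missing_code Integer written for missing calls.
#' @param header Write a locus-label header row?
#' @return `path`, invisibly.
#' @export
write_structure_genotypes <- function(g, path, missing_code = -9L,
                                      header = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  calls[is.na(calls)] <- missing_code
  rows <- paste(g$accession_ids, apply(calls, 1, paste, collapse = " "))
  if (header) rows <- c(paste(g$locus_ids, collapse = " "), rows)
  writeLines(rows, path)
  invisible(path)
}

#' Per-locus summary statistics
#'
#' For each locus, allele frequencies are computed over the non-missing
#' calls (pairwise-available, not listwise). Gene diversity is expected
#' heterozygosity `1 - sum(p^2)`; PIC follows Botstein et al.:
#' `1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2`. A locus with no calls at
#' all is flagged undefined (`NA` statistics) rather than an error.
#'
#' @param g A [genotype_matrix()].
#' @return Tibble with one row per locus: `locus_id`, `n_alleles`,
#'   `major_allele_freq`, `gene_diversity`, `pic`, `missing_fraction`.
#' @export
locus_summaries <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  purrr::map_dfr(seq_along(g$locus_ids), function(l) {
    col <- g$calls[, l]
    obs <- col[!is.na(col)]
    miss <- mean(is.na(col))
    if (length(obs) == 0) {
      return(tibble::tibble(
        locus_id = g$locus_ids[l], n_alleles = 0L,
        major_allele_freq = NA_real_, gene_diversity = NA_real_,
        pic = NA_real_, missing_fraction = miss
      ))
    }
    p <- as.numeric(table(obs)) / length(obs)
    sum_p2 <- sum(p^2)
    # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
    pic <- 1 - sum_p2 - (sum_p2^2 - sum(p^4))
    tibble::tibble(
      locus_id = g$locus_ids[l],
      n_alleles = length(p),
      major_allele_freq = max(p),
      gene_diversity = 1 - sum_p2,
      pic = pic,
      missing_fraction = miss
    )
  })
}

#' Dataset-level genotyping summary
#'
#' Aggregates [locus_summaries()] over the defined loci: means and
#' min-max ranges of alleles per locus, major allele frequency, gene
#' diversity, PIC and missing fraction.
#'
#' @param summaries Tibble from [locus_summaries()].
#' @return One-row tibble of means and ranges.
#' @export
dataset_summary <- function(summaries) {
  ok <- summaries[summaries$n_alleles > 0 & !is.na(summaries$pic), ]
  if (nrow(ok) == 0) stop("all loci undefined; nothing to summarize")
  tibble::tibble(
    n_loci = nrow(ok),
    mean_n_alleles = mean(ok$n_alleles),
    min_n_alleles = min(ok$n_alleles),
    max_n_alleles = max(ok$n_alleles),
    mean_major_allele_freq = mean(ok$major_allele_freq),
    mean_gene_diversity = mean(ok$gene_diversity),
    mean_pic = mean(ok$pic),
    min_pic = min(ok$pic),
    max_pic = max(ok$pic),
    mean_missing = mean(summaries$missing_fraction),
    min_missing = min(summaries$missing_fraction),
    max_missing = max(summaries$missing_fraction)
  )
}
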