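#' Allele-sharing distance between accessions
#'
#' For haploid multi-allelic genotypes, `d_ij = 1 - m_ij / c_ij` where
#' `m_ij` counts loci at which i and j carry the same allele and `c_ij`
#' counts loci at which both calls are present. Pairs with no
#' comparable locus are `NA` (undefined), which [neighbor_joining()]
#' refuses rather than imputing.
#'
#' @param g A [genotype_matrix()].
#' @return List of class `genetic_dist`: `d` (symmetric matrix,
#'   zero diagonal), `n_loci_used` (comparable-locus counts) and
#'   `accession_ids`.
#' @export
allele_sharing_distance <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  n <- nrow(calls)
  if (n < 2) stop("need at least 2 accessions")
  match_count <- matrix(0, n, n)
  comp_count <- matrix(0, n, n)
  for (l in seq_len(ncol(calls))) {
    col <- calls[, l]
    present <- !is.na(col)
    pp <- outer(present, present, `&`)
    eq <- outer(col, col, `==`)
    eq[!pp] <- FALSE
    match_count <- match_count + eq
    comp_count <- comp_count + pp
  }
  d <- 1 - match_count / comp_count   # 0/0 -> NaN for incomparable pairs
  d[comp_count == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(g$accession_ids, g$accession_ids)
  structure(list(d = d, n_loci_used = comp_count,
                 accession_ids = g$accession_ids),
            class = "genetic_dist")
}

#' @export
print.genetic_dist <- function(x, ...) {
  cat(sprintf("Allele-sharing distances over %d accessions (mean %.3f)\n",
              nrow(x$d), mean(x$d[upper.tri(x$d)], na.rm = TRUE)))
  invisible(x)
}

#' Neighbour-joining tree from a genetic distance matrix
#'
#' Standard Saitou-Nei agglomeration (via ape). Negative branch lengths,
#' which NJ can produce on non-additive matrices, are clamped to zero
#' with the deficit transferred to the sibling branch so that sibling
#' path lengths are preserved; clamped edges are counted in the
#' `n_clamped` attribute.
#'
#' @param dm A `genetic_dist` (or symmetric matrix / dist).
#' @return An [ape::phylo] unrooted tree.
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "genetic_dist")) dm$d else as.matrix(dm)
  if (nrow(d) < 3) stop("neighbour joining needs >= 3 accessions")
  if (anyNA(d)) {
    idx <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    pairs <- paste(rownames(d)[idx[, 1]], colnames(d)[idx[, 2]], sep = " ~ ")
    stop("distance undefined (no comparable loci) for pairs: ",
         paste(head(pairs, 5), collapse = ", "),
         if (length(pairs) > 5) sprintf(" and %d more", length(pairs) - 5) else "")
  }
  tree <- ape::nj(as.dist(d))
  clamp_negative_branches(tree)
}

# clamp negative edge lengths to 0, moving the deficit onto the sibling
# edge under the same parent so sibling-to-sibling path lengths persist
clamp_negative_branches <- function(tree) {
  n_clamped <- 0L
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[which.min(tree$edge.length[neg])]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs) > 0) {
      tree$edge.length[sibs] <- tree$edge.length[sibs] + deficit
    }
    n_clamped <- n_clamped + 1L
    if (n_clamped > 10 * length(tree$edge.length)) break  # safety
  }
  # residual negatives (deficit larger than the sibling) are floored
  if (any(tree$edge.length < 0)) tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "n_clamped") <- n_clamped
  tree
}

#' Annotate strong accessions on a tree and export Newick
#'
#' Appends a `|popX` tag to the leaf label of every accession with a
#' strong primary assignment (membership >= 0.9 in
#' [assign_populations()]); other leaves are left unmarked. Topology
#' and branch lengths are untouched.
#'
#' @param tree An [ape::phylo] whose tip labels are accession ids.
#' @param assignments Tibble from [assign_populations()].
#' @param path Optional file path; when given, the Newick string is
#'   also written there.
#' @return Newick string, invisibly when `path` is given.
#' @export
annotate_and_export <- function(tree, assignments, path = NULL) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  strong <- assignments[assignments$strong, , drop = FALSE]
  idx <- match(strong$accession_id, tree$tip.label)
  if (anyNA(idx)) stop("assignment ids must be a subset of leaf ids")
  tree$tip.label[idx] <- paste0(tree$tip.label[idx], "|pop",
                                strong$primary_pop)
  nwk <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Do members of each population form connected subtrees?
#'
#' Utility for validating structure against tree topology: a population
#' is monophyletic here when its members form a clade on the unrooted
#' tree (checked on the tree rooted at an outside leaf).
#'
#' @param tree An [ape::phylo].
#' @param labels Named vector: population label per tip label.
#' @return Tibble `(population, n, monophyletic)`.
#' @export
population_monophyly <- function(tree, labels) {
  labels <- labels[tree$tip.label]
  purrr::map_dfr(unique(labels), function(popn) {
    tips <- tree$tip.label[labels == popn]
    mono <- if (length(tips) <= 1) {
      TRUE
    } else if (length(tips) == length(tree$tip.label)) {
      TRUE
    } else {
      # clade membership on an unrooted tree: root at any outside leaf
      outside <- setdiff(tree$tip.label, tips)[1]
      rooted <- ape::root(tree, outgroup = outside, resolve.root = TRUE)
      ape::is.monophyletic(rooted, tips)
    }
    tibble::tibble(population = popn, n = length(tips), monophyletic = mono)
  })
}
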