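# Patristic distances from a precomputed phylogeny. Tree inference itself is
# out of scope: the package consumes a newick file with branch lengths.

#' Patristic distance matrix from a newick tree
#'
#' Reads a newick tree (branch lengths required) and returns the matrix of
#' leaf-to-leaf patristic distances: the sum of branch lengths along the path
#' connecting each pair of tips.
#'
#' @param path newick file.
#' @param species_map optional named character vector mapping tip labels in
#'   the file to study species ids, e.g. `c("E_aerogenes" = "Ea")`. Tips are
#'   matched by exact string; every name in the map must be a tip.
#' @return symmetric numeric matrix with species ids as dimnames; zero
#'   diagonal.
#' @export
read_tree_distances <- function(path, species_map = NULL) {
  assert_that(file.exists(path), "file not found: ", path)
  tree <- ape::read.tree(path)
  assert_that(inherits(tree, "phylo"), "could not parse newick tree: ", path)
  assert_that(!is.null(tree$edge.length) && !anyNA(tree$edge.length),
              "tree has missing branch lengths: ", path)
  if (!is.null(species_map)) {
    unmatched <- setdiff(names(species_map), tree$tip.label)
    assert_that(length(unmatched) == 0,
                "species_map names not found among tree tips: ",
                paste(unmatched, collapse = ", "))
    idx <- match(names(species_map), tree$tip.label)
    tree$tip.label[idx] <- unname(species_map)
  }
  d <- stats::cophenetic(tree)
  # enforce exact symmetry and zero diagonal against numerical drift
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Check that a matrix is a valid distance matrix over a species set
#'
#' @param d matrix.
#' @param tol symmetry tolerance.
#' @return `d`, invisibly.
#' @export
validate_distances <- function(d, tol = 1e-9) {
  assert_that(is.matrix(d) && nrow(d) == ncol(d), "distances must be square")
  assert_that(!is.null(rownames(d)) && identical(rownames(d), colnames(d)),
              "distance matrix needs matching dimnames")
  assert_that(max(abs(d - t(d))) <= tol, "distance matrix is not symmetric")
  assert_that(all(abs(diag(d)) <= tol), "distance diagonal must be zero")
  assert_that(all(d >= -tol), "distances must be non-negative")
  invisible(d)
}
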