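#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' Thin validation layer over [ape::read.tree()]. The downstream
#' correlation model is meaningless without branch lengths, so trees
#' lacking them are rejected unless `missing_branch_length = "constant"`
#' assigns a constant length to every edge.
#'
#' @param path Newick file path (or a Newick string via `text`); files
#'   ending in `.nex`/`.nexus` are read as Nexus under the same contract.
#' @param text Optional Newick string instead of a file.
#' @param missing_branch_length `"error"` (default) or `"constant"`.
#' @param constant Edge length used when `missing_branch_length = "constant"`.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL,
                        missing_branch_length = c("error", "constant"),
                        constant = 1) {
  missing_branch_length <- match.arg(missing_branch_length)
  tree <- tryCatch({
    if (!is.null(text)) {
      ape::read.tree(text = text)
    } else if (grepl("\\.nex(us)?$", path, ignore.case = TRUE)) {
      ape::read.nexus(path)
    } else {
      ape::read.tree(path)
    }
  }, error = function(e) stop("malformed Newick: ", conditionMessage(e),
                              call. = FALSE))
  if (is.null(tree)) stop("malformed Newick: parser returned no tree",
                          call. = FALSE)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (ape::Ntip(tree) < 2L) stop("tree needs at least 2 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (missing_branch_length == "error") {
      stop("tree has missing branch lengths ",
           "(set missing_branch_length = \"constant\" to assign them)",
           call. = FALSE)
    }
    if (is.null(tree$edge.length)) {
      tree$edge.length <- rep(constant, nrow(tree$edge))
    } else {
      tree$edge.length[is.na(tree$edge.length)] <- constant
    }
  }
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  tree
}

tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

#' Patristic tip-tip distance matrix
#'
#' Computes the matrix of path lengths between tips (sums of branch lengths
#' along the connecting path). By default branch lengths are first rescaled
#' so the tree height (maximum root-to-tip depth) is 1, putting the signal
#' parameter of the regression in comparable units across trees.
#' Tips at zero patristic distance from one another (zero-length terminal
#' branches under a shared node, common in sequence-derived trees) would
#' make the correlation matrix singular, so their terminal branches receive
#' a jitter of `jitter` times the tree height.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param normalize Rescale to unit height first? Default TRUE.
#' @param jitter Relative terminal-branch jitter for coincident tips
#'   (default 1e-8; set 0 to disable).
#' @return An object of class `patristic`: list with `D` (symmetric matrix,
#'   tip labels as dimnames), `height` (tree height after any rescaling)
#'   and `ultrametric` flag. Non-ultrametric trees are accepted with a
#'   warning.
#' @export
patristic_matrix <- function(tree, normalize = TRUE, jitter = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  n <- ape::Ntip(tree)
  H <- tree_height(tree)
  if (H <= 0) stop("tree height is zero", call. = FALSE)
  if (normalize) {
    tree$edge.length <- tree$edge.length / H
    H <- 1
  }
  ultra <- ape::is.ultrametric(tree, tol = 1e-6)
  if (!ultra) warning("tree is not ultrametric; ",
                      "height taken as maximum root-to-tip depth")
  D <- stats::cophenetic(tree)
  if (jitter > 0) {
    off <- D[upper.tri(D)]
    if (any(off <= 0)) {
      # add eps to the terminal branch of every tip involved in a zero pair
      eps <- jitter * H
      hit <- unique(c(row(D)[upper.tri(D) & D <= 0],
                      col(D)[upper.tri(D) & D <= 0]))
      term <- match(hit, tree$edge[, 2L])
      tree$edge.length[term] <- tree$edge.length[term] + eps
      D <- stats::cophenetic(tree)
    }
  }
  D <- D[tree$tip.label, tree$tip.label]
  structure(list(D = D, height = H, ultrametric = ultra),
            class = "patristic")
}

#' @export
print.patristic <- function(x, ...) {
  cat(sprintf("patristic distances: %d tips, height %g%s\n",
              nrow(x$D), x$height,
              if (x$ultrametric) "" else " (non-ultrametric)"))
  invisible(x)
}

as_dist_matrix <- function(dist) {
  if (inherits(dist, "patristic")) dist$D else as.matrix(dist)
}

#' Align a tree with a trait matrix
#'
#' Prunes the tree to the species shared with the trait matrix and reorders
#' the matrix rows to tip order, reporting what was dropped on either side.
#'
#' @param tree An [ape::phylo] tree.
#' @param x A `trait_matrix`.
#' @return List with `tree`, `matrix` (rows in tip order) and `report`
#'   (`dropped_tips`, `dropped_species`).
#' @export
match_tips <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"), inherits(x, "trait_matrix"))
  sp <- species_ids(x)
  common <- intersect(tree$tip.label, sp)
  if (length(common) == 0L) {
    stop("no species shared between tree and trait matrix", call. = FALSE)
  }
  dropped_tips <- setdiff(tree$tip.label, common)
  dropped_species <- setdiff(sp, common)
  if (length(dropped_tips)) tree <- ape::keep.tip(tree, common)
  out <- trait_matrix(x$values[tree$tip.label, , drop = FALSE],
                      x$trait_class)
  attr(out, "missing_ecology") <-
    intersect(attr(x, "missing_ecology") %||% character(0), tree$tip.label)
  attr(out, "excluded_traits") <- attr(x, "excluded_traits")
  list(tree = tree, matrix = out,
       report = list(dropped_tips = dropped_tips,
                     dropped_species = dropped_species))
}

#' Export a patristic distance matrix as CSV
#' @param dist A `patristic` object.
#' @param path Output CSV path.
#' @export
write_patristic <- function(dist, path) {
  D <- as_dist_matrix(dist)
  utils::write.csv(data.frame(species = rownames(D), D, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
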