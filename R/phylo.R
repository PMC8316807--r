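## Time-calibrated phylogeny handling: Newick input, taxon grafting and the
## phylogenetic covariance used by the species-level models.  Branch lengths
## are in million years (Myr).

#' Read and validate a rooted Newick phylogeny
#'
#' @param path path to a Newick file with branch lengths.
#' @return an `ape::phylo` tree.  Missing branch lengths, duplicate tip
#'   labels or an unparsable string are errors.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("read_newick: cannot parse Newick in ", path, call. = FALSE)
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge)) {
    stop("read_newick: missing branch length(s) in ", path, call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("read_newick: negative branch length", call. = FALSE)
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L) {
    stop("read_newick: duplicate tip label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  tree
}

.terminal_branch <- function(tree, tip) {
  idx <- match(tip, tree$tip.label)
  if (is.na(idx)) stop("tip not in tree: ", tip, call. = FALSE)
  tree$edge.length[tree$edge[, 2] == idx]
}

#' Graft a new tip onto a tree as sister to an existing tip
#'
#' Inserts a new internal node on the sister's terminal branch at
#' `divergence` Myr before the sister tip and attaches the new tip there
#' with a branch of length `divergence`, so an ultrametric input stays
#' ultrametric.  Used to add taxa with a known divergence time that are
#' absent from the reference phylogeny (e.g. attaching a missing baboon
#' species to its sister lineage at 1.99 Myr).
#'
#' @param tree an `ape::phylo` tree.
#' @param new_tip label of the tip to add.
#' @param sister existing tip the new taxon is sister to.
#' @param divergence divergence time in Myr; must not exceed the sister's
#'   terminal branch length (grafting deeper than the terminal branch is
#'   refused rather than silently reattaching elsewhere).
#' @return the enlarged tree.
#' @export
graft_taxon <- function(tree, new_tip, sister, divergence) {
  if (new_tip %in% tree$tip.label) {
    stop("tip already present: ", new_tip, call. = FALSE)
  }
  term <- .terminal_branch(tree, sister)
  if (divergence > term + 1e-12) {
    stop(sprintf(
      "divergence %g exceeds terminal branch length %g of sister '%s'",
      divergence, term, sister), call. = FALSE)
  }
  tip_tree <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                             tip.label = new_tip,
                             edge.length = divergence, Nnode = 1L),
                        class = "phylo")
  ape::bind.tree(tree, tip_tree, where = match(sister, tree$tip.label),
                 position = divergence)
}

#' Drop a tip from a tree
#'
#' Thin wrapper over [ape::drop.tip()]; the inverse of [graft_taxon()].
#'
#' @param tree an `ape::phylo` tree.
#' @param tip tip label to remove.
#' @return the reduced tree.
#' @export
prune_taxon <- function(tree, tip) {
  if (!tip %in% tree$tip.label) stop("tip not in tree: ", tip, call. = FALSE)
  ape::drop.tip(tree, tip)
}

#' Phylogenetic covariance matrix with Pagel's lambda
#'
#' `C[i, j]` is the depth (Myr from the root) of the most recent common
#' ancestor of tips i and j, i.e. their shared root-to-ancestor path
#' length; the diagonal is each tip's root-to-tip depth.  Off-diagonal
#' entries are multiplied by `lambda` (`lambda = 1` full Brownian signal,
#' `lambda = 0` independence).
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param species optional character vector selecting and ordering the
#'   rows/columns; defaults to all tips in tree order.
#' @param lambda multiplier on the off-diagonal covariances, in `[0, 1]`.
#' @return the covariance matrix with species as dimnames.
#' @export
phylo_covariance <- function(tree, species = NULL, lambda = 1) {
  stopifnot(lambda >= 0, lambda <= 1)
  C <- ape::vcv.phylo(tree)
  if (!is.null(species)) {
    missing <- setdiff(species, rownames(C))
    if (length(missing) > 0L) {
      stop("species not in tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    C <- C[species, species, drop = FALSE]
  }
  d <- diag(C)
  C <- C * lambda
  diag(C) <- d
  C
}
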