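#' @useDynLib xenoscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort warn inform
#' @import dplyr
NULL

# Canonical postorder of an ape phylo: children visited in stored edge order,
# left before right. Returns node ids (tips + internals) in postorder.
postorder_ids <- function(phy) {
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  kids <- children_list(phy)
  out <- integer(n_tip + phy$Nnode)
  k <- 0L
  # explicit stack; second visit emits the node
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top$stage == 1L) {
      ch <- kids[[top$node]]
      if (length(ch) == 0L) {
        k <- k + 1L; out[k] <- top$node
      } else {
        stack[[length(stack) + 1L]] <- list(node = top$node, stage = 2L)
        for (c in rev(ch)) stack[[length(stack) + 1L]] <- list(node = c, stage = 1L)
      }
    } else {
      k <- k + 1L; out[k] <- top$node
    }
  }
  out
}

children_list <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  kids <- vector("list", n)
  for (i in seq_len(n)) kids[[i]] <- integer(0)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2L])
  }
  kids
}

check_binary <- function(phy, what = "tree") {
  kids <- children_list(phy)
  deg <- lengths(kids)
  bad <- which(deg > 2L)
  if (length(bad)) {
    abort(sprintf("%s contains a polytomy at node(s): %s",
                  what, paste(bad, collapse = ", ")))
  }
  bad1 <- which(deg == 1L)
  if (length(bad1)) {
    abort(sprintf("%s contains unbranched (degree-1) node(s): %s",
                  what, paste(bad1, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Construct a dated species tree
#'
#' Wraps a rooted, binary, ultrametric `phylo` object into a chronogram with
#' node ages (time before present; all leaves at age 0) and canonical
#' postorder node labels `s1, s2, ...` (children visited in stored order,
#' left before right).
#'
#' @param phy A rooted binary ultrametric `ape::phylo` with branch lengths.
#' @param tol Relative tolerance used when checking ultrametricity and
#'   snapping tip ages to zero.
#' @return An object of class `dated_tree`: the `phylo` plus `$age` (numeric,
#'   indexed by ape node id), `$label` (postorder labels), `$postorder`
#'   (node ids in canonical postorder).
#' @export
dated_tree <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) abort("`phy` must be an ape phylo object")
  if (is.null(phy$edge.length)) abort("species tree must have branch lengths (ages)")
  if (!ape::is.rooted(phy)) abort("species tree must be rooted")
  check_binary(phy, "species tree")
  if (!ape::is.ultrametric(phy, tol = tol)) {
    abort("species tree is not ultrametric; a chronogram is required")
  }
  n_tip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)   # distance from root
  h <- max(depth[seq_len(n_tip)])
  age <- h - depth
  age[seq_len(n_tip)] <- 0
  po <- postorder_ids(phy)
  lab <- character(length(age))
  lab[po] <- paste0("s", seq_along(po))
  structure(
    list(phylo = phy, age = age, label = lab, postorder = po,
         n_tip = n_tip, root = n_tip + 1L),
    class = "dated_tree"
  )
}

#' Construct a gene tree with a leaf-to-species map
#'
#' @param phy A rooted binary `ape::phylo`; tip labels are gene identifiers.
#' @param species Character vector of species labels, either named by gene id
#'   or in `phy$tip.label` order. If `NULL`, species are parsed from tip
#'   labels of the form `"<gene>|<species>"`.
#' @param companion Optional `dated_tree`; when given, every leaf species
#'   must occur among its tips.
#' @return An object of class `gene_tree` with `$species` (named by tip
#'   label), `$label` (postorder labels `g1, g2, ...`), `$postorder`.
#' @export
gene_tree <- function(phy, species = NULL, companion = NULL) {
  if (!inherits(phy, "phylo")) abort("`phy` must be an ape phylo object")
  if (!ape::is.rooted(phy)) abort("gene tree must be rooted")
  check_binary(phy, "gene tree")
  tips <- phy$tip.label
  if (anyDuplicated(tips)) abort("gene tree tip labels must be unique")
  if (is.null(species)) {
    if (!all(grepl("|", tips, fixed = TRUE))) {
      abort("no species map supplied and tip labels are not of the form 'gene|species'")
    }
    species <- sub("^.*\\|", "", tips)
    names(species) <- tips
  } else if (is.null(names(species))) {
    if (length(species) != length(tips)) {
      abort("unnamed `species` must have one entry per tip")
    }
    names(species) <- tips
  } else {
    missing <- setdiff(tips, names(species))
    if (length(missing)) {
      abort(paste0("species map lacks entries for gene(s): ",
                   paste(missing, collapse = ", ")))
    }
    species <- species[tips]
  }
  if (!is.null(companion)) {
    bad <- setdiff(unique(species), companion$phylo$tip.label)
    if (length(bad)) {
      abort(paste0("gene-tree species absent from the species tree: ",
                   paste(bad, collapse = ", ")))
    }
  }
  po <- postorder_ids(phy)
  lab <- character(length(po))
  lab[po] <- paste0("g", seq_along(po))
  structure(
    list(phylo = phy, species = species, label = lab, postorder = po,
         n_tip = length(tips), root = length(tips) + 1L),
    class = "gene_tree"
  )
}

#' Read a species or gene tree from a Newick file
#'
#' @param path Path to a Newick file (one tree).
#' @param kind `"species"` for a dated species tree (branch lengths must be
#'   ultrametric) or `"gene"`.
#' @param species,companion Passed to [gene_tree()] when `kind = "gene"`.
#' @return A `dated_tree` or `gene_tree`.
#' @export
read_tree <- function(path, kind = c("species", "gene"),
                      species = NULL, companion = NULL) {
  kind <- match.arg(kind)
  phy <- ape::read.tree(path)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  if (is.null(phy)) abort(paste0("could not parse Newick from ", path))
  if (kind == "species") dated_tree(phy) else gene_tree(phy, species, companion)
}

#' Write a tree to Newick
#'
#' Byte-stable for a fixed input tree.
#'
#' @param x A `dated_tree`, `gene_tree`, or `phylo`.
#' @param path Output file path.
#' @export
write_tree <- function(x, path) {
  phy <- if (inherits(x, "phylo")) x else x$phylo
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("<dated_tree> %d tips, root age %.4g\n", x$n_tip, x$age[x$root]))
  invisible(x)
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("<gene_tree> %d genes from %d species\n",
              x$n_tip, length(unique(x$species))))
  invisible(x)
}

# Leaf tip ids below each node, as a list indexed by ape node id.
tips_below <- function(phy) {
  n_tip <- length(phy$tip.label)
  po <- postorder_ids(phy)
  kids <- children_list(phy)
  below <- vector("list", n_tip + phy$Nnode)
  for (v in po) {
    if (v <= n_tip) below[[v]] <- v
    else below[[v]] <- unlist(below[kids[[v]]], use.names = FALSE)
  }
  below
}

#' Extract the subtree delineated by the LCA of reference leaves
#'
#' Returns the monophyletic clade rooted at the lowest common ancestor of a
#' reference leaf set (e.g. experimentally validated family members), with
#' postorder labels reassigned. This mirrors the prescreening step that
#' restricts a large homolog tree to the clade of interest.
#'
#' @param tree A `gene_tree`.
#' @param reference_leaves Character vector of tip labels; all must be present.
#' @return A `gene_tree` for the LCA clade.
#' @export
extract_lca_clade <- function(tree, reference_leaves) {
  stopifnot(inherits(tree, "gene_tree"))
  phy <- tree$phylo
  missing <- setdiff(reference_leaves, phy$tip.label)
  if (length(missing)) {
    abort(paste0("reference leaves not in tree: ", paste(missing, collapse = ", ")))
  }
  ids <- match(reference_leaves, phy$tip.label)
  if (length(ids) == tree$n_tip) return(gene_tree(phy, tree$species))
  if (length(ids) == 1L) abort("need at least two reference leaves to define a clade")
  mrca <- ape::getMRCA(phy, ids)
  if (mrca == tree$root) return(gene_tree(phy, tree$species))
  sub <- ape::extract.clade(phy, mrca)
  gene_tree(sub, tree$species[sub$tip.label])
}

# tibble view of a tree's nodes (used by tidy methods and reports)
node_table <- function(x) {
  phy <- x$phylo
  n <- x$n_tip + phy$Nnode
  parent <- rep(NA_integer_, n)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  tibble::tibble(
    node = seq_len(n),
    label = x$label,
    is_tip = seq_len(n) <= x$n_tip,
    tip_label = c(phy$tip.label, rep(NA_character_, phy$Nnode)),
    parent = parent,
    age = if (!is.null(x$age)) x$age else NA_real_
  )
}
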