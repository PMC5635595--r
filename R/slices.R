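# Time slices of a chronogram: the intervals between consecutive distinct
# internal-node ages. Transfers are only allowed between species edges alive
# in the same slice (the dated reconciliation model).

#' Cut a dated species tree into time slices
#'
#' Slice boundaries are the distinct internal-node ages; slice `t` spans
#' `(b[t-1], b[t]]` with `b[0] = 0`. Each species edge belongs to exactly
#' the slices its time span covers. Internal nodes whose ages differ by less
#' than `tol * root age` share a (merged) boundary.
#'
#' @param tree A `dated_tree`.
#' @param tol Relative age-merging tolerance.
#' @return An object of class `sliced_tree`: the input tree plus
#'   `$boundaries` (ascending, starting at 0), `$n_slice`, `$bidx` (per-node
#'   boundary index: leaves 0, root `n_slice`), and `$slices`, a tibble with
#'   one row per slice listing the contemporaneous edges (edge = label of
#'   its lower node).
#' @export
build_time_slices <- function(tree, tol = 1e-8) {
  stopifnot(inherits(tree, "dated_tree"))
  phy <- tree$phylo
  n_tip <- tree$n_tip
  internal <- (n_tip + 1L):(n_tip + phy$Nnode)
  root_age <- max(tree$age)
  ia <- sort(tree$age[internal])
  b <- numeric(0)
  for (a in ia) {
    if (!length(b) || a - b[length(b)] > tol * max(root_age, 1)) b <- c(b, a)
  }
  m <- length(b)
  bidx <- integer(length(tree$age))
  bidx[internal] <- vapply(tree$age[internal],
                           function(a) which.min(abs(b - a)), integer(1))
  parent <- rep(NA_integer_, length(tree$age))
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  edges <- setdiff(seq_along(tree$age), tree$root)
  slice_edges <- lapply(seq_len(m), function(t) {
    e <- edges[bidx[edges] <= t - 1L & bidx[parent[edges]] >= t]
    e[order(match(e, tree$postorder))]
  })
  slices <- tibble::tibble(
    slice = seq_len(m),
    lower = c(0, b[-m]),
    upper = b,
    edges = lapply(slice_edges, function(e) tree$label[e])
  )
  structure(
    c(tree, list(boundaries = c(0, b), n_slice = m, bidx = bidx,
                 parent = parent, slices = slices)),
    class = c("sliced_tree", "dated_tree")
  )
}

#' @export
print.sliced_tree <- function(x, ...) {
  cat(sprintf("<sliced_tree> %d tips, %d time slices, root age %.4g\n",
              x$n_tip, x$n_slice, max(x$age)))
  invisible(x)
}

as_sliced <- function(tree) {
  if (inherits(tree, "sliced_tree")) tree else build_time_slices(tree)
}

# 0-based arrays handed to the C++ engine
engine_args <- function(gt, st) {
  stopifnot(inherits(gt, "gene_tree"), inherits(st, "sliced_tree"))
  gkids <- children_list(gt$phylo)
  ng <- gt$n_tip + gt$phylo$Nnode
  gc1 <- gc2 <- rep(-1L, ng)
  for (v in seq_len(ng)) {
    k <- gkids[[v]]
    if (length(k) == 2L) { gc1[v] <- k[1L] - 1L; gc2[v] <- k[2L] - 1L }
  }
  sp_tip <- match(gt$species, st$phylo$tip.label)
  if (anyNA(sp_tip)) {
    bad <- unique(gt$species[is.na(sp_tip)])
    abort(paste0("gene-tree species absent from species tree: ",
                 paste(bad, collapse = ", ")))
  }
  gsp <- rep(-1L, ng)
  gsp[seq_len(gt$n_tip)] <- sp_tip - 1L
  skids <- children_list(st$phylo)
  ns <- st$n_tip + st$phylo$Nnode
  sc1 <- sc2 <- rep(-1L, ns)
  for (v in seq_len(ns)) {
    k <- skids[[v]]
    if (length(k) == 2L) { sc1[v] <- k[1L] - 1L; sc2[v] <- k[2L] - 1L }
  }
  spar <- ifelse(is.na(st$parent), -1L, st$parent - 1L)
  list(g_child1 = gc1, g_child2 = gc2, g_post = gt$postorder - 1L,
       g_species = gsp, s_child1 = sc1, s_child2 = sc2,
       s_parent = as.integer(spar), s_bidx = st$bidx,
       n_slice = st$n_slice, s_root = st$root - 1L)
}
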