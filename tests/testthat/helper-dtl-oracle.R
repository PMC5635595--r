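# Independent brute-force oracle for dated DTL parsimony.
#
# Unlike the package's slice DP (bottom-up over gene subtrees), this oracle
# enumerates explicit event placements top-down: from a lineage's start
# position it walks every descending path through the sliced species tree,
# accumulating one loss per bypassed speciation, and enumerates every
# reachable event placement (speciation at a node, duplication in a segment,
# transfer to any contemporaneous edge) with both child assignments.
# Memoisation is on (gene node, start position); min cost and the number of
# optimal placement vectors are combined directly from the enumeration.

oracle_dtl <- function(gt, st, dup, transfer, loss) {
  st <- xenoscan::build_time_slices(st)
  phy_s <- st$phylo
  m <- st$n_slice
  stem_slice <- m + 1L
  root_s <- st$root
  skids <- children_list_o(phy_s)
  parent <- st$parent
  bidx <- st$bidx
  edges <- c(setdiff(seq_along(st$age), root_s), root_s) # stem edge last
  alive <- function(e, t) {
    if (e == root_s) t == stem_slice
    else bidx[e] <= t - 1L && bidx[parent[e]] >= t
  }
  alive_in <- lapply(seq_len(stem_slice), function(t) {
    edges[vapply(edges, alive, logical(1), t = t)]
  })

  # all reachable (kind, where, slice, acc_losses) from start position (e, t)
  reach <- function(e, t) {
    out <- list()
    walk <- function(e, t, acc) {
      out[[length(out) + 1L]] <<- list(kind = "seg", e = e, t = t, acc = acc)
      bottom_node <- e # edge named by its lower node
      if (bidx[bottom_node] == t - 1L) {
        k <- skids[[bottom_node]]
        if (!length(k)) {
          out[[length(out) + 1L]] <<- list(kind = "leaf", e = bottom_node,
                                           t = t, acc = acc)
        } else {
          out[[length(out) + 1L]] <<- list(kind = "spec", e = bottom_node,
                                           t = t - 1L, acc = acc)
          walk(k[1L], t - 1L, acc + 1L)
          walk(k[2L], t - 1L, acc + 1L)
        }
      } else if (t > 1L) {
        walk(e, t - 1L, acc)
      }
    }
    walk(e, t, 0L)
    out
  }

  gkids <- children_list_o(gt$phylo)
  sp_tip <- match(gt$species, phy_s$tip.label)
  memo <- new.env(parent = emptyenv())

  # best (cost, count) for gene node u whose lineage starts in (e, t)
  best <- function(u, e, t) {
    key <- paste(u, e, t)
    if (!is.null(memo[[key]])) return(memo[[key]])
    kk <- gkids[[u]]
    res <- list(cost = Inf, count = 0)
    consider <- function(co, ct) {
      if (co < res$cost - 1e-9) res <<- list(cost = co, count = ct)
      else if (co < res$cost + 1e-9) res$count <<- res$count + ct
    }
    for (p in reach(e, t)) {
      base <- loss * p$acc
      if (!length(kk)) {
        if (p$kind == "leaf" && sp_tip[u] == p$e) consider(base, 1)
      } else if (p$kind == "spec") {
        f <- skids[[p$e]][1L]; g <- skids[[p$e]][2L]
        b1 <- best(kk[1L], f, p$t); b2 <- best(kk[2L], g, p$t)
        consider(base + b1$cost + b2$cost, b1$count * b2$count)
        b3 <- best(kk[1L], g, p$t); b4 <- best(kk[2L], f, p$t)
        consider(base + b3$cost + b4$cost, b3$count * b4$count)
      } else if (p$kind == "seg") {
        b1 <- best(kk[1L], p$e, p$t); b2 <- best(kk[2L], p$e, p$t)
        consider(base + dup + b1$cost + b2$cost, b1$count * b2$count)
        for (f in alive_in[[p$t]]) {
          if (f == p$e) next
          c1 <- best(kk[1L], p$e, p$t); c2 <- best(kk[2L], f, p$t)
          consider(base + transfer + c1$cost + c2$cost, c1$count * c2$count)
          c3 <- best(kk[2L], p$e, p$t); c4 <- best(kk[1L], f, p$t)
          consider(base + transfer + c3$cost + c4$cost, c3$count * c4$count)
        }
      }
    }
    memo[[key]] <- res
    res
  }

  # the root's event may be placed anywhere, with no losses above it
  r <- gt$root
  kk <- gkids[[r]]
  res <- list(cost = Inf, count = 0)
  consider <- function(co, ct) {
    if (co < res$cost - 1e-9) res <<- list(cost = co, count = ct)
    else if (co < res$cost + 1e-9) res$count <<- res$count + ct
  }
  for (t in seq_len(stem_slice)) {
    for (e in alive_in[[t]]) {
      b1 <- best(kk[1L], e, t); b2 <- best(kk[2L], e, t)
      consider(dup + b1$cost + b2$cost, b1$count * b2$count)
      for (f in alive_in[[t]]) {
        if (f == e) next
        c2 <- best(kk[2L], f, t)
        consider(transfer + b1$cost + c2$cost, b1$count * c2$count)
        c4 <- best(kk[1L], f, t)
        consider(transfer + b2$cost + c4$cost, b2$count * c4$count)
      }
    }
  }
  for (s in seq_along(st$age)) {
    k <- skids[[s]]
    if (!length(k)) next
    ts <- bidx[s]
    b1 <- best(kk[1L], k[1L], ts); b2 <- best(kk[2L], k[2L], ts)
    consider(b1$cost + b2$cost, b1$count * b2$count)
    b3 <- best(kk[1L], k[2L], ts); b4 <- best(kk[2L], k[1L], ts)
    consider(b3$cost + b4$cost, b3$count * b4$count)
  }
  res
}

children_list_o <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  kids <- rep(list(integer(0)), n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2L])
  }
  kids
}

# random small reconciliation instance with integer costs
random_dtl_instance <- function(n_species = sample(3:5, 1),
                                n_genes = sample(3:6, 1)) {
  st <- xenoscan::dated_tree(ape::rcoal(n_species,
                                        tip.label = LETTERS[seq_len(n_species)]))
  topo <- ape::rtree(n_genes, br = NULL)
  topo$edge.length <- NULL
  sp <- sample(LETTERS[seq_len(n_species)], n_genes, replace = TRUE)
  topo$tip.label <- paste0("x", seq_len(n_genes), "|", sp)
  gt <- xenoscan::gene_tree(topo)
  list(gt = gt, st = st,
       dup = sample(1:6, 1), transfer = sample(1:8, 1), loss = sample(1:3, 1))
}

# exhaustive list of optimal scenario signatures, for uniformity checks:
# returns a character signature per optimal reconciliation (small instances
# only). Signature = per-gene-node event/placement plus loss count.
oracle_enumerate <- function(gt, st, dup, transfer, loss) {
  st <- xenoscan::build_time_slices(st)
  phy_s <- st$phylo
  m <- st$n_slice
  stem_slice <- m + 1L
  root_s <- st$root
  skids <- children_list_o(phy_s)
  parent <- st$parent
  bidx <- st$bidx
  edges <- c(setdiff(seq_along(st$age), root_s), root_s)
  alive <- function(e, t) {
    if (e == root_s) t == stem_slice
    else bidx[e] <= t - 1L && bidx[parent[e]] >= t
  }
  alive_in <- lapply(seq_len(stem_slice), function(t) {
    edges[vapply(edges, alive, logical(1), t = t)]
  })
  reach <- function(e, t) {
    out <- list()
    walk <- function(e, t, acc) {
      out[[length(out) + 1L]] <<- list(kind = "seg", e = e, t = t, acc = acc)
      if (bidx[e] == t - 1L) {
        k <- skids[[e]]
        if (!length(k)) {
          out[[length(out) + 1L]] <<- list(kind = "leaf", e = e, t = t, acc = acc)
        } else {
          out[[length(out) + 1L]] <<- list(kind = "spec", e = e, t = t - 1L,
                                           acc = acc)
          walk(k[1L], t - 1L, acc + 1L)
          walk(k[2L], t - 1L, acc + 1L)
        }
      } else if (t > 1L) walk(e, t - 1L, acc)
    }
    walk(e, t, 0L)
    out
  }
  gkids <- children_list_o(gt$phylo)
  sp_tip <- match(gt$species, phy_s$tip.label)

  # all (cost, signature) scenario lists per (u, start)
  enum <- function(u, e, t) {
    kk <- gkids[[u]]
    out <- list()
    for (p in reach(e, t)) {
      base <- loss * p$acc
      if (!length(kk)) {
        if (p$kind == "leaf" && sp_tip[u] == p$e) {
          out[[length(out) + 1L]] <- list(cost = base,
                                          sig = sprintf("%d:leaf@%d+%d", u, p$e, p$acc))
        }
      } else if (p$kind == "spec") {
        f <- skids[[p$e]][1L]; g <- skids[[p$e]][2L]
        for (ord in 1:2) {
          aa <- if (ord == 1) f else g
          bb <- if (ord == 1) g else f
          for (s1 in enum(kk[1L], aa, p$t)) for (s2 in enum(kk[2L], bb, p$t)) {
            out[[length(out) + 1L]] <- list(
              cost = base + s1$cost + s2$cost,
              sig = sprintf("%d:spec@%d+%d[%s|%s]", u, p$e, p$acc, s1$sig, s2$sig))
          }
        }
      } else if (p$kind == "seg") {
        for (s1 in enum(kk[1L], p$e, p$t)) for (s2 in enum(kk[2L], p$e, p$t)) {
          out[[length(out) + 1L]] <- list(
            cost = base + dup + s1$cost + s2$cost,
            sig = sprintf("%d:dup@%d.%d+%d[%s|%s]", u, p$e, p$t, p$acc,
                          s1$sig, s2$sig))
        }
        for (f in alive_in[[p$t]]) {
          if (f == p$e) next
          for (which_mv in 1:2) {
            stay <- if (which_mv == 1) kk[2L] else kk[1L]
            mv <- if (which_mv == 1) kk[1L] else kk[2L]
            for (s1 in enum(stay, p$e, p$t)) for (s2 in enum(mv, f, p$t)) {
              out[[length(out) + 1L]] <- list(
                cost = base + transfer + s1$cost + s2$cost,
                sig = sprintf("%d:tr@%d.%d->%d+%d(mv%d)[%s|%s]", u, p$e, p$t,
                              f, p$acc, mv, s1$sig, s2$sig))
            }
          }
        }
      }
    }
    out
  }
  r <- gt$root
  kk <- gkids[[r]]
  all <- list()
  for (t in seq_len(stem_slice)) for (e in alive_in[[t]]) {
    for (s1 in enum(kk[1L], e, t)) for (s2 in enum(kk[2L], e, t)) {
      all[[length(all) + 1L]] <- list(cost = dup + s1$cost + s2$cost,
                                      sig = sprintf("r:dup@%d.%d[%s|%s]", e, t,
                                                    s1$sig, s2$sig))
    }
    for (f in alive_in[[t]]) {
      if (f == e) next
      for (which_mv in 1:2) {
        stay <- if (which_mv == 1) kk[2L] else kk[1L]
        mv <- if (which_mv == 1) kk[1L] else kk[2L]
        for (s1 in enum(stay, e, t)) for (s2 in enum(mv, f, t)) {
          all[[length(all) + 1L]] <- list(
            cost = transfer + s1$cost + s2$cost,
            sig = sprintf("r:tr@%d.%d->%d(mv%d)[%s|%s]", e, t, f, mv,
                          s1$sig, s2$sig))
        }
      }
    }
  }
  for (s in seq_along(st$age)) {
    k <- skids[[s]]
    if (!length(k)) next
    ts <- bidx[s]
    for (ord in 1:2) {
      aa <- if (ord == 1) k[1L] else k[2L]
      bb <- if (ord == 1) k[2L] else k[1L]
      for (s1 in enum(kk[1L], aa, ts)) for (s2 in enum(kk[2L], bb, ts)) {
        all[[length(all) + 1L]] <- list(cost = s1$cost + s2$cost,
                                        sig = sprintf("r:spec@%d.%d[%s|%s]",
                                                      s, ord, s1$sig, s2$sig))
      }
    }
  }
  costs <- vapply(all, function(x) x$cost, numeric(1))
  sigs <- vapply(all, function(x) x$sig, character(1))
  keep <- costs < min(costs) + 1e-9
  list(cost = min(costs), sigs = sigs[keep])
}
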