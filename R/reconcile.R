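# Dated DTL maximum-parsimony reconciliation: minimum cost, exact optimum
# counts, uniform sampling of optima, cost-grid event support, transfer
# calls, and per-species-branch event summaries.

#' DTL cost scheme
#'
#' Event costs for maximum-parsimony reconciliation (speciation costs 0).
#' The defaults are the profiling grid used throughout: duplication cost 4,
#' transfer costs 5..40, loss costs 1..3.
#'
#' @param dup Duplication cost (scalar).
#' @param transfer Transfer cost(s); a vector defines the profiling grid.
#' @param loss Loss cost(s); a vector defines the profiling grid.
#' @return A list of class `cost_scheme`.
#' @export
cost_scheme <- function(dup = 4, transfer = 5:40, loss = 1:3) {
  if (any(c(dup, transfer, loss) < 0)) abort("event costs must be >= 0")
  structure(list(dup = dup, transfer = transfer, loss = loss),
            class = "cost_scheme")
}

#' Minimum reconciliation cost and exact optimum count
#'
#' Dynamic program over gene nodes and (species edge, time slice) cells.
#' Transfers are restricted to contemporaneous edges (same slice); losses
#' accrue when a lineage passes a speciation boundary on one side only; the
#' gene root may map to any edge/slice. The number of distinct optimal
#' reconciliations is counted in exact arbitrary-precision arithmetic.
#'
#' @param gt A `gene_tree`.
#' @param st A `dated_tree` or `sliced_tree`.
#' @param dup,transfer,loss Scalar event costs.
#' @return List with `cost` (minimum total cost), `count` (number of optima,
#'   numeric; may lose precision beyond 2^53) and `count_str` (exact count
#'   as a decimal string).
#' @export
mpr_cost <- function(gt, st, dup = 4, transfer = 10, loss = 1) {
  stopifnot(length(dup) == 1L, length(transfer) == 1L, length(loss) == 1L)
  st <- as_sliced(st)
  a <- engine_args(gt, st)
  res <- dtl_solve_cpp(a$g_child1, a$g_child2, a$g_post, a$g_species,
                       a$s_child1, a$s_child2, a$s_parent, a$s_bidx,
                       a$n_slice, a$s_root, dup, transfer, loss)
  res
}

event_names <- c("leaf", "speciation", "duplication", "transfer")

#' Uniformly sample optimal reconciliations
#'
#' Backtracks through the dynamic program with branch probabilities
#' proportional to the exact sub-counts, so every minimum-cost
#' reconciliation is returned with equal probability. Identical seeds give
#' identical samples.
#'
#' @inheritParams mpr_cost
#' @param n Number of samples.
#' @param seed Optional integer seed (applied with `set.seed`).
#' @return A `dtl_samples` object: tibbles `$events` (sample, node, event,
#'   species, slice, donor, recipient), `$losses` (sample, edge, slice),
#'   `$stats` (sample, cost, n_dup, n_trans, n_loss), and `$crossings`
#'   (n x species-node matrix of lineages crossing each branch's top
#'   boundary), plus the trees used.
#' @export
sample_optima <- function(gt, st, dup = 4, transfer = 10, loss = 1,
                          n = 1000, seed = NULL) {
  if (n <= 0) abort("`n` must be positive")
  st <- as_sliced(st)
  a <- engine_args(gt, st)
  if (!is.null(seed)) set.seed(seed)
  raw <- dtl_sample_cpp(a$g_child1, a$g_child2, a$g_post, a$g_species,
                        a$s_child1, a$s_child2, a$s_parent, a$s_bidx,
                        a$n_slice, a$s_root, dup, transfer, loss, as.integer(n))
  ng <- length(a$g_child1)
  lab_at <- function(idx0) {
    idx <- idx0 + 1L
    idx[idx <= 0L] <- NA_integer_
    st$label[idx]
  }
  grab <- function(f) unlist(lapply(raw, `[[`, f), use.names = FALSE)
  ev <- tibble::tibble(
    sample = rep(seq_along(raw), each = ng),
    node = rep(gt$label, length(raw)),
    event = event_names[grab("event") + 1L],
    species = lab_at(grab("species")),
    slice = grab("slice"),
    donor = lab_at(grab("donor")),
    recipient = lab_at(grab("recipient")))
  n_lost <- vapply(raw, function(r) length(r$loss_edge), integer(1))
  losses <- tibble::tibble(
    sample = rep(seq_along(raw), n_lost),
    edge = st$label[grab("loss_edge") + 1L],
    slice = grab("loss_slice"))
  stats <- tibble::tibble(
    sample = seq_along(raw),
    cost = vapply(raw, `[[`, numeric(1), "cost"),
    n_dup = vapply(raw, `[[`, integer(1), "n_dup"),
    n_trans = vapply(raw, `[[`, integer(1), "n_trans"),
    n_loss = vapply(raw, `[[`, integer(1), "n_loss"))
  crossings <- do.call(rbind, lapply(raw, function(r) r$crossings))
  colnames(crossings) <- st$label
  structure(list(events = ev,
                 losses = losses,
                 stats = stats,
                 crossings = crossings,
                 gene_tree = gt, species_tree = st,
                 costs = c(dup = dup, transfer = transfer, loss = loss)),
            class = "dtl_samples")
}

#' @export
print.dtl_samples <- function(x, ...) {
  cat(sprintf("<dtl_samples> %d optimal reconciliations, cost %g (D=%g T=%g L=%g)\n",
              nrow(x$stats), x$stats$cost[1L],
              x$costs["dup"], x$costs["transfer"], x$costs["loss"]))
  invisible(x)
}

# clade key of every internal gene node: sorted tip labels, ";"-joined
clade_keys <- function(gt) {
  below <- tips_below(gt$phylo)
  n <- gt$n_tip + gt$phylo$Nnode
  vapply(seq_len(n), function(v) {
    paste(sort(gt$phylo$tip.label[below[[v]]]), collapse = ";")
  }, character(1))
}

#' Event support across a transfer/loss cost grid
#'
#' For every `(transfer, loss)` combination (duplication cost fixed) this
#' samples optimal reconciliations and tabulates per-gene-node event
#' frequencies and modal mappings. The PRNG substream of each cell is keyed
#' by `(tree_id, dup, transfer, loss, seed)`, so enlarging the grid never
#' perturbs existing cells.
#'
#' @inheritParams mpr_cost
#' @param costs A [cost_scheme()]; `transfer` and `loss` may be vectors.
#' @param n Samples per cost combination.
#' @param seed Integer seed.
#' @param tree_id Identifier recorded with the grid (used when several
#'   gene-tree topologies are profiled).
#' @return Tibble of class `event_support` with one row per (gene node,
#'   transfer cost, loss cost): event fractions, modal species mapping,
#'   modal donor/recipient among transfer-labelled samples, clade key,
#'   sample size.
#' @export
event_support <- function(gt, st, costs = cost_scheme(), n = 1000,
                          seed = 1, tree_id = "t1") {
  st <- as_sliced(st)
  keys <- clade_keys(gt)
  grid <- expand.grid(transfer = costs$transfer, loss = costs$loss)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    th <- grid$transfer[i]; lo <- grid$loss[i]
    sub_seed <- (as.integer(seed) + 104729L * as.integer(round(th)) +
                   7919L * as.integer(round(lo * 100)) +
                   sum(utf8ToInt(tree_id))) %% 2147483647L
    smp <- sample_optima(gt, st, dup = costs$dup, transfer = th, loss = lo,
                         n = n, seed = sub_seed)
    smp$events |>
      group_by(.data$node) |>
      summarise(
        frac_speciation = mean(.data$event == "speciation"),
        frac_duplication = mean(.data$event == "duplication"),
        frac_transfer = mean(.data$event == "transfer"),
        frac_leaf = mean(.data$event == "leaf"),
        map_species = modal_value(.data$species),
        modal_donor = modal_value(.data$donor[.data$event == "transfer"]),
        modal_recipient = modal_value(.data$recipient[.data$event == "transfer"]),
        .groups = "drop"
      ) |>
      mutate(dup = costs$dup, transfer = th, loss = lo, n = n,
             tree_id = tree_id)
  })
  out <- bind_rows(cells)
  out$clade <- keys[match(out$node, gt$label)]
  class(out) <- c("event_support", class(out))
  out
}

modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  tb <- sort(table(x), decreasing = TRUE)
  mx <- names(tb)[tb == tb[1L]]
  # ties broken toward the smallest species postorder label
  mx[order(as.integer(sub("^[a-z]+", "", mx)))][1L]
}

#' Call transfers with robustness flags
#'
#' A gene node yields a transfer call if its transfer fraction exceeds the
#' majority threshold in some grid cell. The top transfer cost is the
#' largest transfer cost with majority support at the reporting loss cost;
#' the `consistent` flag requires majority support at two or more
#' consecutive transfer costs for every loss cost in the grid and, when
#' several topologies were profiled, in every topology containing the
#' node's bipartition.
#'
#' @param support An `event_support` tibble (rows from one or more
#'   topologies may be bound together).
#' @param majority Support threshold (strict), default 0.5.
#' @param report_loss Loss cost used for the reported top transfer cost.
#' @return Tibble of class `transfer_calls`: node, tree_id, clade, donor,
#'   recipient, top_cost, consistent, plus per-loss top costs.
#' @export
call_transfers <- function(support, majority = 0.5, report_loss = 1) {
  stopifnot(is.data.frame(support))
  losses <- sort(unique(support$loss))
  if (!report_loss %in% losses) report_loss <- losses[1L]
  thetas <- sort(unique(support$transfer))

  per_node <- support |>
    filter(.data$frac_transfer > majority) |>
    distinct(.data$tree_id, .data$node, .data$clade)
  if (!nrow(per_node)) {
    return(structure(tibble::tibble(
      node = character(), tree_id = character(), clade = character(),
      donor = character(), recipient = character(), top_cost = numeric(),
      consistent = logical()), class = c("transfer_calls", "tbl_df", "tbl",
                                         "data.frame")))
  }
  # majority map per (tree, node, loss): which transfer costs pass
  calls <- purrr::pmap_dfr(per_node, function(tree_id, node, clade) {
    sub <- support[support$tree_id == tree_id & support$node == node, ]
    per_loss <- lapply(losses, function(lo) {
      pass <- sort(sub$transfer[sub$loss == lo & sub$frac_transfer > majority])
      list(pass = pass,
           top = if (length(pass)) max(pass) else NA_real_,
           run2 = has_consecutive_run(pass, thetas))
    })
    names(per_loss) <- paste0("L", losses)
    rep_cell <- sub[sub$loss == report_loss &
                      sub$frac_transfer > majority, , drop = FALSE]
    top <- per_loss[[paste0("L", report_loss)]]$top
    at_top <- rep_cell[rep_cell$transfer %in% top, , drop = FALSE]
    tibble::tibble(
      node = node, tree_id = tree_id, clade = clade,
      donor = if (nrow(at_top)) at_top$modal_donor[1L] else NA_character_,
      recipient = if (nrow(at_top)) at_top$modal_recipient[1L] else NA_character_,
      top_cost = top,
      all_loss_majority = all(vapply(per_loss, function(p) length(p$pass) > 0,
                                     logical(1))),
      run_ok = all(vapply(per_loss, function(p) p$run2, logical(1))),
      top_by_loss = list(stats::setNames(
        vapply(per_loss, function(p) p$top, numeric(1)), paste0("L", losses)))
    )
  })

  # cross-topology consistency on shared bipartitions
  n_trees <- length(unique(support$tree_id))
  if (n_trees > 1L) {
    present <- support |> distinct(.data$tree_id, .data$clade)
    called <- calls |>
      filter(.data$all_loss_majority, .data$run_ok) |>
      distinct(.data$tree_id, .data$clade)
    consistent_clade <- vapply(unique(calls$clade), function(ck) {
      trees_with <- unique(present$tree_id[present$clade == ck])
      all(trees_with %in% called$tree_id[called$clade == ck])
    }, logical(1))
    calls$consistent <- calls$all_loss_majority & calls$run_ok &
      consistent_clade[match(calls$clade, names(consistent_clade))]
  } else {
    calls$consistent <- calls$all_loss_majority & calls$run_ok
  }
  out <- calls |> select(-"all_loss_majority", -"run_ok")
  class(out) <- c("transfer_calls", class(out))
  out
}

# majority at >= 2 consecutive grid transfer costs?
has_consecutive_run <- function(pass, thetas) {
  if (length(pass) < 2L) return(FALSE)
  idx <- sort(match(pass, thetas))
  any(diff(idx) == 1L)
}

#' Per-species-branch event summary
#'
#' Aggregates sampled reconciliations into the per-branch
#' `duplications / losses / genes` summary: modal event placement per gene
#' node for duplications, modal per-branch loss counts, and the modal number
#' of gene lineages crossing each branch's top boundary.
#'
#' @param samples A `dtl_samples` object (or list of them on the same
#'   species tree, pooled).
#' @return Tibble: `branch` (species node label at the lower end of the
#'   branch), `duplications`, `losses`, `genes`.
#' @export
summarize_events_on_species <- function(samples) {
  if (inherits(samples, "dtl_samples")) samples <- list(samples)
  st <- samples[[1L]]$species_tree
  for (s in samples) {
    if (!identical(s$species_tree$label, st$label)) {
      abort("all samples must be on the same species tree")
    }
  }
  branches <- st$label
  dup_counts <- stats::setNames(numeric(length(branches)), branches)
  loss_counts <- stats::setNames(numeric(length(branches)), branches)
  gene_counts <- stats::setNames(numeric(length(branches)), branches)
  modal_int <- function(x) {
    tb <- sort(table(x), decreasing = TRUE)
    as.numeric(names(tb)[1L])
  }
  for (s in samples) {
    n_s <- nrow(s$stats)
    # modal event/placement per gene node
    pl <- s$events |>
      group_by(.data$node) |>
      summarise(event = modal_value(.data$event),
                species = modal_value(.data$species), .groups = "drop")
    dups <- pl |> filter(.data$event == "duplication")
    if (nrow(dups)) {
      tb <- table(dups$species)
      dup_counts[names(tb)] <- dup_counts[names(tb)] + as.numeric(tb)
    }
    # modal per-branch loss count across samples
    if (nrow(s$losses)) {
      lc <- s$losses |> count(.data$sample, .data$edge)
      for (br in unique(lc$edge)) {
        per_sample <- c(lc$n[lc$edge == br],
                        rep(0L, n_s - sum(lc$edge == br)))
        loss_counts[br] <- loss_counts[br] + modal_int(per_sample)
      }
    }
    gene_counts <- gene_counts +
      apply(s$crossings, 2L, modal_int)[branches]
  }
  tibble::tibble(branch = branches,
                 duplications = as.numeric(dup_counts),
                 losses = as.numeric(loss_counts),
                 genes = as.numeric(gene_counts))
}

#' Closed-form duplication-loss reconciliation (LCA mapping)
#'
#' The classical undated duplication-loss reconciliation: each gene node
#' maps to the LCA of its children's mappings; a node is a duplication iff
#' its mapping equals a child's mapping; losses follow the standard
#' depth-difference bookkeeping. This is the exact limit of the DTL model
#' as the transfer cost grows without bound, and serves as its closed-form
#' oracle.
#'
#' @param gt A `gene_tree`.
#' @param st A `dated_tree` (ages unused).
#' @param dup,loss Event costs.
#' @return List with `cost`, `n_dup`, `n_loss`, and a per-node tibble
#'   `events` (node, event, species).
#' @export
lca_dl_reconcile <- function(gt, st, dup = 4, loss = 1) {
  phy_s <- st$phylo
  sp_tip <- match(gt$species, phy_s$tip.label)
  if (anyNA(sp_tip)) abort("gene leaf species missing from species tree")
  ns <- st$n_tip + phy_s$Nnode
  parent <- rep(NA_integer_, ns)
  parent[phy_s$edge[, 2L]] <- phy_s$edge[, 1L]
  depth <- integer(ns)
  for (v in rev(st$postorder)) {
    if (!is.na(parent[v])) depth[v] <- depth[parent[v]] + 1L
  }
  lca2 <- function(a, b) {
    while (a != b) {
      if (depth[a] < depth[b]) b <- parent[b] else a <- parent[a]
    }
    a
  }
  gkids <- children_list(gt$phylo)
  ng <- gt$n_tip + gt$phylo$Nnode
  M <- integer(ng)
  M[seq_len(gt$n_tip)] <- sp_tip
  is_dup <- logical(ng)
  n_loss <- 0L
  for (v in gt$postorder) {
    k <- gkids[[v]]
    if (!length(k)) next
    M[v] <- lca2(M[k[1L]], M[k[2L]])
    is_dup[v] <- M[v] == M[k[1L]] || M[v] == M[k[2L]]
    for (c in k) {
      d <- depth[M[c]] - depth[M[v]]
      n_loss <- n_loss + if (is_dup[v]) d else d - 1L
    }
  }
  n_dup <- sum(is_dup)
  internal <- lengths(gkids) == 2L
  events <- tibble::tibble(
    node = gt$label,
    event = ifelse(!internal, "leaf",
                   ifelse(is_dup, "duplication", "speciation")),
    species = st$label[M])
  list(cost = dup * n_dup + loss * n_loss, n_dup = n_dup, n_loss = n_loss,
       events = events)
}
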