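# Synthetic-data generators: birth-death chronograms, gene families evolved
# under explicit duplication/transfer/loss rates with recorded true events,
# genomic neighborhoods with event-dependent synteny decay, gene structures
# with evolving exon junctions, and block-structured similarity hit tables.
# Every generator is deterministic under a fixed seed and returns the ground
# truth needed to score downstream recovery.

#' Simulation configuration
#'
#' Bundles the generator parameters. Defaults describe the study conditions
#' emulated throughout: a 30-taxon chronogram (root age 1), 50 gene
#' families with DTL rates calibrated to roughly 2 duplications, 0.5
#' transfers and 3 losses per family, +-20-gene neighborhoods drawn from a
#' 400-member CHG pool, and event-specific neighborhood retention 0.40
#' (speciation), 0.11 (duplication), 0.21 (transfer).
#'
#' @param seed Master seed.
#' @param n_taxa Number of extant taxa in the chronogram.
#' @param birth,death Birth-death rates per lineage per unit time.
#' @param n_families Number of gene families.
#' @param dup_rate,transfer_rate,loss_rate DTL rates per gene lineage per
#'   unit time (chronogram normalised to root age 1).
#' @param window Neighborhood half-width in genes.
#' @param chg_pool CHG pool size for neighborhood simulation.
#' @param retention Named event-specific retention probabilities.
#' @param planted_assoc Optional list of planted associations, each
#'   `list(tips=, chg=, p_in=, p_out=)`.
#' @param noise_density,dropout Hit-table noise parameters.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_taxa = 30, birth = 1, death = 0,
                       n_families = 50,
                       dup_rate = 0.21, transfer_rate = 0.06, loss_rate = 0.37,
                       window = 20, chg_pool = 400,
                       retention = c(speciation = 0.40, duplication = 0.11,
                                     transfer = 0.21),
                       planted_assoc = NULL,
                       noise_density = 0.02, dropout = 0) {
  stopifnot(all(retention >= 0 & retention <= 1),
            all(c(dup_rate, transfer_rate, loss_rate, birth, death) >= 0))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a birth-death chronogram conditioned on taxon count
#'
#' Forward simulation from a single lineage: with `k` lineages the waiting
#' time to the next event is exponential with rate `k (birth + death)`;
#' the simulation stops when the extant count first reaches `n_taxa`, after
#' which tips are extended by one final exponential waiting time. Extinct
#' lineages are pruned; if everything dies the attempt is resampled
#' (at most 100 times). Ages are normalised to root age 1 unless
#' `normalize = FALSE`.
#'
#' @param n_taxa Number of extant taxa (>= 3).
#' @param birth,death Rates per lineage per unit time.
#' @param seed Optional seed.
#' @param normalize Rescale so the root age is 1.
#' @return A `dated_tree`.
#' @export
simulate_chronogram <- function(n_taxa = 30, birth = 1, death = 0,
                                seed = NULL, normalize = TRUE) {
  if (n_taxa < 3) abort("need at least 3 taxa")
  if (birth <= 0) abort("birth rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(100)) {
    phy <- bd_forward(n_taxa, birth, death)
    if (!is.null(phy)) {
      if (normalize) {
        h <- max(ape::node.depth.edgelength(phy))
        phy$edge.length <- phy$edge.length / h
      }
      return(dated_tree(phy))
    }
  }
  abort("all lineages went extinct in 100 successive attempts")
}

bd_forward <- function(n_taxa, birth, death) {
  # lineage records
  start <- 0; endt <- NA_real_; kids <- list(integer(0))
  alive <- 1L; n_lin <- 1L
  t <- 0
  repeat {
    k <- length(alive)
    if (k == 0L) return(NULL)
    if (k == n_taxa) { t <- t + stats::rexp(1, k * (birth + death)); break }
    t <- t + stats::rexp(1, k * (birth + death))
    pick <- alive[sample.int(k, 1L)]
    endt[pick] <- t
    if (stats::runif(1) < birth / (birth + death)) {
      c1 <- n_lin + 1L; c2 <- n_lin + 2L
      n_lin <- n_lin + 2L
      start[c(c1, c2)] <- t
      endt[c(c1, c2)] <- NA_real_
      kids[[c1]] <- integer(0); kids[[c2]] <- integer(0)
      kids[[pick]] <- c(c1, c2)
      alive <- c(setdiff(alive, pick), c1, c2)
    } else {
      alive <- setdiff(alive, pick)
    }
  }
  endt[alive] <- t
  extant <- logical(n_lin); extant[alive] <- TRUE
  tip_no <- 0L
  build <- function(id) {
    if (!length(kids[[id]])) {
      if (!extant[id]) return(NULL)
      tip_no <<- tip_no + 1L
      sprintf("t%d:%.10f", tip_no, endt[id] - start[id])
    } else {
      sub <- Filter(Negate(is.null), lapply(kids[[id]], build))
      if (!length(sub)) return(NULL)
      if (length(sub) == 1L) {
        # splice out the unary node, extending the branch
        parts <- sub[[1L]]
        add_len(parts, endt[id] - start[id])
      } else {
        sprintf("(%s,%s):%.10f", sub[[1L]], sub[[2L]], endt[id] - start[id])
      }
    }
  }
  add_len <- function(nwk, extra) {
    # add `extra` to the outermost branch length of a newick fragment
    pos <- max(gregexpr(":", nwk, fixed = TRUE)[[1L]])
    len <- as.numeric(substr(nwk, pos + 1L, nchar(nwk)))
    paste0(substr(nwk, 1L, pos), sprintf("%.10f", len + extra))
  }
  txt <- build(1L)
  if (is.null(txt)) return(NULL)
  phy <- ape::read.tree(text = paste0(txt, ";"))
  if (is.null(phy) || length(phy$tip.label) != n_taxa) return(NULL)
  # drop the root stem retained by build(): read.tree keeps root edge info
  phy$root.edge <- NULL
  phy
}

#' Simulate a gene family under duplication-transfer-loss rates
#'
#' A single gene lineage enters the species root and evolves down the
#' chronogram: duplications copy the lineage in place, transfers regraft a
#' copy onto a uniformly chosen coexisting species branch, losses terminate
#' the lineage, and species bifurcations split it. The surviving-leaf gene
#' tree is returned together with the full recorded event history; families
#' with fewer than 2 surviving genes are resampled (attempt count
#' reported).
#'
#' @param st A `dated_tree` chronogram.
#' @param dup_rate,transfer_rate,loss_rate Events per lineage per unit time.
#' @param family_id Prefix for gene ids.
#' @param seed Optional seed.
#' @param max_retries Resampling cap for extinct families.
#' @return List: `gene_tree`, `node_events` (tibble mapping each internal
#'   pruned-tree node label to its true event, species location, time, and
#'   donor/recipient for transfers), `events` (every simulated event with
#'   survival flags), `attempts`.
#' @export
simulate_dtl_family <- function(st, dup_rate = 0.21, transfer_rate = 0.06,
                                loss_rate = 0.37, family_id = "fam",
                                seed = NULL, max_retries = 100) {
  if (!is.null(seed)) set.seed(seed)
  phy <- st$phylo
  parent <- rep(NA_integer_, length(st$age))
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  skids <- children_list(phy)
  non_root <- setdiff(seq_along(st$age), st$root)
  rho <- dup_rate + transfer_rate + loss_rate

  for (attempt in seq_len(max_retries)) {
    events <- list()
    tip_no <- 0L
    note <- function(type, edge, age, donor = NA, recip = NA) {
      events[[length(events) + 1L]] <<- list(
        id = length(events) + 1L, type = type, species = st$label[edge],
        age = age, donor = if (is.na(donor)) NA_character_ else st$label[donor],
        recipient = if (is.na(recip)) NA_character_ else st$label[recip])
      length(events)
    }
    # returns a nested node list or NULL if no surviving descendants
    rec <- function(edge, a) {
      repeat {
        dt <- if (rho > 0) stats::rexp(1, rho) else Inf
        bottom <- st$age[edge]
        if (a - dt <= bottom) {
          if (!length(skids[[edge]])) { # species tip: sampled gene
            tip_no <<- tip_no + 1L
            return(list(kind = "tip", edge = edge,
                        label = sprintf("%s_%d|%s", family_id, tip_no,
                                        phy$tip.label[edge])))
          }
          ev <- note("speciation", edge, bottom)
          l <- rec(skids[[edge]][1L], bottom)
          r <- rec(skids[[edge]][2L], bottom)
          return(branch_node(ev, l, r))
        }
        a <- a - dt
        type <- sample(c("duplication", "transfer", "loss"), 1L,
                       prob = c(dup_rate, transfer_rate, loss_rate))
        if (type == "loss") {
          note("loss", edge, a)
          return(NULL)
        }
        if (type == "duplication") {
          ev <- note("duplication", edge, a)
          l <- rec(edge, a)
          r <- rec(edge, a)
          return(branch_node(ev, l, r))
        }
        # transfer
        cand <- non_root[st$age[non_root] < a & st$age[parent[non_root]] > a]
        cand <- setdiff(cand, edge)
        if (!length(cand)) next # no coexisting recipient; lineage continues
        recip <- cand[sample.int(length(cand), 1L)]
        ev <- note("transfer", edge, a, donor = edge, recip = recip)
        l <- rec(edge, a)       # donor copy continues
        r <- rec(recip, a)      # transferred copy
        return(branch_node(ev, l, r))
      }
    }
    # mark survival of branching events now that recursion is done
    root_node <- rec(st$root, st$age[st$root] + .Machine$double.eps)
    # the root enters at the root node age: first thing it meets is the
    # root speciation (bottom == start age), unless an in-branch event of
    # rate rho fires in zero time (impossible), so the family effectively
    # starts at the species root.
    if (is.null(root_node) || root_node$kind == "tip" || tip_no < 2L) next
    ev_tbl <- purrr::map_dfr(events, tibble::as_tibble)
    surv <- collect_survival(root_node)
    ev_tbl$survived_both <- ev_tbl$id %in% surv$both
    ev_tbl$in_pruned <- ev_tbl$id %in% surv$any
    nwk <- paste0(to_newick(root_node), ";")
    gphy <- ape::read.tree(text = nwk)
    gt <- gene_tree(gphy)
    ev_by_id <- stats::setNames(seq_len(nrow(ev_tbl)), ev_tbl$id)
    lab <- gphy$node.label
    internal_ids <- as.integer(lab)
    node_events <- tibble::tibble(
      node = gt$label[(gt$n_tip + 1L):(gt$n_tip + gphy$Nnode)],
      event = ev_tbl$type[ev_by_id[as.character(internal_ids)]],
      species = ev_tbl$species[ev_by_id[as.character(internal_ids)]],
      age = ev_tbl$age[ev_by_id[as.character(internal_ids)]],
      donor = ev_tbl$donor[ev_by_id[as.character(internal_ids)]],
      recipient = ev_tbl$recipient[ev_by_id[as.character(internal_ids)]])
    return(list(gene_tree = gt, node_events = node_events,
                events = ev_tbl, attempts = attempt))
  }
  abort(sprintf("family extinct in %d successive attempts", max_retries))
}

branch_node <- function(ev, l, r) {
  if (is.null(l) && is.null(r)) return(NULL)
  if (is.null(l)) return(r)
  if (is.null(r)) return(l)
  list(kind = "branch", ev = ev, left = l, right = r)
}

collect_survival <- function(node) {
  both <- integer(0); any_ <- integer(0)
  walk <- function(nd) {
    if (nd$kind == "branch") {
      both <<- c(both, nd$ev)
      any_ <<- c(any_, nd$ev)
      walk(nd$left); walk(nd$right)
    }
  }
  walk(node)
  list(both = both, any = any_)
}

to_newick <- function(node) {
  if (node$kind == "tip") return(node$label)
  sprintf("(%s,%s)%d", to_newick(node$left), to_newick(node$right), node$ev)
}

#' Simulate gene neighborhoods with event-dependent synteny decay
#'
#' The family's root gene receives a neighborhood of `2w` CHGs drawn from
#' the pool. At each internal node, one child (chosen at random) inherits
#' the parental neighborhood unchanged while the other retains each CHG
#' with the event-specific retention probability and refills from the pool
#' (excluding the parental set, so a retained CHG is never re-drawn by
#' chance). The expected cross-subtree shared fraction at a node whose
#' children are leaves therefore equals the retention probability of its
#' event. Planted clade-specific CHGs are inserted with probability `p_in`
#' inside the clade and `p_out` outside.
#'
#' @param gt The family `gene_tree`.
#' @param node_events Event labels per internal node (from
#'   [simulate_dtl_family()], or constructed).
#' @param window Half-width `w`.
#' @param chg_pool Pool size.
#' @param retention Named retention probabilities per event.
#' @param planted List of `list(tips=, chg=, p_in=, p_out=)`.
#' @param seed Optional seed.
#' @return List: `leaf_chg_sets` (tibble focal/feature), `annotation`
#'   (annotation tibble for focal + neighbor genes), `chg_members` (tibble
#'   gene_id/chg for neighbor genes), `planted` registry.
#' @export
simulate_neighborhoods <- function(gt, node_events, window = 20,
                                   chg_pool = 400,
                                   retention = c(speciation = 0.40,
                                                 duplication = 0.11,
                                                 transfer = 0.21),
                                   planted = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w2 <- 2L * window
  if (chg_pool < 2L * w2) {
    abort("CHG pool must be at least twice the full window (4w)")
  }
  pool <- sprintf("chg%03d", seq_len(chg_pool))
  ev <- stats::setNames(node_events$event, node_events$node)
  kids <- children_list(gt$phylo)
  sets <- vector("list", gt$n_tip + gt$phylo$Nnode)
  sets[[gt$root]] <- sample(pool, w2)
  for (v in rev(gt$postorder)) { # preorder
    k <- kids[[v]]
    if (!length(k)) next
    r <- retention[[ev[[gt$label[v]]]]]
    if (is.null(r) || is.na(r)) r <- retention[["speciation"]]
    keep_child <- sample(1:2, 1L)
    for (i in 1:2) {
      if (i == keep_child) {
        sets[[k[i]]] <- sets[[v]]
      } else {
        kept <- sets[[v]][stats::runif(w2) < r]
        refill <- sample(setdiff(pool, sets[[v]]), w2 - length(kept))
        sets[[k[i]]] <- c(kept, refill)
      }
    }
  }
  tips <- gt$phylo$tip.label
  leaf_sets <- stats::setNames(sets[seq_len(gt$n_tip)], tips)
  below <- tips_below(gt$phylo)
  for (pl in planted) {
    for (tp in tips) {
      inside <- tp %in% pl$tips
      p <- if (inside) pl$p_in else pl$p_out
      has <- pl$chg %in% leaf_sets[[tp]]
      want <- stats::runif(1) < p
      if (want && !has) {
        drop <- sample.int(length(leaf_sets[[tp]]), 1L)
        leaf_sets[[tp]][drop] <- pl$chg
      } else if (!want && has) {
        repl <- sample(setdiff(pool, leaf_sets[[tp]]), 1L)
        leaf_sets[[tp]][leaf_sets[[tp]] == pl$chg] <- repl
      }
    }
  }
  leaf_chg_sets <- purrr::map_dfr(tips, function(tp) {
    tibble::tibble(focal = tp, feature = leaf_sets[[tp]])
  })
  # materialise annotation rows: focal gene mid-scaffold, one neighbor gene
  # per CHG slot on each side
  ann_rows <- list(); memb <- list()
  for (tp in tips) {
    scf <- paste0("scf_", gsub("[^A-Za-z0-9]", "_", tp))
    neigh <- sample(leaf_sets[[tp]]) # shuffle along the scaffold
    ids <- sprintf("%s_nb%02d", gsub("[^A-Za-z0-9]", "_", tp), seq_len(w2))
    starts <- 1000L * seq_len(w2 + 1L)
    ann_rows[[tp]] <- tibble::tibble(
      gene_id = c(ids[seq_len(window)], tp, ids[(window + 1L):w2]),
      scaffold = scf, start = starts, end = starts + 800L,
      strand = "+")
    memb[[tp]] <- tibble::tibble(gene_id = ids, chg = neigh)
  }
  list(leaf_chg_sets = leaf_chg_sets,
       annotation = annotation_table(bind_rows(ann_rows)),
       chg_members = bind_rows(memb),
       planted = planted)
}

#' Simulate gene structures with evolving exon junctions
#'
#' An ancestral set of junctions (alignment column + phase) evolves along
#' the gene tree by per-branch loss and Poisson gains; clade-specific
#' junctions can be planted. Per-row gaps are placed only in non-junction
#' columns, a fraction of which are made low-occupancy to exercise the
#' consensus threshold. Gene models (exon intervals, alternating strands)
#' are emitted whose [cds_junctions()] reproduce the generating junctions
#' exactly.
#'
#' @param gt The family `gene_tree`.
#' @param n_columns Alignment length (ancestral coordinate space).
#' @param n_ancestral Ancestral junction count.
#' @param gain_rate Expected gains per branch.
#' @param loss_prob Per-branch loss probability per junction.
#' @param planted List of `list(tips=, column=, phase=)`.
#' @param gap_prob Per-cell gap probability in ordinary columns.
#' @param low_occ_frac Fraction of non-junction columns made low-occupancy.
#' @param seed Optional seed.
#' @return List: `models` (named list of `gene_model`), `alignment` (`aln`),
#'   `truth` (tibble gene/column/phase), `planted`.
#' @export
simulate_gene_structures <- function(gt, n_columns = 300, n_ancestral = 4,
                                     gain_rate = 0.3, loss_prob = 0.1,
                                     planted = NULL, gap_prob = 0.05,
                                     low_occ_frac = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tips <- gt$phylo$tip.label
  kids <- children_list(gt$phylo)
  planted_cols <- unlist(lapply(planted, `[[`, "column"))
  anc_cols <- sample(setdiff(seq_len(n_columns - 2L) + 1L, planted_cols),
                     n_ancestral)
  jsets <- vector("list", gt$n_tip + gt$phylo$Nnode)
  jsets[[gt$root]] <- tibble::tibble(column = anc_cols,
                                     phase = sample(0:2, n_ancestral,
                                                    replace = TRUE))
  for (v in rev(gt$postorder)) {
    k <- kids[[v]]
    if (!length(k)) next
    for (c_ in k) {
      js <- jsets[[v]]
      js <- js[stats::runif(nrow(js)) >= loss_prob, , drop = FALSE]
      n_gain <- stats::rpois(1, gain_rate)
      if (n_gain > 0) {
        free <- setdiff(seq_len(n_columns - 2L) + 1L,
                        c(js$column, planted_cols))
        gains <- sample(free, min(n_gain, length(free)))
        js <- bind_rows(js, tibble::tibble(
          column = gains, phase = sample(0:2, length(gains), replace = TRUE)))
      }
      jsets[[c_]] <- js
    }
  }
  leaf_j <- stats::setNames(jsets[seq_len(gt$n_tip)], tips)
  for (pl in planted) {
    for (tp in intersect(pl$tips, tips)) {
      leaf_j[[tp]] <- bind_rows(leaf_j[[tp]],
                                tibble::tibble(column = pl$column,
                                               phase = pl$phase %||% 0L))
    }
  }
  junction_cols <- sort(unique(unlist(lapply(leaf_j, `[[`, "column"))))
  ordinary <- setdiff(seq_len(n_columns), junction_cols)
  low_occ <- sample(ordinary, round(low_occ_frac * length(ordinary)))
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  rows <- character(length(tips)); names(rows) <- tips
  occupied <- vector("list", length(tips)); names(occupied) <- tips
  for (tp in tips) {
    gap <- rep(FALSE, n_columns)
    ord2 <- setdiff(ordinary, low_occ)
    gap[ord2] <- stats::runif(length(ord2)) < gap_prob
    gap[low_occ] <- stats::runif(length(low_occ)) < 0.5
    chars <- ifelse(gap, "-", sample(aa, n_columns, replace = TRUE))
    rows[tp] <- paste(chars, collapse = "")
    occupied[[tp]] <- which(!gap)
  }
  aln <- alignment(rows)
  models <- list()
  truth <- list()
  strands <- rep(c("+", "-"), length.out = length(tips))
  for (i in seq_along(tips)) {
    tp <- tips[i]
    occ <- occupied[[tp]]
    js <- leaf_j[[tp]] |> arrange(.data$column)
    residue <- match(js$column, occ) - 1L # 0-based; junction cols never gapped
    offsets <- sort(unique(3L * residue + js$phase))
    p_len <- length(occ)
    cds_len <- 3L * p_len
    widths <- diff(c(0L, offsets, cds_len))
    widths <- widths[widths > 0]
    # lay out exons with 100-bp introns; mirror for minus strand
    starts <- cumsum(c(1L, utils::head(widths, -1L) + 100L))
    ends <- starts + widths - 1L
    if (strands[i] == "-") {
      L <- max(ends)
      new_start <- L + 1L - ends
      new_end <- L + 1L - starts
      starts <- new_start; ends <- new_end
    }
    models[[tp]] <- gene_model(tp, tibble::tibble(start = starts, end = ends),
                               strand = strands[i])
    truth[[tp]] <- tibble::tibble(gene = tp, column = js$column,
                                  phase = js$phase, residue = residue)
  }
  list(models = models, alignment = aln, truth = bind_rows(truth),
       planted = planted)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a block-structured all-vs-all hit table
#'
#' Within-family pairs receive reciprocal hits with E-values log-uniform on
#' `[1e-180, 1e-30]` and coverage uniform on `[0.6, 1]`; between-family
#' noise hits (one direction only) have E-values log-uniform on
#' `[1e-8, 1e-2]` at the given density. `dropout` removes one direction of
#' a within-family pair with the given probability, exercising the
#' bidirectional filter.
#'
#' @param families Named list of gene-id vectors (>= 2 families).
#' @param noise_density Probability of a cross-family noise hit per pair.
#' @param dropout Probability of dropping one direction of a within-family
#'   pair.
#' @param seed Optional seed.
#' @return A hit tibble (see [hit_table()]).
#' @export
simulate_hit_table <- function(families, noise_density = 0.02, dropout = 0,
                               seed = NULL) {
  if (length(families) < 2L) abort("need at least 2 families")
  if (!is.null(seed)) set.seed(seed)
  ids <- unlist(families, use.names = FALSE)
  lens <- stats::setNames(round(stats::runif(length(ids), 350, 450)), ids)
  rows <- list()
  hit_row <- function(q, s, e, cov) {
    al <- round(cov * max(lens[q], lens[s]))
    tibble::tibble(query = q, subject = s,
                   pident = round(stats::runif(1, 30, 95), 1),
                   length = as.integer(al), evalue = e,
                   qlen = as.integer(lens[q]), slen = as.integer(lens[s]))
  }
  for (fam in families) {
    if (length(fam) < 2L) next
    prs <- utils::combn(fam, 2L)
    for (j in seq_len(ncol(prs))) {
      q <- prs[1L, j]; s <- prs[2L, j]
      e1 <- 10^stats::runif(1, -180, -30)
      e2 <- 10^stats::runif(1, -180, -30)
      cov <- stats::runif(1, 0.6, 1)
      keep <- if (stats::runif(1) < dropout) sample(1:2, 1L) else 0L
      if (keep != 2L) rows[[length(rows) + 1L]] <- hit_row(q, s, e1, cov)
      if (keep != 1L) rows[[length(rows) + 1L]] <- hit_row(s, q, e2, cov)
    }
  }
  fam_of <- rep(names(families), lengths(families))
  names(fam_of) <- ids
  if (noise_density > 0) {
    prs <- utils::combn(ids, 2L)
    cross <- prs[, fam_of[prs[1L, ]] != fam_of[prs[2L, ]], drop = FALSE]
    pick <- stats::runif(ncol(cross)) < noise_density
    for (j in which(pick)) {
      rows[[length(rows) + 1L]] <- hit_row(cross[1L, j], cross[2L, j],
                                           10^stats::runif(1, -8, -2),
                                           stats::runif(1, 0.3, 0.8))
    }
  }
  for (g in ids) rows[[length(rows) + 1L]] <- hit_row(g, g, 1e-200, 1)
  hit_table(bind_rows(rows))
}
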