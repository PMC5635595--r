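# Genomic-context analysis: neighborhood extraction, the Fisher-exact
# clade x CHG association scan with Bonferroni correction and local-minimum
# reporting, and neighborhood-retention statistics by event type.

#' Extract gene neighborhoods from an annotation table
#'
#' For each focal gene, the up to `w` genes on each side by ordinal index on
#' the same scaffold (strand ignored, truncated at scaffold ends, focal gene
#' excluded).
#'
#' @param ann Annotation tibble (see [annotation_table()]).
#' @param focal_ids Focal gene ids; all must be annotated.
#' @param w Window half-width in genes, default 20.
#' @return Tibble `(focal, gene_id, offset)`, `offset` in `-w..w` (never 0).
#' @export
extract_neighborhoods <- function(ann, focal_ids, w = 20) {
  missing <- setdiff(focal_ids, ann$gene_id)
  if (length(missing)) {
    abort(paste0("focal gene(s) not annotated: ", paste(missing, collapse = ", ")))
  }
  idx <- ann[match(focal_ids, ann$gene_id), ]
  purrr::map_dfr(seq_along(focal_ids), function(i) {
    scf <- ann |> filter(.data$scaffold == idx$scaffold[i])
    o <- idx$ordinal[i]
    nb <- scf |>
      filter(abs(.data$ordinal - o) <= w, .data$ordinal != o) |>
      mutate(focal = focal_ids[i], offset = .data$ordinal - o) |>
      select("focal", "gene_id", "offset")
    nb
  })
}

#' Binary CHG-presence features of neighborhoods
#'
#' A CHG is "present" for a focal gene when at least one CHG member lies in
#' its window.
#'
#' @param neighborhoods Output of [extract_neighborhoods()].
#' @param chgs A `chg_table` (chg, gene_id).
#' @return Tibble `(focal, feature)` listing present features.
#' @export
neighborhood_features <- function(neighborhoods, chgs) {
  neighborhoods |>
    inner_join(tibble::as_tibble(chgs), by = "gene_id",
               relationship = "many-to-many") |>
    distinct(.data$focal, feature = .data$chg)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' P-value by hypergeometric enumeration (sum of tables at most as probable
#' as the observed one); odds ratio is the sample odds ratio with a Haldane
#' 0.5 correction applied when any cell is zero.
#'
#' @param tab 2x2 integer matrix, or four counts `c(n11, n10, n01, n00)`.
#' @return List with `p` and `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2L, 2L, byrow = TRUE)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("contingency table must hold non-negative integers")
  }
  if (sum(tab) == 0) abort("all-zero contingency table")
  p <- stats::fisher.test(tab)$p.value
  orr <- if (any(tab == 0)) {
    ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  } else {
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  list(p = min(p, 1), odds_ratio = orr)
}

# internal nodes whose clades have >= min_clade leaves
eligible_clades <- function(gt, min_clade) {
  below <- tips_below(gt$phylo)
  n_tip <- gt$n_tip
  internal <- (n_tip + 1L):(n_tip + gt$phylo$Nnode)
  internal[lengths(below[internal]) >= min_clade]
}

#' Clade x feature association scan
#'
#' Tests every subtree with at least `min_clade` leaves against every binary
#' feature (CHG presence in the neighborhood, or any other per-gene binary
#' feature) with a two-sided Fisher exact test on the 2x2 table
#' (in/out of clade) x (feature present/absent). P-values are Bonferroni
#' corrected by the total number of tests (subtrees x features); local
#' minima and nonoverlapping reported associations are flagged via
#' [select_reported()].
#'
#' @param tree A `gene_tree` whose leaves are the focal genes.
#' @param features Tibble `(focal, feature)` of present pairs — e.g. from
#'   [neighborhood_features()] or [junction_clade_features()].
#' @param min_clade Minimum clade size, default 5.
#' @param alpha Corrected-P reporting threshold, default 1e-4.
#' @param require_all_leaves When `TRUE` (default), error if some tree leaf
#'   never appears in `features`' focal set and has no recorded (possibly
#'   empty) neighborhood; pass the full focal set via `focal_ids` to allow
#'   feature-free genes.
#' @param focal_ids Optional full set of focal genes (defaults to features'
#'   focal set, which must then cover all leaves).
#' @return A `chg_scan` tibble: clade (node label), n_leaves, feature,
#'   n11/n10/n01/n00, p_raw, p_corrected, odds_ratio, local_min, reported.
#'   Attributes: `n_tests`, `alpha`.
#' @export
clade_chg_scan <- function(tree, features, min_clade = 5, alpha = 1e-4,
                           require_all_leaves = TRUE, focal_ids = NULL) {
  stopifnot(inherits(tree, "gene_tree"))
  tips <- tree$phylo$tip.label
  if (is.null(focal_ids)) focal_ids <- unique(features$focal)
  if (require_all_leaves) {
    uncovered <- setdiff(tips, focal_ids)
    if (length(uncovered)) {
      abort(paste0("tree leaves without neighborhoods/features: ",
                   paste(uncovered, collapse = ", ")))
    }
  }
  feats <- sort(unique(features$feature))
  clades <- eligible_clades(tree, min_clade)
  n_tests <- length(clades) * length(feats)
  if (n_tests == 0L) {
    abort("no eligible subtree/feature pairs to test")
  }
  below <- tips_below(tree$phylo)
  pres <- matrix(FALSE, length(tips), length(feats),
                 dimnames = list(tips, feats))
  pres[cbind(match(features$focal, tips), match(features$feature, feats))] <- TRUE
  res <- purrr::map_dfr(clades, function(v) {
    in_clade <- tips %in% tips[below[[v]]]
    purrr::map_dfr(feats, function(f) {
      x <- pres[, f]
      n11 <- sum(in_clade & x); n10 <- sum(in_clade & !x)
      n01 <- sum(!in_clade & x); n00 <- sum(!in_clade & !x)
      ft <- fisher_exact_2x2(c(n11, n10, n01, n00))
      tibble::tibble(clade = tree$label[v], node = v,
                     n_leaves = sum(in_clade), feature = f,
                     n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                     p_raw = ft$p, odds_ratio = ft$odds_ratio)
    })
  })
  res$p_corrected <- pmin(1, res$p_raw * n_tests)
  res <- select_reported(res, tree, alpha = alpha)
  structure(res, n_tests = n_tests, alpha = alpha,
            class = c("chg_scan", class(tibble::tibble())))
}

#' Flag local P-value minima and reported associations
#'
#' For each feature, a subtree is a local minimum when its corrected P is
#' lower than at the parent subtree and at every eligible child subtree
#' (ties broken toward the smaller subtree). Reported associations are
#' selected greedily by ascending corrected P among local minima at or
#' below `alpha`, skipping any subtree that shares a leaf with an
#' already-reported subtree for the same feature.
#'
#' @param res Scan result rows (must carry `node`, `feature`, `p_corrected`,
#'   `n_leaves`).
#' @param tree The `gene_tree` the subtrees belong to.
#' @param alpha Reporting threshold on corrected P.
#' @return `res` with logical columns `local_min` and `reported`.
#' @export
select_reported <- function(res, tree, alpha = 1e-4) {
  parent <- rep(NA_integer_, tree$n_tip + tree$phylo$Nnode)
  parent[tree$phylo$edge[, 2L]] <- tree$phylo$edge[, 1L]
  below <- tips_below(tree$phylo)
  kids <- children_list(tree$phylo)
  res$local_min <- FALSE
  res$reported <- FALSE
  # (P, n_leaves) lexicographic: smaller clade wins ties
  beats <- function(p1, l1, p2, l2) p1 < p2 | (p1 == p2 & l1 < l2)
  for (f in unique(res$feature)) {
    rows <- which(res$feature == f)
    sub <- res[rows, ]
    pmap <- stats::setNames(sub$p_corrected, sub$node)
    lmap <- stats::setNames(sub$n_leaves, sub$node)
    eligible <- as.integer(names(pmap))
    is_lm <- vapply(seq_len(nrow(sub)), function(i) {
      v <- sub$node[i]
      pv <- sub$p_corrected[i]; lv <- sub$n_leaves[i]
      pa <- parent[v]
      if (!is.na(pa) && pa %in% eligible &&
          !beats(pv, lv, pmap[as.character(pa)], lmap[as.character(pa)])) {
        return(FALSE)
      }
      for (k in kids[[v]]) {
        if (k %in% eligible &&
            !beats(pv, lv, pmap[as.character(k)], lmap[as.character(k)])) {
          return(FALSE)
        }
      }
      TRUE
    }, logical(1))
    res$local_min[rows] <- is_lm
    cand <- sub[is_lm & sub$p_corrected <= alpha, ]
    if (nrow(cand)) {
      cand <- cand[order(cand$p_corrected, cand$n_leaves, cand$clade), ]
      used <- character(0)
      for (i in seq_len(nrow(cand))) {
        lv <- tree$phylo$tip.label[below[[cand$node[i]]]]
        if (!length(intersect(lv, used))) {
          used <- c(used, lv)
          res$reported[rows][res$node[rows] == cand$node[i]] <- TRUE
        }
      }
    }
  }
  res
}

#' Neighborhood retention across each bipartition
#'
#' For every internal node, the mean over all cross pairs (one leaf from
#' each child subtree) of the shared-CHG fraction
#' `|A intersect B| / denom(A, B)`, with the denominator the smaller set
#' size (`"min"`, default), the mean size (`"mean"`), or the union size
#' (`"jaccard"`). Depth measures how deep (ancient) a node is: by default
#' the maximum edge count from the node down to its leaves, so recent
#' cherries have depth 1 and the root is deepest -- the orientation under
#' which context loss over repeated events shows up as a *negative*
#' retention-depth correlation. `depth = "from_root"` gives the opposite
#' (edge count below the root) convention instead.
#'
#' @param tree A `gene_tree`.
#' @param chg_sets Tibble `(focal, feature)`: CHGs present per leaf's
#'   neighborhood (leaves absent from the table have empty sets).
#' @param mode Denominator mode: `"min"`, `"mean"`, or `"jaccard"`.
#' @param depth Depth convention: `"height"` (default) or `"from_root"`.
#' @return Tibble `(node, retention, depth, n_pairs)`; nodes where every
#'   cross pair has two empty sets are skipped with a warning.
#' @export
neighborhood_retention <- function(tree, chg_sets, mode = c("min", "mean", "jaccard"),
                                   depth = c("height", "from_root")) {
  mode <- match.arg(mode)
  depth_mode <- match.arg(depth)
  tips <- tree$phylo$tip.label
  sets <- split(chg_sets$feature, factor(chg_sets$focal, levels = tips))
  below <- tips_below(tree$phylo)
  kids <- children_list(tree$phylo)
  parent <- rep(NA_integer_, length(below))
  parent[tree$phylo$edge[, 2L]] <- tree$phylo$edge[, 1L]
  dp <- integer(length(below))
  if (depth_mode == "from_root") {
    for (v in rev(tree$postorder)) {
      if (!is.na(parent[v])) dp[v] <- dp[parent[v]] + 1L
    }
  } else {
    for (v in tree$postorder) {
      k <- kids[[v]]
      dp[v] <- if (length(k)) max(dp[k]) + 1L else 0L
    }
  }
  internal <- (tree$n_tip + 1L):(tree$n_tip + tree$phylo$Nnode)
  out <- purrr::map_dfr(internal, function(v) {
    left <- tips[below[[kids[[v]][1L]]]]
    right <- tips[below[[kids[[v]][2L]]]]
    fr <- numeric(0)
    for (a in left) for (b in right) {
      A <- sets[[a]]; B <- sets[[b]]
      den <- switch(mode,
                    min = min(length(A), length(B)),
                    mean = (length(A) + length(B)) / 2,
                    jaccard = length(union(A, B)))
      if (den == 0) next
      fr <- c(fr, length(intersect(A, B)) / den)
    }
    if (!length(fr)) {
      warn(sprintf("node %s skipped: no scorable leaf pairs", tree$label[v]))
      return(NULL)
    }
    tibble::tibble(node = tree$label[v], retention = mean(fr),
                   depth = dp[v], n_pairs = length(fr))
  })
  structure(out, mode = mode, depth = depth_mode,
            class = c("retention_records", class(tibble::tibble())))
}

#' Retention contrasted by reconciliation event type
#'
#' Joins retention records with per-node event labels, reports per-event
#' mean retention, two-sample Wilcoxon rank-sum tests for
#' speciation-vs-duplication and transfer-vs-duplication, and the Pearson
#' correlation of retention with node depth.
#'
#' @param records Output of [neighborhood_retention()] (rows `node,
#'   retention, depth`), possibly pooled over families.
#' @param events Tibble `(node, event)` with events `speciation`,
#'   `duplication`, `transfer` (e.g. modal calls from reconciliation
#'   samples, or generator truth).
#' @return A `retention_summary` list: `$means` (event, mean, n),
#'   `$tests` (comparison, p), `$depth_cor` (rho, p), `$records`.
#' @export
retention_by_event <- function(records, events) {
  d <- tibble::as_tibble(records) |>
    inner_join(tibble::as_tibble(events), by = "node") |>
    filter(.data$event %in% c("speciation", "duplication", "transfer"))
  means <- d |>
    group_by(.data$event) |>
    summarise(mean = mean(.data$retention), n = dplyr::n(), .groups = "drop")
  pairings <- list(c("speciation", "duplication"),
                   c("transfer", "duplication"))
  tests <- purrr::map_dfr(pairings, function(pr) {
    x <- d$retention[d$event == pr[1L]]
    y <- d$retention[d$event == pr[2L]]
    if (length(x) < 2L || length(y) < 2L) {
      inform(sprintf("comparison %s vs %s omitted: fewer than 2 records in a class",
                     pr[1L], pr[2L]))
      return(tibble::tibble(comparison = paste(pr, collapse = "_vs_"),
                            p = NA_real_))
    }
    tibble::tibble(comparison = paste(pr, collapse = "_vs_"),
                   p = stats::wilcox.test(x, y, exact = FALSE)$p.value)
  })
  depth_cor <- if (nrow(d) >= 3L && stats::sd(d$retention) > 0 &&
                   stats::sd(d$depth) > 0) {
    ct <- stats::cor.test(d$retention, d$depth, method = "pearson")
    list(rho = unname(ct$estimate), p = ct$p.value)
  } else {
    list(rho = NA_real_, p = NA_real_)
  }
  structure(list(means = means, tests = tests, depth_cor = depth_cor,
                 records = d),
            class = "retention_summary")
}

#' @export
print.retention_summary <- function(x, ...) {
  cat("<retention_summary>\n")
  for (i in seq_len(nrow(x$means))) {
    cat(sprintf("  %-12s mean retention %.3f (n = %d)\n",
                x$means$event[i], x$means$mean[i], x$means$n[i]))
  }
  for (i in seq_len(nrow(x$tests))) {
    cat(sprintf("  rank-sum %s: P = %.3g\n", x$tests$comparison[i], x$tests$p[i]))
  }
  cat(sprintf("  retention ~ depth: Pearson rho = %.3f (P = %.3g)\n",
              x$depth_cor$rho, x$depth_cor$p))
  invisible(x)
}
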