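# Homolog graph construction and Markov clustering into candidate homolog
# groups (CHGs).

#' Build the filtered homolog similarity graph
#'
#' An undirected edge joins two proteins only if hits exist in *both*
#' directions, each with E-value below `e_max` and coverage of the longer
#' sequence strictly above `cov_min` (the bidirectional best-hit filter).
#' Edge weight is the mean over both directions of `-log10(E)` (E floored
#' at 1e-200); multiple hits per direction contribute their smallest E.
#'
#' @param hits A hit tibble (see [hit_table()]).
#' @param e_max E-value cutoff (strict `<`), default 1e-10.
#' @param cov_min Coverage-of-longer-sequence cutoff (strict `>`), default 0.5.
#' @return A `sim_graph`: tibble of edges `(from, to, weight)` with
#'   `from < to`; attribute `nodes` lists every id seen in `hits`.
#' @export
build_similarity_graph <- function(hits, e_max = 1e-10, cov_min = 0.5) {
  nodes <- sort(unique(c(hits$query, hits$subject)))
  pass <- hits |>
    filter(.data$query != .data$subject,
           .data$evalue < e_max, .data$coverage > cov_min) |>
    group_by(.data$query, .data$subject) |>
    summarise(evalue = min(.data$evalue), .groups = "drop")
  a <- pass |>
    mutate(from = pmin(.data$query, .data$subject),
           to = pmax(.data$query, .data$subject))
  edges <- a |>
    group_by(.data$from, .data$to) |>
    summarise(n_dir = dplyr::n_distinct(.data$query),
              weight = mean(-log10(pmax(.data$evalue, 1e-200))),
              .groups = "drop") |>
    filter(.data$n_dir == 2L) |>
    select("from", "to", "weight")
  structure(edges, nodes = nodes, class = c("sim_graph", class(edges)))
}

#' Markov clustering (MCL) of a similarity graph
#'
#' Standard MCL on the column-stochastic transition matrix with self-loops
#' (each node's self-loop weight is its maximum incident edge weight, 1 for
#' isolated nodes), alternating expansion (matrix squaring) and inflation
#' (elementwise power then column renormalisation) until the largest
#' elementwise change drops below `tol`. Clusters are the weakly connected
#' components of the limit matrix's nonzero structure. Deterministic for
#' fixed input and invariant to node order.
#'
#' @param g A `sim_graph`.
#' @param inflation Inflation exponent (> 1), default 1.4.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the max elementwise change.
#' @param prune Entries below this are zeroed each iteration (numerical
#'   hygiene; default 1e-10).
#' @return A `clustering`: tibble `(gene_id, cluster)`; clusters are
#'   numbered by decreasing size, ties by smallest member id.
#' @export
mcl_cluster <- function(g, inflation = 1.4, max_iter = 1000, tol = 1e-8,
                        prune = 1e-10) {
  if (inflation <= 1) abort("`inflation` must be > 1")
  nodes <- sort(attr(g, "nodes"))
  n <- length(nodes)
  if (n == 0L) abort("empty graph")
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(g)) {
    i <- match(g$from, nodes); j <- match(g$to, nodes)
    M[cbind(i, j)] <- g$weight
    M[cbind(j, i)] <- g$weight
  }
  loop <- apply(M, 1L, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  normalise <- function(m) sweep(m, 2L, colSums(m), "/")
  M <- normalise(M)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M             # expansion
    M2 <- M2^inflation        # inflation
    M2[M2 < prune] <- 0
    M2 <- normalise(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
    if (it == max_iter) {
      abort(sprintf("MCL did not converge in %d iterations (residual %.3g)",
                    max_iter, delta))
    }
  }
  adj <- (M > prune) | t(M > prune)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  cl <- tibble::tibble(gene_id = nodes, cluster = comp$membership)
  canonicalise_clusters(cl)
}

# renumber clusters by decreasing size, ties by smallest member id
canonicalise_clusters <- function(cl) {
  info <- cl |>
    group_by(.data$cluster) |>
    summarise(size = dplyr::n(), first = min(.data$gene_id), .groups = "drop") |>
    arrange(desc(.data$size), .data$first)
  remap <- stats::setNames(seq_len(nrow(info)), info$cluster)
  out <- cl |>
    mutate(cluster = as.integer(remap[as.character(.data$cluster)])) |>
    arrange(.data$cluster, .data$gene_id)
  structure(out, class = c("clustering", class(tibble::tibble())))
}

#' Average silhouette width of a clustering on the similarity graph
#'
#' Distances are `1 - w/w_max` for connected pairs and 1 otherwise. For each
#' node, `a` is its mean within-cluster distance and `b` the smallest mean
#' distance to another cluster; its silhouette is `(b - a)/max(a, b)`.
#' Members of singleton clusters contribute 0. Returns the mean over nodes.
#'
#' @param g A `sim_graph`.
#' @param cl A `clustering` covering the graph's nodes.
#' @return Average silhouette width in `[-1, 1]`.
#' @export
silhouette_width <- function(g, cl) {
  if (length(unique(cl$cluster)) < 2L) {
    abort("silhouette width is undefined for a single cluster")
  }
  nodes <- cl$gene_id
  n <- length(nodes)
  D <- matrix(1, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  if (nrow(g)) {
    wmax <- max(g$weight)
    i <- match(g$from, nodes); j <- match(g$to, nodes)
    D[cbind(i, j)] <- 1 - g$weight / wmax
    D[cbind(j, i)] <- 1 - g$weight / wmax
  }
  memb <- cl$cluster
  s <- vapply(seq_len(n), function(k) {
    own <- memb == memb[k]
    if (sum(own) == 1L) return(0)
    a <- mean(D[k, own & seq_len(n) != k])
    b <- min(vapply(setdiff(unique(memb), memb[k]),
                    function(c2) mean(D[k, memb == c2]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Define candidate homolog groups from a clustering
#'
#' Clusters with at least `min_size` members become CHGs with ids
#' `ch1, ch2, ...` assigned by decreasing size (ties by smallest member id);
#' smaller clusters are discarded but counted in the summary attribute.
#'
#' @param cl A `clustering`.
#' @param min_size Minimum cluster size, default 10.
#' @return Tibble `(chg, gene_id)` of class `chg_table`; attribute `summary`
#'   records total/kept/discarded cluster counts.
#' @export
define_chgs <- function(cl, min_size = 10) {
  sizes <- cl |> count(.data$cluster, name = "size")
  keep <- sizes$cluster[sizes$size >= min_size]
  out <- cl |>
    filter(.data$cluster %in% keep) |>
    mutate(chg = paste0("ch", .data$cluster)) |>
    select("chg", "gene_id")
  structure(out,
            summary = list(n_clusters = nrow(sizes),
                           n_chg = length(keep),
                           n_discarded = nrow(sizes) - length(keep),
                           min_size = min_size),
            class = c("chg_table", class(tibble::tibble())))
}

#' Silhouette-width sweep across MCL inflation settings
#'
#' Runs MCL at each inflation value and reports the cluster count and the
#' average silhouette width, mirroring the use of silhouette profiles to
#' justify the working inflation setting.
#'
#' @param g A `sim_graph`.
#' @param inflations Inflation values to profile.
#' @return Tibble `(inflation, n_clusters, silhouette)`; silhouette is `NA`
#'   when a setting yields a single cluster.
#' @export
inflation_sweep <- function(g, inflations = c(1.2, 1.4, 1.6, 2.0)) {
  purrr::map_dfr(inflations, function(inf) {
    cl <- mcl_cluster(g, inflation = inf)
    sil <- if (length(unique(cl$cluster)) < 2L) NA_real_
    else silhouette_width(g, cl)
    tibble::tibble(inflation = inf,
                   n_clusters = length(unique(cl$cluster)),
                   silhouette = sil)
  })
}

#' Write a clustering or CHG table as TSV
#' @param x Tibble to write.
#' @param path Output file.
#' @export
write_clusters <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
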