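# End-to-end orchestration: simulate (or load) inputs, cluster the homolog
# graph, reconcile families, scan for clade associations, score retention,
# and map junctions -- writing a plain-TSV/JSON report bundle.

#' Run the full analysis pipeline
#'
#' In simulate mode (`cfg` a [sim_config()]), generates a chronogram, gene
#' families, neighborhoods, a hit table, and gene structures, then executes
#' clustering -> reconciliation -> synteny scan -> retention ->
#' gene-structure stages and writes the report bundle: events TSV, transfer
#' report TSV, association report TSV, retention summary TSV, junction
#' counts TSV, and a JSON run manifest. Stages whose inputs are absent are
#' skipped with a notice.
#'
#' @param cfg A `sim_config` (simulate mode) or a named list of input
#'   objects (`species_tree`, `families`, `annotation`, `chg_members`,
#'   `hits`, ...).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param dup,transfer,loss Reconciliation costs used for the event report
#'   (profiling grids are available via [event_support()] directly).
#' @param n_samples Reconciliation samples per family.
#' @param min_clade,alpha Scan parameters.
#' @param quiet Suppress stage messages.
#' @return A list bundle: `species_tree`, `families`, `events`,
#'   `branch_summary`, `clusters`, `chgs`, `scan`, `retention`,
#'   `junctions`, `manifest`.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir = NULL,
                         dup = 4, transfer = 10, loss = 1,
                         n_samples = 200, min_clade = 5, alpha = 1e-4,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  t0 <- Sys.time()

  say("stage 1/5: simulating chronogram (%d taxa) and %d families",
      cfg$n_taxa, cfg$n_families)
  st <- simulate_chronogram(cfg$n_taxa, cfg$birth, cfg$death,
                            seed = cfg$seed)
  sl <- build_time_slices(st)
  fams <- lapply(seq_len(cfg$n_families), function(i) {
    simulate_dtl_family(st, cfg$dup_rate, cfg$transfer_rate, cfg$loss_rate,
                        family_id = sprintf("fam%02d", i),
                        seed = cfg$seed + 1000L + i)
  })

  say("stage 2/5: reconciling %d families (D=%g T=%g L=%g, %d samples)",
      length(fams), dup, transfer, loss, n_samples)
  samples <- lapply(seq_along(fams), function(i) {
    sample_optima(fams[[i]]$gene_tree, sl, dup, transfer, loss,
                  n = n_samples, seed = cfg$seed + 2000L + i)
  })
  events <- purrr::map_dfr(seq_along(samples), function(i) {
    modal_events(samples[[i]]) |> mutate(family = sprintf("fam%02d", i),
                                         .before = 1L)
  })
  branch_summary <- summarize_events_on_species(samples)

  say("stage 3/5: neighborhoods, hit table, MCL clustering")
  nbh <- lapply(seq_along(fams), function(i) {
    simulate_neighborhoods(fams[[i]]$gene_tree, fams[[i]]$node_events,
                           window = cfg$window, chg_pool = cfg$chg_pool,
                           retention = cfg$retention,
                           planted = cfg$planted_assoc,
                           seed = cfg$seed + 3000L + i)
  })
  # one synthetic protein family per CHG in the first family's neighborhoods
  memb <- nbh[[1L]]$chg_members
  fam_split <- split(memb$gene_id, memb$chg)
  fam_split <- fam_split[lengths(fam_split) >= 2L]
  clusters <- chgs <- NULL
  if (length(fam_split) >= 2L) {
    hits <- simulate_hit_table(fam_split, noise_density = cfg$noise_density,
                               dropout = cfg$dropout,
                               seed = cfg$seed + 4000L)
    g <- build_similarity_graph(hits)
    clusters <- mcl_cluster(g)
    chgs <- define_chgs(clusters, min_size = 2L)
  } else {
    say("  clustering skipped: fewer than 2 multi-member CHGs")
  }

  say("stage 4/5: clade association scan and retention statistics")
  scan <- purrr::map_dfr(seq_along(fams), function(i) {
    gt <- fams[[i]]$gene_tree
    if (gt$n_tip < min_clade) return(NULL)
    clade_chg_scan(gt, nbh[[i]]$leaf_chg_sets, min_clade = min_clade,
                   alpha = alpha) |>
      mutate(family = sprintf("fam%02d", i), .before = 1L)
  })
  rec_records <- purrr::map_dfr(seq_along(fams), function(i) {
    neighborhood_retention(fams[[i]]$gene_tree, nbh[[i]]$leaf_chg_sets) |>
      mutate(family = sprintf("fam%02d", i), node = paste0(.data$family,
                                                           ".", .data$node))
  })
  rec_events <- purrr::map_dfr(seq_along(fams), function(i) {
    fams[[i]]$node_events |>
      mutate(node = paste0(sprintf("fam%02d", i), ".", .data$node)) |>
      select("node", "event")
  })
  retention <- retention_by_event(rec_records, rec_events)

  say("stage 5/5: gene structures and junction mapping")
  gs <- simulate_gene_structures(fams[[1L]]$gene_tree,
                                 seed = cfg$seed + 5000L)
  maps <- lapply(gs$models, function(mod) {
    junctions_to_columns(cds_junctions(mod), mod$gene_id, gs$alignment)
  })
  junctions <- junction_column_counts(maps, gs$alignment)

  manifest <- list(
    package = "xenoscan",
    version = as.character(utils::packageVersion("xenoscan")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    parameters = list(n_taxa = cfg$n_taxa, n_families = cfg$n_families,
                      dup_rate = cfg$dup_rate,
                      transfer_rate = cfg$transfer_rate,
                      loss_rate = cfg$loss_rate, window = cfg$window,
                      chg_pool = cfg$chg_pool,
                      retention = as.list(cfg$retention),
                      costs = list(dup = dup, transfer = transfer,
                                   loss = loss),
                      n_samples = n_samples, min_clade = min_clade,
                      alpha = alpha),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  bundle <- list(species_tree = st, families = fams, events = events,
                 branch_summary = branch_summary, clusters = clusters,
                 chgs = chgs, scan = scan, retention = retention,
                 junctions = junctions, manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Modal event and placement per gene node
#'
#' The most frequent event label and species mapping of each gene node
#' across sampled optimal reconciliations (ties broken toward the smallest
#' species postorder label).
#'
#' @param smp A `dtl_samples` object.
#' @return Tibble `(node, event, species, donor, recipient)`.
#' @export
modal_events <- function(smp) {
  smp$events |>
    group_by(.data$node) |>
    summarise(event = modal_value(.data$event),
              species = modal_value(.data$species),
              donor = modal_value(.data$donor[.data$event == "transfer"]),
              recipient = modal_value(.data$recipient[.data$event == "transfer"]),
              .groups = "drop")
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) if (!is.null(x)) {
    readr::write_tsv(tibble::as_tibble(x), file.path(out_dir, f))
  }
  write_tree(bundle$species_tree, file.path(out_dir, "species_tree.nwk"))
  w(bundle$events, "events.tsv")
  w(bundle$branch_summary, "branch_summary.tsv")
  w(bundle$clusters, "clusters.tsv")
  w(bundle$chgs, "chgs.tsv")
  if (!is.null(bundle$scan)) {
    w(bundle$scan |> select(-dplyr::any_of("node")), "associations.tsv")
  }
  w(bundle$retention$records, "retention.tsv")
  w(bundle$retention$means, "retention_means.tsv")
  w(bundle$junctions, "junction_counts.tsv")
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
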