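# independent Fisher oracle: direct hypergeometric enumeration
fisher_oracle <- function(n11, n10, n01, n00) {
  m <- n11 + n10; n <- n01 + n00; k <- n11 + n01
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(n11, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("neighborhood windows truncate at scaffold ends and exclude the focal gene", {
  ann <- annotation_table(tibble::tibble(
    gene_id = paste0("g", 1:100), scaffold = "c1",
    start = 1000 * (1:100), end = 1000 * (1:100) + 500, strand = "+"))
  nb <- extract_neighborhoods(ann, c("g1", "g50"), w = 20)
  expect_equal(sum(nb$focal == "g1"), 20L)   # right side only
  expect_equal(sum(nb$focal == "g50"), 40L)
  expect_false("g50" %in% nb$gene_id[nb$focal == "g50"])
  # two focal genes 5 apart appear in each other's window
  nb2 <- extract_neighborhoods(ann, c("g40", "g45"), w = 20)
  expect_true("g45" %in% nb2$gene_id[nb2$focal == "g40"])
  expect_true("g40" %in% nb2$gene_id[nb2$focal == "g45"])
  expect_error(extract_neighborhoods(ann, "nope"), "nope")
})

test_that("Fisher exact P matches the hypergeometric closed form", {
  expect_equal(fisher_exact_2x2(c(4, 0, 0, 4))$p, 2 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(c(2, 2, 2, 2))$p, 1)
  expect_equal(fisher_exact_2x2(c(10, 0, 0, 10))$p, 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(c(0, 0, 0, 0)), "all-zero")
  # odds ratio: sample OR, Haldane-corrected when a cell is zero
  expect_equal(fisher_exact_2x2(c(6, 2, 1, 3))$odds_ratio, 9)
  expect_equal(fisher_exact_2x2(c(4, 0, 0, 4))$odds_ratio, 4.5^2 / 0.25)
  # exhaustive agreement for all tables with total <= 14 (larger totals in
  # the acceptance suite)
  for (tot in 2:14) {
    for (n11 in 0:tot) for (n10 in 0:(tot - n11)) {
      for (n01 in 0:(tot - n11 - n10)) {
        n00 <- tot - n11 - n10 - n01
        got <- fisher_exact_2x2(c(n11, n10, n01, n00))$p
        expect_equal(got, fisher_oracle(n11, n10, n01, n00),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("the clade scan tests every eligible subtree x feature pair", {
  gt <- fix_balanced_gene(8)
  tips <- gt$phylo$tip.label
  # CHG present exactly in the first 4-leaf clade
  feats <- tibble::tibble(focal = tips[1:4], feature = "chA")
  sc <- clade_chg_scan(gt, feats, min_clade = 4, alpha = 1e-4,
                       focal_ids = tips)
  # eligible subtrees: two 4-leaf clades + root
  expect_equal(attr(sc, "n_tests"), 3L)
  hit <- sc[sc$n11 == 4 & sc$n10 == 0 & sc$n01 == 0, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$p_raw, 2 / 70, tolerance = 1e-12)
  expect_equal(hit$p_corrected, min(1, 2 / 70 * 3))
  # feature everywhere: all raw P = 1, nothing reported
  all_f <- tibble::tibble(focal = tips, feature = "chB")
  sc2 <- clade_chg_scan(gt, all_f, min_clade = 4)
  expect_true(all(sc2$p_raw == 1))
  expect_false(any(sc2$reported))
  # leaves without features are an error unless declared focal
  expect_error(clade_chg_scan(gt, feats, min_clade = 4), "without")
})

test_that("local minima and nonoverlap reporting behave on constructed fixtures", {
  gt <- fix_balanced_gene(16)
  tips <- gt$phylo$tip.label
  # strong signal in one 4-leaf clade: P decreases monotonically toward it
  feats <- tibble::tibble(focal = tips[1:4], feature = "chA")
  sc <- clade_chg_scan(gt, feats, min_clade = 4, alpha = 0.05,
                       focal_ids = tips)
  rep_a <- sc[sc$reported, ]
  expect_equal(nrow(rep_a), 1L)
  expect_equal(rep_a$n11, 4L)
  expect_true(rep_a$local_min)
  # two disjoint significant clades for one CHG: both reported
  gt32 <- fix_balanced_gene(32)
  tips32 <- gt32$phylo$tip.label
  feats2 <- tibble::tibble(focal = c(tips32[1:4], tips32[29:32]),
                           feature = "chC")
  sc2 <- clade_chg_scan(gt32, feats2, min_clade = 4, alpha = 0.05,
                        focal_ids = tips32)
  expect_equal(sum(sc2$reported), 2L)
  expect_equal(sort(sc2$n_leaves[sc2$reported]), c(4L, 4L))
  # nested significant clades: only the lower-P one is reported
  nested <- sc2[sc2$p_corrected <= 0.05, ]
  expect_true(all(!sc2$reported | sc2$local_min))
})

test_that("planted clade associations are recovered in simulated trees", {
  set.seed(5)
  recovered <- 0L
  for (i in 1:10) {
    st <- simulate_chronogram(8, seed = 400 + i)
    gt <- fix_balanced_gene(64, function(k) sprintf("t%d", (k %% 8) + 1))
    tips <- gt$phylo$tip.label
    below <- xenoscan:::tips_below(gt$phylo)
    planted_node <- xenoscan:::eligible_clades(gt, 12)[3] # a 16-leaf clade
    clade_tips <- tips[below[[planted_node]]]
    present <- ifelse(tips %in% clade_tips,
                      stats::runif(64) < 0.95, stats::runif(64) < 0.05)
    feats <- tibble::tibble(focal = tips[present], feature = "chP")
    sc <- clade_chg_scan(gt, feats, min_clade = 5, alpha = 1e-4,
                         focal_ids = tips)
    hit <- sc[sc$reported, ]
    # recovered if a reported subtree sits essentially on the planted clade
    if (nrow(hit) && any(vapply(hit$node, function(v) {
      lv <- tips[below[[v]]]
      length(intersect(lv, clade_tips)) >= 8 &&
        length(setdiff(lv, clade_tips)) <= 2
    }, logical(1)))) recovered <- recovered + 1L
  }
  expect_gte(recovered, 9L)
})

test_that("retention statistics match hand-worked shared fractions", {
  phy <- ape::read.tree(text = "((a,b),c);")
  gt <- gene_tree(phy, species = c(a = "A", b = "B", c = "C"))
  sets <- tibble::tibble(
    focal = c(rep("a", 4), rep("b", 4), rep("c", 4)),
    feature = c("1", "2", "3", "4", "1", "2", "5", "6", "1", "2", "7", "8"))
  ret <- neighborhood_retention(gt, sets)
  # cherry (a,b): single pair |{1,2}|/4 = 0.5
  # root: pairs (a,c) and (b,c): both 0.5 -> mean 0.5
  expect_equal(sort(ret$retention), c(0.5, 0.5))
  expect_equal(ret$depth[ret$node == "g5"], 2L)  # root is deepest
  # identical sets -> 1; disjoint -> 0
  same <- tibble::tibble(focal = rep(c("a", "b", "c"), each = 2),
                         feature = rep(c("x", "y"), 3))
  expect_true(all(neighborhood_retention(gt, same)$retention == 1))
  disj <- tibble::tibble(focal = rep(c("a", "b", "c"), each = 1),
                         feature = c("x", "y", "z"))
  expect_true(all(neighborhood_retention(gt, disj)$retention == 0))
  # invariant to child swap / leaf order
  phy2 <- ape::read.tree(text = "(c,(b,a));")
  gt2 <- gene_tree(phy2, species = c(a = "A", b = "B", c = "C"))
  ret2 <- neighborhood_retention(gt2, sets)
  expect_equal(sort(ret2$retention), sort(ret$retention))
})

test_that("retention-by-event recovers planted class differences", {
  set.seed(91)
  # many single-split families with known event labels
  mk_family <- function(i, event, r) {
    phy <- ape::read.tree(text = sprintf("(L%d|SA,R%d|SB);", i, i))
    gt <- gene_tree(phy)
    ne <- tibble::tibble(node = "g3", event = event, species = "s1",
                         age = 0.5, donor = NA_character_,
                         recipient = NA_character_)
    nb <- simulate_neighborhoods(gt, ne, window = 10, chg_pool = 200,
                                 retention = c(speciation = 0.40,
                                               duplication = 0.11,
                                               transfer = 0.21))
    rr <- neighborhood_retention(gt, nb$leaf_chg_sets)
    rr$node <- paste0("f", i, ".", rr$node)
    list(records = rr,
         events = tibble::tibble(node = rr$node, event = event))
  }
  evs <- rep(c("speciation", "duplication", "transfer"), each = 40)
  fams <- lapply(seq_along(evs), function(i) mk_family(i, evs[i], NA))
  records <- purrr::map_dfr(fams, "records")
  events <- purrr::map_dfr(fams, "events")
  rs <- retention_by_event(records, events)
  m <- stats::setNames(rs$means$mean, rs$means$event)
  expect_lt(abs(m[["speciation"]] - 0.40), 0.05)
  expect_lt(abs(m[["duplication"]] - 0.11), 0.05)
  expect_lt(abs(m[["transfer"]] - 0.21), 0.05)
  expect_lt(rs$tests$p[rs$tests$comparison == "speciation_vs_duplication"],
            0.01)
})

test_that("retention decays with depth when decay is planted", {
  set.seed(17)
  # caterpillar: deeper nodes accumulate more filtered branches
  n <- 12
  txt <- paste0(paste(rep("(", n - 1), collapse = ""), "x1|S1",
                paste(sprintf(",x%d|S%d)", 2:n, 2:n), collapse = ""), ";")
  gt <- gene_tree(ape::read.tree(text = txt))
  ne <- tibble::tibble(node = gt$label[(gt$n_tip + 1):(2 * gt$n_tip - 1)],
                       event = "speciation", species = NA, age = NA,
                       donor = NA, recipient = NA)
  nb <- simulate_neighborhoods(gt, ne, window = 10, chg_pool = 200,
                               retention = c(speciation = 0.5,
                                             duplication = 0.5,
                                             transfer = 0.5))
  ret <- neighborhood_retention(gt, nb$leaf_chg_sets)
  ev <- tibble::tibble(node = ret$node, event = "speciation")
  # add a second class so the summary computes, then check the correlation
  rs <- suppressMessages(retention_by_event(ret, ev))
  expect_lt(rs$depth_cor$rho, 0)
})

test_that("type-I error of the reported set is controlled under the null", {
  set.seed(123)
  gt <- fix_balanced_gene(32)
  tips <- gt$phylo$tip.label
  n_reported <- 0L
  for (i in 1:40) {
    feats <- purrr::map_dfr(paste0("ch", 1:5), function(f) {
      tibble::tibble(focal = tips[stats::runif(32) < 0.3], feature = f)
    })
    if (!nrow(feats)) next
    sc <- clade_chg_scan(gt, feats, min_clade = 5, alpha = 1e-4,
                         focal_ids = tips)
    n_reported <- n_reported + sum(sc$reported)
  }
  expect_equal(n_reported, 0L)
})
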