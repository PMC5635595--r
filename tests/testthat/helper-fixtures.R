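# Shared fixture builders (all fixtures are constructed in code).

# 3-taxon chronogram ((A:1,B:1):1,C:2)
fix_species3 <- function() {
  dated_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
}

# caterpillar 4-taxon chronogram with internal ages 1, 2, 3
fix_caterpillar4 <- function() {
  dated_tree(ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);"))
}

fix_gene <- function(txt) gene_tree(ape::read.tree(text = txt))

# balanced gene tree over n leaves (n a power of 2), species "s" per leaf
fix_balanced_gene <- function(n, species_of = function(i) sprintf("S%d", i)) {
  lab <- vapply(seq_len(n), function(i) paste0("x", i, "|", species_of(i)),
                character(1))
  phy <- ape::stree(n, type = "balanced")
  phy$tip.label <- lab
  gene_tree(phy)
}

# write a temporary file with content, return path
tmpfile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# minimal hit tibble builder
mk_hits <- function(...) {
  rows <- list(...)
  at <- function(r, i, default) if (length(r) >= i) r[[i]] else default
  hit_table(purrr::map_dfr(rows, function(r) {
    tibble::tibble(query = r[[1]], subject = r[[2]],
                   pident = 50, length = as.integer(at(r, 5, 300)),
                   evalue = as.numeric(r[[3]]),
                   qlen = as.integer(at(r, 6, 400)),
                   slen = as.integer(at(r, 7, 400)),
                   coverage = as.numeric(r[[4]]))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
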