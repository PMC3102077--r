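# Independent brute-force oracles and random-instance generators used by the
# property-style tests. These deliberately avoid the package's own code paths
# (matrix membership, environment-hashed resolution) in favour of naive set
# arithmetic, so they can disagree with the implementation if either is wrong.

# Enumerate the Venn partition of named sets by direct set algebra: for every
# non-empty subset S of sources, count elements in all sets of S and in none
# of the others.
oracle_venn <- function(sets) {
  labels <- names(sets)
  k <- length(sets)
  out <- list()
  for (mask in seq_len(2^k - 1)) {
    members <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    inside <- Reduce(intersect, sets[members])
    outside <- unique(unlist(sets[!members], use.names = FALSE))
    out[[paste(labels[members], collapse = ";")]] <-
      length(setdiff(inside, outside))
  }
  out
}

# Per-element support via exhaustive membership checks.
oracle_support <- function(sets) {
  genes <- sort(unique(unlist(sets, use.names = FALSE)), method = "radix")
  lapply(stats::setNames(genes, genes), function(g) {
    names(sets)[vapply(sets, function(s) g %in% s, TRUE)]
  })
}

# Iterative fixed-point alias resolution (naive vector scans, no hashing).
oracle_resolve <- function(id, alias_map, max_iter = 1000) {
  cur <- id
  for (i in seq_len(max_iter)) {
    row <- which(alias_map$alias == cur)
    if (!length(row) || alias_map$status[row] != "merged") return(cur)
    cur <- alias_map$replacement[row]
  }
  stop("no fixed point")
}

# Random source sets over a small gene pool.
random_sets <- function(n_sources = 4, pool_size = 40, p = 0.4) {
  pool <- sprintf("G%d.1", seq_len(pool_size))
  sets <- lapply(seq_len(n_sources), function(i) {
    pool[stats::runif(pool_size) < p]
  })
  names(sets) <- paste0("src", seq_len(n_sources))
  sets
}

# Random acyclic alias map over a gene pool: merges always point to
# higher-numbered identifiers, so chains terminate by construction.
random_alias_map <- function(pool, p_merged = 0.15, p_removed = 0.05,
                             p_pseudo = 0.05) {
  rows <- list()
  n <- length(pool)
  for (i in seq_len(n)) {
    u <- stats::runif(1)
    if (u < p_merged && i < n) {
      target <- pool[sample((i + 1):n, 1)]
      rows[[length(rows) + 1]] <- data.frame(
        alias = pool[i], status = "merged", replacement = target,
        stringsAsFactors = FALSE)
    } else if (u < p_merged + p_removed) {
      rows[[length(rows) + 1]] <- data.frame(
        alias = pool[i], status = "removed", replacement = "",
        stringsAsFactors = FALSE)
    } else if (u < p_merged + p_removed + p_pseudo) {
      rows[[length(rows) + 1]] <- data.frame(
        alias = pool[i], status = "pseudogene", replacement = "",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(alias = character(), status = character(),
                      replacement = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Tiny in-memory source_table builder for tests that do not need files.
tiny_table <- function(label, genes, dialect = "ortholog_pair",
                       subject = "HS1.1") {
  a <- if (length(genes)) {
    data.frame(query_gene = genes, subject_gene = subject,
               relation = "one2one", score = NA_real_, stringsAsFactors = FALSE)
  } else {
    data.frame(query_gene = character(), subject_gene = character(),
               relation = character(), score = numeric(),
               stringsAsFactors = FALSE)
  }
  orthomeld:::.new_source_table(label, dialect, c("cel", "hsa"), a)
}
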