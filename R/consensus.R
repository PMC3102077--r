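# Consensus ortholog list: the union of the per-source predicted gene sets,
# with each gene carrying the exact set of sources supporting it. All derived
# statistics (Venn partition, support-level shares, inter-program congruence)
# work off a genes x sources logical membership matrix.

.new_consensus <- function(roster, membership, counterparts) {
  genes <- rownames(membership)
  support_count <- as.integer(rowSums(membership))
  sources <- apply(membership, 1, function(r) paste(roster[r], collapse = ";"))
  structure(list(
    roster = roster,
    membership = membership,
    entries = data.frame(gene = genes, support_count = support_count,
                         sources = unname(sources), stringsAsFactors = FALSE),
    counterparts = counterparts
  ), class = "ortho_consensus")
}

#' Build the consensus ortholog list
#'
#' One entry per distinct query gene found by at least one source, with the
#' set of supporting sources and the per-source subject-gene counterparts.
#' Inclusion by even a single program is deliberate: the union trades some
#' specificity for sensitivity. Entries are ordered lexicographically
#' (C collation) for byte-reproducible reports.
#'
#' @param tables list of `source_table` objects (labels must be unique).
#' @param alias_map optional alias map applied to every source's gene set.
#' @return an object of class `ortho_consensus` with elements `roster`,
#'   `membership` (logical genes x sources matrix), `entries` (data.frame
#'   gene / support_count / sources) and `counterparts` (data.frame
#'   gene / source / subject_gene).
#' @export
build_consensus <- function(tables, alias_map = NULL) {
  if (!length(tables)) {
    om_stop("orthomeld_config_error", "no source tables supplied")
  }
  stopifnot(all(vapply(tables, inherits, TRUE, "source_table")))
  roster <- vapply(tables, `[[`, "", "source")
  if (anyDuplicated(roster)) {
    om_stop("orthomeld_config_error", "duplicate source label %s",
            sQuote(roster[duplicated(roster)][1]))
  }
  taxa <- lapply(tables, `[[`, "taxa")
  if (length(unique(taxa)) > 1) {
    om_stop("orthomeld_config_error", "source tables do not share taxa")
  }
  sets <- lapply(tables, query_gene_set, alias_map = alias_map)
  names(sets) <- roster

  genes <- om_sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) genes %in% s,
                       logical(length(genes)))
  membership <- matrix(membership, nrow = length(genes),
                       dimnames = list(genes, roster))

  cp <- lapply(seq_along(tables), function(i) {
    a <- tables[[i]]$assertions
    if (!nrow(a)) return(NULL)
    data.frame(gene = a$query_gene, source = roster[i],
               subject_gene = a$subject_gene, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  cp <- do.call(rbind, c(cp, list(make.row.names = FALSE)))
  if (is.null(cp)) {
    cp <- data.frame(gene = character(), source = character(),
                     subject_gene = character(), stringsAsFactors = FALSE)
  } else {
    cp <- unique(cp[cp$gene %in% genes, ])
    cp <- cp[order(cp$gene, cp$source, cp$subject_gene, method = "radix"), ]
    rownames(cp) <- NULL
  }
  .new_consensus(roster, membership, cp)
}

#' Build a consensus object from named gene sets
#'
#' Convenience constructor for comparisons where the per-source prediction
#' files are not available but the per-source gene sets are (e.g. published
#' supplementary lists); counterpart information is empty.
#'
#' @param sets named list of character vectors (one per source).
#' @return an `ortho_consensus` object.
#' @export
consensus_from_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)),
            all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) om_sort(unique(normalize_id(s))))
  genes <- om_sort(unique(unlist(sets, use.names = FALSE)))
  membership <- matrix(vapply(sets, function(s) genes %in% s,
                              logical(length(genes))),
                       nrow = length(genes),
                       dimnames = list(genes, names(sets)))
  .new_consensus(names(sets), membership,
                 data.frame(gene = character(), source = character(),
                            subject_gene = character(), stringsAsFactors = FALSE))
}

#' @export
print.ortho_consensus <- function(x, ...) {
  cat(sprintf("<ortho_consensus> %d genes from %d sources (%s)\n",
              nrow(x$entries), length(x$roster),
              paste(x$roster, collapse = ", ")))
  invisible(x)
}

#' Per-gene support sets
#'
#' @param consensus an `ortho_consensus` object.
#' @return named list: gene -> character vector of supporting source labels.
#' @export
support_sets <- function(consensus) {
  stopifnot(inherits(consensus, "ortho_consensus"))
  m <- consensus$membership
  lapply(stats::setNames(seq_len(nrow(m)), rownames(m)),
         function(i) consensus$roster[m[i, ]])
}

#' Venn partition over the source roster
#'
#' Counts genes in each of the `2^k - 1` non-empty source subsets: each gene
#' falls in exactly the region equal to its support set. The sum over regions
#' equals the union size and per-source marginals equal the source set sizes;
#' both identities are asserted on every call.
#'
#' @param consensus an `ortho_consensus` object.
#' @return object of class `venn_partition`: data.frame with columns
#'   `sources` (semicolon-joined region label), `n_sources`, `count`.
#' @export
venn_partition <- function(consensus) {
  stopifnot(inherits(consensus, "ortho_consensus"))
  if (!nrow(consensus$entries)) {
    om_stop("orthomeld_config_error", "empty consensus")
  }
  roster <- consensus$roster
  k <- length(roster)
  masks <- seq_len(2^k - 1)
  bit <- function(mask) as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
  labels <- vapply(masks, function(m) paste(roster[bit(m)], collapse = ";"), "")
  sizes <- vapply(masks, function(m) sum(bit(m)), 1L)

  sig <- apply(consensus$membership, 1, function(r) paste(roster[r], collapse = ";"))
  counts <- as.integer(table(factor(sig, levels = labels)))

  out <- data.frame(sources = labels, n_sources = sizes, count = counts,
                    stringsAsFactors = FALSE)
  # conservation identities
  stopifnot(sum(out$count) == nrow(consensus$entries))
  for (i in seq_len(k)) {
    marginal <- sum(out$count[vapply(masks, function(m) bit(m)[i], TRUE)])
    stopifnot(marginal == sum(consensus$membership[, i]))
  }
  class(out) <- c("venn_partition", "data.frame")
  out
}

#' Share of genes at a given support level
#'
#' Fraction of the consensus supported by exactly `level` sources (e.g. the
#' found-by-all-four class of a four-program roster).
#'
#' @param consensus an `ortho_consensus` object.
#' @param level integer in `1..k` where `k` is the roster size.
#' @return list with `count`, `union_size`, `fraction`, `percent` (integer,
#'   ties away from zero) and `percent_1dp`.
#' @export
support_share <- function(consensus, level) {
  stopifnot(inherits(consensus, "ortho_consensus"))
  k <- length(consensus$roster)
  if (!is.numeric(level) || length(level) != 1 || level < 1 || level > k) {
    om_stop("orthomeld_domain_error",
            "support level %s out of range 1..%d", format(level), k)
  }
  n <- nrow(consensus$entries)
  count <- sum(consensus$entries$support_count == as.integer(level))
  frac <- count / n
  c(list(count = count, union_size = n, fraction = frac), percent_pair(frac))
}

#' Inter-program congruence statistics
#'
#' For each source P: its total prediction count, the count unique to P, and
#' the fraction of P's predictions found by at least one other source. The
#' pairwise table gives `|P intersect Q| / |P|` (rows P, columns Q), so the
#' matrix is asymmetric for sources of different size.
#'
#' @param consensus an `ortho_consensus` object built from >= 2 sources.
#' @return object of class `congruence_matrix`: list with `per_source`
#'   data.frame (source / total / unique / found_by_other_count /
#'   found_by_other_fraction) and `pairwise` numeric matrix. Fractions for an
#'   empty source are `NA` (undefined), not 0.
#' @export
congruence <- function(consensus) {
  stopifnot(inherits(consensus, "ortho_consensus"))
  roster <- consensus$roster
  if (length(roster) < 2) {
    om_stop("orthomeld_config_error", "congruence needs at least two sources")
  }
  m <- consensus$membership
  support_n <- rowSums(m)
  total <- colSums(m)
  uniq <- vapply(seq_along(roster), function(i) sum(m[, i] & support_n == 1), 1L)
  shared <- vapply(seq_along(roster), function(i) sum(m[, i] & support_n >= 2), 1L)
  frac <- ifelse(total > 0, shared / total, NA_real_)

  pairwise <- matrix(NA_real_, length(roster), length(roster),
                     dimnames = list(roster, roster))
  for (i in seq_along(roster)) {
    if (total[i] == 0) next
    for (j in seq_along(roster)) {
      pairwise[i, j] <- sum(m[, i] & m[, j]) / total[i]
    }
  }
  per_source <- data.frame(source = roster, total = as.integer(total),
                           unique = uniq, found_by_other_count = shared,
                           found_by_other_fraction = unname(frac),
                           stringsAsFactors = FALSE)
  stopifnot(all(per_source$unique + per_source$found_by_other_count ==
                  per_source$total))
  structure(list(per_source = per_source, pairwise = pairwise),
            class = "congruence_matrix")
}

#' @export
print.congruence_matrix <- function(x, ...) {
  cat("<congruence_matrix>\n")
  print(x$per_source)
  invisible(x)
}

#' Write a consensus list as TSV
#'
#' Columns: `gene`, `support_count`, `sources` (semicolon-joined) and
#' `counterparts` (`source=id,id;...`).
#'
#' @param consensus an `ortho_consensus` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_consensus <- function(consensus, path) {
  stopifnot(inherits(consensus, "ortho_consensus"))
  df <- consensus$entries
  cp <- consensus$counterparts
  if (nrow(cp)) {
    per <- vapply(split(cp, cp$gene), function(g) {
      paste(vapply(split(g, g$source), function(s) {
        sprintf("%s=%s", s$source[1], paste(om_sort(unique(s$subject_gene)),
                                            collapse = ","))
      }, ""), collapse = ";")
    }, "")
    df$counterparts <- unname(per[df$gene])
    df$counterparts[is.na(df$counterparts)] <- ""
  } else {
    df$counterparts <- ""
  }
  om_write_tsv(df, path)
}

#' Read back a consensus TSV written by [write_consensus()]
#'
#' Counterpart details are not reconstructed; membership is.
#'
#' @param path TSV path.
#' @return an `ortho_consensus` object.
#' @export
read_consensus <- function(path) {
  df <- om_read_tsv(path, c("gene", "support_count", "sources", "counterparts"))
  sets <- list()
  for (i in seq_len(nrow(df))) {
    for (s in strsplit(df$sources[i], ";", fixed = TRUE)[[1]]) {
      sets[[s]] <- c(sets[[s]], df$gene[i])
    }
  }
  consensus_from_sets(sets)
}
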