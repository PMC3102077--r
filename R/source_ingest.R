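# Ingestion of ortholog predictions from four flat-file dialects into a uniform
# assertion model. The grammars are defined by this package (the historical
# database downloads they are modeled on are version-frozen and not
# reproducible); each dialect captures the shape of one program's output:
#   pairwise_cluster -- seed-ortholog clusters with in-paralog confidences
#   group_line       -- one orthologous group per line, taxon|id members
#   homology_group   -- long-format homology groups keyed by numeric taxon
#   ortholog_pair    -- per-pair calls with a homology type column

SOURCE_DIALECTS <- c("pairwise_cluster", "group_line", "homology_group",
                     "ortholog_pair")

RELATIONS <- c("seed_ortholog", "in_paralog", "group_member",
               "one2one", "one2many", "many2many")

.dialect_headers <- list(
  pairwise_cluster = c("cluster_id", "cluster_score", "taxon", "confidence",
                       "member_id"),
  homology_group = c("group_id", "taxon", "gene_id", "gene_symbol",
                     "protein_accession"),
  ortholog_pair = c("query_gene", "subject_gene", "homology_type")
)

.new_source_table <- function(source, dialect, taxa, assertions, n_collapsed = 0L) {
  assertions <- assertions[order(assertions$query_gene, assertions$subject_gene,
                                 assertions$relation, method = "radix"), ]
  rownames(assertions) <- NULL
  structure(list(
    source = source,
    dialect = dialect,
    taxa = taxa,
    assertions = assertions,
    query_genes = om_sort(unique(assertions$query_gene)),
    subject_genes = om_sort(unique(assertions$subject_gene)),
    n_collapsed = n_collapsed
  ), class = "source_table")
}

.empty_assertions <- function() {
  data.frame(query_gene = character(), subject_gene = character(),
             relation = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Parse an ortholog-prediction source file
#'
#' Reads one source's predictions in one of four dialects and returns a
#' uniform table of ortholog assertions. A query-species gene is asserted only
#' when its cluster/group/pair links it to at least one subject-species gene;
#' query identifiers are canonicalized with [normalize_id()], which collapses
#' isoform-level entries onto their gene (the collapse count is recorded).
#'
#' @param path file path (UTF-8, LF, `#` comments, header optional).
#' @param dialect one of `"pairwise_cluster"`, `"group_line"`,
#'   `"homology_group"`, `"ortholog_pair"`.
#' @param source source label; defaults to the file name without extension.
#' @param taxa length-2 character `(query, subject)` taxon codes. For
#'   `homology_group` these are numeric taxon ids (e.g. `c("6239","9606")`);
#'   for `group_line` they are the member prefixes (e.g. `c("cel","hsa")`);
#'   `pairwise_cluster` uses them to split cluster members; `ortholog_pair`
#'   is implicitly (query, subject) and ignores them.
#' @return an object of class `source_table` with elements `source`,
#'   `dialect`, `taxa`, `assertions` (data.frame query_gene / subject_gene /
#'   relation / score), `query_genes`, `subject_genes`, `n_collapsed`.
#' @export
parse_source <- function(path, dialect, source = NULL,
                         taxa = c("cel", "hsa")) {
  if (!dialect %in% SOURCE_DIALECTS) {
    om_stop("orthomeld_config_error", "unknown dialect %s (expected one of %s)",
            sQuote(dialect), paste(SOURCE_DIALECTS, collapse = ", "))
  }
  if (is.null(source)) source <- sub("\\.[^.]*$", "", basename(path))
  stopifnot(length(taxa) == 2)
  taxa <- as.character(taxa)

  raw <- switch(dialect,
    pairwise_cluster = .parse_pairwise_cluster(path, taxa),
    group_line = .parse_group_line(path, taxa),
    homology_group = .parse_homology_group(path, taxa),
    ortholog_pair = .parse_ortholog_pair(path))

  n_before <- nrow(raw)
  if (n_before) {
    raw$query_gene <- normalize_id(raw$query_gene)
    raw <- unique(raw)
  }
  .new_source_table(source, dialect, taxa, raw,
                    n_collapsed = n_before - nrow(raw))
}

.parse_pairwise_cluster <- function(path, taxa) {
  df <- om_read_tsv(path, .dialect_headers$pairwise_cluster)
  lineno <- attr(df, "line_numbers")
  conf <- suppressWarnings(as.numeric(df$confidence))
  bad <- which(is.na(conf))
  if (length(bad)) {
    om_stop("orthomeld_parse_error", "%s:%d: non-numeric confidence %s",
            path, lineno[bad[1]], sQuote(df$confidence[bad[1]]))
  }
  df$confidence <- conf
  out <- .empty_assertions()
  for (cl in split(df, factor(df$cluster_id, levels = unique(df$cluster_id)))) {
    q <- cl[cl$taxon == taxa[1] & cl$confidence > 0, ]
    s <- cl[cl$taxon == taxa[2] & cl$confidence > 0, ]
    if (!nrow(q) || !nrow(s)) next
    rel <- ifelse(q$confidence >= 1, "seed_ortholog", "in_paralog")
    out <- rbind(out, data.frame(
      query_gene = rep(q$member_id, each = nrow(s)),
      subject_gene = rep(s$member_id, times = nrow(q)),
      relation = rep(rel, each = nrow(s)),
      score = rep(q$confidence, each = nrow(s)),
      stringsAsFactors = FALSE))
  }
  out
}

.parse_group_line <- function(path, taxa) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  out <- .empty_assertions()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^(\\S+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3 || !nzchar(m[2])) {
      om_stop("orthomeld_parse_error",
              "%s:%d: expected 'GROUPID: taxon|id ...', got %s",
              path, lineno[i], sQuote(lines[i]))
    }
    members <- strsplit(trimws(m[3]), "\\s+")[[1]]
    parts <- strsplit(members, "|", fixed = TRUE)
    badm <- which(vapply(parts, length, 1L) != 2)
    if (length(badm)) {
      om_stop("orthomeld_parse_error", "%s:%d: malformed member %s",
              path, lineno[i], sQuote(members[badm[1]]))
    }
    tax <- vapply(parts, `[[`, "", 1)
    ids <- vapply(parts, `[[`, "", 2)
    q <- ids[tax == taxa[1]]
    s <- ids[tax == taxa[2]]
    if (!length(q) || !length(s)) next
    out <- rbind(out, data.frame(
      query_gene = rep(q, each = length(s)),
      subject_gene = rep(s, times = length(q)),
      relation = "group_member", score = NA_real_,
      stringsAsFactors = FALSE))
  }
  out
}

.parse_homology_group <- function(path, taxa) {
  df <- om_read_tsv(path, .dialect_headers$homology_group)
  out <- .empty_assertions()
  for (grp in split(df, factor(df$group_id, levels = unique(df$group_id)))) {
    q <- grp$gene_id[grp$taxon == taxa[1]]
    s <- grp$gene_id[grp$taxon == taxa[2]]
    if (!length(q) || !length(s)) next
    out <- rbind(out, data.frame(
      query_gene = rep(q, each = length(s)),
      subject_gene = rep(s, times = length(q)),
      relation = "group_member", score = NA_real_,
      stringsAsFactors = FALSE))
  }
  out
}

.parse_ortholog_pair <- function(path) {
  df <- om_read_tsv(path, .dialect_headers$ortholog_pair)
  if (!nrow(df)) return(.empty_assertions())
  rel <- rep(NA_character_, nrow(df))
  type <- tolower(df$homology_type)
  rel[grepl("one2one", type)] <- "one2one"
  rel[grepl("one2many", type)] <- "one2many"
  rel[grepl("many2many", type)] <- "many2many"
  if (anyNA(rel)) {
    om_warn("orthomeld_unknown_relation",
            "unknown homology type %s mapped to many2many",
            sQuote(df$homology_type[is.na(rel)][1]))
    rel[is.na(rel)] <- "many2many"
  }
  data.frame(query_gene = df$query_gene, subject_gene = df$subject_gene,
             relation = rel, score = NA_real_, stringsAsFactors = FALSE)
}

#' Predicted query-species gene set of one source
#'
#' Distinct, canonical, alias-updated query genes asserted by the source
#' (seed orthologs and in-paralogs alike). Duplicates and isoforms collapse
#' under set semantics; removed/pseudogene identifiers drop out.
#'
#' @param table a `source_table` from [parse_source()].
#' @param alias_map optional alias map (see [read_alias_map()]).
#' @return character vector of gene identifiers, C-locale sorted.
#' @export
query_gene_set <- function(table, alias_map = NULL) {
  stopifnot(inherits(table, "source_table"))
  if (!length(table$query_genes)) return(character())
  om_sort(unique(update_gene_set(table$query_genes, alias_map)$kept))
}

#' @export
print.source_table <- function(x, ...) {
  cat(sprintf("<source_table> %s [%s]: %d assertions, %d query genes, %d subject genes\n",
              x$source, x$dialect, nrow(x$assertions),
              length(x$query_genes), length(x$subject_genes)))
  invisible(x)
}

# ---- dialect writers (used by the simulator and the pipeline) ---------------

#' Write ortholog assertions in a source dialect
#'
#' Inverse of [parse_source()] up to canonical ordering: emitting a
#' `source_table` and re-parsing it reproduces the assertion multiset.
#'
#' @param table a `source_table`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_source <- function(table, path) {
  stopifnot(inherits(table, "source_table"))
  a <- table$assertions
  taxa <- table$taxa
  switch(table$dialect,
    pairwise_cluster = {
      lines <- paste(.dialect_headers$pairwise_cluster, collapse = "\t")
      cid <- 0L
      for (q in split(a, a$query_gene)) {
        # one cluster per query gene: the query member plus its subjects
        cid <- cid + 1L
        conf <- q$score[1]
        if (is.na(conf)) conf <- 1
        lines <- c(lines,
          sprintf("C%d\t%s\t%s\t%s\t%s", cid, "1.000", taxa[1],
                  format(conf, trim = TRUE), q$query_gene[1]),
          sprintf("C%d\t%s\t%s\t%s\t%s", cid, "1.000", taxa[2], "1",
                  om_sort(unique(q$subject_gene))))
      }
      writeLines(lines, path)
    },
    group_line = {
      grp <- split(a, a$query_gene)
      lines <- vapply(seq_along(grp), function(i) {
        g <- grp[[i]]
        sprintf("OG_%s: %s|%s %s", names(grp)[i], taxa[1], g$query_gene[1],
                paste(sprintf("%s|%s", taxa[2], om_sort(unique(g$subject_gene))),
                      collapse = " "))
      }, "")
      writeLines(lines, path)
    },
    homology_group = {
      grp <- split(a, a$query_gene)
      lines <- paste(.dialect_headers$homology_group, collapse = "\t")
      for (i in seq_along(grp)) {
        g <- grp[[i]]
        qg <- g$query_gene[1]
        lines <- c(lines,
          sprintf("HG_%s\t%s\t%s\t%s\t%s", qg, taxa[1], qg, qg,
                  paste0(qg, "p")),
          sprintf("HG_%s\t%s\t%s\t%s\t%s", qg, taxa[2],
                  om_sort(unique(g$subject_gene)),
                  om_sort(unique(g$subject_gene)),
                  paste0(om_sort(unique(g$subject_gene)), "p")))
      }
      writeLines(lines, path)
    },
    ortholog_pair = {
      rel <- a$relation
      rel[!rel %in% c("one2one", "one2many", "many2many")] <- "many2many"
      lines <- c(paste(.dialect_headers$ortholog_pair, collapse = "\t"),
                 sprintf("%s\t%s\tortholog_%s", a$query_gene, a$subject_gene, rel))
      writeLines(lines, path)
    },
    om_stop("orthomeld_config_error", "unknown dialect %s", table$dialect))
  invisible(path)
}
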