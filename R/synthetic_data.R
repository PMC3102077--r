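# Two-genome ortholog simulation: families related by speciation with
# post-speciation duplications (in-paralogs) and species-specific families,
# observed through several imperfect predictors with per-source miss and
# spurious-call probabilities. Everything downstream (ingestion, consensus,
# harmonization, family evaluation, screen coverage) is testable against the
# known ground truth without any external download.

#' Default simulated source roster
#'
#' Four predictors, one per dialect, with miss/spurious probabilities chosen
#' to mirror the qualitative behaviour of the programs they emulate: the
#' homology-group source is the most conservative (high miss, few spurious
#' calls), the ortholog-pair source is the most sensitive and least specific.
#'
#' @return data.frame with columns label, dialect, miss_prob, spurious_prob.
#' @export
default_roster <- function() {
  data.frame(
    label = c("inparanoid", "orthomcl", "homologene", "compara"),
    dialect = c("pairwise_cluster", "group_line", "homology_group",
                "ortholog_pair"),
    miss_prob = c(0.10, 0.08, 0.20, 0.05),
    spurious_prob = c(0.02, 0.03, 0.005, 0.06),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param n_families number of ancestral gene families.
#' @param p_dup_query,p_dup_subject probability that a family carries a
#'   post-speciation duplication (an in-paralog) in the query / subject genome.
#' @param p_query_specific,p_subject_specific probability that a family is
#'   species-specific (present in only one genome, hence not conserved).
#' @param sources roster data.frame (label, dialect, miss_prob, spurious_prob).
#' @param alias_noise named numeric: per-gene probabilities of carrying a
#'   `merged` historical alias, and rates of decoy `removed` / `pseudogene`
#'   entries in the alias map.
#' @param seed integer random seed (mandatory; single stream per run).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_families = 2000,
                       p_dup_query = 0.15, p_dup_subject = 0.20,
                       p_query_specific = 0.35, p_subject_specific = 0.25,
                       sources = default_roster(),
                       alias_noise = c(merged = 0.02, removed = 0.01,
                                       pseudogene = 0.01),
                       seed) {
  if (missing(seed) || is.null(seed)) {
    om_stop("orthomeld_config_error", "a seed is mandatory")
  }
  probs <- c(p_dup_query, p_dup_subject, p_query_specific, p_subject_specific,
             sources$miss_prob, sources$spurious_prob, alias_noise)
  if (any(probs < 0 | probs > 1)) {
    om_stop("orthomeld_config_error", "all probabilities must be in [0, 1]")
  }
  if (p_query_specific + p_subject_specific > 1) {
    om_stop("orthomeld_config_error",
            "species-specific probabilities sum to more than 1")
  }
  stopifnot(all(c("label", "dialect", "miss_prob", "spurious_prob") %in%
                  names(sources)),
            all(sources$dialect %in% SOURCE_DIALECTS),
            !anyDuplicated(sources$label))
  structure(list(n_families = n_families,
                 p_dup_query = p_dup_query, p_dup_subject = p_dup_subject,
                 p_query_specific = p_query_specific,
                 p_subject_specific = p_subject_specific,
                 sources = sources, alias_noise = alias_noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate ground-truth orthology and noisy predictions
#'
#' Families are conserved (present in both genomes), query-specific or
#' subject-specific; conserved families may carry in-paralogs on either side.
#' Each source misses a conserved query gene independently with its
#' `miss_prob` and calls a non-conserved query gene spuriously with its
#' `spurious_prob` (spurious calls are drawn only from genuinely
#' non-conserved genes, keeping sensitivity/precision definitions clean).
#' Fully reproducible from the seed.
#'
#' @param config a [sim_config()].
#' @return object of class `ground_truth`: list with `config`, `genes`
#'   (data.frame gene / species / family / conserved), `tables` (named list of
#'   `source_table`), `alias_map`, `annotations`, `gold`, `screen_hits`.
#' @export
simulate_orthology <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nf <- config$n_families
  type <- sample(c("conserved", "query_only", "subject_only"), nf,
                 replace = TRUE,
                 prob = c(1 - config$p_query_specific - config$p_subject_specific,
                          config$p_query_specific, config$p_subject_specific))

  q_genes <- vector("list", nf)
  s_genes <- vector("list", nf)
  has_q <- type != "subject_only"
  has_s <- type != "query_only"
  n_q <- ifelse(has_q, 1L + stats::rbinom(nf, 1L, config$p_dup_query), 0L)
  n_s <- ifelse(has_s, 1L + stats::rbinom(nf, 1L, config$p_dup_subject), 0L)
  for (f in seq_len(nf)) {
    if (n_q[f]) q_genes[[f]] <- sprintf("Q%d.%d", f, seq_len(n_q[f]))
    if (n_s[f]) s_genes[[f]] <- sprintf("HS%d.%d", f, seq_len(n_s[f]))
  }

  genes <- rbind(
    data.frame(gene = unlist(q_genes), species = "query",
               family = rep(seq_len(nf), lengths(q_genes)),
               conserved = rep(type == "conserved", lengths(q_genes)),
               stringsAsFactors = FALSE),
    data.frame(gene = unlist(s_genes), species = "subject",
               family = rep(seq_len(nf), lengths(s_genes)),
               conserved = rep(type == "conserved", lengths(s_genes)),
               stringsAsFactors = FALSE))

  qdf <- genes[genes$species == "query", ]
  conserved_q <- qdf$gene[qdf$conserved]
  nonconserved_q <- qdf$gene[!qdf$conserved]
  all_subject <- genes$gene[genes$species == "subject"]

  tables <- list()
  for (i in seq_len(nrow(config$sources))) {
    src <- config$sources[i, ]
    miss <- stats::runif(length(conserved_q)) < src$miss_prob
    kept <- conserved_q[!miss]
    spur <- nonconserved_q[stats::runif(length(nonconserved_q)) <
                             src$spurious_prob]
    asrt <- .truth_assertions(kept, spur, qdf, s_genes, all_subject,
                              src$dialect)
    tables[[src$label]] <- .new_source_table(src$label, src$dialect,
                                             c("cel", "hsa"), asrt)
  }

  # alias map: historical merged names for some query genes, plus decoy
  # removed/pseudogene identifiers that only ever appear in hit lists
  merged_for <- qdf$gene[stats::runif(nrow(qdf)) < config$alias_noise["merged"]]
  n_rm <- stats::rbinom(1, nrow(qdf), config$alias_noise["removed"])
  n_ps <- stats::rbinom(1, nrow(qdf), config$alias_noise["pseudogene"])
  alias_map <- rbind(
    if (length(merged_for))
      data.frame(alias = sprintf("OLD%d.1", seq_along(merged_for)),
                 status = "merged", replacement = merged_for,
                 stringsAsFactors = FALSE),
    if (n_rm) data.frame(alias = sprintf("DEAD%d.1", seq_len(n_rm)),
                         status = "removed", replacement = "",
                         stringsAsFactors = FALSE),
    if (n_ps) data.frame(alias = sprintf("PSG%d.1", seq_len(n_ps)),
                         status = "pseudogene", replacement = "",
                         stringsAsFactors = FALSE))
  if (is.null(alias_map)) {
    alias_map <- data.frame(alias = character(), status = character(),
                            replacement = character(), stringsAsFactors = FALSE)
  }

  annotations <- data.frame(
    gene = qdf$gene,
    term_id = sprintf("IPR%06d", qdf$family),
    namespace = "interpro",
    term_name = sprintf("family %d domain", qdf$family),
    stringsAsFactors = FALSE)

  gold <- data.frame(gene = om_sort(conserved_q), family = "conserved",
                     note = "true conserved query gene",
                     stringsAsFactors = FALSE)

  # screen hit list: sample of query genes; labels mostly track the truth;
  # genes with a historical alias are listed under the old name to exercise
  # the gene-model update path
  hit_idx <- stats::runif(nrow(qdf)) < 0.10
  hits <- qdf[hit_idx, c("gene", "conserved")]
  names(hits)[2] <- "prior_conserved"
  flip <- stats::runif(nrow(hits)) < 0.05
  hits$prior_conserved <- xor(hits$prior_conserved, flip)
  old_of <- stats::setNames(alias_map$alias[alias_map$status == "merged"],
                            alias_map$replacement[alias_map$status == "merged"])
  has_old <- hits$gene %in% names(old_of)
  hits$gene[has_old] <- unname(old_of[hits$gene[has_old]])
  rownames(hits) <- NULL

  structure(list(config = config, genes = genes, tables = tables,
                 alias_map = alias_map, annotations = annotations,
                 gold = gold, screen_hits = hits),
            class = "ground_truth")
}

# Build the assertion table of one simulated source: kept conserved genes pair
# with every subject gene of their family; spurious genes pair with one random
# subject gene. Relation/score depend on the dialect the file will be written in.
.truth_assertions <- function(kept, spurious, qdf, s_genes, all_subject,
                              dialect) {
  fam_of <- stats::setNames(qdf$family, qdf$gene)
  idx_of <- stats::setNames(as.integer(sub("^Q\\d+\\.", "", qdf$gene)),
                            qdf$gene)
  rows <- list()
  for (g in kept) {
    subj <- s_genes[[fam_of[[g]]]]
    if (is.null(subj)) next
    if (dialect == "pairwise_cluster") {
      seed_gene <- idx_of[[g]] == 1L
      rel <- if (seed_gene) "seed_ortholog" else "in_paralog"
      score <- if (seed_gene) 1 else 0.5
    } else if (dialect == "ortholog_pair") {
      nq <- sum(fam_of[kept] == fam_of[[g]])
      rel <- if (nq == 1 && length(subj) == 1) "one2one"
             else if (nq == 1) "one2many" else "many2many"
      score <- NA_real_
    } else {
      rel <- "group_member"; score <- NA_real_
    }
    rows[[g]] <- data.frame(query_gene = g, subject_gene = subj,
                            relation = rel, score = score,
                            stringsAsFactors = FALSE)
  }
  if (length(spurious)) {
    partner <- sample(all_subject, length(spurious), replace = TRUE)
    rel <- switch(dialect, pairwise_cluster = "seed_ortholog",
                  ortholog_pair = "one2one", "group_member")
    score <- if (dialect == "pairwise_cluster") 1 else NA_real_
    rows[["..spurious"]] <- data.frame(query_gene = spurious,
                                       subject_gene = partner,
                                       relation = rel, score = score,
                                       stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.empty_assertions())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Emit a ground truth as flat files
#'
#' Writes the per-source prediction files in their dialects, plus the alias
#' map, annotation table, gold compendium and screen hit list, and a manifest
#' listing every emitted file with its MD5 checksum. Round-tripping a source
#' file through [parse_source()] reproduces the per-source gene sets.
#'
#' @param truth a `ground_truth` from [simulate_orthology()].
#' @param dir output directory (created if needed).
#' @return data.frame manifest (file, md5, bytes), invisibly; also written to
#'   `manifest.tsv`.
#' @export
emit_source_files <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    om_stop("orthomeld_io_error", "cannot create directory %s", dir)
  }
  paths <- character()
  for (tab in truth$tables) {
    p <- file.path(dir, paste0(tab$source, ".tsv"))
    write_source(tab, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "alias_map.tsv")
  om_write_tsv(truth$alias_map, p); paths <- c(paths, p)
  p <- file.path(dir, "annotations.tsv")
  om_write_tsv(truth$annotations, p); paths <- c(paths, p)
  p <- file.path(dir, "gold.tsv")
  om_write_tsv(truth$gold, p); paths <- c(paths, p)
  p <- file.path(dir, "screen_hits.tsv")
  om_write_tsv(data.frame(gene = truth$screen_hits$gene,
                          prior_conserved = as.integer(truth$screen_hits$prior_conserved)),
               p); paths <- c(paths, p)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         bytes = file.size(paths),
                         stringsAsFactors = FALSE)
  om_write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Recovery statistics of predictions against the simulated truth
#'
#' Sensitivity (`|predicted & true conserved| / |true conserved|`) and
#' precision (`|predicted & true conserved| / |predicted|`) for every source,
#' for their union (the consensus) and for their intersection. The union can
#' only gain sensitivity over any single source; the intersection can only
#' gain precision in expectation.
#'
#' @param truth a `ground_truth`.
#' @param consensus consensus built from the truth's sources (object or
#'   character vector); defaults to the union of the truth's source sets.
#' @return data.frame with columns set, n_predicted, n_true_positive,
#'   sensitivity, precision.
#' @export
recovery_stats <- function(truth, consensus = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  true_pos <- truth$genes$gene[truth$genes$species == "query" &
                                 truth$genes$conserved]
  sets <- lapply(truth$tables, `[[`, "query_genes")
  union_set <- if (is.null(consensus)) unique(unlist(sets, use.names = FALSE))
               else consensus_genes(consensus)
  inter_set <- Reduce(intersect, sets)
  sets <- c(sets, list(union = union_set, intersection = inter_set))
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    tp <- length(intersect(s, true_pos))
    data.frame(set = nm, n_predicted = length(s), n_true_positive = tp,
               sensitivity = tp / length(true_pos),
               precision = if (length(s)) tp / length(s) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
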