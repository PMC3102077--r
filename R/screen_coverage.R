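# RNAi-screen coverage: update hit identifiers to current gene models, apply
# orthology reclassification ledgers (RBH/TreeFam adjudications recorded as
# auditable gain/lose decisions, never recomputed), and measure how much of
# the conserved hit set a consensus list would have recovered.

#' Read an RNAi screen hit list
#'
#' TSV columns `gene  prior_conserved` with `prior_conserved` in 0/1 (the
#' original publication's homology call).
#'
#' @param path file path.
#' @return data.frame with columns gene (normalized), prior_conserved (logical).
#' @export
read_screen_hits <- function(path) {
  df <- om_read_tsv(path, c("gene", "prior_conserved"))
  data.frame(gene = normalize_id(df$gene),
             prior_conserved = df$prior_conserved %in% c("1", "TRUE", "true"),
             stringsAsFactors = FALSE)
}

#' Read a reclassification ledger
#'
#' TSV columns `gene  decision  evidence` with decision `gain` or `lose`.
#'
#' @param path file path.
#' @return data.frame ledger.
#' @export
read_reclassification_ledger <- function(path) {
  df <- om_read_tsv(path, c("gene", "decision", "evidence"))
  if (nrow(df)) df$gene <- normalize_id(df$gene)
  df
}

#' Update screen hits to current gene models
#'
#' Applies [update_gene_set()] to the hit identifiers and carries the
#' prior-homology flags through renames; hits dropped as removed/pseudogene or
#' duplicate merges disappear. A merged hit renamed onto a gene absent from
#' the hit list stays a positive under its new name.
#'
#' @param hits data.frame with columns gene, prior_conserved.
#' @param alias_map alias map (see [read_alias_map()]).
#' @return list with `hits` (updated data.frame, unique genes) and `report`
#'   (the `update_report`).
#' @export
update_screen_hits <- function(hits, alias_map = NULL) {
  stopifnot(all(c("gene", "prior_conserved") %in% names(hits)))
  rep <- update_gene_set(hits$gene, alias_map)
  flag <- stats::setNames(hits$prior_conserved, normalize_id(hits$gene))
  kept_flag <- stats::setNames(unname(flag[rep$kept]), rep$kept)
  # renamed survivors inherit the flag of the pre-merge identifier
  if (nrow(rep$renamed)) {
    kept_flag[rep$renamed$new] <- unname(flag[rep$renamed$old])
  }
  out <- data.frame(gene = rep$kept,
                    prior_conserved = unname(kept_flag),
                    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(out$gene), !anyNA(out$prior_conserved))
  list(hits = out, report = rep)
}

#' Apply a reclassification ledger to screen hits
#'
#' The conserved set is the prior-conserved hits plus ledger gains minus
#' ledger losses. Ledger consistency is enforced: one entry per gene, `gain`
#' only on hits not previously called conserved, `lose` only on hits that
#' were; violations raise a ledger-conflict error naming the gene. The
#' arithmetic identity `|result| = prior + gains - losses` is asserted.
#'
#' @param hits data.frame with columns gene, prior_conserved (already updated
#'   via [update_screen_hits()], genes unique).
#' @param ledger data.frame with columns gene, decision (`gain`/`lose`),
#'   evidence; may be empty / NULL.
#' @return character vector of conserved genes (sorted), with attribute
#'   `tally` (list prior / gains / losses / final).
#' @export
reclassify <- function(hits, ledger = NULL) {
  stopifnot(all(c("gene", "prior_conserved") %in% names(hits)))
  if (anyDuplicated(hits$gene)) {
    om_stop("orthomeld_config_error", "duplicate hit gene %s",
            hits$gene[duplicated(hits$gene)][1])
  }
  if (is.null(ledger)) {
    ledger <- data.frame(gene = character(), decision = character(),
                         evidence = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "decision") %in% names(ledger)))
  if (anyDuplicated(ledger$gene)) {
    om_stop("orthomeld_ledger_conflict", "multiple ledger entries for %s",
            ledger$gene[duplicated(ledger$gene)][1])
  }
  bad <- !ledger$decision %in% c("gain", "lose")
  if (any(bad)) {
    om_stop("orthomeld_ledger_conflict", "unknown decision %s for %s",
            sQuote(ledger$decision[bad][1]), ledger$gene[bad][1])
  }
  prior <- stats::setNames(hits$prior_conserved, hits$gene)
  absent <- setdiff(ledger$gene, hits$gene)
  if (length(absent)) {
    om_stop("orthomeld_ledger_conflict",
            "ledger gene %s is not a screen hit", sQuote(absent[1]))
  }
  gains <- ledger$gene[ledger$decision == "gain"]
  losses <- ledger$gene[ledger$decision == "lose"]
  if (any(prior[gains])) {
    om_stop("orthomeld_ledger_conflict",
            "gain entry for %s, already classified as conserved",
            gains[prior[gains]][1])
  }
  if (any(!prior[losses])) {
    om_stop("orthomeld_ledger_conflict",
            "lose entry for %s, not previously classified as conserved",
            losses[!prior[losses]][1])
  }
  conserved <- om_sort(union(setdiff(hits$gene[hits$prior_conserved], losses),
                             gains))
  stopifnot(length(conserved) ==
              sum(hits$prior_conserved) + length(gains) - length(losses))
  attr(conserved, "tally") <- list(prior = sum(hits$prior_conserved),
                                   gains = length(gains),
                                   losses = length(losses),
                                   final = length(conserved))
  conserved
}

#' Consensus coverage of a conserved hit set
#'
#' What fraction of a screen's conserved hits the consensus list contains,
#' and (optionally) what fraction of the screen-targetable gene set the
#' consensus represents -- the screening-effort savings. Both the original
#' screen size and the targetable-set size can be supplied, since published
#' effort figures differ in which denominator they use; when both are given
#' both fractions are reported.
#'
#' @param conserved character vector of conserved hit genes (non-empty).
#' @param consensus an `ortho_consensus` object or character gene vector.
#' @param targetable optional character vector: all genes targetable by the
#'   screen's library/method.
#' @param screen_size optional count of genes originally targeted.
#' @return object of class `coverage_summary`: list with `conserved_final`,
#'   `conserved_in_consensus`, `coverage_fraction`, `coverage_percent`,
#'   `coverage_percent_1dp`, `effort_fraction_targetable`,
#'   `effort_fraction_screen`.
#' @export
coverage_summary <- function(conserved, consensus, targetable = NULL,
                             screen_size = NULL) {
  conserved <- unique(as.character(conserved))
  if (!length(conserved)) {
    om_stop("orthomeld_domain_error",
            "empty conserved hit set: coverage is undefined")
  }
  genes <- consensus_genes(consensus)
  hit <- length(intersect(conserved, genes))
  frac <- hit / length(conserved)
  pp <- percent_pair(frac)
  effort_t <- effort_s <- NA_real_
  if (!is.null(targetable)) {
    targetable <- unique(as.character(targetable))
    inter <- length(intersect(genes, targetable))
    effort_t <- inter / length(targetable)
    if (!is.null(screen_size)) effort_s <- inter / screen_size
  } else if (!is.null(screen_size)) {
    effort_s <- length(genes) / screen_size
  }
  out <- structure(list(
    conserved_final = length(conserved),
    conserved_in_consensus = hit,
    coverage_fraction = frac,
    coverage_percent = pp$percent,
    coverage_percent_1dp = pp$percent_1dp,
    effort_fraction_targetable = effort_t,
    effort_fraction_screen = effort_s
  ), class = "coverage_summary")
  stopifnot(out$conserved_in_consensus <= out$conserved_final)
  out
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("<coverage_summary> %d/%d conserved hits in consensus (%s%%, %s at one decimal)\n",
              x$conserved_in_consensus, x$conserved_final,
              format(x$coverage_percent), format(x$coverage_percent_1dp)))
  invisible(x)
}

#' Clone-library coverage of a consensus list
#'
#' A consensus gene is "represented" if at least one library clone maps to it;
#' clones flagged `incorrect` or mapping to `pseudogene` entries still count
#' as representation but are reported in separate sub-counts for follow-up.
#'
#' @param consensus an `ortho_consensus` object or character gene vector.
#' @param clone_map data.frame with columns clone_id, gene, status
#'   (`ok` / `incorrect` / `pseudogene`).
#' @return list with `represented` (count), `consensus_size`, `fraction`,
#'   `percent`, `percent_1dp`, `flagged_pseudogene`, `flagged_incorrect`
#'   (gene counts among represented genes).
#' @export
library_coverage <- function(consensus, clone_map) {
  stopifnot(all(c("clone_id", "gene", "status") %in% names(clone_map)))
  bad <- !clone_map$status %in% c("ok", "incorrect", "pseudogene")
  if (any(bad)) {
    om_stop("orthomeld_config_error", "unknown clone status %s",
            sQuote(clone_map$status[bad][1]))
  }
  genes <- consensus_genes(consensus)
  if (nrow(clone_map)) clone_map$gene <- normalize_id(clone_map$gene)
  hit <- clone_map[clone_map$gene %in% genes, , drop = FALSE]
  represented <- unique(hit$gene)
  frac <- length(represented) / length(genes)
  pp <- percent_pair(frac)
  list(represented = length(represented),
       consensus_size = length(genes),
       fraction = frac, percent = pp$percent, percent_1dp = pp$percent_1dp,
       flagged_pseudogene = length(unique(hit$gene[hit$status == "pseudogene"])),
       flagged_incorrect = length(unique(hit$gene[hit$status == "incorrect"])))
}

#' Read a clone-to-gene library map
#'
#' TSV columns `clone_id  gene  status`.
#'
#' @param path file path.
#' @return data.frame clone map.
#' @export
read_clone_map <- function(path) {
  om_read_tsv(path, c("clone_id", "gene", "status"))
}
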