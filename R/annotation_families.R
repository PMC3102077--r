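# Annotation attachment (InterPro domains, GO terms), pivot reports,
# term-rule gene-family extraction with auditable manual-correction ledgers,
# evaluation against gold-standard family compendia, and pathway-component
# membership reporting.

ANNOTATION_NAMESPACES <- c("interpro", "go_bp", "go_cc", "go_mf")

#' Read a gene-annotation table
#'
#' TSV columns `gene  term_id  namespace  term_name` with namespace one of
#' `interpro`, `go_bp`, `go_cc`, `go_mf`. (gene, term_id) pairs are unique
#' within a namespace; duplicates collapse silently.
#'
#' @param path file path.
#' @return data.frame of annotation records.
#' @export
read_annotations <- function(path) {
  df <- om_read_tsv(path, c("gene", "term_id", "namespace", "term_name"))
  validate_annotations(df)
}

#' Validate annotation records
#' @param annotations data.frame with columns gene, term_id, namespace, term_name.
#' @return the validated (deduplicated, normalized) data.frame.
#' @export
validate_annotations <- function(annotations) {
  stopifnot(all(c("gene", "term_id", "namespace") %in% names(annotations)))
  if (!"term_name" %in% names(annotations)) annotations$term_name <- ""
  bad <- !annotations$namespace %in% ANNOTATION_NAMESPACES
  if (any(bad)) {
    om_stop("orthomeld_config_error", "unknown annotation namespace %s",
            sQuote(annotations$namespace[bad][1]))
  }
  if (nrow(annotations)) annotations$gene <- normalize_id(annotations$gene)
  annotations <- annotations[!duplicated(annotations[c("gene", "term_id",
                                                       "namespace")]), ]
  rownames(annotations) <- NULL
  annotations[c("gene", "term_id", "namespace", "term_name")]
}

#' Attach annotations to a consensus list
#'
#' Left join: every consensus gene appears at least once; unannotated genes get
#' one row with empty term fields and stay in the coverage denominator.
#' Annotation records for genes outside the consensus are dropped with a
#' logged count.
#'
#' @param consensus an `ortho_consensus` object or character gene vector.
#' @param annotations annotation data.frame (see [read_annotations()]).
#' @return list with `table` (data.frame gene / term_id / namespace /
#'   term_name), `coverage` (per-namespace data.frame with annotated-gene
#'   counts and fractions over all consensus genes) and `n_dropped`.
#' @export
annotate_genes <- function(consensus, annotations) {
  genes <- consensus_genes(consensus)
  annotations <- validate_annotations(annotations)
  outside <- !(annotations$gene %in% genes)
  n_dropped <- sum(outside)
  if (n_dropped) {
    message(sprintf("annotate_genes: dropped %d records for genes outside the consensus",
                    n_dropped))
  }
  ann <- annotations[!outside, ]
  missing <- setdiff(genes, ann$gene)
  tab <- rbind(ann, if (length(missing)) {
    data.frame(gene = missing, term_id = "", namespace = "",
               term_name = "", stringsAsFactors = FALSE)
  })
  tab <- tab[order(tab$gene, tab$namespace, tab$term_id, method = "radix"), ]
  rownames(tab) <- NULL

  coverage <- do.call(rbind, lapply(ANNOTATION_NAMESPACES, function(ns) {
    n_ann <- length(unique(ann$gene[ann$namespace == ns]))
    frac <- n_ann / length(genes)
    data.frame(namespace = ns, genes_annotated = n_ann,
               genes_total = length(genes), fraction = frac,
               percent = round_half_away(100 * frac),
               stringsAsFactors = FALSE)
  }))
  list(table = tab, coverage = coverage, n_dropped = n_dropped)
}

#' Gene- or term-focused pivot report
#'
#' Re-groups an annotated table either one-row-per-gene (all its terms,
#' sorted, deduplicated) or one-row-per-term (all its genes). The total
#' number of gene-term pairs is identical in both orientations.
#'
#' @param annotated result of [annotate_genes()] (or its `table` element).
#' @param namespace one annotation namespace.
#' @param focus `"gene"` or `"term"`.
#' @return data.frame report.
#' @export
pivot_report <- function(annotated, namespace, focus = c("gene", "term")) {
  focus <- match.arg(focus)
  tab <- if (is.list(annotated) && !is.data.frame(annotated)) annotated$table
         else annotated
  if (!namespace %in% ANNOTATION_NAMESPACES) {
    om_stop("orthomeld_config_error", "unknown annotation namespace %s",
            sQuote(namespace))
  }
  tab <- tab[tab$namespace == namespace, , drop = FALSE]
  if (focus == "gene") {
    out <- do.call(rbind, lapply(split(tab, tab$gene), function(g) {
      terms <- om_sort(unique(g$term_id))
      data.frame(gene = g$gene[1], n_terms = length(terms),
                 terms = paste(terms, collapse = ";"), stringsAsFactors = FALSE)
    }))
  } else {
    out <- do.call(rbind, lapply(split(tab, tab$term_id), function(t) {
      genes <- om_sort(unique(t$gene))
      data.frame(term_id = t$term_id[1], term_name = t$term_name[1],
                 n_genes = length(genes),
                 genes = paste(genes, collapse = ";"), stringsAsFactors = FALSE)
    }))
  }
  if (is.null(out)) return(data.frame())
  out <- out[order(out[[1]], method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Define a family-extraction rule
#'
#' A family rule is a set of include terms plus two manual-correction ledgers,
#' mirroring how curated compendium comparisons handle annotation noise:
#' genes matching a family-typical term but rejected on manual review
#' (exclusions, e.g. kinase-associated annotations on non-kinases) and family
#' members present in the consensus but lacking the annotation (inclusions).
#' Every ledger entry carries mandatory reason text.
#'
#' @param family family name.
#' @param include_terms character vector of namespace-qualified term ids
#'   (e.g. `"IPR001810"`, `"GO:0003707"`).
#' @param exclude_ledger,include_ledger data.frame with columns gene, reason
#'   (may be empty / NULL).
#' @return object of class `family_rule`.
#' @export
family_rule <- function(family, include_terms,
                        exclude_ledger = NULL, include_ledger = NULL) {
  mk <- function(df) {
    if (is.null(df) || !nrow(df)) {
      return(data.frame(gene = character(), reason = character(),
                        stringsAsFactors = FALSE))
    }
    stopifnot(all(c("gene", "reason") %in% names(df)))
    if (any(!nzchar(trimws(df$reason)))) {
      om_stop("orthomeld_config_error",
              "ledger entry for %s lacks reason text",
              df$gene[!nzchar(trimws(df$reason))][1])
    }
    df$gene <- normalize_id(df$gene)
    df[c("gene", "reason")]
  }
  excl <- mk(exclude_ledger)
  incl <- mk(include_ledger)
  if (length(intersect(excl$gene, incl$gene))) {
    om_stop("orthomeld_config_error",
            "gene %s appears in both exclude and include ledgers",
            intersect(excl$gene, incl$gene)[1])
  }
  structure(list(family = family, include_terms = unique(include_terms),
                 exclude_ledger = excl, include_ledger = incl),
            class = "family_rule")
}

#' Extract a gene family by annotation rule
#'
#' Raw hits are the genes carrying at least one include term; the exclusion
#' ledger then removes manually rejected genes and the inclusion ledger adds
#' members lacking the annotation. Ledger genes must exist in the annotated
#' gene universe (a ledger referencing an absent gene is inconsistent with the
#' input and raises a hard error). Deterministic and order-independent.
#'
#' @param annotated result of [annotate_genes()] (or its `table` element).
#' @param rule a [family_rule()].
#' @return object of class `family_extraction`: list with `family`, `genes`
#'   (final sorted set), `raw` (pre-ledger hits) and `trace` (data.frame
#'   action / gene / detail logging every ledger application).
#' @export
extract_family <- function(annotated, rule) {
  stopifnot(inherits(rule, "family_rule"))
  tab <- if (is.list(annotated) && !is.data.frame(annotated)) annotated$table
         else annotated
  universe <- unique(tab$gene)
  raw <- om_sort(unique(tab$gene[tab$term_id %in% rule$include_terms]))

  for (ledger in c("exclude_ledger", "include_ledger")) {
    absent <- setdiff(rule[[ledger]]$gene, universe)
    if (length(absent)) {
      om_stop("orthomeld_ledger_error",
              "%s gene %s is absent from the annotated gene universe",
              sub("_ledger", "", ledger), sQuote(absent[1]))
    }
  }
  genes <- om_sort(union(setdiff(raw, rule$exclude_ledger$gene),
                         rule$include_ledger$gene))
  trace_rows <- function(action, gene, detail) {
    if (!length(gene)) return(NULL)
    data.frame(action = action, gene = gene, detail = detail,
               stringsAsFactors = FALSE)
  }
  trace <- rbind(
    trace_rows("raw", raw, "matched include term"),
    trace_rows("exclude", rule$exclude_ledger$gene, rule$exclude_ledger$reason),
    trace_rows("include", rule$include_ledger$gene, rule$include_ledger$reason))
  structure(list(family = rule$family, genes = genes, raw = raw, trace = trace),
            class = "family_extraction")
}

#' @export
print.family_extraction <- function(x, ...) {
  cat(sprintf("<family_extraction> %s: %d raw hits -> %d genes after ledgers\n",
              x$family, length(x$raw), length(x$genes)))
  invisible(x)
}

#' Confusion summary versus a gold compendium
#'
#' Overlap, gold-only and extracted-only counts with the putative
#' false-negative rate (`gold_only / |gold|`) and false-positive rate
#' (`extracted_only / |extracted|`). Conservation identities
#' (`overlap + gold_only == |gold|`, `overlap + extracted_only ==
#' |extracted|`) are asserted on every call. "Putative" because a gold
#' compendium is itself a prediction: apparent errors may be reclassified on
#' deeper inspection.
#'
#' @param extracted extracted gene set (character or `family_extraction`).
#' @param gold gold-standard gene set (character, non-empty).
#' @return object of class `confusion_summary`: list with counts, rates and
#'   rounded percents (`fn_percent`, `fp_percent`, plus one-decimal forms).
#'   An empty extracted set reports `fp_rate` as `NA`.
#' @export
evaluate_against_gold <- function(extracted, gold) {
  if (inherits(extracted, "family_extraction")) extracted <- extracted$genes
  extracted <- unique(extracted)
  gold <- unique(gold)
  if (!length(gold)) {
    om_stop("orthomeld_domain_error",
            "empty gold compendium: rates are undefined")
  }
  overlap <- length(intersect(gold, extracted))
  gold_only <- length(setdiff(gold, extracted))
  extracted_only <- length(setdiff(extracted, gold))
  stopifnot(overlap + gold_only == length(gold),
            overlap + extracted_only == length(extracted))
  fn <- gold_only / length(gold)
  fp <- if (length(extracted)) extracted_only / length(extracted) else NA_real_
  fnp <- percent_pair(fn)
  fpp <- if (is.na(fp)) list(percent = NA_real_, percent_1dp = NA_real_)
         else percent_pair(fp)
  structure(list(
    overlap = overlap, gold_only = gold_only, extracted_only = extracted_only,
    n_gold = length(gold), n_extracted = length(extracted),
    fn_rate = fn, fp_rate = fp,
    fn_percent = fnp$percent, fn_percent_1dp = fnp$percent_1dp,
    fp_percent = fpp$percent, fp_percent_1dp = fpp$percent_1dp
  ), class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> overlap %d | gold-only %d (FN %s%%) | extracted-only %d (FP %s%%)\n",
              x$overlap, x$gold_only, format(x$fn_percent),
              x$extracted_only, format(x$fp_percent)))
  invisible(x)
}

#' Pathway-component membership report
#'
#' For a curated list of pathway components, reports whether each gene is in
#' the consensus and which sources support it. Identifiers whose alias-map
#' resolution ends on a removed/pseudogene entry are flagged `unresolved`
#' rather than dropped.
#'
#' @param consensus an `ortho_consensus` object or character gene vector.
#' @param components character vector (or data.frame with a `gene` column) of
#'   component identifiers; non-empty.
#' @param alias_map optional alias map used to update component identifiers.
#' @return data.frame with columns `component`, `gene` (resolved id),
#'   `present`, `sources`, `unresolved`.
#' @export
membership_coverage <- function(consensus, components, alias_map = NULL) {
  if (is.data.frame(components)) components <- components$gene
  if (!length(components)) {
    om_stop("orthomeld_config_error", "empty component list")
  }
  genes <- consensus_genes(consensus)
  supp <- if (inherits(consensus, "ortho_consensus")) support_sets(consensus)
          else NULL
  lookup <- .alias_lookup(validate_alias_map(alias_map))
  norm <- normalize_id(components)
  rows <- lapply(seq_along(components), function(i) {
    r <- .resolve_one(norm[i], lookup)
    unresolved <- r$status %in% c("removed", "pseudogene")
    present <- !unresolved && r$id %in% genes
    src <- if (present && !is.null(supp)) paste(supp[[r$id]], collapse = ";")
           else ""
    data.frame(component = components[i], gene = r$id, present = present,
               sources = src, unresolved = unresolved,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a gold-compendium file
#'
#' TSV columns `gene  family  note`.
#'
#' @param path file path.
#' @return data.frame with normalized gene identifiers.
#' @export
read_gold <- function(path) {
  df <- om_read_tsv(path, c("gene", "family", "note"))
  if (nrow(df)) df$gene <- normalize_id(df$gene)
  df
}
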