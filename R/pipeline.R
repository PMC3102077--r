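# Run configuration and staged orchestration: chains ingestion, consensus
# building, statistics, annotation, family evaluation and screen coverage into
# one reproducible batch run driven by a YAML config. Every stage emits
# TSV (human-diffable) and/or JSON (machine-readable) reports; a manifest with
# MD5 checksums closes the run. Identical config + inputs give byte-identical
# outputs.

PIPELINE_STAGES <- c("ingest", "consensus", "venn", "congruence", "annotate",
                     "pivot", "family_eval", "pathway_coverage",
                     "screen_coverage", "library_coverage")

.norm_stage <- function(s) gsub("-", "_", s, fixed = TRUE)

#' Read a pipeline run configuration
#'
#' @param path YAML file. Recognized keys: `sources` (list of label / path /
#'   dialect), `taxa`, `alias_map`, `annotations`, `family_rules` (list of
#'   family / include_terms / optional exclude_ledger & include_ledger TSV
#'   paths), `gold` (family -> TSV path), `screens` (list of label / hits /
#'   optional ledger / optional screen_size), `pathways` (list of label /
#'   components path), `clone_map`, `out_dir`.
#' @return the configuration list (class `run_config`). Relative paths are
#'   interpreted relative to the config file's directory.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    om_stop("orthomeld_io_error", "config file does not exist: %s", path)
  }
  cfg <- yaml::read_yaml(path)
  cfg$.base_dir <- dirname(normalizePath(path))
  class(cfg) <- "run_config"
  cfg
}

.cfg_path <- function(cfg, p) {
  if (is.null(p)) return(NULL)
  if (!is.null(cfg$.base_dir) && !grepl("^(/|[A-Za-z]:)", p)) {
    file.path(cfg$.base_dir, p)
  } else p
}

#' Validate a run configuration
#'
#' Collects every problem (missing files, duplicate source labels, unknown
#' dialects or stages) rather than stopping at the first; a valid
#' configuration yields zero findings.
#'
#' @param config a `run_config` (or list, or YAML path).
#' @return data.frame with columns `field`, `message`; zero rows when valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  findings <- list()
  note <- function(field, msg) {
    findings[[length(findings) + 1]] <<- data.frame(
      field = field, message = msg, stringsAsFactors = FALSE)
  }
  if (is.null(config$sources) || !length(config$sources)) {
    note("sources", "at least one source must be configured")
  } else {
    labels <- vapply(config$sources, function(s) s$label %||% "", "")
    if (any(!nzchar(labels))) note("sources.label", "source label missing")
    dup <- unique(labels[duplicated(labels)])
    for (d in dup) note("sources.label", sprintf("duplicate source label '%s'", d))
    for (s in config$sources) {
      if (!is.null(s$dialect) && !s$dialect %in% SOURCE_DIALECTS) {
        note(sprintf("sources[%s].dialect", s$label %||% "?"),
             sprintf("unknown dialect '%s'", s$dialect))
      }
      p <- .cfg_path(config, s$path)
      if (is.null(p) || !file.exists(p)) {
        note(sprintf("sources[%s].path", s$label %||% "?"),
             sprintf("file not found: %s", s$path %||% "<missing>"))
      }
    }
  }
  for (key in c("alias_map", "annotations", "clone_map")) {
    p <- .cfg_path(config, config[[key]])
    if (!is.null(p) && !file.exists(p)) {
      note(key, sprintf("file not found: %s", config[[key]]))
    }
  }
  for (g in names(config$gold)) {
    p <- .cfg_path(config, config$gold[[g]])
    if (!file.exists(p)) note(sprintf("gold.%s", g),
                              sprintf("file not found: %s", config$gold[[g]]))
  }
  for (r in config$family_rules) {
    if (is.null(r$family) || !nzchar(r$family)) {
      note("family_rules.family", "family name missing")
    }
    if (is.null(r$include_terms) || !length(r$include_terms)) {
      note(sprintf("family_rules[%s].include_terms", r$family %||% "?"),
           "no include terms")
    }
    for (lk in c("exclude_ledger", "include_ledger")) {
      p <- .cfg_path(config, r[[lk]])
      if (!is.null(p) && !file.exists(p)) {
        note(sprintf("family_rules[%s].%s", r$family %||% "?", lk),
             sprintf("file not found: %s", r[[lk]]))
      }
    }
  }
  for (s in config$screens) {
    p <- .cfg_path(config, s$hits)
    if (is.null(p) || !file.exists(p)) {
      note(sprintf("screens[%s].hits", s$label %||% "?"),
           sprintf("file not found: %s", s$hits %||% "<missing>"))
    }
    p <- .cfg_path(config, s$ledger)
    if (!is.null(p) && !file.exists(p)) {
      note(sprintf("screens[%s].ledger", s$label %||% "?"),
           sprintf("file not found: %s", s$ledger))
    }
  }
  for (pw in config$pathways) {
    p <- .cfg_path(config, pw$components)
    if (is.null(p) || !file.exists(p)) {
      note(sprintf("pathways[%s].components", pw$label %||% "?"),
           sprintf("file not found: %s", pw$components %||% "<missing>"))
    }
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(field = character(), message = character(),
                  stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the meta-analysis pipeline
#'
#' Executes the requested stages in dependency order, writing each stage's
#' report files under `out_dir` and a `manifest.tsv` with MD5 checksums.
#' A stage whose upstream product is neither requested in the same run nor
#' already present on disk (e.g. `venn` without `consensus`) raises a
#' dependency error naming the stage.
#'
#' @param config a `run_config`, list, or YAML path.
#' @param stages subset of `r paste(PIPELINE_STAGES, collapse = ", ")`
#'   (hyphenated spellings accepted); by default every stage the configuration
#'   provides inputs for.
#' @return invisibly, list with `status` (0 on success) and `manifest`
#'   data.frame.
#' @export
run_pipeline <- function(config, stages = NULL) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    config <- read_run_config(config)
  }
  if (is.null(stages)) {
    stages <- c("ingest", "consensus", "venn", "congruence",
                if (!is.null(config$annotations)) c("annotate", "pivot"),
                if (!is.null(config$annotations) &&
                      length(config$family_rules)) "family_eval",
                if (length(config$pathways)) "pathway_coverage",
                if (length(config$screens)) "screen_coverage",
                if (!is.null(config$clone_map)) "library_coverage")
  }
  stages <- .norm_stage(stages)
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown)) {
    om_stop("orthomeld_config_error", "unknown stage %s", sQuote(unknown[1]))
  }
  findings <- validate_config(config)
  if (nrow(findings)) {
    om_stop("orthomeld_config_error", "invalid configuration: %s (%s)",
            findings$field[1], findings$message[1],
            data = list(findings = findings))
  }
  out_dir <- .cfg_path(config, config$out_dir %||% "orthomeld_out")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    om_stop("orthomeld_io_error", "cannot create output directory %s", out_dir)
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]  # dependency order
  log <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  outputs <- character()
  emit_tsv <- function(df, file) {
    p <- file.path(out_dir, file)
    om_write_tsv(df, p)
    outputs <<- c(outputs, p)
  }
  emit_json <- function(x, file) {
    p <- file.path(out_dir, file)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, p)
  }
  need <- function(stage, dep_stage, value, reload = NULL) {
    if (!is.null(value)) return(value)
    if (!is.null(reload)) {
      v <- reload()
      if (!is.null(v)) return(v)
    }
    om_stop("orthomeld_dependency_error",
            "stage '%s' requires the '%s' stage (not requested and no prior artifact found)",
            stage, dep_stage)
  }

  alias_map <- if (!is.null(config$alias_map)) {
    read_alias_map(.cfg_path(config, config$alias_map))
  } else NULL
  tables <- NULL
  consensus <- NULL
  annotated <- NULL

  for (stage in stages) {
    switch(stage,
      ingest = {
        tables <- lapply(config$sources, function(s) {
          parse_source(.cfg_path(config, s$path), s$dialect, source = s$label,
                       taxa = config$taxa %||% c("cel", "hsa"))
        })
        summary <- do.call(rbind, lapply(tables, function(t) {
          data.frame(source = t$source, dialect = t$dialect,
                     n_assertions = nrow(t$assertions),
                     n_query_genes = length(t$query_genes),
                     n_subject_genes = length(t$subject_genes),
                     n_collapsed = t$n_collapsed, stringsAsFactors = FALSE)
        }))
        emit_tsv(summary, "sources_summary.tsv")
        log(stage, "parsed %d sources", length(tables))
      },
      consensus = {
        tables <- need(stage, "ingest", tables)
        consensus <- build_consensus(tables, alias_map)
        p <- file.path(out_dir, "consensus.tsv")
        write_consensus(consensus, p)
        outputs <- c(outputs, p)
        emit_json(list(n_genes = nrow(consensus$entries),
                       roster = as.list(consensus$roster)),
                  "consensus_summary.json")
        log(stage, "consensus of %d genes", nrow(consensus$entries))
      },
      venn = {
        consensus <- need(stage, "consensus", consensus, reload = function() {
          p <- file.path(out_dir, "consensus.tsv")
          if (file.exists(p)) read_consensus(p) else NULL
        })
        v <- venn_partition(consensus)
        emit_tsv(as.data.frame(v), "venn.tsv")
        emit_json(stats::setNames(as.list(v$count), v$sources), "venn.json")
        log(stage, "%d regions", nrow(v))
      },
      congruence = {
        consensus <- need(stage, "consensus", consensus, reload = function() {
          p <- file.path(out_dir, "consensus.tsv")
          if (file.exists(p)) read_consensus(p) else NULL
        })
        cg <- congruence(consensus)
        emit_tsv(cg$per_source, "congruence.tsv")
        pw <- as.data.frame(cg$pairwise)
        pw <- cbind(data.frame(source = rownames(pw), stringsAsFactors = FALSE),
                    pw)
        emit_tsv(pw, "congruence_pairwise.tsv")
        log(stage, "congruence over %d sources", nrow(cg$per_source))
      },
      annotate = {
        consensus <- need(stage, "consensus", consensus, reload = function() {
          p <- file.path(out_dir, "consensus.tsv")
          if (file.exists(p)) read_consensus(p) else NULL
        })
        if (is.null(config$annotations)) {
          om_stop("orthomeld_dependency_error",
                  "stage 'annotate' requires an annotations file in the config")
        }
        ann <- read_annotations(.cfg_path(config, config$annotations))
        annotated <- annotate_genes(consensus, ann)
        emit_tsv(annotated$table, "annotated.tsv")
        emit_tsv(annotated$coverage, "annotation_coverage.tsv")
        log(stage, "%d records dropped outside consensus", annotated$n_dropped)
      },
      pivot = {
        annotated <- need(stage, "annotate", annotated)
        for (ns in unique(annotated$table$namespace)) {
          if (!nzchar(ns)) next
          emit_tsv(pivot_report(annotated, ns, "gene"),
                   sprintf("pivot_%s_gene.tsv", ns))
          emit_tsv(pivot_report(annotated, ns, "term"),
                   sprintf("pivot_%s_term.tsv", ns))
        }
        log(stage, "pivot reports written")
      },
      family_eval = {
        annotated <- need(stage, "annotate", annotated)
        for (r in config$family_rules) {
          excl <- if (!is.null(r$exclude_ledger)) {
            om_read_tsv(.cfg_path(config, r$exclude_ledger), c("gene", "reason"))
          }
          incl <- if (!is.null(r$include_ledger)) {
            om_read_tsv(.cfg_path(config, r$include_ledger), c("gene", "reason"))
          }
          rule <- family_rule(r$family, unlist(r$include_terms), excl, incl)
          fam <- extract_family(annotated, rule)
          emit_tsv(data.frame(gene = fam$genes), sprintf("family_%s.tsv", r$family))
          emit_tsv(fam$trace, sprintf("family_%s_trace.tsv", r$family))
          if (!is.null(config$gold[[r$family]])) {
            gold <- read_gold(.cfg_path(config, config$gold[[r$family]]))
            cs <- evaluate_against_gold(fam, gold$gene)
            emit_json(unclass(cs), sprintf("family_%s_confusion.json", r$family))
          }
          log(stage, "%s: %d genes", r$family, length(fam$genes))
        }
      },
      pathway_coverage = {
        consensus <- need(stage, "consensus", consensus, reload = function() {
          p <- file.path(out_dir, "consensus.tsv")
          if (file.exists(p)) read_consensus(p) else NULL
        })
        for (pw in config$pathways) {
          comp <- om_read_tsv(.cfg_path(config, pw$components), "gene")
          rep <- membership_coverage(consensus, comp$gene, alias_map)
          emit_tsv(rep, sprintf("pathway_%s.tsv", pw$label))
          log(stage, "%s: %d/%d components present", pw$label,
              sum(rep$present), nrow(rep))
        }
      },
      screen_coverage = {
        consensus <- need(stage, "consensus", consensus, reload = function() {
          p <- file.path(out_dir, "consensus.tsv")
          if (file.exists(p)) read_consensus(p) else NULL
        })
        for (s in config$screens) {
          hits <- read_screen_hits(.cfg_path(config, s$hits))
          upd <- update_screen_hits(hits, alias_map)
          ledger <- if (!is.null(s$ledger)) {
            read_reclassification_ledger(.cfg_path(config, s$ledger))
          }
          conserved <- reclassify(upd$hits, ledger)
          cov <- coverage_summary(conserved, consensus,
                                  screen_size = s$screen_size)
          tally <- attr(conserved, "tally")
          emit_json(c(list(screen = s$label,
                           hits_input = upd$report$counts$input,
                           hits_after_update = upd$report$counts$kept),
                      tally, unclass(cov)),
                    sprintf("screen_%s.json", s$label))
          emit_tsv(data.frame(gene = conserved,
                              in_consensus = conserved %in%
                                consensus_genes(consensus)),
                   sprintf("screen_%s_conserved.tsv", s$label))
          log(stage, "%s: %d/%d conserved hits in consensus", s$label,
              cov$conserved_in_consensus, cov$conserved_final)
        }
      },
      library_coverage = {
        consensus <- need(stage, "consensus", consensus, reload = function() {
          p <- file.path(out_dir, "consensus.tsv")
          if (file.exists(p)) read_consensus(p) else NULL
        })
        if (is.null(config$clone_map)) {
          om_stop("orthomeld_dependency_error",
                  "stage 'library_coverage' requires a clone_map in the config")
        }
        cm <- read_clone_map(.cfg_path(config, config$clone_map))
        lc <- library_coverage(consensus, cm)
        emit_json(lc, "library_coverage.json")
        log(stage, "%d/%d consensus genes in library", lc$represented,
            lc$consensus_size)
      })
  }

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         bytes = file.size(outputs),
                         stringsAsFactors = FALSE)
  om_write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(status = 0L, manifest = manifest, out_dir = out_dir))
}
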