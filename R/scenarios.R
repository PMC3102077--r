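# Deterministic benchmark fixtures. Each scenario is a fully hard-coded
# (seedless, byte-stable) synthetic data set whose marginal counts match a
# published contingency from the C. elegans-human consensus-orthology
# literature; individual identifiers are synthetic except for the handful of
# genes the published analyses name explicitly (e.g. the F53B8.1 -> ZK1151.1
# merge). Tests derive every statistic by running the real pipeline functions
# on these inputs -- none of the published totals is stored as an answer.

PAPER_SCENARIOS <- c("kinase", "nhr", "fbox", "cell_division", "trafficking",
                     "wtf2", "consensus_shares", "library")

#' Deterministic benchmark fixtures
#'
#' Constructs the inputs (hit lists, alias maps, reclassification ledgers,
#' annotation tables, family rules, gold compendia, clone maps, source gene
#' sets) of one named benchmark scenario. Feeding them through the pipeline
#' reproduces the corresponding published contingency:
#'
#' * `kinase` -- 250 raw annotation hits vs a 243-gene gold kinome, with a
#'   10-gene exclusion and 3-gene inclusion ledger.
#' * `nhr` -- nuclear hormone receptors: 17 extracted vs 16 gold, overlap 15.
#' * `fbox` -- 12 raw F-box hits, 2 excluded on manual domain review.
#' * `cell_division` -- 661 screen hits, 7 removed/pseudogene + 2 duplicate
#'   merges, 575 prior-conserved, +14/-17 reclassification, 565 in consensus.
#' * `trafficking` -- 268 hits, 1 duplicate merge + 1 rename, 215
#'   prior-conserved, +8/-20 reclassification, 202 in consensus.
#' * `wtf2` -- a 934-gene transcription-factor compendium with 199 genes
#'   previously called conserved; 195 of those plus 182 others are in the
#'   consensus.
#' * `consensus_shares` -- four 7,663-gene-union source sets whose
#'   found-by-all-four class holds 3,386 genes.
#' * `library` -- a 7,663-gene consensus with 6,198 genes represented in a
#'   clone library (6 pseudogene-status, 11 incorrect-clone genes among them).
#'
#' @param name scenario name (see above).
#' @param dir optional directory; when given, the fixture's tabular inputs are
#'   also written there as TSV files.
#' @return named list of fixture inputs (contents vary by scenario); every
#'   scenario carries `name`.
#' @export
paper_scenario <- function(name, dir = NULL) {
  if (!name %in% PAPER_SCENARIOS) {
    om_stop("orthomeld_config_error", "unknown scenario %s (expected one of %s)",
            sQuote(name), paste(PAPER_SCENARIOS, collapse = ", "))
  }
  scn <- switch(name,
    kinase = .scenario_kinase(),
    nhr = .scenario_nhr(),
    fbox = .scenario_fbox(),
    cell_division = .scenario_cell_division(),
    trafficking = .scenario_trafficking(),
    wtf2 = .scenario_wtf2(),
    consensus_shares = .scenario_consensus_shares(),
    library = .scenario_library())
  scn$name <- name
  if (!is.null(dir)) scn$files <- .write_scenario(scn, dir)
  scn
}

.scenario_kinase <- function() {
  gold <- sprintf("KIN%03d.1", 1:243)
  extras <- sprintf("KX%02d.1", 1:31)
  raw <- c(gold[1:219], extras)            # 250 annotation hits
  unannotated <- gold[220:222]             # in consensus, lacking the terms
  consensus <- om_sort(c(raw, unannotated))
  annotations <- rbind(
    data.frame(gene = raw, term_id = "IPR000719", namespace = "interpro",
               term_name = "Protein kinase domain", stringsAsFactors = FALSE),
    data.frame(gene = raw[1:100], term_id = "GO:0004672", namespace = "go_mf",
               term_name = "protein kinase activity", stringsAsFactors = FALSE))
  rule <- family_rule(
    "kinase", include_terms = c("IPR000719", "GO:0004672"),
    exclude_ledger = data.frame(
      gene = extras[1:10],
      reason = "kinase-associated annotation but not a kinase on manual review",
      stringsAsFactors = FALSE),
    include_ledger = data.frame(
      gene = unannotated,
      reason = "curated kinase present in consensus without kinase annotation",
      stringsAsFactors = FALSE))
  list(consensus = consensus, annotations = annotations, rule = rule,
       gold = gold)
}

.scenario_nhr <- function() {
  overlap <- sprintf("nhr-%d", 20:34)            # 15 previously described
  gold <- c(overlap, "nhr-48")                   # 16; nhr-48 not extracted
  novel <- c("nhr-14", "nhr-35")                 # extracted, not in gold
  consensus <- om_sort(c(overlap, novel, sprintf("OLN%d.1", 1:20)))
  annotations <- rbind(
    data.frame(gene = overlap, term_id = "IPR001628", namespace = "interpro",
               term_name = "Zinc finger, nuclear hormone receptor-type",
               stringsAsFactors = FALSE),
    data.frame(gene = overlap[1:8], term_id = "IPR000536",
               namespace = "interpro",
               term_name = "Nuclear hormone receptor, ligand-binding, core",
               stringsAsFactors = FALSE),
    data.frame(gene = c("nhr-14", "nhr-35"),
               term_id = c("IPR001628", "GO:0003707"),
               namespace = c("interpro", "go_mf"),
               term_name = c("Zinc finger, nuclear hormone receptor-type",
                             "steroid hormone receptor activity"),
               stringsAsFactors = FALSE))
  rule <- family_rule("nhr",
                      include_terms = c("IPR001628", "IPR000536", "GO:0003707"))
  list(consensus = consensus, annotations = annotations, rule = rule,
       gold = gold)
}

.scenario_fbox <- function() {
  final <- c("C10E2.2", "Y60A3A.8", sprintf("FBX%d.1", 1:8))
  rejected <- c("T08D2.2", "Y50D7A.1")     # annotated, no F-box on inspection
  raw <- c(final, rejected)                # 12 raw hits
  consensus <- om_sort(c(raw, sprintf("OLF%d.1", 1:15)))
  annotations <- data.frame(gene = raw, term_id = "IPR001810",
                            namespace = "interpro",
                            term_name = "Cyclin-like F-box",
                            stringsAsFactors = FALSE)
  rule <- family_rule("fbox", include_terms = "IPR001810",
                      exclude_ledger = data.frame(
                        gene = rejected,
                        reason = "no recognizable F-box on domain re-inspection",
                        stringsAsFactors = FALSE))
  # two historical gold compendia of different stringency
  gold_narrow <- c(final[1:6], "T28B11.1")                    # 7 genes
  gold_broad <- c(final[1:8], "T28B11.1", "T28B4.1", "FBW9.1") # 11 genes
  list(consensus = consensus, annotations = annotations, rule = rule,
       gold_narrow = gold_narrow, gold_broad = gold_broad)
}

.scenario_cell_division <- function() {
  ids <- sprintf("CD%03d.1", 1:661)
  alias_map <- rbind(
    data.frame(alias = ids[653:654], status = "merged",
               replacement = ids[1:2], stringsAsFactors = FALSE),
    data.frame(alias = ids[655:658], status = "removed", replacement = "",
               stringsAsFactors = FALSE),
    data.frame(alias = ids[659:661], status = "pseudogene", replacement = "",
               stringsAsFactors = FALSE))
  hits <- data.frame(gene = ids,
                     prior_conserved = seq_along(ids) <= 575,
                     stringsAsFactors = FALSE)
  ledger <- rbind(
    data.frame(gene = ids[576:589], decision = "gain",
               evidence = "human ortholog supported by RBH and tree-based review",
               stringsAsFactors = FALSE),
    data.frame(gene = ids[1:17], decision = "lose",
               evidence = "no human ortholog by RBH or tree-based review",
               stringsAsFactors = FALSE))
  conserved_expected_universe <- c(ids[18:589])
  consensus <- om_sort(c(setdiff(conserved_expected_universe, ids[18:24]),
                         sprintf("OLC%03d.1", 1:40)))
  list(hits = hits, alias_map = alias_map, ledger = ledger,
       consensus = consensus, screen_size = 19075L)
}

.scenario_trafficking <- function() {
  generic <- sprintf("TR%03d.1", 1:265)
  ids <- c(generic, "F53B8.1", "ZK1151.1", "Y113G7B.21")
  alias_map <- data.frame(
    alias = c("F53B8.1", "Y113G7B.21"), status = "merged",
    replacement = c("ZK1151.1", "Y113G7B.18"), stringsAsFactors = FALSE)
  hits <- data.frame(
    gene = ids,
    prior_conserved = ids %in% c(generic[1:213], "F53B8.1", "ZK1151.1",
                                 "Y113G7B.21"),
    stringsAsFactors = FALSE)
  ledger <- rbind(
    data.frame(gene = generic[214:221], decision = "gain",
               evidence = "human ortholog supported by RBH and tree-based review",
               stringsAsFactors = FALSE),
    data.frame(gene = generic[1:20], decision = "lose",
               evidence = "no human ortholog by RBH or tree-based review",
               stringsAsFactors = FALSE))
  conserved_universe <- c(generic[21:221], "ZK1151.1", "Y113G7B.18")
  consensus <- om_sort(c(setdiff(conserved_universe, generic[21]),
                         sprintf("OLT%03d.1", 1:30)))
  list(hits = hits, alias_map = alias_map, ledger = ledger,
       consensus = consensus, screen_size = 16300L)
}

.scenario_wtf2 <- function() {
  tf_conserved <- sprintf("TF%03d.1", 1:199)       # prior RBH calls
  tf_other <- c(sprintf("TF%03d.1", 200:933), "T01C1.3")  # 735, total 934
  alias_map <- data.frame(alias = "T01C1.3", status = "merged",
                          replacement = "T01C1.2", stringsAsFactors = FALSE)
  hits <- data.frame(gene = c(tf_conserved, tf_other),
                     prior_conserved = c(rep(TRUE, length(tf_conserved)),
                                         rep(FALSE, length(tf_other))),
                     stringsAsFactors = FALSE)
  consensus <- om_sort(c(tf_conserved[1:195],
                         sprintf("TF%03d.1", 200:380),   # 181 unannotated TFs
                         "T01C1.2",                       # the merged survivor
                         sprintf("OLW%03d.1", 1:50)))
  list(hits = hits, alias_map = alias_map, consensus = consensus)
}

.scenario_consensus_shares <- function() {
  roster <- c("inparanoid", "orthomcl", "homologene", "compara")
  # region sizes over the four-set Venn; singletons dominated by the
  # pair-dialect source, the homology-group source smallest but most congruent
  regions <- list(
    `inparanoid;orthomcl;homologene;compara` = 3386,
    inparanoid = 600, orthomcl = 800, homologene = 50, compara = 2000,
    `inparanoid;orthomcl` = 300, `orthomcl;compara` = 200,
    `inparanoid;compara` = 127, `inparanoid;orthomcl;homologene` = 200)
  total <- sum(unlist(regions))
  genes <- sprintf("OL%04d.1", seq_len(total))
  sets <- stats::setNames(vector("list", length(roster)), roster)
  offset <- 0
  for (r in names(regions)) {
    g <- genes[offset + seq_len(regions[[r]])]
    offset <- offset + regions[[r]]
    for (s in strsplit(r, ";", fixed = TRUE)[[1]]) {
      sets[[s]] <- c(sets[[s]], g)
    }
  }
  tables <- lapply(roster, function(s) {
    .new_source_table(s, "ortholog_pair", c("cel", "hsa"),
                      data.frame(query_gene = sets[[s]],
                                 subject_gene = "HS1.1",
                                 relation = "one2one", score = NA_real_,
                                 stringsAsFactors = FALSE))
  })
  list(tables = tables, sets = sets)
}

.scenario_library <- function() {
  consensus <- sprintf("OL%04d.1", 1:7663)
  covered <- consensus[1:6198]
  status <- rep("ok", length(covered))
  status[1:6] <- "pseudogene"
  status[7:17] <- "incorrect"
  clone_map <- data.frame(clone_id = sprintf("sjj_%s", covered),
                          gene = covered, status = status,
                          stringsAsFactors = FALSE)
  list(consensus = consensus, clone_map = clone_map)
}

.write_scenario <- function(scn, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    om_stop("orthomeld_io_error", "cannot create directory %s", dir)
  }
  paths <- character()
  emit <- function(obj, file) {
    p <- file.path(dir, file)
    om_write_tsv(obj, p)
    paths <<- c(paths, p)
  }
  if (!is.null(scn$hits)) {
    emit(data.frame(gene = scn$hits$gene,
                    prior_conserved = as.integer(scn$hits$prior_conserved)),
         "hits.tsv")
  }
  if (!is.null(scn$alias_map)) emit(scn$alias_map, "alias_map.tsv")
  if (!is.null(scn$ledger)) emit(scn$ledger, "ledger.tsv")
  if (!is.null(scn$annotations)) emit(scn$annotations, "annotations.tsv")
  if (!is.null(scn$clone_map)) emit(scn$clone_map, "clone_map.tsv")
  if (!is.null(scn$consensus)) {
    emit(data.frame(gene = scn$consensus), "consensus_genes.tsv")
  }
  if (!is.null(scn$gold)) {
    emit(data.frame(gene = scn$gold, family = scn$name, note = ""), "gold.tsv")
  }
  paths
}
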