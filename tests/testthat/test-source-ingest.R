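write_lines_tmp <- function(lines) {
  p <- tempfile(fileext = ".tsv")
  writeLines(lines, p)
  p
}

test_that("ortholog_pair lines parse into typed assertions", {
  p <- write_lines_tmp(c("# downloaded pairs",
                         "F58E6.6\tENSG00000171681\tortholog_one2one",
                         "K07C5.4\tENSG00000000001\tortholog_one2many"))
  tab <- parse_source(p, "ortholog_pair", source = "compara")
  expect_s3_class(tab, "source_table")
  expect_equal(nrow(tab$assertions), 2)
  expect_equal(tab$assertions$relation[tab$assertions$query_gene == "F58E6.6"],
               "one2one")
  expect_equal(tab$query_genes, c("F58E6.6", "K07C5.4"))
  # unknown relation maps to many2many with a warning
  p2 <- write_lines_tmp("A1.1\tHSG1\twithin_species_paralog")
  expect_warning(tab2 <- parse_source(p2, "ortholog_pair"),
                 class = "orthomeld_unknown_relation")
  expect_equal(tab2$assertions$relation, "many2many")
})

test_that("group_line groups assert only cross-species members", {
  p <- write_lines_tmp(c("OG1_42: cel|K07C5.4 hsa|HG1 hsa|HG2",
                         "OG1_43: cel|T05A1.1 cel|T05A1.2",
                         "OG1_44: hsa|HG3 hsa|HG4"))
  tab <- parse_source(p, "group_line")
  expect_equal(tab$query_genes, "K07C5.4")
  expect_equal(nrow(tab$assertions), 2)
  expect_true(all(tab$assertions$relation == "group_member"))
  expect_equal(sort(tab$assertions$subject_gene), c("HG1", "HG2"))
})

test_that("homology_group requires both taxa in a group", {
  p <- write_lines_tmp(c(
    "group_id\ttaxon\tgene_id\tgene_symbol\tprotein_accession",
    "1\t6239\tK07C5.4\tkin-1\tCE00001",
    "1\t9606\tPKA1\tPKA1\tNP00001",
    "2\t9606\tLONE1\tLONE1\tNP00002"))
  tab <- parse_source(p, "homology_group", taxa = c("6239", "9606"))
  expect_equal(tab$query_genes, "K07C5.4")
  expect_equal(tab$subject_genes, "PKA1")
})

test_that("pairwise_cluster includes in-paralogs and skips one-species clusters", {
  p <- write_lines_tmp(c(
    "cluster_id\tcluster_score\ttaxon\tconfidence\tmember_id",
    "1\t1.000\tcel\t1\tB0205.7",
    "1\t1.000\tcel\t0.6\tB0205.6",
    "1\t1.000\thsa\t1\tHSG1",
    "2\t1.000\tcel\t1\tC05C8.1"))     # worm-only cluster: no assertion
  tab <- parse_source(p, "pairwise_cluster")
  expect_equal(tab$query_genes, c("B0205.6", "B0205.7"))
  a <- tab$assertions
  expect_equal(a$relation[a$query_gene == "B0205.7"], "seed_ortholog")
  expect_equal(a$relation[a$query_gene == "B0205.6"], "in_paralog")
  expect_equal(a$score[a$query_gene == "B0205.6"], 0.6)
})

test_that("malformed input yields parse errors naming file and line", {
  p <- write_lines_tmp(c("A1.1\tHSG1\tortholog_one2one", "B1.1\tonly_two"))
  err <- expect_error(parse_source(p, "ortholog_pair"),
                      class = "orthomeld_parse_error")
  expect_match(conditionMessage(err), ":2:")
  expect_error(parse_source(p, "no_such_dialect"),
               class = "orthomeld_config_error")
  p2 <- write_lines_tmp("OG1 missing colon delimiter")
  expect_error(parse_source(p2, "group_line"), class = "orthomeld_parse_error")
})

test_that("parsing is insensitive to record order", {
  lines <- c("A1.1\tHSG1\tortholog_one2one",
             "B2.2\tHSG2\tortholog_one2many",
             "B2.2\tHSG3\tortholog_one2many",
             "C3.3\tHSG1\tortholog_many2many")
  t1 <- parse_source(write_lines_tmp(lines), "ortholog_pair", source = "s")
  t2 <- parse_source(write_lines_tmp(rev(lines)), "ortholog_pair", source = "s")
  expect_equal(t1$assertions, t2$assertions)
  expect_equal(t1$query_genes, t2$query_genes)
})

test_that("isoform entries collapse onto one gene with a recorded count", {
  p <- write_lines_tmp(c("F53B8.1a\tHSG1\tortholog_one2one",
                         "F53B8.1b\tHSG1\tortholog_one2one"))
  tab <- parse_source(p, "ortholog_pair")
  expect_equal(tab$query_genes, "F53B8.1")
  expect_equal(tab$n_collapsed, 1L)
})

test_that("emit -> parse round trip reproduces per-source assertions", {
  truth <- simulate_orthology(sim_config(n_families = 120, seed = 11))
  d <- withr::local_tempdir()
  emit_source_files(truth, d)
  for (tab in truth$tables) {
    re <- parse_source(file.path(d, paste0(tab$source, ".tsv")), tab$dialect,
                       source = tab$source)
    expect_equal(re$query_genes, tab$query_genes)
    expect_equal(re$subject_genes, tab$subject_genes)
    key <- function(a) sort(paste(a$query_gene, a$subject_gene),
                            method = "radix")
    expect_equal(key(re$assertions), key(tab$assertions))
  }
  # emitted bytes are deterministic given the seed
  d2 <- withr::local_tempdir()
  emit_source_files(simulate_orthology(sim_config(n_families = 120, seed = 11)),
                    d2)
  for (f in list.files(d)) {
    expect_equal(unname(tools::md5sum(file.path(d, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("query_gene_set applies alias updates and set semantics", {
  p <- write_lines_tmp(c("A1.1\tHSG1\tortholog_one2many",
                         "A1.1\tHSG2\tortholog_one2many",
                         "OLD1.1\tHSG3\tortholog_one2one",
                         "DEAD1.1\tHSG4\tortholog_one2one"))
  tab <- parse_source(p, "ortholog_pair")
  m <- data.frame(alias = c("OLD1.1", "DEAD1.1"),
                  status = c("merged", "removed"),
                  replacement = c("B2.2", ""), stringsAsFactors = FALSE)
  expect_equal(query_gene_set(tab, m), c("A1.1", "B2.2"))
})
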