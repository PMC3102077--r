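make_ann <- function(genes, terms, ns = "interpro") {
  data.frame(gene = genes, term_id = terms, namespace = ns,
             term_name = terms, stringsAsFactors = FALSE)
}

test_that("annotate_genes keeps unannotated genes and drops out-of-scope records", {
  cons <- c("A1.1", "B2.2", "C3.3")
  ann <- rbind(make_ann(c("A1.1", "A1.1"), c("IPR1", "IPR2")),
               make_ann("Z9.9", "IPR3"))       # outside consensus
  expect_message(res <- annotate_genes(cons, ann), "dropped 1")
  expect_equal(res$n_dropped, 1L)
  # fan-out join: two terms -> two rows; left join keeps B2.2 and C3.3
  expect_equal(sum(res$table$gene == "A1.1"), 2)
  expect_true(all(c("B2.2", "C3.3") %in% res$table$gene))
  expect_equal(res$table$term_id[res$table$gene == "B2.2"], "")
  cov <- res$coverage
  expect_equal(cov$genes_annotated[cov$namespace == "interpro"], 1L)
  expect_equal(cov$genes_total[cov$namespace == "interpro"], 3L)
  expect_error(annotate_genes(cons, make_ann("A1.1", "X", ns = "kegg")),
               class = "orthomeld_config_error")
})

test_that("pivot reports conserve gene-term pairs across orientations", {
  cons <- sprintf("G%d.1", 1:6)
  ann <- rbind(make_ann(c("G1.1", "G2.1"), "IPR7"),
               make_ann("G1.1", c("IPR8", "IPR8")),   # duplicate collapses
               make_ann("G3.1", "IPR9"))
  res <- annotate_genes(cons, ann)
  g <- pivot_report(res, "interpro", "gene")
  t <- pivot_report(res, "interpro", "term")
  expect_equal(t$genes[t$term_id == "IPR7"], "G1.1;G2.1")
  expect_equal(g$terms[g$gene == "G1.1"], "IPR7;IPR8")
  pairs_g <- sum(g$n_terms)
  pairs_t <- sum(t$n_genes)
  expect_equal(pairs_g, pairs_t)
  expect_equal(pairs_g, 4)
})

test_that("extract_family applies term rules and correction ledgers", {
  cons <- c(sprintf("G%d.1", 1:5), "H9.1")
  ann <- make_ann(sprintf("G%d.1", 1:4), "IPR1")
  res <- annotate_genes(cons, ann)
  rule <- family_rule("fam", "IPR1",
                      exclude_ledger = data.frame(gene = "G4.1",
                                                  reason = "manual reject"),
                      include_ledger = data.frame(gene = "H9.1",
                                                  reason = "known member"))
  fam <- extract_family(res, rule)
  expect_equal(fam$raw, sprintf("G%d.1", 1:4))
  expect_equal(fam$genes, c("G1.1", "G2.1", "G3.1", "H9.1"))
  expect_equal(fam$trace$detail[fam$trace$action == "exclude"], "manual reject")

  # ledger inconsistent with input universe is a hard error
  bad <- family_rule("fam", "IPR1",
                     include_ledger = data.frame(gene = "Z1.1",
                                                 reason = "typo"))
  expect_error(extract_family(res, bad), class = "orthomeld_ledger_error")
  # reasons are mandatory; overlapping ledgers rejected
  expect_error(family_rule("f", "T", exclude_ledger =
                             data.frame(gene = "a", reason = " ")),
               class = "orthomeld_config_error")
  expect_error(family_rule("f", "T",
                           exclude_ledger = data.frame(gene = "G1.1",
                                                       reason = "x"),
                           include_ledger = data.frame(gene = "G1.1",
                                                       reason = "y")),
               class = "orthomeld_config_error")
})

test_that("extract_family is order-independent in annotations and ledgers", {
  cons <- sprintf("G%d.1", 1:10)
  ann <- make_ann(sprintf("G%d.1", c(3, 1, 7, 5)), "IPR1")
  rule <- family_rule("fam", "IPR1",
                      exclude_ledger = data.frame(gene = c("G5.1", "G7.1"),
                                                  reason = "reject"))
  f1 <- extract_family(annotate_genes(cons, ann), rule)
  f2 <- extract_family(annotate_genes(cons, ann[4:1, ]),
                       family_rule("fam", "IPR1",
                                   exclude_ledger = data.frame(
                                     gene = c("G7.1", "G5.1"),
                                     reason = "reject")))
  expect_equal(f1$genes, f2$genes)
})

test_that("evaluate_against_gold computes counts, rates and identities", {
  gold <- sprintf("K%d.1", 1:16)
  extracted <- c(sprintf("K%d.1", 1:15), "N1.1", "N2.1")
  cs <- evaluate_against_gold(extracted, gold)
  expect_equal(cs$overlap, 15)
  expect_equal(cs$gold_only, 1)
  expect_equal(cs$extracted_only, 2)
  expect_equal(cs$fn_percent, 6)    # 1/16
  expect_equal(cs$fp_percent, 12)   # 2/17
  # perfect agreement
  cs <- evaluate_against_gold(gold, gold)
  expect_equal(c(cs$fn_rate, cs$fp_rate), c(0, 0))
  # undefined cases
  expect_error(evaluate_against_gold(extracted, character()),
               class = "orthomeld_domain_error")
  cs <- evaluate_against_gold(character(), gold)
  expect_true(is.na(cs$fp_rate))
  expect_equal(cs$fn_rate, 1)
})

test_that("confusion identities hold on random gold/extracted pairs", {
  set.seed(707)
  for (rep in 1:50) {
    pool <- sprintf("G%d.1", 1:60)
    gold <- sample(pool, sample(5:40, 1))
    extracted <- sample(pool, sample(5:40, 1))
    cs <- evaluate_against_gold(extracted, gold)
    expect_equal(cs$overlap + cs$gold_only, length(gold))
    expect_equal(cs$overlap + cs$extracted_only, length(extracted))
    # brute-force per-gene comparison
    expect_equal(cs$overlap, sum(vapply(gold, `%in%`, TRUE, extracted)))
    expect_true(cs$fn_rate >= 0 && cs$fn_rate <= 1)
    expect_true(cs$fp_rate >= 0 && cs$fp_rate <= 1)
  }
})

test_that("membership_coverage flags presence, support and unresolved ids", {
  cc <- consensus_from_sets(list(A = c("G1.1", "G2.1"), B = "G1.1"))
  m <- data.frame(alias = c("OLD1.1", "DEAD1.1"),
                  status = c("merged", "removed"),
                  replacement = c("G2.1", ""), stringsAsFactors = FALSE)
  rep <- membership_coverage(cc, c("G1.1", "OLD1.1", "DEAD1.1", "Q9.9"), m)
  expect_equal(rep$present, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rep$unresolved, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(rep$gene[2], "G2.1")       # resolved through the merge
  expect_equal(rep$sources[1], "A;B")
  # empty consensus: all absent
  rep <- membership_coverage(character(), c("G1.1", "G2.1"))
  expect_false(any(rep$present))
  expect_error(membership_coverage(cc, character()),
               class = "orthomeld_config_error")
})
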