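test_that("normalize_id strips isoform suffixes, folds cosmid case, is idempotent", {
  expect_equal(normalize_id("F53B8.1a"), "F53B8.1")
  expect_equal(normalize_id("t01c1.3"), "T01C1.3")
  expect_equal(normalize_id("C10E2.2"), "C10E2.2")
  # locus symbols and non-cosmid names are untouched
  expect_equal(normalize_id(c("nhr-48", "mdt-17")), c("nhr-48", "mdt-17"))
  # policy switches: stripping off keeps the isoform letter, folding the stem
  expect_equal(normalize_id("f53b8.1a", strip_isoform = FALSE), "F53B8.1a")
  expect_equal(normalize_id("t01c1.3", fold_case = FALSE), "t01c1.3")
  expect_equal(normalize_id(normalize_id("f53b8.1a", strip_isoform = FALSE),
                            strip_isoform = FALSE), "F53B8.1a")
  # idempotence over a mixed bag
  mixed <- c("F53B8.1a", "t01c1.3", "C10E2.2", "nhr-48", "Y113G7B.21b")
  expect_equal(normalize_id(normalize_id(mixed)), normalize_id(mixed))
  expect_error(normalize_id("   "), class = "orthomeld_invalid_identifier")
  expect_error(normalize_id(c("ok", "")), class = "orthomeld_invalid_identifier")
})

test_that("resolve_alias follows merge chains to a fixed point", {
  m <- data.frame(alias = "T01C1.3", status = "merged", replacement = "T01C1.2",
                  stringsAsFactors = FALSE)
  r <- resolve_alias("T01C1.3", m)
  expect_equal(r[c("id", "status", "steps")],
               list(id = "T01C1.2", status = "merged", steps = 1L))

  m <- data.frame(alias = "F53B8.1", status = "merged",
                  replacement = "ZK1151.1", stringsAsFactors = FALSE)
  expect_equal(resolve_alias("F53B8.1", m)$id, "ZK1151.1")

  chain <- data.frame(alias = c("A1.1", "B1.1"), status = "merged",
                      replacement = c("B1.1", "C1.1"), stringsAsFactors = FALSE)
  r <- resolve_alias("A1.1", chain)
  expect_equal(r$id, "C1.1")
  expect_equal(r$steps, 2L)

  # absent identifier: identity, current, zero steps
  r <- resolve_alias("X99Z9.9", data.frame(alias = character(),
                                           status = character(),
                                           replacement = character()))
  expect_equal(r, list(id = "X99Z9.9", status = "current", steps = 0L))
})

test_that("resolve_alias matches a naive fixed-point oracle on random acyclic maps", {
  set.seed(101)
  for (rep in 1:25) {
    pool <- sprintf("G%d.1", 1:30)
    m <- random_alias_map(pool)
    for (id in sample(pool, 10)) {
      expect_equal(resolve_alias(id, m)$id, oracle_resolve(id, m))
    }
  }
})

test_that("merge cycles are detected and named", {
  cyc <- data.frame(alias = c("A1.1", "B1.1"), status = "merged",
                    replacement = c("B1.1", "A1.1"), stringsAsFactors = FALSE)
  err <- expect_error(resolve_alias("A1.1", cyc),
                      class = "orthomeld_cyclic_alias")
  expect_match(conditionMessage(err), "A1.1")
  expect_error(update_gene_set(c("A1.1", "C1.1"), cyc),
               class = "orthomeld_cyclic_alias")
})

test_that("alias map invariants are enforced", {
  expect_error(validate_alias_map(
    data.frame(alias = "a", status = "merged", replacement = "")),
    class = "orthomeld_config_error")
  expect_error(validate_alias_map(
    data.frame(alias = "a", status = "removed", replacement = "b")),
    class = "orthomeld_config_error")
  expect_error(validate_alias_map(
    data.frame(alias = "a", status = "merged", replacement = "a")),
    class = "orthomeld_config_error")
  expect_error(validate_alias_map(
    data.frame(alias = "a", status = "retired", replacement = "")),
    class = "orthomeld_config_error")
})

test_that("update_gene_set drops removals, renames merges, collapses duplicates", {
  m <- data.frame(
    alias = c("F53B8.1", "Y113G7B.21", "DEAD1.1", "PSG1.1"),
    status = c("merged", "merged", "removed", "pseudogene"),
    replacement = c("ZK1151.1", "Y113G7B.18", "", ""),
    stringsAsFactors = FALSE)
  # merge onto an existing member drops the old id; merge onto an absent
  # target renames and keeps
  r <- update_gene_set(c("F53B8.1", "ZK1151.1", "Y113G7B.21", "DEAD1.1",
                         "PSG1.1", "T05A1.1"), m)
  expect_equal(r$kept, c("ZK1151.1", "Y113G7B.18", "T05A1.1"))
  expect_equal(r$removed$id, c("DEAD1.1", "PSG1.1"))
  expect_equal(r$removed$reason, c("removed", "pseudogene"))
  expect_equal(r$duplicate_merges$old, "F53B8.1")
  expect_equal(r$duplicate_merges$surviving, "ZK1151.1")
  expect_equal(r$renamed, data.frame(old = "Y113G7B.21", new = "Y113G7B.18"))

  # identity update with empty map
  r <- update_gene_set(c("A1.1", "B1.1"), NULL)
  expect_equal(r$kept, c("A1.1", "B1.1"))
  expect_equal(r$counts, list(input = 2L, kept = 2L, removed = 0L,
                              duplicate = 0L))
})

test_that("update_gene_set conservation and idempotence hold on random inputs", {
  set.seed(202)
  for (rep in 1:30) {
    pool <- sprintf("G%d.1", 1:40)
    m <- random_alias_map(pool)
    ids <- sample(pool, 25, replace = TRUE)
    r <- update_gene_set(ids, m)
    # conservation: |input| = |kept| + |removed| + |duplicate_merges|
    expect_equal(length(ids),
                 length(r$kept) + nrow(r$removed) + nrow(r$duplicate_merges))
    expect_false(anyDuplicated(r$kept) > 0)
    # no non-current identifiers survive
    for (g in r$kept) {
      expect_equal(resolve_alias(g, m)[c("id", "status")],
                   list(id = g, status = "current"))
    }
    # idempotence
    if (length(r$kept)) {
      r2 <- update_gene_set(r$kept, m)
      expect_equal(r2$kept, r$kept)
      expect_equal(nrow(r2$removed) + nrow(r2$duplicate_merges), 0L)
    }
  }
})

test_that("alias maps round-trip through their file format", {
  m <- data.frame(alias = c("F53B8.1", "DEAD1.1"),
                  status = c("merged", "removed"),
                  replacement = c("ZK1151.1", ""), stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment line", "alias\tstatus\treplacement",
               "F53B8.1\tmerged\tZK1151.1", "DEAD1.1\tremoved\t"), p)
  expect_equal(read_alias_map(p), m)
})
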