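test_that("build_consensus unions sources and records exact support", {
  tabs <- list(tiny_table("A", "X1.1"), tiny_table("B", c("X1.1", "Y2.2")))
  cc <- build_consensus(tabs)
  expect_equal(cc$entries$gene, c("X1.1", "Y2.2"))
  expect_equal(support_sets(cc), list(X1.1 = c("A", "B"), Y2.2 = "B"))
  # neutral element: adding an empty source changes nothing but the roster
  cc2 <- build_consensus(c(tabs, list(tiny_table("C", character()))))
  expect_equal(cc2$entries$gene, cc$entries$gene)
  expect_equal(cc2$entries$support_count, cc$entries$support_count)
  expect_error(build_consensus(list()), class = "orthomeld_config_error")
  expect_error(build_consensus(list(tiny_table("A", "X1.1"),
                                    tiny_table("A", "Y1.1"))),
               class = "orthomeld_config_error")
})

test_that("support map equals exhaustive membership enumeration on random sets", {
  set.seed(303)
  for (rep in 1:20) {
    sets <- random_sets(4, 50)
    cc <- consensus_from_sets(sets)
    expect_equal(support_sets(cc), oracle_support(sets))
  }
})

test_that("venn partition matches brute-force subset enumeration on 100 random instances", {
  set.seed(404)
  for (rep in 1:100) {
    k <- sample(2:4, 1)
    sets <- random_sets(k, sample(10:40, 1))
    if (!length(unlist(sets))) next
    cc <- consensus_from_sets(sets)
    v <- venn_partition(cc)
    got <- stats::setNames(as.list(v$count), v$sources)
    expect_equal(got[order(names(got))],
                 oracle_venn(lapply(sets, unique))[order(names(oracle_venn(sets)))])
    # conservation: region sum = union size; marginals = set sizes
    expect_equal(sum(v$count), nrow(cc$entries))
    for (s in names(sets)) {
      marg <- sum(v$count[vapply(strsplit(v$sources, ";"),
                                 function(x) s %in% x, TRUE)])
      expect_equal(marg, length(unique(sets[[s]])))
    }
  }
})

test_that("degenerate venn shapes behave", {
  cc <- consensus_from_sets(list(A = "G1.1", B = "G2.1"))
  v <- venn_partition(cc)
  expect_equal(v$count[v$sources == "A"], 1L)
  expect_equal(v$count[v$sources == "B"], 1L)
  expect_equal(v$count[v$sources == "A;B"], 0L)
  # total overlap: only the full region is populated
  cc <- consensus_from_sets(list(A = c("G1.1", "G2.1"), B = c("G1.1", "G2.1")))
  v <- venn_partition(cc)
  expect_equal(v$count[v$sources == "A;B"], 2L)
  expect_equal(sum(v$count), 2L)
})

test_that("support_share computes class fractions with away-from-zero rounding", {
  sets <- list(A = sprintf("G%d.1", 1:10), B = sprintf("G%d.1", 1:7))
  cc <- consensus_from_sets(sets)
  sh <- support_share(cc, 2)
  expect_equal(sh$count, 7)
  expect_equal(sh$fraction, 0.7)
  expect_equal(sh$percent, 70)
  # degenerate single-source roster: share at level 1 is 100%
  cc1 <- consensus_from_sets(list(A = c("G1.1", "G2.1")))
  expect_equal(support_share(cc1, 1)$percent, 100)
  expect_error(support_share(cc, 3), class = "orthomeld_domain_error")
  expect_error(support_share(cc, 0), class = "orthomeld_domain_error")
})

test_that("rounding rule is nearest integer, ties away from zero", {
  expect_equal(round_half_away(c(44.18, 98.78, 99.5, 0.5, 1.5, 2.5)),
               c(44, 99, 100, 1, 2, 3))
  expect_equal(round_half_away(-0.5), -1)
  expect_equal(round_half_away(98.776, 1), 98.8)
})

test_that("congruence matches direct set-intersection recomputation", {
  set.seed(505)
  for (rep in 1:20) {
    sets <- lapply(random_sets(4, 40), unique)
    cc <- consensus_from_sets(sets)
    cg <- congruence(cc)
    for (i in seq_along(sets)) {
      p <- sets[[i]]
      others <- unique(unlist(sets[-i], use.names = FALSE))
      expect_equal(cg$per_source$total[i], length(p))
      expect_equal(cg$per_source$found_by_other_count[i],
                   length(intersect(p, others)))
      if (length(p)) {
        expect_equal(cg$per_source$found_by_other_fraction[i],
                     length(intersect(p, others)) / length(p))
      }
      for (j in seq_along(sets)) {
        if (!length(p)) next
        expect_equal(cg$pairwise[i, j],
                     length(intersect(p, sets[[j]])) / length(p))
        # asymmetry identity: pairwise(P,Q)|P| = |P  Q|
        expect_equal(cg$pairwise[i, j] * length(p),
                     length(intersect(p, sets[[j]])))
      }
    }
  }
})

test_that("congruence limit cases: identical, disjoint and empty sources", {
  cc <- consensus_from_sets(list(A = c("G1.1", "G2.1"), B = c("G1.1", "G2.1")))
  cg <- congruence(cc)
  expect_equal(cg$per_source$found_by_other_fraction, c(1, 1))
  expect_true(all(cg$pairwise == 1))

  cc <- consensus_from_sets(list(A = "G1.1", B = "G2.1"))
  expect_equal(congruence(cc)$per_source$found_by_other_fraction, c(0, 0))

  cc <- build_consensus(list(tiny_table("A", "G1.1"),
                             tiny_table("B", character())))
  cg <- congruence(cc)
  expect_true(is.na(cg$per_source$found_by_other_fraction[2]))
})

test_that("adding a source never shrinks the union or any support set", {
  set.seed(606)
  for (rep in 1:10) {
    sets <- random_sets(3, 30)
    extra <- random_sets(1, 30)
    cc <- consensus_from_sets(sets)
    cc2 <- consensus_from_sets(c(sets, list(srcX = extra[[1]])))
    expect_gte(nrow(cc2$entries), nrow(cc$entries))
    s1 <- support_sets(cc); s2 <- support_sets(cc2)
    for (g in names(s1)) expect_true(all(s1[[g]] %in% s2[[g]]))
  }
})

test_that("consensus TSV output round-trips membership", {
  tabs <- list(tiny_table("A", c("X1.1", "Z3.3")), tiny_table("B", "X1.1"))
  cc <- build_consensus(tabs)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_consensus(cc, p)
  back <- read_consensus(p)
  expect_equal(back$entries$gene, cc$entries$gene)
  expect_equal(back$entries$support_count, cc$entries$support_count)
  lines <- readLines(p)
  expect_match(lines[1], "^gene\tsupport_count\tsources\tcounterparts$")
  expect_match(lines[grepl("^X1.1", lines)], "A=HS1.1;B=HS1.1")
})
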