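test_that("re-prescription of an earlier drug does not open a new line", {
  expect_equal(derive_lines(rep("bevacizumab", 3)), "bevacizumab")
  expect_equal(
    derive_lines(c("bevacizumab", "triamcinolone", "bevacizumab",
                   "dexamethasone")),
    c("bevacizumab", "triamcinolone", "dexamethasone"))
  expect_equal(
    derive_lines(c("triamcinolone", "bevacizumab", "triamcinolone")),
    c("triamcinolone", "bevacizumab"))
})

test_that("line derivation orders by date with canonical same-day tie-break", {
  ing <- c("triamcinolone", "bevacizumab", "dexamethasone")
  days <- c(10, 10, 0)
  expect_equal(derive_lines(ing, days),
               c("dexamethasone", "bevacizumab", "triamcinolone"))
  expect_error(derive_lines(character(0)), "contract violation")
  expect_error(derive_lines("aspirin"), "unknown drug")
})

test_that("line derivation is idempotent and matches the dedup oracle", {
  set.seed(7)
  for (i in 1:200) {
    x <- sample(drug_ingredients()$ingredient, sample(1:8, 1), replace = TRUE)
    lines <- derive_lines(x)
    expect_equal(derive_lines(lines), lines)
    expect_equal(lines, dedup_oracle(x))
  }
})

trio <- list(c("bevacizumab"), c("bevacizumab", "triamcinolone"),
             c("triamcinolone"))

test_that("pathway trees count every sequence prefix", {
  tree <- pathway_tree(trio)
  expect_equal(tree$root, 3L)
  nd <- tree$nodes
  expect_equal(nd$count[nd$sequence == "bev"], 2L)
  expect_equal(nd$count[nd$sequence == "triam"], 1L)
  expect_equal(nd$count[nd$sequence == "bev>triam"], 1L)
  expect_equal(nrow(nd), 3)

  single <- pathway_tree(list("dexamethasone"))
  expect_equal(single$root, 1L)
  expect_equal(single$nodes$sequence, "dex")

  empty <- pathway_tree(list())
  expect_equal(empty$root, 0L)
  expect_equal(nrow(empty$nodes), 0)
})

test_that("sequences beyond max_depth fold into the truncation node", {
  four <- list(c("bevacizumab", "triamcinolone", "dexamethasone",
                 "ranibizumab"))
  tree <- pathway_tree(four, max_depth = 3)
  expect_equal(max(tree$nodes$depth), 3L)
  expect_equal(tree$nodes$count[tree$nodes$sequence == "bev>triam>dex"], 1L)
  full <- pathway_tree(four, max_depth = Inf)
  expect_equal(max(full$nodes$depth), 4L)
})

test_that("continuation and switch fractions partition the at-risk set", {
  tree <- pathway_tree(trio)
  ts <- transition_summary(tree, 1)
  expect_equal(ts$continued_fraction, 2 / 3)
  expect_equal(ts$switched_fraction, 1 / 3)
  expect_equal(ts$continued_fraction + ts$switched_fraction, 1,
               tolerance = 1e-9)

  all_single <- pathway_tree(list("bevacizumab", "triamcinolone"))
  expect_equal(transition_summary(all_single, 1)$continued_fraction, 1)
  expect_error(transition_summary(all_single, 2), "zero denominator")
})

test_that("second-line breakdown uses the first-line subgroup as denominator", {
  tree <- pathway_tree(list(c("bevacizumab", "triamcinolone"),
                            c("bevacizumab", "dexamethasone")))
  bd <- switch_breakdown(tree, "anti_VEGF")
  expect_equal(bd$fraction[bd$second_drug == "triamcinolone"], 0.5)
  expect_equal(bd$fraction[bd$second_drug == "dexamethasone"], 0.5)
  expect_equal(bd$n[bd$second_drug == "none"], 0L)
  expect_equal(sum(bd$fraction), 1)
  expect_error(switch_breakdown(tree, "triamcinolone"), "zero denominator")
})

test_that("sunburst export conserves counts at every ring", {
  sb <- to_sunburst(pathway_tree(list("bevacizumab", "bevacizumab")))
  expect_equal(sb$value, 2L)
  expect_equal(sb$children[[1]]$name, "bev")
  expect_equal(sb$children[[1]]$value, 2L)
  expect_equal(sb$children[[1]]$children[[1]],
               list(name = "stop", value = 2L))

  mixed <- pathway_tree(list(
    c("bevacizumab"), c("bevacizumab", "triamcinolone"),
    c("bevacizumab", "triamcinolone", "dexamethasone"),
    c("triamcinolone"), c("aflibercept", "ranibizumab")))
  check_sunburst_conservation(to_sunburst(mixed))
})

test_that("sankey export balances inflow and outflow through stop nodes", {
  sk <- to_sankey(pathway_tree(list(c("bevacizumab", "triamcinolone"))))
  expect_true(any(sk$links$source_name == "1:bev" &
                    sk$links$target_name == "2:triam" & sk$links$value == 1))
  # node outflow equals inflow (root inflow = tree root)
  tree <- pathway_tree(list(
    c("bevacizumab"), c("bevacizumab", "triamcinolone"),
    c("triamcinolone", "bevacizumab"), c("dexamethasone")))
  sk <- to_sankey(tree)
  for (nm in sk$nodes$name) {
    if (grepl(":stop$", nm)) next
    inflow <- sum(sk$links$value[sk$links$target_name == nm])
    outflow <- sum(sk$links$value[sk$links$source_name == nm])
    if (grepl("^1:", nm)) {
      inflow <- tree$nodes$count[tree$nodes$depth == 1 &
                                   tree$nodes$sequence ==
                                     sub("^1:", "", nm)]
    }
    expect_equal(outflow, as.integer(inflow))
  }

  empty <- to_sankey(pathway_tree(list()))
  expect_equal(nrow(empty$links), 0)
})

test_that("merging site trees is an exact node-wise sum", {
  t1 <- pathway_tree(list("bevacizumab", "bevacizumab"))
  t2 <- pathway_tree(list("bevacizumab", "triamcinolone"))
  m <- merge_pathway_trees(t1, t2)
  expect_equal(m$root, 4L)
  expect_equal(m$nodes$count[m$nodes$sequence == "bev"], 3L)
  expect_equal(m$nodes$count[m$nodes$sequence == "triam"], 1L)

  doubled <- merge_pathway_trees(t1, t1)
  expect_equal(doubled$nodes$count, t1$nodes$count * 2L)

  with_empty <- merge_pathway_trees(t1, pathway_tree(list()))
  expect_equal(with_empty$nodes, t1$nodes)
  expect_equal(with_empty$root, t1$root)

  # associativity / commutativity
  t3 <- pathway_tree(list(c("triamcinolone", "dexamethasone")))
  a <- merge_pathway_trees(merge_pathway_trees(t1, t2), t3)
  b <- merge_pathway_trees(t3, merge_pathway_trees(t2, t1))
  expect_equal(a$nodes, b$nodes)

  expect_error(
    merge_pathway_trees(t1, pathway_tree(list("bevacizumab"), max_depth = 2)),
    "max_depth")
})

test_that("per-site mining then merging equals pooled mining on the fixture", {
  t <- fixture_cdm()
  b <- suppressMessages(build_cohort(t))
  ex <- cohort_exposures(t, b$cohort)
  pooled <- mine_pathways(b$cohort, ex, "none")$all
  merged <- merge_pathway_trees(mine_pathways(b$cohort, ex, "site"))
  expect_equal(merged$nodes, pooled$nodes)
  expect_equal(merged$root, pooled$root)
})

test_that("first-line shares within a stratum sum to one", {
  t <- fixture_cdm()
  b <- suppressMessages(build_cohort(t))
  trees <- mine_pathways(b$cohort, t, "era")
  for (tree in trees) {
    d1 <- tree$nodes[tree$nodes$depth == 1, ]
    expect_equal(sum(d1$count) / tree$root, 1, tolerance = 1e-3)
  }
})

test_that("the pathway observation window caps contributing exposures", {
  t <- fixture_cdm()
  b <- suppressMessages(build_cohort(t))
  ex <- cohort_exposures(t, b$cohort)
  # f5 switches to dexamethasone on day 200; a 180-day window hides it
  tree <- mine_pathways(b$cohort, ex, "none", max_depth = Inf,
                        window_days = 180)$all
  expect_equal(nrow(tree$nodes[tree$nodes$sequence == "bev>triam>dex", ]), 0)
  expect_equal(tree$nodes$count[tree$nodes$sequence == "bev>triam"], 2L)
})
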