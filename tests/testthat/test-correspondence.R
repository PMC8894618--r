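test_that("ortholog matching partitions calls and preserves order", {
  kb <- make_kb(c("APOA1\tDECREASE\tDECREASE\tx",
                  "HBB\tDECREASE\tINCREASE\ty"),
                synonyms = "Hbbl\tHBB")
  calls <- call_tbl(c("Apoa1", "Ckbl", "Hbbl"), c(-3.2, 4.33, -2.4))
  parts <- match_orthologs(calls, kb)
  expect_equal(parts$matched$symbol, c("Apoa1", "Hbbl"))
  expect_equal(parts$matched$human_symbol, c("APOA1", "HBB"))
  expect_equal(parts$excluded$symbol, "Ckbl")
  expect_match(parts$excluded$reason, "no human ortholog")
  expect_equal(nrow(parts$matched) + nrow(parts$excluded), nrow(calls))

  empty <- match_orthologs(call_tbl(character(0), numeric(0)), kb)
  expect_equal(nrow(empty$matched), 0)
  expect_equal(nrow(empty$excluded), 0)
})

test_that("correspondence scoring reads the codirected annotation slot", {
  kb <- make_kb(c(
    "APOA1\tDECREASE\tDECREASE\tboth harmful",
    "GH1\tDECREASE\tINCREASE\tgrowth hormone",
    "ZZZ9\tUNKNOWN\tUNKNOWN\tnothing known"
  ))
  calls <- call_tbl(c("Apoa1", "Gh1", "Zzz9"), c(-3.2, 2.1, 1.0))
  matched <- match_orthologs(calls, kb)$matched
  recs <- score_correspondences(matched, kb)

  apoa1 <- recs[recs$human_symbol == "APOA1", ]
  expect_equal(apoa1$lineage, c("DOMESTIC", "WILD"))
  expect_equal(apoa1$direction, c("DOWN", "UP"))
  expect_equal(apoa1$rp_effect, c("DECREASE", "DECREASE"))

  gh1 <- recs[recs$human_symbol == "GH1", ]
  expect_equal(gh1$rp_effect[gh1$lineage == "DOMESTIC"], "INCREASE")
  expect_equal(gh1$rp_effect[gh1$lineage == "WILD"], "DECREASE")

  # unknown slots on both lineages emit nothing
  expect_false(any(recs$human_symbol == "ZZZ9"))
  expect_false(any(recs$rp_effect == "UNKNOWN"))
})

test_that("one-sided annotations yield exactly one record per matched DEG", {
  kb <- make_kb("ACKR2\tUNKNOWN\tDECREASE\texcess only")
  up <- match_orthologs(call_tbl("Ackr2", 1.5), kb)$matched
  recs_up <- score_correspondences(up, kb)
  expect_equal(nrow(recs_up), 1)
  expect_equal(recs_up$lineage, "DOMESTIC")

  down <- match_orthologs(call_tbl("Ackr2", -1.5), kb)$matched
  recs_down <- score_correspondences(down, kb)
  expect_equal(recs_down$lineage, "WILD")
})

test_that("contingency tallies are exact and order-invariant", {
  recs <- tibble::tibble(
    lineage = c(rep("DOMESTIC", 3), rep("WILD", 2)),
    rp_effect = c("DECREASE", "DECREASE", "INCREASE", "INCREASE", "DECREASE")
  )
  tab <- build_contingency(recs)
  expect_equal(unclass(tab)[1:4],
               list(n_dom_decrease = 2L, n_dom_increase = 1L,
                    n_wild_decrease = 1L, n_wild_increase = 1L))
  set.seed(1)
  shuffled <- recs[sample(nrow(recs)), ]
  expect_identical(build_contingency(shuffled), tab)

  empty <- build_contingency(recs[0, ])
  expect_equal(sum(unlist(unclass(empty))), 0)

  ten <- tibble::tibble(lineage = rep("DOMESTIC", 10),
                        rp_effect = rep("DECREASE", 10))
  expect_equal(build_contingency(ten)$n_dom_decrease, 10L)
})

test_that("fully annotated KBs give 2 records per matched DEG; totals conserve", {
  set.seed(7)
  n <- 50
  effects <- matrix(sample(c("DECREASE", "INCREASE"), 2 * n, replace = TRUE),
                    ncol = 2)
  kb <- make_kb(sprintf("G%03d\t%s\t%s\tsim", seq_len(n),
                        effects[, 1], effects[, 2]))
  lfc <- stats::rnorm(n)
  lfc[lfc == 0] <- 1
  calls <- call_tbl(sprintf("g%03d", seq_len(n)), lfc)
  matched <- match_orthologs(calls, kb)$matched
  expect_equal(nrow(matched), n)
  recs <- score_correspondences(matched, kb)
  expect_equal(nrow(recs), 2 * n)
  tab <- build_contingency(recs)
  expect_equal(tab$n_dom_decrease + tab$n_dom_increase, n)
  expect_equal(tab$n_wild_decrease + tab$n_wild_increase, n)
  expect_equal(sum(unlist(unclass(tab))), nrow(recs))
})
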