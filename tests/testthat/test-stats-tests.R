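# Frozen expected values below were computed with the independent oracles in
# helper-degconcord.R (hypergeometric enumeration, numeric integration,
# exact coefficient sums) before being asserted here.

test_that("two-sided Fisher exact test follows the point-probability rule", {
  expect_equal(fisher_exact_two_sided(contingency_2x2(1, 1, 1, 1)), 1)
  # exact rational value 1609/33263, computed by full-support enumeration
  expect_equal(fisher_exact_two_sided(contingency_2x2(16, 4, 9, 11)),
               0.04837206505727084, tolerance = 1e-12)
  # cross-check against base R's conditional exact test (independent code path)
  for (cells in list(c(16, 4, 9, 11), c(3, 7, 8, 2), c(1, 9, 9, 1))) {
    expect_equal(
      fisher_exact_two_sided(do.call(contingency_2x2, as.list(cells))),
      stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
      tolerance = 1e-10
    )
  }
  expect_error(fisher_exact_two_sided(contingency_2x2(0, 0, 3, 4)),
               "zero margin")
})

test_that("Fisher p equals brute-force enumeration on random small tables", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(4:30, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = rep(0.25, 4)))
    if (any(c(cells[1] + cells[2], cells[3] + cells[4],
              cells[1] + cells[3], cells[2] + cells[4]) == 0)) next
    expect_equal(
      fisher_exact_two_sided(do.call(contingency_2x2, as.list(cells))),
      fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
      tolerance = 1e-12
    )
  }
})

test_that("Pearson chi-square matches the closed forms, with and without Yates", {
  t <- contingency_2x2(16, 4, 9, 11)
  plain <- pearson_chi2(t)
  expect_equal(plain$statistic, 40 * (16 * 11 - 4 * 9)^2 / (20 * 20 * 25 * 15))
  expect_equal(plain$statistic, 5.226667, tolerance = 1e-6)
  expect_equal(plain$p, 0.022243, tolerance = 1e-4)
  yates <- pearson_chi2(t, yates = TRUE)
  expect_equal(yates$statistic, 3.84)
  expect_lte(yates$statistic, plain$statistic)
  # perfectly balanced tables carry no signal
  for (k in c(1, 5, 9)) {
    bal <- pearson_chi2(contingency_2x2(k, k, k, k))
    expect_equal(bal$statistic, 0)
    expect_equal(bal$p, 1)
  }
  # Yates over-correction is floored at zero, never negative
  small <- pearson_chi2(contingency_2x2(1, 2, 2, 1), yates = TRUE)
  expect_equal(small$statistic, 0)
  expect_error(pearson_chi2(contingency_2x2(3, 0, 4, 0)), "zero margin")
})

test_that("chi-square upper tail at 1 df agrees with numeric integration", {
  for (x in c(1e-8, 0.1, 0.5, 1, 2.5, 3.84, 5.226667, 10, 25)) {
    expect_equal(pearson_chi2(contingency_2x2(1, 1, 1, 1))$p, 1)
    impl <- degconcord:::chi2_upper_tail_df1(x)
    expect_equal(impl, chi2_tail_oracle(x), tolerance = 1e-10)
    expect_equal(impl, stats::pchisq(x, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("binomial upper tail is exact, monotone, and complementary", {
  expect_equal(binomial_tail(16, 20, 0.5), 6196 / 1048576, tolerance = 1e-14)
  expect_equal(binomial_tail(11, 20, 0.5), 431910 / 1048576, tolerance = 1e-14)
  # symmetry identity for the 11/20 tail
  expect_equal(binomial_tail(11, 20, 0.5),
               (1 - choose(20, 10) / 2^20) / 2, tolerance = 1e-14)
  expect_equal(binomial_tail(0, 20, 0.5), 1)
  tails <- vapply(0:20, binomial_tail, numeric(1), n = 20, p0 = 0.3)
  expect_true(all(diff(tails) <= 0))
  for (k in 1:20) {
    expect_equal(binomial_tail(k, 20, 0.3) +
                   sum(choose(20, 0:(k - 1)) * 0.3^(0:(k - 1)) *
                         0.7^(20:(21 - k))), 1, tolerance = 1e-12)
    expect_equal(binomial_tail(k, 20, 0.3),
                 stats::pbinom(k - 1, 20, 0.3, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(binomial_tail(21, 20, 0.5), "k must satisfy")
})

test_that("the full battery populates every field with coherent values", {
  rep1 <- run_all_tests(contingency_2x2(16, 4, 9, 11))
  expect_s3_class(rep1, "stat_report")
  expect_lte(rep1$fisher_p, 0.05)
  expect_lte(rep1$chi2_p, 0.05)
  expect_lte(rep1$binom_p_domestic, 0.01)
  expect_gte(rep1$binom_p_wild, 0.4)
  expect_lte(rep1$chi2_yates_stat, rep1$chi2_stat)
  probs <- unlist(rep1[c("fisher_p", "chi2_p", "chi2_yates_p",
                         "binom_p_domestic", "binom_p_wild")])
  expect_true(all(probs >= 0 & probs <= 1))

  rep2 <- run_all_tests(contingency_2x2(10, 10, 10, 10))
  expect_equal(rep2$fisher_p, 1)
  expect_equal(rep2$chi2_stat, 0)
  expect_equal(rep2$binom_p_domestic, (1 + choose(20, 10) / 2^20) / 2,
               tolerance = 1e-14)
  expect_equal(rep2$binom_p_wild, rep2$binom_p_domestic)

  expect_error(run_all_tests(contingency_2x2(0, 0, 9, 11)), "zero margin")
})

test_that("a stat report serializes to JSON with table and all seven fields", {
  path <- withr::local_tempfile(fileext = ".json")
  write_stat_report(run_all_tests(contingency_2x2(16, 4, 9, 11)), path)
  got <- jsonlite::read_json(path)
  expect_setequal(names(got), c("fisher_p", "chi2_stat", "chi2_p",
                                "chi2_yates_stat", "chi2_yates_p",
                                "binom_p_domestic", "binom_p_wild", "table"))
  expect_equal(got$table$n_dom_decrease, 16)
  expect_equal(got$fisher_p, 0.04837206505727084, tolerance = 1e-12)
})
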