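# Exact and asymptotic tests for the 2x2 lineage-by-effect table, written
# out from the underlying distributions rather than delegated, so every
# convention (two-sided rule, continuity correction, tail direction) is
# explicit and auditable.

check_margins <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  a <- t$n_dom_decrease; b <- t$n_dom_increase
  c <- t$n_wild_decrease; d <- t$n_wild_increase
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("test undefined: contingency table has a zero margin", call. = FALSE)
  }
  # doubles, so closed-form products can exceed integer range safely
  c(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c), d = as.numeric(d))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditional on both margins, the first cell follows a hypergeometric law.
#' The two-sided p-value is the sum, over the full admissible support, of
#' the point probabilities of all tables whose probability does not exceed
#' that of the observed table (point-probability rule, with a relative
#' tolerance of 1e-7 on the comparison to absorb floating-point noise).
#' Point probabilities are computed from log binomial coefficients.
#'
#' @param t A `contingency_2x2` with all margins positive.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(contingency_2x2(16, 4, 9, 11))
#' @export
fisher_exact_two_sided <- function(t) {
  m <- check_margins(t)
  a <- m["a"]; b <- m["b"]; c <- m["c"]; d <- m["d"]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p_obs <- exp(logp[support == a])
  p <- sum(exp(logp)[exp(logp) <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Pearson chi-square test on a 2x2 table
#'
#' The uncorrected statistic is the closed form
#' `N (ad - bc)^2 / (r1 r2 c1 c2)`; with the Yates continuity correction
#' `|ad - bc|` is reduced by `N/2` (floored at zero) before squaring. The
#' upper-tail p-value of the 1-df chi-square law is evaluated through the
#' complementary error function identity `p = erfc(sqrt(x/2))`.
#'
#' @param t A `contingency_2x2` with all margins positive.
#' @param yates Apply the Yates continuity correction?
#' @return List with `statistic` and `p`.
#' @examples
#' pearson_chi2(contingency_2x2(16, 4, 9, 11))
#' @export
pearson_chi2 <- function(t, yates = FALSE) {
  m <- check_margins(t)
  a <- m["a"]; b <- m["b"]; c <- m["c"]; d <- m["d"]
  n <- a + b + c + d
  dev <- abs(a * d - b * c)
  if (yates) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = unname(stat), p = unname(chi2_upper_tail_df1(stat)))
}

# Upper tail of the chi-square law with one degree of freedom via
# erfc(sqrt(x/2)) = 2 * Phi(-sqrt(x)).
chi2_upper_tail_df1 <- function(x) {
  stopifnot(all(x >= 0))
  2 * stats::pnorm(-sqrt(x))
}

#' Exact upper tail of a binomial distribution
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, summed term by term from exact
#' binomial coefficients (no normal approximation).
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability, in (0, 1).
#' @return The upper-tail probability.
#' @examples
#' binomial_tail(16, 20, 0.5) # = 6196 / 2^20
#' @export
binomial_tail <- function(k, n, p0 = 0.5) {
  stopifnot(length(k) == 1, length(n) == 1, n >= 0, n == round(n),
            k == round(k), p0 > 0, p0 < 1)
  if (k < 0 || k > n) {
    stop("k must satisfy 0 <= k <= n (got k=", k, ", n=", n, ")",
         call. = FALSE)
  }
  j <- k:n
  min(sum(choose(n, j) * p0^j * (1 - p0)^(n - j)), 1)
}

#' Run the full test battery on a 2x2 lineage-by-effect table
#'
#' Computes the two-sided Fisher exact p-value, the Pearson chi-square
#' statistic and p-value with and without the Yates correction, and, for
#' each lineage, the exact one-sided binomial tail of the majority cell
#' against a symmetric null (`p0 = 0.5`): `k` is the larger of the two
#' lineage cells and `n` their sum.
#'
#' @param t A `contingency_2x2` with all margins positive.
#' @return An object of class `stat_report`: a list with `fisher_p`,
#'   `chi2_stat`, `chi2_p`, `chi2_yates_stat`, `chi2_yates_p`,
#'   `binom_p_domestic`, `binom_p_wild`, and the input `table`.
#' @examples
#' run_all_tests(contingency_2x2(16, 4, 9, 11))
#' @export
run_all_tests <- function(t) {
  check_margins(t)
  plain <- pearson_chi2(t, yates = FALSE)
  yates <- pearson_chi2(t, yates = TRUE)
  n_dom <- t$n_dom_decrease + t$n_dom_increase
  n_wild <- t$n_wild_decrease + t$n_wild_increase
  structure(list(
    fisher_p = fisher_exact_two_sided(t),
    chi2_stat = plain$statistic,
    chi2_p = plain$p,
    chi2_yates_stat = yates$statistic,
    chi2_yates_p = yates$p,
    binom_p_domestic = binomial_tail(
      max(t$n_dom_decrease, t$n_dom_increase), n_dom, 0.5),
    binom_p_wild = binomial_tail(
      max(t$n_wild_decrease, t$n_wild_increase), n_wild, 0.5),
    table = t
  ), class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("<stat_report>\n")
  print(as.matrix(x$table))
  cat(sprintf("  Fisher exact (two-sided)  p = %.4g\n", x$fisher_p))
  cat(sprintf("  Pearson chi2              X2 = %.4f, p = %.4g\n",
              x$chi2_stat, x$chi2_p))
  cat(sprintf("  Pearson chi2 (Yates)      X2 = %.4f, p = %.4g\n",
              x$chi2_yates_stat, x$chi2_yates_p))
  cat(sprintf("  Binomial tail, domestic   p = %.4g\n", x$binom_p_domestic))
  cat(sprintf("  Binomial tail, wild       p = %.4g\n", x$binom_p_wild))
  invisible(x)
}

#' Serialize a statistics report (with its input table) to JSON
#'
#' @param report A `stat_report` from [run_all_tests()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_stat_report <- function(report, path) {
  stopifnot(inherits(report, "stat_report"))
  payload <- report[c("fisher_p", "chi2_stat", "chi2_p", "chi2_yates_stat",
                      "chi2_yates_p", "binom_p_domestic", "binom_p_wild")]
  payload$table <- unclass(report$table)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
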