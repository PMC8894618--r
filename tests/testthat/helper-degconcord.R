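# Shared fixtures and independent oracles for the test suite.

# Write a small annotation KB + optional synonyms to temp files and load it.
make_kb <- function(rows, synonyms = NULL, env = parent.frame()) {
  ann_path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  writeLines(c("symbol\teffect_under\teffect_over\tevidence", rows), ann_path)
  syn_path <- NULL
  if (!is.null(synonyms)) {
    syn_path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
    writeLines(c("alias\tcanonical", synonyms), syn_path)
  }
  load_annotation_kb(ann_path, syn_path)
}

# Write a DEG TSV from record lines and read it back.
make_degs <- function(rows, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  header <- "symbol\tdomestic_taxon\twild_taxon\ttissue\tlog2fc\tpvalue\tsource"
  writeLines(c(header, rows), path)
  read_deg_table(path)
}

# One-line DEG row constructor (tissue varies to keep keys unique).
deg_row <- function(symbol, log2fc, tissue = "tissue") {
  paste(symbol, "dom_taxon", "wild_taxon", tissue, log2fc, "0.01", "src",
        sep = "\t")
}

# In-memory divergence-called tibble, bypassing file I/O.
call_tbl <- function(symbols, log2fc) {
  infer_divergence(tibble::tibble(
    record_id = sprintf("r%03d", seq_along(symbols)),
    symbol = symbols,
    domestic_taxon = "d", wild_taxon = "w", tissue = "t",
    log2fc = log2fc, pvalue = NA_real_, source = "s", note = NA_character_
  ))
}

# Independent Fisher oracle: enumerate the full hypergeometric support with
# stats::dhyper (a different computational route than the implementation's
# log-binomial summation) and apply the point-probability two-sided rule.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[support == a]
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

# Independent chi-square upper-tail oracle: numeric integration of the
# 1-df chi-square density.
chi2_tail_oracle <- function(x) {
  if (x == 0) return(1)
  stats::integrate(function(u) stats::dchisq(u, df = 1),
                   lower = x, upper = Inf, rel.tol = 1e-13)$value
}

# All 2x2 tables with positive margins and total at most n_max.
all_tables_upto <- function(n_max) {
  g <- expand.grid(a = 0:n_max, b = 0:n_max, c = 0:n_max, d = 0:n_max)
  g <- g[rowSums(g) >= 1 & rowSums(g) <= n_max, ]
  ok <- (g$a + g$b) > 0 & (g$c + g$d) > 0 & (g$a + g$c) > 0 & (g$b + g$d) > 0
  g[ok, ]
}
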