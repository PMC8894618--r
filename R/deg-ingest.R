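#' Read a table of domestic-versus-wild differentially expressed genes
#'
#' Each row is one differential-expression observation: an animal gene
#' symbol, the domestic and wild taxa compared, the tissue, and the signed
#' log2 fold change of expression in the domestic animal relative to its
#' wild congener (positive = higher in the domestic form). The p-value and
#' citation are carried through from the source study; no significance
#' filtering is applied here — the sign is the datum.
#'
#' @param path DEG TSV with columns `symbol`, `domestic_taxon`, `wild_taxon`,
#'   `tissue`, `log2fc`, `pvalue`, `source` (an optional `note` column is
#'   preserved). `#` comment lines are ignored.
#' @return Tibble of DEG records with a stable `record_id` column
#'   (`deg_0001`, ...) prepended; `log2fc` numeric, `pvalue` numeric with
#'   `NA` for absent values.
#' @examples
#' degs <- read_deg_table(fixture_worked_example()$deg_tsv)
#' degs[degs$symbol == "Ckbl", c("symbol", "log2fc")]
#' @export
read_deg_table <- function(path) {
  raw <- read_tsv_commented(path)
  required <- c("symbol", "domestic_taxon", "wild_taxon", "tissue",
                "log2fc", "pvalue", "source")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("DEG table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(
      record_id = character(), symbol = character(),
      domestic_taxon = character(), wild_taxon = character(),
      tissue = character(), log2fc = numeric(), pvalue = numeric(),
      source = character(), note = character()
    ))
  }
  lines <- attr(raw, "source_line")

  lfc <- suppressWarnings(as.numeric(raw$log2fc))
  bad <- which(is.na(lfc) | !is.finite(lfc))
  if (length(bad) > 0) {
    stop(sprintf("non-numeric or non-finite log2fc '%s' in %s at line %d",
                 raw$log2fc[bad[1]], path, lines[bad[1]]), call. = FALSE)
  }
  pv <- suppressWarnings(as.numeric(raw$pvalue))
  pv[trimws(raw$pvalue) %in% c("", "NA", ".")] <- NA_real_
  oob <- which(!is.na(pv) & (pv <= 0 | pv > 1))
  if (length(oob) > 0) {
    stop(sprintf("pvalue out of (0,1] in %s at line %d", path, lines[oob[1]]),
         call. = FALSE)
  }

  key <- paste(trimws(raw$symbol), trimws(raw$domestic_taxon),
               trimws(raw$wild_taxon), trimws(raw$tissue),
               trimws(raw$source), sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(sprintf("duplicate DEG record (%s) in %s at line %d",
                 raw$symbol[dup[1]], path, lines[dup[1]]), call. = FALSE)
  }

  tibble::tibble(
    record_id = sprintf("deg_%04d", seq_len(nrow(raw))),
    symbol = trimws(raw$symbol),
    domestic_taxon = trimws(raw$domestic_taxon),
    wild_taxon = trimws(raw$wild_taxon),
    tissue = trimws(raw$tissue),
    log2fc = lfc,
    pvalue = pv,
    source = trimws(raw$source),
    note = if ("note" %in% names(raw)) trimws(raw$note) else NA_character_
  )
}

#' Infer per-lineage divergence polarity from the most recent common ancestor
#'
#' The domestic-versus-wild contrast is interpreted as oppositely directed,
#' equivalent expression changes of the two lineages since their unobserved
#' most recent common ancestor: a positive log2 fold change means the
#' domestic lineage went UP and the wild lineage DOWN, a negative one the
#' reverse. A zero fold change carries no polarity.
#'
#' @param degs Tibble of DEG records, as from [read_deg_table()].
#' @param zero_policy What to do with `log2fc == 0`: `"EXCLUDE"` drops the
#'   record (default), `"ERROR"` aborts naming it.
#' @return The input tibble with `domestic_direction` and `wild_direction`
#'   columns (`"UP"`/`"DOWN"`, always opposite); zero-change rows dropped
#'   under `"EXCLUDE"`.
#' @examples
#' degs <- tibble::tibble(
#'   record_id = "r1", symbol = "Ckbl", domestic_taxon = "dog",
#'   wild_taxon = "wolf", tissue = "blood", log2fc = 4.33,
#'   pvalue = NA_real_, source = "x", note = NA_character_
#' )
#' infer_divergence(degs)[, c("domestic_direction", "wild_direction")]
#' @export
infer_divergence <- function(degs, zero_policy = c("EXCLUDE", "ERROR")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(is.data.frame(degs), "log2fc" %in% names(degs))
  if (any(!is.finite(degs$log2fc))) {
    stop("log2fc must be finite for divergence inference", call. = FALSE)
  }
  zero <- degs$log2fc == 0
  if (any(zero)) {
    if (zero_policy == "ERROR") {
      stop("zero log2fc for record ",
           paste(degs$record_id[zero], collapse = ", "),
           ": no divergence direction is inferable", call. = FALSE)
    }
    degs <- degs[!zero, , drop = FALSE]
  }
  degs$domestic_direction <- ifelse(degs$log2fc > 0, "UP", "DOWN")
  degs$wild_direction <- ifelse(degs$log2fc > 0, "DOWN", "UP")
  degs
}
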