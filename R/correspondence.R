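#' Partition divergence-called DEGs by ortholog membership in the KB
#'
#' Each animal DEG symbol is normalized and resolved through the synonym map;
#' records whose symbol is present in the annotation knowledge base are kept,
#' the rest are excluded from further analysis (the exclusion is logged, not
#' an error). Input order is preserved in both partitions.
#'
#' @param calls Tibble of divergence-called DEGs ([infer_divergence()]).
#' @param kb An `annotation_kb`.
#' @return List with `matched` (calls plus a `human_symbol` column) and
#'   `excluded` (calls plus a `reason` column).
#' @export
match_orthologs <- function(calls, kb) {
  stopifnot(is.data.frame(calls), inherits(kb, "annotation_kb"))
  if (nrow(calls) == 0) {
    return(list(
      matched = dplyr::mutate(calls, human_symbol = character(0)),
      excluded = dplyr::mutate(calls, reason = character(0))
    ))
  }
  human <- resolve_symbol(kb, calls$symbol)
  hit <- human %in% kb$entries$symbol
  matched <- calls[hit, , drop = FALSE]
  matched$human_symbol <- human[hit]
  excluded <- calls[!hit, , drop = FALSE]
  excluded$reason <- sprintf("no human ortholog among annotated genes (%s)",
                             human[!hit])
  list(matched = matched, excluded = excluded)
}

#' Score lineage-wise correspondences with human annotation effects
#'
#' For each matched DEG and each lineage (domestic, wild), the lineage's
#' divergence direction selects the codirected human annotation slot —
#' UP reads `effect_over`, DOWN reads `effect_under` — and one correspondence
#' record is emitted iff that effect is annotated (not UNKNOWN). A matched
#' DEG therefore yields 0, 1 or 2 records.
#'
#' @param matched Tibble from [match_orthologs()]`$matched`.
#' @param kb The `annotation_kb` the matching was done against.
#' @return Tibble of correspondence records: `record_id`, `animal_symbol`,
#'   `human_symbol`, `lineage` (`"DOMESTIC"`/`"WILD"`), `direction`
#'   (`"UP"`/`"DOWN"`), `rp_effect` (`"DECREASE"`/`"INCREASE"`), `evidence`.
#' @export
score_correspondences <- function(matched, kb) {
  stopifnot(is.data.frame(matched), inherits(kb, "annotation_kb"))
  template <- tibble::tibble(
    record_id = character(), animal_symbol = character(),
    human_symbol = character(), lineage = character(),
    direction = character(), rp_effect = character(), evidence = character()
  )
  if (nrow(matched) == 0) return(template)
  stopifnot(all(c("domestic_direction", "wild_direction", "human_symbol")
                %in% names(matched)))

  idx <- match(matched$human_symbol, kb$entries$symbol)
  if (anyNA(idx)) {
    stop("matched record(s) with human symbol absent from KB: ",
         paste(matched$human_symbol[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  ann <- kb$entries[idx, , drop = FALSE]

  effect_for <- function(direction) {
    ifelse(direction == "UP", ann$effect_over, ann$effect_under)
  }
  one_lineage <- function(lineage, direction) {
    eff <- effect_for(direction)
    keep <- eff != "UNKNOWN"
    tibble::tibble(
      record_id = matched$record_id[keep],
      animal_symbol = matched$symbol[keep],
      human_symbol = matched$human_symbol[keep],
      lineage = lineage,
      direction = direction[keep],
      rp_effect = eff[keep],
      evidence = ann$evidence[keep]
    )
  }
  out <- dplyr::bind_rows(
    one_lineage("DOMESTIC", matched$domestic_direction),
    one_lineage("WILD", matched$wild_direction)
  )
  # stable order: by input record, domestic before wild
  out[order(match(out$record_id, matched$record_id),
            match(out$lineage, c("DOMESTIC", "WILD"))), , drop = FALSE]
}

#' Tally correspondence records into the 2x2 lineage-by-effect table
#'
#' @param records Tibble from [score_correspondences()].
#' @return An object of class `contingency_2x2`: a list with integer cells
#'   `n_dom_decrease`, `n_dom_increase`, `n_wild_decrease`,
#'   `n_wild_increase`.
#' @examples
#' recs <- tibble::tibble(lineage = c("DOMESTIC", "WILD"),
#'                        rp_effect = c("DECREASE", "INCREASE"))
#' build_contingency(recs)
#' @export
build_contingency <- function(records) {
  stopifnot(is.data.frame(records))
  cell <- function(lineage, effect) {
    if (nrow(records) == 0) return(0L)
    sum(records$lineage == lineage & records$rp_effect == effect)
  }
  contingency_2x2(
    n_dom_decrease = cell("DOMESTIC", "DECREASE"),
    n_dom_increase = cell("DOMESTIC", "INCREASE"),
    n_wild_decrease = cell("WILD", "DECREASE"),
    n_wild_increase = cell("WILD", "INCREASE")
  )
}

#' Construct a 2x2 lineage-by-effect contingency table
#'
#' @param n_dom_decrease,n_dom_increase,n_wild_decrease,n_wild_increase
#'   Non-negative integer cell counts (domestic/wild lineage crossed with
#'   reproductive-potential DECREASE/INCREASE).
#' @return A `contingency_2x2` object.
#' @export
contingency_2x2 <- function(n_dom_decrease, n_dom_increase,
                            n_wild_decrease, n_wild_increase) {
  cells <- c(n_dom_decrease, n_dom_increase, n_wild_decrease, n_wild_increase)
  stopifnot(length(cells) == 4, all(is.finite(cells)),
            all(cells >= 0), all(cells == round(cells)))
  structure(list(
    n_dom_decrease = as.integer(n_dom_decrease),
    n_dom_increase = as.integer(n_dom_increase),
    n_wild_decrease = as.integer(n_wild_decrease),
    n_wild_increase = as.integer(n_wild_increase)
  ), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- as.matrix(x)
  cat("<contingency_2x2> lineage x reproductive-potential effect\n")
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$n_dom_decrease, x$n_dom_increase,
           x$n_wild_decrease, x$n_wild_increase),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("domestic", "wild"), c("decrease", "increase")))
}
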