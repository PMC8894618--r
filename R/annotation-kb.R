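#' @keywords internal
"_PACKAGE"

# Effect levels on the reproductive-potential axis.
RP_EFFECTS <- c("DECREASE", "INCREASE", "UNKNOWN")

#' Normalize a gene symbol for ortholog lookup
#'
#' Animal gene symbols are reported in mixed case and occasionally carry a
#' trailing species decoration (e.g. `"Apoa1_CAVPO"`). Matching against the
#' human annotation list is done on a canonical form: whitespace stripped,
#' a single trailing `_TOKEN` decoration removed, and the remainder
#' uppercased. No fuzzy matching is ever attempted; family-level aliases
#' (e.g. avian hemoglobin subunits onto human `HBB`/`HBD`) must be supplied
#' through an explicit synonym table.
#'
#' @param x Character vector of raw symbol tokens.
#' @return Character vector of normalized (uppercase) symbols.
#' @examples
#' normalize_symbol(c(" Apoa1 ", "cyp17a1", "Apoa1_CAVPO"))
#' @export
normalize_symbol <- function(x) {
  stopifnot(is.character(x))
  x <- trimws(x)
  x <- sub("_[A-Za-z0-9]+$", "", x)
  toupper(x)
}

parse_effect <- function(x, path, lines) {
  eff <- toupper(trimws(x))
  bad <- which(!eff %in% RP_EFFECTS)
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown effect token '%s' in %s at line %d (expected decrease/increase/unknown)",
      x[bad[1]], path, lines[bad[1]]
    ), call. = FALSE)
  }
  eff
}

#' Load the human reproductive-potential annotation knowledge base
#'
#' Reads a curated table of human genes annotated, per expression direction,
#' with the effect of that direction on human reproductive potential:
#' `effect_under` is the annotated consequence of reduced expression,
#' `effect_over` of elevated expression, each one of
#' `decrease`/`increase`/`unknown` (case-insensitive). An optional synonym
#' table maps animal-symbol aliases onto canonical human symbols; this is how
#' e.g. species-specific hemoglobin subunit names resolve to `HBB`/`HBD`.
#'
#' @param path Path to an annotation TSV with columns `symbol`,
#'   `effect_under`, `effect_over`, `evidence`. Lines starting with `#` are
#'   ignored.
#' @param synonyms_path Optional path to a synonym TSV with columns `alias`,
#'   `canonical`.
#' @return An object of class `annotation_kb`: a list with `entries` (tibble,
#'   one row per gene, normalized symbols) and `synonyms` (named character
#'   vector, alias -> canonical).
#' @examples
#' kb <- load_annotation_kb(
#'   fixture_worked_example()$annotation_tsv,
#'   fixture_worked_example()$synonym_tsv
#' )
#' nrow(kb$entries)
#' @export
load_annotation_kb <- function(path, synonyms_path = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  raw <- read_tsv_commented(path)
  required <- c("symbol", "effect_under", "effect_over", "evidence")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("annotation table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  if (nrow(raw) == 0) {
    entries <- tibble::tibble(
      symbol = character(), effect_under = character(),
      effect_over = character(), evidence = character(),
      usable = logical()
    )
  } else {
    lines <- attr(raw, "source_line")
    symbol <- normalize_symbol(as.character(raw$symbol))
    empty <- which(symbol == "")
    if (length(empty) > 0) {
      stop(sprintf("malformed row (empty symbol) in %s at line %d",
                   path, lines[empty[1]]), call. = FALSE)
    }
    dup <- which(duplicated(symbol))
    if (length(dup) > 0) {
      stop(sprintf("duplicate symbol '%s' in %s at line %d",
                   symbol[dup[1]], path, lines[dup[1]]), call. = FALSE)
    }
    entries <- tibble::tibble(
      symbol = symbol,
      effect_under = parse_effect(as.character(raw$effect_under), path, lines),
      effect_over = parse_effect(as.character(raw$effect_over), path, lines),
      evidence = as.character(raw$evidence)
    )
    # entries with neither direction known are loadable but flagged
    entries$usable <- entries$effect_under != "UNKNOWN" |
      entries$effect_over != "UNKNOWN"
  }

  synonyms <- character(0)
  if (!is.null(synonyms_path)) {
    syn <- read_tsv_commented(synonyms_path)
    if (!all(c("alias", "canonical") %in% names(syn))) {
      stop("synonym table must have columns alias, canonical", call. = FALSE)
    }
    if (nrow(syn) > 0) {
      alias <- normalize_symbol(as.character(syn$alias))
      canonical <- normalize_symbol(as.character(syn$canonical))
      clash <- tapply(canonical, alias, function(v) length(unique(v)))
      if (any(clash > 1)) {
        stop("alias '", names(clash)[clash > 1][1],
             "' maps to more than one canonical symbol", call. = FALSE)
      }
      keep <- !duplicated(alias)
      alias <- alias[keep]
      canonical <- canonical[keep]
      orphan <- setdiff(canonical, entries$symbol)
      if (length(orphan) > 0) {
        stop("synonym target(s) absent from annotation table: ",
             paste(orphan, collapse = ", "), call. = FALSE)
      }
      synonyms <- stats::setNames(canonical, alias)
    }
  }

  structure(list(entries = entries, synonyms = synonyms),
            class = "annotation_kb")
}

#' Look up a raw symbol token in the knowledge base
#'
#' Normalizes the token ([normalize_symbol()]), resolves it through the
#' synonym map, then queries the annotation entries. Absence is a valid
#' outcome (the corresponding animal DEG is simply excluded downstream).
#'
#' @param kb An `annotation_kb`.
#' @param token Raw symbol string (length 1).
#' @return A one-row tibble with the annotation, or `NULL` when not found.
#' @export
lookup <- function(kb, token) {
  stopifnot(inherits(kb, "annotation_kb"), length(token) == 1)
  sym <- resolve_symbol(kb, token)
  hit <- kb$entries[kb$entries$symbol == sym, , drop = FALSE]
  if (nrow(hit) == 0) NULL else hit
}

# Vectorized normalize + synonym resolution (no entry query).
resolve_symbol <- function(kb, tokens) {
  sym <- normalize_symbol(as.character(tokens))
  if (length(kb$synonyms) > 0) {
    hit <- match(sym, names(kb$synonyms))
    sym[!is.na(hit)] <- unname(kb$synonyms[hit[!is.na(hit)]])
  }
  sym
}

#' Serialize an annotation knowledge base back to TSV
#'
#' Writes the four annotation columns in the dialect [load_annotation_kb()]
#' reads, so that a load/write cycle round-trips field-for-field.
#'
#' @param kb An `annotation_kb`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_kb <- function(kb, path) {
  stopifnot(inherits(kb, "annotation_kb"))
  out <- kb$entries[, c("symbol", "effect_under", "effect_over", "evidence")]
  readr::write_tsv(out, path)
  invisible(path)
}

#' @export
print.annotation_kb <- function(x, ...) {
  cat(sprintf(
    "<annotation_kb> %d gene(s), %d synonym(s), %d flagged unusable\n",
    nrow(x$entries), length(x$synonyms), sum(!x$entries$usable)
  ))
  invisible(x)
}

# Shared TSV reader: tab-separated, '#' comment lines ignored, all columns
# read as character so numeric validation stays in the caller's hands.
# Records the 1-based physical line number of each surviving row in
# attr "source_line" so error messages can name the offending line.
read_tsv_commented <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  all_lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*#", all_lines) & nzchar(trimws(all_lines))
  phys <- which(keep)
  if (length(phys) == 0) stop("no header row in ", path, call. = FALSE)
  df <- utils::read.delim(
    text = paste(all_lines[keep], collapse = "\n"),
    colClasses = "character", check.names = FALSE,
    na.strings = NULL, quote = "", stringsAsFactors = FALSE
  )
  out <- tibble::as_tibble(df)
  attr(out, "source_line") <- phys[-1]
  out
}
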