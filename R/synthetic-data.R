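# Synthetic DEG corpora with known ground truth. The generator works
# backwards from the quantity the analysis estimates: it samples, per
# matched gene, the (lineage, reproductive-potential effect) assignment
# directly, then constructs a signed log2 fold change and a per-direction
# human annotation that make the real pipeline recover exactly that
# assignment. Only the sign of the fold change matters downstream, so
# magnitudes are cosmetic (exponential law).

#' Configuration for the synthetic DEG corpus generator
#'
#' @param n_degs Number of animal DEG records to generate (>= 1).
#' @param match_rate Probability a DEG's symbol has a human ortholog in the
#'   generated knowledge base.
#' @param theta_dom Probability that a matched DEG's domestic-lineage
#'   correspondence lands in the reproductive-potential DECREASE column.
#' @param theta_wild Same for the wild lineage (sampled independently).
#' @param annot_missing Probability that a given direction slot of a matched
#'   gene's annotation is UNKNOWN (that lineage then contributes no record).
#' @param lfc_scale Scale (mean) of the exponential law for |log2fc|.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_degs = 40, match_rate = 0.7,
                              theta_dom = 0.8, theta_wild = 0.45,
                              annot_missing = 0.1, lfc_scale = 1.5,
                              seed = 1L) {
  probs <- c(match_rate = match_rate, theta_dom = theta_dom,
             theta_wild = theta_wild, annot_missing = annot_missing)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1 | !is.finite(probs)],
               collapse = ", "), call. = FALSE)
  }
  stopifnot(n_degs >= 1, n_degs == round(n_degs),
            is.finite(lfc_scale), lfc_scale > 0)
  structure(list(
    n_degs = as.integer(n_degs), match_rate = match_rate,
    theta_dom = theta_dom, theta_wild = theta_wild,
    annot_missing = annot_missing, lfc_scale = lfc_scale,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Generate a synthetic DEG bundle with ground truth
#'
#' Produces a DEG table, an annotation knowledge base and a (header-only)
#' synonym table in the dialects the ingest functions read, together with
#' the ground-truth correspondence assignments and the 2x2 table they imply.
#' Running the real pipeline on the generated inputs reproduces the truth
#' table exactly, for every seed. Two calls with the same configuration
#' write byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, `degs.tsv`, `annotations.tsv`,
#'   `synonyms.tsv` and `truth.json` are written there.
#' @param forced_effects Optional list with character vectors `dom` and/or
#'   `wild` (values `"DECREASE"`/`"INCREASE"`, recycled over the matched
#'   genes) overriding the Bernoulli effect sampling — used to pin an exact
#'   contingency composition.
#' @return List with `deg` (tibble, DEG-table columns), `kb`
#'   (an `annotation_kb`), `truth` (list: `expected_table` as
#'   `contingency_2x2`, `assignments` tibble), and `paths` (when `dir`
#'   given).
#' @export
generate_synthetic_bundle <- function(config, dir = NULL,
                                      forced_effects = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_degs

  matched <- stats::runif(n) < config$match_rate
  n_m <- sum(matched)
  symbol <- ifelse(matched,
                   sprintf("Sg%04d", seq_len(n)),
                   sprintf("Zzun%04d", seq_len(n)))

  dom_effect <- wild_effect <- rep(NA_character_, n)
  dom_dir <- rep(NA_character_, n)
  lfc <- numeric(n)
  dom_known <- wild_known <- rep(FALSE, n)

  if (n_m > 0) {
    draw_eff <- function(theta, forced) {
      if (is.null(forced)) {
        ifelse(stats::runif(n_m) < theta, "DECREASE", "INCREASE")
      } else {
        stopifnot(all(forced %in% c("DECREASE", "INCREASE")))
        rep_len(forced, n_m)
      }
    }
    dom_effect[matched] <- draw_eff(config$theta_dom, forced_effects$dom)
    wild_effect[matched] <- draw_eff(config$theta_wild, forced_effects$wild)
    dom_dir[matched] <- ifelse(stats::runif(n_m) < 0.5, "UP", "DOWN")
    mag <- round(stats::rexp(n_m, rate = 1 / config$lfc_scale) + 1e-4, 4)
    lfc[matched] <- ifelse(dom_dir[matched] == "UP", mag, -mag)
    dom_known[matched] <- stats::runif(n_m) >= config$annot_missing
    wild_known[matched] <- stats::runif(n_m) >= config$annot_missing
  }
  lfc[!matched] <- round(stats::rexp(n - n_m, rate = 1 / config$lfc_scale) +
                           1e-4, 4) *
    ifelse(stats::runif(n - n_m) < 0.5, 1, -1)

  deg <- tibble::tibble(
    record_id = sprintf("deg_%04d", seq_len(n)),
    symbol = symbol,
    domestic_taxon = "Simulus domesticus",
    wild_taxon = "Simulus ferus",
    tissue = "simulated tissue",
    log2fc = lfc,
    pvalue = 0.001,
    source = "synthetic generator",
    note = NA_character_
  )

  # annotation slots: the domestic direction's slot carries the domestic
  # effect, the (opposite) wild direction's slot the wild effect
  ann <- tibble::tibble(
    symbol = toupper(symbol[matched]),
    effect_under = NA_character_, effect_over = NA_character_,
    evidence = "synthetic generator"
  )
  if (n_m > 0) {
    up_dom <- dom_dir[matched] == "UP"
    de <- dom_effect[matched]; we <- wild_effect[matched]
    dk <- dom_known[matched]; wk <- wild_known[matched]
    ann$effect_over <- ifelse(up_dom, ifelse(dk, de, "UNKNOWN"),
                              ifelse(wk, we, "UNKNOWN"))
    ann$effect_under <- ifelse(up_dom, ifelse(wk, we, "UNKNOWN"),
                               ifelse(dk, de, "UNKNOWN"))
  }
  ann$usable <- if (n_m > 0) ann$effect_under != "UNKNOWN" |
    ann$effect_over != "UNKNOWN" else logical(0)
  kb <- structure(list(entries = ann, synonyms = character(0)),
                  class = "annotation_kb")

  assignments <- tibble::tibble(
    record_id = deg$record_id,
    matched = matched,
    dom_effect = ifelse(dom_known, dom_effect, NA_character_),
    wild_effect = ifelse(wild_known, wild_effect, NA_character_)
  )
  truth <- list(
    expected_table = contingency_2x2(
      n_dom_decrease = sum(assignments$dom_effect == "DECREASE", na.rm = TRUE),
      n_dom_increase = sum(assignments$dom_effect == "INCREASE", na.rm = TRUE),
      n_wild_decrease = sum(assignments$wild_effect == "DECREASE", na.rm = TRUE),
      n_wild_increase = sum(assignments$wild_effect == "INCREASE", na.rm = TRUE)
    ),
    assignments = assignments
  )

  out <- list(deg = deg, kb = kb, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      deg_tsv = file.path(dir, "degs.tsv"),
      annotation_tsv = file.path(dir, "annotations.tsv"),
      synonym_tsv = file.path(dir, "synonyms.tsv"),
      truth_json = file.path(dir, "truth.json")
    )
    readr::write_tsv(deg[, setdiff(names(deg), "record_id")], paths$deg_tsv)
    write_annotation_kb(kb, paths$annotation_tsv)
    readr::write_tsv(tibble::tibble(alias = character(),
                                    canonical = character()),
                     paths$synonym_tsv)
    jsonlite::write_json(
      list(expected_table = unclass(truth$expected_table),
           assignments = truth$assignments),
      paths$truth_json, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
    out$paths <- paths
  }
  out
}

#' Monte-Carlo calibration of the Fisher test's type-I error
#'
#' Under a null configuration (`theta_dom == theta_wild`) the lineage-by-
#' effect table carries no real contrast; this runs the generator and the
#' full correspondence pipeline `n_reps` times (per-replicate seeds derived
#' from the master seed by unit increments) and reports the fraction of
#' replicates whose two-sided Fisher p-value falls at or below `alpha`.
#' Replicates whose table has a zero margin (Fisher undefined) count as
#' non-rejections and are tallied separately.
#'
#' @param config A [simulation_config()] with `theta_dom == theta_wild`.
#' @param n_reps Number of replicates.
#' @param alpha Nominal level.
#' @return List with `rate`, `n_reps`, `n_rejected`, `n_undefined`.
#' @export
calibrate_type1 <- function(config, n_reps = 200, alpha = 0.05) {
  stopifnot(inherits(config, "simulation_config"),
            n_reps >= 1, alpha >= 0, alpha <= 1)
  if (config$theta_dom != config$theta_wild) {
    stop("type-I calibration requires theta_dom == theta_wild", call. = FALSE)
  }
  rejected <- logical(n_reps)
  undefined <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    bundle <- generate_synthetic_bundle(cfg_i)
    calls <- infer_divergence(bundle$deg)
    parts <- match_orthologs(calls, bundle$kb)
    tab <- build_contingency(score_correspondences(parts$matched, bundle$kb))
    p <- tryCatch(fisher_exact_two_sided(tab), error = function(e) NA_real_)
    undefined[i] <- is.na(p)
    rejected[i] <- !is.na(p) && p <= alpha
  }
  list(rate = mean(rejected), n_reps = n_reps,
       n_rejected = sum(rejected), n_undefined = sum(undefined))
}
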