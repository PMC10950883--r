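# End-to-end orchestration: spectral validation over a pair table, and the
# full simulate -> catalog -> reports -> validation run with a
# machine-readable report.

#' Run spectral validation over a pair table
#'
#' Compares every (experimental, synthetic) spectrum pair and summarises
#' the pass fraction at the similarity threshold.
#'
#' @param pairs Tibble with `pair_id`, `experimental_id`, `synthetic_id`
#'   (e.g. from [generate_validation_set()]).
#' @param spectra Spectra tibble holding all referenced spectra.
#' @param params A [match_params()] object.
#' @return A `validation_summary`: list with `results` (tibble: pair id,
#'   score, matched count, slots, passed), `n_pairs`, `n_passed`,
#'   `pass_fraction`, `params`. Has [tidy()] and [glance()] methods.
#' @export
run_validation <- function(pairs, spectra, params = match_params()) {
  idx <- match(c(pairs$experimental_id, pairs$synthetic_id),
               spectra$spectrum_id)
  if (anyNA(idx)) {
    bad <- c(pairs$experimental_id, pairs$synthetic_id)[is.na(idx)][1]
    pair <- pairs$pair_id[
      pairs$experimental_id == bad | pairs$synthetic_id == bad][1]
    stop("spectrum '", bad, "' referenced by pair '", pair,
         "' not found", call. = FALSE)
  }
  results <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- spectra$peaks[[match(pairs$experimental_id[i],
                              spectra$spectrum_id)]]
    b <- spectra$peaks[[match(pairs$synthetic_id[i],
                              spectra$spectrum_id)]]
    res <- compare_spectra(a, b, params)
    tibble::tibble(pair_id = pairs$pair_id[i], score = res$score,
                   matched_count = res$matched_count,
                   n_slots = res$n_slots, passed = res$passed)
  })
  structure(list(
    results = results,
    n_pairs = nrow(results),
    n_passed = sum(results$passed),
    pass_fraction = mean(results$passed),
    params = params
  ), class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf(
    "<validation_summary> %d/%d pairs passed (%.1f%%) at threshold %.2f\n",
    x$n_passed, x$n_pairs, 100 * x$pass_fraction, x$params$threshold))
  invisible(x)
}

#' @export
tidy.validation_summary <- function(x, ...) {
  x$results
}

#' @export
glance.validation_summary <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, n_passed = x$n_passed,
                 pass_fraction = x$pass_fraction,
                 threshold = x$params$threshold)
}

#' Score distributions of a validation run
#'
#' @param object A `validation_summary`.
#' @param truth Optional pair tibble with `pair_id` and `is_decoy` to
#'   colour true pairs and decoys.
#' @param ... Unused.
#' @return A ggplot histogram of cosine scores with the threshold marked.
#' @export
autoplot.validation_summary <- function(object, truth = NULL, ...) {
  d <- object$results
  if (!is.null(truth)) {
    d <- dplyr::left_join(d, truth[, c("pair_id", "is_decoy")],
                          by = "pair_id")
    d$pair_type <- ifelse(d$is_decoy, "decoy", "true pair")
  } else {
    d$pair_type <- "pair"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$pair_type)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            position = "identity", alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$params$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "Cosine similarity score", y = "Pairs", fill = NULL,
                  title = sprintf("%d/%d pairs over %.2f",
                                  object$n_passed, object$n_pairs,
                                  object$params$threshold)) +
    ggplot2::theme_minimal()
}

#' Run the full analysis pipeline
#'
#' Simulates an enrichment experiment (or ingests supplied PSMs and
#' FASTA), builds the nitro-site catalog, computes N-terminal fractions,
#' cross-antibody overlaps, union counts and motif matrices, runs spectral
#' validation on a paired set, and returns a run report whose per-stage
#' counts reconcile. Identical config and seed give identical reports.
#'
#' @param cfg A [sim_config()]; ignored for the simulation stage when
#'   `psms` and `fasta` are supplied (ingest mode) but still supplies
#'   analysis parameters.
#' @param psms,fasta Optional experimental inputs (validated PSM table
#'   and named sequence vector). When `NULL`, data are simulated from
#'   `cfg`.
#' @param n_pairs Validation pairs to generate (simulation mode only;
#'   set to 0 to skip validation).
#' @param decoy_fraction Planted decoy fraction for validation pairs.
#' @param params A [match_params()] object.
#' @param motif_k Motif window half-width.
#' @param out_dir Optional directory; when given, catalog, summary tables,
#'   MGFs and the JSON report are written there.
#' @return A `nitrocat_report` list: `counts` (per-stage reconciliation),
#'   `catalog`, `nterm`, `overlap` (per mode), `union_counts`, `motif`
#'   (per mode), `validation`, `pairs`, `outputs` (files written).
#' @export
run_full <- function(cfg = sim_config(), psms = NULL, fasta = NULL,
                     n_pairs = 100L, decoy_fraction = 0.3,
                     params = match_params(), motif_k = 7L,
                     out_dir = NULL) {
  simulated <- is.null(psms)
  if (simulated) {
    sim <- simulate_experiment(cfg)
    fasta <- sim$proteome
    raw_psms <- sim$psms
    pool <- sim$pool
  } else {
    if (is.null(fasta)) {
      stop("ingest mode needs both psms and fasta", call. = FALSE)
    }
    raw_psms <- psms
    pool <- NULL
  }
  psms_val <- validate_psm_table(raw_psms, fasta = fasta)
  catalog <- build_catalog(psms_val, fasta)
  nterm <- nterm_fraction(catalog)
  modes <- unique(catalog$mode)
  overlaps <- purrr::map(
    stats::setNames(modes, modes),
    function(m) overlap_summary(catalog, unit = "protein", mode = m))
  unions <- union_catalog(catalog)
  bg <- residue_frequencies(fasta)
  motifs <- purrr::map(
    stats::setNames(modes, modes),
    function(m) {
      w <- site_windows(catalog[catalog$mode == m, ], fasta, k = motif_k)
      motif_matrix(w, bg)
    })
  validation <- NULL
  pairs <- NULL
  if (simulated && n_pairs > 0) {
    vset <- generate_validation_set(cfg, n_pairs = n_pairs,
                                    decoy_fraction = decoy_fraction,
                                    pool = pool)
    validation <- run_validation(vset$pairs, vset$spectra, params)
    pairs <- vset$pairs
  }
  counts <- tibble::tibble(
    stage = c("psm_input", "psm_valid", "psm_rejected",
              "catalog_sites", "catalog_rejected"),
    n = c(nrow(raw_psms), nrow(psms_val), nrow(psm_rejections(psms_val)),
          nrow(catalog), nrow(psm_rejections(catalog)))
  )
  report <- structure(list(
    counts = counts,
    catalog = catalog,
    nterm = nterm,
    overlap = overlaps,
    union_counts = unions,
    motif = motifs,
    validation = validation,
    pairs = pairs,
    params = params,
    seed = cfg$seed,
    outputs = character(0)
  ), class = "nitrocat_report")
  if (!is.null(out_dir)) {
    report$outputs <- write_report_outputs(report, out_dir,
                                           fasta = fasta)
  }
  report
}

write_report_outputs <- function(report, out_dir, fasta = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  w <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(x, path)
    files <<- c(files, path)
  }
  w(report$catalog, "catalog.tsv")
  w(report$nterm, "nterm_fractions.tsv")
  w(report$union_counts, "union_counts.tsv")
  for (m in names(report$overlap)) {
    w(tidy(report$overlap[[m]]), paste0("overlap_", m, ".tsv"))
  }
  for (m in names(report$motif)) {
    w(tidy(report$motif[[m]]), paste0("motif_", m, ".tsv"))
  }
  if (!is.null(report$validation)) {
    w(tidy(report$validation), "validation_scores.tsv")
    w(report$pairs, "validation_pairs.tsv")
  }
  if (!is.null(fasta)) {
    path <- file.path(out_dir, "proteome.fasta")
    write_fasta(fasta, path)
    files <- c(files, path)
  }
  json <- list(
    seed = report$seed,
    counts = report$counts,
    nterm = report$nterm,
    union_counts = report$union_counts,
    validation = if (!is.null(report$validation))
      glance(report$validation) else NULL,
    files = basename(files)
  )
  path <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  c(files, path)
}

#' @export
print.nitrocat_report <- function(x, ...) {
  cat("<nitrocat_report>\n")
  cat("counts:\n")
  print(x$counts)
  if (!is.null(x$validation)) {
    print(x$validation)
  }
  invisible(x)
}
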