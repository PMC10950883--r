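# Cross-antibody overlap: exact region counts over all 2^A - 1 antibody
# combinations, Venn-style.

#' Cross-antibody overlap summary
#'
#' Computes, for one enrichment mode, the set of distinct units (proteins
#' or peptidoforms) captured by each antibody and the exact count of every
#' exclusive region of the Venn diagram (each of the 2^A - 1 non-empty
#' antibody combinations), plus all intersection counts and the union.
#' Exclusive region counts always sum to the union (inclusion-exclusion
#' consistency by construction).
#'
#' @param catalog Catalog tibble from [build_catalog()].
#' @param unit `"protein"` or `"peptidoform"`.
#' @param mode Enrichment mode to restrict to (`"protein_level"`,
#'   `"peptide_level"`), or `NULL` for the whole catalog.
#' @return An `overlap_summary` object: list with `sets` (named list of
#'   unit vectors per antibody), `regions` (tibble: `combination`,
#'   `n_antibodies`, `exclusive_count`, `intersection_count`), `union_count`,
#'   `unit`, `mode`. Has [tidy()] and [glance()] methods.
#' @export
overlap_summary <- function(catalog, unit = c("protein", "peptidoform"),
                            mode = NULL) {
  unit <- match.arg(unit)
  if (!is.null(mode)) {
    catalog <- catalog[catalog$mode == mode, ]
  }
  antibodies <- sort(unique(catalog$antibody))
  if (length(antibodies) < 2) {
    stop("overlap needs at least 2 antibodies, found ",
         length(antibodies), call. = FALSE)
  }
  col <- if (unit == "protein") "protein" else "peptidoform"
  sets <- purrr::map(
    stats::setNames(antibodies, antibodies),
    function(ab) unique(catalog[[col]][catalog$antibody == ab])
  )
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) {
    membership <- matrix(membership, nrow = 1,
                         dimnames = list(NULL, antibodies))
  }
  combos <- purrr::map(seq_along(antibodies),
                       ~ utils::combn(antibodies, .x, simplify = FALSE))
  combos <- purrr::flatten(combos)
  regions <- purrr::map_dfr(combos, function(cmb) {
    inside <- rowSums(membership[, cmb, drop = FALSE]) == length(cmb)
    outside <- if (length(cmb) == length(antibodies)) {
      rep(TRUE, length(universe))
    } else {
      rowSums(membership[, setdiff(antibodies, cmb), drop = FALSE]) == 0
    }
    tibble::tibble(
      combination = paste(cmb, collapse = "&"),
      n_antibodies = length(cmb),
      exclusive_count = sum(inside & outside),
      intersection_count = sum(inside)
    )
  })
  structure(list(
    sets = sets,
    regions = regions,
    union_count = length(universe),
    unit = unit,
    mode = mode %||% "all"
  ), class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  full <- x$regions$intersection_count[
    x$regions$n_antibodies == length(x$sets)]
  cat(sprintf(
    "<overlap_summary> %d distinct %ss (%s mode); shared by all %d antibodies: %d\n",
    x$union_count, x$unit, x$mode, length(x$sets), full))
  invisible(x)
}

#' @export
tidy.overlap_summary <- function(x, ...) {
  x$regions
}

#' @export
glance.overlap_summary <- function(x, ...) {
  full <- x$regions$intersection_count[
    x$regions$n_antibodies == length(x$sets)]
  tibble::tibble(
    unit = x$unit, mode = x$mode, n_antibodies = length(x$sets),
    union_count = x$union_count, all_antibody_count = full,
    shared_fraction = full / x$union_count
  )
}

#' Bar chart of exclusive overlap regions
#'
#' @param object An `overlap_summary`.
#' @param ... Unused.
#' @return A ggplot of exclusive region counts, ordered by the number of
#'   antibodies in the combination.
#' @export
autoplot.overlap_summary <- function(object, ...) {
  d <- object$regions
  d$combination <- stats::reorder(d$combination,
                                  d$n_antibodies * 1e6 + d$exclusive_count)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$combination,
                                  y = .data$exclusive_count,
                                  fill = factor(.data$n_antibodies))) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste("Distinct", object$unit, "count"),
                  fill = "Antibodies",
                  title = sprintf("Overlap of %ss across antibodies (%s)",
                                  object$unit, object$mode)) +
    ggplot2::theme_minimal()
}
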