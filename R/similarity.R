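# Spectral validation: base-peak filtering, tolerance peak matching into
# aligned intensity vectors u and v, and the cosine score
#   cos(theta) = sum(u_i v_i) / sqrt(sum(u_i^2) * sum(v_i^2)).

#' Spectral comparison parameters
#'
#' @param tolerance Peak-matching tolerance in Da (default 0.01).
#' @param filter Base-peak filter fraction: peaks are kept only when their
#'   intensity is strictly over this fraction of the base peak
#'   (default 0.02, i.e. 2%).
#' @param threshold Similarity acceptance threshold; a comparison passes
#'   when the score strictly exceeds it (default 0.7).
#' @return A `match_params` list.
#' @export
match_params <- function(tolerance = 0.01, filter = 0.02, threshold = 0.7) {
  stopifnot(tolerance > 0, filter >= 0, filter < 1,
            threshold >= 0, threshold <= 1)
  structure(list(tolerance = tolerance, filter = filter,
                 threshold = threshold), class = "match_params")
}

peaks_of <- function(x) {
  if (is.data.frame(x) && all(c("mz", "intensity") %in% names(x))) {
    return(tibble::as_tibble(x)[, c("mz", "intensity")])
  }
  if (is.data.frame(x) && "peaks" %in% names(x) && nrow(x) == 1) {
    return(tibble::as_tibble(x$peaks[[1]]))
  }
  if (is.list(x) && !is.null(x$peaks)) {
    return(tibble::as_tibble(x$peaks))
  }
  stop("cannot interpret input as a spectrum (need mz/intensity columns, ",
       "a one-row spectra table, or a list with $peaks)", call. = FALSE)
}

#' Normalize to relative intensity and apply the base-peak filter
#'
#' Intensities are rescaled so the base peak is 100, then peaks whose
#' relative intensity is strictly greater than `100 * filter` are kept
#' (at 2% that keeps peaks over 2% of the base peak; a peak at exactly
#' the boundary is removed). The base peak itself is always retained and
#' m/z order is preserved.
#'
#' @param spectrum A peaks data frame (`mz`, `intensity`), a one-row
#'   spectra-table row, or a list with a `$peaks` element.
#' @param params A [match_params()] object.
#' @return A tibble of filtered peaks with relative intensities.
#' @export
normalize_filter_peaks <- function(spectrum, params = match_params()) {
  p <- peaks_of(spectrum)
  if (nrow(p) == 0 || all(p$intensity <= 0)) {
    stop("spectrum has no positive-intensity peaks", call. = FALSE)
  }
  base <- max(p$intensity)
  p$intensity <- 100 * p$intensity / base
  keep <- p$intensity > 100 * params$filter | p$intensity == 100
  p[keep, ]
}

#' Match peaks between two spectra into aligned vectors
#'
#' One-to-one matching: candidate pairs within `tolerance` Da are accepted
#' greedily in ascending |delta m/z| order (ties broken by lower m/z), so
#' the matching is deterministic. Unmatched peaks of either spectrum
#' become slots with a zero on the other side; every input peak occupies
#' exactly one slot.
#'
#' @param a,b Spectra (peaks data frames or spectra-table rows), normally
#'   already normalized and filtered.
#' @param params A [match_params()] object.
#' @return A `peak_alignment` tibble with columns `mz_a`, `mz_b`, `u`
#'   (intensity from `a`), `v` (intensity from `b`), and `matched`;
#'   attributes `matched_count` and `tolerance`.
#' @export
match_peaks <- function(a, b, params = match_params()) {
  pa <- peaks_of(a)
  pb <- peaks_of(b)
  if (nrow(pa) == 0 && nrow(pb) == 0) {
    stop("cannot align two empty spectra", call. = FALSE)
  }
  tol <- params$tolerance
  pair_i <- integer(0)
  pair_j <- integer(0)
  if (nrow(pa) > 0 && nrow(pb) > 0) {
    # candidate pairs within tolerance via interval lookup on sorted b
    ord_b <- order(pb$mz)
    mzb <- pb$mz[ord_b]
    eps <- 1e-9  # keep boundary pairs at exactly |delta| == tol
    lo <- findInterval(pa$mz - tol - eps, mzb) + 1L
    hi <- findInterval(pa$mz + tol + eps, mzb)
    cand_i <- rep.int(seq_len(nrow(pa)), pmax(hi - lo + 1L, 0L))
    cand_j <- unlist(purrr::map2(lo, hi, function(l, h) {
      if (h >= l) ord_b[l:h] else integer(0)
    }), use.names = FALSE)
    if (length(cand_i) > 0) {
      dmz <- abs(pa$mz[cand_i] - pb$mz[cand_j])
      inside <- dmz <= tol
      cand_i <- cand_i[inside]
      cand_j <- cand_j[inside]
      dmz <- dmz[inside]
    }
    if (length(cand_i) > 0) {
      ord <- order(dmz, pmin(pa$mz[cand_i], pb$mz[cand_j]))
      used_a <- logical(nrow(pa))
      used_b <- logical(nrow(pb))
      for (idx in ord) {
        i <- cand_i[idx]
        j <- cand_j[idx]
        if (!used_a[i] && !used_b[j]) {
          used_a[i] <- TRUE
          used_b[j] <- TRUE
          pair_i <- c(pair_i, i)
          pair_j <- c(pair_j, j)
        }
      }
    }
  }
  matched <- tibble::tibble(
    mz_a = pa$mz[pair_i], mz_b = pb$mz[pair_j],
    u = pa$intensity[pair_i], v = pb$intensity[pair_j], matched = TRUE
  )
  only_a <- setdiff(seq_len(nrow(pa)), pair_i)
  only_b <- setdiff(seq_len(nrow(pb)), pair_j)
  slots <- dplyr::bind_rows(
    matched,
    tibble::tibble(mz_a = pa$mz[only_a], mz_b = NA_real_,
                   u = pa$intensity[only_a], v = 0, matched = FALSE),
    tibble::tibble(mz_a = NA_real_, mz_b = pb$mz[only_b],
                   u = 0, v = pb$intensity[only_b], matched = FALSE)
  )
  slots <- dplyr::arrange(slots, dplyr::coalesce(.data$mz_a, .data$mz_b))
  attr(slots, "matched_count") <- length(pair_i)
  attr(slots, "tolerance") <- tol
  class(slots) <- c("peak_alignment", class(slots))
  slots
}

#' Cosine similarity of an alignment
#'
#' The dot product of the aligned intensity vectors u and v over the
#' product of their norms. Intensities enter untransformed. The score is
#' 0 when no slots are matched and 1 exactly when u and v are
#' proportional.
#'
#' @param alignment A `peak_alignment` from [match_peaks()], or any data
#'   frame with columns `u` and `v`.
#' @return Numeric score in [0, 1] for non-negative intensities.
#' @export
cosine_score <- function(alignment) {
  u <- alignment$u
  v <- alignment$v
  su <- sum(u^2)
  sv <- sum(v^2)
  if (su == 0 || sv == 0) {
    stop("cosine undefined: one intensity vector is all zero", call. = FALSE)
  }
  sum(u * v) / sqrt(su * sv)
}

#' Compare two spectra
#'
#' Full spectral-validation composition: both spectra are normalized to
#' relative intensity and base-peak filtered, peaks are matched one to one
#' at the tolerance, and the cosine score of the aligned vectors is
#' computed. The comparison passes when the score strictly exceeds the
#' threshold.
#'
#' @param a Experimental-side spectrum.
#' @param b Synthetic-side spectrum.
#' @param params A [match_params()] object.
#' @return A `spectral_similarity` object with elements `score`, `passed`,
#'   `alignment`, `matched_count`, `n_slots`, `peaks_a`, `peaks_b`, and
#'   `params`. Has [tidy()], [glance()] and [ggplot2::autoplot()] methods.
#' @examples
#' s <- tibble::tibble(mz = c(100, 200, 300), intensity = c(50, 100, 10))
#' compare_spectra(s, s)$score  # 1
#' @export
compare_spectra <- function(a, b, params = match_params()) {
  fa <- normalize_filter_peaks(a, params)
  fb <- normalize_filter_peaks(b, params)
  al <- match_peaks(fa, fb, params)
  score <- if (attr(al, "matched_count") == 0) 0 else cosine_score(al)
  structure(list(
    score = score,
    passed = score > params$threshold,
    alignment = al,
    matched_count = attr(al, "matched_count"),
    n_slots = nrow(al),
    peaks_a = fa,
    peaks_b = fb,
    params = params
  ), class = "spectral_similarity")
}

#' @export
print.spectral_similarity <- function(x, ...) {
  cat(sprintf(
    "<spectral_similarity> score %.3f (%s at threshold %.2f); %d/%d slots matched\n",
    x$score, if (x$passed) "pass" else "fail", x$params$threshold,
    x$matched_count, x$n_slots))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.spectral_similarity <- function(x, ...) {
  tibble::as_tibble(x$alignment)
}

#' @export
glance.spectral_similarity <- function(x, ...) {
  tibble::tibble(score = x$score, passed = x$passed,
                 matched_count = x$matched_count, n_slots = x$n_slots,
                 tolerance = x$params$tolerance, filter = x$params$filter,
                 threshold = x$params$threshold)
}

#' Annotate spectrum peaks with theoretical b/y fragment ions
#'
#' Each peak is labeled with the closest theoretical b/y ion of the
#' peptidoform within the annotation tolerance; peaks with no ion in range
#' stay unlabeled. When two ions are equally close the tie is broken by
#' lower charge, then y over b.
#'
#' @param spectrum A spectrum (peaks data frame or spectra-table row).
#' @param p The `peptidoform` whose theoretical ions annotate the peaks.
#' @param tolerance Annotation tolerance in Da (default 0.01, matching the
#'   peak-matching tolerance).
#' @param max_charge Highest fragment charge considered (default 2).
#' @return The peak tibble with added columns `label`, `series`, `ordinal`,
#'   `fragment_charge`, `delta_mz` (NA where unannotated).
#' @export
annotate_fragments <- function(spectrum, p, tolerance = 0.01,
                               max_charge = 2L) {
  pk <- peaks_of(spectrum)
  ions <- fragment_ions(p, max_charge = max_charge)
  # tie-break ordering: smaller |delta| first, then lower charge, y before b
  pk$label <- NA_character_
  pk$series <- NA_character_
  pk$ordinal <- NA_integer_
  pk$fragment_charge <- NA_integer_
  pk$delta_mz <- NA_real_
  if (nrow(pk) == 0) {
    return(pk)
  }
  for (i in seq_len(nrow(pk))) {
    d <- abs(ions$mz - pk$mz[i])
    ok <- which(d <= tolerance)
    if (length(ok) == 0) next
    ord <- ok[order(d[ok], ions$charge[ok],
                    match(ions$series[ok], c("y", "b")))]
    best <- ord[1]
    pk$label[i] <- ions$label[best]
    pk$series[i] <- ions$series[best]
    pk$ordinal[i] <- ions$ordinal[best]
    pk$fragment_charge[i] <- ions$charge[best]
    pk$delta_mz[i] <- pk$mz[i] - ions$mz[best]
  }
  pk
}

#' Mirror-plot data for a spectral comparison
#'
#' The experimental spectrum plots upward, the synthetic spectrum with
#' negated relative intensities downward; matched peaks are flagged.
#'
#' @param result A `spectral_similarity` from [compare_spectra()].
#' @return A tibble with columns `mz`, `intensity` (negative for the
#'   synthetic side), `side` (`"experimental"`/`"synthetic"`), `matched`.
#' @export
mirror_data <- function(result) {
  stopifnot(inherits(result, "spectral_similarity"))
  al <- result$alignment
  top <- tibble::tibble(mz = al$mz_a, intensity = al$u,
                        side = "experimental", matched = al$matched)
  top <- top[!is.na(top$mz), ]
  bottom <- tibble::tibble(mz = al$mz_b, intensity = -al$v,
                           side = "synthetic", matched = al$matched)
  bottom <- bottom[!is.na(bottom$mz), ]
  out <- dplyr::bind_rows(top, bottom)
  attr(out, "score") <- result$score
  out
}

#' Mirror plot of a spectral comparison
#'
#' @param object A `spectral_similarity` object.
#' @param ... Unused.
#' @return A ggplot: experimental spectrum up, synthetic spectrum down,
#'   matched peaks highlighted, cosine score in the title.
#' @export
autoplot.spectral_similarity <- function(object, ...) {
  md <- mirror_data(object)
  ggplot2::ggplot(md, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                   y = 0, yend = .data$intensity,
                                   colour = .data$matched)) +
    ggplot2::geom_segment(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#D62728", `FALSE` = "grey55"),
      labels = c(`TRUE` = "matched", `FALSE` = "unmatched"),
      name = NULL) +
    ggplot2::labs(
      title = sprintf("Cosine similarity %.3f", object$score),
      x = "m/z", y = "Relative intensity (experimental up / synthetic down)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
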