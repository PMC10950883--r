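# Flanking-sequence motif analysis: windows around nitrated tyrosines from
# the protein sequence, position x residue count matrices, log-odds vs a
# background.

GAP_SYMBOL <- "-"
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Extract flanking-sequence windows around catalog sites
#'
#' Windows of length 2k+1 centered on each nitrated tyrosine are taken
#' from the protein sequence (not the identified peptide), left/right
#' padded with `"-"` where the window runs past a protein terminus.
#' De-duplicated to distinct (protein, position) sites by default, so a
#' site identified in many PSMs contributes one window.
#'
#' @param catalog Catalog tibble from [build_catalog()].
#' @param fasta Named sequence vector.
#' @param k Window half-width in residues (default 7, a 15-mer).
#' @param distinct_sites Collapse to distinct protein sites (default TRUE).
#' @return A tibble with `protein`, `protein_position`, `window`.
#' @export
site_windows <- function(catalog, fasta, k = 7L, distinct_sites = TRUE) {
  stopifnot(k >= 1)
  sites <- catalog[, c("protein", "protein_position")]
  if (distinct_sites) {
    sites <- dplyr::distinct(sites)
  }
  pad <- strrep(GAP_SYMBOL, k)
  sites$window <- purrr::map2_chr(
    sites$protein, sites$protein_position,
    function(acc, pos) {
      padded <- paste0(pad, fasta[[acc]], pad)
      substr(padded, pos, pos + 2 * k)
    }
  )
  sites
}

#' Residue frequencies of a sequence set
#'
#' @param sequences Character vector of sequences (e.g. a FASTA).
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
residue_frequencies <- function(sequences) {
  counts <- table(factor(
    stringr::str_split_1(paste(sequences, collapse = ""), ""),
    levels = AA_ALPHABET))
  freq <- as.numeric(counts) / sum(counts)
  stats::setNames(freq, AA_ALPHABET)
}

#' Position x residue motif matrix
#'
#' Counts each residue (plus the terminal-gap symbol `"-"`) at each window
#' position, with the center at position 0. Frequencies at each position
#' are computed over the non-gap windows there, and per-cell log2-odds are
#' taken against the background residue frequencies (gap cells carry no
#' odds). Column counts (gaps included) sum to the number of windows at
#' every position; the center column is 100% Y for nitroY windows.
#'
#' @param windows Character vector of equal-length odd-length windows, or
#'   the tibble from [site_windows()].
#' @param background Named background residue frequencies, e.g.
#'   [residue_frequencies()] of the FASTA searched. Renormalized to sum
#'   to 1.
#' @return A `motif_matrix` object: list with `counts` (long tibble:
#'   `position`, `residue`, `count`, `frequency`, `log_odds`), `k`,
#'   `n_windows`, `background`. Has [tidy()] and [ggplot2::autoplot()]
#'   methods.
#' @export
motif_matrix <- function(windows, background) {
  if (is.data.frame(windows)) {
    windows <- windows$window
  }
  if (length(windows) == 0) {
    stop("no windows supplied", call. = FALSE)
  }
  widths <- unique(nchar(windows))
  if (length(widths) != 1 || widths %% 2 != 1) {
    stop("windows must all have the same odd length", call. = FALSE)
  }
  k <- (widths - 1L) / 2L
  background <- background[AA_ALPHABET]
  if (anyNA(background)) {
    stop("background must cover the 20 standard residues", call. = FALSE)
  }
  background <- background / sum(background)
  chars <- matrix(stringr::str_split_fixed(windows, "", widths),
                  nrow = length(windows))
  levels <- c(AA_ALPHABET, GAP_SYMBOL)
  long <- purrr::map_dfr(seq_len(widths), function(j) {
    counts <- table(factor(chars[, j], levels = levels))
    tibble::tibble(
      position = j - k - 1L,
      residue = levels,
      count = as.integer(counts)
    )
  })
  long <- dplyr::mutate(
    dplyr::group_by(long, .data$position),
    nongap = sum(.data$count[.data$residue != GAP_SYMBOL]),
    frequency = dplyr::if_else(
      .data$residue == GAP_SYMBOL,
      .data$count / length(windows),
      dplyr::if_else(.data$nongap > 0, .data$count / .data$nongap, 0)
    )
  )
  long <- dplyr::ungroup(long)
  bg <- c(background, stats::setNames(NA_real_, GAP_SYMBOL))
  long$log_odds <- ifelse(
    long$residue == GAP_SYMBOL | long$count == 0,
    NA_real_,
    log2(long$frequency / bg[long$residue])
  )
  long$nongap <- NULL
  structure(list(
    counts = long,
    k = k,
    n_windows = length(windows),
    background = background
  ), class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("<motif_matrix> %d windows, positions -%d..+%d\n",
              x$n_windows, x$k, x$k))
  top <- dplyr::slice_max(
    x$counts[x$counts$position != 0 & !is.na(x$counts$log_odds), ],
    .data$log_odds, n = 5)
  cat("top enriched cells:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %s at %+d: log2-odds %.2f\n",
                top$residue[i], top$position[i], top$log_odds[i]))
  }
  invisible(x)
}

#' @export
tidy.motif_matrix <- function(x, ...) {
  x$counts
}

#' Heatmap of motif log-odds
#'
#' @param object A `motif_matrix`.
#' @param ... Unused.
#' @return A ggplot heatmap of per-cell log2-odds vs background, residues
#'   by window position.
#' @export
autoplot.motif_matrix <- function(object, ...) {
  d <- object$counts[object$counts$residue != GAP_SYMBOL, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position,
                                  y = .data$residue,
                                  fill = .data$log_odds)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", na.value = "grey92",
                                  name = "log2 odds") +
    ggplot2::labs(x = "Position relative to nitroY", y = NULL,
                  title = sprintf("Flanking-sequence motif (%d windows)",
                                  object$n_windows)) +
    ggplot2::theme_minimal()
}
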