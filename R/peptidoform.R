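# Peptidoforms: a peptide sequence plus localized modifications.

#' Construct a peptidoform
#'
#' A peptidoform is a peptide sequence together with its localized
#' modifications. Modification positions are 1-based within the peptide;
#' at most one modification per position; each modification must target
#' the residue at its position (a protein N-terminal modification such as
#' acetylation is only valid at position 1).
#'
#' @param sequence Peptide sequence (one-letter codes, uppercased).
#' @param modifications `NULL`, a string like `"1:nitroY,5:oxidation"`,
#'   or a data frame with columns `position` and `name`.
#' @param charge Precursor charge state (positive integer; the instrument
#'   selected 2--7 but any positive charge is accepted here).
#' @param mod_defs Modification definition table, see
#'   [default_modifications()].
#' @return An object of class `peptidoform`.
#' @examples
#' peptidoform("YLTVAAVFR", "1:nitroY", charge = 2)
#' @export
peptidoform <- function(sequence, modifications = NULL, charge = 2L,
                        mod_defs = default_modifications()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (!stringr::str_detect(sequence, "^[ACDEFGHIKLMNPQRSTVWY]+$")) {
    stop("sequence contains residues outside the 20-residue table: ",
         sequence, call. = FALSE)
  }
  mods <- parse_modifications(modifications)
  n <- nchar(sequence)
  if (nrow(mods) > 0) {
    if (any(mods$position < 1 | mods$position > n)) {
      stop("modification position outside [1, ", n, "]", call. = FALSE)
    }
    if (anyDuplicated(mods$position)) {
      stop("at most one modification per position", call. = FALSE)
    }
    unknown <- setdiff(mods$name, mod_defs$name)
    if (length(unknown) > 0) {
      stop("unknown modification(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    idx <- match(mods$name, mod_defs$name)
    mods$delta_mass <- mod_defs$delta_mass[idx]
    for (i in seq_len(nrow(mods))) {
      targets <- mod_defs$targets[[idx[i]]]
      res <- substr(sequence, mods$position[i], mods$position[i])
      nterm_ok <- "N-term" %in% targets && mods$position[i] == 1
      if (!(res %in% targets || nterm_ok)) {
        stop("modification '", mods$name[i], "' does not target residue ",
             res, " at position ", mods$position[i], call. = FALSE)
      }
    }
  } else {
    mods$delta_mass <- numeric(0)
  }
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  structure(
    list(sequence = sequence, modifications = mods, charge = charge),
    class = "peptidoform"
  )
}

#' Parse a modification specification
#'
#' @param x `NULL`, a string like `"1:nitroY;5:oxidation"` (comma or
#'   semicolon separated), or a data frame with `position` and `name`.
#' @return A tibble with integer `position` and character `name`.
#' @export
parse_modifications <- function(x) {
  empty <- tibble::tibble(position = integer(0), name = character(0))
  if (is.null(x) || (is.character(x) && length(x) == 1 &&
                     (is.na(x) || stringr::str_trim(x) %in% c("", "-")))) {
    return(empty)
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("position", "name") %in% names(x)))
    return(tibble::tibble(position = as.integer(x$position),
                          name = as.character(x$name)))
  }
  stopifnot(is.character(x), length(x) == 1)
  parts <- stringr::str_split_1(x, "[,;]")
  parts <- stringr::str_trim(parts)
  parts <- parts[parts != ""]
  m <- stringr::str_match(parts, "^(\\d+)\\s*:\\s*(\\S+)$")
  if (anyNA(m[, 1])) {
    stop("malformed modification string: '", x,
         "' (expected 'position:name' pairs)", call. = FALSE)
  }
  tibble::tibble(position = as.integer(m[, 2]), name = m[, 3])
}

#' @export
print.peptidoform <- function(x, ...) {
  mods <- if (nrow(x$modifications) == 0) "unmodified" else {
    paste(x$modifications$position, x$modifications$name,
          sep = ":", collapse = ", ")
  }
  cat(sprintf("<peptidoform> %s [%s] %d+\n", x$sequence, mods, x$charge))
  invisible(x)
}

#' Canonical peptidoform identifier
#'
#' Sequence plus sorted `position:name` modification pairs; charge and
#' replicate are deliberately ignored so that the identifier matches how
#' distinct modified peptides are counted across experiments.
#'
#' @param p A `peptidoform`.
#' @return Character scalar.
#' @export
peptidoform_id <- function(p) {
  mods <- p$modifications
  if (nrow(mods) == 0) {
    return(p$sequence)
  }
  ord <- order(mods$position)
  paste0(p$sequence, "/",
         paste(mods$position[ord], mods$name[ord], sep = ":", collapse = ","))
}

#' Neutral monoisotopic mass of a peptidoform
#'
#' Sum of residue masses, one water, and all modification delta masses.
#'
#' @param p A `peptidoform`.
#' @return Neutral mass in Da.
#' @examples
#' peptidoform_mass(peptidoform("GY"))            # 238.0954
#' peptidoform_mass(peptidoform("GY", "2:nitroY")) # 283.0804
#' @export
peptidoform_mass <- function(p) {
  stopifnot(inherits(p, "peptidoform"))
  rm <- residue_masses()
  res <- stringr::str_split_1(p$sequence, "")
  sum(rm[res]) + WATER_MASS + sum(p$modifications$delta_mass)
}

#' Precursor m/z of a peptidoform
#'
#' @param p A `peptidoform`.
#' @param charge Charge state; defaults to the peptidoform's own.
#' @return m/z in Th: (neutral mass + charge * proton) / charge.
#' @export
precursor_mz <- function(p, charge = p$charge) {
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (peptidoform_mass(p) + charge * PROTON_MASS) / charge
}

#' Theoretical b/y fragment ions
#'
#' Generates the b1..b(n-1) and y1..y(n-1) series at charges 1 to
#' `max_charge`. Each fragment carries exactly the modifications localized
#' within it: a b_k ion the modifications at positions 1..k, a y_k ion
#' those in the C-terminal k residues. Only b/y ions are produced (HCD
#' fragmentation); a/c/z series and neutral losses are out of scope.
#'
#' @param p A `peptidoform` of length >= 2.
#' @param max_charge Highest fragment charge to emit (default 1).
#' @return A tibble with columns `series` ("b"/"y"), `ordinal`, `charge`,
#'   `neutral_mass` (Da), `mz` (Th), `label` (e.g. `"y3"`, `"b2^2"`), and
#'   `modifications` (list column of modification names in the fragment).
#' @export
fragment_ions <- function(p, max_charge = 1L) {
  stopifnot(inherits(p, "peptidoform"))
  n <- nchar(p$sequence)
  if (n < 2) {
    stop("peptide must have length >= 2 to fragment", call. = FALSE)
  }
  max_charge <- as.integer(max_charge)
  stopifnot(max_charge >= 1)
  rm <- residue_masses()
  res <- rm[stringr::str_split_1(p$sequence, "")]
  mod_delta <- numeric(n)
  mod_name <- rep(NA_character_, n)
  if (nrow(p$modifications) > 0) {
    mod_delta[p$modifications$position] <- p$modifications$delta_mass
    mod_name[p$modifications$position] <- p$modifications$name
  }
  site_mass <- res + mod_delta
  k <- seq_len(n - 1)
  site_mass <- unname(site_mass)
  b_neutral <- cumsum(site_mass)[k]
  y_neutral <- cumsum(rev(site_mass))[k] + WATER_MASS
  # modifications carried by each ordinal
  b_mods <- purrr::map(k, ~ mod_name[seq_len(.x)][!is.na(mod_name[seq_len(.x)])])
  y_mods <- purrr::map(k, function(kk) {
    idx <- seq(n - kk + 1, n)
    mod_name[idx][!is.na(mod_name[idx])]
  })
  base <- dplyr::bind_rows(
    tibble::tibble(series = "b", ordinal = k, neutral_mass = b_neutral,
                   modifications = b_mods),
    tibble::tibble(series = "y", ordinal = k, neutral_mass = y_neutral,
                   modifications = y_mods)
  )
  out <- tidyr::expand_grid(base, charge = seq_len(max_charge))
  out$mz <- (out$neutral_mass + out$charge * PROTON_MASS) / out$charge
  out$label <- paste0(out$series, out$ordinal,
                      ifelse(out$charge > 1, paste0("^", out$charge), ""))
  out[, c("series", "ordinal", "charge", "neutral_mass", "mz", "label",
          "modifications")]
}
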