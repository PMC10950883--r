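# Monoisotopic mass arithmetic. All masses in Da; internal precision is the
# full atomic-mass precision, rounding happens only in user-facing display.

#' Monoisotopic atomic masses
#'
#' Masses of the elements occurring in unmodified and nitrated peptides,
#' in daltons.
#'
#' @return Named numeric vector of monoisotopic atomic masses (Da).
#' @export
atomic_masses <- function() {
  c(
    H = 1.0078250319,
    C = 12.0,
    N = 14.0030740052,
    O = 15.9949146221,
    S = 31.97207069,
    P = 30.97376151
  )
}

# Proton (charge carrier) and water; community-standard values.
PROTON_MASS <- 1.007276
WATER_MASS <- 2 * 1.0078250319 + 15.9949146221

# Residue elemental compositions (the residue, i.e. amino acid minus water).
.residue_formulas <- c(
  G = "C2H3NO",   A = "C3H5NO",    S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",   C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2",  D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",   M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O",  Y = "C9H9NO2",  W = "C11H10N2O"
)

#' Parse an elemental formula into element counts
#'
#' Accepts compact formulas (`"C2H3NO"`), space-separated signed terms
#' (`"N O2 H-1"` or `"+N +2O -H"`), or an already-named numeric vector.
#' Counts may be negative, describing a mass difference.
#'
#' @param formula Character scalar or named numeric vector.
#' @return Named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) && length(formula) > 0) {
      stop("numeric formula must be a named vector of element counts",
           call. = FALSE)
    }
    return(formula)
  }
  stopifnot(is.character(formula), length(formula) == 1)
  txt <- stringr::str_trim(formula)
  if (txt == "") {
    return(stats::setNames(numeric(0), character(0)))
  }
  counts <- c(H = 0, C = 0, N = 0, O = 0, S = 0, P = 0)[0]
  # split into signed terms; a bare compact formula is a single "+" term
  terms <- stringr::str_split_1(txt, "\\s+")
  for (term in terms) {
    sign <- 1
    body <- term
    if (stringr::str_starts(body, "[+-]")) {
      sign <- if (stringr::str_starts(body, "-")) -1 else 1
      body <- stringr::str_sub(body, 2)
    }
    # leading multiplier as in "+2O"
    lead <- stringr::str_match(body, "^(\\d+)([A-Za-z].*)$")
    mult <- 1
    if (!is.na(lead[1, 1])) {
      mult <- as.numeric(lead[1, 2])
      body <- lead[1, 3]
    }
    pieces <- stringr::str_match_all(body, "([A-Z][a-z]?)(-?\\d*)")[[1]]
    if (nrow(pieces) == 0 || paste0(pieces[, 1], collapse = "") != body) {
      stop("cannot parse formula term: '", term, "'", call. = FALSE)
    }
    for (i in seq_len(nrow(pieces))) {
      el <- pieces[i, 2]
      n <- ifelse(pieces[i, 3] == "", 1, as.numeric(pieces[i, 3]))
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) +
        sign * mult * n
    }
  }
  counts
}

#' Mass shift of an elemental composition
#'
#' Signed sum of monoisotopic atomic masses of a (possibly negative)
#' elemental composition, e.g. the delta mass of a modification.
#'
#' @inheritParams parse_formula
#' @return Mass shift in Da (numeric scalar). The empty formula gives 0.
#' @examples
#' delta_mass("N O2 H-1")  # nitration of tyrosine, +44.985
#' delta_mass("O")         # oxidation, +15.995
#' @export
delta_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (length(counts) == 0) {
    return(0)
  }
  am <- atomic_masses()
  unknown <- setdiff(names(counts), names(am))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(am[names(counts)] * counts)
}

#' Monoisotopic residue mass table
#'
#' Residue (amino acid minus water) masses for the 20 standard amino acids,
#' derived from elemental compositions.
#'
#' @return Named numeric vector, one entry per one-letter residue code.
#' @export
residue_masses <- function() {
  vapply(.residue_formulas, delta_mass, numeric(1))
}

#' Built-in modification definitions
#'
#' The four modifications used in the enrichment workflow: nitration of
#' tyrosine, oxidation of methionine, protein N-terminal acetylation, and
#' carbamidomethylation of cysteine (the only fixed one). Delta masses are
#' computed from elemental formulas, not hard-coded.
#'
#' @return A tibble with columns `name`, `formula`, `delta_mass` (Da),
#'   `targets` (list column of residue codes; `"N-term"` marks a protein
#'   N-terminal modification), and `fixed` (logical).
#' @export
default_modifications <- function() {
  tbl <- tibble::tibble(
    name = c("nitroY", "oxidation", "acetyl_nterm", "carbamidomethyl"),
    formula = c("N O2 H-1", "O", "C2H2O", "C2H3NO"),
    targets = list("Y", "M", "N-term", "C"),
    fixed = c(FALSE, FALSE, FALSE, TRUE)
  )
  tbl$delta_mass <- vapply(tbl$formula, delta_mass, numeric(1),
                           USE.NAMES = FALSE)
  tbl[, c("name", "formula", "delta_mass", "targets", "fixed")]
}

#' Load modification definitions from a YAML file
#'
#' Each entry needs a `name`, one of `formula` or `delta`, and `targets`
#' (residue letters and/or `"N-term"`); `fixed` defaults to `FALSE`.
#' Loaded entries are appended to the built-in four, overriding by name.
#'
#' @param path Path to a YAML file.
#' @param append Prepend the built-in modifications (default `TRUE`).
#' @return A modification tibble as in [default_modifications()].
#' @export
load_modifications <- function(path, append = TRUE) {
  raw <- yaml::read_yaml(path)
  rows <- purrr::map(raw, function(m) {
    if (is.null(m$name) || is.null(m$targets)) {
      stop("modification entry needs 'name' and 'targets'", call. = FALSE)
    }
    dm <- if (!is.null(m$delta)) as.numeric(m$delta) else delta_mass(m$formula)
    if (!is.finite(dm)) stop("non-finite delta mass for ", m$name, call. = FALSE)
    tibble::tibble(
      name = m$name,
      formula = m$formula %||% NA_character_,
      delta_mass = dm,
      targets = list(as.character(unlist(m$targets))),
      fixed = isTRUE(m$fixed)
    )
  })
  loaded <- dplyr::bind_rows(rows)
  if (!append) {
    return(loaded)
  }
  base <- default_modifications()
  dplyr::bind_rows(base[!base$name %in% loaded$name, ], loaded)
}
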