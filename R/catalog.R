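# Nitro-site catalog: one record per (peptidoform, site, experiment), with
# the summary statistics reported over it.

#' Build the nitration-site catalog from validated PSM records
#'
#' Maps every nitroY modification to its protein coordinate
#' (`protein_position = start + peptide position - 1`) and checks against
#' the FASTA that the residue there is Y. Records failing the check are
#' rejected with diagnostics (accession and position), available via
#' [psm_rejections()] on the result.
#'
#' @param psms Validated PSM tibble ([read_psm_table()] /
#'   [validate_psm_table()]).
#' @param fasta Named sequence vector ([read_fasta()]).
#' @param site_mod Modification name that defines a site (default
#'   `"nitroY"`).
#' @return A tibble with one row per nitro site per PSM: `protein`,
#'   `protein_position`, `peptide_position`, `sequence`, `peptidoform`,
#'   `is_nterm` (site at peptide position 1), `antibody`, `mode`,
#'   `replicate`, `spectrum_id`.
#' @export
build_catalog <- function(psms, fasta, site_mod = "nitroY") {
  psms <- tibble::as_tibble(psms)
  stopifnot(all(c("sequence", "mods", "protein", "start", "antibody",
                  "mode", "replicate", "peptidoform") %in% names(psms)))
  sites <- tidyr::unnest(
    dplyr::mutate(psms, .row = dplyr::row_number()),
    "mods"
  )
  sites <- sites[sites$name == site_mod, ]
  if (nrow(sites) == 0) {
    warning("no ", site_mod, " sites found in the PSM table")
  }
  sites$protein_position <- sites$start + sites$position - 1L
  m <- nrow(sites)
  reason <- character(m)
  in_fasta <- sites$protein %in% names(fasta)
  reason[!in_fasta] <- paste0("protein ", sites$protein[!in_fasta],
                              " not in FASTA")
  prot_seq <- character(m)
  prot_seq[in_fasta] <- unname(fasta[sites$protein[in_fasta]])
  beyond <- in_fasta & sites$protein_position > nchar(prot_seq)
  reason[beyond] <- paste0("position ", sites$protein_position[beyond],
                           " beyond end of ", sites$protein[beyond])
  chk <- in_fasta & !beyond
  res <- substr(prot_seq, sites$protein_position, sites$protein_position)
  not_y <- chk & res != "Y"
  reason[not_y] <- paste0("residue at ", sites$protein[not_y], ":",
                          sites$protein_position[not_y], " is ",
                          res[not_y], ", not Y")
  ok <- reason == ""
  out <- tibble::tibble(
    protein = sites$protein[ok],
    protein_position = sites$protein_position[ok],
    peptide_position = sites$position[ok],
    sequence = sites$sequence[ok],
    peptidoform = sites$peptidoform[ok],
    is_nterm = sites$position[ok] == 1L,
    antibody = sites$antibody[ok],
    mode = sites$mode[ok],
    replicate = sites$replicate[ok],
    spectrum_id = sites$spectrum_id[ok]
  )
  rejected <- tibble::tibble(row = sites$.row[!ok], reason = reason[!ok])
  if (nrow(rejected) > 0) {
    warning(nrow(rejected), " site(s) rejected during catalog build; ",
            "see psm_rejections()")
  }
  attr(out, "rejected") <- rejected
  out
}

#' N-terminal nitrotyrosine fraction per experiment group
#'
#' For each group (antibody x enrichment mode by default), the fraction of
#' distinct nitroY peptidoforms whose nitroY sits at peptide position 1.
#' Distinct peptidoforms are counted across replicates, the way modified
#' peptides are tallied across an experiment.
#'
#' @param catalog Catalog tibble from [build_catalog()].
#' @param ... Grouping columns (tidy-select style); default
#'   `antibody, mode`.
#' @return A tibble with the grouping columns plus `n_peptidoforms`,
#'   `n_nterm`, and `nterm_fraction`. Empty groups are omitted (a grouped
#'   count cannot produce them); an empty catalog warns and returns an
#'   empty tibble.
#' @export
nterm_fraction <- function(catalog, ...) {
  groups <- rlang::enquos(...)
  if (length(groups) == 0) {
    groups <- rlang::quos(.data$antibody, .data$mode)
  }
  if (nrow(catalog) == 0) {
    warning("empty catalog: no groups to summarise")
    return(tibble::tibble())
  }
  per_pf <- dplyr::summarise(
    dplyr::group_by(catalog, !!!groups, .data$peptidoform),
    is_nterm = any(.data$is_nterm), .groups = "drop_last"
  )
  dplyr::ungroup(dplyr::summarise(
    per_pf,
    n_peptidoforms = dplyr::n(),
    n_nterm = sum(.data$is_nterm),
    nterm_fraction = mean(.data$is_nterm),
    .groups = "drop"
  ))
}

#' Distinct peptidoform and protein counts, by mode and overall
#'
#' The union catalog: how many distinct nitroY peptidoforms and proteins
#' each enrichment mode contributed, and the de-duplicated totals. The
#' overall count is at most the sum of the per-mode counts.
#'
#' @param catalog Catalog tibble from [build_catalog()].
#' @return A tibble with columns `mode` (including `"all"`),
#'   `n_peptidoforms`, `n_proteins`.
#' @export
union_catalog <- function(catalog) {
  per_mode <- dplyr::summarise(
    dplyr::group_by(catalog, .data$mode),
    n_peptidoforms = dplyr::n_distinct(.data$peptidoform),
    n_proteins = dplyr::n_distinct(.data$protein),
    .groups = "drop"
  )
  overall <- tibble::tibble(
    mode = "all",
    n_peptidoforms = dplyr::n_distinct(catalog$peptidoform),
    n_proteins = dplyr::n_distinct(catalog$protein)
  )
  dplyr::bind_rows(per_mode, overall)
}
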