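# Readers and writers: MGF peak lists, FASTA databases, PSM tables.
# Spectra live in a tibble with one row per spectrum and a `peaks` list
# column of tibble(mz, intensity); that row shape flows through dplyr.

#' Assemble a spectra table
#'
#' @param spectrum_id Character vector of identifiers.
#' @param precursor_mz Numeric precursor m/z (Th).
#' @param precursor_charge Integer charge states.
#' @param peaks List of data frames with columns `mz` and `intensity`.
#' @param provenance `"experimental"` or `"synthetic"` per spectrum.
#' @return A tibble with one row per spectrum; peaks are sorted by m/z and
#'   duplicate m/z values within a spectrum are merged by intensity sum.
#' @export
spectra_table <- function(spectrum_id, precursor_mz = NA_real_,
                          precursor_charge = NA_integer_, peaks = list(),
                          provenance = "experimental") {
  tibble::tibble(
    spectrum_id = as.character(spectrum_id),
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = as.integer(precursor_charge),
    provenance = provenance,
    peaks = purrr::map(peaks, tidy_peaks)
  )
}

#' Canonicalize a peak list
#'
#' Sorts ascending by m/z, drops negative-intensity peaks (with a warning),
#' and merges duplicate m/z values by summing intensities, so downstream
#' one-to-one matching is well defined.
#'
#' @param peaks Data frame with numeric `mz` and `intensity`.
#' @return A tibble sorted by `mz`, unique in `mz`.
#' @export
tidy_peaks <- function(peaks) {
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  p <- tibble::tibble(mz = as.numeric(peaks$mz),
                      intensity = as.numeric(peaks$intensity))
  if (any(p$intensity < 0)) {
    warning("dropping ", sum(p$intensity < 0), " negative-intensity peak(s)")
    p <- p[p$intensity >= 0, ]
  }
  p <- dplyr::summarise(dplyr::group_by(p, .data$mz),
                        intensity = sum(.data$intensity), .groups = "drop")
  dplyr::arrange(p, .data$mz)
}

#' Read an MGF peak-list file
#'
#' Parses BEGIN IONS / END IONS blocks. TITLE is used as the spectrum
#' identifier, PEPMASS as precursor m/z (required), CHARGE as precursor
#' charge. Peaks are returned sorted by m/z with duplicates merged.
#'
#' @param path Path to an MGF file.
#' @return A spectra tibble as produced by [spectra_table()].
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) {
    stop("MGF file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- stringr::str_trim(lines)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) == 0) {
    if (all(lines == "" | stringr::str_starts(lines, "#"))) {
      warning("empty MGF file: ", path)
      return(spectra_table(character(0)))
    }
    stop("no BEGIN IONS blocks found in ", path, call. = FALSE)
  }
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("unbalanced BEGIN IONS/END IONS in ", path, call. = FALSE)
  }
  blocks <- purrr::map2(begins, ends, function(b, e) lines[(b + 1):(e - 1)])
  rows <- purrr::imap(blocks, function(block, i) {
    kv <- block[stringr::str_detect(block, "^[A-Z]+=")]
    peak_lines <- block[!stringr::str_detect(block, "^[A-Z]+=") & block != ""]
    keys <- stringr::str_match(kv, "^([A-Z]+)=(.*)$")
    vals <- stats::setNames(keys[, 3], keys[, 2])
    title <- if ("TITLE" %in% names(vals)) vals[["TITLE"]] else
      paste0("spectrum_", i)
    if (!"PEPMASS" %in% names(vals)) {
      stop("block ", i, " ('", title, "') is missing PEPMASS", call. = FALSE)
    }
    pepmass <- suppressWarnings(
      as.numeric(stringr::str_split_1(vals[["PEPMASS"]], "\\s+")[1]))
    if (is.na(pepmass)) {
      stop("block ", i, " ('", title, "') has unparseable PEPMASS",
           call. = FALSE)
    }
    charge <- NA_integer_
    if ("CHARGE" %in% names(vals)) {
      charge <- suppressWarnings(
        as.integer(stringr::str_remove(vals[["CHARGE"]], "\\+$")))
    }
    fields <- stringr::str_split(peak_lines, "\\s+")
    bad <- lengths(fields) < 2
    if (any(bad)) {
      stop("block ", i, " ('", title, "') has malformed peak line: '",
           peak_lines[which(bad)[1]], "'", call. = FALSE)
    }
    mz <- suppressWarnings(as.numeric(purrr::map_chr(fields, 1)))
    int <- suppressWarnings(as.numeric(purrr::map_chr(fields, 2)))
    if (anyNA(mz) || anyNA(int)) {
      stop("block ", i, " ('", title, "') has non-numeric peak values",
           call. = FALSE)
    }
    spectra_table(title, pepmass, charge,
                  list(tibble::tibble(mz = mz, intensity = int)))
  })
  dplyr::bind_rows(rows)
}

#' Write a spectra table to MGF
#'
#' m/z values are written with 6 decimals, so a read/write round trip is
#' lossless at that precision.
#'
#' @param spectra A spectra tibble ([spectra_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  for (i in seq_len(nrow(spectra))) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", spectra$spectrum_id[i]), con)
    writeLines(sprintf("PEPMASS=%.6f", spectra$precursor_mz[i]), con)
    if (!is.na(spectra$precursor_charge[i])) {
      writeLines(sprintf("CHARGE=%d+", spectra$precursor_charge[i]), con)
    }
    pk <- spectra$peaks[[i]]
    if (nrow(pk) > 0) {
      writeLines(sprintf("%.6f %.6f", pk$mz, pk$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read a protein FASTA
#'
#' Headers are parsed to a primary accession: for UniProt-style headers
#' (`>sp|P07437|TBB5_HUMAN ...`) the middle field, otherwise the first
#' whitespace-delimited token. Sequences are uppercased; trailing stop
#' characters `*` are stripped with a warning.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, accession -> sequence.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(aa))
  if (any(stringr::str_detect(seqs, "\\*"))) {
    warning("stripping stop characters '*' from ",
            sum(stringr::str_detect(seqs, "\\*")), " sequence(s)")
    seqs <- stringr::str_remove_all(seqs, "\\*")
  }
  headers <- names(aa)
  acc <- purrr::map_chr(headers, function(h) {
    first <- stringr::str_split_1(h, "\\s+")[1]
    if (stringr::str_detect(first, "^(sp|tr)\\|")) {
      stringr::str_split_1(first, "\\|")[2]
    } else {
      first
    }
  })
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in ", path, ": ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(seqs, acc)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector, accession -> sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read a peptide-spectrum-match table
#'
#' The TSV must have columns `sequence`, `modifications`, `protein`,
#' `start`, `spectrum_id`, `antibody`, `mode`, `replicate`. Modification
#' strings are `position:name` pairs separated by `,` or `;` (empty or
#' `-` for none). Parsing is total: every row is either returned as a
#' valid record or collected in the `rejected` attribute with its row
#' number and a reason, and the two counts always add up to the input.
#'
#' @param path Path to the TSV file.
#' @param fasta Optional named sequence vector ([read_fasta()]); when
#'   supplied, each peptide must occur at its stated protein offset.
#' @param mod_defs Modification definition table.
#' @return A tibble of validated PSM records with a parsed `mods` list
#'   column and a `peptidoform` id column; rejected rows (if any) are in
#'   `attr(, "rejected")` and reported with a warning. Use
#'   [psm_rejections()] to retrieve them.
#' @export
read_psm_table <- function(path, fasta = NULL,
                           mod_defs = default_modifications()) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("sequence", "modifications", "protein", "start",
                "spectrum_id", "antibody", "mode", "replicate")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("PSM table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_psm_table(raw, fasta = fasta, mod_defs = mod_defs)
}

#' Validate an in-memory PSM table
#'
#' Same contract as [read_psm_table()], for tables that are already data
#' frames (e.g. simulator output).
#'
#' @inheritParams read_psm_table
#' @param psms Data frame with the PSM-table columns.
#' @export
validate_psm_table <- function(psms, fasta = NULL,
                               mod_defs = default_modifications()) {
  psms <- tibble::as_tibble(psms)
  n <- nrow(psms)
  reason <- character(n)
  flag <- function(bad, msg) {
    hit <- bad & reason == ""
    hit[is.na(hit)] <- FALSE
    reason[hit] <<- msg[hit]
    invisible(NULL)
  }
  start <- suppressWarnings(as.integer(psms$start))
  repl <- suppressWarnings(as.integer(psms$replicate))
  seqs <- toupper(as.character(psms$sequence))
  flag(is.na(start) | start < 1,
       paste0("invalid start '", psms$start, "'"))
  flag(is.na(repl), paste0("invalid replicate '", psms$replicate, "'"))
  flag(!psms$mode %in% c("protein_level", "peptide_level"),
       paste0("unknown enrichment mode '", psms$mode, "'"))
  flag(is.na(psms$antibody) | psms$antibody == "",
       rep("empty antibody", n))
  flag(is.na(seqs) | !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs),
       paste0("invalid sequence '", psms$sequence, "'"))
  # modification parsing (vectorized split, light per-row checks)
  mod_idx <- stats::setNames(seq_len(nrow(mod_defs)), mod_defs$name)
  mods_list <- vector("list", n)
  pf_id <- seqs
  ms <- as.character(psms$modifications)
  has_mods <- !is.na(ms) & !trimws(ms) %in% c("", "-")
  split_ms <- strsplit(ms, "[,;]")
  for (i in which(has_mods & reason == "")) {
    parts <- trimws(split_ms[[i]])
    parts <- parts[parts != ""]
    if (!all(grepl("^\\d+\\s*:\\s*\\S+$", parts))) {
      reason[i] <- paste0("malformed modification string '", ms[i], "'")
      next
    }
    pos <- as.integer(sub("^(\\d+).*$", "\\1", parts))
    nm <- sub("^\\d+\\s*:\\s*", "", parts)
    len <- nchar(seqs[i])
    if (any(pos < 1 | pos > len)) {
      reason[i] <- paste0("modification position outside [1, ", len, "]")
      next
    }
    if (anyDuplicated(pos)) {
      reason[i] <- "more than one modification at a position"
      next
    }
    unknown <- setdiff(nm, names(mod_idx))
    if (length(unknown) > 0) {
      reason[i] <- paste0("unknown modification(s): ",
                          paste(unknown, collapse = ", "))
      next
    }
    bad_target <- FALSE
    for (j in seq_along(pos)) {
      targets <- mod_defs$targets[[mod_idx[[nm[j]]]]]
      res <- substr(seqs[i], pos[j], pos[j])
      if (!(res %in% targets || ("N-term" %in% targets && pos[j] == 1))) {
        reason[i] <- paste0("modification '", nm[j],
                            "' does not target residue ", res,
                            " at position ", pos[j])
        bad_target <- TRUE
        break
      }
    }
    if (bad_target) next
    ord <- order(pos)
    mods_list[[i]] <- tibble::new_tibble(
      list(position = pos[ord], name = nm[ord]), nrow = length(pos))
    pf_id[i] <- paste0(seqs[i], "/",
                       paste(pos[ord], nm[ord], sep = ":", collapse = ","))
  }
  empty_mods <- tibble::tibble(position = integer(0), name = character(0))
  for (i in which(!has_mods & reason == "")) {
    mods_list[[i]] <- empty_mods
  }
  if (!is.null(fasta)) {
    in_fasta <- psms$protein %in% names(fasta)
    flag(!in_fasta, paste0("protein ", psms$protein, " not in FASTA"))
    chk <- reason == "" & in_fasta
    prot_seq <- character(n)
    prot_seq[chk] <- unname(fasta[psms$protein[chk]])
    end <- start + nchar(seqs) - 1L
    mismatch <- chk & (end > nchar(prot_seq) |
                         substr(prot_seq, start, end) != seqs)
    flag(mismatch, paste0("peptide does not match protein ", psms$protein,
                          " at position ", psms$start))
  }
  keep <- reason == ""
  out <- psms[keep, ]
  out$sequence <- seqs[keep]
  out$start <- as.integer(out$start)
  out$replicate <- as.integer(out$replicate)
  out$mods <- mods_list[keep]
  out$peptidoform <- pf_id[keep]
  rejected <- tibble::tibble(row = which(!keep), reason = reason[!keep])
  if (nrow(rejected) > 0) {
    warning(nrow(rejected), " of ", n, " PSM row(s) rejected; see ",
            "psm_rejections()")
  }
  attr(out, "rejected") <- rejected
  out
}

#' Rejected rows of a PSM table
#'
#' @param psms Result of [read_psm_table()] or [validate_psm_table()].
#' @return Tibble with columns `row` and `reason` (empty if all rows
#'   validated).
#' @export
psm_rejections <- function(psms) {
  attr(psms, "rejected") %||%
    tibble::tibble(row = integer(0), reason = character(0))
}
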