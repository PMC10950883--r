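make_psms <- function(rows) {
  tbl <- dplyr::bind_rows(rows)
  tbl$spectrum_id <- paste0("s", seq_len(nrow(tbl)))
  tbl$replicate <- tbl$replicate %||% 1
  validate_psm_table(tbl)
}

psm_row <- function(sequence, mods, protein, start, antibody = "AB1",
                    mode = "peptide_level", replicate = 1) {
  tibble::tibble(sequence = sequence, modifications = mods,
                 protein = protein, start = start, antibody = antibody,
                 mode = mode, replicate = replicate)
}

test_that("catalog maps peptide sites to protein coordinates", {
  fa <- toy_fasta()
  psms <- make_psms(list(
    psm_row("YLTVAAVFR", "1:nitroY", "PROT1", 10),
    psm_row("AYRGGK", "2:nitroY", "PROT1", 3),
    psm_row("GGYAAAK", "3:nitroY", "PROT2", 1)
  ))
  ct <- build_catalog(psms, fa)
  expect_equal(nrow(ct), 3)
  expect_equal(ct$protein_position, c(10L, 4L, 3L))
  expect_equal(ct$is_nterm, c(TRUE, FALSE, FALSE))
  # every record's protein residue is Y (site-mapping round trip)
  expect_true(all(
    substr(fa[ct$protein], ct$protein_position, ct$protein_position) == "Y"))
})

test_that("catalog rejects sites not mapping to tyrosine", {
  fa <- c(P1 = "AAKYAAAGGK")
  psms <- make_psms(list(
    psm_row("YAAAGGK", "1:nitroY", "P1", 4),   # Y at 4: valid
    psm_row("YAAAGGK", "1:nitroY", "P1", 5)    # position 5 is A
  ))
  expect_warning(ct <- build_catalog(psms, fa), "rejected")
  expect_equal(nrow(ct), 1)
  rej <- psm_rejections(ct)
  expect_match(rej$reason, "P1:5 is A, not Y")
})

test_that("one record per nitro site per PSM", {
  fa <- c(P1 = "KYAYAAAK")
  psms <- make_psms(list(
    psm_row("YAYAAAK", "1:nitroY,3:nitroY", "P1", 2)
  ))
  ct <- build_catalog(psms, fa)
  expect_equal(nrow(ct), 2)
  expect_equal(sort(ct$protein_position), c(2L, 4L))
})

test_that("N-terminal fraction counts distinct peptidoforms per group", {
  # 3 of 10 distinct peptidoforms N-terminal; rows duplicated across
  # replicates must not change the distinct counts
  ct <- tibble::tibble(
    peptidoform = paste0("pep", 1:10),
    is_nterm = c(rep(TRUE, 3), rep(FALSE, 7)),
    antibody = "AB1", mode = "peptide_level", protein = "P1"
  )
  ct <- dplyr::bind_rows(ct, ct, ct)
  nf <- nterm_fraction(ct)
  expect_equal(nf$nterm_fraction, 0.3)
  expect_equal(nf$n_peptidoforms, 10L)
  expect_equal(nf$n_nterm, 3L)
})

test_that("zero N-terminal sites give fraction 0 and empty catalog warns", {
  fa <- c(P1 = "AAKAYAAK")
  psms <- make_psms(list(psm_row("AYAAK", "2:nitroY", "P1", 4)))
  ct <- build_catalog(psms, fa)
  nf <- nterm_fraction(ct)
  expect_equal(nf$nterm_fraction, 0)
  expect_warning(nterm_fraction(ct[0, ]), "empty catalog")
})

test_that("union catalog counts distinct units by mode and overall", {
  ct <- tibble::tibble(
    peptidoform = c(paste0("pep", 1:5), paste0("pep", c(1, 2, 6:10))),
    protein = "P1",
    mode = c(rep("protein_level", 5), rep("peptide_level", 7))
  )
  u <- union_catalog(ct)
  expect_equal(u$n_peptidoforms[u$mode == "protein_level"], 5L)
  expect_equal(u$n_peptidoforms[u$mode == "peptide_level"], 7L)
  expect_equal(u$n_peptidoforms[u$mode == "all"], 10L)  # 2 shared
  # disjoint modes sum; identical modes collapse
  ct2 <- ct; ct2$peptidoform[6:12] <- paste0("x", 1:7)
  expect_equal(union_catalog(ct2)$n_peptidoforms[3], 12L)
  ct3 <- ct[c(1:5, 1:5), ]; ct3$mode[6:10] <- "peptide_level"
  expect_equal(union_catalog(ct3)$n_peptidoforms[3], 5L)
})

test_that("overlap regions match direct set arithmetic", {
  # antibody sets {A,B,C}, {B,C}, {B,C,D}, {B,C}
  ct <- tibble::tibble(
    protein = c("A", "B", "C", "B", "C", "B", "C", "D", "B", "C"),
    peptidoform = paste0("p", 1:10),
    antibody = rep(c("AB1", "AB2", "AB3", "AB4"), c(3, 2, 3, 2)),
    mode = "protein_level"
  )
  ov <- overlap_summary(ct, unit = "protein")
  expect_equal(ov$union_count, 4)
  r <- tidy(ov)
  expect_equal(
    r$intersection_count[r$combination == "AB1&AB2&AB3&AB4"], 2)
  expect_equal(r$exclusive_count[r$combination == "AB1"], 1)  # A
  expect_equal(r$exclusive_count[r$combination == "AB1&AB3"], 0)
  expect_equal(r$exclusive_count[r$combination == "AB3"], 1)  # D
  # exclusive regions partition the union
  expect_equal(sum(r$exclusive_count), ov$union_count)
})

test_that("a single shared element yields all intersections equal to 1", {
  ct <- tibble::tibble(protein = "X", peptidoform = paste0("p", 1:4),
                       antibody = paste0("AB", 1:4), mode = "m")
  ov <- overlap_summary(ct, unit = "protein")
  expect_true(all(tidy(ov)$intersection_count == 1))
  expect_equal(ov$union_count, 1)
})

test_that("overlap requires at least two antibodies", {
  ct <- tibble::tibble(protein = "X", peptidoform = "p", antibody = "AB1",
                       mode = "m")
  expect_error(overlap_summary(ct, unit = "protein"), "at least 2")
})

test_that("window extraction pads with the terminal-gap symbol", {
  fa <- c(P1 = "AAYKKKKKKKKKK")
  ct <- tibble::tibble(protein = "P1", protein_position = 3L)
  w <- site_windows(ct, fa, k = 7)
  expect_equal(nchar(w$window), 15)
  expect_equal(substr(w$window, 1, 5), "-----")  # 5 gaps: site at position 3
  expect_equal(substr(w$window, 8, 8), "Y")      # center is always Y
})

test_that("motif matrix counts, frequencies and log-odds are coherent", {
  w <- c("AYA", "AYA", "AYA")
  bg <- stats::setNames(rep(0.05, 20),
                        strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  mm <- motif_matrix(w, bg)
  d <- tidy(mm)
  expect_equal(d$frequency[d$position == -1 & d$residue == "A"], 1)
  expect_equal(d$frequency[d$position == 1 & d$residue == "A"], 1)
  expect_equal(d$frequency[d$position == 0 & d$residue == "Y"], 1)
  # column counts (gaps included) sum to the window count at each position
  sums <- tapply(d$count, d$position, sum)
  expect_true(all(sums == 3))
  # uniform background equal to the observed frequency: log-odds 0
  w2 <- c("AYC", "CYA")
  bg2 <- stats::setNames(rep(0.5, 20), names(bg)); bg2 <- bg2 / sum(bg2)
  mm2 <- motif_matrix(w2, bg2)
  d2 <- tidy(mm2)
  flank <- d2[d2$position != 0 & d2$residue %in% c("A", "C"), ]
  expect_true(all(abs(flank$log_odds - log2(0.5 / 0.05)) < 1e-12))
  expect_error(motif_matrix(character(0), bg), "no windows")
})

test_that("motif center column is degenerate at Y for real catalogs", {
  fa <- toy_fasta()
  psms <- make_psms(list(
    psm_row("YLTVAAVFR", "1:nitroY", "PROT1", 10),
    psm_row("AYRGGK", "2:nitroY", "PROT1", 3),
    psm_row("GGYAAAK", "3:nitroY", "PROT2", 1)
  ))
  ct <- build_catalog(psms, fa)
  w <- site_windows(ct, fa, k = 7)
  expect_true(all(substr(w$window, 8, 8) == "Y"))
  mm <- motif_matrix(w, residue_frequencies(fa))
  d <- tidy(mm)
  expect_equal(d$frequency[d$position == 0 & d$residue == "Y"], 1)
})
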