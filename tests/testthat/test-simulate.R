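small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_proteins = 40, protein_length_mean = 250,
             protein_length_sd = 50, ...)
}

test_that("every generator is deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 123)
  expect_identical(generate_proteome(cfg), generate_proteome(cfg))
  pr <- generate_proteome(cfg)
  s1 <- assign_nitration_sites(pr, cfg)
  s2 <- assign_nitration_sites(pr, cfg)
  expect_identical(s1, s2)
  pool <- nitropeptide_pool(pr, s1, cfg)
  expect_identical(simulate_capture(pool, cfg, "peptide_level"),
                   simulate_capture(pool, cfg, "peptide_level"))
  p <- peptidoform("YLTVAAVFR", "1:nitroY")
  expect_identical(simulate_spectrum(p, cfg, noisy = TRUE, seed = 4),
                   simulate_spectrum(p, cfg, noisy = TRUE, seed = 4))
})

test_that("proteome matches the requested size and background", {
  cfg <- sim_config(seed = 2, n_proteins = 50, protein_length_mean = 2000,
                    protein_length_sd = 10)
  pr <- generate_proteome(cfg)
  expect_length(pr, 50)
  # ~1e5 residues: frequencies recover the background within multinomial
  # error (3 SE per residue)
  obs <- residue_frequencies(pr)
  n <- sum(nchar(pr))
  expect_gt(n, 9e4)
  se <- sqrt(cfg$background * (1 - cfg$background) / n)
  expect_true(all(abs(obs - cfg$background) < 3.5 * se + 1e-4))
})

test_that("tryptic digestion applies K/R cleavage with proline suppression", {
  d <- digest_trypsin("MKAYRGGKR", 0, c(1, 30))
  expect_equal(d$peptide, c("MK", "AYR", "GGK", "R"))
  expect_equal(d$start, c(1L, 3L, 6L, 9L))
  # no cleavage after K before P
  d2 <- digest_trypsin("AKPGR", 0, c(1, 30))
  expect_equal(d2$peptide, "AKPGR")
  d2b <- digest_trypsin("AKPGR", 0, c(1, 30), proline_rule = FALSE)
  expect_equal(d2b$peptide, c("AK", "PGR"))
  # sequence without K/R: one peptide spanning the protein
  d3 <- digest_trypsin("AAAGGAA", 2, c(1, 30))
  expect_equal(d3$peptide, "AAAGGAA")
  # missed cleavages enumerate contiguous runs
  d4 <- digest_trypsin("MKAYRGGKR", 2, c(1, 30))
  expect_true("MKAYR" %in% d4$peptide)        # 1 missed
  expect_true("AYRGGKR" %in% d4$peptide)      # 2 missed
  expect_false("MKAYRGGKR" %in% d4$peptide)   # would be 3 missed
  expect_equal(max(d4$missed_cleavages), 2L)
})

test_that("digestion products are brute-force consistent", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      seq <- paste0(sample(c("A", "G", "K", "R", "P", "Y", "L"), 40,
                           replace = TRUE), collapse = "")
      d <- digest_trypsin(seq, 2, c(1, 40))
      # every product is a substring at its stated position
      expect_true(all(substring(seq, d$start, d$end) == d$peptide))
      # products with 0 missed cleavages contain no internal cut site
      zero <- d[d$missed_cleavages == 0, ]
      for (i in seq_len(nrow(zero))) {
        body <- substr(zero$peptide[i], 1, nchar(zero$peptide[i]) - 1)
        res <- strsplit(body, "")[[1]]
        nxt <- strsplit(substr(zero$peptide[i], 2,
                               nchar(zero$peptide[i])), "")[[1]]
        internal_cut <- res %in% c("K", "R") & nxt != "P"
        expect_false(any(internal_cut))
      }
    }
  })
})

test_that("nitration respects base rate, context bonus, and edge cases", {
  cfg0 <- small_cfg(seed = 3, nitration_base_rate = 0)
  pr <- generate_proteome(cfg0)
  expect_equal(nrow(assign_nitration_sites(pr, cfg0)), 0)

  # bonus 1: empirical rate ~ base rate (binomial 3 SE)
  cfg1 <- sim_config(seed = 4, n_proteins = 100, context_bonus = 1,
                     nitration_base_rate = 0.2)
  pr1 <- generate_proteome(cfg1)
  n_y <- sum(stringr::str_count(pr1, "Y"))
  sites <- assign_nitration_sites(pr1, cfg1)
  se <- sqrt(0.2 * 0.8 / n_y)
  expect_lt(abs(nrow(sites) / n_y - 0.2), 3 * se)

  # strong bonus: nitrated windows enriched in context residues vs all Y
  cfg2 <- sim_config(seed = 5, n_proteins = 100, context_bonus = 8,
                     nitration_base_rate = 0.05)
  pr2 <- generate_proteome(cfg2)
  sites2 <- assign_nitration_sites(pr2, cfg2)
  expect_gt(mean(sites2$context), 0.9)
})

test_that("peptide-mode capture recovers the planted N-terminal bias", {
  cfg <- sim_config(seed = 6, n_proteins = 150)
  pr <- generate_proteome(cfg)
  pool <- nitropeptide_pool(pr, assign_nitration_sites(pr, cfg), cfg)
  psms <- simulate_capture(pool, cfg, "peptide_level")
  distinct_pf <- unique(psms[, c("antibody", "sequence", "modifications")])
  distinct_pf$nterm <- startsWith(distinct_pf$modifications, "1:")
  per_ab <- dplyr::count(distinct_pf, antibody, wt = NULL)
  per_ab$frac <- tapply(distinct_pf$nterm, distinct_pf$antibody,
                        mean)[per_ab$antibody]
  biases <- cfg$antibodies$p_nterm_bias[
    match(per_ab$antibody, cfg$antibodies$name)]
  se <- sqrt(biases * (1 - biases) / per_ab$n)
  expect_true(all(abs(per_ab$frac - biases) < 3.5 * se))
})

test_that("full capture probability makes the four-way overlap the union", {
  cfg <- small_cfg(seed = 7)
  cfg$antibodies$capture_protein <- 1
  pr <- generate_proteome(cfg)
  pool <- nitropeptide_pool(pr, assign_nitration_sites(pr, cfg), cfg)
  psms <- simulate_capture(pool, cfg, "protein_level")
  psv <- validate_psm_table(psms, fasta = pr)
  ct <- build_catalog(psv, pr)
  ov <- overlap_summary(ct, unit = "protein", mode = "protein_level")
  r <- tidy(ov)
  expect_equal(r$intersection_count[r$n_antibodies == 4], ov$union_count)
})

test_that("unknown capture mode errors", {
  cfg <- small_cfg()
  expect_error(simulate_capture(tibble::tibble(), cfg, "lysate"))
})

test_that("noise-free twins score ~1; heavy noise destroys the score", {
  cfg0 <- sim_config(seed = 8, peak_dropout = 0, mz_jitter_sd = 0,
                     intensity_cv = 0, n_contaminants = 0)
  p <- peptidoform("LLYNNVSNFGR", "3:nitroY")
  noisy <- simulate_spectrum(p, cfg0, noisy = TRUE, seed = 21)
  clean <- simulate_spectrum(p, cfg0, noisy = FALSE, seed = 21)
  expect_gte(compare_spectra(noisy$peaks[[1]], clean$peaks[[1]])$score,
             0.99)

  cfg_bad <- sim_config(seed = 8, peak_dropout = 0.9, n_contaminants = 50)
  scores <- vapply(1:100, function(i) {
    a <- simulate_spectrum(p, cfg_bad, noisy = TRUE, seed = 100 + i)
    b <- simulate_spectrum(p, cfg_bad, noisy = FALSE, seed = 100 + i)
    compare_spectra(a$peaks[[1]], b$peaks[[1]])$score
  }, numeric(1))
  expect_gte(mean(scores < 0.5), 0.95)
})

test_that("validation sets plant the requested decoy structure", {
  cfg <- small_cfg(seed = 9)
  vs <- generate_validation_set(cfg, n_pairs = 100, decoy_fraction = 0.3)
  expect_equal(nrow(vs$pairs), 100)
  expect_equal(sum(vs$pairs$is_decoy), 30)
  expect_equal(sum(!vs$pairs$is_decoy), 70)
  # decoys pair spectra of different peptidoforms; true pairs the same
  expect_true(all(vs$pairs$peptidoform_exp[!vs$pairs$is_decoy] ==
                    vs$pairs$peptidoform_syn[!vs$pairs$is_decoy]))
  expect_true(all(vs$pairs$peptidoform_exp[vs$pairs$is_decoy] !=
                    vs$pairs$peptidoform_syn[vs$pairs$is_decoy]))
  expect_equal(nrow(vs$spectra), 200)
  expect_error(generate_validation_set(cfg, n_pairs = 1e6),
               "exceeds available")
})
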