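test_that("normalization and base-peak filter follow the strict 2% rule", {
  s <- tibble::tibble(mz = c(100, 200, 300), intensity = c(1000, 25, 19))
  out <- normalize_filter_peaks(s, match_params())
  expect_equal(out$intensity, c(100, 2.5))  # the 1.9% peak removed
  # a peak at exactly 2.0% is removed ("over" is strict)
  s2 <- tibble::tibble(mz = c(100, 200), intensity = c(1000, 20))
  expect_equal(nrow(normalize_filter_peaks(s2, match_params())), 1)
  # single-peak spectrum normalizes to 100
  s3 <- tibble::tibble(mz = 500, intensity = 42)
  expect_equal(normalize_filter_peaks(s3)$intensity, 100)
  expect_error(
    normalize_filter_peaks(tibble::tibble(mz = 1, intensity = 0)),
    "no positive-intensity")
})

test_that("raising the filter fraction never increases retained peaks", {
  withr::with_seed(31, {
    for (i in 1:20) {
      s <- tibble::tibble(mz = sort(runif(30, 100, 1000)),
                          intensity = rlnorm(30, 3, 2))
      kept <- vapply(c(0, 0.01, 0.02, 0.05, 0.2), function(f) {
        nrow(normalize_filter_peaks(s, match_params(filter = f)))
      }, numeric(1))
      expect_true(all(diff(kept) <= 0))
    }
  })
})

test_that("peak matching is one-to-one within tolerance, closest first", {
  p <- match_params(tolerance = 0.01)
  a <- tibble::tibble(mz = 100.0, intensity = 10)
  b <- tibble::tibble(mz = 100.005, intensity = 20)
  al <- match_peaks(a, b, p)
  expect_equal(attr(al, "matched_count"), 1)
  expect_equal(nrow(al), 1)

  b2 <- tibble::tibble(mz = 100.02, intensity = 20)
  al2 <- match_peaks(a, b2, p)
  expect_equal(attr(al2, "matched_count"), 0)
  expect_equal(nrow(al2), 2)

  # the closer of two competing peaks wins
  a3 <- tibble::tibble(mz = c(100.000, 100.008), intensity = c(5, 7))
  b3 <- tibble::tibble(mz = 100.006, intensity = 9)
  al3 <- match_peaks(a3, b3, p)
  expect_equal(attr(al3, "matched_count"), 1)
  m <- al3[al3$matched, ]
  expect_equal(m$mz_a, 100.008)
  # slot accounting: every input peak occupies exactly one slot
  expect_equal(nrow(al3), 3 - 1)
  expect_error(match_peaks(tibble::tibble(mz = numeric(0),
                                          intensity = numeric(0)),
                           tibble::tibble(mz = numeric(0),
                                          intensity = numeric(0)), p),
               "empty")
})

test_that("alignment slots partition the input peaks", {
  withr::with_seed(32, {
    for (i in 1:25) {
      # narrow window + large jitter: deliberately ambiguous matching
      sp <- random_spectrum_pair(window = c(100, 100.5), jitter = 0.005)
      a <- sp$a
      b <- sp$b
      al <- match_peaks(a, b, match_params())
      mc <- attr(al, "matched_count")
      expect_equal(nrow(al), nrow(a) + nrow(b) - mc)
      expect_equal(sum(al$u > 0 | is.na(al$mz_b)), nrow(a))
      expect_equal(sum(al$v > 0 | is.na(al$mz_a)), nrow(b))
      matched <- al[al$matched, ]
      expect_true(all(abs(matched$mz_a - matched$mz_b) <= 0.01))
    }
  })
})

test_that("cosine score matches the aligned-vector equation", {
  expect_equal(
    cosine_score(tibble::tibble(u = c(100, 50, 0), v = c(100, 0, 80))),
    0.698, tolerance = 1e-3)
  u <- c(3, 1, 4, 1, 5)
  expect_equal(cosine_score(tibble::tibble(u = u, v = u)), 1)
  expect_equal(cosine_score(tibble::tibble(u = u, v = 7.3 * u)), 1)
  expect_equal(cosine_score(tibble::tibble(u = c(1, 0), v = c(0, 1))), 0)
  expect_error(cosine_score(tibble::tibble(u = c(0, 0), v = c(1, 1))),
               "all zero")
})

test_that("compare_spectra composes filter, matching and cosine", {
  s <- tibble::tibble(mz = c(100, 200, 300), intensity = c(50, 100, 10))
  res <- compare_spectra(s, s)
  expect_equal(res$score, 1)
  expect_true(res$passed)

  t <- tibble::tibble(mz = c(120, 220), intensity = c(10, 20))
  res2 <- compare_spectra(s, t)
  expect_equal(res2$score, 0)
  expect_false(res2$passed)
  g <- glance(res2)
  expect_equal(g$matched_count, 0)
})

test_that("comparison is symmetric and bounded in [0, 1]", {
  withr::with_seed(33, {
    for (i in 1:25) {
      sp <- random_spectrum_pair(window = c(100, 100.5), jitter = 0.005)
      a <- sp$a
      b <- sp$b
      sab <- compare_spectra(a, b)$score
      sba <- compare_spectra(b, a)$score
      expect_equal(sab, sba, tolerance = 1e-12)
      expect_gte(sab, 0)
      expect_lte(sab, 1)
    }
  })
})

test_that("fragment annotation labels simulated peaks and respects ties", {
  cfg <- sim_config(seed = 9)
  p <- peptidoform("YLTVAAVFR", "1:nitroY")
  clean <- simulate_spectrum(p, cfg, noisy = FALSE, seed = 5)
  ann <- annotate_fragments(clean$peaks[[1]], p)
  expect_true(all(!is.na(ann$label)))  # noise-free peaks all annotated
  y1 <- ann[abs(ann$mz - 175.119) < 0.01, ]
  expect_equal(y1$label, "y1")
  # against an unrelated peptide of different composition, labeling is
  # near chance: far fewer peaks annotated than against the true peptide
  withr::with_seed(34, {
    frac <- vapply(1:30, function(i) {
      decoy <- random_peptidoform(9)
      a <- annotate_fragments(clean$peaks[[1]], decoy)
      mean(!is.na(a$label))
    }, numeric(1))
  })
  expect_lt(mean(frac), 0.2)
})

test_that("mirror data negates the synthetic side and flags matches", {
  s <- tibble::tibble(mz = c(100, 200, 300), intensity = c(50, 100, 10))
  t <- tibble::tibble(mz = c(100.002, 200, 410), intensity = c(40, 90, 30))
  res <- compare_spectra(s, t)
  md <- mirror_data(res)
  bottom <- md[md$side == "synthetic", ]
  expect_true(all(bottom$intensity <= 0))
  expect_equal(sort(-bottom$intensity),
               sort(normalize_filter_peaks(t)$intensity))
  expect_equal(sum(md$matched & md$side == "experimental"),
               res$matched_count)
  # identical spectra give point-symmetric data
  res_id <- compare_spectra(s, s)
  md_id <- mirror_data(res_id)
  up <- md_id[md_id$side == "experimental", ]
  dn <- md_id[md_id$side == "synthetic", ]
  expect_equal(up$intensity, -dn$intensity)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
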