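# Independent oracles and fixture builders shared across tests.

# Exhaustive one-to-one peak matching: among all matchings of pairs within
# tolerance, maximize the matched count, then minimize total |delta m/z|.
# Feasible for spectra of <= 8 peaks; used as the oracle for the greedy
# matcher.
exhaustive_match <- function(mza, mzb, tol) {
  na <- length(mza)
  nb <- length(mzb)
  best <- list(count = -1L, total = Inf, pairs = cbind(integer(0), integer(0)))
  consider <- function(pairs) {
    cnt <- nrow(pairs)
    total <- if (cnt == 0) 0 else sum(abs(mza[pairs[, 1]] - mzb[pairs[, 2]]))
    if (cnt > best$count || (cnt == best$count && total < best$total)) {
      best <<- list(count = cnt, total = total, pairs = pairs)
    }
  }
  rec <- function(i, used_b, pairs) {
    if (i > na) {
      consider(pairs)
      return(invisible(NULL))
    }
    rec(i + 1L, used_b, pairs)  # leave peak i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && abs(mza[i] - mzb[j]) <= tol) {
        used_b[j] <- TRUE
        rec(i + 1L, used_b, rbind(pairs, c(i, j)))
        used_b[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nb), cbind(integer(0), integer(0)))
  best
}

# Cosine score implied by an explicit pairing of two peak lists: unmatched
# peaks contribute zero to the dot product but fully to the norms.
pairing_cosine <- function(pa, pb, pairs) {
  if (nrow(pairs) == 0) return(0)
  sum(pa$intensity[pairs[, 1]] * pb$intensity[pairs[, 2]]) /
    sqrt(sum(pa$intensity^2) * sum(pb$intensity^2))
}

# Random small peak list over an m/z window.
random_small_spectrum <- function(n_peaks, window = c(100, 500)) {
  mz <- stats::runif(n_peaks, window[1], window[2])
  tibble::tibble(mz = sort(mz), intensity = stats::runif(n_peaks, 1, 100))
}

# A pair of small spectra resembling an (experimental, synthetic) pair:
# part of b is a jittered copy of a, the rest is independent. Defaults
# mirror centroided MS/MS conditions: peaks spread over hundreds of Th,
# shared peaks reproduced with ~3 mDa jitter. A narrow window plus larger
# jitter makes matching deliberately ambiguous for stress tests.
random_spectrum_pair <- function(window = c(100, 500), jitter = 0.003) {
  a <- random_small_spectrum(sample(2:8, 1), window)
  n_b <- sample(2:8, 1)
  n_shared <- sample(0:min(n_b, nrow(a)), 1)
  shared <- sample(a$mz, n_shared) + stats::rnorm(n_shared, 0, jitter)
  rest <- stats::runif(n_b - n_shared, window[1], window[2])
  b <- tibble::tibble(mz = sort(c(shared, rest)),
                      intensity = stats::runif(n_b, 1, 100))
  list(a = a, b = b)
}

# Random valid peptidoform with 0-2 modifications drawn from the default
# registry (targets respected).
random_peptidoform <- function(len = sample(6:15, 1)) {
  mods_tbl <- default_modifications()
  seq <- paste0(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                       len, replace = TRUE), collapse = "")
  res <- strsplit(seq, "")[[1]]
  candidates <- list()
  for (i in seq_len(nrow(mods_tbl))) {
    targets <- mods_tbl$targets[[i]]
    pos <- if ("N-term" %in% targets) 1L else which(res %in% targets)
    for (p in pos) {
      candidates[[length(candidates) + 1]] <-
        list(position = p, name = mods_tbl$name[i])
    }
  }
  n_mods <- sample(0:2, 1)
  mods <- NULL
  if (n_mods > 0 && length(candidates) > 0) {
    pick <- sample(length(candidates), min(n_mods, length(candidates)))
    mods <- tibble::tibble(
      position = vapply(candidates[pick], `[[`, integer(1), "position"),
      name = vapply(candidates[pick], `[[`, character(1), "name")
    )
    mods <- mods[!duplicated(mods$position), ]
  }
  peptidoform(seq, mods, charge = sample(2:4, 1))
}

# Tiny deterministic FASTA used by catalog tests.
toy_fasta <- function() {
  c(PROT1 = "MKAYRGGKRYLTVAAVFRAAYK",
    PROT2 = "GGYAAAKRYPPLYE",
    PROT3 = "AAAAAKYGGGGRKLLY")
}
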