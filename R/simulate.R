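# Ground-truthed synthetic data: a random proteome, probabilistic nitration
# with a sequence-context bonus, antibody capture with a mode-dependent
# N-terminal bias, and noisy/clean fragment-spectrum pairs. Everything is
# deterministic under the config seed.

#' Simulation configuration
#'
#' Defaults emulate the statistical structure of the enrichment study at
#' desk scale: four antibodies in triplicate, protein-level capture acting
#' on whole proteins (no positional bias, N-terminal nitroY fraction at
#' the unbiased tryptic baseline of roughly 8--12%) and peptide-level
#' capture with per-antibody N-terminal biases spanning 0.35--0.65;
#' nitration susceptibility boosted where small non-polar residues
#' (G, L, P, A, E) flank the tyrosine; tryptic digestion with up to two
#' missed cleavages and proline suppression.
#'
#' @param seed Integer seed; fixed seed gives identical outputs.
#' @param n_proteins Number of simulated proteins.
#' @param protein_length_mean,protein_length_sd Protein length
#'   distribution (normal, truncated at 60 residues).
#' @param background Named residue background frequencies (defaults to
#'   human-proteome-like frequencies).
#' @param nitration_base_rate Per-tyrosine nitration probability without
#'   context.
#' @param context_bonus Multiplier applied when any context residue lies
#'   within `context_halfwidth` of the tyrosine.
#' @param context_residues Residues conferring susceptibility.
#' @param context_halfwidth Flank width for the context check (residues).
#' @param antibodies Data frame with columns `name`, `capture_protein`
#'   and `capture_peptide` (per-replicate capture probabilities),
#'   `p_nterm_bias` (target N-terminal peptidoform fraction in
#'   peptide-level mode).
#' @param replicates Replicates per antibody (default 3).
#' @param missed_cleavage_max Maximum tryptic missed cleavages (default 2).
#' @param peptide_length_bounds Peptide length bounds (default 6--30).
#' @param proline_rule Suppress cleavage before proline (default TRUE).
#' @param peak_dropout,mz_jitter_sd,intensity_cv,n_contaminants Spectrum
#'   noise: per-peak dropout probability, m/z jitter SD in Da,
#'   multiplicative intensity coefficient of variation, and number of
#'   uniform contaminant peaks added to noisy spectra.
#' @param intensity_meanlog,intensity_sdlog Log-normal fragment intensity
#'   model shared between a clean spectrum and its noisy twin.
#' @param doubly_charged_min_mass Fragments above this neutral mass (Da)
#'   also appear doubly charged.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 300L,
                       protein_length_mean = 420,
                       protein_length_sd = 110,
                       background = NULL,
                       nitration_base_rate = 0.12,
                       context_bonus = 3,
                       context_residues = c("G", "L", "P", "A", "E"),
                       context_halfwidth = 2L,
                       antibodies = default_antibodies(),
                       replicates = 3L,
                       missed_cleavage_max = 2L,
                       peptide_length_bounds = c(6L, 30L),
                       proline_rule = TRUE,
                       peak_dropout = 0.10,
                       mz_jitter_sd = 0.003,
                       intensity_cv = 0.25,
                       n_contaminants = 6L,
                       intensity_meanlog = log(300),
                       intensity_sdlog = 0.7,
                       doubly_charged_min_mass = 900) {
  if (is.null(background)) {
    background <- default_background()
  }
  background <- background[AA_ALPHABET]
  if (anyNA(background) || any(background <= 0)) {
    stop("background must assign positive frequency to all 20 residues",
         call. = FALSE)
  }
  background <- background / sum(background)
  stopifnot(
    nitration_base_rate >= 0, nitration_base_rate <= 1,
    context_bonus >= 0, peak_dropout >= 0, peak_dropout <= 1,
    all(c("name", "capture_protein", "capture_peptide",
          "p_nterm_bias") %in% names(antibodies)),
    all(antibodies$p_nterm_bias > 0 & antibodies$p_nterm_bias < 1),
    replicates >= 1
  )
  cfg <- list(
    seed = as.integer(seed), n_proteins = as.integer(n_proteins),
    protein_length_mean = protein_length_mean,
    protein_length_sd = protein_length_sd,
    background = background,
    nitration_base_rate = nitration_base_rate,
    context_bonus = context_bonus,
    context_residues = context_residues,
    context_halfwidth = as.integer(context_halfwidth),
    antibodies = tibble::as_tibble(antibodies),
    replicates = as.integer(replicates),
    missed_cleavage_max = as.integer(missed_cleavage_max),
    peptide_length_bounds = as.integer(peptide_length_bounds),
    proline_rule = proline_rule,
    peak_dropout = peak_dropout, mz_jitter_sd = mz_jitter_sd,
    intensity_cv = intensity_cv, n_contaminants = as.integer(n_contaminants),
    intensity_meanlog = intensity_meanlog,
    intensity_sdlog = intensity_sdlog,
    doubly_charged_min_mass = doubly_charged_min_mass
  )
  structure(cfg, class = "sim_config")
}

#' Default antibody panel
#'
#' Four antibodies in the style of the commercial panel: capture
#' probabilities high enough at protein level that most proteins are
#' shared by all four, lower at peptide level, and N-terminal biases
#' spanning the 0.35--0.65 range seen in peptide-level enrichment.
#'
#' @return A tibble with one row per antibody.
#' @export
default_antibodies <- function() {
  tibble::tibble(
    name = c("AB1", "AB2", "AB3", "AB4"),
    capture_protein = c(0.65, 0.62, 0.60, 0.55),
    capture_peptide = c(0.45, 0.42, 0.40, 0.35),
    p_nterm_bias = c(0.35, 0.45, 0.55, 0.65)
  )
}

#' Human-proteome-like residue background frequencies
#'
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
default_background <- function() {
  f <- c(A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0138,
         Q = 0.0393, E = 0.0672, G = 0.0707, H = 0.0227, I = 0.0591,
         L = 0.0965, K = 0.0580, M = 0.0241, F = 0.0386, P = 0.0474,
         S = 0.0664, T = 0.0536, W = 0.0110, Y = 0.0292, V = 0.0686)
  f[AA_ALPHABET] / sum(f)
}

# deterministic derived seeds, kept below 2^31
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * stream) %% 2147483629)
}

#' Generate a random proteome
#'
#' @param cfg A [sim_config()].
#' @return Named character vector of protein sequences (accessions
#'   `SIMP0001`...). Deterministic under the config seed.
#' @export
generate_proteome <- function(cfg) {
  withr::with_seed(sub_seed(cfg$seed, 1), {
    lens <- pmax(60L, as.integer(round(
      stats::rnorm(cfg$n_proteins, cfg$protein_length_mean,
                   cfg$protein_length_sd))))
    seqs <- vapply(lens, function(n) {
      paste0(sample(AA_ALPHABET, n, replace = TRUE, prob = cfg$background),
             collapse = "")
    }, character(1))
  })
  stats::setNames(seqs, sprintf("SIMP%04d", seq_len(cfg$n_proteins)))
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K/R, optionally suppressed before proline, and
#' emits every product with 0 to `missed_cleavage_max` missed cleavages
#' whose length lies within the bounds.
#'
#' @param sequence Uppercase protein sequence.
#' @param missed_cleavage_max Maximum missed cleavages (default 2).
#' @param length_bounds Length bounds, inclusive (default c(6, 30)).
#' @param proline_rule Suppress cleavage before P (default TRUE).
#' @return A tibble with `peptide`, `start`, `end` (1-based, inclusive),
#'   `missed_cleavages`.
#' @export
digest_trypsin <- function(sequence, missed_cleavage_max = 2L,
                           length_bounds = c(6L, 30L), proline_rule = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  n <- nchar(sequence)
  res <- stringr::str_split_1(sequence, "")
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (proline_rule && length(cut_after) > 0) {
    cut_after <- cut_after[res[cut_after + 1] != "P"]
  }
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  nfrag <- length(starts)
  rows <- purrr::map_dfr(0:missed_cleavage_max, function(mc) {
    if (mc >= nfrag) return(tibble::tibble())
    i <- seq_len(nfrag - mc)
    tibble::tibble(start = starts[i], end = ends[i + mc],
                   missed_cleavages = mc)
  })
  rows <- rows[rows$end - rows$start + 1 >= length_bounds[1] &
                 rows$end - rows$start + 1 <= length_bounds[2], ]
  rows$peptide <- stringr::str_sub(sequence, rows$start, rows$end)
  rows[, c("peptide", "start", "end", "missed_cleavages")]
}

#' Assign ground-truth nitration sites
#'
#' Every tyrosine is nitrated independently with probability
#' `nitration_base_rate`, multiplied by `context_bonus` (capped at 0.99)
#' when any context residue occurs within `context_halfwidth` positions.
#'
#' @param proteome Named sequence vector ([generate_proteome()]).
#' @param cfg A [sim_config()].
#' @return A tibble of true sites: `protein`, `position`, `context`.
#' @export
assign_nitration_sites <- function(proteome, cfg) {
  all_y <- purrr::imap_dfr(as.list(proteome), function(seq, acc) {
    pos <- stringr::str_locate_all(seq, "Y")[[1]][, 1]
    if (length(pos) == 0) return(tibble::tibble())
    hw <- cfg$context_halfwidth
    ctx <- vapply(pos, function(p) {
      flank <- paste0(
        stringr::str_sub(seq, max(1, p - hw), p - 1),
        stringr::str_sub(seq, p + 1, min(nchar(seq), p + hw)))
      any(stringr::str_split_1(flank, "") %in% cfg$context_residues)
    }, logical(1))
    tibble::tibble(protein = acc, position = as.integer(pos), context = ctx)
  })
  if (nrow(all_y) == 0) {
    return(tibble::tibble(protein = character(0), position = integer(0),
                          context = logical(0)))
  }
  p <- pmin(0.99, cfg$nitration_base_rate *
              ifelse(all_y$context, cfg$context_bonus, 1))
  withr::with_seed(sub_seed(cfg$seed, 2), {
    hit <- stats::runif(nrow(all_y)) < p
  })
  all_y[hit, ]
}

#' Enumerate the nitropeptidoform pool
#'
#' Digests every protein and crosses the products with the true nitration
#' sites they cover. Each peptidoform carries exactly one nitro site
#' (sub-stoichiometric nitration); peptides covering several sites yield
#' one peptidoform per site.
#'
#' @param proteome Named sequence vector.
#' @param sites Site tibble from [assign_nitration_sites()].
#' @param cfg A [sim_config()].
#' @return A tibble of distinct peptidoforms: `protein`, `peptide`,
#'   `start`, `end`, `missed_cleavages`, `site_position` (protein
#'   coordinate), `peptide_position`, `is_nterm`, `peptidoform`.
#' @export
nitropeptide_pool <- function(proteome, sites, cfg) {
  with_sites <- unique(sites$protein)
  peptides <- purrr::map_dfr(with_sites, function(acc) {
    d <- digest_trypsin(proteome[[acc]], cfg$missed_cleavage_max,
                        cfg$peptide_length_bounds, cfg$proline_rule)
    d$protein <- acc
    d
  })
  pool <- dplyr::inner_join(peptides, sites, by = "protein",
                            relationship = "many-to-many")
  pool <- pool[pool$position >= pool$start & pool$position <= pool$end, ]
  pool$site_position <- pool$position
  pool$peptide_position <- pool$position - pool$start + 1L
  pool$is_nterm <- pool$peptide_position == 1L
  pool$peptidoform <- paste0(pool$peptide, "/", pool$peptide_position,
                             ":nitroY")
  pool <- dplyr::distinct(pool, .data$peptidoform, .keep_all = TRUE)
  tibble::as_tibble(pool[, c("protein", "peptide", "start", "end",
                             "missed_cleavages", "site_position",
                             "peptide_position", "is_nterm", "peptidoform")])
}

# Solve replicate-union capture probabilities so that the expected
# distinct-peptidoform N-terminal fraction equals the antibody bias b.
# U1/U0 = (b/(1-b)) * (n0/n1); the per-replicate probability follows as
# 1 - (1-U)^(1/R).
nterm_capture_probs <- function(c_rep, bias, n1, n0, replicates) {
  u0 <- 1 - (1 - c_rep)^replicates
  r <- (bias / (1 - bias)) * (n0 / n1)
  u1 <- u0 * r
  if (u1 > 0.995) {
    u1 <- 0.995
    u0 <- u1 / r
  }
  list(q1 = 1 - (1 - u1)^(1 / replicates),
       q0 = 1 - (1 - u0)^(1 / replicates))
}

#' Simulate antibody capture
#'
#' Protein-level mode captures whole proteins per antibody x replicate
#' with the antibody's protein capture probability and emits every
#' nitropeptidoform of a captured protein (no positional bias). In
#' peptide-level mode capture acts on individual peptidoforms, with the
#' capture probability of position-1 (N-terminal nitroY) peptidoforms
#' boosted so that the expected N-terminal fraction among distinct
#' captured peptidoforms equals the antibody's `p_nterm_bias`.
#'
#' @param pool Peptidoform pool from [nitropeptide_pool()].
#' @param cfg A [sim_config()].
#' @param mode `"protein_level"` or `"peptide_level"`.
#' @return A PSM-format tibble (columns as in [read_psm_table()]).
#' @export
simulate_capture <- function(pool, cfg,
                             mode = c("protein_level", "peptide_level")) {
  mode <- match.arg(mode)
  abs_tbl <- cfg$antibodies
  n1 <- sum(pool$is_nterm)
  n0 <- sum(!pool$is_nterm)
  stream <- if (mode == "protein_level") 10 else 20
  rows <- withr::with_seed(sub_seed(cfg$seed, stream), {
    purrr::map_dfr(seq_len(nrow(abs_tbl)), function(a) {
      ab <- abs_tbl$name[a]
      purrr::map_dfr(seq_len(cfg$replicates), function(r) {
        if (mode == "protein_level") {
          prots <- unique(pool$protein)
          caught <- prots[stats::runif(length(prots)) <
                            abs_tbl$capture_protein[a]]
          hit <- pool$protein %in% caught
        } else {
          probs <- nterm_capture_probs(abs_tbl$capture_peptide[a],
                                       abs_tbl$p_nterm_bias[a],
                                       n1, n0, cfg$replicates)
          q <- ifelse(pool$is_nterm, probs$q1, probs$q0)
          hit <- stats::runif(nrow(pool)) < q
        }
        caught_pool <- pool[hit, ]
        if (nrow(caught_pool) == 0) return(tibble::tibble())
        tibble::tibble(
          sequence = caught_pool$peptide,
          modifications = paste0(caught_pool$peptide_position, ":nitroY"),
          protein = caught_pool$protein,
          start = caught_pool$start,
          spectrum_id = sprintf("%s|%s|r%d|%s", mode, ab, r,
                                caught_pool$peptidoform),
          antibody = ab,
          mode = mode,
          replicate = r
        )
      })
    })
  })
  rows
}

#' Simulate a fragment spectrum for a peptidoform
#'
#' Peaks sit at the theoretical b/y m/z values (singly charged, plus
#' doubly charged for fragments above `doubly_charged_min_mass`), with
#' log-normal intensities drawn under `seed`. The clean spectrum stops
#' there; the noisy twin (same seed, hence the same base intensity draw)
#' additionally drops peaks, jitters m/z, perturbs intensities, and adds
#' uniform contaminant peaks, so the noise parameters are the sole driver
#' of score degradation between twins.
#'
#' @param p A `peptidoform`.
#' @param cfg A [sim_config()].
#' @param noisy Apply the noise model (default FALSE).
#' @param seed Seed for this spectrum (defaults to the config seed).
#' @param spectrum_id Identifier (defaults to the peptidoform id).
#' @return A one-row spectra tibble ([spectra_table()]).
#' @export
simulate_spectrum <- function(p, cfg, noisy = FALSE,
                              seed = cfg$seed,
                              spectrum_id = peptidoform_id(p)) {
  ions <- fragment_ions(p, max_charge = 2L)
  ions <- ions[ions$charge == 1L |
                 ions$neutral_mass > cfg$doubly_charged_min_mass, ]
  withr::with_seed(seed, {
    base_int <- stats::rlnorm(nrow(ions), cfg$intensity_meanlog,
                              cfg$intensity_sdlog)
    mz <- ions$mz
    int <- base_int
    if (noisy) {
      keep <- stats::runif(length(mz)) >= cfg$peak_dropout
      if (sum(keep) < 3) {
        # floor of 3 peaks so a spectrum never empties out; drawn at
        # random to avoid biasing survivors toward dominant ions
        keep[sample(which(!keep), 3 - sum(keep))] <- TRUE
      }
      mz <- mz[keep]
      int <- int[keep]
      mz <- mz + stats::rnorm(length(mz), 0, cfg$mz_jitter_sd)
      sdlog_noise <- sqrt(log(1 + cfg$intensity_cv^2))
      int <- int * stats::rlnorm(length(int), -sdlog_noise^2 / 2, sdlog_noise)
      if (cfg$n_contaminants > 0) {
        cmz <- stats::runif(cfg$n_contaminants, min = 100,
                            max = max(ions$mz) + 50)
        cint <- stats::rlnorm(cfg$n_contaminants,
                              cfg$intensity_meanlog - 0.7,
                              cfg$intensity_sdlog)
        mz <- c(mz, cmz)
        int <- c(int, cint)
      }
    }
  })
  spectra_table(
    spectrum_id,
    precursor_mz = precursor_mz(p),
    precursor_charge = p$charge,
    peaks = list(tibble::tibble(mz = mz, intensity = int)),
    provenance = if (noisy) "experimental" else "synthetic"
  )
}

#' Generate a paired validation set
#'
#' Builds `n_pairs` (experimental-like noisy, synthetic-like clean)
#' spectrum pairs from the nitropeptidoform pool. A fraction of pairs are
#' planted decoys whose experimental spectrum comes from a different
#' peptidoform; the assignment is recorded in the ground truth.
#'
#' @param cfg A [sim_config()].
#' @param n_pairs Number of pairs.
#' @param decoy_fraction Fraction of decoy pairs (default 0.3).
#' @param pool Optional pre-built peptidoform pool; simulated from `cfg`
#'   when missing.
#' @return A list with `spectra` (spectra tibble, experimental and
#'   synthetic), `pairs` (tibble: `pair_id`, `experimental_id`,
#'   `synthetic_id`, `peptidoform_syn`, `peptidoform_exp`, `is_decoy`).
#' @export
generate_validation_set <- function(cfg, n_pairs = 100L,
                                    decoy_fraction = 0.3, pool = NULL) {
  if (is.null(pool)) {
    proteome <- generate_proteome(cfg)
    sites <- assign_nitration_sites(proteome, cfg)
    pool <- nitropeptide_pool(proteome, sites, cfg)
  }
  n_pairs <- as.integer(n_pairs)
  n_decoy <- as.integer(round(n_pairs * decoy_fraction))
  need <- n_pairs + n_decoy
  if (need > nrow(pool)) {
    stop("n_pairs (+ decoy sources) exceeds available peptidoforms: need ",
         need, ", have ", nrow(pool), call. = FALSE)
  }
  withr::with_seed(sub_seed(cfg$seed, 30), {
    picked <- sample(nrow(pool), need)
    decoy_flag <- c(rep(FALSE, n_pairs - n_decoy), rep(TRUE, n_decoy))
    decoy_flag <- sample(decoy_flag)
  })
  targets <- pool[picked[seq_len(n_pairs)], ]
  decoy_sources <- pool[picked[n_pairs + seq_len(n_decoy)], ]
  decoy_idx <- which(decoy_flag)
  exp_source <- targets
  if (n_decoy > 0) {
    exp_source[decoy_idx, ] <- decoy_sources
  }
  make_pf <- function(row) {
    peptidoform(row$peptide,
                paste0(row$peptide_position, ":nitroY"), charge = 2L)
  }
  spectra <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    syn_p <- make_pf(targets[i, ])
    exp_p <- make_pf(exp_source[i, ])
    dplyr::bind_rows(
      simulate_spectrum(exp_p, cfg, noisy = TRUE,
                        seed = sub_seed(cfg$seed, 1000 + i),
                        spectrum_id = sprintf("exp|pair%04d", i)),
      simulate_spectrum(syn_p, cfg, noisy = FALSE,
                        seed = sub_seed(cfg$seed,
                                        if (decoy_flag[i]) 2000 + i
                                        else 1000 + i),
                        spectrum_id = sprintf("syn|pair%04d", i))
    )
  })
  pairs <- tibble::tibble(
    pair_id = sprintf("pair%04d", seq_len(n_pairs)),
    experimental_id = sprintf("exp|pair%04d", seq_len(n_pairs)),
    synthetic_id = sprintf("syn|pair%04d", seq_len(n_pairs)),
    peptidoform_syn = targets$peptidoform,
    peptidoform_exp = exp_source$peptidoform,
    is_decoy = decoy_flag
  )
  list(spectra = spectra, pairs = pairs)
}

#' Simulate a full enrichment experiment
#'
#' Proteome, ground-truth nitration sites, peptidoform pool, and PSM
#' tables for both enrichment modes across the antibody panel.
#'
#' @param cfg A [sim_config()].
#' @return A list with `proteome`, `sites`, `pool`, `psms` (both modes
#'   bound together, PSM-table format), and `config`.
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  proteome <- generate_proteome(cfg)
  sites <- assign_nitration_sites(proteome, cfg)
  pool <- nitropeptide_pool(proteome, sites, cfg)
  psms <- dplyr::bind_rows(
    simulate_capture(pool, cfg, "protein_level"),
    simulate_capture(pool, cfg, "peptide_level")
  )
  list(proteome = proteome, sites = sites, pool = pool, psms = psms,
       config = cfg)
}
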