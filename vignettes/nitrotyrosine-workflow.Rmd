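---
title: "Cataloging and validating nitrotyrosine peptides: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloging and validating nitrotyrosine peptides: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrocat)
```

# The analysis problem

Tyrosine nitration (3-nitrotyrosine, nitroY; +44.985 Da monoisotopic) is a
low-stoichiometry oxidative modification. Global studies enrich it with
anti-nitrotyrosine antibodies before LC-MS/MS, either capturing modified
**proteins** (then digesting) or capturing modified **peptides** from a
digest. The two designs have different biases, and different commercial
antibodies capture overlapping but not identical sets of targets. After a
search engine has produced peptide-spectrum matches (PSMs), the downstream
questions this package answers are:

1. Where are the nitro sites on the proteins, and how are they distributed
   within peptides (in particular: how often at the peptide N-terminus)?
2. How much do the antibodies' captures overlap, per enrichment mode?
3. What sequence context surrounds nitrated tyrosines?
4. Do the identifications survive validation against synthetic peptide
   standards, judged by cosine spectral similarity?

# Mass and fragment conventions

Residue masses are derived at full precision from elemental compositions
and monoisotopic atomic masses — the same `delta_mass()` arithmetic that
produces the modification deltas, so there is a single source of truth.
The charge carrier is the proton at 1.007276 Da and water is 18.010565 Da.
The four built-in modifications are nitration of tyrosine (N O2 H-1,
+44.985), oxidation of methionine (+15.995), protein N-terminal
acetylation (+42.011) and the fixed carbamidomethylation of cysteine
(+57.021); further definitions load from YAML.

Fragment generation emits the b and y series only, matching higher-energy
collisional dissociation behaviour; a/c/z ions, neutral losses (including
the nitro-specific losses of O and NO some instruments show), isotope
envelopes and internal fragments are out of scope. A b_k ion carries
exactly the modifications localized in residues 1..k and a y_k ion those
in the C-terminal k residues, which yields the conservation law checked by
the property tests: neutral b_k + neutral y_(n−k) equals the peptidoform's
neutral mass to 1e−9 Da for every k. At most one modification is allowed
per residue position, mirroring the search space of the upstream engine.

# Spectral validation

The score between an experimental spectrum and its synthetic-standard
counterpart is the cosine of the aligned intensity vectors:

$$\cos\theta = \frac{\sum_i u_i v_i}{\sqrt{\sum_i u_i^2 \cdot \sum_i v_i^2}}$$

The stages, in order, with the choices that were genuinely open:

- **Normalization.** Both spectra are rescaled to relative intensity
  (base peak = 100) before filtering and scoring. Cosine similarity is
  scale-invariant, so this changes nothing about the score while making
  the base-peak filter well defined across acquisitions.
- **Base-peak filter.** Only peaks *strictly over* 2% of the base peak are
  kept; a peak at exactly 2.0% is removed. The filter is applied
  symmetrically to both spectra.
- **Peak matching.** One-to-one matching at a 0.01 Da tolerance, greedy in
  ascending |Δm/z| with ties broken by lower m/z — deterministic and
  order-independent, hence the score is symmetric in its arguments.
  Greedy matching is maximal but not guaranteed maximum-cardinality; on
  randomly generated small spectra with peaks spread over a realistic m/z
  range it reproduces the exhaustively enumerated optimal matching
  exactly (property-tested at n = 1000). Pathologically dense peak lists
  (several peaks within ~2 tolerances of each other) can make greedy drop
  a match relative to the optimum; such densities do not arise in
  centroided spectra at 0.01 Da.
- **Scoring.** Intensities enter the cosine untransformed — no square-root
  or log stabilization — and unmatched peaks contribute zeros on the
  other side. The score is 0 with no matched peaks and 1 exactly when the
  aligned vectors are proportional.
- **Acceptance.** A pair passes when the score strictly exceeds 0.7.
- Precursor m/z agreement between the paired spectra is *not* enforced:
  pairs are declared explicitly by the pair table. A precursor pre-filter
  would be a reasonable addition for untargeted use.

Fragment annotation labels each peak with the nearest theoretical b/y ion
within 0.01 Da (configurable, and deliberately the matching tolerance
rather than the wider tolerance a search engine uses); ties resolve to the
smaller mass error, then the lower charge, then y over b.

# Catalog statistics

A catalog record is one nitro site in one PSM: protein accession, protein
position (`start + peptide position − 1`, validated to be a tyrosine in
the FASTA), peptidoform, antibody, mode, replicate. Parsing and cataloging
are *total*: every input row is either a valid record or a row-numbered
rejection, and counts reconcile in the run report.

- **Counting unit.** "Peptide" counts are distinct modified peptidoforms —
  sequence plus the localized nitro sites — ignoring charge and replicate.
  The N-terminal fraction per antibody × mode is the share of distinct
  nitroY peptidoforms whose nitroY sits at peptide position 1, counted
  across replicates.
- **Overlap.** For each enrichment mode, exact counts of every exclusive
  Venn region over the antibody combinations (2⁴ − 1 regions for four
  antibodies); exclusive regions partition the union by construction, and
  the suite cross-checks them against brute-force set arithmetic.
- **Motif.** Windows of ±7 residues (a 15-mer; configurable) around each
  distinct protein site, taken from the protein sequence and padded with
  `-` past the termini. Cell log2-odds compare the within-window residue
  frequency (over non-gap entries) to a background. The background is the
  residue composition of the supplied FASTA — not of the identified
  peptides — to avoid circularity. Note one interpretive caveat: in
  peptide-level data a K/R enrichment at position −1 is partly a tryptic
  artifact (any peptide starting at the nitroY is preceded by a cleavage
  site), so the matrix reports, and the analyst adjudicates.

# What the simulator emulates

`sim_config()` defaults define the study conditions end to end:

- **Proteome.** 300 random proteins, length ~N(420, 110²) truncated at 60,
  residues drawn i.i.d. from human-proteome-like frequencies. Real
  proteins have domain structure, homology and biased local composition;
  none of that is emulated, so motif results on simulated data only test
  recovery of *planted* context, not biological plausibility.
- **Nitration.** Every tyrosine is nitrated independently with base
  probability 0.12, multiplied by 3 when any of G, L, P, A, E lies within
  ±2 residues (small non-polar context raises susceptibility). The
  chemistry of peroxynitrite is not modeled — treatment only creates
  sites. Because ~84% of tyrosines have such context under this
  background, the per-cell enrichment this plants is modest (~1.1×), which
  is why recovery tests read the *pooled* context-residue count near the
  center rather than single cells.
- **Digestion.** Trypsin: cleave after K/R, suppressed before P (the
  common engine default, toggleable), up to 2 missed cleavages, peptide
  length 6–30.
- **Capture.** Four antibodies in triplicate. Protein-level capture takes
  whole proteins (per-replicate probabilities 0.65/0.62/0.60/0.55, high
  enough that most proteins are shared by all four antibodies) and emits
  every nitropeptidoform of a captured protein, so its N-terminal
  fraction sits at the unbiased digest baseline (~7–10%). Peptide-level
  capture acts on individual peptidoforms with the position-1 class
  boosted so that the *expected distinct-peptidoform N-terminal fraction
  across the replicate union* equals the antibody's bias
  (0.35/0.45/0.55/0.65 across the panel). The boost is solved at the
  union level and converted to per-replicate probabilities as
  1 − (1 − U)^(1/R); when the boosted class saturates (bias 0.65), the
  unboosted class is scaled down instead. A separate per-antibody motif
  preference is deliberately not modeled: position-1 bias *is* the
  positional/motif preference (an N-terminal nitroY is preceded by K/R in
  the protein), and a second knob would be confounded with it.
- **Peptidoforms.** Each carries exactly one nitro site; a peptide
  covering several true sites yields one peptidoform per site,
  emulating sub-stoichiometric modification.
- **Spectra.** Peaks at all b/y m/z (charge 1; charge 2 additionally for
  fragments above 900 Da), intensities log-normal (meanlog log 300,
  sdlog 0.7) drawn once per pair so the clean "synthetic-standard"
  spectrum and its noisy "experimental" twin share the draw — the noise
  parameters are then the sole driver of score degradation. Noise:
  10% peak dropout (with a floor of three randomly chosen surviving
  peaks), m/z jitter sd 3 mDa, 25% multiplicative intensity CV, and six
  uniform contaminant peaks at about one e-fold below signal intensity.
  No retention time, isotope patterns, charge-state envelopes or
  replicate-level quantitation.
- **Validation sets.** n pairs with a configurable planted decoy fraction
  (default 0.3): a decoy's experimental spectrum comes from a different
  peptidoform. Under default noise the true/decoy score distributions are
  far apart (true pairs mostly 0.85–0.99, decoys near 0), so the 0.7
  threshold separates them with sensitivity and specificity above 0.95
  and a pass fraction tracking the true-pair fraction.

Everything is deterministic under the config seed; derived sub-seeds keep
the generators independent of each other and below 2³¹.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical checks have comfortable power:
parameter-recovery simulations use 1700 proteins (so that even the
0.65-bias antibody captures over 2000 distinct peptidoforms, giving
3-standard-error bands of about ±0.03), motif recovery uses 150 proteins
(≈600 windows, pooled z ≈ 5 for the planted bonus), and spectral
validation uses 500 pairs. Mass comparisons against printed 3-decimal
values round only at the comparison; internal arithmetic keeps full
precision, since 0.01 Da matching would be corrupted by 3-decimal
rounding. Degenerate inputs fail loudly and early: empty spectra, all-zero
intensity vectors, unknown residues or modifications, out-of-range
positions and non-tyrosine site mappings are all rejected with diagnostics
rather than propagated.

# Limitations

- Protein inference is out of scope: each PSM carries one accession, as
  search-engine exports provide; shared-peptide parsimony is not
  attempted.
- The cosine score uses raw relative intensities; square-root or rank
  transforms, spectral library search, chimera deconvolution and
  retention-time alignment are out of scope.
- The simulator's i.i.d. proteome understates real sequence structure;
  passing recovery tests demonstrates the statistics recover planted
  parameters, not that real data will show the same effect sizes.
- GO/KEGG functional enrichment of the cataloged proteins is left to
  dedicated tools.
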