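---
title: "Stub-doublet detection for MS-cleavable crosslinkers: models and methods"
author: "xldoublet developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stub-doublet detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xldoublet)
```

## The problem

MS-cleavable crosslinkers covalently join spatially proximal residues
(typically lysines, through NHS-ester chemistry) and carry labile bonds that
break inside the mass spectrometer. Gas-phase cleavage releases each of the
two linked peptides with a small crosslinker remnant — a *stub*. Because the
same peptide can appear with two different stubs, each peptide produces a
characteristic pair of peaks (a *doublet*) separated by a fixed delta mass.
Acquisition software exploits this: when an MS2 scan contains a peak pair at
the signature delta, one of the pair is isolated for MS3 so each peptide can
be sequenced separately.

Two failure modes limit this strategy. Collisional activation cleaves
crosslinker and peptide backbone under similar conditions, so doublets sit
in a forest of backbone fragments (poor sensitivity), and accidental peak
pairs at the signature delta trigger useless MS3 scans on linear peptides
(poor specificity). A UVPD-cleavable reagent whose benzylic C–S bonds break
selectively at 213 nm shifts the intensity balance strongly toward
crosslinker cleavage; an improved doublet-detection algorithm (tight ppm
tolerance, a restricted delta-mass variant set, and an exclusion window
around already-triggered m/z) recovers specificity. This package implements
that computational core: stub-mass chemistry, doublet detection and MS3
precursor selection, spectrum annotation, the comparative statistics, and a
ground-truth simulator so the whole chain is testable without raw LC-MS
data.

## Mass model

All masses derive from one bundled monoisotopic atomic-mass table
(`atomic_masses`); residue masses are computed from elemental compositions
at load time, so composition arithmetic and peptide masses cannot drift
apart. Key conventions:

* proton 1.00727646688 Da; hydrogen-shift variants use the **H-atom** mass
  (1.0078250319 Da), not the proton mass, because the ±1 Da satellites
  arise from hydrogen-atom transfer after homolytic bond cleavage;
* a stub fragment of a peptide is `peptide_mass + stub + k·H` at charge z:
  `(M + z·proton)/z`;
* backbone series offsets: `b` = prefix + proton, `a` = b − CO,
  `c` = b + NH3, `y` = suffix + H2O + proton, `x` = y + CO − H2, and `z`
  uses the z-dot convention (y − NH3 + H) by default, configurable, since
  radical-driven fragmentation practice varies.

Crosslinker definitions are JSON (spacer and stub elemental compositions,
the doublet pair, hydrogen shifts, and the complementary stub pairs that
must sum exactly to the spacer — an integer-level invariant checked at
construction). Three configs ship with the package:

* **UCCL** (UVPD-cleavable): stubs A/B/C/D read off the published
  structure (A = C2H2O, B = C2H2OS, C = C10H10OS, D = C10H10OS2, spacer
  C12H12O2S2). These are structure-derived, not transcribed from a printed
  table, and the JSON is the single place to correct them. Doublet pair
  B–C, base delta = C8H8 = 104.06260 Da.
* **DSSO** (CID-cleavable): alkene A = C3H2O, unsaturated thiol
  T = C3H2OS, sulfenic acid S = C3H4O2S. Only A+S reconstitute the spacer
  (T is the water-loss partner of S), which is why complementary pairs are
  declared explicitly rather than assumed for every label. The A–T doublet
  delta is exactly one sulfur atom, 31.972071 Da.
* **DSBU** (CID-cleavable): Bu = C4H7NO, BuUr = C5H5NO2, spacer
  C9H12N2O3.

## Doublet detection and MS3 selection

`find_doublets()` reports every peak pair (i, j), `mz_j > mz_i`, and
assumed charge z with

```
|(mz_j − mz_i)·z − δ| ≤ tol_ppm · 1e-6 · (mz_j · z)
```

for some delta variant δ. Numerical choices that matter for
reproducibility, all documented so a brute-force oracle matches
bit-for-bit:

* the ppm reference mass is the **heavy** peak's charge-scaled m/z;
* each (i, j, z) is reported once with the closest variant (ties to the
  smaller delta);
* assumed charges default to 1..(precursor charge − 1) — stub fragments
  carry a single peptide and usually 1–2 charges — and both peaks must
  share the assumed charge;
* with a rank cutoff, at least one peak of the pair must be in the top
  `max_rank` by intensity (rank ties broken toward lower m/z).

`dedupe_window()` processes matches in descending summed intensity and
keeps a match only if its trigger m/z is more than 1.5 Th (default) from
every previously kept trigger — emulating the vendor exclusion-list
behaviour and collapsing hydrogen-shift satellites of the same doublet.
`select_ms3_precursors()` then truncates to the MS3 budget. The isolated
species defaults to the **heavier** doublet peak (the acquisition
literature does not pin this down; it is configurable to the lighter one).

Detection defaults (5 ppm, shifts {0, +1H, +2H}, ±1.5 m/z window, rank
cutoff 20, 5 triggers) are the optimized acquisition values.

## Annotation and orthogonality statistics

`annotate_spectrum()` builds backbone fragments per peptide alone plus the
stub fragments (stub × shift × charge cross product) and assigns candidate
(peak, fragment) pairs within tolerance greedily by absolute ppm error,
one-to-one; ties go to the lower-m/z peak, then fragment table order.
Global greedy assignment (rather than per-fragment nearest) guarantees a
deterministic one-to-one annotation. Intact crosslinked fragments (both
peptides in one ion) are deliberately not modelled — the analysis is built
on the stub-versus-backbone dichotomy. Default annotation tolerance is
10 ppm (not stated by the source analyses; configurable).

`stub_backbone_sums()` partitions annotated intensity into stub and
backbone sums; `orthogonality_stats()` reports the median stub/backbone
ratio and the fraction of spectra with stub > backbone. Records with a
zero backbone sum are excluded from the median (no finite ratio) but kept
in the fraction. Representative spectra are chosen as the record nearest
(Euclidean, log10 intensity plane by default — the published plots are
log-scaled by appearance, and a flag selects linear space) to the
geometric median of the (backbone, stub) cloud. The geometric median uses
Weiszfeld iteration with the Vardi–Zhang adjustment when an iterate lands
on a data point; tol 1e-9, cap 10000 iterations, and non-convergence
raises a condition carrying the last iterate.

`cleavage_efficiency()` is 1 minus the intensity fraction of surviving
precursor species. Whether charge-reduced precursors count as survivors is
not defined by the source analyses; they do by default, and a flag turns
that off.

## The synthetic world

The generator emulates the statistical structure the dataset-level
analyses assume, with defaults frozen as one stated world:

* **Peptides**: uniform residues, lengths 6–18 (tryptic scale; minimum 5
  enforced), one non-C-terminal lysine forced as the link site.
* **Intensity partition**: log(stub_sum/backbone_sum) ~ Normal(mu, sigma),
  default mu = ln 5.3 (the UVPD-reagent median; a CID-like world uses
  ln 1.3), sigma = 1 (about one decade of spread, matching the visual
  spread of the published density plots). The partition is imposed
  exactly on the planted peaks, so parameter recovery is a clean test of
  the metrics chain. Within each class, peak intensities are lognormal
  (sdlog 1, heavy-tailed like real spectra).
* **Doublets**: the B/C-type pair at charge 1, each peptide's doublet
  dropped with probability q = 0.04, so both-doublet prevalence is
  (1 − q)² = 0.9216 ≈ the observed 92%.
* **Hydrogen shifts**: satellites at −1H and +1H, probability 0.5 each,
  at half the parent peak's intensity draw. The published observation
  that the three most common doublet deltas are 0, +1H and +2H emerges
  here from *combinations* (B with C+1 gives +1H; B−1 with C+1 gives
  +2H) under a symmetric single-H-transfer model; per-stub shift
  frequencies are not published in the accessible text, so symmetry is
  the neutral choice and the probabilities are configurable.
* **Noise and precursor**: 20 chemical-noise peaks uniform in m/z over
  150–1800 Th at ~0.2% of the fragment current each, re-drawn if within
  20 ppm of a true peak so ground truth stays unambiguous (an
  idealization: real noise can sit on signals); half the ion current
  survives as unfragmented precursor (published cleavage efficiency
  41–71%).
* **Mass error**: i.i.d. per-peak jitter (sd 2 ppm default read of
  "m/z jitter") plus an optional per-spectrum systematic calibration
  offset — the component `median_ppm_error()`/`recalibrate()` remove.
* Charges: 3–5 for crosslinked precursors, 2–3 for linear; seeded
  generation is byte-reproducible.

What a green test on this world establishes: the detection, selection,
annotation and metrics code do what their contracts say on spectra with
known truth. What it does not establish: performance on real LC-MS data,
where noise is structured, isotope envelopes exist (not modelled),
backbone fragments carry stub modifications across the link site in
charge states above 1, and doublet dropout is not independent of
intensity.

## Known limitations

* **Per-peak jitter vs tolerance.** With i.i.d. 2 ppm per-peak error, the
  delta of a peak pair has ~2.8 ppm error sd, so a single pair passes a
  5 ppm window ~93.5% of the time; satellite redundancy lifts per-peptide
  doublet recovery to ~98%, and both-peptide recovery to ~95–96%. A
  target of ≥99% for both peptides is unreachable in this world — it
  would require either correlated (calibration-type) mass error, which
  deltas cancel, or a wider tolerance.
* **Accidental deltas.** With full a/b/y ladders for both peptides and
  assumed charges up to (precursor − 1), accidental cross-series peak
  pairs land in a 5 ppm × 3-variant window often enough that ~20–25% of
  crosslinked spectra get a third-or-more MS3 trigger, even noise-free.
  This mirrors the real observation that MS3 scans per crosslinked MS2
  stay above the ideal 2 after algorithmic optimization; "exactly 2
  triggers in ≥99% of spectra" holds only for spectra reduced to their
  doublet content.
* No isotope envelopes, profile data, retention time, or MS3 spectrum
  content; monoisotopic, centroided MS2 only.
* MGF is the only peak-list format (gzip accepted); mzML/raw are out of
  scope.

## A worked pass through the chain

```{r example, eval = FALSE}
uccl <- load_crosslinker("uccl")
stub_masses(uccl)
doublet_delta_set(uccl, shifts = 0:2)

cfg <- generator_config(n_crosslinked = 200, n_linear = 100, seed = 7)
ds <- generate_dataset(cfg)
records <- run_trigger_simulation(ds, detect_params())
orthogonality_stats(records[records$class == "crosslinked", ])
trigger_sensitivity(records)
ms3_trigger_stats(records)
```
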