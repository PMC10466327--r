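# xldoublet

Computational toolkit for analysing **MS-cleavable crosslinkers** in
crosslinking mass spectrometry (crosslinking MS), centred on the detection
of crosslinker **stub doublets** in MS2 spectra and the emulation of
doublet-triggered MS3 acquisition.

## Who this is for

Crosslinking-MS method developers and analysts who want to

* model cleavable-reagent chemistry (spacer/stub elemental compositions,
  hydrogen-shift variants, doublet delta masses) for UVPD-cleavable and
  CID-cleavable reagents (UCCL-, DSSO- and DSBU-style configs are bundled);
* detect signature peak doublets in centroided MGF peak lists and emulate
  MS3 precursor selection, including the exclusion-window filter that
  prevents repeated triggering on hydrogen-shift satellites;
* annotate spectra with backbone (a/b/c/x/y/z) and stub fragments and
  quantify how *orthogonal* crosslinker cleavage is to backbone cleavage;
* benchmark detection sensitivity/specificity on seeded synthetic spectra
  with full ground truth.

## The core statistic and algorithm

For a crosslinker whose doublet pair has stub masses m_light < m_heavy,
the signature delta is Δ = m_heavy − m_light (for the bundled
UVPD-cleavable config, Δ = C8H8 = 104.06260 Da; for DSSO, Δ = S =
31.972071 Da exactly). Hydrogen-atom transfer after homolytic cleavage
adds variants Δ + k·1.0078250319 Da. A doublet is any peak pair (i, j)
and assumed charge z with

    |(mz_j − mz_i)·z − Δ_k| ≤ tol_ppm · 1e-6 · (mz_j · z)

Detected doublets are deduplicated greedily by summed intensity within a
±1.5 m/z trigger window, and the heavier peak of each surviving doublet
becomes an MS3 precursor (budget-capped). Orthogonality of cleavage is
summarised by the median ratio of summed stub to summed backbone fragment
intensity per spectrum, with representative spectra chosen nearest to the
geometric median (Weiszfeld) of the log-intensity cloud.

## Worked example

```r
library(xldoublet)

uccl <- load_crosslinker("uccl")
uccl
#> <crosslinker UCCL  spacer 252.027871 Da>
#>   stub A        42.010565 Da
#>   stub B        73.982635 Da
#>   stub C       178.045236 Da
#>   stub D       210.017306 Da
#>   doublet pair B-C, hydrogen shifts {-2,-1,0,1,2}

# a seeded synthetic dataset: 200 crosslinked + 100 linear MS2 spectra
cfg <- generator_config(n_crosslinked = 200, n_linear = 100, seed = 7)
ds  <- generate_dataset(cfg)

# detect doublets, select MS3 precursors, score against ground truth
records <- run_trigger_simulation(ds, detect_params())

orthogonality_stats(records[records$class == "crosslinked", ])
#> $median_ratio              5.49      # median stub/backbone intensity ratio
#> $fraction_stub_gt_backbone 0.945     # spectra where stub signal dominates
doublet_prevalence(records)
#> $p_at_least_one 1      $p_both 0.945 # spectra containing >=1 / both doublets
trigger_sensitivity(records)
#> $p_one_triggered 0.975  $p_both_triggered 0.875
ms3_trigger_stats(records)
#>         class   n  mean  ci_lower ci_upper
#> 1 crosslinked 200 2.045  1.966    2.124    # ideal value is 2
#> 2      linear 100 0.090  0.021    0.159    # false MS3 triggers per linear scan
```

The generator's defaults describe a UVPD-like acquisition (median
stub/backbone ratio ln 5.3, doublet dropout 0.04, 2 ppm mass jitter); the
measured median ratio (5.49), both-doublet prevalence (0.945 ≈ 0.96²) and
mean MS3-per-MS2 near 2 recover those settings through the full
detect-and-trigger chain. Swapping `log_ratio_mu = log(1.3)` emulates a
CID-cleavable reagent for comparison.

Command-line equivalents (installed under `exec/`):

```sh
xldoublet simulate --config gen.json --out-prefix sim
xldoublet detect   --mgf sim.mgf --crosslinker uccl --out triggers.tsv
xldoublet annotate --mgf sim.mgf --csms sim.csms.tsv --crosslinker uccl --out annotated.tsv
xldoublet metrics  --records records.tsv --out report.json
```

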