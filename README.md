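# grkselect

Quantitative analysis of **GRK-selective β-arrestin recruitment** measured
by intermolecular BRET in GRK-knockout cells, for receptor pharmacologists
running NanoLuc/Halo-Tag recruitment screens (and the matching label-free
DMR experiments) who need the full chain from raw dual-channel plate reads
to selectivity calls in one tested, scriptable toolbox.

## What it computes

The core statistic is the **Δ net BRET fold change** of a well:

1. per-timepoint BRET ratio = acceptor / donor;
2. minus the mean ratio of mock-labelled wells (labelling-efficiency
   correction);
3. stimulated-window mean over baseline-window mean (3 min baseline,
   5 min stimulation; the injection timepoint excluded);
4. divided by the matched vehicle wells' fold change.

Downstream of the reduction:

* **Gated concentration–response fits** — a condition is "functional
  recruitment" only if its top-dose response significantly exceeds vehicle
  (one-sided pooled-variance t); gated series are fitted with
  `r(c) = bottom + (top − bottom) / (1 + 10^((log10 EC50 − log10 c)·h))`,
  Hill slope fixed at 1 by default, per-experiment log EC50 mean ± SEM.
* **GRK-selectivity classification** — per GPCR–arrestin pair, ANOVA-pooled
  Bonferroni contrasts of each GRK-rescue condition against the GRK-null
  (ΔQ-GRK) reference; pairs are called *GRK2/3/5/6-regulated*,
  *GRK2/3-regulated* or *unclassified*; a signed −log10(p) heatmap is
  clustered by Canberra distance (|uᵢ−vᵢ| / (|uᵢ|+|vᵢ|), complete linkage).
* **Pre-coupling detection** — one-sided Dunnett test (multivariate-t,
  Genz–Bretz) for baselines elevated over the GRK-null reference.
* **Phospho-motif positional analysis** — scans IL3/C-terminal segments for
  Ser/Thr sites and the P/X grammars (PPP, PXPP, PXPXXP, PXXPXXP; P ∈
  {S,T,D,E}), relative positions in [0, 1], central (0.25–0.75) vs
  peripheral, Fisher's exact association with selectivity groups.
* **DMR analysis** — empty-vector-corrected traces, trapezoidal AUC over
  0–1800 s, bottom-constrained concentration–effect fits.
* **Synthetic-data generators** with known ground truth
  (`simulate_bret_plate()`, `simulate_segment_set()`,
  `simulate_dmr_traces()`), so every stage is testable without raw data.

## Worked example

```r
library(grkselect)

plates <- demo_screen_plates(seed = 1)        # 4 synthetic GPCR-arrestin pairs
red <- reduce_plate(plates[["M5R-barr2"]])

cm <- do.call(rbind, lapply(names(plates), function(pair) {
  r <- reduce_plate(plates[[pair]])
  sat <- r[r$role == "sample" & r$concentration_M == max(r$concentration_M), ]
  tibble::tibble(pair = pair, condition = sat$condition,
                 replicate = sat$replicate, value = sat$net_fold_change)
}))
classify_pairs(cm)$calls
#> # A tibble: 4 × 3
#>   pair        group                cluster_position
#> 1 PTH1R-barr2 GRK2/3/5/6-regulated                3
#> 2 M5R-barr2   GRK2/3-regulated                    2
#> 3 M3R-barr1   unclassified                        1
#> 4 V2R-barr2   GRK2/3/5/6-regulated                4
```

The calls recover the planted structure: the PTH1R-like pair is rescued by
any single GRK, the M5R-like pair only by GRK2/3, the M3R pair by none
(endogenous-GRK control only), and the V2R-like pair — simulated with a
1.5-fold elevated baseline — is additionally flagged by
`call_precoupling()` (adjusted p ≈ 3.6e-15 for its GRK2 baseline in this
run). Fitting the reduced M5R GRK2 series gives log EC50 ≈ −7.0 ± 0.1
(planted −7). The numbered scripts under `analysis/` run the same chain
file-to-file (simulate → reduce → fit → classify → motifs → DMR), writing
their tables under `results/`; on the bundled synthetic segment set the
PXPP central-vs-peripheral association yields Fisher p ≈ 1.4e-11, and the
DMR fit recovers log EC50 −8.00 with top ≈ 101% (planted −8, 100%).

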