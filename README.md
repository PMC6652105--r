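# chemcis

Genome-wide localization of a small molecule on chromatin (Chem-seq) and
the statistics of its cis-regulatory effect, as a tested, reproducible R
pipeline.

Chem-seq pulls down chromatin bound by a biotinylated compound
(here: quercetin) with streptavidin beads. Because the beads bind DNA on
their own, three libraries are sequenced — compound–bead, bead-only and
input DNA — and binding sites must be inferred as compound-over-bead
enrichment with bead-derived regions excluded. `chemcis` implements the
full analysis chain for this design:

* **Peak calling** — a control-subtracted sliding-window caller
  (window 300 bp, stride 100 bp): treatment count *k* per window against a
  depth-normalized Poisson expectation λ from the control,
  *p* = P(Poisson(λ) ≥ *k*), Benjamini–Hochberg across all windows, merge
  at q < 0.05. Two scoring modes (genome-wide λ vs MACS-style local λ over
  1/5/10 kb backgrounds, floored by the global rate) stand in for the two
  external callers whose calls the design intersects.
* **Consensus + bead exclusion** — run 1: compound–bead vs bead, both
  modes, intersected; run 2: bead vs input; final peaks are run-1 peaks
  with zero overlap against the run-2 list; top-1000 selection by score.
* **Promoter association** — peaks within 500 bp upstream of a TSS
  (window includes the TSS base), hypergeometric gene-set enrichment, and
  log-odds PWM motif enrichment (both strands, one-sided Fisher on the
  hit table) with a packaged E2F-like matrix.
* **Expression** — coding genes with > 10 reads in ≥ 1 sample,
  median-of-ratios size factors, per-gene fold change
  FC = (mean_t + 0.5)/(mean_c + 0.5), Welch-t differential calls with FC
  outside [0.5, 2] and FDR < 0.05.
* **Cis-regulatory statistics** — target-vs-background KS comparison of
  FC values; a permutation scheme of 10 cycles × 100 permutations
  producing P_empirical (target vs random 36-gene set) and P_random
  (random vs random) distributions; Welch t-tests comparing the compound
  and biotinylated-compound responses.
* **Synthetic data with planted truth** — Poisson tag tracks with
  planted binding sites and sticky bead regions, negative-binomial counts
  with a planted 1.2× fold change on 36 regulated genes, promoter
  sequences with a planted motif — so every stage is testable offline and
  recovery is scored against known ground truth.
* **Mass utility** — Hill-formula parsing, monoisotopic mass, ESI adduct
  m/z for verifying the biotinylated-adduct identification.

## Worked example

The `analysis/` directory holds the pipeline as numbered drivers
(simulate → peaks → annotate → expression → statistics → mass check), each
a thin script over the package API writing under `results/run/`. Running
them in order on the default configuration prints:

```
$ Rscript analysis/01_simulate.R
genes:            1000 (900 coding)
regulated genes:  36
binding sites:    36 in regulated promoters
bead sticky sites:50
tags (compound/bead/input): 204415 / 201958 / 200092

$ Rscript analysis/02_chemseq_peaks.R
raw compound peaks:   38
bead-derived peaks:   52
final compound peaks: 38
planted-site recall:  36/36 (100%)

$ Rscript analysis/03_annotate.R
candidate genes (promoter-associated): 36
cell-cycle set enrichment p: 7.04e-67
motif enrichment: 81% of targets vs 0% background, p = 2.47e-23

$ Rscript analysis/05_cisstats.R
median FC: target 1.10 vs background 1.00 (KS p = 0.00025)
permutations: 1000 p_empirical + 1000 p_random
frac(P_empirical < P_random) = 0.94
t-test compound vs biotinylated compound: p = 0.75
t-test biotinylated compound vs background: p = 7.05e-05
```

Reading: all 36 planted binding sites survive bead exclusion and map back
to exactly the 36 regulated genes; their promoters carry the planted
motif while background promoters do not; the regulated set's median fold
change sits above the background median of 1.0 and the permutation
contrast (94% of paired draws with P_empirical < P_random) shows the
shift is not a sampling accident; the biotin tag leaves the response
statistically indistinguishable from the untagged compound (p = 0.75)
while both differ from background. The same computations are available in
one call as `run_all(config, outdir, seed)`, which writes a deterministic
`report.json` (counts per stage, ground-truth recovery, parameter echo,
file checksums).

```r
library(chemcis)
res <- run_all(sim_config(), outdir = "results/run_all", seed = 1)
res$report$truth_recovery$site_recall   # 1
```

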