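---
title: "Methods: Chem-seq peak inference and cis-regulatory statistics in chemcis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Chem-seq peak inference and cis-regulatory statistics in chemcis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemcis)
```

## The problem

Chem-seq localizes a biotinylated small molecule on chromatin: the
compound is captured with streptavidin beads and the co-purified DNA is
sequenced. Unlike ChIP-seq, the assay has a structural artifact —
streptavidin beads bind DNA on their own — so three libraries are
sequenced (compound-bead, bead-only, input DNA), and compound binding must
be inferred as enrichment of the compound-bead library over the bead
library, with regions that the beads alone enrich excluded outright.
Downstream, the question is whether the compound acts as a cis-regulator:
do the genes whose promoters carry binding sites shift expression more
than chance, and does the biotin tag itself perturb expression?

`chemcis` implements that whole chain as a tested pipeline — peak calling,
bead exclusion, promoter association, motif and gene-set enrichment,
fold-change statistics, a cycle-structured permutation test — and exercises
it end-to-end on synthetic data with planted ground truth, because the
original sequencing data of this design is not publicly deposited. All
quantitative guarantees in the test suite are therefore statements about
recovery of planted signal, not about any real genome.

## The synthetic study

`sim_config()` fixes the study conditions. Defaults: a 2 × 5 Mb genome
carrying 1,000 genes (10% flagged non-coding), 36 regulated genes with one
300 bp binding site planted inside each of their 501 bp promoter windows,
50 sticky bead regions placed away from promoters, 200,000 tags per
Chem-seq library, and RNA-seq with 4 replicates per condition (DMSO,
quercetin, biotinylated quercetin).

The scale mirrors the structure of the real design — a 36-gene regulated
set against a ~900-gene coding background standing in for the ~16,000-gene
transcriptome, a planted expression fold change of 1.2 against background
1.0 — at sizes where every test runs in seconds. Values the study never
states were chosen once at what a sequencing experiment of this kind would
plausibly give, and are not tuned: 8× tag-rate enrichment at binding and
sticky sites (mid-range for a pulldown assay), negative-binomial counts
with dispersion 0.05 (typical for cell-line replicates), log-normal
baseline means (meanlog = log 200, sdlog = 1.2), ±10% log-normal
library-depth variation, and an E2F-like consensus (`TTTGGCGCC`) planted
in 80% of regulated promoters.

What the generator emulates: Poisson tag backgrounds, additive site
enrichment, bead stickiness shared between the bead and compound-bead
libraries, count overdispersion, depth variation. What it deliberately does
not: fragment-length structure, GC and mappability bias, copy-number
variation, correlated gene programs, or any relationship between binding
strength and expression response. Passing tests therefore demonstrate that
the inference machinery is correct and calibrated under its stated model,
not that it is robust to artifacts of real chromatin data.

## Peak calling

Both external peak callers used in this experimental design reduce, at
their core, to the same test: is the treatment tag count in a window
surprising under a control-derived Poisson expectation? `call_peaks()`
implements that core twice, as two scoring modes, because the downstream
consensus step needs two call sets to intersect:

* windows of `window_w = 300` bp slide at `step = 100` bp;
* the control expectation λ is depth-normalized
  (`scale = treatment_total / control_total`);
* `global_lambda` mode uses the genome-wide control rate;
* `local_lambda` mode takes the maximum over the in-window control count
  and control rates in centered 1 kb / 5 kb / 10 kb windows, floored by the
  global rate — the local-background idea of MACS-style callers, which
  punishes peaks sitting inside broad enriched domains;
* window p = P(Poisson(λ) ≥ k); Benjamini–Hochberg runs **once across all
  windows genome-wide**, then windows with q < 0.05 are merged when
  separated by ≤ 200 bp.

Numerical choices worth stating: λ is floored at 0.25 tags/window so an
empty control region cannot produce infinite enrichment; window p-values
are clamped at the smallest positive double so the (0, 1] contract and the
−log10 score stay finite; a merged peak reports the minimum window p and
that window's q (no re-adjustment after merging — the correction is a
single genome-wide pass, which keeps the procedure one-shot and exactly
reproducible); peak ties are broken by (chrom, start); the summit is the
tag position with the highest ±25 bp tag count, leftmost on ties. Each
peak also carries the `(k, λ)` of its scoring window so the p-value is
auditable after the fact.

Because the Poisson tail is discrete and conservative, the window-level
type-I error is at most nominal, and on null data (no planted enrichment)
the BH step across ~10⁵ windows returns zero peaks in ≥ 95% of seeds — the
calibration the test suite asserts.

## Consensus, bead exclusion, top-N

Run 1 calls compound-bead against bead under both modes and keeps
local-mode peaks that overlap a global-mode peak (`consensus()`;
coordinates and scores from the first list, so each peak keeps one
significance value for ranking). Run 2 derives the bead-background list
against input DNA; `exclude_bead_signal()` then removes every run-1 peak
with ≥ 1 bp overlap against it. Exclusion and consensus partition the
input list — an identity the tests assert — and the final list never
overlaps the bead-derived list, asserted on every run.

One design question was genuinely open: whether run 2's treatment should
be the bead library alone or the pooled compound+bead tags. We default to
**beads alone**. The pooled variant contains the compound-specific tags,
so every true binding site is re-called in run 2 and then excluded —
planted-site recall collapses to ~0, which defeats the purpose of the
exclusion step (its role is to remove *bead* artifacts, not compound
signal). The pooled reading remains available as
`run2_treatment = "pooled"`, and a test documents exactly this behavior.

`select_top_n()` ranks by score with (chrom, start) tie-breaks; the
pipeline carries the top 1,000 (or all, when fewer) into annotation.

## Promoter association and enrichment

The promoter is the upstream-only window that includes the TSS base:
`[tss − 500, tss + 1)` on the plus strand, mirrored on the minus strand,
clipped at zero — length 501 off-edge. Including the TSS base itself is
our call; excluding it would make a peak ending exactly at the TSS
non-associated, which seems indefensible. A gene is a candidate when ≥ 1
peak overlaps its promoter.

Gene-set enrichment is the hypergeometric upper tail on
(universe, set, candidates), BH-adjusted across sets. The packaged
"cell_cycle" set is wired to the simulator's regulated genes — real
ontologies are version-dependent external resources and stay out of the
tests. Motif enrichment scans promoters with a log-odds PWM on both
strands (`N` scores 0), calls a sequence hit-positive at ≥ 80% of the
maximum achievable score (at the packaged 9-mer this admits only exact
consensus matches, keeping background hits at the ~0.4%/sequence level),
and tests the 2×2 hit table with a one-sided Fisher exact test — the
smallest-assumption test for that table.

## Expression

Filtering keeps coding genes with > 10 reads (strictly) in ≥ 1 sample.
Normalization is median-of-ratios: per-gene geometric-mean reference over
all-positive genes, per-sample median ratio. Fold change is the ratio of
mean normalized counts with a pseudocount of 0.5 on each side — FC of an
all-zero gene is exactly 1, and shrinkage toward 1 is negligible at the
simulated depths (means ~200). The differential rule takes "FC between
0.5 and 2" to mean |log2 FC| ≥ 1 **outside** the interval (bounds
included), because the inside reading would label unchanged genes
differential; the literal inside reading is available via `inside = TRUE`.
Significance comes from a per-gene Welch t-test on log2 normalized counts,
BH-adjusted — an explicit, documented stand-in: the downstream statistics
consume only FC values, so NB-GLM machinery would add fit complexity
without adding coverage of the procedures under test.

## The permutation scheme and its statistics

`compare_target_to_background()` compares target-gene FC values against
the **full** FC table (targets included — the background is defined as all
filtered genes) with a two-sample KS test, reporting both medians.

`permutation_scheme()` runs 10 cycles × 100 permutations. Per
permutation: `p_empirical` = KS p of target FC vs a random 36-gene set;
`p_random` = KS p of two further independent random 36-gene sets. Draws
are without replacement from the full table (targets not excluded, by
default — matching the background definition; `exclude_targets_from_draws`
flips it). One root seed spawns per-cycle streams, so any cycle can be
reproduced alone. The scheme's two numeric summaries are the fraction of
paired draws with `p_empirical < p_random` and the pooled two-sample KS
distance between the two collections — the distributional contrast the
design inspects visually is thereby testable.

KS p-values in the pipeline are asymptotic; at 36-vs-36 the exact and
asymptotic tails differ by less than the granularity of the statistic
(below). The exact small-sample path (`exact = TRUE`) exists for
verification against full enumeration. The t-tests comparing the
compound and biotinylated-compound FC vectors are Welch unpaired
(a paired variant is available; the design does not state pairing).

Two statistical facts discovered while validating deserve record, because
they bound what this scheme can show:

1. **Granularity.** With 36-gene sets the two-sample KS statistic lives on
   multiples of 1/36 — about 18 achievable p-values. The pooled null
   `p_empirical` distribution is therefore a step function whose maximal
   deviation from U(0,1) is ≈ 0.19 *by construction*, for any correct KS
   implementation. Claims that this pooled distribution is uniform to
   within a few percent are unattainable at this set size; the appropriate
   null statement is stochastic dominance (p-values conservative) plus
   exchangeability with `p_random`, and that is what holds.
2. **Conditional dependence.** All 1,000 `p_empirical` draws share the one
   fixed target set, so they are exchangeable with `p_random` only
   *marginally* (over fresh target draws). Within a single run, a mildly
   atypical random target shifts the whole conditional distribution. The
   exchangeability test in the suite therefore draws one p-pair per
   independent target.

`kde_summary()` provides the Gaussian-kernel density (Silverman bandwidth
by default) on a fixed grid for plotting the two p-value distributions;
it integrates to ~1 over a wide grid by construction.

## Mass utility

`monoisotopic_mass()` sums monoisotopic atomic masses (¹²C exact; H, N,
O, S, P, Na at IUPAC values) over a Hill-style formula;
`adduct_mz()` adds electron-corrected cation masses (M+H: +1.007276,
M+Na: +22.989218, spacing 21.981942 Da for any formula). For the
biotinylated quercetin adduct C₂₉H₃₃N₃O₉S this gives 599.1938 Da —
matching the reported value to < 0.001 Da. Note that value is labelled a
molecular weight in the source report but is numerically the monoisotopic
mass (the average mass is ≈ 599.65); the utility computes monoisotopic
throughout. Theoretical adduct m/z agree with the measured ESI peaks
within 0.005 Da (instrument-scale tolerance, not an equality).

## Problem sizes and determinism

Tests and the acceptance script run the generators at the default
2 × 5 Mb / 1,000-gene scale where the property under test concerns the
default study (site recovery, planted FC, permutation contrast), and at
smaller scales — one 1–2 Mb chromosome, 100–300 genes — for calibration
loops repeated over many seeds; each test states its sizes in code. Every
stochastic function takes an explicit seed and is bit-reproducible;
`run_all()` writes a report whose bytes are identical across runs with the
same seed and config.

## Known limitations

* The peak caller is a window scanner: no fragment-shift model, duplicate
  filtering, broad-peak mode, or paired-end support; summit resolution is
  bounded by the 100 bp stride.
* The bead-exclusion logic assumes sticky regions are detectable against
  input; bead artifacts below peak-calling power pass through.
* The expression stand-in has no dispersion shrinkage, so its per-gene
  power at 3–4 replicates is below that of NB-GLM tools; the pipeline's
  conclusions rest on set-level statistics, which are insensitive to this.
* The permutation scheme inherits the KS granularity and conditional
  dependence noted above; with 36-gene sets, `p_empirical` should be read
  as a contrast against `p_random`, not against an absolute uniform scale.
* The synthetic genome has no sequence composition; motif enrichment
  against i.i.d. background is easier than against real promoters.
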