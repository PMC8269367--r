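---
title: "quadcoloc: models, conventions and the synthetic stated world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quadcoloc: models, conventions and the synthetic stated world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadcoloc)
```

`quadcoloc` asks a specific scientific question — do quadruplex-prone DNA
sites colocalize with protein-bound sites, and is the implied recruitment
supported by in vitro binding? — and packages the full analytical chain
behind it. This vignette is the package's own account of the models it
implements, the conventions and defaults it chose where the field leaves
room, and what its tests do and do not establish.

## 1. Motif model

The scanner implements the consensus quadruplex pattern: `runs_required`
(default 4) runs of at least `min_run` (default 3) consecutive guanines,
separated by loops of `loop_min`–`loop_max` nucleotides (default 1–7, the
standard quadruplex-prediction convention). i-motifs are the same pattern
in cytosines. Three conventions matter:

* **Run maximality.** Runs absorb all contiguous G: `GGGGGG` is one run of
  6, never two runs of 3. Candidate motifs are windows of consecutive
  maximal runs; a run shorter than `min_run` inside a gap simply counts as
  loop sequence.
* **Strand reporting.** A C-pattern match found while scanning for G4s is
  the footprint of a quadruplex on the other strand and is reported with
  strand `-` at the same coordinates. Consequently the scan of a sequence
  and of its reverse complement agree after mirroring coordinates and
  swapping strands (a tested invariant).
* **Overlap resolution.** All candidate windows are enumerated, scored, and
  resolved greedily: descending score, ties to the leftmost start, then the
  plus strand. Retained hits are mutually non-overlapping per strand;
  opposite strands may co-locate. Greedy selection is the documented
  contract — it is *not* claimed to maximize total score over a cluster
  (two cheap hits can outweigh one expensive one; an exhaustive
  weighted-interval schedule would differ there), and the tests assert the
  greedy contract, not optimality.

The stability score,
`alpha * sum(run_len - min_run) - beta * sum(loop_len) + runs_required * min_run`
(defaults `alpha = 1`, `beta = 0.5`), is a deliberately simple monotone
heuristic: longer runs stabilize, longer loops destabilize. It is a proxy,
not a thermodynamic model: no folding prediction, no pH-dependent i-motif
stability, no bulged or two-quartet motifs (the published imperfection-
tolerant scanners support these; their parameters are not reproduced here).
`score_threshold` exists as a configurable stand-in for "keeps only
physiologically plausible structures" filters whose exact criteria are
typically opaque.

## 2. Interval conventions

All coordinates are 0-based half-open (BED semantics); abutting intervals
share zero base pairs and do not overlap. All overlap logic is strand-blind,
as peak-level analyses conventionally are.

* `classify_relative()` labels each query interval `overlap` (≥ 1 shared
  bp, taking precedence), `flank` (edge-to-edge gap ≤ `flank_width`), or
  `free`. The default flank of 200 bp is the scale of one nucleosome plus
  linker and is used uniformly; analyses that quote a flank at one place
  and not another should set it explicitly.
* `coverage_fraction()` reports covered bp of the (optionally
  flank-extended, merged) query footprint divided by that footprint's total
  bp. Note that the *fraction* is not monotone in the flank width — flanks
  add mostly-uncovered base pairs to the denominator — while the covered-bp
  numerator is; the per-interval-average reading of "average coverage" is
  available via `per_interval = TRUE`.
* `relative_distances()` uses the conventional reldist definition: for each
  query midpoint strictly between two consecutive reference midpoints, the
  distance to the nearer one scaled by the midpoint spacing, a value in
  [0, 0.5] that is uniform under spatial independence. Query midpoints
  outside the reference midpoint range are skipped, as are chromosomes
  with fewer than two distinct reference midpoints.
* `profile_matrix()` drops windows truncated by chromosome edges rather
  than padding them, so every bin mean averages the same number of windows.

## 3. Association statistics

`chi_square()` computes the uncorrected Pearson statistic from the 2×2
closed form; the Yates correction is exposed but off by default, because
large-count genomic contingency tables are conventionally reported
uncorrected and the correction changes the statistic materially. A warning
fires when any expected count drops below 5.

`fisher_exact()` computes the two-sided p-value by summing hypergeometric
probabilities at most that of the observed table (relative tolerance
1 + 1e-7, the customary guard against floating-point ties). It reports the
*sample* odds ratio ad/bc — not the conditional-MLE estimate that
`stats::fisher.test()` reports — with a Woolf log-OR 95% interval and a
Haldane 0.5 correction (flagged) when a cell is zero. The test suite checks
the p-value against full enumeration and against `stats::fisher.test()`.

`genome_fisher()` must invent a 2×2 table from two interval sets, and there
is no canonical construction; the package adopts the bedtools-fisher style:
`n11` = overlapping pairs (smaller of the two directional counts on the
merged sets), `n12`/`n21` = set-unique intervals, and `n22` = remaining
"slots", `genome_length / (mean_len_A + mean_len_B)` minus the other cells.
Because `n22` is a modeling fiction, the full construction is recorded in
the result's `"construction"` attribute; treat the odds ratio as a
descriptive enrichment index, calibrated only in the sense (verified by
simulation in the tests) that its CI covers 1 for independent sets.

`permutation_test()` randomizes the second set per draw, preserving
per-chromosome interval counts and lengths, with starts uniform within the
chromosome — or within mask segments (chosen length-weighted among segments
that can hold the interval) when an open-chromatin mask restricts the null.
The statistic is the overlap count by default (coverage fraction as an
alternative), the test is upper-tail (enrichment), and the empirical
p-value `(r + 1)/(n_iter + 1)` can never undercut `1/(n_iter + 1)`. The
null draws are kept for box-plot-style reporting via `glance()` /
`autoplot()`.

## 4. Methylation aggregation

Per-interval mean over contained CpGs (unweighted by default — bisulfite
percentages already normalize depth; coverage weighting is a flag), then
median and quartiles across CpG-containing intervals. Intervals without
usable CpGs are excluded from the set-level summary and counted separately,
and a pooled-CpG median is emitted alongside, since "average methylation of
a region class" is computed both ways in the literature and the two can
disagree.

## 5. Binding model

MST titrations hold the labeled protein at P (default 50 nM) against a
two-fold serial dilution of ligand (default 16 points, 20 µM down to
~0.61 nM). Because P is not negligible against nanomolar Kd values, the
package fits the exact 1:1 depletion isotherm

    fb(c) = ((c + P + Kd) - sqrt((c + P + Kd)^2 - 4cP)) / (2P)
    F(c)  = f_free + (f_bound - f_free) * fb(c)

by unweighted least squares (no per-point errors are available from typical
exports) over (Kd, f_free, f_bound), with Kd log-parameterized to stay
positive. Initialization: plateaus from the curve extremes, Kd from the
concentration nearest half-signal; optimization is Nelder-Mead followed by
BFGS at tight tolerance, which recovers noiseless curves to at least four
significant digits. Standard errors come from the local quadratic
approximation of the loss at the optimum (delta method back to the Kd
scale); reported `±` values are these standard errors. Flat curves are
returned as unidentifiable with `converged = FALSE` rather than a number.
Fits above the top tested concentration are censored by
`compare_affinities()` to "> top µM", the reporting convention for
non-binders. Out of scope: raw thermophoresis traces, Hill or two-site
models, vendor normalization details (irrelevant to the contract since the
plateaus are free parameters).

## 6. ChIP-qPCR quantification

The printed formula fixes base 2, i.e. 100% amplification efficiency:
`ΔCq = Cq_site − Cq_control` per sample, `ΔΔCq = 2^(ΔCq_input −
ΔCq_sample)`. The replicate structure (biological × technical) does not
dictate an averaging order; the package averages technical replicates on
the Cq (log) scale within each biological replicate and summarizes
biological replicates after the fold change is formed (mean, SD, min–max) —
averaging before exponentiation is the less biased choice for cycle-scale
noise. Control-site normalization cancels any condition-wide Cq shift, a
tested invariant.

## 7. The synthetic stated world

The generator defaults *are* the analysis conditions, chosen once:

* Genome: 5 chromosomes × 2 Mb, i.i.d. bases at 41% G+C (desk scale;
  no attempt to match real base composition or repeat structure).
* Peak widths uniform 100–500 bp (ChIP fragments are a few hundred bp);
  island-like regions 300–1500 bp.
* Enrichment by a mixture: with probability π an interval is placed to
  overlap a uniformly chosen anchor, else uniformly. The default scenario
  uses π = 0.5, which produces unambiguous enrichment, and π is the
  recorded truth that power checks recover. Placement allows intervals of
  one set to overlap each other (the simplest null, mirroring shuffled-peak
  nulls); `allow_self_overlap = FALSE` is available.
* Methylation: CpG sites every 100 bp, stratum means 10/15/30% for
  peak/island/quadruplex strata over a 70% background, clipped Gaussian
  noise of 5 points, Poisson(30)+1 coverage. Innermost (smallest
  containing) stratum wins; equal-extent ties keep the earlier stratum and
  warn.
* Binding: true Kd 140/120/70 nM at the titration design above, additive
  Gaussian noise of 2% of span.
* Cq tables: fold changes planted by shifting IP Cq by −log2(fold);
  2 biological × 2 technical replicates, 0.2-cycle noise.

Planted motifs are recoverable *by construction*: loops contain no run
base, flanking sequence one base wider than the longest loop is rewritten
to A/T on both sides, and planted sites keep that much separation — so no
candidate window can cross a planted-site boundary and the planted
decomposition is the unique candidate over its runs. This is what makes
"100% recall of planted sites" a meaningful assertion rather than a
statistical accident.

What a green test establishes: that the estimators recover the parameters
of *this* world at the stated tolerances, and that the statistics are
calibrated under *this* null (type-I rate inside the exact binomial band,
CI coverage of OR = 1). What it does not establish: behavior under real
peak-width and GC heterogeneity, real CpG clustering, genome-scale multiple
structure classes, or peak-calling artifacts — real data keep all of those.

## 8. Numerical and degenerate-input choices

* Seeds: every generator takes one; the pipeline derives per-stage streams
  from the single run seed by stage-name hashing (stages are individually
  reproducible and insertion-order independent). All derived seeds stay
  below 2^31.
* Empty inputs: scanning an empty sequence returns an empty hit set;
  an empty reference set gives permutation p = 1 with observed 0; empty
  interval sets are rejected where a statistic would be undefined
  (`genome_fisher`).
* Ties: overlap resolution breaks score ties leftmost-then-plus;
  methylation stratum ties keep the earlier stratum with a warning;
  reldist midpoints coincident with a reference midpoint score 0, and a
  query at the last reference midpoint is scored against the final pair.
* The discriminant of the depletion quadratic is clamped at zero against
  floating-point rounding; fraction bound is clamped to [0, 1].
* Fisher p-values sum probabilities with the 1 + 1e-7 relative tolerance;
  the enumeration oracle in the tests uses the same tolerance, so equality
  there is exact, not approximate.

## 9. Configuration and orchestration

`run_colocalization()` takes an R list or a JSON file (JSON was chosen as
the single config format; the package avoids a YAML dependency). Every
stage is logged and failures abort with the stage name. `run_demo(seed)`
runs the default synthetic scenario end to end in a few minutes on one CPU.
The report is a versioned list written as `report.json` plus TSVs under the
output directory with a manifest.

## 10. Known limitations

* The scanner is a consensus-pattern stand-in: no bulges, no imperfect
  quartets, no thermodynamic scoring.
* `genome_fisher`'s 2×2 construction, like any such construction, is a
  model; the permutation test is the primary inferential tool and the
  Fisher odds ratio a descriptive one.
* The permutation null preserves lengths and per-chromosome counts but not
  inter-peak spacing or GC matching; masks mitigate accessibility
  confounding, not composition confounding.
* Methylation aggregation assumes percentages are comparable across sites;
  no bisulfite-level processing is attempted.
* ΔΔCq assumes perfect efficiency (base 2) per the printed formula; no
  efficiency calibration layer.
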