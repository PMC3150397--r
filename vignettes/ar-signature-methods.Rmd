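---
title: "Methods: androgen-response signatures from two-color arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: androgen-response signatures from two-color arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arsig)
```

## The problem

Prostate epithelial cells depend on androgen receptor (AR) signaling, and
hormonal therapy-resistant prostate cancer cells commonly adapt the AR
pathway rather than abandon it: the receptor may be lost, overexpressed, or
mutated so that antiandrogens act as agonists. `arsig` implements an
analysis pipeline for characterizing the AR target-gene response across a
panel of four such cell lines (wild-type AR; vestigial AR; AR
overexpression; T877A-mutant AR) profiled on spotted two-color oligoarrays
after stimulation with the synthetic androgen R1881 (1 nM) or the
antiandrogen hydroxyflutamide (1 uM) versus time-matched vehicle, at 4, 8
and 16 h, in two dye-swapped biological replicates. Downstream, it links
the resulting signature to external gene-level study tables and quantifies
candidate markers by qPCR standard curves.

Because the raw arrays of any particular study are not needed to exercise
the method, the package ships a spot-level simulator with planted truth
(`generate_experiment()`), so every stage is testable end to end, plus a
curated reference table of the published-style gene lists
(`load_signature_fixture()`) used in worked examples and tests.

## Preprocessing model

Each array carries Cy3/Cy5 intensities per spot. Writing
$M = \log_2(\mathrm{cy5}/\mathrm{cy3})$ and
$A = \tfrac12 \log_2(\mathrm{cy5}\cdot \mathrm{cy3})$, the cascade is, in
fixed order:

1. **Per-subarray lowess** (`normalize_subarray_lowess()`): $M$ is replaced
   by its residual from a robust locally weighted regression of $M$ on $A$
   fitted on non-control spots; channels are back-computed so $A$ is
   preserved. Span 0.4 with 3 robustifying iterations — typical values for
   array normalization; subarrays with fewer than `min_spots = 50` usable
   spots are left unnormalized with a warning rather than fitted unstably.
2. **Global median scaling** (`scale_to_global_median()`): one scalar per
   array sets the pooled (both channels) median over non-control spots to
   1000. Control spots are excluded from the median but scaled alongside.
3. **Intensity floor** (`apply_intensity_floor()`): channel values below
   200 are raised to 200, stabilizing fold changes at low intensity. This
   deliberately compresses the fold change of spots whose weaker channel
   sits under the floor.
4. **Low-intensity exclusion** (`filter_low_intensity_spots()`): within the
   six arrays of a time-course (3 times x 2 replicates), a probe is
   excluded when *both* channels sit at or below the floor in more than
   half the arrays (more than 3 of 6). A value *at* the floor counts as
   below — flooring precedes the test, so "below" would otherwise be
   undetectable; with that convention the rule is order-invariant.
   Time-courses with a different array count scale the threshold
   proportionally, with a warning.
5. **Log ratios** (`compute_log_ratios()`): $M = \log_2(\text{stim}/\text{vehicle})$
   with channels resolved via the design's dye orientation, so $M$ is
   invariant to the dye swap.
6. **Dye-swap discordance filter** (`filter_dye_swap_discordant()`): a
   probe is excluded for a condition when its replicate means over the
   three time points are at or above $+0.5$ in one dye orientation and at
   or below $-0.5$ in the other (both bounds inclusive).
7. **Replicate averaging** (`average_replicates()`): per time point, the
   mean of surviving replicates. When one replicate is missing after QC the
   surviving value is used rather than dropping the time point — this
   maximizes data use and is logged via `n_rep`. A profile is *complete*
   only with all three time points present.

## Signature calling and SAM

**Fold-change rule** (`call_signature()`): a probe enters the signature
when, in at least one (cell line, treatment), all three per-time-point
averaged ratios share a sign and satisfy $|M| \ge 0.5$ (fold change
$\ge 1.41$ or $\le 0.71$). Sign consistency is required deliberately: the
reported gene lists carry a single signed mean per condition, so a
mixed-sign profile with three large $|M|$ values is not a coherent call.
Gene-level counts (`summarize_signature_counts()`) collapse probes by HUGO
symbol when present, otherwise by accession, so multi-probe genes count
once.

**One-class SAM** (`sam_one_class()`): each gene contributes the pooled
vector of (up to) six ratios of one condition — pooling all three time
points is justified by the negligible kinetic effect at these early time
points, and the six values are treated as exchangeable, which is exactly
what pooling implies. The statistic is

$$d_i = \frac{\bar{x}_i}{s_i + s_0}, \qquad s_i = \mathrm{sd}(x_i)/\sqrt{n_i},$$

with the exchangeability factor $s_0$ selected from candidate percentiles
$\{0, 5, \dots, 100\}$ of the $s$ distribution by minimizing the
coefficient of variation of the windowed median absolute $d$ (the
Tusher-style rule; the number of windows adapts to the gene count, at most
100). The null comes from sign-flip permutations — the natural null for
paired log ratios — exhaustive over all $2^6 = 64$ sign vectors when a
gene has six values, sampled with a seed otherwise. For a grid of
thresholds $\delta$, observed order statistics are compared with their
permutation expectations; genes beyond the first crossing are called, the
estimated FDR is $\hat\pi_0 \cdot$ (median permuted call count) / (observed
call count), and $\hat\pi_0 = \min(1,\, 2\,\Pr(d \in [q_{25}, q_{75}]))$
with quartiles taken from the permuted $d$. A gene's q-value is the
smallest FDR at which it is called, clipped to $[0,1]$.

Two numerical choices matter here:

* **Per-tail q monotonization.** q-values are made non-increasing in the
  statistic's extremity *within each tail separately*. Because the cutting
  rule is asymmetric, pooling both tails by $|d|$ would let genes in a
  never-called tail inherit small q-values from the other tail, which
  measurably degrades FDR calibration when all signal is one-sided.
* **FDR at empty calls.** A $\delta$ with zero observed calls has FDR
  defined as 0 (nothing is falsely called).

Degenerate inputs: a gene with zero variance and $s_0 = 0$ has undefined
$d$ and raises an error; fewer than two finite values per gene is an
error; fewer than 10 sampled permutations is refused.

## Cross-study concordance

External study tables (gene symbol, signed value, study, comparison class)
are harmonized (`harmonize_identifiers()`: upper-casing, whitespace
stripping, user alias map, duplicate symbols averaged), filtered on
presence (`presence_filter()`: a gene is kept when non-missing in at least
`min_present` studies, boundary inclusive), and clustered
(`hierarchical_cluster()`) with distance $1 -$ centered Pearson
correlation over pairwise-complete columns and average linkage — matching
the defaults of the classic Cluster/TreeView tools. Undefined correlations
(zero variance, insufficient overlap) are set to the maximum distance 2
with a warning; leaf order is deterministic with ties broken by input
order. Progression clusters (`assign_progression_clusters()`) combine the
androgen direction with the consensus metastasis-versus-primary direction
(strict sign majority over non-missing studies; $|v| < 0.1$ counts as no
direction because external tables mix effect sizes with direction calls):
repressed/up is cluster 1, repressed/down 2, induced/down 3, induced/up 4;
ties and missing data stay unassigned. The published source databases are
not bundled; `simulate_study_pack()` generates synthetic study packs with
tunable concordance and missingness for testing.

## qPCR quantification

`fit_standard_curve()` fits Ct on $\log_{10}$ input quantity
(least squares; at least three distinct dilutions), reporting $r^2$ and
efficiency $10^{-1/\text{slope}} - 1$ with a warning outside $[0.8, 1.1]$.
`quantify_from_ct()` inverts the line; replicate wells are averaged on the
quantity scale (`collapse_wells()`). `normalize_expression()` supports
plain housekeeping normalization (target/reference) and dual-reference
calibrated mode: target over the *arithmetic* mean of two endogenous
references (the plain reading of "average"; a geometric option is
available), relative to the same ratio in a calibrator sample.
`compare_groups()` runs two-sided Mann-Whitney tests between ordered
disease groups — exact when both groups have at most 8 untied
observations, normal approximation with tie correction otherwise — plus a
linear-trend test implemented as the ANOVA linear contrast of group means
with equally spaced scores (two-sided t on the within-group error), with a
Jonckheere-Terpstra normal-approximation alternative. p-values are
reported unadjusted, as is conventional for these figure-level
comparisons.

## What the simulator emulates — and what it does not

`generate_experiment()` reproduces the design (7 condition time-courses:
the vestigial-AR line receives the androgen arm only; 42 arrays), planted
effects `base_effect` x per-line multipliers (defaults
PC346C = 1, PC346DCC = 0, PC346Flu1 = 2.5, PC346Flu2 = 1 for R1881 and
0/0/0/0.6 for hydroxyflutamide — calibration knobs encoding the
qualitative response pattern of the panel, not published effect sizes), a
smooth sinusoidal intensity-dependent dye bias (so lowess removal is
exercisable), i.i.d. Gaussian noise on $M$ (sd 0.25 2log units by
default), per-probe low-intensity censoring (2%) plus per-spot dropouts
(1%) so the more-than-3-of-6 rule has both pass and fail cases, and three
two-probe genes to exercise symbol collapse. Effects are constant across
time by default (`time_multiplier` overrides for kinetics tests), and
directions are assigned per gene (30% repressed). Baseline abundances are
uniform on 9.3-13.5 log2 units, chosen so regular probes stay clear of
the floor after median scaling and censoring is governed by
`frac_low_intensity`.

It does **not** emulate: image-level artifacts (gridding, saturation),
probe-sequence effects, correlated noise between replicates, batch or
print-run structure, heavy-tailed spot noise, or realistic gene-gene
correlation. Passing recovery tests therefore demonstrates that the
pipeline's logic and calibration are correct under its own assumptions,
not that real arrays meet those assumptions.

## Problem sizes and runtime choices

Tests and the acceptance script use 2000 probes per array (42 arrays) for
recovery studies, 20 replicate seeds for averaged recall/FDP properties,
and exhaustive 64-permutation SAM nulls; these sizes give stable averages
while keeping the default suite fast. Recovery under the default
simulation is scored as: a probe is *called* when it qualifies in any
condition with SAM q at most 0.05, *truly responsive* when any condition
has a nonzero planted effect.

## Numerical choices

* Inclusive thresholds (signature 0.5; discordance bounds) are applied
  with a $10^{-9}$ absolute slack: planted boundary values can land half
  an ulp under the representable threshold after the log2 round trip
  through normalization.
* The lowess fit is evaluated at all spots by linear interpolation of the
  fitted curve (ties averaged, endpoints extended flat); control spots are
  normalized alongside but never influence the fit.
* Zero-variance genes are admissible in SAM whenever $s_0 > 0$.
* In the exclusion rule, "below the floor" is evaluated as at-or-below,
  making the rule insensitive to whether flooring has already been
  applied.

## Known limitations

* With sparse strong responders, lowess can in principle absorb part of a
  planted effect; robust iterations reject such outliers in practice, but
  effects sitting exactly at the calling threshold remain sensitive to any
  upstream distortion — in particular the intensity floor, which by design
  compresses fold changes of near-floor spots.
* SAM q-values from 64 exhaustive sign flips are granular; with very few
  genes the s0 selection windows degenerate and a fixed `s0` should be
  supplied.
* The progression-cluster consensus is a simple sign majority; it ignores
  effect magnitude and study quality weighting.
* Patient-level qPCR comparisons are implemented, but published
  figure-level p-values depend on unpublished per-sample measurements and
  are not reproduced here.
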