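---
title: "Quantifying bimodal immunostaining and song stereotypy with stainmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bimodal immunostaining and song stereotypy with stainmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainmix)
```

## The scientific problem

In the songbird basal ganglia nucleus Area X, the transcription factor
FoxP2 is expressed by medium spiny neurons at two visibly different
levels: a small population of *intensely-stained* nuclei (dark after
DAB-based immunohistochemistry) and a large population of
*weakly-stained* nuclei. The intensely-stained cells are enriched in
newborn neurons, their density falls steeply with age, and weak-cell
density responds to singing. Quantifying these populations requires three
ingredients that this package implements as reusable, tested components:

1. **Per-nucleus intensity measurement** in grayscale photomicrographs:
   background estimation from nucleus-free tissue, detection of stained
   nuclei, and a small circular measurement window over each nucleus
   center.
2. **An objective two-class split** of each animal's gray-value
   distribution: a univariate Gaussian mixture fitted by EM, the number of
   components chosen by BIC, and the class boundary placed at the peak of
   classification uncertainty.
3. **Song stereotypy statistics** (linearity, consistency, motif
   similarity) and the inference layer relating densities and song to age
   (one-phase exponential decay), behavioral group (ANOVA + Tukey), and
   birthdate labeling (Fisher's exact test).

Because the original images and recordings are microscope photographs and
audio that are not deposited anywhere, the package ships a first-class
synthetic-cohort generator that emulates the statistical structure of the
study, so every stage — including the image-processing front end — is
testable end to end against known ground truth.

## Gray-value convention

Darker staining means more antigen, so **the intense class is the left
tail** of the gray-value distribution: `intense_mean_gray <
weak_mean_gray < background_gray` is enforced by the configuration. All
cutoff logic labels a nucleus intense when its gray value falls *below*
the cutoff.

## The mixture model and the uncertainty-peak cutoff

For each animal, the kept gray values $g_1,\dots,g_n$ are modeled as a
$K$-component normal mixture with unequal variances,
$$ p(g) = \sum_{k=1}^{K} \pi_k\, \phi(g;\ \mu_k, \sigma_k^2), $$
fitted by EM ([fit_em()]) and selected by maximizing
$\mathrm{BIC} = 2\ell - (3K-1)\log n$ ([select_model()]; this is the sign
convention of model-based clustering software, and $3K-1$ counts free
weights, means and variances). Numerical choices:

* **Initialization.** `n_starts` restarts: quantile-spread means, a
  deterministic *left-tail* start that seeds one component on the darkest
  1% of values (so a rare intense population is found even when it holds
  only a handful of nuclei), and random draws; each start is refined by
  one nearest-mean reassignment before EM.
* **Variance floor** `sigma_floor = 0.5` gray. 8-bit quantization makes
  narrower components meaningless, and the floor prevents likelihood
  singularities. The EM log-likelihood is asserted non-decreasing at every
  iteration (up to floating-point slack introduced by the floor).
* **Convergence**: absolute log-likelihood change below `tol = 1e-8`
  (default), `max_iter = 1000`. Degenerate fits with coinciding means are
  discarded in favor of the next-best start.

Given the selected fit, the posterior membership probabilities
$\tau_k(g)$ are computed in log space, and the *classification
uncertainty* is $u(g) = 1 - \max_k \tau_k(g)$. The lowest-mean component
is the intense class; all higher components are merged into "weak" (in
fits with three components, the extra components subdivide the weak
population and must not affect the labels). The cutoff is the argmax of
$u$ on a grid (step 0.1 gray) spanning the interval between the intense
mean and the adjacent weak mean, which guarantees a boundary *between*
the classes; grid ties resolve to the midpoint of the tied span. For a
symmetric equal-weight mixture this lands at the midpoint with
$u = 1/2$; for unequal weights it equals the analytic root of
$\tau_1(g) = \tau_2(g)$, a quadratic in $g$.

### When there is no intense component to find

Two situations produce a fit without a usable between-class boundary, and
both occur routinely in adult-like data where intense cells are ~3% of
nuclei:

* **K = 1 selected** — the animal's intensity sample simply contains no
  intense nuclei.
* **Entangled components** — the maximum-likelihood 2-component fit
  absorbs a few intense values *plus* the lower fringe of the weak bulk
  into one wide component. We quantify separation by Ashman's
  $D = |\mu_2 - \mu_1| / \sqrt{(\sigma_1^2 + \sigma_2^2)/2}$ and treat
  the lowest component as a genuine intense class only when $D \ge 3$
  (`min_separation`). On synthetic animals, weak-bulk subdivisions measure
  $D \approx 1.7{-}2.7$ while genuine intense components sit above 3 (and
  typically far above, $D \approx 7{-}14$); the threshold also stays below
  $D = 4$, the smallest class separation at which the classifier is
  expected to agree with the Bayes rule for essentially every nucleus. The
  guard generalizes the merge rule for three-component fits to the
  two-component case. With the guard fired,
  [classify_nuclei()] labels everything weak and flags the cutoff
  undefined.

At the pipeline level a flagged animal still needs intense *counts* from
its counting fields (the study counts intense cells over a much larger
sampled area precisely because they are rare). [analyze_measurements()]
then falls back to a tail rule: nuclei darker than `fallback_sd = 4`
standard deviations below the weak population — the moment-matched pool of
every component except the intense candidate, so a weak bulk the mixture
split into sub-components is re-merged first — are counted intense. This is the automated analogue of recognizing the conspicuously
darker nuclei by eye, and it removes the false zeros and order-of-
magnitude density errors that an undefined cutoff would otherwise inject
into the age-decay fits. Under the weak component itself, the rule
mislabels a fraction $\Phi(-4) \approx 3\times10^{-5}$ of weak nuclei —
negligible at the sampled areas involved.

## Staining quantification

* **Background** $B$ is the mean of mean gray values over at least three
  nucleus-free regions of nidopallium ([estimate_background()]).
* **Detection** thresholds the raster at `detect_frac * B` (default 0.9 —
  permissive enough to catch nuclei staining only 5–10% below
  background), labels connected components (EBImage), and keeps
  components of at least 13 µm² (nuclei substantially smaller than the
  measurement window are not measured). Shape is classified from the
  principal-axis ratio of the component's pixel second moments: ratio
  ≥ 2 is *fusiform* (putative migrating young neurons, excluded from the
  intensity analysis and counted separately); the generator draws round
  nuclei at ratio ≤ 1.25 and fusiform at ≥ 2.2, so the 2.0 threshold is
  unambiguous on synthetic data.
* **Measurement** averages the pixels whose centers fall in a circular
  window of 12.9 µm² placed at the nucleus center — small enough to fit
  inside both nucleus classes.
* **Exclusion rule**: with staining signal defined as $B - g$, a nucleus
  is removed when $B - g \le 0.05\,B$ — stained at background level or
  only 5% above it. The default generator calibration (weak mean 170,
  SD 12, background 200) puts ~4% of round nuclei inside this margin,
  matching the exclusion rate the rule is meant to reproduce. The rule
  only bites on measurements that reach it: a nucleus stained at
  background has no contrast, so thresholded detection never sees most
  such nuclei — the ~4% exclusion is fully visible when analyzing
  pre-measured nucleus tables (the CSV-bypass input mode, mirroring how a
  human observer can measure even the faintest nucleus they spot).
  Setting `min_stain_frac = 0` reruns any analysis without the cutoff,
  and the group-level conclusions must not change (this is tested on
  both input routes).
* **Densities** are areal (cells/mm² of sampled field area on fixed-depth
  sections; no volumetric correction is applied because none is defined
  for this protocol). Weak density comes from the 62×62 µm intensity
  fields; intense and fusiform densities from the 128×162 µm counting
  fields, where the rare classes are sampled over ~5× more area; the
  fusiform inside:outside ratio uses counting fields placed in the
  striatum outside Area X.

## Song statistics

Syllable streams are segmented by two silence thresholds: a new *bout*
after > 2 s of silence, a new *strophe* after > 300 ms ("a couple hundred
milliseconds"; config-exposed). Motifs are found by a greedy left-to-right
scan for in-order template labels, omissions allowed (short motifs).
*Linearity* divides the number of distinct syllables by the number of
distinct transition types; *consistency* divides typical-transition
occurrences (the modal outgoing transition of each syllable, ties
resolved to the earliest observed) by all transitions; *stereotypy* is
their mean. Each strophe contributes a terminal "end" transition, without
which single-transition songs would be ill-defined; tallies pool the
first 20 strophes. Motif similarity — standing in for proprietary
spectrogram-correlation scores — pairs syllables by position, averages
the seven bioacoustic feature differences in units of the corpus-wide
feature SD (clipped at 3), and scales by the length ratio; it is
symmetric, deterministic, 100 for identical motifs, and is used for the
first-vs-third-motif (within-bout) and first-vs-neighboring-first
(across-bout) comparisons over 15 qualifying bouts.

## The synthetic cohort: what it emulates, and what it does not

[gen_animal()] renders each animal's fields as 8-bit rasters: anti-
aliased discs (round nuclei) and ellipses (fusiform) of per-nucleus gray
drawn from the class distribution, placed by rejection sampling with one
nucleus diameter minimum separation, on a noisy background canvas.
[gen_song_corpus()] emits bouts of template motifs with an
age-shrinking rendition jitter CV and occasional transition noise;
[gen_colocalization()] samples BrdU×intensity tables at a configured
odds ratio. Defaults (all config-exposed, chosen once as the package's
study conditions):

* gray means 80 (intense) / 170 (weak) / 200 (background), class SD 12,
  pixel noise SD 3 — giving the ~4% near-background exclusion rate above;
  there is no absolute gray scale in the source protocol, so these means
  are free parameters on the 8-bit scale;
* intense fraction among round nuclei decaying as
  $0.03 + 0.37\,e^{-0.004\,\mathrm{age}}$ (per-day rate of the order
  recovered for density decay), total round density 1200/mm²;
* fusiform density inside Area X decaying 150 → 10 cells/mm² with the
  same rate; constant 40/mm² outside;
* singing (Dir/Undir groups) thins the weak class to 60% and leaves the
  intense class untouched;
* song: 4-syllable template, transition noise 5%, jitter CV falling
  0.12 → 0.03 with age, single-motif strophes by default (so noise-free
  corpora are perfectly linear and consistent), third-and-later motifs
  lengthened by 5%;
* BrdU odds ratio 5 with a 3% weak-class labeling rate.

Intensity/background fields default to 0.2 µm/px (the 12.9 µm² window is
then ~10 px in radius); counting fields render at 0.4 µm/px — nuclei of
~3 µm radius remain over-resolved while the larger raster stays small.
Tests and the acceptance study use 0.4–0.6 µm/px throughout and field
counts at or below the protocol's ranges (e.g. 26-animal cohorts with
3–6 intensity and 10–15 counting fields); these sizes are stated here as
the package's chosen problem scale.

Deliberately **not** emulated: microscope optics (point-spread function,
vignetting, chromatic effects), z-stacks, touching/overlapping nuclei
(minimum-separation placement; the detection stage does no watershed
splitting), audio waveforms, and batch-to-batch staining offsets (a
per-batch gray offset could be added to the generator, but the analysis —
like the original protocol, which interleaved groups across staining
batches — would ignore it). Passing tests therefore demonstrate
correctness of the measurement and inference chain under the generator's
assumptions, not robustness to optical artifacts in real micrographs.

## Statistical layer

* **One-phase decay/association**: both forms are the curve
  $a + b\,e^{-kx}$ ($Y_0 = a + b$, plateau $= a$). [fit_one_phase()]
  profiles $k$ over a log-spaced grid on $[0, 1]$ per day (ages span
  ~100–3000 days, so rates far outside this box are not plausible) with
  the linear pair $(a, b)$ solved exactly at each $k$, then refines the
  best $k$ by golden-section search. The fitted SSres therefore never
  exceeds the constant model's, and $R^2 = 1 - SS_{res}/SS_{tot}$ — the
  convention graphing software reports for nonlinear fits. A constant
  response returns the mean with `k_unidentifiable` flagged; `k` landing
  on the box bound is flagged.
* **ANOVA + compact letters**: standard unbalanced one-way ANOVA
  (`stats::aov`); Tukey HSD p-values feed a letter display in which
  maximal windows of mutually non-significant groups (sorted by mean)
  share a letter.
* **Fisher's exact test**: two-sided probability-mass ordering
  (`stats::fisher.test`), verified in the test suite against a complete
  log-space hypergeometric enumeration written independently.
* Multiple-testing correction is *not* applied across the many
  stereotypy correlations, matching the uncorrected reporting convention
  of this analysis style; users can correct the returned p-values with
  `p.adjust` if desired.

## Reproducibility

Every generator and the pipeline take explicit integer seeds;
[derive_seed()] gives each animal, field and stage its own stream, and
[with_seed()] restores the caller's RNG state. Two runs of
[run_pipeline()] with the same configuration produce byte-identical
reports; [report_summary()] flattens a report for JSON serialization and
hashing.

## Known limitations

* The tail-threshold fallback assumes the dominant mixture component is
  the weak class; in data where intense cells are the majority (very
  young animals) the mixture cutoff will essentially always be defined,
  so the fallback is not exercised there.
* Densities are 2-D areal densities; comparisons across section
  thicknesses would need a volumetric correction the package does not
  implement.
* The motif-similarity statistic is a defined stand-in in feature space;
  its absolute values are not comparable to spectrogram-correlation
  similarity scores, only its ordering behavior is (identical → 100,
  decreasing with jitter and length mismatch).
* Transition tallies treat the strophe as the sequence unit (with the
  terminal token); corpora in which strophes regularly hold multiple
  motifs will count motif-to-motif transitions, lowering linearity below
  1 even for perfect syntax. The generator's default single-motif
  strophes avoid this; `strophe_motifs` exposes the alternative.

## A worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_animals = 12, group_labels = "NS0h",
                     n_intensity_fields = c(4, 4),
                     n_counting_fields = c(8, 8),
                     pixel_scale_um = 0.4, counting_pixel_scale_um = 0.6,
                     seed = 7)
report <- run_pipeline(cfg, stages = c("quantify", "infer"))
print(report)
report$decay$intense        # one-phase decay of intense density vs age
report$animals[, c("age_days", "K", "cutoff", "density_intense")]
```
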