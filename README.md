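# stainmix

Mixture-model classification of nuclear immunostaining intensity, with the
song-stereotypy and inference layer needed to relate staining populations to
age and behavior in songbirds.

## The problem

In the songbird striatal song nucleus Area X, FoxP2-expressing medium spiny
neurons come in two visibly different staining classes after DAB
immunohistochemistry: a rare, dark **intensely-stained** population (enriched
in newly born neurons, collapsing in density as birds age) and an abundant
**weakly-stained** population (whose density drops after singing). Separating
the two objectively — per animal, without a hand-picked threshold — is the
core analysis problem. `stainmix` implements the full chain:

- **Staining quantification** — background estimation from nucleus-free
  tissue, nucleus detection by connected components, mean gray value in a
  12.9 µm² circular window per nucleus, exclusion of nuclei stained ≤ 5%
  above background, and areal densities (cells/mm²) per class, including
  fusiform (putative migratory) nuclei counted separately.
- **Mixture classification** — per animal, a univariate Gaussian mixture
  `p(g) = Σ_k π_k N(g; μ_k, σ_k²)` fitted by EM with multiple starts,
  `K` selected by maximizing `BIC = 2ℓ − (3K−1)·log n`, posterior
  memberships `τ_k(g)` computed in log space, and the weak/intense cutoff
  placed at the **peak of classification uncertainty**
  `u(g) = 1 − max_k τ_k(g)` between the component means. Darker staining =
  lower gray value, so nuclei below the cutoff are "intense".
- **Song analysis** — bout (> 2 s silence) and strophe (> 300 ms)
  segmentation, greedy motif identification, linearity (distinct syllables /
  distinct transition types), consistency (typical transitions / all
  transitions), stereotypy (their mean), within/across-bout motif similarity,
  motif-duration ratios, inter-syllable intervals, per-feature rendition CVs
  and singer classification (≥ 90 motifs singer, < 10 non-singer).
- **Inference** — one-phase decay/association fits
  `Y(x) = plateau + (Y0 − plateau)·e^(−kx)`, OLS regression, one-way ANOVA
  with Tukey-HSD compact letter displays, and Fisher's exact test by
  complete hypergeometric enumeration.
- **Synthetic cohorts** — a seeded generator that renders 8-bit histology
  fields with known nucleus ground truth, Markov-chain song corpora with
  age-shrinking rendition jitter, and BrdU×intensity contingency tables at a
  configured odds ratio, so the whole pipeline is testable end to end.

See the methods vignette (`vignettes/stainmix-methods.Rmd`) for the model,
its assumptions and every tunable parameter.

## A worked example

```r
library(stainmix)

cfg <- cohort_config(n_animals = 12, group_labels = "NS0h",
                     n_intensity_fields = c(4, 4),
                     n_counting_fields = c(8, 8),
                     pixel_scale_um = 0.4, counting_pixel_scale_um = 0.6,
                     seed = 7)
report <- run_pipeline(cfg, stages = c("quantify", "infer"))
print(report)
#> Study report: 12 animals (seed 7)
#>   intense-density decay: k = 0.004391 /day, R2 = 0.963

print(report$decay$intense)
#> One-phase decay fit: Y0 = 534.5, plateau = 31.35, k = 0.004391,
#> R2 = 0.9625 (n = 12)

head(report$animals[, c("age_days", "K", "cutoff", "density_intense")], 4)
#>    age_days K    cutoff density_intense
#> 1  183.8899 2 129.03123       259.21103
#> 2 2450.9476 2  95.38025        18.08449
#> 3 2269.8266 2  81.05000        12.05633
#> 4 1481.5688 3 140.91124        78.36613
```

Twelve synthetic animals aged ~100–3000 post-hatch days are rendered as
histology fields, quantified and classified; the fitted decay recovers the
generator's configured decay rate of 0.004/day from images alone, with
density falling from ~530 to ~31 cells/mm² — the order-of-magnitude
juvenile-to-adult drop the biology shows. `cutoff` is each animal's
uncertainty-peak (or tail-threshold) gray value; `K` the BIC-selected
number of mixture components.

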