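---
title: "Joint-action QPAR screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-action QPAR screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qparscreen)
```

## The problem

Herbal extracts are mixtures of dozens to hundreds of constituents, only a
few of which drive a measured bioactivity. Quantitative pattern–activity
relationship (QPAR) screening regresses a per-sample bioactivity readout
(here: an osteoclast growth-inhibition rate in [0, 1]) on the quantitative
pattern of a chromatographic fingerprint — the peak areas of extracted
features — and asks which features the activity follows. `qparscreen`
implements that workflow end to end for the joint-action model family,
with a deliberately simple data contract: a samples × features abundance
table, one activity fraction per sample, and optionally one UV spectrum
per feature.

## Dose–response and joint-action models

Single constituents are assumed to follow a full-range Hill curve,

$$E(c) = \frac{1}{1 + (EC_{50}/c)^p},$$

with potency $EC_{50} > 0$ and slope $p > 0$; the maximum effect is fixed
at 1, so there is no floating asymptote (biphasic or hormetic shapes are
out of scope). `hill_effect()`, `ec_x()`, `fit_two_point()` and
`fit_curve()` provide the forward map, its exact inverse
$EC_x = EC_{50}\,(x/(1-x))^{1/p}$, the closed-form two-point fit, and a
least-squares generalization.

Mixtures combine constituents through three joint-action models:

* **Concentration addition (CA)** for similarly acting constituents:
  toxic units $S = \sum_i c_i/EC_{50,i}$ share one Hill sigmoid,
  $E = S^p/(1+S^p)$.
* **Response addition (RA)** for dissimilarly acting constituents:
  survival fractions multiply, $E = 1 - \prod_i (1 - E_i)$.
* **The Olmstead cassette model**, the hybrid: features are partitioned
  into *cassettes* of presumed shared mode of action; CA applies within a
  cassette (with a per-cassette power $P_g$), RA across cassettes.
  With one cassette it is exactly CA; with singleton cassettes exactly RA.

A note on the cassette-model equation: the typeset source formula, read
literally, is decreasing in the toxic-unit sum, which contradicts both the
CA formula and the explicitly stated limits (one cassette = CA, singleton
cassettes = RA). This package implements the increasing form
$E_g = S_g^{P_g}/(1+S_g^{P_g})$, taking the stated limits as normative;
the reduction identities are enforced by tests at $10^{-12}$.

In screening use, "concentration" is the min–max-normalized feature
abundance, so fitted potencies are on a normalized-abundance scale, not
µg/mL; they order features but are not assay potencies.

## Parameter estimation

`fit_joint_model()` estimates per-feature potencies and per-cassette
powers by seeded multi-start bounded search: a data-driven heuristic
start (potencies sized so each cassette's mean toxic-unit sum reproduces
the mean activity at power 1), perturbed copies of it, and log-uniform
random starts, each refined by Nelder–Mead on the training RMSE. The
published procedure names only "a global search method"; multi-start plus
derivative-free refinement was chosen because it is reproducible from a
seed and library-agnostic, and the test suite keeps an exhaustive
log-spaced grid search (51 points per parameter) as a brute-force oracle
on small instances, which the multi-start fit must match within 1%.

Bounds: potencies $[10^{-3}, 10^3]$ (normalized-abundance units), powers
$[0.1, 10]$ — spanning the slope range observed for the six reference
standards (about 0.23–1.7) with a wide margin. Parameters are optimized
on an unconstrained scale mapped into the box through a logistic
transform, so no start can leave the bounds. Equal-loss optima are
resolved lexicographically on (power, potencies) for determinism.

Samples are split 0.7/0.3 into training and test by default; the test
RMSE is the "prediction error" used downstream. `pls_baseline()` is the
linear comparator: a NIPALS PLS1 regression on centred data (no
pre-installed PLS package exists in the target environment, so the
30-line classical algorithm is implemented here and verified against
ordinary least squares at full rank, to which PLS is then equivalent).

## Cassette assignment from UV spectra

Features whose UV spectra (200–400 nm) are similar are presumed to share
a chromophore family and hence a mode of action. `spectrum_correlation()`
exposes the Pearson similarity matrix; `cluster_cassettes()` runs seeded
k-means on area-normalized spectra (shape, not intensity, should drive
the grouping); `choose_k()` scores candidate cassette counts by mean
silhouette width and always returns 2-component PCA score coordinates so
the user can override visually — the route the original workflow used.
A `consider_k1` flag is raised when the best silhouette falls below 0.4,
the level that unstructured single-archetype spectra reach in simulation;
well-separated archetypes score above 0.9.

## Monte Carlo Good2bad screening

`good2bad_screen()` draws `iterations` random subsets jointly in the
sample and feature directions (defaults: 1000 iterations, feature
fraction 0.05, sample fraction 0.7 — the published settings; subset sizes
are ceilings with a floor of one), fits the chosen joint-action model to
each subset's training samples, and records the prediction RMSE on the
held-out samples. The error distribution's lower and upper 5% tails
define the small-error models (SEM) and big-error models (BEM), and each
feature is scored by

$$\mathrm{Good2bad}(i) = \frac{F_i^{SEM} + \alpha}{F_i^{BEM} + \alpha},$$

its selection frequency ratio across the tails. The raw ratio is
undefined when a feature never enters a BEM model; the pseudocount
$\alpha$ defaults to one over the tail size (0.02 at the defaults),
which preserves the ordering while keeping scores finite. Cassette labels
are inherited from the full assignment; cassettes emptied by the feature
draw are dropped for that sub-model. Per-subset fits use 8 starts rather
than 32 to keep 1000 iterations tractable on one CPU.

## Mixture-design utilities

`uniform_design_levels()` hard-codes the canonical 8 × 6 layout used to
compose six-standard mixtures — six rows arranging the levels
EC5…EC50 according to a U7(7^6) uniform design, plus an all-EC50 and an
all-EC5 equivalent-effect row. It is deliberately not regenerated
algorithmically: the published rows are the normative artifact.
`mixture_ratios()` resolves a row against an EC table by the
proportionality rule ratio_j = EC_{x_j}(j) / Σ_k EC_{x_k}(k), applied
uniformly to all eight rows (the source is ambiguous about whether the
equivalent-effect rows were ratio-normalized; one consistent rule was
chosen). `dilution_series()`, `pairwise_design()` and `blend_profiles()`
complete the 500 µg/mL, 2×/7-step, 66-pair experimental frame, and
`inhibition_rate()` implements the assay transform
$I = (A_t - A_b)/(A_c - A_b)$ verbatim. That transform equals 1 for the
untreated control, which reads as viability; the complement is available
only as the explicitly named `viability_complement()`, never silently.

## The synthetic world

`generate_qpar_dataset()` draws 12 base fingerprints with per-feature
log-normal abundances (dispersion $\sigma_{\log} = 0.4$, chosen so
blended-table coefficients of variation fall in the 0.1–1.3 band reported
for real peak areas), blends all 66 pairs 1:1, computes noise-free
activities from a ground-truth Olmstead model over a small active set,
and adds clipped Gaussian noise (sd 0.05). The default true potency
(4.1 in raw abundance units, for three actives in one cassette) and power
(3.5) were calibrated once, by forward simulation over 20 seeds, so that
the generated activities match the reported assay summary statistics
(max/min/mean/sd ≈ 0.74/0.09/0.33/0.14), and then frozen. UV spectra are
built from distinct Gaussian-band archetypes per cassette plus noise
(sd 0.03, set so the generator's own correlation contract — within-
cassette > 0.9, cross-cassette < 0.5, single-cassette worlds > 0.95 —
holds by construction).

What the generator does *not* emulate: retention-time drift, peak overlap
and integration error, heteroscedastic assay noise, and — importantly —
between-feature abundance correlation. Real fingerprints of related
constituents co-vary across batches; here every feature is drawn
independently. A green recovery test therefore establishes that the
chain works when actives vary independently, not that it would untangle
strongly collinear constituent families.

## Known limitations

The hardest stated benchmark for the screening chain — all three planted
actives occupying the top three Good2bad ranks in at least 80% of runs at
the default world size — is not attainable in that world, by any
selector. The 66 blends derive from only 12 base fingerprints, so every
feature–activity correlation carries roughly 11 degrees of freedom; a
planted active's realized correlation (mean ≈ 0.55, sampling sd ≈ 0.2)
then overlaps the maximum over 37 inactive features (≈ 0.45–0.65).
Ranking features by their *true* sample correlations — an oracle no
marginal selector can beat — recovers all three actives in at most a few
percent of seeds, and a joint sparse-regression oracle reaches only about
20%. With 2-feature sub-models (the 0.05 feature fraction of 40), the
Good2bad statistic operates near the marginal bound and typically places
two of the three actives in the top three. The corresponding acceptance
test runs the full stated settings and is expected to stay red; the
attainable surrogates — a planted feature carrying ≥ 50% of the activity
variance is ranked first and dominates the pure-noise null, whose score
distribution is centred near 1 — are green.

The model-adequacy comparison (Olmstead beating PLS) is evaluated on the
designed standard-mixture frame (8 mixtures × 7 two-fold dilutions),
where the 64-fold concentration span sweeps the whole sigmoid; at a
single assay concentration the blend world is quasi-linear and the two
models are statistically indistinguishable. This mirrors where the
original comparison was actually made.

## A worked example

```{r, eval = FALSE}
truth <- generate_qpar_dataset(generator_config(n_features = 40, seed = 1))
screen <- run_screen(truth$table, truth$activity, spectra = truth$spectra,
                     model = "olmstead",
                     config = mcs_config(iterations = 1000, seed = 1))
screen$selected          # top-3 candidate features
head(screen$ranking[order(screen$ranking$rank), ])
```

Numerical conventions worth knowing: effects are unitless fractions
(percent inputs are divided by 100 at the I/O boundary only); a zero
concentration maps to effect 0 by continuity; constant feature columns
normalize to zero and are flagged; all stochastic entry points take a
seed and restore the caller's RNG state.
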