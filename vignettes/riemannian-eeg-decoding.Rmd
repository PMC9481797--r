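---
title: "Decoding consumer preference from EEG covariance geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding consumer preference from EEG covariance geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riemeeg)
```

## The problem and the descriptor

When a person decides whether they would buy a product, several cognitive
processes — attention, valuation, memory, approach/withdrawal — engage
concurrently, and each expresses itself in coordinated activity across brain
regions and in different frequency bands. `riemeeg` decodes this binary
preference ("buy"/"no-buy") from multichannel EEG single trials using the
trial's **spatial sample covariance matrix** (SCM) as the descriptor: for a
trial \(X \in \mathbb{R}^{S\times T}\) (sensors × samples),
\[
C = \frac{XX^\top}{T-1}.
\]
The SCM captures the covariation between recording sites — exactly the
between-region coordination that single-channel band power ignores. SCMs are
symmetric positive-definite (SPD), so they live on the curved manifold
\(\mathrm{Sym}^+_S\), not in a vector space, and sensible statistics on them
require the manifold's own geometry.

## The geometry

The manifold is endowed with the affine-invariant Riemannian metric (AIRM),
whose geodesic distance is
\[
\delta(C_1, C_2) \;=\; \bigl\lVert \operatorname{logm}\!\bigl(C_1^{-1/2} C_2\,
C_1^{-1/2}\bigr)\bigr\rVert_F \;=\; \Bigl(\sum_k \log^2 \lambda_k\bigl(C_1^{-1}
C_2\bigr)\Bigr)^{1/2}.
\]
Two properties make this the right metric for EEG covariances: invariance
under any joint congruence \(C \mapsto WCW^\top\) (re-referencing, gain
changes, linear mixing) and under joint rescaling (amplifier units cancel).
The centre of mass of a set of SCMs is the **Karcher/Fréchet mean**
\(\bar{B} = \arg\min_P \sum_i \delta^2(C_i, P)\), computed by fixed-point
iteration in the tangent space (`karcher_mean()`): at iterate \(B\), average
the tangent images \(\operatorname{logm}(B^{-1/2} C_i B^{-1/2})\), take a
unit step through the exponential map, and stop when the tangent-mean norm
drops below `tol`.

**Numerical choices.** All matrix functions are computed by symmetric
eigendecomposition with eigenvalues clipped at a small floor before logs and
negative powers, because short 8-channel trials can be numerically
near-singular. `estimate_scm()` adds an explicit ridge (relative floor
`1e-10` of the mean diagonal) with a warning when needed. The Karcher solver
initialises at the log-Euclidean mean (exact for commuting sets and far
closer to the optimum than the arithmetic mean when the set is dispersed),
takes unit steps halved under an Armijo sufficient-decrease condition — a
plain fixed unit step demonstrably zigzags without converging on dispersed
SCM sets such as near-singular narrow-band covariances under strong subject
shifts — and stops at `tol = 1e-9` on the tangent-mean norm, at numerical
stationarity (no representable step decreases the objective), or errors
after 200 iterations with a typed condition carrying the last iterate.
These solver settings are package decisions — the underlying fixed-point
scheme has no canonical tolerance.

## Per-subject alignment

Different subjects' SCM clouds are similar in shape but sit at different
locations on the manifold — a covariate shift that degrades any pooled
classifier. The congruence
\[
C^A = \bar{B}^{-1/2}\, C\, \bar{B}^{-1/2},
\]
with \(\bar{B}\) the subject's own training-set Fréchet mean, recentres every
subject at the identity while preserving all within-subject distances
(congruences are AIRM isometries). Two policies are fixed here that the
method description leaves open:

* test-time trials are aligned with the **stored training mean** of their
  subject — means are never recomputed with test data, so nothing leaks
  across the evaluation split;
* trials from a subject absent at training are rejected (strict mode,
  default) or aligned by the pooled mean of the per-subject means (lenient
  mode).

## Embedding and out-of-sample extension

Classifiers need vectors, so each band's aligned SCMs are embedded by
classical (Torgerson) MDS on the pairwise AIRM distances: double-centre
\(-\tfrac12 D^{\circ 2}\), eigendecompose, scale eigenvectors by
\(\sqrt{\lambda}\). The spectral form is deliberate — the Nyström
out-of-sample extension needs the eigenpairs and centering terms. An unseen
aligned SCM with distances \(d(x, x_i)\) to the training set is placed at
\[
y_k = \frac{1}{\sqrt{\lambda_k}} \sum_i v_{ik}\,\kappa_i, \qquad
\kappa_i = -\tfrac12\Bigl(d^2(x,x_i) - r_i - \overline{d^2(x,\cdot)} + g\Bigr),
\]
which reproduces a training point's coordinates exactly when fed its own
distance row. AIRM distances are not exactly Euclidean; negative eigenvalues
are dropped (never flipped) and their share of spectral mass is kept as the
`neg_mass` distortion diagnostic. The default dimension is `"auto"` (every
eigenvalue above `1e-9` of the largest); the classifier-space dimension is
not something the method prescribes, so it is exposed in the configuration.

## The seven-band ensemble

Decision-making engages multiple rhythms, and which band separates the
classes varies across individuals. The decoder therefore runs the whole
chain — band-pass filter, SCM, per-subject alignment, MDS, linear SVM —
independently in seven bands (delta 1–4, theta 4–8, alpha1 8–10, alpha2
10–13, beta1 13–20, beta2 20–30, gamma 30–45 Hz) and combines the seven
binary votes by **majority**: a trial is labelled "buy" when at least 4 of
the 7 band classifiers say so.

Filtering is a 3rd-order Butterworth band-pass applied forward–backward
(zero phase; 6th-order magnitude response), with odd-reflection padding of
three filter lengths at each edge to suppress transients — continuous
recordings can instead be filtered before segmentation, which avoids edge
handling altogether. Trials shorter than 1 s are excluded: they cannot
express a full delta cycle. The linear SVM uses soft-margin cost \(C = 1\)
on the unscaled MDS coordinates (they already share one scale). Class
weights default to inverse class frequency: the grouped evaluation protocol
removes whole stimuli from training, which structurally unbalances the
labels and would otherwise bias every band toward the majority class.

## Quantifying separability: the ww-score

To measure how well two labelled clouds separate in an embedding, the
package uses the multivariate Wald–Wolfowitz test (Friedman–Rafsky): build
the Euclidean minimal spanning tree of the pooled points, delete edges
joining opposite labels, and count the resulting subtrees \(R\). The
**ww-score** standardises \(R\) by its exact permutation-null mean
\(2mn/N + 1\) and the null variance conditional on the tree (a function of
\(m, n, N\) and the tree's degree statistics), giving an asymptotic
z-statistic; both the normal lower-tail p-value and a seeded permutation
p-value are reported, since the test is one-sided toward few runs. Strongly
negative scores mean well-separated classes. MST ties are broken by node
order so degenerate inputs stay reproducible. The null mean and variance
formulas were verified against exact enumeration of all label assignments
on small trees.

## Artifact cleaning

Continuous recordings are wide-band filtered (0.5–45 Hz, zero phase) and
then cleaned by a wavelet-ICA chain: split into non-overlapping 10 s
segments; decompose each segment by ICA (a seeded symmetric fixed-point
algorithm with tanh contrast — any non-Gaussianity-maximising ICA satisfies
the contract, which is determinism plus an exact round-trip); flag
components whose |excess kurtosis| > 5, |skewness| > 2, or sub-3 Hz power
fraction > 0.6 (fixed, configurable thresholds replacing by-eye spectrum
inspection; per-component statistics are returned for audit); correct
flagged components; remix.

The correction deserves a precise statement. `wavelet_shrink()` is a
*keep-significant* denoiser: multilevel periodized biorthogonal-4.4
decomposition, noise scale from the finest level's MAD, Benjamini–Hochberg
FDR selection of detail coefficients, hard threshold, inverse transform. For
an **artifactual** component, the statistically significant part *is* the
artifact — blinks and muscle bursts are exactly the large coherent
coefficients — so the cleaning chain replaces a flagged component by
`source - wavelet_shrink(source)`: the sub-threshold residual, i.e. the
low-amplitude background activity that leaked into that component. Unflagged
components pass through untouched, so a recording with nothing flagged
round-trips to numerical precision. The wavelet family order and depth
(bior4.4, 5 levels) are package defaults; the transform was validated
against an independent reference implementation and reconstructs perfectly.

## Evaluation protocol

Accuracy is estimated by repeated **grouped** 85/15 splits: whole stimulus
groups (all views of one product), never individual trials, are assigned to
train or test, the number of held-out groups chosen to bring the realised
trial fraction closest to 15%. Per split the decoder is refit from scratch
on the training portion — subject means, embeddings and classifiers included
— and the report gives mean ± sd accuracy overall and per band. The default
is 100 repeats with a seed ladder (`seed + i`); the acceptance checks use 20
repeats, and the full 10,000-repeat protocol is reachable through the same
argument. Splits whose training portion loses a class are resampled and
counted. Two Riemannian comparators are included on the same preprocessing:
R-kNN (AIRM distances fed to a k-nearest-neighbour rule) and the
tangent-space SVM (aligned SCMs mapped to the tangent space at the training
barycenter, upper triangle with \(\sqrt{2}\) off-diagonal weighting, length
\(S(S+1)/2\)).

## The synthetic generator

Real recordings of this kind cannot ship with the package, so
`sample_trials()` generates the study design the decoder targets, with known
ground truth: 8 sensors at 500 Hz; 2 subjects; 6 stimulus groups × 3 views;
trial lengths uniform in 1.5–2.5 s (comfortably above the 1 s exclusion
rule, matching product-viewing fixations); class separation `effect_size =
2` confined to beta2 + gamma; subject congruence shifts of scale 0.5. Each
trial sums seven band-limited Gaussian processes — white noise coloured by
the band's class covariance, band-pass filtered, with a mild \(1/\sqrt{f}\)
spectral tilt — mapped through the subject's congruence
\(A_s = \operatorname{expm}(s\,G_s)\). The class-1 covariance of an
informative band is \(W\Sigma W^\top\) with
\(W = \operatorname{expm}(e\,G)\), so the AIRM class gap grows monotonically
with \(e\), and `effect_size = 0` gives exactly exchangeable classes.
`sample_scm_cloud()` bypasses time series entirely (Wishart draws around the
class covariances; `dispersion` ≈ 1/degrees-of-freedom) for unit-level
checks of alignment, embedding and classification.

What the generator does **not** emulate: realistic source geometry and
volume conduction, 1/f spectral detail, non-stationarity within a trial,
artifacts (except the dedicated blink injector used by the cleaning
benchmark), and label noise. Passing the synthetic checks therefore
demonstrates that the machinery recovers the structure it models — not that
any particular accuracy will be achieved on human recordings.

## Expected behaviour of the majority vote

One structural property of majority voting is worth stating because it
governs what the synthetic benchmarks can show. If exactly \(k\) of the 7
bands carry class information and their classifiers are essentially perfect
while the remaining \(7-k\) vote at chance independently, the expected
ensemble accuracy is \(P(\mathrm{Binom}(7-k, 1/2) \ge 4-k)\): about 0.66 for
\(k=1\), 0.81 for \(k=2\), 0.94 for \(k=3\). With two informative bands the
ensemble therefore cannot exceed ~0.81 on average no matter how clean the
signal — the uninformative bands dilute the vote. This is a property of the
decision rule itself, visible in the per-band accuracies the evaluation
report prints (informative bands near 1.0, others near 0.5), and it is the
reason the decoder's value on real data rests on *several* bands carrying
at least partial information.

## Known limitations

* Only binary labels; multiclass incentives are out of scope.
* No online/incremental operation; the Karcher mean is recomputed per fit.
* Strict subject mode requires every test subject in the training set; the
  lenient fallback is a pooled mean, not a transfer method.
* The EDF format is not read directly; continuous data enter as delimited
  matrices with a JSON-lines manifest.
* Headline accuracies on human datasets are not reproduced here: those
  require the original recordings, which are not redistributable.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run the full pipeline at the
generator's default design (36 trials of 8 channels, seven bands, 20
grouped splits; 50 paired splits for the alignment contrast; 1000 null
simulations for the runs-test calibration; 20 seeds for the blink
benchmark). These sizes were chosen so that every property is exercised at
the study's own scale while a complete run stays desk-friendly; the repeat
counts are arguments, not constants.
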