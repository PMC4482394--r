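---
title: "Models and methods in waveCNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in waveCNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveCNA)
```

waveCNA de-convolutes absolute somatic copy number, tumor genotype and loss
of heterozygosity (LOH) from tumor SNP-array signals of the Affymetrix kind:
a Log R Ratio (LRR) per probe, measuring relative total intensity, and a B
allele frequency (BAF), measuring the allelic fraction. These arrays are
noisy — LRR standard deviations around 0.17, several times those of
competing platforms — and the BAF noise grows as the tumor copy number
falls. Both facts shape the model below.

## Signal model

For probe $i$ with hidden tumor genotype $G = (m_t, n_t)$ ($m_t$ B-allele
copies out of $n_t$ total), a normal-cell fraction $w$ dilutes the tumor
signal with diploid normal material. The LRR mean is

$$\mu_L = \beta \log_{10}\frac{2w + (1-w)\,n_t}{2} + o + h\,g_i ,$$

where $\beta$ is a platform contraction coefficient (fixed at 0.55 and
exposed in the configuration rather than EM-estimated, to keep the EM
identifiable), $o$ absorbs the baseline shift that aneuploid genomes induce
in within-array normalization, and $h$ couples LRR to the centered local GC
content $g_i$ (GC waviness). For a homozygous deletion with $w = 0$ the
effective copy number is floored at 0.05, reflecting the residual signal
real arrays report at null loci and keeping the logarithm finite.

BAF is mirrored upward around 0.5 (the two parental assignments are
indistinguishable), so all BAF densities live on $[0.5, 1]$. Conditional on
the normal genotype being heterozygous, the mirrored BAF mean is the
contamination-mixed allele fraction
$(w + (1-w) m_t) / (2w + (1-w) n_t)$, with standard deviation
$\sigma^{Bhet}$. Conditional on a homozygous normal genotype the tumor
genotype is the homozygous variant of the state and the mirrored mean is
exactly 1, with the copy-number-specific spread

$$\sigma^{Bhom}_{n_t} = \sigma^{Bhom}_2\, e^{K (n_t - 2)} ,$$

a log-linear law with increment coefficient $K$ (negative in practice:
lower copy number, more BAF noise). The PFB track (population frequency of
the B allele, $p_i$) supplies the prior that the normal genotype is
homozygous, $p_i^2 + (1 - p_i)^2$; probes missing from the PFB get the
uninformative 0.5.

BAF component densities are normals folded at 0.5 and truncated to
$[0.5, 1]$, so each integrates to exactly 1 on its support (the tests
verify this by quadrature). At the upper rail this folded-truncated form
equals the half-normal law of a signal whose noise is reflected at the BAF
boundary — which is also how the simulator generates boundary values, so
the estimator is exactly consistent with the generator.

A two-component mixture guards against signal fluctuation: with prior
$p_f$ (default 0.01) a probe is an outlier with uniform LRR on $[-5, 5]$
and uniform BAF, density 2 on the mirrored scale. We define the
fluctuation BAF density post-mirroring; defining it pre-mirroring would
only rescale a constant.

The hidden states enumerate $n_t = 0, \dots, 7$ with mirrored-unique
genotypes (per-$n_t$ counts 1, 1, 2, 2, 3, 3, 4, 4), 20 states in total.
The $n_t = 0$ state has no tumor alleles; with $w = 0$ its BAF is uniform
on the mirrored scale. LOH is flagged for homozygous states with at least
one copy and for the null state; $(2, 2)$ is copy-neutral LOH.

## Inference

Chromosomes are independent chains. The transition matrix has diagonal
$1 - p_t$ and uniform off-diagonal mass ($p_t = 10^{-5}$ by default) and is
held fixed; re-estimating it tends to absorb segmentation structure into
the transition dynamics. Posteriors come from scaled forward–backward
(implemented in C++), with a uniform initial distribution per chromosome.

EM estimates $\theta = \{w, h, o, \sigma_L, K, \sigma^{Bhom}_2,
\sigma^{Bhet}\}$, seven updates per iteration:

* The E-step computes state posteriors $\gamma_i(s)$, the fluctuation
  posteriors $\gamma_{i,f}(s)$ (the share of $\gamma_i(s)$ carried by the
  outlier component), and, within the signal branch, the responsibility of
  the homozygous BAF component. The complete-data weights for the signal
  branch are $\gamma_i(s) - \gamma_{i,f}(s)$; writing them as
  $1 - \gamma_{i,f}(s)$ (a shorthand that appears in some presentations of
  this decomposition) would over-count probes, and the difference form is
  what makes the likelihood provably non-decreasing.
* $o$ and $h$ are a weighted least-squares fit of the copy-number-corrected
  LRR residual on $(1, g_i)$; $\sigma_L$, $\sigma^{Bhet}$ and
  $\sigma^{Bhom}_2$ are weighted root-mean-square updates. GC is centered
  before use so that $h$ is identifiable against $o$.
* $K$ takes one Newton step with the analytic gradient and Hessian of the
  expected log-likelihood (weighted by the homozygous-component
  responsibilities), using the freshly updated $\sigma^{Bhom}_2$; the step
  is halved (up to 10 times) whenever it would lower the objective.
* $w$ takes one safeguarded Newton step with numeric derivatives of its
  expected log-likelihood profile (LRR plus heterozygous-BAF terms), with a
  local bounded search as fallback when the curvature is unusable, and is
  clamped to $[0, 0.95]$.

Iteration stops when the relative log-likelihood change falls below 0.1%
(configurable). Because the scale updates use squared deviations while the
emissions carry the folded-truncation normalizers, the M-step is very
slightly approximate; if an update ever lowers the likelihood, the previous
parameters are kept and the fit is declared converged, so the recorded
trace is non-decreasing by construction (and asserted in tests).

EM on this model is multi-modal in $w$ (the classic
contamination–ploidy–baseline ridge), so `fit_cna()` restarts from a grid
of $w$ values (default 0.1, 0.3, 0.5) with $o$ initialized at the LRR
median, $\sigma_L$ at the scaled median absolute probe-to-probe difference,
both BAF scales at 0.06, and $K$ at $-0.1$, keeping the best final
likelihood. On a genome with no aberrations $w$ is genuinely
unidentifiable; calls remain neutral there, and the reported $w$ should not
be interpreted.

States are decoded per probe by maximum posterior (Viterbi is available
behind `hmm.decode = "viterbi"`); the average copy number (ACN) is the
posterior-weighted mean of $n_t$. Each probe also receives a goodness
score: the geometric mean of the two-sided Gaussian tail probability of its
LRR under the assigned state and the two-sided tail of its mirrored BAF
under the assigned state's best-matching BAF component. The score is 1 at
the expected values and near 0 for probes no modelled state explains —
runs of low scores are candidate subclonal regions. The literature this
model descends from names such a score without printing its formula; the
geometric-mean construction is this package's own, chosen so both signal
channels contribute symmetrically on a common probability scale.

## Wavelet de-noising

LRR tracks are block signals plus approximately white noise, the setting
wavelet shrinkage was made for. `denoise_lrr()` decomposes each chromosome
(or arm, when a centromere table is given) with the sym8 wavelet to depth 6
by default, using half-sample symmetric boundary extension (it minimizes
edge artifacts on block signals; the transform was validated
coefficient-by-coefficient against an independent reference
implementation). Each level's detail coefficients are soft-thresholded at
the minimizer of Stein's unbiased risk estimate for that level, with the
noise scale taken per level as the median absolute coefficient deviation
over 0.6745 — a per-level rather than global threshold, since the
signal-to-noise mix differs by scale. Reconstruction from the untouched
approximation plus shrunk details preserves segment means and breakpoints
while the white-noise floor drops several-fold.

Two guards connect the smoother to the HMM in the pipeline:

* isolated outliers are winsorized toward a running median (window 9, four
  MADs) before the transform, because a single $\pm 5$ fluctuation spike
  would otherwise be smeared by the smoother into a local bump wide enough
  to mimic a focal aberration;
* the fitted $\sigma_L$ is floored at the raw probe-to-probe noise scale
  estimated before smoothing. Smoothing removes variance but adds no
  information, and its residuals are autocorrelated; an unconstrained
  $\sigma_L$ fitted to the smoothed residual would overstate per-probe
  evidence and let slow residual wander masquerade as shallow aberrations.
  With the floor, the smoothed means sharpen segmentation while the
  evidence accounting matches the raw data.

`level_diagnostics()` quantifies the depth trade-off with a
sensitivity/specificity sweep over an elevated-versus-baseline labelling:
AUC rises steeply from the raw signal through depths 3 and 6, then declines
past depth 6 on tracks that contain focal segments and outliers
(over-de-noising: the smoothing support outgrows the features). The
bundled `denoise_roc_fixture()` reproduces this with broad plus focal
amplifications at platform noise levels.

## Recurrence testing

Across $M > 1$ samples aligned on their common probe grid, per-probe
statistics sum aberration levels: $T^{amp}_i = \sum_j \max(n_{i,j,t} - 2,
0)$, analogously for deletions, and a count of LOH flags. Under the null
that aberrations land at random positions independently per sample, the
cohort statistic is a sum of independent draws from each sample's observed
per-probe statistic histogram, so the exact null is the $M$-fold discrete
convolution of those histograms (copy numbers are integers, so there is no
discretization error). p-values are the inclusive tail $\Pr(T \ge t_i)$ —
the strict-inequality variant, which assigns probability zero to the most
extreme attainable value, is available behind `inclusive = FALSE` — and
are corrected per statistic family with Benjamini–Hochberg, the standard
reading of an FDR "q-value" procedure; families are corrected separately
because pooling them would mix null distributions of different shapes.

## The simulator

`simulate_sample()` draws data from exactly the generative process the
model assumes: segments of constant $(m_t, n_t)$, normal genotypes from the
PFB, contamination-mixed means, Gaussian LRR noise, the log-linear
homozygous BAF scale, GC waviness as a slow sinusoid (amplitude
configurable, period 2000 probes — slow enough to emulate genomic GC
structure yet identifiable against the baseline), and uniform fluctuation
outliers. BAF noise is reflected at the $[0, 1]$ rails rather than
clipped: homozygous BAF sits at the rail, where clipping would place half
its mass in an atom at exactly 1 and make every scale estimate biased by
construction; reflection matches both array behaviour near the rails and
the folded form of the emission density. Default parameters are
$w = 0.3$, $o = -0.1$, $\sigma_L = 0.17$, $K = -0.15$,
$\sigma^{Bhom}_2 = \sigma^{Bhet} = 0.06$ — the noise regime of the arrays
this model targets — over a five-chromosome layout spanning copy numbers 1
to 5 with roughly half the genome diploid.

What the simulator does not emulate: probe-specific response biases,
spatially structured (non-sinusoidal) waviness, correlated noise, subclonal
mixtures, and real PFB structure (it draws PFB uniformly). Tests passing on
this generator therefore demonstrate internal consistency of model and
inference, not performance on any particular real dataset.

## Problem sizes and numerical choices

The test suite and the acceptance script use: exhaustive-enumeration
oracles at 2–4 probes and 2–3 states; derivative checks at $10^{-5}$ step;
parameter recovery at 50 000 probes; pure-versus-70%-contaminated twins at
25 000 probes; ROC diagnostics at about 20 000 probes; cohorts of 6–8
samples at 2 500–4 000 probes. These sizes give sampling error well inside
the asserted tolerances while keeping a full run in a few minutes.

Other numerical choices: emissions are computed in log space with the
fluctuation floor preventing zero rows; posterior rows are renormalized
after the backward pass; scale parameters are bounded below at $10^{-4}$;
$K$ is clamped to $[-2, 2]$ and $w$ to $[0, 0.95]$; odd-length chromosomes
pass through the transform's native padding and are truncated back; ties
in maximum-posterior decoding resolve to the lowest state index.

## Known limitations

* The 20-state catalogue tops out at $n_t = 7$; higher amplifications are
  absorbed into the top states.
* Chromosome X is modelled like an autosome (diploid normal), which is
  only appropriate for female samples; Y is excluded by default.
* The exact composition of the state set and the QC thresholds
  (`max_sigma_l` 0.35, `|h|` 0.2, convergence required) are this package's
  choices, set so that clean synthetic samples always pass; they are
  configurable and should be tuned on real batches.
* Subclonal fractions are not deconvoluted; the goodness score only flags
  candidate regions.
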