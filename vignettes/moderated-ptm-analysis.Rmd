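---
title: "Moderated differential abundance of proteins and histone PTMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated differential abundance of proteins and histone PTMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmdiff)
```

## The analysis problem

Bottom-up mass spectrometry of histone preparations yields, after peak-area
integration by upstream tools, an intensity for every observed modification
state of every histone peptide — for example the unmodified, mono-, di- and
trimethylated forms of H3 K27 — across a handful of biological replicates in
two experimental arms. The same experiments usually produce a whole-proteome
MS1 intensity matrix from the cell lysate. The questions are the same in
both cases: which features change between the arms, and is a change at the
chromatin level explained by abundance of the histone-modifying enzymes
themselves? `ptmdiff` covers that workflow: relative-abundance transforms
for the PTM data, a moderated two-sample test for both data types,
false-discovery-rate control, annotation of writer/eraser/reader proteins,
and the standard figures.

## Relative abundance: beta- and M-values

Raw modification intensities are not comparable across peptides or samples.
Within a *peptide family* — all modification states of the same site-bearing
peptide — the natural quantity is the share of the family's signal carried by
one state. For modification $i$ in family $F$ of sample $s$,

$$\beta_{is} = \frac{x_{is}}{\sum_{j \in F} x_{js} + c}, \qquad c = 100
\text{ by default},$$

where the offset $c$ in the denominator regularizes low-intensity families:
a family whose entire signal is comparable to $c$ has all its betas shrunk
toward zero rather than being amplified into unstable proportions. The cost
is that betas become dependent on the raw intensity scale, so the offset is
configurable (`compute_beta(ptm, offset = )`), recorded on the result, and
echoed in every run log. With `offset = 0` the transform reduces to the
plain percent-of-family value (`family_percent()`); the sample-wide variant,
where the denominator is the whole sample's modification total, is
`total_intensity_normalize()`.

Betas live in $[0, 1)$ and violate the Gaussian working assumption of a
t-test, so testing is done on the logit scale:

$$M = \log_2 \frac{\beta}{1 - \beta}.$$

The base-2 logit is the M-value convention of DNA methylation analysis,
which this transform mirrors; a natural-log logit would differ only by a
constant factor, but the base must be fixed for fold changes to be
interpretable. Betas of exactly 0 or 1 (possible only for empty or
single-member families) are clamped to $\varepsilon = 10^{-6}$ from the
boundary, with a warning, never silently.

Which rows form a family is itself a modelling choice: grouping by single
amino-acid site (`histone_site`, the default) treats H3 K27me and H3 K27me3
as competing states of one site, while grouping by tryptic peptide
(`histone_peptide`, requires a `peptide` column) co-normalizes all sites on
the same peptide. Both are supported because upstream tools report both ways;
the default is the site rule, which requires no extra input column.

## The moderated t-test

With $n = 3$ replicates per arm, per-feature variance estimates on 4
residual degrees of freedom are so noisy that the ordinary t-test is
dominated by features whose variance is underestimated by chance. The
moderated test treats the per-feature variances as draws from a scaled
inverse-chi-square prior, $\sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}$, and
replaces each feature's pooled variance $s_g^2$ (on $d_g$ degrees of
freedom) by the posterior mean

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

testing $t_g = \widehat{\mathrm{lfc}}_g \big/ \tilde s_g
\sqrt{1/n_a + 1/n_b}$ against a t distribution on $d_0 + d_g$ degrees of
freedom (two-sided, computed from the upper tail for numerical stability).

The hyperparameters are estimated across features by the method of moments
on the log variances. Under the model,
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$ is an unbiased estimator of
$\log \sigma_g^2$ up to the prior terms, and

$$\psi'(d_0/2) = \operatorname{mean}_g\!\Big[(e_g - \bar e)^2
\tfrac{n}{n-1} - \psi'(d_g/2)\Big], \qquad
s_0^2 = \exp\!\big(\bar e + \psi(d_0/2) - \log(d_0/2)\big),$$

with $\psi$ and $\psi'$ the digamma and trigamma functions. The trigamma
equation is solved by Newton iteration with monotone bracketing (tolerance
$10^{-8}$, at most 50 iterations); when the moment target is non-positive
the sample variances are under-dispersed relative to any finite prior, and
the $d_0 = \infty$ limit is taken — every feature receives the common
variance $\exp(\bar e)$ and a Gaussian reference. The estimator is the
plain, non-robust method of moments; a single extreme-variance feature can
pull the prior, which is a documented limitation. At the other limit,
$d_0 = 0$ recovers the classical pooled t-test exactly, which the test suite
asserts to $10^{-12}$.

Bookkeeping choices that matter with missing data: each feature uses its own
effective $n_a$, $n_b$ and $d_g$ both in prior estimation and in the test's
degrees of freedom (the exact rule, not the balanced-design shortcut);
features with $d_g = 0$ but at least one observation per arm get the prior
variance on $d_0$ degrees of freedom and are flagged; features missing an
entire arm are reported with missing statistics rather than dropped. Missing
values are represented as absent, never as zero — a zero intensity is a
measured zero, and with the default `zero_policy = "missing"` it becomes
missing only at the log2 step, where no usable value exists.

Significance combines two gates: Benjamini–Hochberg adjusted $p <$ `alpha`
(default 0.05) and $|\mathrm{log2FC}| > \log_2($`fc_threshold`$)$ (default
2, read symmetrically — up or down). The fold-change sign convention is
treatment minus control, with the treatment arm an explicit argument
(defaulting to the first level appearing in the metadata, announced in a
message and echoed in the run log).

Whether PTM testing should run on M-values or on log2 intensities is an
explicit choice (`value_mode` in `run_ptm()`), defaulting to M-values —
the transform exists precisely to make the Gaussian machinery applicable —
with log2 intensities available when upstream normalization already
produced testable values. No hidden between-sample normalization is applied
to protein intensities; if the input matrix was not normalized upstream,
that is visible in the per-sample boxplots and is the user's call.

## Figures

The preliminary set (histogram, per-sample boxplots, PCA on centered log2
values of complete-case features with percent variance in the axis labels,
classical MDS on Euclidean sample distances) diagnoses scale and grouping
problems before any testing. The volcano plot draws
$-\log_{10} p$ (raw or adjusted, selectable) against log2 fold change with
dashed lines at the two thresholds; the significant set is red,
modifier-catalogue matches blue, and a modifiers-only view is a flag.
$-\log_{10}(0)$ is clipped to one unit above the largest finite value in the
result set. Heatmaps cluster features by Euclidean distance with complete
linkage (fixed for reproducibility, configurable) and keep samples in
metadata order; protein heatmaps show row z-scores (sample, $n-1$
denominator), PTM heatmaps show the M-values themselves — the literal
reading of the display convention — with z-scoring available as a flag.
Every plot builder returns its backing data frame, and `save_plot()` writes
a CSV sidecar next to each image, so figures are testable and diffable
without pixel comparison.

## Modifier annotation

Differential results are cross-referenced against a writer/eraser/reader
catalogue (protein, organism, role, mark). Matching is gene-symbol-first and
case-insensitive — such catalogues are symbol-centric — with exact Uniprot
accession as fallback; a feature matching several catalogue rows keeps all
of them and is flagged ambiguous rather than arbitrarily resolved. A small
bundled catalogue of canonical mouse (plus a few human) writers, erasers
and readers ships for tests and examples.

## The synthetic-data generators

`simulate_protein()` draws from exactly the model the test assumes: true
variances from the inverse-chi-square prior ($d_0 = 8$, $s_0^2 = 0.25$ by
default — a typical shrinkage strength and residual spread for log2 MS1
data), Gaussian log2 abundances with baselines at $25 \pm 3$ log2 units
(the usual MS1 range), two arms of 3, a 10% planted fraction with
$|\mathrm{log2FC}| = 2$ and random sign, and export on the raw exponentiated
scale so the pipeline's own log2 step is exercised. `simulate_ptm()` draws
within-family compositions from a Dirichlet around group-specific mean
proportions (concentration 200, giving the few-percent replicate scatter
typical of histone PTM measurements) with log-normal family totals around
$10^5$; planted shifts move one member's treatment-arm mean proportion and
rescale the rest, erroring when the composition would leave the simplex.
Both generators are pure functions of their argument tuple including the
seed, restore the caller's RNG state, and write a ground-truth sidecar
separate from the data file.

What the generators do *not* emulate bounds what passing tests show about
real data: missingness is at most completely-at-random (a flag), there are
no batch effects, no intensity-dependent variance trend, no correlated
features, no isotope or peak-integration artifacts, and no
between-sample normalization drift. The checks calibrate the statistics on
their own assumptions; they do not certify behaviour under violations of
those assumptions.

The routine verification sizes — 2,000 features for null calibration and
planted-effect recovery, 10 replicate seeds pooled, 5,000 features for
hyperparameter recovery — keep every property estimable with comfortable
margins while the full suite runs in seconds.

## Reading the example data

The readers accept plain comma-delimited CSV (tab-delimited input is
rejected with a message rather than mis-parsed), match metadata `file_name`
to intensity columns by exact string comparison, and disambiguate duplicate
feature identifiers by appending the row ordinal — never by aggregating
rows, which would silently change every downstream statistic. Binding
reorders samples canonically by display label, so results are invariant to
metadata row order and matrix column order.

## Known limitations

Only two-group designs are supported — no blocking, multi-factor designs, or
multi-group ANOVA — and the prior estimator is the plain method of moments
without robustification or a variance trend. The beta offset operates on the
raw intensity scale and therefore interacts with instrument scaling; when
comparing across acquisitions, either normalize totals first or set
`offset = 0` and accept noisier low-intensity families.
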