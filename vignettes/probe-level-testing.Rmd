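---
title: "Probe-level t-testing: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-level t-testing: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probetest)
```

## The model and why the test needs no preprocessing

Probe fluorescence is modeled as

$$Y_{ijg} = B_{jg} + \varphi_{jg}\,\theta_{ig},$$

where $i$ indexes samples, $j$ probes and $g$ genes (probe sets):
$B_{jg} \ge 0$ is background from optical noise and non-specific
hybridization, $\varphi_{jg} > 0$ a probe-specific affinity, and
$\theta_{ig}$ the transcript concentration. Two assumptions matter:
intensity is **linear** in concentration, and after quantile normalization
the background is **sample-independent**. Under them, the pooled two-sample
t-statistic of one probe's intensities,

$$t = \frac{\langle Y\rangle_A - \langle Y\rangle_B}{s}, \qquad
  s = \sqrt{a\,(SS_A + SS_B)}, \qquad
  a = \frac{1/n_A + 1/n_B}{n_A + n_B - 2},$$

is invariant under $Y \mapsto aY + b$ for $a > 0$, so the additive constant
$B_{jg}$ and the multiplicative constant $\varphi_{jg}$ cancel: the t on raw
normalized intensities equals the t on $\theta$ itself. Background
correction — the step whose estimation errors classically inflate
low-expression variance and motivate shrinkage methods — is skipped, not
fixed. No log transform is applied anywhere: the t-test is not invariant
under monotone transforms, and the linearity argument holds on the natural
scale.

Each gene's probes give a *set* of t-values; the per-gene statistic is their
**median** (robust to the occasional cross-hybridizing or dead probe), and
genes are ranked by $|$median $t|$ since differential expression can go
either way. The ranking, which is the method's primary output, does not
depend on the p-value machinery below.

## The null distribution of a median of t-variates

For a gene with $n$ probes, treat its probe t-values under the null as $n$
i.i.d. Student-t variates with $\nu = n_A + n_B - 2$ degrees of freedom
(independence across a gene's probes is an assumption, not a theorem — see
Limitations). For odd $n$ the median is the central order statistic, with
density

$$g(t) = C_n\,[F(t)]^{(n-1)/2}\,[1-F(t)]^{(n-1)/2} f(t),\qquad
  C_n = \frac{n!}{\left(\frac{n-1}{2}\right)!\,\left(\frac{n-1}{2}\right)!},$$

where $F$, $f$ are the t cdf/pdf. `median_t_cdf()` integrates $g$ by
adaptive quadrature (absolute tolerance $10^{-9}$, exploiting the symmetry
$g(t) = g(-t)$ and integrating piecewise over geometric segments so very
large $|t|$ cannot hide the central peak from the first coarse pass), and
`p_value()` returns the left-tail mass (one-sided) or
$2\min\{G(t_m),\,1-G(t_m)\}$ (two-sided, the default, because the direction
of change is unspecified a priori). For fixed $n$ and $\nu$ the two-sided
p-value is strictly decreasing in $|t_m|$, so ranking by ascending p equals
ranking by descending $|$median $t|$ — the suite asserts this.

**The even-$n$ constant cannot be used as printed.** The analogous
expression with exponents $n/2$ and $C_n = n!/((n/2)!)^2$ is *not* a
density: at $n = 2$ it integrates to $2\int_0^1 u(1-u)\,du = 1/3$. The
package therefore defines the even-$n$ median — consistently with
`median_t_per_gene()` — as the mean of the two central order statistics
$X_{(k)}, X_{(k+1)}$ ($k = n/2$), whose exact density is obtained by
quadrature of their joint density
$\frac{n!}{((k-1)!)^2} F(x)^{k-1} (1-F(y))^{k-1} f(x) f(y)$ along the
anti-diagonal. This corrected density normalizes to 1 and matches a
$10^6$-draw Monte-Carlo oracle; the as-printed expression is retained only
in `median_t_pdf_as_printed()`, with a test witnessing its mass defect. On
the common 11-probe platform $n$ is odd and the closed form applies
directly.

Degenerate cases. A gene with a single probe has $g = f$ (the plain
t-test). Zero pooled variance yields $t = 0$ when group means are equal and
a signed-infinity sentinel otherwise; sentinels order above all finite
values in the ranking and get $p = 0$. An opposite $(-\infty, +\infty)$
central pair (only possible for even $n$) is defined as median 0 —
perfectly balanced evidence.

## Quantile normalization

The only preprocessing: every array is forced to the reference distribution
whose value at rank $r$ is the across-array mean of the $r$-th order
statistics, replacing values rank by rank. Tied values all receive the mean
of the reference values over their tied rank range ("average ranks"), so
equal inputs map to equal outputs and the result is invariant to sample
permutations; this matches `limma::normalizeQuantiles(ties = TRUE)`, which
the tests use as an independent oracle. One honest caveat: with ties the
columns' value multisets are *not* exactly identical afterwards (a tie
block's range mean is a value other columns need not contain), so exact
idempotence and the shared-multiset invariant are guaranteed only for
tie-free columns — the measure-one case for continuous intensities.
Normalization is computed jointly over all arrays of both conditions before
testing, since the sample-independence of $B$ is a post-normalization
assumption.

## What the synthetic generator emulates

`simulate_latin_square()` reproduces the HG-U133-style spike-in world:
42 spiked genes in 14 groups of 3, concentrations $0$ and the doubling
series $0.125, 0.25, \ldots, 512$ pM, 3 replicate arrays per group, 11
probes per gene, and 22,958 unspiked genes for a 23,000-gene array. Gene
group $g$ on sample group $s$ receives concentration index
$((s + g - 2) \bmod 14) + 1$ — the cyclic Latin square: every gene group
visits every concentration exactly once. `rearrange_latin_square()` then
forms 14 two-condition "experiments" by pairing consecutive sample groups
($k$ vs $k+1$, cyclically). In each experiment every gene group steps one
position along the concentration series — a fold change of exactly 2 —
except the group wrapping from 512 pM back to 0, which is excluded from
evaluation, leaving $42 - 3 = 39$ true positives per experiment (the group
stepping $0 \to 0.125$ pM stays in the truth set; its "fold change" is
infinite rather than 2, but it is genuinely differential).

Stated-world parameter choices (fixed before any acceptance run, with
units and rationale):

* **Noise**: the intensity model carries no explicit noise term, so the
  generator multiplies by lognormal noise with mean 1 and coefficient of
  variation `noise_cv = 0.2` — microarray error is predominantly
  multiplicative at moderate-to-high intensity, and 20% is a typical
  between-replicate CV.
* **Background** $B_{jg}$: lognormal, median 100 a.u., `sdlog` 0.5 —
  places the low end of the spike series (0.125–4 pM at affinity ~1) at or
  below background, exactly the regime where background-correction errors
  dominate.
* **Affinities** $\varphi_{jg}$: lognormal, median 1, `sdlog` 0.5 —
  order-of-magnitude probe-to-probe sensitivity spread.
* **Unspiked concentrations**: lognormal, median 4 pM, `sdlog` 1.5, drawn
  once per gene and held constant across samples (they are nulls by
  construction).
* **Generic two-condition data** (`simulate_two_condition()`): 2,000 genes,
  100 DEG at fold change 2, 20 + 20 samples, 11 probes/gene; baseline
  concentrations lognormal median 50 a.u., `sdlog` 1, spanning
  below-background to well-above-background expression.
* **Imperfect preprocessing baseline**
  (`summarize_with_background_error()`): subtracts
  $\hat B = B + \mathcal N(0, \sigma)$ with default $\sigma = 50$ a.u.
  (half the median background — a deliberately *moderate* error), clamps at
  a floor of 1 a.u., and summarizes genes by the median over probes. It is
  the "background-correct-then-t-test" comparator, with the estimation
  error made explicit and tunable.

What a green test does **not** establish: the generator draws independent
lognormal noise per probe and sample, so it cannot witness spatial optical
artifacts, probe-sequence-driven cross-hybridization (correlated errors
*within* a gene), saturation at the top of the dynamic range, or the
real-data possibility that normalization fails to make $B$
sample-independent. Results on the synthetic world are directional evidence
for the method's mechanism, not a claim about any particular real dataset.

## Evaluation procedures

*Sensitivity.* Each rearranged experiment yields an ROC curve of the
ranking against its truth set (excluded genes removed; TP rate over 39
truths, FP rate over the unspiked genes). The 14 curves are averaged TP-
and FP-rate-wise on a common grid of called-gene counts — the only
parameterization that keeps the curves commensurable without interpolation
assumptions — and the averaged polyline's trapezoid AUC is reported. Note
that averaging a perfect curve with a chance diagonal gives AUC $3/4$
(the mean function $(1+x)/2$), a useful sanity anchor.

*Robustness.* `robustness()` draws random sample subsets (without
replacement, stratified proportionally by condition so every subset keeps
$\ge 2$ samples per group — the pooled variance must stay estimable),
reruns the full ranking per subset, takes the top $N$ (reference $N=100$)
and averages the pairwise shared fraction $f = \langle f_{a,b}
\rangle_{a \ne b}$ over all unordered pairs. Because subsets share samples,
$f$ on pure-null data sits slightly above the hypergeometric expectation
$N/n_{\text{genes}}$.

## Numerical choices and degenerate inputs

* $C_n$ is computed by exact integer arithmetic ($C_n = n\binom{n-1}{k}$ for
  odd $n = 2k+1$), representable without error in doubles for $n \le 50$;
  density evaluation works in log space via `pt(log.p = TRUE)` to keep the
  far tails finite.
* Quadrature: `stats::integrate` with `rel.tol = 1e-10`,
  `abs.tol = 1e-12`, piecewise over $(0, 10^m]$ segments.
* Ties in the ranking are broken lexicographically by gene id —
  deterministic output files byte-identical across runs with equal seeds.
* Missing values are rejected at parse time ("NA" is a parse error): the
  formulas assume complete matrices, and silent imputation would be worse.
* All randomness flows from explicit `seed` arguments through `with_seed()`,
  which restores the caller's RNG state; no global state is consumed.

## Open choices made here (and why)

* **Ranking key**: $|$median $t|$, not signed — DEG direction is rarely
  known a priori; a one-sided flag exists for when it is.
* **Sidedness of p**: two-sided by default for the same reason; the
  one-sided left-tail integral is available via `sided = "one"`.
* **Subsampling stratification**: proportional to the full-data condition
  sizes; unstratified draws can produce subsets where a condition has < 2
  samples, which the t-test cannot use.
* **Normalization scope**: over all probes of all arrays (not spiked
  probes only) — the realistic analysis setting.
* **Equal-variance pooled t only**: the invariance argument is exact for
  the pooled form; a Welch variant would change df per probe and break the
  single-null-per-(n, df) structure.

## Limitations

* Probes of one gene are treated as independent under the null. Real
  probes of a probe set share target-driven and sequence-driven
  correlation; the analytic p-values are therefore approximate (the
  ranking is unaffected). No inter-probe dependence correction is applied.
* The method deliberately produces **no expression estimates** — genes are
  ranked and tested, but if you need $\hat\theta$ you need a summarization
  method.
* p-values assume the probe t's are t-distributed, which holds exactly
  under normal noise; under the generator's lognormal noise (CV 0.2) the
  approximation is good (the null calibration test holds the 5% level
  within its exact binomial 99% band) but heavier-tailed real noise can
  decalibrate the tails.
* Perfect-match intensities only; mismatch probes, CEL/CDF parsing, RMA or
  other preprocessing reimplementations, and FDR control beyond ranking are
  out of scope.
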