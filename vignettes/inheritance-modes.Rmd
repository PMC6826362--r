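---
title: "Heterosis and expression inheritance in reciprocal crosses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterosis and expression inheritance in reciprocal crosses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetexpress)
```

This vignette is the package's account of its statistical machinery: the
models, the tunable parameters and their defaults, what the simulator
does and does not emulate, and the design choices made where more than
one defensible option existed.

## The design

Everything operates on a fixed four-group layout: two purebred parental
lines `P1` and `P2` (in the motivating broiler × layer experiment, the
CC and RR lines) and the two reciprocal hybrids `F1A` (sire P1 × dam P2;
CR) and `F1B` (the reverse; RC). Reciprocal hybrids share the nuclear
genome, so comparing them cancels—or exposes—maternal and cytoplasmic
effects. External labels map onto these four via `group_map` arguments;
nothing downstream is organism-specific.

## Phenotypic heterosis

Mid-parent heterosis of a trait is

$$H\% = 100\cdot\frac{\bar F_1 - \tfrac12(\bar P_1 + \bar P_2)}
                      {\tfrac12(\bar P_1 + \bar P_2)}.$$

`heterosis_percent()` refuses a zero mid-parent value rather than
returning an infinity: with AFP, the layer line contributes 0 % fat, so
the mid-parent is half the broiler mean and the statistic is well
defined, but a user feeding two zero-mean parents gets an error, not a
silently infinite percentage.

Significance is assessed by
$t = H\%\cdot(\bar P_1+\bar P_2)\sqrt{n_1} \,/\, (2\,s_{F1})$ on
$n_1-1$ df, which algebraically reduces to the one-sample Student test
of the F1 mean against the mid-parent value with the parental means
treated as fixed constants. Treating them as fixed is a deliberate
simplification: the parental samples are purebred lines with small
within-line variance relative to the F1 − MP gap, and the reduction to a
textbook one-sample t keeps the statistic interpretable. Published
typesettings of this formula are ambiguous about a $\sqrt2$ factor; the
package exposes `t_variant = "sqrt2"`, which divides the statistic by
$\sqrt2$ and is therefore uniformly more conservative. On the observed
female AFP summaries the default reading gives p < 0.01 for both
hybrids; the conservative reading still gives p < 0.05 for both but
crosses the 0.01 line for the smaller-effect hybrid. P-values are
two-sided because heterosis can be negative. With $s_{F1}=0$ the
statistic is undefined; the result carries a `degenerate` flag and
reports p = 0 when the F1 mean is off the mid-parent (all observations
identical and displaced) or p = 1 when it is exactly on it.

## The count model

### Normalisation

Raw counts are scaled by per-sample size factors. The default is the
median-of-ratios estimator (per-sample median of gene-wise ratios to the
geometric-mean reference, zero-containing genes excluded). The simpler
column-sum factor is available as `norm_method = "colsum"`, but it is
*not* the default for a reason worth spelling out: in a hybrid whose
over- and high-parent-dominant genes are systematically up, those genes
inflate the hybrid's library total, so column-sum scaling deflates every
other gene in that sample and manufactures spurious "down" calls in
hybrid-vs-parent contrasts. On simulated data with 200 such genes among
1500, column-sum scaling pushed the raw false-positive rate of
hybrid-vs-parent contrasts to ~27 % (all downward); median-of-ratios
restored it to ~7 %. This composition-robustness argument is the
standard one in count-based differential expression.

### Filtering

FPKM is computed as $10^9 \cdot c_{gs} / (\ell_g N_s)$ from supplied
transcript lengths and library sizes (column sums by default), and genes
with mean FPKM below 1 across **all** samples are removed before any
testing. The boundary is inclusive on the keep side: mean FPKM exactly
1.0 is retained, matching the "below 1 removed" phrasing of the decision
rule. The filter exists to stabilise dispersion estimation and reduce
the multiple-testing burden; the threshold is conventional, not tuned.

### Dispersion

Per gene, a single NB dispersion $\alpha$ (variance $\mu + \alpha\mu^2$)
is estimated by method of moments on normalised counts: within-group
variances pooled across the four groups (weighted by df), compared with
the overall mean, floored at $10^{-8}$. There is no shrinkage toward a
mean–dispersion trend. This is a conscious simplification: with ~19 df
the raw moment estimator is noisy and the resulting Wald test runs
slightly hot (empirically ~6–7 % at nominal 5 % with six replicates per
group), which the test suite pins as an explicit calibration bound
rather than hiding. Users who need tighter calibration on real data
should prefer a dedicated DE package; the contribution here is the
downstream inheritance-mode logic, which only consumes per-contrast
calls.

### The Wald contrast

For a contrast of groups $a$ vs $b$ the effect is
$\log_2\!\big((\hat\mu_a + c)/(\hat\mu_b + c)\big)$ with pseudo-mean
$c = 0.5$ normalised counts guarding against zero means, the standard
error follows from the delta method with
$\mathrm{Var}(\hat\mu_g) = (\hat\mu_g + \alpha\hat\mu_g^2)/n_g$, and the
statistic is referred to N(0, 1). The statistic is antisymmetric under
swapping the contrast sides and its p-value invariant, which the suite
checks. BH adjustment is applied **within** each contrast, matching an
analysis that runs each comparison independently.

The additivity test needs a contrast with no physical group: the hybrid
against the parental mid-point. The `MID` pseudo-group has mean
$(\hat\mu_{P1}+\hat\mu_{P2})/2$ and variance
$(\mathrm{Var}(\hat\mu_{P1})+\mathrm{Var}(\hat\mu_{P2}))/4$ from
independence of the parental groups. The published analyses this
reproduces never state how "not different from the parental mean" was
tested; an explicit Wald contrast at the same BH-adjusted α was the
cleanest mechanisation and is stated here as this package's choice.

## The twelve types and five categories

Per gene and cross, four calls are made at adjusted p < 0.05 (strictly
below; an adjusted p of exactly 0.05 is non-significant): parents
(`P2_vs_P1`), hybrid vs each parent, hybrid vs mid-parent. Rules fire in
fixed precedence:

1. **over** (V/VI/VIII): hybrid significantly above both parents; the
   subtype records whether P1 was higher, P2 was higher, or the parents
   were indistinguishable.
2. **under** (III/VII/X): the mirror image below both parents.
3. **high-parent** (II/IV): parents differ; hybrid indistinguishable
   from the higher parent and significantly above the lower.
4. **low-parent** (IX/XI): parents differ; hybrid at the lower parent
   and significantly below the higher.
5. **additive** (I/XII): parents differ; hybrid non-significant against
   the mid-parent **and** its point estimate lies strictly between the
   parents. The subtype records the direction of the parental
   difference.
6. anything else is `none` / `other` — including discordant patterns
   such as a hybrid above one parent and below the other with no rule
   satisfied; forcing such genes into a bin would misstate the evidence.

Precedence makes the table exhaustive and exclusive by construction, and
the suite verifies this by enumerating all 144 sign-consistent evidence
tuples, together with the relabeling symmetry: swapping P1 and P2 maps
I↔XII, II↔IV, IX↔XI, V↔VIII, III↔X, fixes VI and VII, and leaves every
category count unchanged. The numeral-to-pattern assignment follows the
conventional twelve-bin scheme for hybrid expression; all category-level
semantics are independent of that labelling.

A gene enters classification only if significant in at least one of the
three *pairwise* contrasts (parents, hybrid vs either parent) — genes
flat everywhere are conserved, not "other". Category proportions are
reported over the non-additive total (high + low + over + under), the
convention used when comparing dominance spectra across crosses.

## Over-representation analysis

Study list vs universe overlap per gene set:
$p = P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, upper tail
including the observed $k$. The universe is the *tested* population —
genes passing the FPKM filter — not the whole genome; using the genome
would overstate enrichment of anything liver-expressed. Set memberships
are restricted to the universe first; sets left empty are skipped
entirely so they cannot dilute the BH correction, which runs across the
tested sets only. Pathway membership arrives as a user-supplied GMT
file; a small synthetic six-set collection ships for demonstrations and
tests, with its planted structure documented in its description fields.

## 2^−ΔΔCt quantification

Technical replicates are averaged on the Ct scale (before any
differencing — the standard practice when a run is performed in
triplicate), then per sample ΔCt = Ct(target) − Ct(reference), ΔΔCt
subtracts the calibrator-group mean ΔCt, and the fold change is
2^−ΔΔCt with amplification efficiency fixed at 2. Two structural
consequences double as tests: a constant shift applied to every well
cancels exactly, and the calibrator group's geometric-mean fold change
is exactly 1. The calibrator group is a required argument — no default
is assumed because published figures often leave it implicit.

## The simulator

`generate_counts()` plants genes in six modes with noiseless group-mean
patterns that satisfy each category's defining inequalities exactly
(checked symbolically in the suite), then draws NB counts with variance
$\mu + \alpha\mu^2$. Defaults are the study conditions the package is
exercised under: six replicates per group (the motivating liver design
used 6/6/6/5, which the analysis drivers reproduce), parental log2
difference 2 for non-conserved genes, dominance shift 1.5, dispersion
0.05 — a conventional bulk RNA-seq value, chosen once because the
motivating study reports no within-group variance estimates — and a
baseline of 100 expected counts at library size 10⁶, giving mean FPKM
well above the filter so the planted structure, not the filter, drives
results. 1000 conserved plus 100 genes per non-conserved mode keep the
discovery problem realistic (a two-thirds-null genome) while every
analysis stage finishes in seconds. Which parent is the higher expressor
is randomised per gene, so subtype symmetry is exercised. Reciprocal
hybrids are i.i.d. around identical means by default — parent-of-origin
asymmetry is an observable outcome in real crosses, not a mechanism this
simulator models — with `cross_shift_log2` available to inject an F1B
shift when asymmetric calls need testing.

Phenotypes are Gaussian around per-group means, truncated at zero (the
observed layer-line AFP of 0 % ± 0 % makes truncation non-optional); the
default means, SDs and group sizes are the observed female and male AFP
summaries.

What the simulator does **not** emulate — and therefore what passing
tests do not establish about real data: GC/length bias, sample-specific
library-preparation effects, correlated genes, sex-chromosome dosage,
outlier replicates, and dispersion varying with mean. Recovery rates
quoted anywhere in this package are statements about this generative
model at its stated effect sizes.

## Numerical choices and degenerate inputs

* Counts must be integers; fractional values are rejected, never
  rounded — an FPKM table fed in as "counts" fails loudly.
* Dispersion floor $10^{-8}$; zero within-group variance lands on the
  floor rather than producing a zero SE.
* Pseudo-mean $c=0.5$ in the log-ratio; a gene at zero in both groups
  gets log2FC 0, SE 0, and is reported at p = 1 (Wald statistic defined
  as 0 when the SE vanishes).
* BH inputs outside [0, 1] are errors, not clamped.
* All-zero count matrices, empty post-filter gene sets, and configs with
  every stage disabled all return well-formed empty results rather than
  failing.

## Problem sizes

The suite's simulation-backed checks use 1500-gene designs (1000
conserved + 5 × 100 planted) for recovery, 5000 null genes for Wald
calibration, and 10⁵ Monte-Carlo replicates for heterosis-t calibration;
the whole suite runs in well under a minute on a laptop, and the numbers
above give binomial standard errors comfortably inside every asserted
band.

## Known limitations

* The NB test's mild anti-conservatism at n = 6 (above) is inherent to
  unshrunk moment dispersion; the classifier consumes its calls at a
  fixed α and inherits that calibration.
* DEG counts from this engine on real data will not match counts
  produced by shrinkage-based packages; cross-study comparisons should
  be made at the category level, which is the level this package treats
  as its contract.
* No imprinting inference: F1A/F1B differences are reported, not
  modelled.
* No efficiency-corrected (Pfaffl) qPCR variant; efficiency is fixed
  at 2.
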