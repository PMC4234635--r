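---
title: "Methods: two-library digital gene expression analysis with tagdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library digital gene expression analysis with tagdge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The problem

Early transcriptome studies of non-model organisms — a cotton fiber
line against its parent, a treated tissue against a control — often
sequence exactly one deep tag library per condition. With no biological
replicates there is no within-condition variance to estimate, so the
only tractable noise model is the sampling noise of sequencing itself:
each gene's tag count is treated as Poisson. `tagdge` implements the
full downstream pipeline for this design: expression quantification,
an exact two-library test, multiple-testing control, term enrichment,
and qRT-PCR validation arithmetic.

## Quantification

RPKM (reads per kilobase of transcript model per million mapped reads)
corrects a raw count \(C\) for gene length \(L\) (bp) and sequencing
depth \(N\):
\[
\mathrm{RPKM} = \frac{10^9\, C}{N \cdot L}.
\]
It is zero exactly when the count is zero, and invariant to scaling a
count and its library depth together.

The report statistic is \(\log_2(\mathrm{RPKM}_B / \mathrm{RPKM}_A)\).
With the default pseudocount of 0, a zero on one side produces a signed
infinity sentinel rather than a fabricated finite ratio: infinite ratios
honestly satisfy any threshold, and a `pseudo` argument is available
when finite values are required for plotting or reporting. We chose the
sentinel as the default because any floor value silently encodes an
arbitrary detection limit; published tables sometimes print large finite
ratios (about 12–13) for genes undetected in one library, implying such
an undocumented floor, and we prefer to expose the choice. Report
columns are rounded half-away-from-zero (`round_half_out()`), the
convention that matches how one-decimal ratio columns are printed in
this literature (base R's `round()` rounds half to even).

## The exact test

Let \(x\) and \(y\) be a gene's counts in libraries with totals
\(N_1\) and \(N_2\), each Poisson. Conditioning on \(x\), if the gene is
expressed at the same per-tag rate in both libraries, \(y\) follows
\[
p(y \mid x) \;=\; \Big(\tfrac{N_2}{N_1}\Big)^{y}
  \frac{(x+y)!}{x!\,y!\,\big(1 + N_2/N_1\big)^{x+y+1}},
\]
a negative-binomial law with mean \((x+1)N_2/N_1\) whose mixing over the
gamma posterior of the shared rate is exact (Audic & Claverie 1997,
Genome Research 7:986). `ac_probability()` evaluates it through
`lgamma`, so counts of any realistic magnitude are handled without
overflow, and \(\sum_y p(y\mid x) = 1\) to machine precision.

`ac_pvalue()` returns the two-sided p-value as the doubled smaller tail,
capped at one, with the observed \(y\) included in both tails:
\[
p = \min\big\{1,\; 2\min\big(P(Y \le y \mid x),\, P(Y \ge y \mid x)\big)\big\}.
\]
Two-sidedness reflects the null of *equal* expression with no preferred
direction; including the observed point keeps the test valid
(conservative) in the discrete setting. Numerically, whichever tail lies
below the conditional mean is accumulated directly from log-space terms
(the upper tail in geometric-decay chunks until the remainder is below
\(10^{-17}\) of the running sum), and the other tail is taken by
complement; the small tail therefore keeps full relative precision down
to the double-precision underflow limit (~\(10^{-308}\)), below which
the p-value is reported as 0.

One subtlety is worth stating plainly: the conditional *pmf* is
exchangeable in \(x\) and \(y\) at equal totals, but the tail-based
two-sided p-value is not exactly so — conditioning on \(x\) places the
two libraries in asymmetric roles, and the orientation difference is of
the order of one pmf term (noticeable at single-digit counts, negligible
at the depths this pipeline targets). This is an inherent property of
the conditional construction, not an implementation artifact; the test
suite asserts the exchangeability that does hold (the pmf), and that
confidently called genes keep their (direction-flipped) calls when the
libraries are swapped.

### Multiple testing and the DEG rule

`bh_fdr()` applies Benjamini–Hochberg step-up adjustment (via
`stats::p.adjust`): the standard choice for genome-scale count tests
when the FDR procedure itself is not the object of study. `call_degs()`
then labels a gene **up** when \(\mathrm{FDR} \le 0.001\) and
\(\log_2\) ratio \(\ge 1\), **down** symmetrically, otherwise **ns**.
Defaults: `fdr_max = 0.001` (dimensionless) and `min_abs_log2 = 1`
(i.e. a two-fold change), the conventional gates for this design.

Genes with zero counts in both libraries carry no information and are
excluded from the multiple-testing family (reported with
\(p = \mathrm{FDR} = 1\), status **ns**); leaving them in would inflate
the BH denominator arbitrarily with untestable rows. The number of
genes actually tested is attached to the output and echoed in the run
manifest, because "how many genes entered the test" is precisely the
kind of denominator that is otherwise irrecoverable from published
reports.

## Term enrichment

`hypergeom_upper_tail()` computes
\(P(X \ge m) = \sum_{i=m}^{\min(n,M)} \binom{M}{i}\binom{N-M}{n-i}
/ \binom{N}{n}\)
from log binomial coefficients combined by log-sum-exp. The tail
*includes* the observed \(m\): the alternative \(P(X > m)\) fails to
reproduce published enrichment cells, so inclusion is pinned by tests.

`enrich_terms()` builds the universe \(N\) independently per namespace —
the genes with at least one GO (resp. KEGG) assignment — because the
two annotation sources cover different gene sets and a shared universe
would distort both. Terms with \(m = 0\) are reported with \(p = 1\)
rather than dropped, keeping output exhaustive; q-values are BH across
the namespace's terms. GO terms are gated on the raw p-value
(`p_max = 0.05`), KEGG pathways on the q-value (`q_max = 0.05`),
mirroring the two gates conventional in this literature; both gates are
arguments, and both p and q are always reported so readers can apply
either. The output is ranked by ascending p-value with ties broken by
term id — a deterministic order for a ranked list (gene tables, by
contrast, always preserve input order).

No GO-graph propagation is performed: a gene contributes only to the
terms it is directly assigned. Enrichment against a parent-closed
annotation requires pre-propagated assignments.

## qRT-PCR

`relative_expression()` implements Livak's \(2^{-\Delta\Delta Ct}\):
\(\Delta Ct\) is the target's mean Ct minus the internal control's mean
Ct within a sample, \(\Delta\Delta Ct\) subtracts the calibrator
sample's \(\Delta Ct\), and the fold change is \(2^{-\Delta\Delta Ct}\).
Technical replicates are averaged as arithmetic means of Ct (the Livak
convention; equivalently a geometric mean of efficiencies), with the
replicate SD carried as a side column. The calibrator is a required,
explicit argument — it self-normalises to fold 1, and folds are
invariant to any constant Ct shift. No amplification-efficiency
correction (Pfaffl) is applied; Ct values must lie in (0, 60) cycles.

## The synthetic-data generator

`simulate_pair()` emulates the structure the exact test assumes:

- baseline relative abundances drawn from a gamma distribution
  (`expression_shape = 0.6` by default, giving the strong right skew of
  real transcript abundances; `Inf` collapses to equal expression, the
  cleanest null), normalised to one;
- library depths `total_a = total_b = 1e6` tags by default — real
  two-library studies run to tens of millions of tags over ~70k genes;
  1e6 tags over 5000 genes preserves the per-gene depth regime
  (mean count ~200) at a scale where thousands of simulations are cheap;
- a `de_fraction = 0.05` subset of genes planted at
  `log2_fc_magnitude = 2` (sign random, applied in library B), drawn
  from genes whose baseline expected count clears `de_min_mean = 50` so
  that planted effects are detectable rather than lost in shot noise;
- counts Poisson (`overdispersion = 0`); a negative-binomial knob
  exists to probe robustness, but the default tests the test under its
  own model;
- gene lengths uniform on `length_range_bp = c(200, 3000)`, used by
  RPKM but, under the default tag-count model, not by the count means
  (`length_weighted = TRUE` switches to a read-count model where longer
  genes draw more reads).

`simulate_terms()` adds `n_terms = 50` annotation terms (alternating GO
and KEGG namespaces, sizes uniform on 10–100 genes): background terms
sample genes uniformly; each of `planted_terms = 2` terms samples
members with `planted_odds = 10`:1 preference for DE genes, so at the
default 5% DE fraction a planted term is roughly one-third DE in
expectation against a 5% background.

One integer seed drives everything (the term generator uses its own
stream derived from the same seed), and the global RNG state is saved
and restored, so simulations are bit-reproducible and do not perturb a
caller's session.

What the generator deliberately does **not** emulate: biological
replicate variability (there are no replicates in this design),
overdispersion beyond the optional knob, mapping ambiguity and
multi-mapping tags, assembly artifacts (chimeric or fragmented gene
models), length-dependent biases, and correlated annotation structure
(real GO terms nest hierarchically; simulated terms are independent
draws). Tests that pass on these simulations therefore certify the
statistics under the stated Poisson model — not robustness to
everything real libraries contain.

## Validation strategy and problem sizes

The test suite checks, among others:

- tail computations against brute-force plain-arithmetic summation
  (all \(x + y \le 30\), three depth ratios, relative error
  \(10^{-10}\)), and pmf normalisation to \(10^{-12}\);
- the hypergeometric tail against direct rational summation
  (\(N \le 200\)) and against `stats::phyper` on random contingencies;
- BH adjustment against an independent hand implementation;
- type-I calibration: 20 null simulations of 10,000 equal-expression
  genes at \(10^6\) tags per library — the pooled fraction of p-values
  below 0.05 must sit within 0.05 ± 0.007, and no gene may pass
  FDR ≤ 0.001 in at least 19 of the 20 runs (equal expected expression
  is used here because gamma-skewed abundances push many genes into the
  low-count regime where the discrete test is legitimately conservative,
  which is a property of the test, not a calibration failure);
- recovery: ten simulations at the default configuration (5000 genes,
  5% DE at |log2 FC| = 2) must average ≥ 0.9 sensitivity with observed
  FDR ≤ 0.05 among calls, and ≥ 90% of planted terms must reach
  q ≤ 0.05;
- published-cell reproduction: four enrichment p-values recomputed from
  their printed contingencies to three significant figures, and
  one-decimal log2 RPKM ratio columns recovered from their printed RPKM
  pairs.

These sizes keep the whole suite within a few minutes on one CPU while
leaving Monte-Carlo margins comfortably wider than the asserted bands.

## Known limitations

- The Poisson model understates biological variability; with replicates
  available, a dispersion-aware framework (edgeR, DESeq2) is the right
  tool, and this pipeline is deliberately not that.
- The exact test's two-sided p-value is conservative at very low counts
  (discreteness) and orientation-dependent at the one-pmf-term level.
- Enrichment treats terms independently; nested GO terms will co-fire.
- TSV is the only I/O dialect, by design: strict, diffable, round-trip
  exact.
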