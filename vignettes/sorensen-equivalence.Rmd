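---
title: "Equivalence testing between feature lists: model, calibration and design choices"
author: "sorequiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalence testing between feature lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorequiv)
```

## The statistical model

Fix a set of $n$ terms (for example all Gene Ontology terms at a given
level, or any other pre-selected collection of gene sets) and an
enrichment criterion that declares each term enriched or not in a given
feature list. For two lists the per-term enrichment statuses
cross-tabulate into counts $(n_{11}, n_{10}, n_{01}, n_{00})$ — both /
first only / second only / neither — modelled as one draw from a
multinomial with probabilities $p = (p_{11}, p_{10}, p_{01}, p_{00})$.
The dissimilarity between the lists is the Sorensen–Dice index written
as a dissimilarity,

$$d_S(p) = 1 - \frac{2 p_{11}}{2 p_{11} + p_{10} + p_{01}},$$

estimated by the plug-in $\hat d_S = d_S(\hat p)$ with
$\hat p_{ij} = n_{ij}/n$. The double negatives $p_{00}$ never enter:
terms enriched in neither list can be inflated arbitrarily by taking a
larger or deeper term universe, and counting them would let the analyst
make any two lists look similar.

By the delta method, $\sqrt{n}(\hat d_S - d_S)$ is asymptotically
normal with variance

$$\sigma_S^2 = \frac{4 p_{11} (p_{01}+p_{10}) (p_{11}+p_{01}+p_{10})}
{(2 p_{11}+p_{01}+p_{10})^4},$$

implemented in `sorensen_variance()` and verified in the test suite
against a finite-difference gradient composed with the trinomial
covariance of $(\hat p_{11}, \hat p_{01}, \hat p_{10})$, and against
the empirical variance of the estimator under multinomial sampling.

## The equivalence test

The hypotheses are

$$H_0: d_S \ge d_0 \qquad vs \qquad H_1: d_S < d_0,$$

so that *rejection* is the informative outcome: it certifies that the
dissimilarity is below the irrelevance limit $d_0$. By the interval
inclusion principle the test rejects when the one-sided $(1-\alpha)$
interval $[0, d_u]$, $d_u = \hat d_S + z_{1-\alpha}\,\hat\sigma_S/\sqrt n$,
lies inside the equivalence region, i.e. $d_u < d_0$; equivalently when

$$p(d_0) = \Phi\!\left(\frac{\sqrt n (\hat d_S - d_0)}{\hat\sigma_S}\right)
\le \alpha.$$

Both routes are derived from the same studentized statistic, so they
agree everywhere except on the measure-zero boundary $p(d_0) = \alpha$;
the implementation defines the decision as $p \le \alpha$ and the suite
property-checks route agreement over thousands of random tables. A note
on quantile conventions: with $z_q$ denoting lower quantiles the upper
limit reads $d_u = \hat d_S - z_{\alpha}\hat\sigma_S/\sqrt n$; the code
uses positive critical values and a plus sign, and a test asserts the
two readings are numerically identical.

Confidence limits are reported *unclipped* — $d_u$ may exceed 1 and a
two-sided lower limit may be negative — because the decision compares
$d_u$ with $d_0$ on the real line and clipping would silently change
borderline decisions under reparametrization. `sorensen_ci(clip = TRUE)`
gives a display-friendly clipped version.

### Choosing the limit $d_0$

$d_0$ is irreducibly an analysis choice; the package refuses to default
it. A defensible route is a lower bound $\rho_0$ on the concordance
ratio $\rho = 2p_{11}/(p_{01}+p_{10})$, giving $d_0 = 1/(1+\rho_0)$
(`convention = "double"`; the Sorensen–Dice index counts the overlap
twice) or, with $\rho = p_{11}/(p_{01}+p_{10})$, the stricter
$d_0 = 1/(1+2\rho_0)$ (`convention = "single"`). The reference ratios
$10/8$ and $10/9$, borrowed from the bioavailability limits of
bioequivalence practice, translate to $0.4444$ and $0.4737$, or
$0.2857$ and $0.3103$ under the single-counting convention
(`d0_from_rho()`, `rho_from_d0()`).

### Degenerate tables

When $n_{11} = 0$ (so $\hat d_S = 1$) or $n_{10} + n_{01} = 0$ (so
$\hat d_S = 0$) the variance estimate is exactly zero and the
studentized statistic does not exist; when all three are zero not even
$\hat d_S$ exists. These cases are signalled with a dedicated condition
class (`sorequiv_undefined_statistic`, testable with
`is_undefined_statistic()`) rather than returning `NaN`, so that the
bootstrap and simulation layers can *count* them: they discard such
replicates and report effective replicate numbers. This is the right
accounting because the events are informative about sparsity, not
ignorable numerical noise.

## The studentized bootstrap

The normal approximation converges slowly when the expected number of
enriched terms $E(\nu) = n(p_{11}+p_{01}+p_{10})$ is small; the true
law of the studentized statistic then has a heavier left tail than
$N(0,1)$, which inflates the type-I error of the asymptotic test. The
bootstrap flavour resamples $B$ tables from
$\mathrm{Multinomial}(n, \hat p)$, forms
$t^*_b = \sqrt n\,(d_S(\hat p^*_b) - d_S(\hat p))/\hat\sigma^*_{S,b}$,
and substitutes the empirical distribution of $t^*$ for $\Phi$ in the
p-value and for the normal quantile in $d_u$.

Two design points deserve record:

* **Resampling scale.** Resampling is done at the full table size $n$
  with scale $\sqrt n$, making the bootstrap statistic the exact
  plug-in analogue of the original one. An equivalent two-stage
  scheme — draw $\nu^* \sim \mathrm{Binomial}(n, \hat p_{11}+\hat
  p_{01}+\hat p_{10})$, then the enriched cells conditionally
  multinomial — factorizes the same multinomial law; the suite checks
  the distributional identity of the two generators by goodness-of-fit.
* **Quantile convention.** The empirical $\alpha$-quantile used for the
  bootstrap $d_u$ is the order statistic of rank
  $\lfloor \alpha (B_{\mathrm{eff}}+1) \rfloor$, which is the exact
  inverse of the conservative bootstrap p-value
  $(\#\{t^* \le t_{\mathrm{obs}}\}+1)/(B_{\mathrm{eff}}+1)$. An
  interpolated quantile would be marginally smoother but cannot
  guarantee that the p-value and interval-inclusion routes always give
  the same decision; exact route consistency was judged more valuable
  than interpolation and is property-tested.

All $B$ replicates are drawn in one vectorized pass from a single
seeded generator, so discarding undefined replicates does not perturb
the stream of the remaining ones, and results are bit-reproducible
under a fixed seed. Resampling the underlying gene lists themselves
(rather than the table) would capture the enrichment-testing stage too,
but is orders of magnitude slower and is not offered.

## Several lists

`pairwise_equiv_tests()` runs the test over all $h = s(s-1)/2$ pairs
(or $s-1$ versus-reference comparisons) and adjusts the p-values by
Holm's step-down (via `stats::p.adjust`), the standard choice when $h$
is at most a few tens; BH/FDR is available behind a flag for large
families, and `"none"` disables adjustment. Pairs with undefined
statistics are excluded from the family size $h$ and reported as
not-testable — counting never-rejectable comparisons toward $h$ would
only dilute the correction, but the exclusion is a package choice and
is flagged in the output so users can see the effective family.

For comparing two testing approaches over the same list collection, the
natural objects are the triangular matrices of their one-sided upper
confidence limits; `mantel_cor()` computes the Pearson correlation of
the vectorized lower triangles with a label-permutation p-value
(two-sided, $(\#\{|r^{perm}| \ge |r^{obs}|\}+1)/(P+1)$, or exact
enumeration of all $s!$ relabelings for small $s$).

## The ORA front-end

`ora_test()` implements one-sided hypergeometric over-representation:
$P(X \ge a)$ with $a$ list genes in the term, $K$ universe genes in the
term, list size $m$, universe size $N$ — identical to one-sided
Fisher's exact test on the 2×2 membership table (a unit test asserts
the identity, and an exhaustive-enumeration oracle pins the tail
probabilities on small universes). Defaults are Bonferroni adjustment
at cutoff 0.05 across the collection's terms. Production enrichment
pipelines add gene-set size filters, q-value estimation and
ontology-aware pruning; those are deliberately out of scope — the
universe and the term collection are explicit caller inputs (GMT file
plus gene-universe file, or the union-of-annotation convenience), and
the package never queries an ontology graph. Consequently, enrichment
profiles computed here from public collections need not coincide
term-for-term with those of annotation-versioned pipelines; the
equivalence machinery downstream is agnostic to how the profile was
obtained.

## The simulation engine and what it can show

`simulation_scenario()` fixes a generating law and test settings;
`run_scenario()` estimates the rejection probability (type-I error at
the boundary $d_S = d_0$, power below it) and one-sided coverage, with
binomial Monte-Carlo standard errors and effective-replicate
accounting; `run_grid()` crosses levels into reproducible sweeps, with
per-scenario child seeds derived deterministically from one master seed
so results are independent of evaluation order. Scenario placement uses
the boundary solver $p_{11} = (1-d_S)(p_{10}+p_{01})/(2 d_S)$
(`p11_for_target()`).

Problem sizes used by the shipped tests are chosen to keep the whole
suite in the minutes range while leaving Monte-Carlo error well below
the effects being checked: $10^5$ replicates for normal-test type-I
error (standard error $\approx 7\times10^{-4}$), $2\times10^3$
simulations of $2\times10^3$ bootstrap replicates for the bootstrap
type-I error (standard error $\approx 5\times10^{-3}$), and $2\times
10^4$ replicates for trend and coverage checks. Reference studies of
this design are typically run at $10^6$ replicates; nothing but
patience changes at that scale. The family-wise error simulation for
the Holm layer uses six independent boundary tables per replicate
(there is no canonical joint-profile model for correlated pairs) in a
high-enrichment regime ($n = 10^4$, $p = (0.5, 0.2, 0.2)$) — this
isolates the multiplicity layer's FWER control from the known
small-sample inflation of the marginal normal test, which is measured
separately.

The synthetic-list generator `synth_gene_lists()` plants a known
enrichment pattern: disjoint gene sets of equal size, lists built from
a strong fraction (default 0.9) of each planted term's genes plus
uniform background genes (defaults: 2000-gene universe, 20 terms of 40
genes, 100 background genes per list). Its purpose is end-to-end
ground-truth testing of the ORA front-end. What it does *not* emulate:
overlapping and nested gene sets, correlated enrichment across terms,
annotation bias, or realistic list-size distributions — so passing
recovery tests demonstrates the pipeline's correctness, not its
robustness on real annotation structure.

## Known limitations

* Both inferential routes are intrinsically asymptotic in the number of
  *enriched* terms. With very sparse enrichment the normal test is
  anti-conservative and the bootstrap conservative; when most generated
  or observed tables are degenerate, no reliable decision is possible
  and the package says so through effective-replicate counts and typed
  errors rather than numbers.
* The enrichment statuses of different terms are modelled as one
  multinomial draw over terms, ignoring between-term dependence induced
  by the ontology structure and shared genes; the same simplification
  underlies the delta-method variance.
* Only the Sorensen–Dice dissimilarity is exposed, though the variance
  machinery is written against the generic three-probability statistic
  and other indices ignoring double negatives could be added.
* The decision threshold $d_0$ cannot be estimated from data; the
  package only converts between $d_0$ and the concordance-ratio scale.
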