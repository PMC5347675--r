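---
title: "Disproportionality analysis of spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prrsignal)
```

## The problem

Spontaneous adverse-event databases such as FAERS collect reports without a
denominator: the number of patients actually exposed to a drug is unknown,
so raw event counts cannot be compared between drugs. Disproportionality
analysis sidesteps the missing denominator by comparing *reporting
proportions*. prrsignal implements this for the classic two-drug design —
here, the two approved alopecia treatments, oral finasteride and topical
minoxidil — stratified by sex, since the two drugs have strongly
sex-dependent use and physiology.

## Cohort construction

A case cohort is defined by four filters applied to a parsed report stream:

* **Sex.** Reports whose sex code is not the male or female code (including
  absent and zero) are `unknown` and never enter a cohort; the male and
  female cohorts and the excluded unknown-sex reports partition the
  drug-matching reports.
* **Receipt date.** Half-open window `[2004-01-01, 2014-07-01)` by default,
  i.e. January 2004 through June 2014.
* **Drug and indication.** A report qualifies only if *the matching drug's
  own entry* carries a qualifying indication term. This mirrors the per-drug
  `drugindication` field of openFDA records; an alopecia indication attached
  to a co-medication does not qualify. The default indication list is the
  eight alopecia MedDRA preferred terms returned by
  `default_alopecia_terms()`. Drug matching is case-insensitive exact
  matching against the generic name plus an optional synonym list.
* **Exclusions.** For a pairwise drug comparison, reports listing both drugs
  are excluded from both cohorts (`exclude_drugs`), keeping the arms
  disjoint; combined-exposure reports are too few to analyze on their own.

Whether a real openFDA query matches indications per drug entry or per
report is not externally documented; the per-drug rule is this package's
design choice, stated here rather than asserted as anyone else's.

## The PRR model

With `A1` of `A0` exposure-drug cases and `B1` of `B0` comparator cases
reporting event X,

$$\mathrm{PRR}_X = \frac{A_1/A_0}{B_1/B_0}, \qquad
\mathrm{CI}_{95\%} = \exp\!\Big(\ln \mathrm{PRR}_X \pm 1.96
\sqrt{\tfrac{1}{A_1}+\tfrac{1}{B_1}-\tfrac{1}{A_0}-\tfrac{1}{B_0}}\Big).$$

The PRR resembles a risk ratio in distribution and interpretation, but it is
a ratio of *reporting* rates: confounding by age, comorbidity, reporting
fashion and channel is untouched, so a significant PRR is a signal for
follow-up, not an incidence estimate.

**Zero cells.** No continuity correction is applied. `B1 = 0` makes the
ratio undefined (`NA`, rendered "N/A"); `A1 = 0` with `B1 > 0` gives exactly
0 (rendered "0.00"); in both cases the interval is suppressed. These
sentinels match how published comparison tables print such rows.

**Significance.** The two-tailed Fisher exact test is computed on the 2×2
whose cells are the table as printed — `(A1, A0)` against `(B1, B0)`,
affected versus *total* cases. This is deliberately the layout the published
tables use (their p-values reproduce to the printed digit under it, and not
under the affected/unaffected layout); it is conservative, since the total
column double-counts the affected cases in the margins. The two-tailed rule
sums all tables with the observed margins whose probability is at most the
observed table's, within relative tolerance 1e-7 to guard floating-point
ties. Stars follow 0.05 / 0.01 / 0.001.

**Rendering.** PRR and CI bounds are rounded to two decimals half-up;
proportions print as percentages; p-values below 0.01 print in scientific
notation with three significant digits and values below 1e-300 print as
"0" (the Fisher p of a multi-million-count gender table genuinely
underflows double precision; the rendered "0" makes that explicit).
Full-precision values are always kept in the returned tibbles; rounding is
display-only. Two published CI bounds differ from the formula in the last
digit (chorioretinopathy upper 0.08 vs 0.0872 computed; induced-abortion
upper 39.53 vs 39.554 computed); the formula is implemented as stated and
those cells are not asserted anywhere.

**Default event list.** `compare_drugs()` defaults to the union of both
cohorts' top-10 events. Ties in the top-10 cut are broken lexicographically
— a stated, reproducible rule. Published tables whose own tie order was
editorial may therefore differ at the margin of the cut; an explicit
`events` vector reproduces any fixed row set.

## The synthetic generator

`synthetic_cohort_spec()` fixes the study conditions under which the
pipeline is validated: two arms of 2000 reports (the scale at which the
delta-method interval is trusted), sex drawn Bernoulli with the latent sex
driving event probabilities and a 2% missing-sex mask on top, a 5%
off-label indication rate, independent per-event inclusion, and a small
background reaction pool (5% per term) with a uniform background rescue for
reports that would otherwise have no reaction, since real reports always
carry at least one. The default differential events encode a true
reporting-probability ratio of 8 (0.40 vs 0.05 in the male stratum; 0.16 vs
0.02 in the female stratum), matching the recovery tests, which check that
the 95% CI covers the truth in 95% ± 3 percentage points of 500 seeded
replicates.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: duplicate and follow-up reports sharing a
case, correlated reaction terms, secular reporting trends, stimulated
reporting after label changes, and channel effects. The generator validates
the *computation*, not the epidemiology.

`fixture_from_counts()` is the deterministic counterpart: it rebuilds report
collections whose marginal counts equal a printed table exactly, by
assigning each event to the earliest report ids (so events co-occur on the
lowest ids and every margin round-trips). Filler reactions for otherwise
empty reports are unique per report so they can never enter a ranking.

## Drug–gene network

`build_network()` recruits first neighbors of the directly associated genes
(FAGs) from a PPI edge list; only edges incident to a FAG are kept, so
IAG–IAG edges are dropped. This first-neighbor-without-closure rule is what
produces the near-tree topology (a 260-node network with 262 edges) such
drug-centered networks show. The topological coefficient uses the Cytoscape
convention: for node $n$ with degree $k_n$,
$TC(n) = \mathrm{avg}_m J(n,m) / k_n$ over all $m \neq n$ sharing at least
one neighbor with $n$, where $J(n,m)$ counts shared neighbors plus 1 if $n$
and $m$ are adjacent; nodes with no qualifying partner have no defined
value and are dropped from degree profiles. Betweenness is shortest-path
betweenness normalized by $2/((N-1)(N-2))$; graphs with fewer than three
nodes return zeros rather than NaN.

`fit_power_law()` fits $y = a x^b$ by ordinary least squares on
$(\ln x, \ln y)$, with $R^2$ on that fitted scale; zero-valued profile
points are excluded before fitting (a per-degree mean of 0 carries no
information on the log scale), and constant-$y$ input defines $R^2 = 1$
(a zero-slope model with zero residuals, avoiding 0/0). The published
$R^2$ values (0.99 and 0.84) and the exact 260/262 network size depend on
unprinted database snapshots and are out of scope; the implementation is
validated against hand-evaluated graphs, a brute-force shortest-path
oracle on random graphs up to 12 nodes, and exact recovery on noiseless
power-law input.

## Gene-set enrichment

`enrich()` performs the hypergeometric over-representation test
$P(X \ge k)$ for an overlap of $k$ query genes with a $K$-gene category in
an $N$-gene universe at query size $n$, with Benjamini–Hochberg adjustment
across the tested categories. Design choices:

* The default universe is the union of all genes annotated in the loaded
  collection (the reference-set behavior of common enrichment servers when
  no universe is given); a universe can be supplied explicitly and set
  members outside it are dropped.
* Categories with zero overlap are not tested and do not appear in the
  output (nor in the BH family).
* Published tables label their effect size "OR of enrichment" without
  defining it; the package emits both candidates — the enrichment ratio
  $R = k/(nK/N)$ (observed over expected overlap) in the
  `enrichment_ratio` column, and the sample odds ratio of the underlying
  2×2 in `odds_ratio` — asserting neither as anyone's original choice.
  Published ORs/p-values for specific categories depend on unprinted
  annotation releases and universe sizes and are not reproduction targets;
  the machinery is validated against exhaustive enumeration for universes
  up to 30 genes.

## Numerical and degenerate-input policy

* Contingency counts are validated (`0 ≤ A1 ≤ A0`, `A0 > 0`); violations
  are errors, not NA propagation.
* The CI radicand cannot be negative under valid counts; a negative value
  raises a defensive error rather than NaN.
* An empty cohort is a valid query result; comparing against one is an
  error (no denominator).
* All randomness flows through a single integer seed per spec;
  `generate_reports()` restores the session RNG state.

## Problem sizes used in validation

The shipped suite validates Fisher p-values by full enumeration over all
tables with cohort totals summing to 24, hypergeometric tails by full
enumeration up to a 30-gene universe, betweenness on 50 random graphs of up
to 12 nodes, and CI coverage over 500 synthetic replicates of 2000 reports
per arm — sizes chosen so each oracle is exhaustive or statistically
decisive at its scale.
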