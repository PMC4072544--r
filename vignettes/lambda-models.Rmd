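---
title: "Estimating the non-conservative substitution rate ratio lambda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the non-conservative substitution rate ratio lambda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ncrates)
library(dplyr)
```

## Why split dN?

The classical rate ratio $\omega = dN/dS$ treats every amino-acid change
the same. Biophysically they are not the same: a swap between similar
residues (Leu to Ile) usually leaves the fold alone, while a swap that
disrupts packing or charge is likely to destabilize the protein. `ncrates`
splits the nonsynonymous rate $dN$ into a conservative part $dC$ and a
non-conservative part $dNC$, and estimates

$$\lambda = \frac{dNC}{dC},$$

the relative rate at which likely-destabilizing substitutions accumulate
compared to benign ones. $\lambda$ is a selection readout orthogonal to
$\omega$: $\omega$ measures how much amino-acid change is tolerated at all,
$\lambda$ measures which *kind* of change is tolerated.

## The C/NC classification

Substitutions are classified at the amino-acid-pair level. Only pairs of
residues whose codons are direct single-nucleotide neighbors in the
standard genetic code are in the domain of the classification — these are
the 75 pairs that a single point mutation can produce, and they are the
only pairs the codon models act on; everything else raises an error rather
than being guessed.

The canonical classification (`table1_classification()`) labels a pair
non-conservative when mutations between the two residues are predicted to
be highly destabilizing ($\Delta\Delta G < -2$ kcal/mol) in at least 20% of
sampled sequence contexts, pooling predictions over both mutation
directions because a pairwise alignment does not reveal which ortholog
incurred the change. 60 pairs come out conservative and 15
non-conservative:

```{r}
cls <- table1_classification()
cls$nc_pairs
blosum62_positive_nc_count(cls)
```

The zero above is a useful sanity check: no pair called "likely
destabilizing" exchanges frequently in homologous proteins (positive
BLOSUM62 score).

Two boundary conventions matter and are fixed deliberately:

* a pair destabilizing in *exactly* the cutoff fraction of contexts is NC
  (conservative is defined strictly as "less than the cutoff");
* "highly destabilizing" is the strict inequality
  $\Delta\Delta G < -2$ kcal/mol.

`derive_classification()` rebuilds a classification from any per-mutation
$\Delta\Delta G$ table with these conventions; neighbor pairs without
records are returned in an `uncovered` list, never silently defaulted.
Raising the fraction cutoff can only move pairs from NC to C, which the
test suite checks as a monotonicity property.

## The maximum-likelihood model

The ML estimator is a reversible 61-state Markov model of codon
substitution in the Goldman–Yang tradition. For sense codons $i \ne j$,

$$
q_{ij} = \pi_j \times
\begin{cases}
0 & \text{more than one position differs} \\
1 & \text{synonymous transversion} \\
\kappa & \text{synonymous transition} \\
\gamma \,(\times\, \kappa) & \text{conservative nonsynonymous} \\
\gamma\lambda \,(\times\, \kappa) & \text{non-conservative nonsynonymous,}
\end{cases}
$$

with multipliers composing, so an NC transition has rate
$\pi_j\,\kappa\,\gamma\,\lambda$. This parameterisation was chosen because
it matches the intended meaning of every parameter — $\kappa$ a transition
multiplier, $\gamma$ the nonsynonymous (conservative) rate ratio, $\lambda$
the extra factor on destabilizing changes — and because fixing
$\lambda = 1$ collapses it exactly to the standard $\omega$-style model,
which `fit_standard_omega()` exploits: the two models are nested, so the
extended fit can never have a lower maximized likelihood.

Conventions:

* $Q$ is rescaled so that $-\sum_i \pi_i q_{ii} = 1$: one unit of $t$ is
  one expected substitution per codon, making $t$ comparable across pairs.
* The two sequences sit at total separation $t$ under reversibility
  (equivalently two branches of $t/2$ from an unobserved ancestor), giving
  the column likelihood $\pi_i\,p_{ij}(t)$ and
  $\ell = \sum_{ij} n_{ij} \log(\pi_i\,p_{ij}(t))$ over the codon pair
  counts $n_{ij}$. Because the chain is reversible, transposing $n$ leaves
  $\ell$ unchanged, so the order of the two input sequences is immaterial
  and $n$ is not symmetrized.
* $\pi$ defaults to F61-style frequencies pooled from the two sequences
  with a pseudocount of 0.5 per sense codon (`pi_mode = "from_pair"`);
  genome-wide codon tables can be supplied instead to mirror average genome
  composition.
* $P(t) = e^{Qt}$ is computed through the symmetrized eigendecomposition
  $D^{1/2} Q D^{-1/2}$ ($D = \mathrm{diag}(\pi)$), which is exact for
  reversible $Q$, fast enough to sit inside an optimizer, and keeps row
  sums at 1 to $10^{-10}$; entries are clipped at zero before entering
  logarithms.

Optimization is a derivative-free Nelder–Mead simplex on
$\log$-transformed parameters, the first start seeded from count-model
estimates and further starts displaced by fixed log-scale offsets (no RNG in
the optimizer, so fits are reproducible). Ties across starts are broken by
highest $\ell$, then smallest $t$. Estimates pinned at the internal bounds
($t < 10^{-6}$, multipliers outside $[10^{-4}, 10^{4}]$) are flagged in
`notes` rather than silently returned — identical input sequences, for
example, drive $t$ to its lower bound.

## The count model

`estimate_rates_count()` is an independent estimator in the Nei–Gojobori
tradition, extended to four classes:

1. **Sites.** For each codon position, among the single-nucleotide mutants
   that are sense codons, the synonymous fraction defines the synonymous
   site share; mutants creating stop codons are excluded from numerator
   and denominator alike, so $s + n = 3$ per codon exactly, and the
   nonsynonymous share is partitioned into C and NC by classifying each
   mutant pair ($c + nc = n$ exactly). Site counts of the two sequences
   are averaged.
2. **Differences.** Codons differing at $k$ positions are resolved by
   averaging the per-class step labels over all $k!$ mutational pathways;
   pathways that traverse a stop codon are discarded. In the degenerate
   case where *every* pathway is blocked, all pathways are retained and
   only their stop-free steps contribute (a documented fallback; the
   alternative of dropping such columns would silently lose signal).
3. **Correction.** Each class proportion is Jukes–Cantor corrected
   independently, $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$; a proportion
   at or beyond $3/4$ raises a saturation error naming the class.

Ratios $\omega = dN/dS$ and $\lambda = dNC/dC$ carry explicit
undefined-ratio flags when a denominator is zero, rather than NaNs of
unclear origin. Columns containing gaps, ambiguity codes or stop codons are
dropped codon-wise, never partially counted. The count model has no
transition/transversion parameter; under strong transition bias its site
partition is mildly miscalibrated relative to the ML model (one reason the
two estimators are kept as mutual cross-checks — their $\lambda$ estimates
correlate strongly on simulated panels, but the count value is the noisier
and slightly upward-shifted of the two).

## What the simulator does and does not emulate

`simulate_codon_pair()` draws ancestor codons i.i.d. from $\pi$ and
samples both descendant endpoints exactly from $P(t/2)$ (or one lineage
from $P(t)$ in `single_branch` mode — under reversibility the two designs
are distributionally identical, and a test checks this). Endpoint sampling
is exact, not an event-level (Gillespie) simulation; the pairwise
likelihood only ever sees endpoints, so nothing is lost. Default $\pi$ is
uniform over the 61 sense codons.

The simulator deliberately omits: indels (alignments are gap-free),
among-site rate variation, codon-usage bias unless supplied through $\pi$,
and any proteome-scale structure. Passing recovery tests on simulated data
therefore demonstrates the correctness of the estimators *under the model*,
not robustness to alignment error or heterotachy in real orthologs.

One subtlety worth spelling out: at $\lambda = 0$ the NC *instantaneous*
rate is exactly zero, yet at finite divergence a pair can still display an
NC amino-acid difference through two successive conservative hits in one
codon (GCT→GAT→GTT leaves Ala/Val endpoints via two conservative steps).
The probability is $O(t^2)$ per codon — negligible at the divergences used
here, but not identically zero.

`synthetic_ddg_table()` plants per-pair destabilizing fractions with a
deterministic count (`round(fraction * n_per_pair)`) placed strictly below
$-2$ with Gaussian jitter, so a planted classification is recovered
*exactly* at moderate per-pair sample sizes. `synthetic_network_pair()`
builds two Erdős–Rényi graphs over a shared orthologous core and plants
re-wired nodes by wiring them to species-specific partners in both
networks.

## Precision: what to expect from 500 codons

The study-scale simulations use 500-codon pairs at
$(t, \kappa, \gamma, \lambda) = (0.3, 2.0, 0.3, 0.5)$ — a divergence and
selection regime typical of closely related yeast orthologs — with 100
replicates per setting, sizes at which the full experiment runs in a few
minutes on one core.

At these settings roughly 150 substitution events separate a pair, of
which only ~7 are non-conservative ($\lambda$ suppresses them twice: via
$\gamma$ and via $\lambda$ itself). That scarcity sets a hard information
floor: the Fisher information for $\log\lambda$ is governed by the NC event
count, giving $\mathrm{sd}(\log\hat\lambda) \approx \sqrt{1/7 + 1/54}
\approx 0.4$ and hence a median relative error around 30% for *any*
estimator at this problem size. The ML estimator attains this floor and is
essentially median-unbiased (median $\hat\lambda \approx 0.48$ at true
0.5); $\hat t$ and $\hat\kappa$, informed by all events, land near 7% and
13% median relative error. Per-gene $\lambda$ values at moderate divergence
are therefore rankings and group-level signals, not precise per-gene
constants — which is also why the estimators flag low NC counts instead of
hiding them, and why a minimum-NC-substitution curation filter exists.

## Curation

`curate()` implements the pre-analysis filters with exact boundary
semantics:

* gap rule: fails only when *more than* 1/3 of alignment columns contain a
  gap in either sequence — exactly 1/3 passes. Gap columns are counted
  codon-wise over columns, not nucleotides.
* optional length rule: at least `min_codons` valid codon columns
  (80 is the conventional choice for distant ortholog sets);
* optional signal rule: at least `min_nc_subs` estimated NC substitutions
  (3 is the conventional choice), with the estimate supplied by the caller
  from either estimator.

`batch_estimate()` applies curation and both estimators across a manifest,
logging per-pair failures (curation, saturation, optimizer errors) as
skips with reasons instead of aborting a run.

## Network statistics

For cross-species comparisons of interaction networks the package computes
degree, exact unnormalized betweenness (via igraph's Brandes
implementation, cross-checked against exhaustive path enumeration in the
tests), and a per-node re-wiring score: the number of neighbors lacking an
ortholog in the other species. Hubs are the top decile of degree, non-hubs
the bottom decile; bottlenecks the top decile of betweenness *minus* the
hubs; the re-wired consensus is the intersection, through the ortholog
map, of both networks' top deciles of the re-wiring score, with
zero-score nodes never qualifying. Quantile ties are included on the
qualifying side, so selections are deterministic and invariant to node
relabeling; an all-equal score distribution is reported with a degeneracy
flag rather than an arbitrary subset. Betweenness is left unnormalized
because only within-network rank deciles are ever used. Alternative
stringencies (top/bottom 5%, 1%) are the `top_fraction`/`bottom_fraction`
arguments, not separate code paths.

Group contrasts use two-sided Wilcoxon rank-sum tests (Fisher's exact test
for 2×2 enrichments) plus the standardized mean difference — Cohen's $d$
with pooled, $n-1$ denominators — as the effect size; two identical
constant samples return $p = 1$ by convention.

## Known limitations

* The classification is a single genome-wide dichotomy; context-dependent
  stability effects (surface vs core, disordered vs folded regions) are
  averaged out, and classifications tuned to other species or compartments
  are out of scope (though `derive_classification()` accepts any ddG
  table).
* Pairwise only: no phylogenies beyond two taxa, no site-class mixtures,
  no empirical codon exchangeability matrices.
* The count model's multiple-hit correction is Jukes–Cantor per class;
  at high divergence ($p \to 3/4$) it saturates and errors out rather than
  extrapolating.
* $\lambda$ at realistic per-gene NC counts is noisy (see the precision
  section); treat per-gene values accordingly.
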