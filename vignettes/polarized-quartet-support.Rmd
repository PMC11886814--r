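---
title: "Polarized quartet support: model, filters, and design choices"
author: "polarquart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarized quartet support: model, filters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarquart)
```

## The problem

Deep divergences among predefined clades — for instance the four myriapod
subgroups against a panarthropod outgroup — are hard to resolve because
site patterns that look like shared derived states can instead be
convergences or retained ancestral states, and fast-evolving lineages
produce such misleading patterns disproportionately.  `polarquart`
addresses this with a divide-and-conquer analysis of *rooted quartets*:
every hypothesis about the clades is broken into quartets of one outgroup
sequence plus one sequence from each of three ingroup clades, where the
outgroup polarizes character change and Hennigian logic separates putative
apomorphies from plesiomorphies.

## The scoring model

For a species-quartet in role order $(O, x_1, x_2, x_3)$, only alignment
columns free of missing or ambiguous states for all four sequences are
used (so the site set varies slightly per quartet, and missing data never
force whole-alignment column deletion).  The three rooted topologies are
indexed by the basal ingroup taxon: topology $k$ is
$(O,(x_k,(x_i,x_j)))$.

**Observed support $N_a$.**  A column supports topology $k$ when the
derived pair $x_i, x_j$ shares a state that differs from the outgroup
state — the shared state is then potentially apomorphic.  Under the
default `relaxed` rule the shared state must also differ from $x_k$;
the `strict` rule instead requires the outgroup and $x_k$ to agree.
Columns whose shared pair state equals the outgroup state are
plesiomorphy-prone and never counted.  Each column supports at most one
topology.

**Expected convergence $N_c$.**  Support counts are corrected for the
number of supporting patterns expected to arise *by chance if the
topology is wrong*.  For each of the three topologies the quartet tree
(five branches) is fitted by maximum likelihood; for target topology $i$
the fitted models of the two alternatives $j \ne i$ give exact expected
counts $E_j = n \sum_{\text{patterns supporting } i} P_j(\text{pattern})$
via complete enumeration of all $4^4 = 256$ site patterns, and
$N_{c,i}$ is the mean of the two.  A topology is considered genuinely
supported only when $N_a > N_c$.

**Normalized support.**  The default score is the excess count
$S_k = \max(N_{a,k} - N_{c,k},\, 0)$ (`score = "ratio"` uses
$\max(1 - N_c/N_a, 0)$ instead), normalized as

$$R_k = \frac{S_k}{S_1 + S_2 + S_3},$$

so $R$ sums to one and $R_k = 0.8$ means 80% of the normalized signal
favours topology $k$.  When all $S_k = 0$ the quartet is flagged
`no_signal`, given uniform $R = (1/3, 1/3, 1/3)$, and can never pass the
filters.

### Likelihood machinery

The substitution model is a homogeneous reversible GTR (optionally with
four discrete gamma rate categories; `"GTR+G"` is the pipeline default,
`"JC"`/`"JC+G"` are available).  Branch lengths are free per branch;
model parameters are shared across branches — branch-heterogeneous
composition is out of scope.  The likelihood is computed by the pruning
algorithm with the root placed on the internal branch (valid for
reversible models), implemented in C++ over the 256-pattern count vector,
so cost is independent of alignment length.  Gamma categories are
quantile medians at shape $\alpha$, normalized to mean rate one.

Optimization is a deterministic coordinate-wise bounded line search
(golden section per coordinate; branch lengths on a log scale in
$[10^{-8}, 10]$, exchangeabilities in $[10^{-3}, 10^{3}]$, frequencies
via softmax weights, $\alpha \in [0.05, 50]$), swept until the
log-likelihood improves by less than $10^{-6}$ (at most 200 sweeps,
otherwise the fit is flagged unconverged).  Two deterministic starts are
used — equal branch lengths 0.1, and distance-scaled lengths derived from
pairwise mismatch fractions — and the better optimum kept.  Because the
line-search order depends on the role order, results for permuted ingroup
roles agree to optimizer precision (about $10^{-4}$), not bit-for-bit.

## Filters

Two per-species-quartet filters remove unreliable quartets (RISK first,
then DIST; `no_signal` quartets never pass):

* **RISK** keeps a quartet when the best topology's convergence ratio
  $N_c/N_a$ is strictly below a threshold $L_\mathrm{RISK} \in (0, 1]$
  ($N_a = 0$ means an infinite ratio, always rejected).
* **DIST** keeps a quartet when the support distance
  $SD_{1,2} = R_\mathrm{best} - R_\mathrm{second}$ is at least
  $L_\mathrm{DIST}$ (boundary kept; default 0.1).

$L_\mathrm{RISK}$ is optimized per clade-quartet by a deterministic
uphill climber: start at $L = 1$, step 0.05, move to the better of
$L \pm \delta$ (ties toward the larger threshold), halve the step on a
failed move, stop when $\delta < 10^{-3}$.

**Threshold objective.**  The objective is pluggable; the default is

$$f(L) = \left(\frac{\#\text{retained}}{\#\text{total}}\right)^{1/2}
  \times \left(1 - \overline{N_c/N_a}\big|_\text{retained}\right).$$

The design here was genuinely open, and the exponent matters: with a
*linear* retention term the objective reduces to
$\sum_\text{retained}(1 - r_i)/n$, which is monotone non-decreasing in
$L$ whenever all ratios are below one — and the best topology of any
signal-bearing quartet has $N_a > N_c$, i.e. $r < 1$ — so the "optimum"
would always be the trivial $L = 1$.  The concave retention term makes
admitting high-ratio quartets cost more purity than it gains retention,
which produces a genuine interior threshold between well-separated ratio
clusters while still returning $L = 1$ when all ratios are uniformly low.
`riskObjective(..., exponent = 1)` restores the plain product for
comparison.  Because the climber only ever probes points within a
shrinking step of its current position, it can stall on objective
plateaus wider than the current step; on the plateau-free fixture
families used in the tests it matches an exhaustive $10^{-3}$-grid
search exactly.

## Aggregation and the supertree stage

Retained quartet supports are aggregated per clade-quartet by the
per-topology **median** $\omega_k$ (robust to outliers; computed
independently per topology and deliberately *not* renormalized, so the
three medians need not sum to one).  Clade-quartets left empty by
filtering contribute zero with a warning.

Each rooted clade-quartet topology $(O,(A,(B,C)))$ with median $\omega$
contributes $\omega$ to three relation cells of a
pairwise-compatibility support matrix: $A$ *precedes* $B$, $A$
*precedes* $C$ (closer to the root), and $\{B, C\}$ form a *derived
pair*.  Every rooted binary tree of the $n$ ingroup clades — all
$(2n-3)!!$ of them, enumerated exhaustively up to a configurable limit
of 9 clades — induces exactly one topology per clade-quartet, and its
**canonical score** is the sum of the induced $\omega$.  The cell set
induced by a valid rooted tree is pairwise compatible by construction,
so per-tree scoring replaces an explicit maximum-clique search.  The
matrix-sum variant (three cells per induced quartet) is exactly three
times the canonical score and is reported alongside; rankings under the
two are identical, and ties are broken by canonical Newick string
(children of every node ordered by smallest leaf label).

Per-species summaries report, for every taxon, the percentage of its
quartet participations that survived filtering and the medians of its
retained participations per clade-quartet; a taxon is *consistent* when
one rooted clade tree induces all of its per-clade-quartet best
topologies (found by exhaustive witness search), and supports below 0.6
are flagged moderate.

## The simulator

`simulateAlignment()` evolves a root sequence drawn from the stationary
frequencies along a rooted tree with branch lengths, using
matrix-exponential transition probabilities; gamma rate categories are
i.i.d. per site.  The default parameter set is a mildly AT-rich GTR+Γ4
(frequencies 0.28/0.22/0.22/0.28, transition bias 4:1, shape 0.5) —
plausible for second-codon-position nucleotide data, where composition is
near-balanced and rate variation moderate.

Indels are optional: events are placed per branch with expected count
(rate × branch length × current sequence length), insertion:deletion
1:1, and lengths drawn from the bounded heavy-tailed Lavalette law
$P(L = k) \propto \left(\frac{kM}{M - k + 1}\right)^{-\alpha}$ with
defaults $\alpha = 2.4$, rate 0.01747, $M = 400$.  The rate constant is
interpreted per site per unit branch length (relative to the
substitution rate), the convention of standard indel simulators.
Insertions create columns gapped in all non-descendants and deletions
write gaps in descendants, so output is pre-aligned.  Output is
bit-identical for a fixed seed.

What the simulator does *not* emulate: alignment error, compositional
heterogeneity across lineages (non-SRH evolution), site-specific
partitions, and codon structure.  Passing recovery tests on simulated
data therefore demonstrates that the scoring, filtering and ranking
machinery recovers the generating topology under model-conforming
evolution — not that real transcriptome data meet those assumptions.

## The validation study

`recoveryStudy()` simulates alignments on two generating clade trees of
four ingroup clades — a caterpillar `(C,(D,(P,S)))` and a balanced
`((C,D),(P,S))`, internal branches 0.08, clade stems 0.2–0.3, three taxa
per clade (within-clade depth 0.05, terminals 0.15), outgroup stem 0.3 —
with 20 replicates per tree at 20,000 sites, every second replicate with
Lavalette indels.  Each replicate is scored once and evaluated both
unfiltered and with `risk+dist` filtering; the study reports how often
the generating tree ranks first and whether filtering increased its
support.  The substitution model for this study is Jukes–Cantor on both
the simulation and inference side: the study's purpose is to validate the
pattern-scoring, correction and ranking chain, and matching a minimal
model keeps the result attributable to that chain rather than to model
estimation, while keeping the per-replicate ML stage (972 quartet fits)
fast enough to run routinely.  The same conditions are rerun from
scratch by `scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Pattern counts are collapsed to the 256-vector once per quartet; all
  likelihood work is pattern-based.
* Branch lengths at the $10^{-8}$ lower bound stand in for zero; the
  "star tree" symmetry of the three pattern classes holds to that order.
* Quartets with zero usable columns are flagged and skipped with a
  warning, not errors; they appear in reports with NA scores.
* Best-topology ties (equal $R$) resolve to the lowest topology index;
  tree-score ties resolve by canonical Newick order.
* Empirical base frequencies (with a pseudocount) start the GTR
  frequency optimization.
* Column indices are 0-based internally and 1-based in reports.

## Known limitations

* Site-pattern analysis is inherently quartet-wise; there is no
  multi-taxon generalization of the polarized pattern classes here.
* The homogeneous GTR correction underestimates convergence when
  composition drifts across lineages.
* Exhaustive tree ranking grows as $(2n-3)!!$ and is capped at 9 ingroup
  clades by default.
* The exact threshold objective used by the original description of the
  RISK optimization is not public; the retention–purity family
  implemented here reproduces its stated intent, not its exact values,
  and optimized thresholds on real data will differ accordingly.
```{r session}
sessionInfo()
```
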