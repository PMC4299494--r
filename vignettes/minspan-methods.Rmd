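---
title: "Sparsest null-space pathway bases: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparsest null-space pathway bases: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A constraint-based metabolic model is a stoichiometric matrix $S \in
\mathbb{R}^{m\times n}$ with flux bounds $lb \le v \le ub$
(mmol·gDW⁻¹·h⁻¹).  Steady state confines flux distributions to the null
space $\{v : Sv = 0\}$, whose dimension is $n - r$ with $r =
\mathrm{rank}(S)$.  This package defines pathways as the columns of the
*sparsest* feasible basis $P$ of that null space: the fewest total
reactions that still span every steady-state behaviour, while respecting
irreversibility ($lb_i \ge 0$ forces $v_i \ge 0$ in every column).
Sparsity is what makes the basis biologically legible: it maximally
segregates the network into reaction sets that must operate together.

### Preprocessing

Before enumeration the model is reduced (`preprocess()`): every exchange
reaction (a column touching a single metabolite) is opened to
$[-1000, 1000]$; the biomass pseudo-reaction is removed; reactions whose
flux-variability minimum and maximum are both within $10^{-9}$ of zero are
removed as blocked.  Exchanges are opened *before* blocked detection so
that every uptake/secretion route is available to the enumeration — the
alternative order would declare nutrient-dependent reactions blocked.
Irreversibility of internal reactions is preserved: those constraints are
part of the pathway definition, not an artifact.

### The MILP sweep

The orthonormal basis $N = \mathrm{null}(S)$ comes from the SVD, with the
numerical rank cut at $\max(m,n)\,\varepsilon_{mach}\,\sigma_{max}$ (an
error is raised if the singular-value gap at the cutoff is under $10^3$).
Starting from $P = N$, the sweep visits columns $j = 1,\dots,n-r$ in
ascending order and replaces each by the solution of

$$\min \textstyle\sum_i w_i b_i \quad \text{s.t.}\quad Sv = 0,\;
lb \le v \le ub,\; |v_i| \le M b_i,\; |x^\top v| \ge \epsilon,$$

where $x$ is the unit component of $p_j$ orthogonal to the other columns
(computed by QR within the null space), $\epsilon = 0.1$, $M = 1000$
(the global flux bound, so $M$ is never the binding constraint), and
$w_i = 1$.  The not-equal constraint $x^\top v \ne 0$ is realised as the
disjunction $x^\top v \ge \epsilon$ or $x^\top v \le -\epsilon$; the two
orientations are solved as separate trees and the better solution kept.
Any $v$ with $x^\top v \ne 0$ is automatically independent of the
remaining columns, so replacements can never collapse the basis.  Sweeps
repeat until $\mathrm{nnz}(P)$ is unchanged between consecutive sweeps.
The total $\mathrm{nnz}$ of the optimum is unique even when the
individual pathways are not; the suite checks this stability across
solver seeds.

MaxSpan switches the objective to maximisation ($w_i = -1$) and adds the
linking constraints ($b_i = 1 \Rightarrow |v_i| \ge \epsilon$, the "OR"
encoded with auxiliary binaries) so that counted reactions genuinely
carry flux.  RandSpan draws $w_i \sim U(-0.5, 0.5)$ once per basis, so
reaction use is randomly rewarded or penalised; the draw is made per
basis rather than per column so that the sweep's convergence criterion
remains well defined.

### The built-in solver

No MILP (or LP) solver library is assumed.  The package implements a
bounded-variable two-phase primal simplex (`lp_bounded()`): equality
constraints plus finite box bounds, bound-flip ratio tests, a maintained
basis inverse with eta updates and periodic refactorisation, and Bland's
rule as an anti-cycling fallback.  The branch-and-bound branches directly
on the support indicators: excluding a reaction fixes $v_i = 0$; including
a costed reaction commits its weight (and, for rewarded reactions, forces
$|v_i| \ge \epsilon$ with a chosen sign, giving three-way branching).
Every node LP minimises $\sum t_i \ge |v_i|$ over the free costed
reactions — an L1 surrogate whose vertex solutions are near-circuits — so
every node yields a feasible incumbent via its support.  Nodes are pruned
when their committed weight cannot beat the incumbent within the relative
gap.  Defaults: `rel_gap = 1e-3`, `time_limit = 60` s per MILP (the
published genome-scale practice is 1800 s; desk-scale studies here use
2–10 s), `epsilon = 0.1`, `tol_zero = 1e-6` separating solver noise from
structural zeros.  On a per-column timeout the previous column is kept,
which preserves the monotone decrease of $\mathrm{nnz}$.

### The oracle

For small models (n ≤ 20, null-space dimension ≤ 5)
`brute_force_sparsest_basis()` enumerates every support-minimal,
sign-feasible null-space vector — each circuit is pinned by $d-1$
independent vanishing coordinates, so all $\binom{n}{d-1}$ row subsets of
$N$ are examined — and then greedily selects circuits by ascending
support subject to independence.  Greedy selection is globally optimal
for the sparse-basis problem, so the oracle certifies the MILP sweep; the
suite demands exact agreement of total $\mathrm{nnz}$ on 50 seeded random
models.

## The toy fixture

`toy_glycolysis_tca()` reconstructs the simplified glycolysis + TCA
example: 14 metabolites, 18 reactions, rank 14, a 4-dimensional null
space.  The printed facts fix the dimensions but not the exact reaction
table, so the fixture is a faithful reconstruction: a lumped glycolytic
chain (hexokinase → pyruvate kinase), a complete TCA-like cycle,
PEP-carboxylase-like anaplerosis, a malic-enzyme-like bypass, and four
exchanges (glucose, pyruvate, succinate, CO₂).  Its sparsest basis has
30 non-zero entries across supports of size 6, 6, 8 and 10, two of which
are exactly the glycolysis-like and TCA-like routes; the oracle certifies
the optimum.  The fixture is deterministic and checksummed in the suite.

## Flux decomposition and TF activity

Sampling uses coordinate hit-and-run in null-space coordinates: warm-up
of $10n$ steps and thinning of $n$ steps, seeded.  Two implementation
choices matter for condition comparisons.  First, the walk consumes one
uniform variate per step whether or not the chord is degenerate, so two
runs under different bounds share an aligned random stream — regions of
the polytope untouched by a bound change yield *identical* samples, which
makes the seed-paired Wilcoxon test exact rather than merely paired.
Second, the chord directions may be the sparse pathway basis itself
(`directions = pm$P`): moves are then local to one pathway's reactions.
Both choices leave the stationary distribution uniform (the
parametrisation is a fixed linear bijection).

Condition bounds follow the standard constructions: anaerobic shifts
close oxygen uptake; alternate C/N/P/S sources zero the original source
and admit the replacement at an equal atom flow of the defining element
(computed from metabolite formulas — a C6→C2 swap triples the molar
uptake); supplements are admitted at the biomass-stoichiometry × growth
rate; and growth is bounded below at 90% of the optimum under the new
bounds.  Samples are divided by the condition's median growth for
comparability.  Each sample decomposes uniquely as $v = P\alpha$ (QR
least squares; residuals above `tol_decomp = 1e-6` indicate the vector is
outside the span and raise an error).  Pathways changed between
conditions are called by a two-sided paired Wilcoxon signed-rank test at
$P < 0.05$ (raw, no multiplicity correction — exposed as a parameter);
TFs are mapped to pathways by hypergeometric enrichment of regulon genes
in pathway gene sets at $P < 0.01$ over the universe of genes appearing
in the model's GPRs, dropping TFs that regulate one metabolic reaction or
appear in one pathway; a TF is predicted active when its associated
pathways are hypergeometrically enriched among the changed ones at
$P < 0.05$.

## Set statistics

Gene sets per pathway collect every gene in the GPR of any reaction with
a non-zero pathway coefficient; at protein level each disjunct of the
GPR's DNF is one protein, so isozymes count separately and complexes as a
unit.  Co-occurrence correlation is Spearman over binary membership
profiles, which coincides with the Pearson/phi coefficient and is
computed as such; significance comes from shuffling each entity's
memberships across pathways (preserving per-entity pathway counts), 1000
permutations by default, keeping pairs at $P \le 0.05$.  ROC curves vary
the correlation threshold over kept pairs against gold-standard
positive/negative pair sets, reduce to the convex hull (the attainable
upper envelope under threshold randomisation), and AUCs are compared with
the Hanley–McNeil normal approximation.  The near-ubiquitous-gene filter
models the membership entries as draws over the gene × pathway grid and
removes genes whose hypergeometric CDF exceeds 0.85 — the exact
parameterisation of this "empirically derived" filter is not pinned down
in the literature, so the threshold is exposed.  CSI of pathways A and B
is the fraction of all pathways whose correlation with both A and B falls
below $PCC_{AB} - t$; $t$ defaults to the 5th percentile of the absolute
off-diagonal correlation distribution (presets 0.0350 / 0.0562 reproduce
the published organism-scale choices), and pairs in the top 15% of CSI
values are called similar.  Nearest-neighbour assignment across
definitions uses Pearson distance with ties broken by higher CSI and then
lexicographic identifier; definition-pair counts are tested against the
size-proportional expectation (two-sided binomial, Bonferroni).

## Synthetic-data experiments

The generators are first-class code and define the study conditions of
the test suite.

* `random_consistent_model(n_mets, n_rxns, rev, seed)` builds an
  irreversible backbone chain with an inflow and an outflow exchange plus
  random shortcut reactions; every reaction can carry flux by
  construction, which flux-variability analysis re-verifies.  Internal
  reactions carry synthetic GPRs (60% single gene, 25% two-gene complex,
  15% isozyme pair), reflecting that real reactions are frequently
  catalysed by complexes or isozymes.
* `random_modular_model(blocks, ...)` direct-sums such networks with
  disjoint gene namespaces into a block-diagonal model, emulating the
  modular organisation of metabolism in which a nutrient shift perturbs a
  local subsystem.  Pathways never straddle blocks.
* `synthetic_regulon(membership, n_tfs, noise, seed)` plants each TF's
  regulon as one pathway's gene set with a `noise` fraction swapped for
  random genes, recording the truth for recovery scoring.

The TF-recovery study uses one modular model (6 blocks of 5 metabolites /
9 reactions, ~24 pathways), computes the basis once with a 2 s per-MILP
cap, and over 10 seeds plants regulons at noise 0.2, closes a reaction
feeding the planted TF's pathway in the reference condition, reopens it
in the shift, samples 150 paired flux distributions per condition and
runs the full test chain.  The correlation/ROC study plants 4 gene
modules across 60 single-module pathway draws (90% inclusion) and
corrupts 10% of the co-membership interaction list with spurious pairs.
Problem sizes were chosen so each study completes in minutes while
leaving clear statistical margins.

What passing these tests shows — and what it does not: the generators
produce mass-balanced, consistent, modular networks with planted truth,
so the tests certify the algorithmic chain (enumeration optimality,
decomposition exactness, calibrated error rates, recovery power under
the planted effect sizes).  They do not certify performance on curated
genome-scale reconstructions, where GPR structure, cofactor coupling and
network diameter are far richer; genome-scale runs additionally need the
published 30-minute per-MILP limits.

## Numerical choices and degenerate inputs

Zero thresholds: `tol_zero = 1e-6` for support counting, $10^{-9}$ for
blocked-reaction calls, $10^{-6}$ steady-state residual in
`verify_basis()`.  Normalised pathway columns are thresholded, snapped
back onto the null space restricted to their support (so thresholding
cannot leave a steady-state residual), divided by their smallest non-zero
magnitude, and oriented positive-first when fully reversible.  Models
with an empty null space after reduction raise a "no pathways exist"
error; a constant membership row is dropped from correlation with a
warning; an all-zero difference column in the shift test reports $p = 1$
and a `constant` flag.  Ties between equally sparse MILP solutions are
left to the deterministic search order, so runs are reproducible
bit-for-bit under a fixed seed.

## Known limitations

Thermodynamically infeasible internal loops (type-3 loops) are not
detected or removed; published condition lists exclude a handful of
shifts on that ground, and the same exclusion is available here as a
configuration choice rather than automated loop detection.  The simplex
and branch-and-bound are dense and intended for desk-scale models
(tens of reactions); genome-scale networks require a commercial-grade
solver behind the same interfaces.  The supplement-shift construction
derives the minimal uptake from the biomass stoichiometry directly,
which assumes the constituent is drained only by biomass.
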