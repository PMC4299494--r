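# minspan

Pathway analysis of genome-scale metabolic networks from the sparsest
basis of the stoichiometric null space.

## The problem

A metabolic network with stoichiometric matrix **S** (m metabolites × n
reactions) holds every steady-state flux distribution **v** in the null
space: **S v = 0**, with flux bounds lb ≤ **v** ≤ ub encoding reaction
irreversibility.  Any basis of that null space is a set of "pathways", but
the basis is not unique.  Convex-analysis definitions (elementary flux
modes, extreme pathways) enumerate exhaustively and do not scale;
human-curated databases are subjective.  **MinSpan** instead defines
pathways as the *sparsest* linearly independent, thermodynamically
feasible basis **P** of null(**S**): the shortest set of n − rank(**S**)
flux routes that together span everything the network can do at steady
state.

The sparsest-basis problem is solved here as an iterative mixed-integer
linear program: starting from the orthonormal null-space basis **N**
(SVD), each column **p**ⱼ is replaced by the flux vector of minimal
support that satisfies **S v = 0**, lb ≤ **v** ≤ ub and |**x**ᵀ**v**| ≥ ε,
where **x** is the component of **p**ⱼ orthogonal to the remaining
columns (so the replacement must span the removed direction, forcing
linear independence).  Binary indicators **b** with |vᵢ| ≤ M·bᵢ make
Σbᵢ the objective; the sweep repeats until the total number of non-zero
entries nnz(**P**) stops decreasing.  The package ships its own
branch-and-bound over a bounded-variable simplex, so no external MILP
solver is needed.

Around the core the package provides the companion analyses used to
evaluate and apply such pathway definitions:

* **MaxSpan / RandSpan** control bases (densest / randomly weighted).
* A **brute-force oracle** (exhaustive circuit enumeration + greedy) that
  certifies global optimality on small networks.
* **Flux decomposition**: hit-and-run samples of the flux polytope are
  decomposed as **v = P α**; paired Wilcoxon signed-rank tests on α
  between nutrient conditions flag changed pathways, and hypergeometric
  enrichment of changed, TF-associated pathways predicts
  **transcription-factor activity**.
* **Set statistics**: gene/protein sets per pathway from GPR rules,
  co-occurrence Spearman correlation with a permutation filter, ROC
  convex-hull AUC against interaction gold standards with the
  Hanley–McNeil test, connection-specificity-index (CSI) similarity and
  k-nearest-neighbour comparison across pathway definitions, and the
  dual-perturbation gene-set algebra
  ((E2 Δ E1) \ G1) ∪ (G2 \ G1).
* **I/O**: SBML Level 3 + FBC and the community JSON model dialect; TSV
  regulons and interaction tables; GMT pathway definitions.

## Worked example

The packaged fixture reconstructs a simplified glycolysis + TCA network:
14 metabolites, 18 reactions, rank 14, so the null space — and the
pathway count — is 4.

```r
library(minspan)
toy <- toy_glycolysis_tca()
red <- preprocess(toy)        # open exchanges, drop blocked reactions
pm  <- minspan(red)
pm
#> pathway_matrix (minspan): 18 reactions x 4 pathways, nnz = 30
round(pm$P, 2)
#>        pw01 pw02 pw03 pw04
#> EX_glc    0   -1   -1    0
#> HEX1      0    1    1    0
#> PGI       0    1    1    0
#> EMP       0    1    1    0
#> PYK       0    1    0    0
#> PDH       0    0    0    1
#> CS        0    0    0    1
#> ACN       0    0    0    1
#> ICDH      0    0    0    1
#> AKGDH     0    0    0    1
#> SDH       1    0    0    1
#> FUM       1    0    0    1
#> MDH       0    0   -1    1
#> PPC       0    0    1    0
#> ME        1    0    1    0
#> EX_pyr    1    1    1   -1
#> EX_co2    1    0    0    3
#> EX_suc   -1    0    0    0
```

Column `pw02` is the glycolysis-like route (glucose uptake → pyruvate
secretion, 6 reactions), `pw04` the TCA-like cycle (pyruvate uptake →
3 CO₂ secreted, 10 reactions); the other two are a succinate-to-pyruvate
route and the anaplerotic (PEP-carboxylase/malic-enzyme) route.
The total of 30 non-zero entries is certified globally minimal by
`brute_force_sparsest_basis()`.  A `verify_basis()` report checks the
steady-state residual, the rank, and sign feasibility of every column.

A command-line wrapper is installed at `inst/scripts/minspan`:

```sh
Rscript inst/scripts/minspan fixtures --toy --out fx
Rscript inst/scripts/minspan run --model fx/toy_glycolysis_tca.json --out res
```

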