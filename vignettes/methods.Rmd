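---
title: "Models and procedures in paleowgd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and procedures in paleowgd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleowgd)
```

`paleowgd` reimplements, as a tested and reusable pipeline, the
comparative-genomic workflow used to detect an ancient whole-genome
duplication (WGD) from collections of multilabeled gene trees and to model
karyotype and genome-size evolution on a species phylogeny. This vignette is
the package's own account of the science: the models, the tunable parameters
that matter, the numerical choices, and what the synthetic-data tests do and
do not demonstrate about real data.

## 1. Single-copy reduction of orthogroups

Transcriptome-derived gene families contain isoform and allele redundancy: a
well-supported clade whose tips all belong to one species is almost always
one gene observed several times, not several genes.
`collapse_single_species_clades()` therefore replaces every **maximal**
clade that (i) comprises a single species and (ii) has bootstrap support at
or above `support_min` (default 50, on the 0--100 scale) with its single
longest transcript. Two details this rule leaves open are fixed
here for reproducibility: equal-length transcripts tie-break to the
lexicographically smallest id, and the pass iterates bottom-up to a fixpoint
(one pass suffices on all inputs we have constructed; the loop guards
pathological cases). Single tips are never collapsed, and clades below the
support threshold are left untouched. A family is *single copy*
(`is_single_copy()`) when, after reduction, every species occurs exactly
once among the tips. `filter_orthogroups()` applies the taxon-occupancy
filter; the boundary is inclusive (a family with exactly `min_taxa` distinct
species is kept).

## 2. Placing gene duplications on the species tree

The placement procedure works from same-species paralog pairs:

1. Each gene tree is rerooted on the most preferred outgroup species present
   (`reroot_by_preference()`); the root goes on the edge above that
   species' transcripts (their MRCA when there are several). Trees with no
   outgroup species are marked *unrootable* and excluded, a status rather
   than an error, because it is an expected property of sparse
   transcriptome sampling.
2. Every pair of transcripts from the same species is enumerated
   (`enumerate_paralog_pairs()`); the candidate duplication event is the
   pair's gene-tree MRCA, and the bootstrap support attached to the
   placement is that node's support — the duplication *is* that node.
3. `place_pair()` accepts a placement when the species set `T` below the
   MRCA equals the descendant species set of some species-tree node
   (composition match), and at least one species from that node's sister
   clade appears in the gene-tree MRCA's sister subtree (the sister check,
   which separates duplication nodes from spurious MRCA matches). A pair
   whose MRCA is the gene-tree root has no sister and is reported
   `root-unplaceable`; every rejection carries its reason so audits can
   reconstruct the decision.
4. `tally_duplications()` drops placements with support below the threshold
   (default 80) and counts either *unique* duplications — one per distinct
   (family, gene-tree MRCA) event, however many pairs coalesce there — or
   every pair (`all_pairs`).

Two design points deserve emphasis. *Set equality* is the only reading of a
"composition match" that yields a unique species-tree node, so that is what
is implemented. And because transcriptomes sample genomes incompletely, the
species tree is restricted to the species present in each family before
matching (`prune_species_tree = TRUE`, the default); without this, nearly
every placement in sparsely sampled families would fail. The unpruned
behaviour is available for comparison. Within-species duplications (the
gene subtree spans one species) map to a terminal branch; they are reported
but never contribute to internal-node tallies.

## 3. Chromosome-number evolution as a CTMC

Chromosome counts evolve on the tree as a continuous-time Markov chain over
haploid numbers `n` (data arrive as diploid `2n`; odd `2n` values are
rejected rather than silently halved). `build_rate_matrix()` parameterizes:

* ascending dysploidy `i -> i+1` at rate `max(0, gain + gain_slope (i - n_min))`,
* descending dysploidy `i -> i-1` analogously with `loss`,
* polyploidy `i -> 2i` at rate `dupl`,
* demipolyploidy `i -> 1.5i` at rate `demi`, odd `i` splitting the rate
  evenly between `(3i-1)/2` and `(3i+1)/2`.

Constant-rate models pin the slopes at 0; linear models free them, with
rates clamped at zero after the linear adjustment. Duplication mass that
would leave the state space is routed to `n_max` so the generator stays
proper. The default state space is `[1, max(observed n) + 10]`; truncation
sensitivity can be probed by widening it.

The likelihood is Felsenstein pruning with per-edge `exp(Q t)`. One
numerical point matters enough to state plainly: generators of
constant single-rate models (for example pure gain) have a repeated
eigenvalue and are **defective** — eigendecomposition-based matrix
exponentials return garbage without warning there. `paleowgd` uses the
spectral route only when the decomposition reconstructs `Q` to high
precision, and otherwise switches to uniformization (shared jump-matrix
powers) or scaling-and-squaring, both exact for arbitrary generators. The
unit tests pin this behaviour against series expansion.

Root handling is `"ml"` (maximize over root states) by default, with a
uniform-prior alternative; marginal ancestral states
(`chrom_ancestral_states()`) use the standard two-pass conditioning, with
argmax ties broken toward the smaller count. Expected numbers of events by
type (`expected_chrom_changes()`) come from stochastic mapping: node states
are drawn from the joint conditional distribution and branch histories are
sampled by endpoint-conditioned rejection, falling back to a uniformization
bridge when a branch exceeds the rejection cap (such branches are flagged
in the output).

Fitting (`fit_chrom_model()`) is bounded multi-start optimization on log
rates. The first start is a deterministic moderate point (all rates 0.1);
further starts are log-uniform on `[1e-4, 10]`. When the gradient-based
line search aborts on numerical noise, a derivative-free polish continues
from the stopping point. `compare_models()` ranks fits by AIC and reports
Akaike weights `exp(-Delta/2) / sum(exp(-Delta/2))`.

The ten-model battery (`chrom_model_battery()`) crosses constant and linear
dysploidy with polyploidy and demipolyploidy (tied or free), plus a
duplication-only and a linear gain-only model — the model families a
standard ChromEvol comparison spans. It is this package's own default;
other compositions assemble directly from `chrom_model_spec()`.
Tip exclusion by id before fitting supports the standard outlier protocol
(removing, e.g., a single extreme polyploid such as a `2n = 596` record).

## 4. Continuous-trait comparative methods

* `asr_bm()` — BM ancestral states by two-pass best-linear-unbiased
  estimation. The root estimate equals the GLS phylogenetic mean
  `(1'C^-1 x)/(1'C^-1 1)`; `sigma2` is the ML estimate (sum of squared
  standardized contrasts over `n`), and 95% CIs are
  `estimate ± 1.96 sqrt(sigma2 * v)` with `v` the conditional variance in
  branch-length units. The dense-matrix GLS formulas serve as the test
  oracle; the implementation itself is linear-time pruning.
* `pagel_lambda()` — ML over the lambda transform with a likelihood-ratio
  test against `lambda = 0` on a chi-square(1) reference (delegated to
  `phytools::phylosig`, which implements exactly this contract; the
  orientation of the test matches an estimate near 0 giving p near 1).
* `blomberg_k()` — authored in-package:
  `K = (MSE0/MSE) / E[MSE0/MSE]` with the trace formula for the
  expectation, and a seed-controlled one-tailed permutation p-value with
  the add-one correction, so `p >= 1/(n_perm + 1)` by construction
  (999 permutations by default, the field's convention). The K statistic itself is cross-checked against
  `phytools` in the tests.
* `pic_contrasts()` / `pic_correlation()` — Felsenstein contrasts (via
  `ape::pic`) and regression through the origin; `m` contrasts give a
  residual df of `m - 1` (equivalently `n_tips - 2`), the standard
  through-origin accounting.
* Genome size is analyzed on the log scale for signal and contrasts
  (`log_x`/`log_y` flags) and on the raw scale for ancestral-state display.
  Chromosome number *can* be run through these continuous-trait methods,
  but the CTMC module is the appropriate model; treating a discrete count
  as continuous is supported only for comparison.

### OU shift selection

`ou_shift_scan()` finds adaptive-optimum shifts with no prior on their
locations. For each pull strength `alpha` on a grid, tip expectations are
linear in the regime optima — the design column of a shift starting on edge
`e` is `1 - exp(-alpha (T - depth(e)))` for tips below `e` — so after
whitening by the OU covariance, shift placement is variable selection:
forward selection followed by a backward pruning pass, scored by an
information criterion, best configuration across the grid returned. This is
an approximation with the same contract as the lasso-based original (no a
priori shift locations, criterion-based selection), not a reimplementation
of its solver.

The default criterion (`"pBIC"`) charges each shift two parameters (its
optimum and its location) *plus* a combinatorial term
`2 log(choose(E, s))` for choosing `s` of `E` edges. The reason is
statistical, not cosmetic: with ~`2n` candidate edges, the best single-edge
improvement under the null behaves like the maximum of ~`2n` chi-square(1)
draws (≈ `2 log(2n)`), which plain BIC's `log n` penalty cannot resist —
spurious shifts would be routine. The multiplicity-corrected criterion is
the standard answer in the shift-detection literature. Plain `"BIC"`
remains available. A planted shift on a child-of-root edge is statistically
indistinguishable from a base-optimum change plus a shift on the sister
edge; simulation studies should plant shifts on deeper edges (the
recovery tests do).

Because a configuration's fitted optima are offsets against the base
optimum, `ou_shift_scan()` reports both raw coefficients and absolute
optima.

## 5. What the synthetic-data generator emulates

`simulate_species_tree()` is a forward birth--death simulation conditioned
on reaching exactly `n` extant tips (restarting on extinction), returning
an ultrametric binary tree. `simulate_gene_families()` evolves each family
inside the species tree under per-lineage duplication and loss, with an
episodic WGD modeled as one synchronous duplication at the stem of a chosen
node, retained per family with probability `retention_prob` — the
biological reading of paralog retention after post-polyploid fractionation.
Ground-truth attributes record whether the WGD was applied and whether it
is *observable* (both copies survive to tips in at least one common
species, i.e. some paralog pair witnesses the event), so placement
sensitivity and specificity can be scored without re-deriving events.
Gene-tree branch lengths inherit species-tree lengths; the placement
algorithm is topology-only, so rate variation is cosmetic here. Synthetic
bootstrap supports are 100 by default; with support noise `p_low`, a node
draws from uniform {0..79} with probability `p_low` and uniform {80..100}
otherwise, which exercises the bootstrap-80 filter exactly at its
threshold.

`simulate_chromosome_counts()` is exact Gillespie simulation along each
edge with a full event log; `simulate_trait()` draws BM increments
edge-by-edge, exact OU transitions with regime switches on designated
edges, or lambda-transformed BM from the exact multivariate normal.

What passing tests show — and do not. The simulators match the models the
estimators assume, so the tests certify correctness of the machinery
(likelihoods equal enumeration; placements equal an exhaustive oracle;
estimators are calibrated under their generating model: mean Pagel's
lambda ≈ 1 and mean Blomberg's K ≈ 1 under BM, F-test size ≈ 5%). They do
not certify robustness to the ways real data deviate: gene-tree estimation
error, hidden paralogy from incomplete sampling, chromosome counts
violating the Markov assumption, or traits with measurement error. Those
caveats transfer directly from the original tools this package
reimplements.

## 6. Study conditions used by the automated experiments

The experiment sizes are the package's chosen study conditions: 6-taxon
random scenarios (500) for the placement oracle; an 8-tip species tree with
1,000 families at retention 0.4 for WGD recovery; support noise
`p_low = 0.3` for the filter checks; 200-tip trees scaled to depth 4 with
rates (gain 0.5, loss 0.35, duplication 0.1) — about four expected events
per root-to-tip lineage, and enough duplication events (~15-20 per
replicate) for the rate to be estimable to the stated 25% median error,
a sample-size choice made when the experiment was designed; 100-tip trees
with 50 replicates for signal calibration; 500 replicate pairs for the
F-test's size; and 50-tip trees with 50 replicates for OU shift
specificity (no-shift data) and sensitivity (a planted shift of eight
stationary standard deviations on a mid-depth edge). The acceptance script
reruns the same experiments at reduced replicate counts, which it reports
alongside each value.

## 7. Known limitations

* Base-number (x) transition models and cladogenetic chromosome change are
  documented extension points, not implemented.
* Ks-based paralog dating and auto- vs allopolyploidy discrimination are
  out of scope; the placement machinery cannot distinguish them.
* The OU scan's forward/backward selection is greedy; it can merge two
  adjacent true shifts into one, and its BIC values are not numerically
  comparable to those of the lasso-based original.
* Polytomies pass through tree I/O unchanged but must be resolved (zero-
  length edges) before contrasts or BM reconstruction.
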