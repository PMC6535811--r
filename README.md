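# paleowgd

Detecting ancient whole-genome duplications (WGDs) from collections of gene
trees, and modelling chromosome-number and genome-size evolution on a
species phylogeny.

Plant lineages — palms are a canonical case — carry the scars of ancient
polyploidy: hundreds of gene families in which two copies from the same
species coalesce at the same phylogenetic depth. `paleowgd` provides the
full desk-side pipeline for this kind of study, for phylogeneticists and
comparative genomicists working from transcriptome-derived gene families
and trait databases:

* **Single-copy reduction** — collapse well-supported single-species clades
  (isoforms/alleles) to their longest transcript and filter orthogroups by
  taxon occupancy, yielding the single-copy gene set used for species-tree
  inference.
* **Duplication placement** — reroot multilabeled gene trees on a preferred
  outgroup, enumerate all same-species paralog pairs, and map each pair's
  MRCA onto the species tree. A placement of a pair with gene-subtree
  species set *T* is accepted iff some species-tree node's descendant set
  equals *T* **and** the gene-tree MRCA's sister subtree shares at least
  one species with that node's sister clade. Placements below a bootstrap
  threshold (default 80) are discarded; *unique* mode counts each distinct
  duplication node once. A WGD announces itself as an excess of unique
  duplications concentrated on one species-tree node.
* **Chromosome-number CTMC** — a ChromEvol-style continuous-time Markov
  chain over haploid counts with ascending/descending dysploidy (constant
  or state-linear rates `max(0, r0 + r1 (i - n_min))`), polyploidy
  (`i -> 2i`) and demipolyploidy (`i -> 1.5i`); pruning likelihood, ML
  fitting, a ten-model battery compared by AIC and Akaike weights
  `w_m = exp(-Δ_m/2)/Σ exp(-Δ/2)`, marginal ancestral states, and expected
  event counts by stochastic mapping.
* **Continuous-trait methods** — BM ancestral reconstruction with 95% CIs
  (root = GLS phylogenetic mean), Pagel's λ with a likelihood-ratio test,
  Blomberg's K with a seed-controlled permutation test, phylogenetically
  independent contrasts with through-origin regression, and
  Ornstein–Uhlenbeck shift selection with no prior on shift locations.
* **Simulators** for every input: birth–death species trees,
  duplication–loss gene families with an episodic WGD and a per-family
  retention probability, Gillespie chromosome counts under any generator,
  and BM/OU/λ-BM traits — so the whole pipeline is testable end to end
  without external downloads.

Trees are `ape::phylo` objects throughout; bootstrap supports live in
`node.label` (RAxML convention), and a `[&support=...]` comment dialect is
also read.

## Worked example

Simulate a known WGD, then recover it:

```r
library(paleowgd)

tree <- simulate_species_tree(8, birth_rate = 1, death_rate = 0, seed = 42)
wgd_node <- ape::getMRCA(tree, c("t2", "t3", "t4"))   # node 12

scenario <- wgd_scenario(tree, wgd_node = wgd_node, retention_prob = 0.4,
                         n_families = 200, seed = 7)
families <- simulate_gene_families(scenario)
records  <- place_families(families, tree)
tally_duplications(records, mode = "unique", support_min = 80)
#>   node    clade count
#> 1   12 t2,t3,t4    75
```

All 75 unique, well-supported duplications land on node 12 — the node where
the WGD was planted (75/200 ≈ the 0.4 retention probability after loss of
unobservable families), and no other node accumulates any. With
`retention_prob = 0` the tally at node 12 is exactly zero.
`annotate_counts(tree, tally)` writes the counts onto the species tree as
node labels for plotting.

Chromosome numbers on the same tree (counts are haploid `n`; use
`haploid_counts()` to convert diploid `2n` data, which must be even):

```r
Q <- build_rate_matrix(chrom_model_spec("truth", c("gain", "loss", "dupl"),
                                        n_max = 40),
                       c(gain = 0.5, loss = 0.35, dupl = 0.1))
tree4 <- tree
tree4$edge.length <- tree4$edge.length * 4 / max(ape::node.depth.edgelength(tree4))
counts <- simulate_chromosome_counts(tree4, Q, root_count = 8,
                                     seed = 3)$tip_states
counts
#> t1 t2 t3 t4 t5 t6 t7 t8
#> 14 16 16 14 15 15  7  7

fit <- fit_chrom_model(tree4, counts,
                       chrom_model_spec("CONST_DUPL",
                                        c("gain", "loss", "dupl"),
                                        n_max = 30),
                       n_starts = 2, seed = 1)
fit
#> <chrom_fit> CONST_DUPL | logL = -10.8517 | k = 3 | AIC = 27.7035

asr <- chrom_ancestral_states(fit, tree4, counts)
2 * asr$ml_state[9]   # ML reconstruction at the root, on the 2n scale
#> [1] 14
```

The fit reads the tip pattern the way a cytogeneticist would: most tips sit
at 14–16 (the doubled clade), `t7`/`t8` retain the low count 7, and the
model explains the jump with a duplication rate rather than dysploidy
(fitted loss ≈ 0). `compare_models()` on a list of such fits returns the
AIC ranking with Akaike weights, and `expected_chrom_changes()` counts
events by type via stochastic mapping.

For trait data, `match_tips()` articulates a tree with a trait table,
borrowing values from a congeneric species when the exact species is
missing (flagged `congener`; ties go to the lexicographically smallest
species id), then `asr_bm()`, `pagel_lambda()`, `blomberg_k()`,
`pic_correlation()` and `ou_shift_scan()` take the matched tree and named
trait vector directly.

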