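# Independent oracles and small fixture builders shared across test files.
# These deliberately re-derive results from definitions (exhaustive
# enumeration, dense matrices) rather than calling the implementation paths
# they are used to check.

# Brute-force placement oracle: test EVERY node of the species tree against
# the acceptance rule's definition and return the accepted node ids.
oracle_place_pair <- function(pair, family, species_tree,
                              prune_species_tree = TRUE) {
  gt <- family$tree
  root_g <- ape::Ntip(gt) + 1L
  if (pair$mrca_node == root_g) return(list(node = NA, reason = "root"))
  # species below the pair MRCA, from scratch
  subtips <- ape::extract.clade(gt, pair$mrca_node)$tip.label
  Tset <- sort(unique(unname(family$map[subtips])))
  st <- species_tree
  fam_sp <- unique(unname(family$map[gt$tip.label]))
  if (prune_species_tree) {
    keep <- intersect(st$tip.label, fam_sp)
    if (length(keep) < 2L) return(list(node = NA, reason = "no-clade"))
    st <- ape::keep.tip(st, keep)
  }
  # gene-tree sister species
  gpar <- gt$edge[match(pair$mrca_node, gt$edge[, 2L]), 1L]
  gsib <- setdiff(gt$edge[gt$edge[, 1L] == gpar, 2L], pair$mrca_node)
  Gset <- unique(unname(family$map[unlist(lapply(gsib, function(n) {
    if (n <= ape::Ntip(gt)) gt$tip.label[n]
    else ape::extract.clade(gt, n)$tip.label
  }))]))
  nn <- ape::Ntip(st) + st$Nnode
  for (v in seq_len(nn)) {
    vt <- if (v <= ape::Ntip(st)) st$tip.label[v]
      else ape::extract.clade(st, v)$tip.label
    if (!setequal(vt, Tset)) next
    # candidate: check its sister set
    if (v == ape::Ntip(st) + 1L) return(list(node = NA, reason = "sister"))
    par <- st$edge[match(v, st$edge[, 2L]), 1L]
    sibs <- setdiff(st$edge[st$edge[, 1L] == par, 2L], v)
    Sset <- unique(unlist(lapply(sibs, function(n) {
      if (n <= ape::Ntip(st)) st$tip.label[n]
      else ape::extract.clade(st, n)$tip.label
    })))
    if (length(intersect(Gset, Sset)) > 0) {
      full <- if (length(Tset) == 1L) match(Tset, species_tree$tip.label)
        else ape::getMRCA(species_tree, Tset)
      return(list(node = full, reason = "accepted"))
    }
    return(list(node = NA, reason = "sister"))
  }
  list(node = NA, reason = "no-clade")
}

# Exhaustive CTMC likelihood: sum over all internal-node state assignments
# of products of transition probabilities (uniform root prior).
oracle_ctmc_loglik <- function(tree, counts, Q, root_prior = "uniform") {
  states <- as.integer(rownames(Q))
  S <- length(states)
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  P <- lapply(tree$edge.length, function(t) paleowgd:::.expm_ss(Q * t))
  x <- counts[tree$tip.label]
  grids <- rep(list(seq_len(S)), nint)
  combos <- as.matrix(expand.grid(grids))
  tot_by_root <- rep(0, S)
  for (r in seq_len(nrow(combos))) {
    assign_state <- function(v) {
      if (v <= ntip) match(x[[v]], states) else combos[r, v - ntip]
    }
    pr <- 1
    for (e in seq_len(nrow(tree$edge))) {
      i <- assign_state(tree$edge[e, 1L])
      j <- assign_state(tree$edge[e, 2L])
      pr <- pr * P[[e]][i, j]
    }
    rs <- combos[r, 1L]   # root is first internal node
    tot_by_root[rs] <- tot_by_root[rs] + pr
  }
  if (root_prior == "uniform") log(mean(tot_by_root)) else log(max(tot_by_root))
}

# Random generator matrix over `S` states (dense off-diagonal draws).
random_generator <- function(S, rate_scale = 1) {
  Q <- matrix(stats::runif(S * S, 0, rate_scale), S, S)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(1:S, 1:S)
  Q
}

# Random gene family on a species tree: each species gets 1 or 2 transcript
# copies placed by attaching duplicate subtrees at random; built from an
# independent coalescent-free construction (random topology via ape::rtree
# over the multiset of labels).
random_multilabel_family <- function(species, id = "fam", p_dup = 0.5,
                                     support = 100) {
  labs <- unlist(lapply(species, function(s) {
    k <- 1L + stats::rbinom(1L, 1L, p_dup)
    paste0(s, "@", seq_len(k))
  }))
  if (length(labs) < 3L) labs <- c(labs, paste0(species[1L], "@9"))
  gt <- ape::rtree(length(labs), tip.label = sample(labs))
  gt$node.label <- rep(as.character(support), gt$Nnode)
  gene_family(gt, id = id)
}

# Yule tree scaled to unit depth, deterministic.
fixture_tree <- function(n, seed, depth = 1) {
  tr <- simulate_species_tree(n, 1, 0, seed = seed)
  tr$edge.length <- tr$edge.length * depth / max(ape::node.depth.edgelength(tr))
  tr
}
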