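# Internal helpers shared across modules. Trees are ape "phylo" objects;
# internal-node bootstrap support lives in node.label (RAxML convention).

#' @noRd
child_list <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  kids
}

#' Postorder list of tip-label sets for every node (tips included).
#' @noRd
tip_label_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  sets <- vector("list", n)
  sets[seq_len(ntip)] <- as.list(tree$tip.label)
  for (i in ape::postorder(tree)) {
    p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  sets
}

#' Support value of each node (1..Ntip+Nnode); tips get 100 by convention,
#' unlabeled internals NA.
#' @noRd
node_support <- function(tree) {
  ntip <- ape::Ntip(tree)
  sup <- rep(NA_real_, ntip + tree$Nnode)
  sup[seq_len(ntip)] <- 100
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    num <- suppressWarnings(as.numeric(lab))
    sup[ntip + seq_len(tree$Nnode)] <- num
  }
  sup
}

#' Root node id of a phylo object.
#' @noRd
root_node <- function(tree) ape::Ntip(tree) + 1L

#' Parent of each node (0 for root).
#' @noRd
parent_vec <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  par <- integer(n)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

#' Deterministic, seed-scoped RNG: run `expr` with `seed` without disturbing
#' the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
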