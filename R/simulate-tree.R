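#' Simulate an ultrametric birth-death species tree
#'
#' Forward Gillespie simulation from two lineages under constant per-lineage
#' speciation and extinction rates, stopped the instant the number of extant
#' lineages reaches `n_tips`; extinct lineages are pruned, so the returned tree
#' is ultrametric with exactly `n_tips` tips. Simulations that go extinct are
#' restarted.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth_rate Speciation rate (> death_rate).
#' @param death_rate Extinction rate (>= 0).
#' @param seed Integer seed; the simulation is bit-reproducible given it.
#' @return A rooted ultrametric `phylo` with tips `t1..tN`.
#' @export
simulate_species_tree <- function(n_tips, birth_rate = 1, death_rate = 0,
                                  seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (!(birth_rate > death_rate) || death_rate < 0)
    stop("need birth_rate > death_rate >= 0")
  with_seed(seed, {
    repeat {
      tr <- .bd_forward(n_tips, birth_rate, death_rate)
      if (!is.null(tr)) return(tr)
    }
  })
}

# One forward attempt; NULL on extinction before reaching n_tips.
.bd_forward <- function(n, b, d) {
  # each alive lineage owns an "open" edge in the growing timed edge table
  next_id <- 1L
  new_id <- function() { id <- next_id; next_id <<- next_id + 1L; id }
  root_id <- new_id()
  a1 <- new_id(); a2 <- new_id()
  alive <- data.frame(id = c(a1, a2), t0 = c(0, 0))
  edges <- data.frame(parent = c(root_id, root_id), child = c(a1, a2),
                      t0 = c(0, 0), t1 = NA_real_)
  t <- 0
  repeat {
    k <- nrow(alive)
    if (k == 0L) return(NULL)
    if (k == n) break
    t <- t + stats::rexp(1L, k * (b + d))
    i <- sample.int(k, 1L)
    if (stats::runif(1L) < b / (b + d)) {
      # speciation: close lineage i's edge, open two children
      id <- alive$id[i]
      edges$t1[edges$child == id] <- t
      c1 <- new_id(); c2 <- new_id()
      edges <- rbind(edges,
                     data.frame(parent = id, child = c(c1, c2),
                                t0 = t, t1 = NA_real_))
      alive <- rbind(alive[-i, , drop = FALSE],
                     data.frame(id = c(c1, c2), t0 = t))
    } else {
      # extinction: close the edge; extinct paths are pruned at conversion
      id <- alive$id[i]
      edges$t1[edges$child == id] <- t
      alive <- alive[-i, , drop = FALSE]
    }
  }
  # stop at the moment the n-th lineage appeared; extend tips by an
  # exponential grace period so terminal branches are not zero at the last
  # speciation (standard simple stop: draw the time to the next event)
  t_end <- t + stats::rexp(1L, n * (b + d))
  edges$t1[is.na(edges$t1)] <- t_end
  .edges_to_phylo(edges, root_id, alive$id)
}

# Convert the timed edge table to an ape phylo, pruning extinct paths and
# suppressing the unifurcations pruning creates.
.edges_to_phylo <- function(edges, root_id, tip_ids) {
  kids <- split(seq_len(nrow(edges)), edges$parent)
  build <- function(id, t0) {
    rows <- kids[[as.character(id)]]
    if (is.null(rows)) {                       # leaf
      if (!(id %in% tip_ids)) return(NULL)     # extinct
      return(list(label = id, len = NA))       # length filled by caller
    }
    subs <- list()
    for (r in rows) {
      s <- build(edges$child[r], edges$t0[r])
      if (is.null(s)) next
      len <- edges$t1[r] - edges$t0[r]
      s$len <- if (is.na(s$len)) len else s$len + len  # collapse unifurcation
      if (is.null(s$str)) {
        s$str <- as.character(s$label)
      }
      subs <- c(subs, list(s))
    }
    if (length(subs) == 0L) return(NULL)
    if (length(subs) == 1L) {
      # unifurcation: pass child through, caller adds this edge's length
      return(list(str = subs[[1L]]$str, len = subs[[1L]]$len, label = NULL))
    }
    inner <- paste(vapply(subs, function(s) paste0(s$str, ":", s$len),
                          character(1L)), collapse = ",")
    list(str = paste0("(", inner, ")"), len = NA, label = NULL)
  }
  top <- build(root_id, 0)
  if (is.null(top) || is.null(top$str) || substr(top$str, 1L, 1L) != "(")
    return(NULL)
  tr <- ape::read.tree(text = paste0(top$str, ";"))
  if (is.null(tr) || !ape::is.binary(tr)) return(NULL)
  tr$tip.label <- paste0("t", seq_along(tr$tip.label))
  tr
}
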