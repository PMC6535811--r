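#' Simulate chromosome-number evolution along a tree
#'
#' Exact Gillespie simulation of a continuous-time Markov chain over haploid
#' chromosome counts: the state jumps along every edge according to the
#' generator `Q`, starting from `root_count` at the root. Every realized event
#' is logged and classified (gain `i -> i+1`, loss `i -> i-1`, duplication
#' `i -> 2i`, demiduplication `i -> ~1.5i`, otherwise `other`).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param Q Generator matrix over counts; rows sum to 0, off-diagonals >= 0.
#'   `dimnames` give the states as integer counts (e.g. built by
#'   [build_rate_matrix()]).
#' @param root_count Haploid count at the root; must be in `Q`'s state space.
#' @param seed Integer seed.
#' @return A list: `tip_states` (named integer vector of haploid counts),
#'   `node_states` (states at every node, indexed by node id), and `events`
#'   (data.frame with `edge`, `time`, `from`, `to`, `type`).
#' @export
simulate_chromosome_counts <- function(tree, Q, root_count, seed = NULL) {
  states <- as.integer(rownames(Q))
  if (is.null(rownames(Q)) || anyNA(states))
    stop("Q must have integer state dimnames")
  if (any(abs(rowSums(Q)) > 1e-8)) stop("Q rows must sum to 0")
  offd <- Q; diag(offd) <- 0
  if (any(offd < 0)) stop("off-diagonal rates must be >= 0")
  if (!(root_count %in% states))
    stop("root_count ", root_count, " outside state space [",
         min(states), ", ", max(states), "]")
  with_seed(seed, {
    nn <- ape::Ntip(tree) + tree$Nnode
    node_state <- integer(nn)
    node_state[root_node(tree)] <- root_count
    ev <- list()
    pre <- .preorder_edges(tree)
    for (e in pre) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      s <- node_state[p]
      t_len <- tree$edge.length[e]
      pos <- 0
      repeat {
        i <- match(s, states)
        rate <- -Q[i, i]
        if (rate <= 0) break
        w <- stats::rexp(1L, rate)
        if (pos + w > t_len) break
        pos <- pos + w
        probs <- Q[i, ] / rate; probs[i] <- 0
        j <- sample.int(length(states), 1L, prob = probs)
        s_new <- states[j]
        ev[[length(ev) + 1L]] <-
          data.frame(edge = e, time = pos, from = s, to = s_new,
                     type = classify_chrom_event(s, s_new))
        s <- s_new
      }
      node_state[ch] <- s
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(edge = integer(0), time = numeric(0), from = integer(0),
                 to = integer(0), type = character(0))
    tips <- stats::setNames(node_state[seq_len(ape::Ntip(tree))],
                            tree$tip.label)
    list(tip_states = tips, node_states = node_state, events = events)
  })
}

#' @noRd
classify_chrom_event <- function(from, to) {
  if (to == from + 1L && to != 2L * from) "gain"
  else if (to == from - 1L) "loss"
  else if (to == 2L * from) "duplication"
  else if (to %in% c(floor(1.5 * from), ceiling(1.5 * from))) "demiduplication"
  else "other"
}

#' Edges in preorder (root outwards).
#' @noRd
.preorder_edges <- function(tree) {
  rev(ape::postorder(tree))
}
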