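#' Marginal ancestral chromosome numbers
#'
#' Standard two-pass conditioning: a postorder (pruning) pass computes the
#' likelihood of the data below each node, a preorder pass propagates the
#' likelihood of the data outside each node's subtree; their product,
#' normalized, is the marginal posterior over states at that node. The root
#' prior follows the fit: `"uniform"` averages over states, `"ml"` puts a
#' point mass on the root's maximum-likelihood state. The ML state is the
#' posterior argmax; ties break toward the smaller count.
#'
#' @param fit A [fit_chrom_model()] result.
#' @param tree,counts The data the model was fitted to.
#' @return A list: `posterior` (matrix, nodes x states), `ml_state` (named
#'   integer per node, tips included), `states`.
#' @export
chrom_ancestral_states <- function(fit, tree, counts) {
  Q <- build_rate_matrix(fit$spec, fit$par)
  states <- as.integer(rownames(Q))
  S <- length(states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  cl <- .chrom_prune(tree, counts, Q, need_P = TRUE)
  down <- cl$partial; P <- cl$P
  kids <- child_list(tree)
  prior <- rep(1 / S, S)
  if (fit$root_prior == "ml") {
    r <- down[[root_node(tree)]]
    prior <- rep(0, S); prior[which.max(r)] <- 1
  }
  # up[v, ] = (scaled) likelihood of data outside v's subtree given state at v
  up <- vector("list", nn)
  up[[root_node(tree)]] <- prior
  for (e in .preorder_edges(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    sibs <- setdiff(kids[[p]], ch)
    at_p <- up[[p]]
    for (b in sibs) {
      eb <- match(b, tree$edge[, 2L])
      at_p <- at_p * as.numeric(P[[eb]] %*% down[[b]])
    }
    u <- as.numeric(t(P[[e]]) %*% at_p)
    m <- max(u)
    if (m > 0) u <- u / m
    up[[ch]] <- u
  }
  post <- matrix(0, nn, S, dimnames = list(NULL, states))
  ml <- integer(nn)
  for (v in seq_len(nn)) {
    w <- up[[v]] * down[[v]]
    s <- sum(w)
    if (s <= 0) w <- rep(1 / S, S) else w <- w / s
    post[v, ] <- w
    top <- which(w == max(w))
    ml[v] <- states[min(top)]
  }
  list(posterior = post, ml_state = ml, states = states)
}

#' Expected chromosome-number changes by stochastic mapping
#'
#' Samples complete histories conditional on the tip data: node states are
#' drawn from the joint conditional distribution (root from its posterior,
#' then each child given its parent), and each branch history is simulated
#' conditional on its endpoints by rejection sampling of forward Gillespie
#' paths, falling back to uniformization when a branch exceeds the rejection
#' cap. Event counts are classified as in
#' [simulate_chromosome_counts()] and averaged over mappings.
#'
#' @param fit A [fit_chrom_model()] result.
#' @param tree,counts The fitted data.
#' @param n_mappings Number of stochastic maps (>= 1).
#' @param seed Integer seed.
#' @param reject_cap Forward-simulation attempts per branch before the
#'   uniformization fallback.
#' @return A list: `by_type` (named mean counts: gain, loss, duplication,
#'   demiduplication, other), `by_branch` (matrix, edges x types),
#'   `total` (mean total events), `flagged_branches` (edges that needed the
#'   fallback at least once).
#' @export
expected_chrom_changes <- function(fit, tree, counts, n_mappings = 100,
                                   seed = 1, reject_cap = 50) {
  stopifnot(n_mappings >= 1)
  Q <- build_rate_matrix(fit$spec, fit$par)
  states <- as.integer(rownames(Q))
  S <- length(states)
  ntip <- ape::Ntip(tree)
  cl <- .chrom_prune(tree, counts, Q, need_P = TRUE)
  down <- cl$partial; P <- cl$P
  asr <- chrom_ancestral_states(fit, tree, counts)
  types <- c("gain", "loss", "duplication", "demiduplication", "other")
  ne <- nrow(tree$edge)
  acc <- matrix(0, ne, length(types), dimnames = list(NULL, types))
  flagged <- logical(ne)
  # uniformization pieces (computed lazily)
  Omega <- max(-diag(Q)) * 1.05 + 1e-12
  R <- diag(S) + Q / Omega
  with_seed(seed, {
    for (m in seq_len(n_mappings)) {
      node_state <- integer(ntip + tree$Nnode)
      r <- root_node(tree)
      node_state[r] <- sample(states, 1L, prob = asr$posterior[r, ])
      for (e in .preorder_edges(tree)) {
        p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
        i <- match(node_state[p], states)
        w <- P[[e]][i, ] * down[[ch]]
        if (sum(w) <= 0) w <- P[[e]][i, ] + 1e-300
        j <- sample.int(S, 1L, prob = w)
        node_state[ch] <- states[j]
        h <- .bridge_history(Q, states, i, j, tree$edge.length[e],
                             reject_cap, Omega, R)
        if (h$fallback) flagged[e] <- TRUE
        if (length(h$from)) {
          for (k in seq_along(h$from)) {
            ty <- classify_chrom_event(h$from[k], h$to[k])
            acc[e, ty] <- acc[e, ty] + 1
          }
        }
      }
    }
  })
  by_branch <- acc / n_mappings
  by_type <- colSums(by_branch)
  list(by_type = by_type, by_branch = by_branch,
       total = sum(by_type), flagged_branches = which(flagged))
}

# Conditional CTMC path on [0, t] from state index i to j.
#' @noRd
.bridge_history <- function(Q, states, i, j, t_len, cap, Omega, R) {
  S <- length(states)
  for (a in seq_len(cap)) {
    s <- i; pos <- 0; from <- integer(0); to <- integer(0)
    ok <- TRUE
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      w <- stats::rexp(1L, rate)
      if (pos + w > t_len) break
      pos <- pos + w
      probs <- Q[s, ]; probs[s] <- 0
      s2 <- sample.int(S, 1L, prob = probs)
      from <- c(from, states[s]); to <- c(to, states[s2])
      s <- s2
      if (length(from) > 200L) { ok <- FALSE; break }
    }
    if (ok && s == j)
      return(list(from = from, to = to, fallback = FALSE))
  }
  # uniformization fallback: sample the number of self-transition-padded
  # jumps N | endpoints, then the intermediate states as a Markov bridge
  nmax <- 60L
  Rp <- vector("list", nmax + 1L)
  Rp[[1L]] <- diag(S)
  for (n in seq_len(nmax)) Rp[[n + 1L]] <- Rp[[n]] %*% R
  pois <- stats::dpois(0:nmax, Omega * t_len)
  pn <- vapply(0:nmax, function(n) pois[n + 1L] * Rp[[n + 1L]][i, j],
               numeric(1L))
  if (sum(pn) <= 0) return(list(from = integer(0), to = integer(0),
                                fallback = TRUE))
  N <- sample.int(nmax + 1L, 1L, prob = pn) - 1L
  path <- integer(N + 1L); path[1L] <- i
  if (N > 0) {
    for (k in seq_len(N - 1L)) {
      pr <- R[path[k], ] * vapply(seq_len(S), function(s)
        Rp[[N - k + 1L]][s, j], numeric(1L))
      path[k + 1L] <- sample.int(S, 1L, prob = pr)
    }
    path[N + 1L] <- j
  }
  keep <- which(diff(path) != 0L)
  list(from = states[path[keep]], to = states[path[keep + 1L]],
       fallback = TRUE)
}

#' Count detected chromosome-number changes
#'
#' Summarizes a stochastic-mapping result as a count of "detected" changes:
#' branch-and-type cells whose expected number of events reaches
#' `threshold`. The raw expectations in `$by_branch` remain the primary
#' output; the threshold (default 0.5, a majority-vote reading of the
#' mappings) only discretizes them for reporting.
#'
#' @param changes Result of [expected_chrom_changes()].
#' @param threshold Minimum expected events per branch and type.
#' @return Named integer vector of detected changes by event type, with the
#'   total as attribute `"total"`.
#' @export
count_chrom_changes <- function(changes, threshold = 0.5) {
  hits <- changes$by_branch >= threshold
  out <- colSums(hits)
  storage.mode(out) <- "integer"
  attr(out, "total") <- sum(out)
  out
}
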