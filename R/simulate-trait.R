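#' Specify a continuous-trait simulation
#'
#' @param model `"BM"`, `"OU"`, or `"lambda-BM"`.
#' @param sigma2 Brownian rate (trait^2 per unit branch length, > 0 unless the
#'   degenerate zero-variance limit is wanted).
#' @param alpha OU pull strength (1/time); required > 0 for `model = "OU"`.
#' @param optima Named numeric of regime optima; regime `"base"` applies from
#'   the root, other regimes start on `shift_edges`.
#' @param shift_edges Integer edge indices (rows of `tree$edge`) where the
#'   regime changes; regime names follow `names(optima)[-1]` in order.
#' @param lambda Pagel's lambda in `[0, 1]` for `model = "lambda-BM"`.
#' @param root_value Trait value at the root.
#' @param seed Integer seed.
#' @export
trait_sim_spec <- function(model = c("BM", "OU", "lambda-BM"), sigma2 = 1,
                           alpha = NULL, optima = c(base = 0),
                           shift_edges = integer(0), lambda = 1,
                           root_value = 0, seed = NULL) {
  model <- match.arg(model)
  if (model == "OU" && (is.null(alpha) || alpha <= 0))
    stop("OU model requires alpha > 0")
  if (model != "OU") alpha <- NULL
  stopifnot(sigma2 >= 0, lambda >= 0, lambda <= 1)
  if (length(shift_edges) && length(optima) != length(shift_edges) + 1L)
    stop("need one optimum per regime: base + one per shift edge")
  structure(list(model = model, sigma2 = sigma2, alpha = alpha,
                 optima = optima, shift_edges = as.integer(shift_edges),
                 lambda = lambda, root_value = root_value, seed = seed),
            class = "trait_sim_spec")
}

#' Simulate a continuous trait on a tree
#'
#' BM: Gaussian increments with variance `sigma2 * branch_length`.
#' lambda-BM: BM on the lambda-transformed covariance (off-diagonal shared
#' path lengths multiplied by `lambda`), drawn from the exact multivariate
#' normal. OU: exact per-edge transitions
#' `x_child ~ N(theta + (x_parent - theta) e^(-alpha t),
#' sigma2 (1 - e^(-2 alpha t)) / (2 alpha))` with regime-specific optima
#' switching on `shift_edges`.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param spec A [trait_sim_spec()].
#' @return A list: `tip_values` (named numeric) and `node_values` (all nodes;
#'   for lambda-BM only tips are drawn and `node_values` is `NA` for
#'   internals).
#' @export
simulate_trait <- function(tree, spec) {
  stopifnot(inherits(spec, "trait_sim_spec"))
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  with_seed(spec$seed, {
    if (spec$model == "lambda-BM") {
      C <- ape::vcv(tree)
      Cl <- C * spec$lambda
      diag(Cl) <- diag(C)
      L <- chol(spec$sigma2 * Cl + diag(1e-12, ntip))
      x <- spec$root_value + as.numeric(t(L) %*% stats::rnorm(ntip))
      tips <- stats::setNames(x, colnames(C))[tree$tip.label]
      node_values <- rep(NA_real_, nn)
      node_values[seq_len(ntip)] <- tips
      return(list(tip_values = tips, node_values = node_values))
    }
    # regime per edge: inherit from parent edge, override on shift edges
    regime <- rep(1L, nrow(tree$edge))
    if (length(spec$shift_edges)) {
      pre <- .preorder_edges(tree)
      edge_of_node <- match(seq_len(nn), tree$edge[, 2L])
      for (k in seq_along(spec$shift_edges))
        regime[spec$shift_edges[k]] <- k + 1L
      for (e in pre) {
        if (e %in% spec$shift_edges) next
        pe <- edge_of_node[tree$edge[e, 1L]]
        if (!is.na(pe)) regime[e] <- regime[pe]
      }
    }
    val <- numeric(nn)
    val[root_node(tree)] <- spec$root_value
    for (e in .preorder_edges(tree)) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      t_len <- tree$edge.length[e]
      if (spec$model == "BM") {
        val[ch] <- val[p] + stats::rnorm(1L, 0, sqrt(spec$sigma2 * t_len))
      } else {                                   # OU
        th <- spec$optima[[regime[e]]]
        a <- spec$alpha
        m <- th + (val[p] - th) * exp(-a * t_len)
        v <- spec$sigma2 * (1 - exp(-2 * a * t_len)) / (2 * a)
        val[ch] <- stats::rnorm(1L, m, sqrt(v))
      }
    }
    tips <- stats::setNames(val[seq_len(ntip)], tree$tip.label)
    list(tip_values = tips, node_values = val)
  })
}
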