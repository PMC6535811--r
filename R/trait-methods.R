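#' Brownian-motion ancestral state reconstruction with confidence intervals
#'
#' Two-pass best-linear-unbiased estimation under BM. The downpass
#' (Felsenstein pruning) combines child estimates precision-weighted; the
#' uppass folds in the rest of the tree, so every internal-node estimate
#' conditions on all tips. The root estimate equals the GLS phylogenetic mean
#' `(1' C^-1 x) / (1' C^-1 1)` and its variance `sigma2 / (1' C^-1 1)`.
#' `sigma2` is the ML estimate (sum of squared standardized contrasts over
#' n); the 95% CI is `estimate +/- 1.96 sqrt(var)`.
#'
#' @param tree Binary rooted `phylo` with branch lengths (resolve polytomies
#'   with zero-length edges first).
#' @param trait Named numeric (or [trait_vector()]) covering every tip.
#' @return A data.frame with one row per internal node: `node`, `estimate`,
#'   `se`, `ci_lower`, `ci_upper`; attributes `sigma2` (ML) and `root`
#'   (the root-row estimate).
#' @export
asr_bm <- function(tree, trait) {
  x <- .tip_values(tree, trait)
  ntip <- ape::Ntip(tree)
  if (ntip < 2L) stop("need at least two tips")
  if (sum(tree$edge.length) <= 0) stop("zero total tree depth")
  nn <- ntip + tree$Nnode
  kids <- child_list(tree)
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2L])
  # downpass: per-node estimate m and extra variance v (branch-length units)
  m <- numeric(nn); v <- rep(NA_real_, nn)
  m[seq_len(ntip)] <- x; v[seq_len(ntip)] <- 0
  contrasts2 <- numeric(0)
  po_par <- tree$edge[ape::postorder(tree), 1L]
  for (p in po_par[!duplicated(po_par, fromLast = TRUE)]) {
    ch <- kids[[p]]
    if (length(ch) != 2L) stop("polytomy at node ", p,
                               "; resolve with zero-length edges")
    Vc <- v[ch] + elen[as.character(ch)]
    w <- 1 / Vc
    m[p] <- sum(w * m[ch]) / sum(w)
    v[p] <- 1 / sum(w)
    contrasts2 <- c(contrasts2, (m[ch[1L]] - m[ch[2L]])^2 / sum(Vc))
  }
  sigma2 <- sum(contrasts2) / ntip                      # ML estimate
  # uppass: "outside" estimate (mu_up, vu) seen from above each node
  mu_up <- rep(NA_real_, nn); vu <- rep(NA_real_, nn)
  est <- numeric(nn); varu <- numeric(nn)
  r <- root_node(tree)
  est[r] <- m[r]; varu[r] <- v[r]
  for (e in .preorder_edges(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    sib <- setdiff(kids[[p]], ch)
    # combine sibling-down and parent-up views at p
    ms <- m[sib]; vs <- v[sib] + elen[as.character(sib)]
    if (!is.na(mu_up[p])) {
      w <- c(1 / vs, 1 / vu[p])
      mm <- c(ms, mu_up[p])
    } else {
      w <- 1 / vs; mm <- ms
    }
    mu <- sum(w * mm) / sum(w)
    vv <- 1 / sum(w)
    mu_up[ch] <- mu
    vu[ch] <- vv + elen[as.character(ch)]
    if (ch > ntip) {
      wd <- 1 / v[ch]; wu <- 1 / vu[ch]
      est[ch] <- (wd * m[ch] + wu * mu_up[ch]) / (wd + wu)
      varu[ch] <- 1 / (wd + wu)
    }
  }
  nodes <- (ntip + 1L):nn
  se <- sqrt(sigma2 * varu[nodes])
  out <- data.frame(node = nodes, estimate = est[nodes], se = se,
                    ci_lower = est[nodes] - 1.96 * se,
                    ci_upper = est[nodes] + 1.96 * se)
  attr(out, "sigma2") <- sigma2
  attr(out, "root") <- est[r]
  out
}

#' @noRd
.tip_values <- function(tree, trait) {
  x <- stats::setNames(as.numeric(trait), names(trait))
  missing <- setdiff(tree$tip.label, names(x))
  if (length(missing))
    stop("no trait value for tip \"", missing[1L], "\"")
  x[tree$tip.label]
}

#' Pagel's lambda with a likelihood-ratio test
#'
#' ML over the lambda transform (off-diagonal phylogenetic covariance scaled
#' by lambda, bounded above by the tallest-tip ratio); the p-value is a
#' likelihood-ratio test of the fitted lambda against lambda = 0 (no
#' phylogenetic covariance) on a chi-square(1) reference. Computation is
#' delegated to [phytools::phylosig()].
#'
#' @param tree Rooted `phylo` with branch lengths, >= 4 tips.
#' @param trait Named numeric covering every tip.
#' @return A list of class `signal_estimate`: `statistic = "lambda"`,
#'   `estimate`, `logL`, `logL0`, `p_value`, `n_species`.
#' @export
pagel_lambda <- function(tree, trait) {
  x <- .tip_values(tree, trait)
  if (length(x) < 4L) stop("need >= 4 tips")
  fit <- phytools::phylosig(tree, x, method = "lambda", test = TRUE)
  structure(list(statistic = "lambda", estimate = unname(fit$lambda),
                 logL = unname(fit$logL), logL0 = unname(fit$logL0),
                 p_value = unname(fit$P), n_species = length(x)),
            class = "signal_estimate")
}

#' Blomberg's K with a permutation test
#'
#' `K = (MSE0/MSE) / E[MSE0/MSE]`, where `MSE0` is the mean squared deviation
#' of tip values from the GLS phylogenetic mean, `MSE` the phylogenetically
#' corrected mean square (quadratic form in `C^-1`), and the expectation is
#' the covariance-trace formula
#' `(tr(C) - n / (1'C^-1 1)) / (n - 1)`; `E[K] = 1` under BM. The p-value
#' permutes tip labels: `p = (1 + #{perm ratio >= observed}) / (1 + n_perm)`
#' (one-tailed, add-one corrected), so `p >= 1 / (n_perm + 1)` always.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param trait Named numeric covering every tip.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed for the permutations.
#' @return A list of class `signal_estimate`: `statistic = "K"`, `estimate`,
#'   `p_value`, `n_permutations`, `n_species`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = 1) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  x <- .tip_values(tree, trait)
  n <- length(x)
  C <- ape::vcv(tree)[names(x), names(x)]
  Ci <- solve(C)
  one <- rep(1, n)
  denom_mu <- as.numeric(one %*% Ci %*% one)
  expected <- (sum(diag(C)) - n / denom_mu) / (n - 1)
  ratio <- function(z) {
    mu <- as.numeric(one %*% Ci %*% z) / denom_mu
    d <- z - mu
    mse0 <- sum(d^2) / (n - 1)
    mse <- as.numeric(d %*% Ci %*% d) / (n - 1)
    mse0 / mse
  }
  obs <- ratio(x)
  K <- obs / expected
  exceed <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (ratio(x[sample.int(n)]) >= obs) hits <- hits + 1L
    }
    hits
  })
  p <- (1 + exceed) / (1 + n_perm)
  structure(list(statistic = "K", estimate = K, p_value = p,
                 n_permutations = n_perm, n_species = n),
            class = "signal_estimate")
}

#' @export
print.signal_estimate <- function(x, ...) {
  cat("<signal_estimate>", x$statistic, "=", format(x$estimate, digits = 4),
      "| p =", format(x$p_value, digits = 4),
      "| n =", x$n_species, "\n")
  invisible(x)
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's standardized contrasts via [ape::pic()]: contrast
#' `(x_i - x_j) / sqrt(v_i + v_j)` at each internal node, with the parent
#' edge extended by `v_i v_j / (v_i + v_j)`.
#'
#' @param tree Binary rooted `phylo` with positive branch lengths.
#' @param trait Named numeric covering every tip.
#' @return A data.frame `node`, `contrast`, `variance` (the contrast's
#'   expected variance, i.e. the sum of adjusted branch lengths).
#' @export
pic_contrasts <- function(tree, trait) {
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    stop("tree has polytomies or is unrooted; resolve polytomies with ",
         "zero-length edges (ape::multi2di) before computing contrasts")
  x <- .tip_values(tree, trait)
  pc <- ape::pic(x, tree, var.contrasts = TRUE)
  data.frame(node = as.integer(rownames(pc)), contrast = pc[, 1L],
             variance = pc[, 2L], row.names = NULL)
}

#' Correlation between two traits via independent contrasts
#'
#' Regression of y-contrasts on x-contrasts through the origin (the standard
#' PIC test); F on `(1, m - 1)` degrees of freedom where `m` is the number
#' of contrasts.
#'
#' @param tree Binary rooted `phylo`.
#' @param trait_x,trait_y Named numeric vectors on the same tip set.
#' @param log_x,log_y Log10-transform a trait before computing contrasts.
#' @return A list: `F`, `p_value`, `slope`, `slope_se`, `df`, `n_contrasts`.
#' @export
pic_correlation <- function(tree, trait_x, trait_y,
                            log_x = FALSE, log_y = FALSE) {
  x <- .tip_values(tree, trait_x)
  y <- .tip_values(tree, trait_y)
  if (log_x) x <- log10(x)
  if (log_y) y <- log10(y)
  cx <- ape::pic(x, tree)
  cy <- ape::pic(y, tree)
  m <- length(cx)
  if (m < 3L) stop("fewer than 3 contrasts")
  fit <- stats::lm(cy ~ cx - 1)
  sm <- summary(fit)
  Fst <- unname(sm$fstatistic)
  list(F = Fst[1L], p_value = stats::pf(Fst[1L], Fst[2L], Fst[3L],
                                        lower.tail = FALSE),
       slope = unname(stats::coef(fit)[1L]),
       slope_se = sm$coefficients[1L, 2L],
       df = c(Fst[2L], Fst[3L]), n_contrasts = m)
}
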