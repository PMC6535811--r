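#' Pruning log-likelihood of chromosome counts under a CTMC
#'
#' Felsenstein pruning over the haploid state space with per-edge transition
#' matrices `exp(Q t)`. Root handling: `"ml"` maximizes over root states
#' (ChromEvol's default behaviour for reporting the best reconstruction);
#' `"uniform"` averages over a flat root prior.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param counts Named integer haploid counts for every tip (see
#'   [haploid_counts()] to convert diploid 2n data).
#' @param spec A [chrom_model_spec()] (its `$par` values are used), or a
#'   generator matrix with integer state dimnames.
#' @param par Optional parameter override passed to [build_rate_matrix()].
#' @param root_prior `"ml"` or `"uniform"`.
#' @return The log-likelihood (scalar). `-Inf` is possible for frozen chains
#'   with incompatible tips.
#' @export
chrom_likelihood <- function(tree, counts, spec, par = NULL,
                             root_prior = c("ml", "uniform")) {
  root_prior <- match.arg(root_prior)
  Q <- if (inherits(spec, "chrom_model_spec"))
    build_rate_matrix(spec, par) else spec
  states <- as.integer(rownames(Q))
  bad <- counts[!(counts %in% states)]
  if (length(bad))
    stop("tip count ", bad[1L], " outside state space [", min(states), ", ",
         max(states), "]; widen the state space (n_max)")
  cl <- .chrom_prune(tree, counts, Q)
  lroot <- cl$partial[[root_node(tree)]]
  lf <- cl$logfac[root_node(tree)]
  if (root_prior == "ml") {
    m <- max(lroot)
    if (m <= 0) return(-Inf)
    log(m) + lf
  } else {
    s <- mean(lroot)
    if (s <= 0) return(-Inf)
    log(s) + lf
  }
}

# Spectral decomposition of Q when numerically trustworthy (see
# transition_mats for why defective generators must be rejected).
#' @noRd
.q_decomp <- function(Q) {
  ev <- tryCatch(eigen(Q), error = function(e) NULL)
  if (is.null(ev) || !all(is.finite(Re(ev$values)))) return(NULL)
  Vi <- tryCatch(solve(ev$vectors), error = function(e) NULL)
  if (is.null(Vi) || !all(is.finite(abs(Vi)))) return(NULL)
  recon <- Re(ev$vectors %*% (ev$values * Vi))
  ok <- max(abs(recon - Q)) < 1e-9 * max(1, max(abs(Q))) &&
    max(abs(Vi)) * max(abs(ev$vectors)) < 1e12
  if (!ok) return(NULL)
  list(V = ev$vectors, Vi = Vi, values = ev$values)
}

# Postorder pruning with per-node rescaling. Returns per-node scaled partial
# likelihood vectors and the accumulated log scaling factor per node. The
# edge messages exp(Q t) v are computed spectrally (two matrix-vector
# products per edge) when Q is cleanly diagonalizable; otherwise full
# transition matrices are built once. Set `need_P = TRUE` to always get the
# per-edge transition matrices back (ancestral states, stochastic mapping).
#' @noRd
.chrom_prune <- function(tree, counts, Q, need_P = FALSE) {
  states <- as.integer(rownames(Q))
  S <- length(states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  if (ntip == 1L) {
    part <- rep(0, S); part[match(counts[[1L]], states)] <- 1
    pl <- vector("list", nn); pl[[1L]] <- part
    if (nn >= 2L) pl[[2L]] <- part
    return(list(partial = pl, logfac = rep(0, nn),
                P = list(), states = states))
  }
  dec <- .q_decomp(Q)
  P <- NULL
  if (is.null(dec) || need_P) P <- transition_mats(Q, tree$edge.length)
  partial <- vector("list", nn)
  logfac <- rep(0, nn)
  x <- counts[tree$tip.label]
  for (i in seq_len(ntip)) {
    v <- rep(0, S); v[match(x[[i]], states)] <- 1
    partial[[i]] <- v
  }
  po <- ape::postorder(tree)
  for (e in po) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    msg <- if (!is.null(dec)) {
      m0 <- Re(dec$V %*% (exp(dec$values * tree$edge.length[e]) *
                            (dec$Vi %*% partial[[ch]])))
      m0[m0 < 0] <- 0
      as.numeric(m0)
    } else {
      as.numeric(P[[e]] %*% partial[[ch]])
    }
    if (is.null(partial[[p]])) {
      partial[[p]] <- msg
      logfac[p] <- logfac[ch]
    } else {
      partial[[p]] <- partial[[p]] * msg
      logfac[p] <- logfac[p] + logfac[ch]
    }
    m <- max(partial[[p]])
    if (m > 0 && (m < 1e-100 || m > 1e100)) {
      partial[[p]] <- partial[[p]] / m
      logfac[p] <- logfac[p] + log(m)
    }
  }
  # final rescale at root for numerical sanity
  r <- root_node(tree)
  m <- max(partial[[r]])
  if (m > 0 && m < 1e-10) {
    partial[[r]] <- partial[[r]] / m
    logfac[r] <- logfac[r] + log(m)
  }
  list(partial = partial, logfac = logfac, P = P, states = states)
}

#' Fit a chromosome model by maximum likelihood
#'
#' Bounded multi-start optimization (`optim` L-BFGS-B): base rates are
#' optimized on the log scale, linear slopes on the raw scale within
#' `[-5, 5]`. The first start is a deterministic moderate point (all rates
#' 0.1, slopes 0); the remaining starts are drawn log-uniformly from
#' `[1e-4, 10]` (slopes from `[-0.5, 0.5]`). Deterministic given `seed`.
#'
#' @param tree,counts As in [chrom_likelihood()].
#' @param spec A [chrom_model_spec()].
#' @param n_starts Number of random starts (>= 1).
#' @param seed Integer seed.
#' @param root_prior Passed to [chrom_likelihood()].
#' @return An object of class `chrom_fit`: `spec`, `par` (ML values of the
#'   free parameters), `logL`, `k` (free-parameter count), `AIC`,
#'   `root_prior`, and a `data_id` fingerprint used by [compare_models()].
#' @export
fit_chrom_model <- function(tree, counts, spec, n_starts = 3, seed = 1,
                            root_prior = "ml") {
  stopifnot(inherits(spec, "chrom_model_spec"), n_starts >= 1)
  free <- spec$free
  is_slope <- grepl("_slope$", free)
  nf <- length(free)
  negll <- function(theta) {
    par <- numeric(nf); names(par) <- free
    par[!is_slope] <- exp(theta[!is_slope])
    par[is_slope] <- theta[is_slope]
    ll <- tryCatch(chrom_likelihood(tree, counts, spec, par, root_prior),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  lower <- ifelse(is_slope, -5, log(1e-8))
  upper <- ifelse(is_slope, 5, log(100))
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      th0 <- numeric(nf)
      if (s == 1L) {
        # deterministic moderate start; random log-uniform starts follow
        th0[!is_slope] <- log(0.1)
        th0[is_slope] <- 0
      } else {
        th0[!is_slope] <- stats::runif(sum(!is_slope), log(1e-4), log(10))
        th0[is_slope] <- stats::runif(sum(is_slope), -0.5, 0.5)
      }
      fit <- tryCatch(
        stats::optim(th0, negll, method = "L-BFGS-B", lower = lower,
                     upper = upper,
                     control = list(maxit = 200, factr = 1e9)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (fit$convergence != 0 && nf > 1L) {
        # line searches can abort on numerical noise in the matrix
        # exponential; polish derivative-free from where we stopped
        nm <- tryCatch(
          stats::optim(fit$par, negll, method = "Nelder-Mead",
                       control = list(maxit = 300)),
          error = function(e) NULL)
        if (!is.null(nm) && nm$value < fit$value &&
            all(nm$par >= lower) && all(nm$par <= upper)) fit <- nm
      }
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  if (is.null(best) || best$value >= 1e10)
    stop("non-finite likelihood at all starts; widen the state space")
  par <- numeric(nf); names(par) <- free
  par[!is_slope] <- exp(best$par[!is_slope])
  par[is_slope] <- best$par[is_slope]
  logL <- -best$value
  k <- nf
  structure(list(spec = spec, par = par, logL = logL, k = k,
                 AIC = 2 * k - 2 * logL, root_prior = root_prior,
                 data_id = .chrom_data_id(tree, counts)),
            class = "chrom_fit")
}

#' @noRd
.chrom_data_id <- function(tree, counts) {
  paste(c(sort(tree$tip.label), as.character(counts[sort(names(counts))]),
          format(sum(tree$edge.length), digits = 10)), collapse = "|")
}

#' @export
print.chrom_fit <- function(x, ...) {
  cat("<chrom_fit>", x$spec$name, "| logL =", format(x$logL, digits = 6),
      "| k =", x$k, "| AIC =", format(x$AIC, digits = 6), "\n")
  print(x$par)
  invisible(x)
}

#' Compare fitted chromosome models by AIC and Akaike weights
#'
#' `weight_m = exp(-Delta_m / 2) / sum(exp(-Delta / 2))` with
#' `Delta_m = AIC_m - min(AIC)`.
#'
#' @param fits List of [fit_chrom_model()] results on identical data.
#' @return A data.frame (`model`, `k`, `logL`, `AIC`, `delta_AIC`, `weight`)
#'   sorted by ascending AIC.
#' @export
compare_models <- function(fits) {
  ids <- vapply(fits, function(f) f$data_id, character(1L))
  if (length(unique(ids)) != 1L)
    stop("fits were computed on different data")
  aic <- vapply(fits, function(f) f$AIC, numeric(1L))
  delta <- aic - min(aic)
  w <- exp(-delta / 2); w <- w / sum(w)
  out <- data.frame(
    model = vapply(fits, function(f) f$spec$name, character(1L)),
    k = vapply(fits, function(f) f$k, numeric(1L)),
    logL = vapply(fits, function(f) f$logL, numeric(1L)),
    AIC = aic, delta_AIC = delta, weight = w)
  out <- out[order(out$AIC), , drop = FALSE]
  rownames(out) <- NULL
  out
}
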