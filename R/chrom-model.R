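#' Specify a chromosome-number evolution model
#'
#' A CTMC over haploid counts `n_min..n_max` with per-state rates
#' `gain_i = max(0, gain + gain_slope * (i - n_min))` for `i -> i+1`,
#' `loss_i = max(0, loss + loss_slope * (i - n_min))` for `i -> i-1`
#' (linear models free the slopes; constant models pin them at 0),
#' whole-genome duplication `i -> 2i` at rate `dupl`, and demiduplication
#' `i -> 1.5i` at rate `demi` (odd `i` splits the rate evenly between
#' `(3i-1)/2` and `(3i+1)/2`). `demi = "linked"` ties the demiduplication
#' rate to `dupl` (one shared parameter, as in the ChromEvol "demi" setting).
#'
#' @param name Model label.
#' @param free Character vector of free parameters, a subset of
#'   `c("gain", "loss", "gain_slope", "loss_slope", "dupl", "demi")`.
#' @param demi_linked Tie `demi` to `dupl` (adds no free parameter).
#' @param n_min,n_max Haploid state-space bounds (`n_min >= 1`).
#' @param fixed Named numeric of fixed parameter values (defaults 0).
#' @return An object of class `chrom_model_spec`.
#' @export
chrom_model_spec <- function(name, free,
                             demi_linked = FALSE, n_min = 1, n_max = 50,
                             fixed = NULL) {
  all_par <- c("gain", "loss", "gain_slope", "loss_slope", "dupl", "demi")
  stopifnot(all(free %in% all_par), n_min >= 1, n_max > n_min)
  if (demi_linked && "demi" %in% free)
    stop("demi cannot be both free and linked to dupl")
  par <- stats::setNames(rep(0, length(all_par)), all_par)
  if (!is.null(fixed)) par[names(fixed)] <- fixed
  structure(list(name = name, free = free, demi_linked = demi_linked,
                 n_min = as.integer(n_min), n_max = as.integer(n_max),
                 par = par),
            class = "chrom_model_spec")
}

#' The default ten-model comparison battery
#'
#' Constant-rate and state-linear variants of dysploidy (gain/loss) with and
#' without polyploidy (`dupl`) and demipolyploidy (`demi`, either tied to
#' `dupl` or free), plus a duplication-only and a linear gain-only model.
#'
#' @param n_min,n_max Haploid state-space bounds applied to every model.
#' @return A named list of [chrom_model_spec()] objects.
#' @export
chrom_model_battery <- function(n_min = 1, n_max = 50) {
  mk <- function(name, free, linked = FALSE)
    chrom_model_spec(name, free, demi_linked = linked,
                     n_min = n_min, n_max = n_max)
  list(
    CONST            = mk("CONST", c("gain", "loss")),
    CONST_DUPL       = mk("CONST_DUPL", c("gain", "loss", "dupl")),
    CONST_DUPL_DEMIL = mk("CONST_DUPL_DEMIL", c("gain", "loss", "dupl"),
                          linked = TRUE),
    CONST_DUPL_DEMI  = mk("CONST_DUPL_DEMI", c("gain", "loss", "dupl", "demi")),
    LINEAR           = mk("LINEAR", c("gain", "loss", "gain_slope",
                                      "loss_slope")),
    LINEAR_DUPL      = mk("LINEAR_DUPL", c("gain", "loss", "gain_slope",
                                           "loss_slope", "dupl")),
    LINEAR_DUPL_DEMIL = mk("LINEAR_DUPL_DEMIL",
                           c("gain", "loss", "gain_slope", "loss_slope",
                             "dupl"), linked = TRUE),
    LINEAR_DUPL_DEMI = mk("LINEAR_DUPL_DEMI",
                          c("gain", "loss", "gain_slope", "loss_slope",
                            "dupl", "demi")),
    DUPL_ONLY        = mk("DUPL_ONLY", "dupl"),
    LINEAR_GAIN_DUPL = mk("LINEAR_GAIN_DUPL", c("gain", "gain_slope", "dupl"))
  )
}

#' Build the generator matrix of a chromosome model
#'
#' @param spec A [chrom_model_spec()]; its `$par` values are used.
#' @param par Optional named numeric overriding `spec$par` (fitted values).
#' @return A square generator matrix with integer state dimnames; rows sum
#'   to 0. Duplication mass from states with `2i > n_max` is routed to
#'   `n_max` (absorbing boundary) so the generator stays proper; self-loops
#'   are dropped.
#' @export
build_rate_matrix <- function(spec, par = NULL) {
  p <- spec$par
  if (!is.null(par)) p[names(par)] <- par
  if (spec$demi_linked) p[["demi"]] <- p[["dupl"]]
  if (p[["gain"]] < 0 || p[["loss"]] < 0 || p[["dupl"]] < 0 || p[["demi"]] < 0)
    stop("negative base rate")
  states <- spec$n_min:spec$n_max
  S <- length(states)
  Q <- matrix(0, S, S, dimnames = list(states, states))
  add <- function(i, j, r) {
    if (r > 0 && j >= 1L && j <= S && j != i) Q[i, j] <<- Q[i, j] + r
  }
  for (k in seq_len(S)) {
    i <- states[k]
    gain_i <- max(0, p[["gain"]] + p[["gain_slope"]] * (i - spec$n_min))
    loss_i <- max(0, p[["loss"]] + p[["loss_slope"]] * (i - spec$n_min))
    add(k, k + 1L, gain_i)
    add(k, k - 1L, loss_i)
    if (p[["dupl"]] > 0) {
      j <- min(2L * i, spec$n_max)
      add(k, match(j, states), p[["dupl"]])
    }
    if (p[["demi"]] > 0) {
      if (i %% 2L == 0L) {
        j <- min(as.integer(1.5 * i), spec$n_max)
        add(k, match(j, states), p[["demi"]])
      } else {
        j1 <- min((3L * i - 1L) %/% 2L, spec$n_max)
        j2 <- min((3L * i + 1L) %/% 2L, spec$n_max)
        add(k, match(j1, states), p[["demi"]] / 2)
        add(k, match(j2, states), p[["demi"]] / 2)
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Convert diploid counts to the haploid model scale
#'
#' @param counts2n Named integer vector of diploid (2n) counts.
#' @return Named haploid counts. Odd 2n values are rejected: the model state
#'   is the haploid number n = 2n/2.
#' @export
haploid_counts <- function(counts2n) {
  x <- as.numeric(counts2n)
  if (any(x %% 2 != 0))
    stop("odd diploid count(s): ",
         paste(names(counts2n)[x %% 2 != 0], collapse = ", "),
         "; the model needs even 2n (haploid n = 2n/2)")
  stats::setNames(as.integer(x / 2), names(counts2n))
}

# Transition probability matrices exp(Q t) for all edges. Fast path: one
# eigendecomposition of Q reused across edges, accepted only when the
# reconstruction is numerically faithful (generators with repeated
# eigenvalues -- e.g. constant single-rate models -- are defective and fail
# eigen-based exponentials, silently so for ape::matexpo). Fallback:
# uniformization with shared jump-matrix powers, or scaling-and-squaring
# when the uniformization series would be too long.
#' @noRd
transition_mats <- function(Q, times) {
  S <- nrow(Q)
  out <- vector("list", length(times))
  ev <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eig <- FALSE
  Vi <- NULL
  if (!is.null(ev) && all(is.finite(Re(ev$values)))) {
    Vi <- tryCatch(solve(ev$vectors), error = function(e) NULL)
    if (!is.null(Vi) && all(is.finite(abs(Vi)))) {
      recon <- Re(ev$vectors %*% (ev$values * Vi))
      use_eig <- max(abs(recon - Q)) < 1e-9 * max(1, max(abs(Q))) &&
        max(abs(Vi)) * max(abs(ev$vectors)) < 1e12
    }
  }
  if (use_eig) {
    for (k in seq_along(times)) {
      P <- Re(ev$vectors %*% (exp(ev$values * times[k]) * Vi))
      P[P < 0] <- 0
      out[[k]] <- P / rowSums(P)
    }
    return(out)
  }
  Omega <- max(-diag(Q))
  if (Omega <= 0) {
    for (k in seq_along(times)) out[[k]] <- diag(S)
    return(out)
  }
  Kmax <- stats::qpois(1 - 1e-12, Omega * max(times)) + 5L
  if (Kmax <= 600L) {
    R <- diag(S) + Q / Omega
    Rk <- vector("list", Kmax + 1L)
    Rk[[1L]] <- diag(S)
    for (n in seq_len(Kmax)) Rk[[n + 1L]] <- Rk[[n]] %*% R
    for (k in seq_along(times)) {
      w <- stats::dpois(0:Kmax, Omega * times[k])
      P <- matrix(0, S, S)
      for (n in which(w > 1e-16)) P <- P + w[n] * Rk[[n]]
      P[P < 0] <- 0
      out[[k]] <- P / rowSums(P)
    }
  } else {
    for (k in seq_along(times)) {
      P <- .expm_ss(Q * times[k])
      P[P < 0] <- 0
      out[[k]] <- P / rowSums(P)
    }
  }
  out
}

# Scaling-and-squaring Taylor matrix exponential (any square matrix).
#' @noRd
.expm_ss <- function(A) {
  nrm <- max(rowSums(abs(A)))
  j <- max(0L, ceiling(log2(max(nrm, 1e-300) / 0.5)))
  B <- A / 2^j
  S <- diag(nrow(A))
  term <- S
  for (i in 1:25) {
    term <- term %*% B / i
    S <- S + term
  }
  for (i in seq_len(j)) S <- S %*% S
  S
}
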