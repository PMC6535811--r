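test_that("rate matrices encode gain, duplication and demiduplication", {
  Qg <- build_rate_matrix(chrom_model_spec("g", "gain", n_min = 1,
                                           n_max = 4), c(gain = 1))
  expect_equal(Qg["1", "2"], 1)
  expect_equal(Qg["2", "3"], 1)
  expect_equal(Qg["3", "4"], 1)
  expect_equal(Qg["4", "4"], 0)            # absorbing boundary

  Qd <- build_rate_matrix(chrom_model_spec("d", "dupl", n_min = 1,
                                           n_max = 10), c(dupl = 0.5))
  expect_equal(Qd["3", "6"], 0.5)

  Qm <- build_rate_matrix(chrom_model_spec("m", "demi", n_min = 1,
                                           n_max = 10), c(demi = 1))
  expect_equal(Qm["5", "7"], 0.5)          # odd state splits 1.5i evenly
  expect_equal(Qm["5", "8"], 0.5)
  expect_equal(Qm["4", "6"], 1)            # even state: single target

  # every generator row sums to zero
  for (Q in list(Qg, Qd, Qm)) expect_true(all(abs(rowSums(Q)) < 1e-12))

  # duplication mass beyond n_max routes to n_max
  Qc <- build_rate_matrix(chrom_model_spec("c", "dupl", n_min = 1,
                                           n_max = 8), c(dupl = 1))
  expect_equal(Qc["5", "8"], 1)

  expect_error(build_rate_matrix(chrom_model_spec("b", "gain"),
                                 c(gain = -1)), "negative")
})

test_that("linear rates clamp at zero", {
  sp <- chrom_model_spec("lin", c("gain", "gain_slope"), n_min = 1,
                         n_max = 6)
  Q <- build_rate_matrix(sp, c(gain = 1, gain_slope = -0.4))
  expect_equal(Q["1", "2"], 1)             # 1 + (-0.4)*0
  expect_equal(Q["2", "3"], 0.6)
  expect_equal(Q["4", "5"], 0)             # clamped: 1 - 1.2 < 0
})

test_that("exp(Qt) rows sum to one for fitted generators", {
  set.seed(5)
  for (i in 1:10) {
    Q <- random_generator(sample(3:8, 1L), rate_scale = 2)
    P <- paleowgd:::transition_mats(Q, c(0.1, 1, 5))
    for (Pt in P) {
      expect_true(all(abs(rowSums(Pt) - 1) < 1e-10))
      expect_true(all(Pt >= 0))
    }
  }
})

test_that("transition matrices are exact for defective generators", {
  # constant single-rate generators have repeated eigenvalues; eigen-based
  # exponentials silently fail there, so check against scaling-and-squaring
  Q <- build_rate_matrix(chrom_model_spec("g", "gain", n_min = 1,
                                          n_max = 30), c(gain = 0.3))
  P <- paleowgd:::transition_mats(Q, 0.5)[[1L]]
  expect_equal(P, paleowgd:::.expm_ss(Q * 0.5), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("pruning likelihood equals exhaustive enumeration", {
  set.seed(7)
  topologies <- c("((A:0.3,B:0.5):0.2,C:0.7);",
                  "(((A:0.2,B:0.4):0.3,C:0.5):0.1,D:0.9);",
                  "((A:0.6,B:0.1):0.4,(C:0.2,D:0.3):0.5);")
  for (top in topologies) {
    tr <- read_newick(top)
    for (S in c(3, 5)) {
      Q <- random_generator(S)
      cts <- stats::setNames(sample(1:S, ape::Ntip(tr), replace = TRUE),
                             tr$tip.label)
      ll <- chrom_likelihood(tr, cts, Q, root_prior = "uniform")
      oracle <- oracle_ctmc_loglik(tr, cts, Q, root_prior = "uniform")
      expect_equal(ll, oracle, tolerance = 1e-8)
    }
  }
})

test_that("frozen chains and degenerate trees behave as limits demand", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  states <- 1:4
  Q0 <- matrix(0, 4, 4, dimnames = list(states, states))
  expect_equal(chrom_likelihood(tr, c(A = 2L, B = 2L, C = 2L), Q0), 0)
  expect_equal(chrom_likelihood(tr, c(A = 2L, B = 3L, C = 2L), Q0), -Inf)
  expect_error(chrom_likelihood(tr, c(A = 9L, B = 2L, C = 2L), Q0),
               "widen")
  # single tip, zero-length tree
  tip1 <- ape::read.tree(text = "(A:0);")
  expect_equal(chrom_likelihood(tip1, c(A = 2L), Q0), 0)
})

test_that("model fitting is deterministic and respects nesting", {
  tr <- fixture_tree(50, seed = 21, depth = 3)
  Q <- build_rate_matrix(chrom_model_spec("t", c("gain", "loss"),
                                          n_max = 30),
                         c(gain = 0.8, loss = 0.5))
  sim <- simulate_chromosome_counts(tr, Q, 8, seed = 2)
  spec_c <- chrom_model_spec("CONST", c("gain", "loss"), n_max = 25)
  f1 <- fit_chrom_model(tr, sim$tip_states, spec_c, n_starts = 2, seed = 5)
  f2 <- fit_chrom_model(tr, sim$tip_states, spec_c, n_starts = 2, seed = 5)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$logL, f2$logL)
  expect_equal(f1$AIC, 2 * f1$k - 2 * f1$logL)

  spec_l <- chrom_model_spec("LINEAR", c("gain", "loss", "gain_slope",
                                         "loss_slope"), n_max = 25)
  fl <- fit_chrom_model(tr, sim$tip_states, spec_l, n_starts = 3, seed = 5)
  expect_gte(fl$logL, f1$logL - 1e-6)
})

test_that("Akaike weights follow the closed form", {
  mk <- function(name, aic, k) structure(
    list(spec = list(name = name), par = numeric(0), logL = (2 * k - aic) / 2,
         k = k, AIC = aic, root_prior = "ml", data_id = "d"),
    class = "chrom_fit")
  one <- compare_models(list(mk("a", 100, 2)))
  expect_equal(one$weight, 1)
  two <- compare_models(list(mk("a", 100, 2), mk("b", 100, 3)))
  expect_equal(two$weight, c(0.5, 0.5))
  three <- compare_models(list(mk("a", 10, 2), mk("b", 12, 3),
                               mk("c", 14, 4)))
  expect_equal(three$weight, c(0.66524096, 0.24472847, 0.09003057),
               tolerance = 1e-6)
  expect_error(compare_models(list(mk("a", 10, 2),
                                   structure(list(spec = list(name = "x"),
                                                  AIC = 1, k = 1, logL = 0,
                                                  data_id = "other"),
                                             class = "chrom_fit"))),
               "different data")
})

test_that("the ten-model battery has the documented structure", {
  bat <- chrom_model_battery(n_min = 1, n_max = 20)
  expect_length(bat, 10L)
  ks <- vapply(bat, function(s) length(s$free), integer(1L))
  expect_equal(unname(ks[c("CONST", "CONST_DUPL", "LINEAR",
                           "LINEAR_DUPL_DEMI", "DUPL_ONLY")]),
               c(2L, 3L, 4L, 6L, 1L))
  # linked-demi models tie demi to dupl in the generator
  Q <- build_rate_matrix(bat$CONST_DUPL_DEMIL,
                         c(gain = 1, loss = 1, dupl = 0.4))
  expect_equal(Q["4", "8"], 0.4)   # duplication
  expect_equal(Q["4", "6"], 0.4)   # demiduplication at the same rate
})

test_that("marginal ancestral states match exhaustive posteriors", {
  tr <- read_newick("((A:0.4,B:0.6):0.3,C:0.8);")
  cts <- c(A = 2L, B = 3L, C = 1L)
  states <- 1:4
  spec <- chrom_model_spec("gl", c("gain", "loss"), n_min = 1, n_max = 4)
  spQ <- build_rate_matrix(spec, c(gain = 0.7, loss = 0.4))
  fitQ <- structure(list(spec = spec, par = c(gain = 0.7, loss = 0.4),
                         root_prior = "uniform"), class = "chrom_fit")
  asrQ <- chrom_ancestral_states(fitQ, tr, cts)
  PQ <- lapply(tr$edge.length, function(t) paleowgd:::.expm_ss(spQ * t))
  # enumerate both internal nodes (4 = root, 5 = mrca(A, B)) generically
  tipstate <- match(cts[tr$tip.label], states)
  postQ <- matrix(0, 2, 4); totQ <- 0
  for (r in states) for (v in states) {
    node_state <- c(tipstate, r, v)
    w <- 0.25
    for (e in seq_len(nrow(tr$edge)))
      w <- w * PQ[[e]][node_state[tr$edge[e, 1L]],
                       node_state[tr$edge[e, 2L]]]
    postQ[1L, r] <- postQ[1L, r] + w
    postQ[2L, v] <- postQ[2L, v] + w
    totQ <- totQ + w
  }
  postQ <- postQ / totQ
  expect_equal(unname(asrQ$posterior[4L, ]), postQ[1L, ], tolerance = 1e-8)
  expect_equal(unname(asrQ$posterior[5L, ]), postQ[2L, ], tolerance = 1e-8)
  # posteriors normalize at every node
  expect_true(all(abs(rowSums(asrQ$posterior) - 1) < 1e-10))
})

test_that("frozen-chain reconstruction is certain everywhere", {
  tr <- fixture_tree(8, seed = 3)
  states <- 14:18
  Q0 <- matrix(0, 5, 5, dimnames = list(states, states))
  spec <- chrom_model_spec("z", "gain", n_min = 14, n_max = 18)
  fit <- structure(list(spec = spec, par = c(gain = 0),
                        root_prior = "uniform"), class = "chrom_fit")
  cts <- stats::setNames(rep(16L, 8), tr$tip.label)
  asr <- chrom_ancestral_states(fit, tr, cts)
  expect_true(all(asr$ml_state == 16L))
  expect_true(all(abs(apply(asr$posterior, 1, max) - 1) < 1e-12))
})

test_that("stochastic mapping recovers simulated event counts", {
  tr <- fixture_tree(40, seed = 2, depth = 3)
  spec <- chrom_model_spec("g", "gain", n_min = 1, n_max = 30)
  Q <- build_rate_matrix(spec, c(gain = 0.5))
  nrep <- 30
  true_counts <- exp_counts <- numeric(nrep)
  for (i in seq_len(nrep)) {
    sim <- simulate_chromosome_counts(tr, Q, 6, seed = 50 + i)
    fit <- structure(list(spec = spec, par = c(gain = 0.5),
                          root_prior = "uniform"), class = "chrom_fit")
    ec <- expected_chrom_changes(fit, tr, sim$tip_states, n_mappings = 20,
                                 seed = i)
    true_counts[i] <- nrow(sim$events)
    exp_counts[i] <- ec$total
    expect_true(all(ec$by_branch >= 0))
    expect_equal(sum(ec$by_branch), ec$total, tolerance = 1e-10)
  }
  se <- stats::sd(true_counts - exp_counts) / sqrt(nrep)
  expect_lt(abs(mean(true_counts - exp_counts)), 3 * se + 1e-9)

  # frozen chain: zero expected changes
  states <- 1:3
  Q0 <- matrix(0, 3, 3, dimnames = list(states, states))
  sp0 <- chrom_model_spec("z", "gain", n_min = 1, n_max = 3)
  fit0 <- structure(list(spec = sp0, par = c(gain = 0),
                         root_prior = "uniform"), class = "chrom_fit")
  ct0 <- stats::setNames(rep(2L, ape::Ntip(tr)), tr$tip.label)
  ec0 <- expected_chrom_changes(fit0, tr, ct0, n_mappings = 5, seed = 1)
  expect_equal(ec0$total, 0)
})

test_that("diploid inputs convert to haploid states, odd 2n rejected", {
  expect_equal(unname(haploid_counts(c(A = 30, B = 36))), c(15L, 18L))
  expect_error(haploid_counts(c(A = 31)), "odd diploid")
})

test_that("detected-change counting thresholds the mapping expectations", {
  ec <- list(by_branch = matrix(c(0.9, 0.1, 0.6, 0.4), 2, 2,
                                dimnames = list(NULL, c("gain", "loss"))))
  out <- count_chrom_changes(ec, threshold = 0.5)
  expect_equal(as.integer(out), c(1L, 1L))
  expect_equal(attr(out, "total"), 2L)
})
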