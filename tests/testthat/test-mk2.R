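test_that("transition matrix has the closed-form limits", {
  expect_equal(mk2_transition_matrix(0.7, 0.12, 0),
               diag(2), ignore_attr = TRUE)
  # symmetric rates equilibrate to (0.5, 0.5)
  q <- 0.3
  P <- mk2_transition_matrix(q, q, 1e6 / q)
  expect_equal(as.vector(P), rep(0.5, 4), tolerance = 1e-12)
  expect_error(mk2_transition_matrix(0.1, 0.1, -1), ">= 0")
  expect_error(mk2_transition_matrix(0, 0.1, 1), "> 0")
})

test_that("transition matrix matches a matrix-exponential oracle", {
  P <- mk2_transition_matrix(0.2, 0.1, 3)
  Q <- matrix(c(-0.2, 0.1, 0.2, -0.1), 2, 2)
  expect_lt(max(abs(P - as.matrix(Matrix::expm(Q * 3)))), 1e-10)
})

test_that("transition rows sum to one over random rates and times", {
  set.seed(1)
  for (k in 1:1000) {
    g <- exp(stats::runif(1, -8, 2))
    l <- exp(stats::runif(1, -8, 2))
    t <- stats::runif(1, 0, 300)
    P <- mk2_transition_matrix(g, l, t)
    expect_equal(rowSums(P), c(1, 1), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("two-tip likelihood matches the hand closed form", {
  q <- 0.3
  t <- 1.2
  tr <- read_chronogram(text = "(A:1.2,B:1.2);")
  P <- mk2_transition_matrix(q, q, t)
  expect_equal(mk2_loglik(tr, c(A = 0, B = 0), q, q, root_prior = "equal"),
               log(0.5 * P[1, 1]^2 + 0.5 * P[2, 1]^2), tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration on small random trees", {
  set.seed(2)
  for (k in 1:40) {
    n <- sample(3:6, 1)
    tr <- sim_chronogram(n, depth = stats::runif(1, 1, 50))
    x <- random_states(tr, p_missing = ifelse(k %% 3 == 0, 0.25, 0))
    g <- exp(stats::runif(1, -4, 0))
    l <- exp(stats::runif(1, -4, 0))
    prior <- sample(c("equal", "stationary"), 1)
    expect_equal(mk2_loglik(tr, x, g, l, root_prior = prior),
                 enum_loglik(tr, x, g, l, root_prior = prior),
                 tolerance = 1e-10)
  }
})

test_that("constrained pruning equals constrained enumeration", {
  set.seed(3)
  for (k in 1:15) {
    tr <- sim_chronogram(5, depth = 10)
    x <- random_states(tr)
    cons <- stats::setNames(sample(0:1, 2, replace = TRUE), c("6", "8"))
    g <- 0.1; l <- 0.25
    expect_equal(mk2_loglik(tr, x, g, l, constraints = cons,
                            root_prior = "stationary"),
                 enum_loglik(tr, x, g, l, constraints = cons,
                             root_prior = "stationary"),
                 tolerance = 1e-10)
  }
})

test_that("missing tips marginalize: likelihood sums over their states", {
  set.seed(4)
  tr <- sim_chronogram(6, depth = 20)
  x <- random_states(tr)
  x[3] <- NA
  x0 <- x; x0[3] <- 0L
  x1 <- x; x1[3] <- 1L
  lnl <- mk2_loglik(tr, x, 0.05, 0.1)
  expect_equal(lnl,
               log(exp(mk2_loglik(tr, x0, 0.05, 0.1)) +
                   exp(mk2_loglik(tr, x1, 0.05, 0.1))),
               tolerance = 1e-10)
})

test_that("root-fixed likelihoods decompose the unconstrained one", {
  set.seed(5)
  tr <- sim_chronogram(8, depth = 30)
  x <- random_states(tr)
  root <- as.character(length(tr$tip.label) + 1L)
  l <- mk2_loglik(tr, x, 0.04, 0.09)
  l0 <- mk2_loglik(tr, x, 0.04, 0.09, constraints = stats::setNames(0, root))
  l1 <- mk2_loglik(tr, x, 0.04, 0.09, constraints = stats::setNames(1, root))
  expect_equal(l, log(exp(l0) + exp(l1)), tolerance = 1e-10)
  expect_lte(l0, l + 1e-10)
  expect_lte(l1, l + 1e-10)
})

test_that("likelihood errors are informative", {
  tr <- read_chronogram(text = "((A:1,B:1):1,C:2);")
  expect_error(mk2_loglik(tr, c(A = NA, B = NA, C = NA), 0.1, 0.1),
               "non-missing")
  expect_error(mk2_loglik(tr, c(A = 1, B = 0, C = 0), 0.1, 0.1,
                          constraints = c(A = 0)), "contradicts")
})

test_that("tip-state probabilities sum to one over all configurations", {
  set.seed(6)
  tr <- sim_chronogram(5, depth = 15)
  for (prior in c("equal", "stationary")) {
    tot <- 0
    for (cfg in 0:31) {
      x <- stats::setNames(as.integer(intToBits(cfg))[1:5], tr$tip.label)
      tot <- tot + exp(mk2_loglik(tr, x, 0.07, 0.21, root_prior = prior))
    }
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("lnL is invariant to re-rooting under the stationary prior", {
  set.seed(7)
  for (k in 1:5) {
    tr <- sim_chronogram(sample(5:9, 1), depth = 20)
    x <- random_states(tr)
    g <- exp(stats::runif(1, -3, -0.5))
    l <- exp(stats::runif(1, -3, -0.5))
    ref <- mk2_loglik(tr, x, g, l, root_prior = "stationary")
    for (node in sample(2:(length(tr$tip.label) + tr$Nnode), 3)) {
      tr2 <- try(phytools::reroot(tr, node,
                                  position = 0.3 * tr$edge.length[
                                    which(tr$edge[, 2] == node)]),
                 silent = TRUE)
      if (inherits(tr2, "try-error")) next
      expect_equal(mk2_loglik(tr2, x, g, l, root_prior = "stationary"),
                   ref, tolerance = 1e-9)
    }
  }
})

test_that("marginals equal node-fixing likelihood ratios everywhere", {
  set.seed(8)
  for (k in 1:10) {
    n <- sample(4:6, 1)
    tr <- sim_chronogram(n, depth = 12)
    x <- random_states(tr, p_missing = ifelse(k %% 2 == 0, 0.2, 0))
    g <- exp(stats::runif(1, -3, 0)); l <- exp(stats::runif(1, -3, 0))
    m <- mk2_marginal(tr, x, g, l, root_prior = "stationary")
    expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-9)
    for (v in rownames(m)) {
      l1 <- mk2_loglik(tr, x, g, l, constraints = stats::setNames(1, v),
                       root_prior = "stationary")
      l0 <- mk2_loglik(tr, x, g, l, constraints = stats::setNames(0, v),
                       root_prior = "stationary")
      expect_equal(unname(m[v, "p1"]), exp(l1) / (exp(l0) + exp(l1)),
                   tolerance = 1e-9)
    }
  }
})

test_that("marginals respect constraints and saturated data", {
  set.seed(9)
  tr <- sim_chronogram(10, depth = 50)
  ones <- stats::setNames(rep(1L, 10), tr$tip.label)
  m <- mk2_marginal(tr, ones, gain = 0.01, loss = 1e-7)
  expect_true(all(m[, "p1"] > 0.99))
  x <- random_states(tr)
  m2 <- mk2_marginal(tr, x, 0.05, 0.05,
                     constraints = stats::setNames(1, "12"))
  expect_equal(unname(m2["12", "p1"]), 1)
})

test_that("rate fitting is deterministic and beats the generating rates", {
  tr <- sim_chronogram(120, depth = 100, seed = 101)
  sim <- sim_character(tr, 0.01, 0.03, seed = 102)
  f1 <- fit_mk2(tr, sim$states, seed = 7)
  f2 <- fit_mk2(tr, sim$states, seed = 7)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$lnL, f2$lnL)
  expect_gte(f1$lnL, mk2_loglik(tr, sim$states, 0.01, 0.03) - 1e-8)
  expect_true(f1$converged)
  expect_lt(f1$lnL, 0)
})

test_that("monomorphic data pin the gain rate at its lower bound", {
  tr <- sim_chronogram(30, depth = 50, seed = 103)
  zeros <- stats::setNames(rep(0L, 30), tr$tip.label)
  f <- fit_mk2(tr, zeros, seed = 1)
  expect_lt(coef(f)[["gain"]], 1e-6)
  # all mass on state 0 at the root: lnL near log of prior mass on 0
  expect_gt(f$lnL, log(0.5) - 0.1)
})

test_that("mk2_fit methods expose rates, likelihood and reconstructions", {
  tr <- sim_chronogram(25, depth = 60, seed = 104)
  sim <- sim_character(tr, 0.02, 0.05, seed = 105)
  f <- fit_mk2(tr, sim$states, seed = 2)
  expect_named(coef(f), c("gain", "loss"))
  expect_equal(attr(logLik(f), "df"), 2L)
  m <- predict(f)
  expect_equal(nrow(m), tr$Nnode)
  st <- predict(f, "states")
  expect_true(all(st %in% c(0L, 1L, NA)))
  s <- summary(f)
  expect_equal(s$AIC, -2 * f$lnL + 4)
  sims <- simulate(f, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_named(sims[[1]], tr$tip.label, ignore.order = TRUE)
  expect_output(print(f), "gain")
})
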