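make_origin_fixture <- function(seed = 1, n = 60) {
  tr <- sim_chronogram(n, depth = 100, seed = seed)
  ntip <- length(tr$tip.label)
  ages <- node_age(tr)
  node <- which.max(replace(ages, seq_len(ntip + 1L), -Inf))  # deep non-root
  sim <- sim_single_origin(tr, node, loss_rate = 0.003, seed = seed + 1)
  list(tree = tr, node = node, sim = sim)
}

test_that("identical models tie at delta lnL zero and are not rejected", {
  fx <- make_origin_fixture(2)
  cons <- stats::setNames(1, as.character(fx$node))
  tab <- evaluate_origin_models(fx$tree, fx$sim$states,
                                models = list(a = cons, b = cons), seed = 5)
  expect_equal(tab$delta_lnl, c(0, 0), tolerance = 1e-6)
  expect_false(any(tab$rejected))
})

test_that("the rejection rule uses >= on the log-likelihood gap", {
  fx <- make_origin_fixture(3)
  models <- list(
    present = stats::setNames(1, as.character(fx$node)),
    absent = stats::setNames(0, as.character(fx$node)))
  tab <- evaluate_origin_models(fx$tree, fx$sim$states, models, seed = 6)
  gap <- max(tab$delta_lnl)
  expect_gt(gap, 0)
  # re-evaluate with the threshold placed exactly at, then just above, the gap
  at <- evaluate_origin_models(fx$tree, fx$sim$states, models, seed = 6,
                               reject_delta = gap)
  above <- evaluate_origin_models(fx$tree, fx$sim$states, models, seed = 6,
                                  reject_delta = gap * (1 + 1e-9) + 1e-12)
  expect_true(any(at$rejected))
  expect_false(any(above$rejected))
})

test_that("constraints never increase the likelihood", {
  set.seed(7)
  fx <- make_origin_fixture(4, n = 40)
  free <- fit_mk2(fx$tree, fx$sim$states, seed = 1)
  ntip <- length(fx$tree$tip.label)
  for (k in 1:10) {
    nodes <- sample((ntip + 1L):(ntip + fx$tree$Nnode), sample(1:3, 1))
    cons <- stats::setNames(sample(0:1, length(nodes), replace = TRUE),
                            as.character(nodes))
    lnl_c <- mk2_loglik(fx$tree, fx$sim$states,
                        free$rates[["gain"]], free$rates[["loss"]],
                        constraints = cons)
    expect_lte(lnl_c, free$lnL + 1e-6)
  }
})

test_that("the unconstrained model tops every comparison table", {
  fx <- make_origin_fixture(5, n = 40)
  models <- list(
    unconstrained = NULL,
    present = stats::setNames(1, as.character(fx$node)),
    absent = stats::setNames(0, as.character(fx$node)))
  tab <- evaluate_origin_models(fx$tree, fx$sim$states, models, seed = 2)
  lnl_un <- tab$lnL[tab$model == "unconstrained"]
  expect_true(all(tab$lnL <= lnl_un + 1e-6))
  expect_equal(tab$model[1], "unconstrained")
})

test_that("shared-rates scoring reuses one rate pair for all models", {
  fx <- make_origin_fixture(6, n = 30)
  models <- list(
    present = stats::setNames(1, as.character(fx$node)),
    absent = stats::setNames(0, as.character(fx$node)))
  tab <- evaluate_origin_models(fx$tree, fx$sim$states, models,
                                shared_rates = TRUE, seed = 3)
  expect_equal(tab$gain[1], tab$gain[2])
  expect_equal(tab$loss[1], tab$loss[2])
})

test_that("comparison tables export in a delimited Table S2-like layout", {
  fx <- make_origin_fixture(7, n = 30)
  tab <- evaluate_origin_models(
    fx$tree, fx$sim$states,
    models = list(one = stats::setNames(1, as.character(fx$node)),
                  none = stats::setNames(0, as.character(fx$node))),
    seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_origin_comparison(tab, f)
  re <- utils::read.table(f, sep = "\t", header = TRUE)
  expect_named(re, c("model", "gain", "loss", "lnL", "delta_lnl", "rejected"))
  expect_equal(nrow(re), 2L)
  expect_equal(re$delta_lnl[1], 0)
})

test_that("model files with two-tip node specs parse and validate", {
  tr <- read_chronogram(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("model\tnode\tstate",
               "one\tA|B\t1",
               "two\tA|B\t1", "two\tC|D\t1"), f)
  models <- read_origin_models(f, tr)
  expect_named(models, c("one", "two"))
  expect_length(models$two, 2L)
  writeLines(c("model\tnode\tstate", "bad\tA|B\t1", "bad\tA|B\t0"), f)
  expect_error(read_origin_models(f, tr), "twice")
})

test_that("origin counting handles uniform, nested and root-stem cases", {
  tr <- read_chronogram(text = "(((A:1,B:1):1,C:2):1,D:3);")
  ntip <- 4L
  recon <- function(p1) {
    m <- cbind(p0 = 1 - p1, p1 = p1)
    rownames(m) <- as.character((ntip + 1L):(ntip + 3L))
    m
  }
  # everything present: 0 origins but a root-stem origin is flagged
  oc <- count_origins(tr, recon(c(1, 1, 1)),
                      c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(oc$origins, 0L)
  expect_true(oc$root_stem_origin)
  # single clade of 1s within 0s: exactly one origin
  oc2 <- count_origins(tr, recon(c(0, 0, 1)),
                       c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(oc2$origins, 1L)
  expect_false(oc2$root_stem_origin)
  # two independent tip-level gains
  oc3 <- count_origins(tr, recon(c(0, 0, 0)),
                       c(A = 1, B = 0, C = 1, D = 0))
  expect_equal(oc3$origins, 2L)
  # a tied node widens the count to an interval
  oc4 <- count_origins(tr, recon(c(0, 0, 0.5)),
                       c(A = 1, B = 1, C = 0, D = 0))
  expect_true(is.na(oc4$origins))
  expect_equal(c(oc4$min, oc4$max), c(1L, 2L))
  # missing tips are excluded from the count
  oc5 <- count_origins(tr, recon(c(0, 0, 0)),
                       c(A = 1, B = 0, C = NA, D = 0))
  expect_equal(oc5$origins, 1L)
})

test_that("planted single-origin histories are recovered by count_origins", {
  hits <- 0L
  for (k in 1:8) {
    fx <- make_origin_fixture(100 + k, n = 80)
    f <- fit_mk2(fx$tree, fx$sim$states, seed = k)
    oc <- count_origins(fx$tree, predict(f), fx$sim$states)
    if (identical(oc$origins, 1L) ||
        (isTRUE(oc$root_stem_origin) && identical(oc$origins, 0L)))
      hits <- hits + 1L
  }
  expect_gte(hits, 6L)
})
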