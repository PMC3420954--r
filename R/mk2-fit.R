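#' Fit the asymmetric two-rate model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over (log gain, log loss) with
#' bounded quasi-Newton (L-BFGS-B) from several starting points. Likelihood
#' surfaces for rare gains are flat and multimodal, hence the restarts;
#' rates are bounded in \[1e-8, 1e3\] per MY. Rate parameters are optimized
#' jointly with any ancestral-node constraints in place, so constrained
#' (hypothesis) models get their own ML rates.
#'
#' @inheritParams mk2_loglik
#' @param n_restarts number of optimizer starting points (first is a
#'   data-driven heuristic, the rest random; deterministic given `seed`).
#' @param seed integer seed controlling the random restarts.
#' @param rate_bounds lower/upper bounds on each rate, per MY.
#' @return an object of class `mk2_fit` with components `rates` (named
#'   vector: gain, loss), `lnL`, `converged`, `n_restarts_used`, plus the
#'   inputs needed by downstream methods.
#' @examples
#' tr <- sim_chronogram(40, depth = 100, seed = 1)
#' ch <- sim_character(tr, gain = 0.02, loss = 0.05, seed = 2)
#' fit <- fit_mk2(tr, ch$states, seed = 3)
#' coef(fit)
#' logLik(fit)
#' @seealso [predict.mk2_fit()] for marginal ancestral states,
#'   [simulate.mk2_fit()], [count_origins()], [evaluate_origin_models()]
#' @export
fit_mk2 <- function(tree, states, constraints = NULL,
                    root_prior = "stationary", n_restarts = 5, seed = NULL,
                    rate_bounds = c(1e-8, 1e3)) {
  validate_chronogram(tree)
  x <- align_character(tree, states)
  cons <- resolve_constraints(tree, constraints)
  if (n_restarts < 1) stopf("n_restarts must be >= 1")
  lb <- log(rate_bounds[1L]); ub <- log(rate_bounds[2L])

  negll <- function(par) {
    v <- -mk2_loglik(tree, x, exp(par[1L]), exp(par[2L]),
                     constraints = cons, root_prior = root_prior)
    if (!is.finite(v)) 1e10 else v
  }

  # heuristic start: one expected event over the total tree length per
  # minority-state tip, symmetric in gain/loss
  tlen <- sum(tree$edge.length)
  n1 <- sum(x == 1, na.rm = TRUE)
  n0 <- sum(x == 0, na.rm = TRUE)
  r0 <- max(min(n0, n1) + 0.5, 1) / max(tlen, .Machine$double.eps)
  r0 <- min(max(r0, rate_bounds[1L] * 10), rate_bounds[2L] / 10)
  starts <- matrix(log(r0), n_restarts, 2L)
  if (n_restarts > 1L) {
    starts[-1L, ] <- with_seed(seed, matrix(
      log(r0) + stats::rnorm(2L * (n_restarts - 1L), 0, 2),
      n_restarts - 1L, 2L))
    starts <- pmin(pmax(starts, lb), ub)
  }

  best <- NULL
  any_conv <- FALSE
  for (k in seq_len(n_restarts)) {
    res <- tryCatch(
      stats::optim(starts[k, ], negll, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stopf("optimization failed from every starting point")

  rates <- stats::setNames(exp(best$par), c("gain", "loss"))
  structure(list(
    rates = rates,
    lnL = -best$value,
    converged = any_conv,
    n_restarts_used = n_restarts,
    tree = tree,
    states = x,
    constraints = cons,
    root_prior = root_prior,
    rate_bounds = rate_bounds
  ), class = "mk2_fit")
}

#' @export
print.mk2_fit <- function(x, ...) {
  cat("Asymmetric two-rate (Mk2) model fit\n")
  cat(sprintf("  tips: %d (%d missing)   constraints: %d   root prior: %s\n",
              length(x$states), sum(is.na(x$states)),
              length(x$constraints),
              if (is.numeric(x$root_prior))
                paste(signif(x$root_prior, 4), collapse = "/")
              else x$root_prior))
  cat(sprintf("  gain (0->1): %.6g per MY\n  loss (1->0): %.6g per MY\n",
              x$rates[["gain"]], x$rates[["loss"]]))
  cat(sprintf("  log-likelihood: %.4f%s\n", x$lnL,
              if (x$converged) "" else "  (optimizer did not converge)"))
  invisible(x)
}

#' @export
coef.mk2_fit <- function(object, ...) object$rates

#' @export
logLik.mk2_fit <- function(object, ...) {
  structure(object$lnL, df = 2L, nobs = sum(!is.na(object$states)),
            class = "logLik")
}

#' Marginal ancestral-state probabilities from a fitted model
#'
#' @param object an `mk2_fit`.
#' @param type `"marginal"` for the (p0, p1) matrix over internal nodes,
#'   `"states"` for the ML state per internal node (`NA` when the marginal
#'   ties at 0.5 within `tie_tol`).
#' @param tie_tol half-width of the tie band around 0.5.
#' @param ... unused.
#' @export
predict.mk2_fit <- function(object, type = c("marginal", "states"),
                            tie_tol = 1e-9, ...) {
  type <- match.arg(type)
  m <- mk2_marginal(object$tree, object$states,
                    object$rates[["gain"]], object$rates[["loss"]],
                    constraints = object$constraints,
                    root_prior = object$root_prior)
  if (type == "marginal") return(m)
  st <- ifelse(m[, "p1"] >= 0.5 + tie_tol, 1L,
               ifelse(m[, "p1"] <= 0.5 - tie_tol, 0L, NA_integer_))
  stats::setNames(st, rownames(m))
}

#' Summarize an Mk2 fit
#'
#' Adds the stationary distribution, AIC, and the ancestral root-state call.
#' @param object an `mk2_fit`.
#' @param ... unused.
#' @export
summary.mk2_fit <- function(object, ...) {
  m <- predict(object, "marginal")
  root <- as.character(length(object$states) + 1L)
  out <- list(
    rates = object$rates,
    stationary = stats::setNames(
      mk2_stationary(object$rates[["gain"]], object$rates[["loss"]]),
      c("p0", "p1")),
    lnL = object$lnL,
    AIC = -2 * object$lnL + 4,
    converged = object$converged,
    root_posterior = m[root, ],
    n_tips = length(object$states),
    n_missing = sum(is.na(object$states))
  )
  class(out) <- "summary.mk2_fit"
  out
}

#' @export
print.summary.mk2_fit <- function(x, ...) {
  cat("Asymmetric two-rate (Mk2) model\n")
  cat(sprintf("  gain %.6g, loss %.6g per MY (stationary p1 = %.3f)\n",
              x$rates[["gain"]], x$rates[["loss"]], x$stationary[["p1"]]))
  cat(sprintf("  lnL = %.4f, AIC = %.4f, tips = %d (%d missing)\n",
              x$lnL, x$AIC, x$n_tips, x$n_missing))
  cat(sprintf("  root posterior: P(absent) = %.4f, P(present) = %.4f\n",
              x$root_posterior[["p0"]], x$root_posterior[["p1"]]))
  invisible(x)
}

#' Simulate binary characters from a fitted model
#'
#' Re-simulates tip data on the fitted tree under the fitted rates, starting
#' from a root state drawn from the model's root prior.
#'
#' @param object an `mk2_fit`.
#' @param nsim number of replicate characters.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` named 0/1 tip-state vectors.
#' @export
simulate.mk2_fit <- function(object, nsim = 1, seed = NULL, ...) {
  prior <- resolve_root_prior(object$root_prior,
                              object$rates[["gain"]], object$rates[["loss"]])
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    root_state <- stats::rbinom(1L, 1L, prior[2L])
    sim_character(object$tree, object$rates[["gain"]], object$rates[["loss"]],
                  root_state = root_state, seed = NULL)$states
  }))
}

#' Plot a fitted model's ancestral reconstruction
#'
#' Draws the chronogram with pie charts of the marginal posterior at each
#' internal node (grey = absent, black = present).
#'
#' @param x an `mk2_fit`.
#' @param cex tip-label size.
#' @param ... passed to [ape::plot.phylo()].
#' @export
plot.mk2_fit <- function(x, cex = 0.6, ...) {
  m <- predict(x, "marginal")
  ape::plot.phylo(x$tree, cex = cex, ...)
  ape::nodelabels(pie = m[, c("p0", "p1")], piecol = c("grey85", "black"),
                  cex = 0.4)
  invisible(x)
}
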