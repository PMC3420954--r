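#' Compare trait-origin hypotheses by constrained-node likelihoods
#'
#' Each hypothesis (one origin, two origins, ...) is encoded as a set of
#' ancestral nodes fixed to state 0 (absent) or 1 (present). Every model's
#' likelihood is computed with the asymmetric two-rate model — by default
#' with rates re-optimized per model, the conservative choice — and models
#' are compared on \eqn{\Delta lnL} relative to the best fit. A model is
#' rejected when its log-likelihood falls two or more units below the best
#' model's.
#'
#' @inheritParams fit_mk2
#' @param models named list of constraint sets; each element is a named
#'   vector of 0/1 states whose names are node ids or two-tip MRCA specs
#'   `"A|B"`. An element may be `NULL` (the unconstrained model).
#' @param shared_rates if `TRUE`, rates are estimated once without
#'   constraints and each model is scored at those shared rates instead of
#'   re-optimizing.
#' @param reject_delta rejection threshold in log-likelihood units
#'   (default 2).
#' @return an `origin_comparison`: a data frame with one row per model
#'   (`model`, `gain`, `loss`, `lnL`, `delta_lnl`, `rejected`), best model
#'   first, with the fits attached as attribute `"fits"`.
#' @examples
#' tr <- sim_chronogram(40, depth = 100, seed = 1)
#' sim <- sim_single_origin(tr, mrca_node(tr, c("t1", "t2")),
#'                          loss_rate = 0.002, seed = 2)
#' anc <- "t1|t2"
#' tab <- evaluate_origin_models(tr, sim$states,
#'   models = list(origin_here = stats::setNames(1, anc),
#'                 absent_here = stats::setNames(0, anc)),
#'   seed = 3)
#' @export
evaluate_origin_models <- function(tree, states, models, shared_rates = FALSE,
                                   root_prior = "stationary", n_restarts = 5,
                                   seed = NULL, reject_delta = 2) {
  if (length(models) < 1L) stopf("at least one model required")
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stopf("models must be named")
  x <- align_character(tree, states)

  base_fit <- NULL
  if (shared_rates)
    base_fit <- fit_mk2(tree, x, constraints = NULL, root_prior = root_prior,
                        n_restarts = n_restarts,
                        seed = substream_seed(seed, "shared"))

  fits <- vector("list", length(models))
  names(fits) <- names(models)
  for (nm in names(models)) {
    cons <- models[[nm]]
    if (shared_rates) {
      lnL <- mk2_loglik(tree, x, base_fit$rates[["gain"]],
                        base_fit$rates[["loss"]],
                        constraints = cons, root_prior = root_prior)
      fits[[nm]] <- list(rates = base_fit$rates, lnL = lnL,
                         converged = base_fit$converged, constraints = cons)
    } else {
      fits[[nm]] <- fit_mk2(tree, x, constraints = cons,
                            root_prior = root_prior, n_restarts = n_restarts,
                            seed = substream_seed(seed, nm))
    }
  }

  lnL <- vapply(fits, function(f) f$lnL, numeric(1L))
  delta <- max(lnL) - lnL
  tab <- data.frame(
    model = names(models),
    gain = vapply(fits, function(f) f$rates[["gain"]], numeric(1L)),
    loss = vapply(fits, function(f) f$rates[["loss"]], numeric(1L)),
    lnL = lnL,
    delta_lnl = delta,
    rejected = delta >= reject_delta,
    row.names = NULL
  )
  tab <- tab[order(tab$delta_lnl), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  attr(tab, "shared_rates") <- shared_rates
  attr(tab, "reject_delta") <- reject_delta
  class(tab) <- c("origin_comparison", "data.frame")
  tab
}

#' @export
print.origin_comparison <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Origin-hypothesis comparison (%s rates; reject at delta lnL >= %g)\n",
    if (attr(x, "shared_rates")) "shared" else "per-model",
    attr(x, "reject_delta")))
  y <- as.data.frame(x)
  y$gain <- signif(y$gain, digits)
  y$loss <- signif(y$loss, digits)
  y$lnL <- round(y$lnL, digits)
  y$delta_lnl <- round(y$delta_lnl, digits)
  y$rejected <- ifelse(y$rejected, "yes", "")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Read origin-hypothesis models from delimited text
#'
#' Expected columns: `model`, `node` (a two-tip MRCA spec `"A|B"` or a tip
#' label), `state` (0/1); tab- or comma-separated, header optional.
#'
#' @param file path.
#' @param tree tree against which node specs are validated.
#' @return named list of constraint vectors, suitable for
#'   [evaluate_origin_models()].
#' @export
read_origin_models <- function(file, tree = NULL) {
  if (!file.exists(file)) stopf("model file not found: %s", file)
  first <- readLines(file, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- grepl("model", first, ignore.case = TRUE)
  d <- utils::read.table(file, sep = sep, header = has_header,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 3L) stopf("model file needs columns: model, node, state")
  names(d)[1:3] <- c("model", "node", "state")
  if (!all(d$state %in% c(0L, 1L))) stopf("states must be 0 or 1")
  models <- lapply(split(d, d$model), function(g) {
    if (anyDuplicated(g$node)) stopf("node constrained twice in model '%s'",
                                     g$model[1L])
    stats::setNames(as.integer(g$state), g$node)
  })
  if (!is.null(tree))
    for (m in models) resolve_constraints(tree, m)
  models[unique(d$model)]
}

#' Export an origin-comparison table to delimited text
#'
#' @param x an `origin_comparison`.
#' @param file output path.
#' @export
write_origin_comparison <- function(x, file) {
  utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Count trait origins implied by an ancestral reconstruction
#'
#' Assigns each internal node its ML state (marginal posterior of state 1 at
#' least 0.5, with an explicit tie band) and each tip its observed state,
#' then counts parent-to-child edges that switch 0 to 1. Edges leading to
#' missing tips are excluded. A root in state 1 is reported separately as an
#' origin on the root stem (the gain predates the root). Nodes whose
#' marginal ties at 0.5 are never broken silently: the count becomes an
#' interval `[min, max]` over their possible assignments.
#'
#' @param tree a `phylo` chronogram.
#' @param reconstruction matrix from [mk2_marginal()] /
#'   [predict.mk2_fit()] (rows = internal node ids, columns `p0`, `p1`), or
#'   an `mk2_fit` (its own reconstruction is used).
#' @param states named tip-state vector (0/1/NA).
#' @param tie_tol half-width of the tie band around 0.5.
#' @return an `origin_count`: list with `origins` (point count, `NA` when
#'   ambiguous), `min`, `max`, `ambiguous_nodes`, `root_state`,
#'   `root_stem_origin`.
#' @export
count_origins <- function(tree, reconstruction, states = NULL,
                          tie_tol = 1e-9) {
  if (inherits(reconstruction, "mk2_fit")) {
    if (is.null(states)) states <- reconstruction$states
    tree <- reconstruction$tree
    reconstruction <- predict(reconstruction, "marginal")
  }
  validate_chronogram(tree)
  x <- align_character(tree, states)
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  ids <- as.integer(rownames(reconstruction))
  if (!setequal(ids, (ntip + 1L):n_all))
    stopf("reconstruction must cover every internal node")
  p1 <- reconstruction[match((ntip + 1L):n_all, ids), "p1"]

  node_state <- rep(NA_integer_, n_all)
  node_state[seq_len(ntip)] <- x
  internal <- (ntip + 1L):n_all
  node_state[internal] <- ifelse(p1 >= 0.5 + tie_tol, 1L,
                                 ifelse(p1 <= 0.5 - tie_tol, 0L, NA_integer_))
  amb <- internal[is.na(node_state[internal])]
  missing_tips <- which(is.na(node_state[seq_len(ntip)]))

  count_for <- function(assign_amb) {
    st <- node_state
    st[amb] <- assign_amb
    gains <- 0L
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
      if (v %in% missing_tips) next
      if (st[p] == 0L && st[v] == 1L) gains <- gains + 1L
    }
    gains
  }

  root <- ntip + 1L
  if (length(amb) == 0L) {
    n <- count_for(integer())
    cmin <- cmax <- n
  } else if (length(amb) <= 12L) {
    grid <- as.matrix(expand.grid(rep(list(0:1), length(amb))))
    counts <- apply(grid, 1L, count_for)
    cmin <- min(counts); cmax <- max(counts)
  } else {
    stopf("%d ambiguous nodes; too many tied marginals to enumerate",
          length(amb))
  }

  root_state <- node_state[root]
  structure(list(
    origins = if (cmin == cmax) cmin else NA_integer_,
    min = cmin,
    max = cmax,
    ambiguous_nodes = amb,
    root_state = root_state,
    root_stem_origin = isTRUE(root_state == 1L)
  ), class = "origin_count")
}

#' @export
print.origin_count <- function(x, ...) {
  if (is.na(x$origins)) {
    cat(sprintf("Origins (0 -> 1 transitions): between %d and %d (%d tied node%s)\n",
                x$min, x$max, length(x$ambiguous_nodes),
                if (length(x$ambiguous_nodes) == 1L) "" else "s"))
  } else {
    cat(sprintf("Origins (0 -> 1 transitions): %d\n", x$origins))
  }
  if (x$root_stem_origin)
    cat("Root reconstructed in state 1: one origin predates the root (root stem).\n")
  invisible(x)
}
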