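#' Transition probabilities of the asymmetric two-state model
#'
#' Closed-form transition matrix of the continuous-time Markov chain with
#' gain rate \eqn{q_{01}} (state 0 to 1) and loss rate \eqn{q_{10}} (1 to 0),
#' both per MY. With \eqn{s = q_{01} + q_{10}} and stationary frequency
#' \eqn{\pi_1 = q_{01}/s}:
#' \deqn{P_{01}(t) = \pi_1 (1 - e^{-st}), \quad
#'       P_{10}(t) = (1 - \pi_1)(1 - e^{-st}),}
#' diagonals one minus the off-diagonals.
#'
#' @param gain rate of 0 to 1 transitions per MY (> 0).
#' @param loss rate of 1 to 0 transitions per MY (> 0).
#' @param t elapsed time in MY (>= 0).
#' @return 2x2 matrix with rows = starting state (0, 1), columns = ending
#'   state; rows sum to 1.
#' @examples
#' mk2_transition_matrix(0.2, 0.1, 3)
#' @export
mk2_transition_matrix <- function(gain, loss, t) {
  check_rates(gain, loss)
  if (length(t) != 1L || is.na(t) || t < 0) stopf("t must be a single value >= 0")
  s <- gain + loss
  pi1 <- gain / s
  f <- 1 - exp(-s * t)
  p01 <- pi1 * f
  p10 <- (1 - pi1) * f
  matrix(c(1 - p01, p10, p01, 1 - p10), 2L, 2L,
         dimnames = list(from = c("0", "1"), to = c("0", "1")))
}

check_rates <- function(gain, loss) {
  if (!is.finite(gain) || !is.finite(loss) || gain <= 0 || loss <= 0)
    stopf("gain and loss rates must be finite and > 0")
  invisible(NULL)
}

# Stationary distribution (p0, p1) of the chain.
mk2_stationary <- function(gain, loss) {
  s <- gain + loss
  c(loss / s, gain / s)
}

# Resolve a root prior specification to a length-2 probability vector.
resolve_root_prior <- function(root_prior, gain, loss) {
  if (is.numeric(root_prior)) {
    if (length(root_prior) != 2L || any(root_prior < 0) ||
        abs(sum(root_prior) - 1) > 1e-9)
      stopf("numeric root prior must be two non-negative values summing to 1")
    return(as.numeric(root_prior))
  }
  switch(match.arg(root_prior, c("stationary", "equal", "state0", "state1")),
         stationary = mk2_stationary(gain, loss),
         equal = c(0.5, 0.5),
         state0 = c(1, 0),
         state1 = c(0, 1))
}

# Normalize and sanity-check a constraint specification: a vector of 0/1
# fixed states whose names are node ids, or node specs "A|B" resolved
# against the tree. Returns integer states named by node id, or NULL.
resolve_constraints <- function(tree, constraints) {
  if (is.null(constraints) || length(constraints) == 0L) return(NULL)
  if (is.null(names(constraints))) stopf("constraints must be named by node")
  ids <- names(constraints)
  num <- suppressWarnings(as.integer(ids))
  node <- ifelse(is.na(num), NA_integer_, num)
  if (anyNA(node)) node[is.na(node)] <- resolve_node_spec(tree, ids[is.na(node)])
  n_all <- length(tree$tip.label) + tree$Nnode
  if (any(node < 1L | node > n_all)) stopf("constraint on unknown node")
  if (anyDuplicated(node)) stopf("node constrained twice")
  st <- as.integer(constraints)
  if (!all(st %in% c(0L, 1L))) stopf("constrained states must be 0 or 1")
  stats::setNames(st, node)
}

# Tip partial likelihoods: rows = nodes (tips first), columns = states 0/1.
# Missing tips get (1, 1). Constraints on tips are checked against
# observations here.
init_partials <- function(tree, x, cons) {
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  L <- matrix(1, n_all, 2L)
  obs <- which(!is.na(x))
  if (length(obs) == 0L) stopf("all tips missing")
  L[cbind(obs, 2L - x[obs])] <- 0  # observed state s keeps column s+1
  if (!is.null(cons)) {
    cn <- as.integer(names(cons))
    tip_cons <- cn[cn <= ntip]
    for (v in tip_cons) {
      st <- cons[[as.character(v)]]
      if (!is.na(x[v]) && x[v] != st)
        stopf("constraint on tip '%s' contradicts its observed state",
              tree$tip.label[v])
      L[v, ] <- 0
      L[v, st + 1L] <- 1
    }
  }
  L
}

#' Pruning log-likelihood of a binary character under the asymmetric model
#'
#' Felsenstein's pruning algorithm from tips to root. Missing tips
#' contribute partial likelihood (1, 1). A constrained internal node has the
#' partial likelihood of its disallowed state zeroed after its children are
#' combined, i.e. the likelihood is conditioned on that node being in the
#' fixed state — the device used to compare trait-origin hypotheses. Root
#' partials are dotted with the root prior (default: the stationary
#' distribution of the rate matrix).
#'
#' @param tree a `phylo` chronogram (need not be ultrametric).
#' @param states named 0/1/NA vector over the tips.
#' @inheritParams mk2_transition_matrix
#' @param constraints `NULL`, or named vector of fixed states: names are
#'   node ids or two-tip specs `"A|B"`, values 0/1.
#' @param root_prior `"stationary"` (default), `"equal"`, `"state0"`,
#'   `"state1"`, or a numeric length-2 probability vector.
#' @return log-likelihood (a single negative number for discrete data).
#' @export
mk2_loglik <- function(tree, states, gain, loss, constraints = NULL,
                       root_prior = "stationary") {
  check_rates(gain, loss)
  validate_chronogram(tree)
  x <- align_character(tree, states)
  cons <- resolve_constraints(tree, constraints)
  post <- stats::reorder(tree, "postorder")
  L <- init_partials(tree, x, cons)
  ntip <- length(tree$tip.label)
  root <- post$edge[nrow(post$edge), 1L]

  s <- gain + loss
  pi1 <- gain / s
  f <- 1 - exp(-s * post$edge.length)
  P01 <- pi1 * f
  P10 <- (1 - pi1) * f
  parent <- post$edge[, 1L]
  child <- post$edge[, 2L]
  logscale <- 0

  # postorder guarantees a child's partials are complete when its edge is
  # processed; internal-node constraints are applied at that moment
  cons_nodes <- if (is.null(cons)) integer() else as.integer(names(cons))
  for (i in seq_along(parent)) {
    v <- child[i]
    c0 <- L[v, 1L]; c1 <- L[v, 2L]
    if (v > ntip && v %in% cons_nodes) {
      st <- cons[[as.character(v)]]
      if (st == 0L) c1 <- 0 else c0 <- 0
    }
    p <- parent[i]
    l0 <- (1 - P01[i]) * c0 + P01[i] * c1
    l1 <- P10[i] * c0 + (1 - P10[i]) * c1
    n0 <- L[p, 1L] * l0
    n1 <- L[p, 2L] * l1
    m <- max(n0, n1)
    if (m == 0) return(-Inf)
    if (m < 1e-200) { n0 <- n0 / m; n1 <- n1 / m; logscale <- logscale + log(m) }
    L[p, 1L] <- n0
    L[p, 2L] <- n1
  }
  if (root %in% cons_nodes) {
    st <- cons[[as.character(root)]]
    if (st == 0L) L[root, 2L] <- 0 else L[root, 1L] <- 0
  }
  prior <- resolve_root_prior(root_prior, gain, loss)
  lik <- sum(prior * L[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + logscale
}

#' Marginal ancestral-state probabilities
#'
#' Up–down algorithm: downward (pruning) partial likelihoods are combined
#' with upward, outside-subtree partials so that each internal node's
#' marginal posterior integrates over the states of all other nodes. The
#' marginal at a node equals the ratio of the node-fixed likelihoods
#' \eqn{L(\mathrm{node}=1) / (L(\mathrm{node}=0) + L(\mathrm{node}=1))}.
#'
#' @inheritParams mk2_loglik
#' @param tips also return rows for tips (posterior given the data; observed
#'   tips are 0/1, missing tips are genuinely inferred). Default `FALSE`:
#'   internal nodes only.
#' @return matrix with columns `p0`, `p1` (rows sum to 1), row names = node
#'   ids.
#' @export
mk2_marginal <- function(tree, states, gain, loss, constraints = NULL,
                         root_prior = "stationary", tips = FALSE) {
  check_rates(gain, loss)
  validate_chronogram(tree)
  x <- align_character(tree, states)
  cons <- resolve_constraints(tree, constraints)
  post <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  root <- post$edge[nrow(post$edge), 1L]
  cons_nodes <- if (is.null(cons)) integer() else as.integer(names(cons))

  s <- gain + loss
  pi1 <- gain / s
  f <- 1 - exp(-s * post$edge.length)
  P01 <- pi1 * f
  P10 <- (1 - pi1) * f
  parent <- post$edge[, 1L]
  child <- post$edge[, 2L]

  # ---- down pass: D[v,] = partials at v from its subtree (constraint at v
  # applied); contrib[i,] = edge i's message to its parent (per parent state)
  D <- init_partials(tree, x, cons)
  contrib <- matrix(0, length(parent), 2L)
  for (i in seq_along(parent)) {
    v <- child[i]
    if (v > ntip && v %in% cons_nodes) {
      st <- cons[[as.character(v)]]
      D[v, 2L - st] <- 0  # zero the disallowed state (column st+1 kept)
    }
    c0 <- D[v, 1L]; c1 <- D[v, 2L]
    contrib[i, 1L] <- (1 - P01[i]) * c0 + P01[i] * c1
    contrib[i, 2L] <- P10[i] * c0 + (1 - P10[i]) * c1
    p <- parent[i]
    D[p, ] <- D[p, ] * contrib[i, ]
    m <- max(D[p, ])
    if (m == 0) stopf("zero likelihood: constraints contradict the data")
    D[p, ] <- D[p, ] / m  # per-node factors cancel in the normalized marginal
  }
  if (root %in% cons_nodes) D[root, 2L - cons[[as.character(root)]]] <- 0

  # ---- up pass (preorder = reversed postorder edges): U[v,] carries the
  # prior and everything outside v's subtree
  U <- matrix(0, n_all, 2L)
  prior <- resolve_root_prior(root_prior, gain, loss)
  U[root, ] <- prior
  rootmask <- c(1, 1)
  if (root %in% cons_nodes) rootmask[2L - cons[[as.character(root)]]] <- 0
  for (i in rev(seq_along(parent))) {
    p <- parent[i]
    v <- child[i]
    # message from p to v: U[p] times siblings' contributions (D[p] without
    # edge i), times p's own constraint mask, propagated through edge i
    sib <- U[p, ]
    for (j in which(parent == p)) if (j != i) sib <- sib * contrib[j, ]
    if (p > ntip && p %in% cons_nodes) {
      st <- cons[[as.character(p)]]
      sib[2L - st] <- 0
    }
    a0 <- sib[1L]; a1 <- sib[2L]
    u0 <- a0 * (1 - P01[i]) + a1 * P10[i]
    u1 <- a0 * P01[i] + a1 * (1 - P10[i])
    m <- max(u0, u1)
    if (m > 0) { u0 <- u0 / m; u1 <- u1 / m }
    U[v, ] <- c(u0, u1)
  }

  post_prob <- U * D
  post_prob[root, ] <- prior * rootmask * D[root, ]
  tot <- rowSums(post_prob)
  if (any(tot == 0)) stopf("zero posterior mass at a node; contradictory constraints")
  post_prob <- post_prob / tot
  colnames(post_prob) <- c("p0", "p1")
  rownames(post_prob) <- as.character(seq_len(n_all))
  if (tips) post_prob else post_prob[(ntip + 1L):n_all, , drop = FALSE]
}
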