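# Independent oracles used across tests. These deliberately avoid the
# package's pruning/marginal code paths: likelihoods by exhaustive
# enumeration, MRCA by root-to-tip path intersection.

# Brute-force log-likelihood: sum over every assignment of states to
# internal nodes and to missing tips, multiplying closed-form transition
# probabilities edge by edge.
enum_loglik <- function(tree, states, gain, loss, constraints = NULL,
                        root_prior = "equal") {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  x <- states[tree$tip.label]
  prior <- switch(root_prior,
                  equal = c(0.5, 0.5),
                  stationary = c(loss, gain) / (gain + loss),
                  state0 = c(1, 0),
                  state1 = c(0, 1))
  cons_nodes <- if (is.null(constraints)) integer()
                else as.integer(names(constraints))
  free <- c(which(is.na(x)), ntip + seq_len(nn))  # missing tips + internals
  tot <- 0
  for (cfg in 0:(2^length(free) - 1L)) {
    st <- rep(NA_integer_, ntip + nn)
    st[seq_len(ntip)] <- x
    st[free] <- as.integer(intToBits(cfg))[seq_along(free)]
    if (length(cons_nodes) &&
        !all(st[cons_nodes] == as.integer(constraints))) next
    p <- prior[st[ntip + 1L] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      P <- mk2_transition_matrix(gain, loss, tree$edge.length[e])
      p <- p * P[st[tree$edge[e, 1L]] + 1L, st[tree$edge[e, 2L]] + 1L]
    }
    tot <- tot + p
  }
  log(tot)
}

# MRCA by intersecting root-to-tip paths: the common ancestor with the
# greatest depth.
mrca_oracle <- function(tree, taxa) {
  ntip <- length(tree$tip.label)
  path_to_root <- function(v) {
    path <- v
    repeat {
      p <- tree$edge[tree$edge[, 2L] == v, 1L]
      if (length(p) == 0L) break
      path <- c(path, p)
      v <- p
    }
    path
  }
  paths <- lapply(match(taxa, tree$tip.label), path_to_root)
  common <- Reduce(intersect, paths)
  depth <- ape::node.depth.edgelength(tree)
  common[which.max(depth[common])]
}

# Random tip states with optional missing entries.
random_states <- function(tree, p1 = 0.5, p_missing = 0) {
  n <- length(tree$tip.label)
  x <- stats::rbinom(n, 1L, p1)
  if (p_missing > 0) x[stats::runif(n) < p_missing] <- NA
  # keep at least two observed states
  if (sum(!is.na(x)) < 2L) x[1:2] <- c(0L, 1L)
  stats::setNames(x, tree$tip.label)
}
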