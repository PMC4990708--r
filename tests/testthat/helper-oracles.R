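# Independent oracles and small fixture builders shared across tests.

# dense multivariate-normal log density via Cholesky -- the reference
# against which the O(n) pruning likelihood is checked
dense_mvn_loglik <- function(x, mu, S) {
  R <- chol(S)
  z <- backsolve(R, x - mu, transpose = TRUE)
  -length(x) / 2 * log(2 * pi) - sum(log(diag(R))) - sum(z^2) / 2
}

dense_bm_loglik <- function(phy, traits, sigma2, root_state) {
  C <- ape::vcv(phy)[phy$tip.label, phy$tip.label]
  dense_mvn_loglik(as.numeric(traits[phy$tip.label]), root_state, sigma2 * C)
}

# closed-form conditional means of all internal node states given the
# tips under single-rate BM with a flat root prior (independent of
# sigma2): mu_gls + C_IT C_TT^-1 (x - mu_gls)
bm_conditional_means <- function(phy, traits) {
  n <- length(phy$tip.label)
  ntot <- n + phy$Nnode
  depth <- ape::node.depth.edgelength(phy)
  M <- ape::mrca(phy, full = TRUE)
  Cfull <- matrix(depth[M], ntot, ntot)
  tips <- seq_len(n); ints <- (n + 1L):ntot
  xv <- as.numeric(traits[phy$tip.label])
  iC <- solve(Cfull[tips, tips])
  one <- rep(1, n)
  mu <- sum(iC %*% xv) / sum(iC %*% one)
  as.numeric(mu + Cfull[ints, tips, drop = FALSE] %*% iC %*% (xv - mu))
}

random_time_tree <- function(n, seed, fossil = 0.3) {
  simulate_tree(n, birth_rate = 0.3, seed = seed, fossil_fraction = fossil)
}

# minimal posterior stand-in carrying exact node means, for arithmetic
# tests of the rate-space construction
fake_posterior <- function(phy, means) {
  phy <- ape::reorder.phylo(phy, "cladewise")
  ntot <- length(phy$tip.label) + phy$Nnode
  stopifnot(length(means) == ntot)
  parent_of <- rep(NA_integer_, ntot)
  duration <- rep(NA_real_, ntot)
  parent_of[phy$edge[, 2L]] <- phy$edge[, 1L]
  duration[phy$edge[, 2L]] <- phy$edge.length
  structure(list(
    node_summary = data.frame(node_id = seq_len(ntot),
                              parent_id = parent_of,
                              duration_myr = duration,
                              state_mean = means),
    tree_signature = bitephylo:::.tree_signature(phy)
  ), class = "mvbm_posterior")
}

# seven points classified unambiguously against the identity line
# (slope 1, intercept 0): one per scenario
scenario_fixture <- function() {
  data.frame(
    node_id = 1:7,
    rate_hw  = c(0.2,  0.9, -0.3, -0.8, -0.2,  0.3, 0.5),
    rate_rap = c(0.9,  0.2,  0.4, -0.2, -0.9, -0.4, 0.5),
    expected = c("AI", "DI", "SEP_POS", "DD", "AD", "SEP_NEG", "ISO"),
    stringsAsFactors = FALSE
  )
}

identity_rma <- function() rma_fit(c(0, 1, 2), c(0, 1, 2))
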