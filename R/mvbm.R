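# Multiple-variance Brownian motion: Bayesian estimation of ancestral
# states and branch-specific rate multipliers.

#' Configuration for the mvBM sampler
#'
#' @param iterations total MCMC iterations. The default 100,000 is a
#'   desk-scale setting that mixes well on trees of a few dozen taxa;
#'   production analyses simply raise it (it is a config value, not a
#'   code path).
#' @param burn_in fraction of iterations discarded, in (0, 1).
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed integer seed; the whole chain is a pure function of
#'   (data, config, seed).
#' @param rate_prior_sd sd `nu` of the Normal(0, nu^2) prior on the log
#'   branch-rate multipliers. `nu = 0` pins every multiplier at 1,
#'   reducing the model to single-rate BM (used by the calibration
#'   checks).
#' @param sigma2_prior_shape,sigma2_prior_rate shape and rate of the
#'   inverse-gamma prior on the base rate; the defaults are the usual
#'   weakly-informative conjugate choice.
#' @param proposal_sd random-walk sd for the Metropolis updates of
#'   `ln r_b`.
#' @param store_chains keep the thinned chains in the result (needed for
#'   draw-level post-processing; summaries are always kept).
#' @return a list of class `mvbm_config`.
#' @export
mvbm_config <- function(iterations = 100000L, burn_in = 0.2, thin = 10L,
                        seed = 1L, rate_prior_sd = 1,
                        sigma2_prior_shape = 0.001,
                        sigma2_prior_rate = 0.001,
                        proposal_sd = 1.6, store_chains = TRUE) {
  iterations <- as.integer(iterations); thin <- as.integer(thin)
  if (thin < 1L || iterations < thin) stop("need iterations >= thin >= 1")
  if (burn_in <= 0 || burn_in >= 1) stop("burn_in must be in (0, 1)")
  if (rate_prior_sd < 0) stop("rate_prior_sd must be >= 0")
  if (proposal_sd <= 0) stop("proposal_sd must be > 0")
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), rate_prior_sd = rate_prior_sd,
                 sigma2_prior_shape = sigma2_prior_shape,
                 sigma2_prior_rate = sigma2_prior_rate,
                 proposal_sd = proposal_sd,
                 store_chains = isTRUE(store_chains)),
            class = "mvbm_config")
}

#' Ancestral states and branch rates under multiple-variance Brownian motion
#'
#' Fits the mvBM model by Metropolis-within-Gibbs MCMC. Along each branch
#' b the trait evolves as Brownian motion with variance
#' `sigma2 * r_b * t_b`, where `t_b` is the branch duration and `r_b` a
#' branch-specific rate multiplier with prior `ln r_b ~ N(0, nu^2)`;
#' `sigma2` carries an inverse-gamma prior and the root state a flat one.
#' Internal node states and `sigma2` are Gibbs-sampled from their
#' conjugate full conditionals; `ln r_b` by random-walk Metropolis. Tip
#' states are data and are never altered.
#'
#' The result summarizes the thinned post-burn-in chain: per-node
#' posterior mean, sd and central 95% credible interval of the state, and
#' per-branch summaries of the rate multiplier and of the effective rate
#' `sigma2 * r_b`. Identical data, config and seed give identical output.
#'
#' @param phy a `phylo` object with branch durations in Myr.
#' @param traits named numeric vector of tip values (ln units).
#' @param config an [mvbm_config()].
#' @return an object of class `mvbm_posterior` with elements
#'   `node_summary` (node_id, parent_id, duration, is_tip, label,
#'   state_mean/sd/lo/hi), `branch_summary` (node_id = child node id,
#'   mult_mean/sd/lo/hi, eff_rate_mean/sd/lo/hi, accept_frac, ess_ln_mult),
#'   `sigma2_summary`, `diagnostics` and (optionally) `chains`.
#' @export
mvbm_mcmc <- function(phy, traits, config = mvbm_config()) {
  stopifnot(inherits(config, "mvbm_config"))
  validate_time_tree(phy)
  x_tip <- .check_traits(phy, traits)
  phy <- ape::reorder.phylo(phy, "cladewise")
  n <- length(phy$tip.label)
  ntot <- n + phy$Nnode
  m <- nrow(phy$edge)

  # initialization: tips at data, internal nodes at the post-order average
  # of their children, multipliers at 1, sigma2 at the BM ML estimate
  init <- numeric(ntot)
  init[seq_len(n)] <- as.numeric(x_tip)
  po <- ape::reorder.phylo(phy, "postorder")
  cnt <- numeric(ntot)
  for (i in seq_len(m)) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    init[p] <- (init[p] * cnt[p] + init[ch]) / (cnt[p] + 1)
    cnt[p] <- cnt[p] + 1
  }
  bm <- fit_trait_model(phy, traits, "BM")
  init_sigma2 <- if (bm$degenerate || bm$parameters$sigma2 <= 0) {
    1e-8
  } else bm$parameters$sigma2
  if (!all(is.finite(init))) stop("non-finite state initialization")

  burnin <- as.integer(floor(config$iterations * config$burn_in))
  set.seed(config$seed)
  raw <- mvbm_mcmc_cpp(phy$edge, phy$edge.length, n, init,
                       config$iterations, burnin, config$thin,
                       config$rate_prior_sd, config$sigma2_prior_shape,
                       config$sigma2_prior_rate, config$proposal_sd,
                       init_sigma2)
  if (any(!is.finite(raw$log_joint))) {
    stop("non-finite log joint density in retained samples")
  }

  q <- function(v, p) unname(stats::quantile(v, p, type = 7))
  node_ids <- seq_len(ntot)
  parent_of <- rep(NA_integer_, ntot)
  duration <- rep(NA_real_, ntot)
  parent_of[phy$edge[, 2L]] <- phy$edge[, 1L]
  duration[phy$edge[, 2L]] <- phy$edge.length

  st <- raw$states
  node_summary <- data.frame(
    node_id = node_ids,
    parent_id = parent_of,
    duration_myr = duration,
    is_tip = node_ids <= n,
    label = c(phy$tip.label,
              if (is.null(phy$node.label)) rep(NA_character_, phy$Nnode)
              else phy$node.label),
    state_mean = colMeans(st),
    state_sd = apply(st, 2L, stats::sd),
    state_lo = apply(st, 2L, q, 0.025),
    state_hi = apply(st, 2L, q, 0.975),
    stringsAsFactors = FALSE
  )
  # tip "posteriors" are the observations, exactly
  node_summary$state_mean[seq_len(n)] <- as.numeric(x_tip)
  node_summary$state_sd[seq_len(n)] <- 0
  node_summary$state_lo[seq_len(n)] <- as.numeric(x_tip)
  node_summary$state_hi[seq_len(n)] <- as.numeric(x_tip)

  r <- exp(raw$lnr)
  eff <- r * raw$sigma2
  branch_summary <- data.frame(
    node_id = phy$edge[, 2L],
    parent_id = phy$edge[, 1L],
    duration_myr = phy$edge.length,
    mult_mean = colMeans(r),
    mult_sd = apply(r, 2L, stats::sd),
    mult_lo = apply(r, 2L, q, 0.025),
    mult_hi = apply(r, 2L, q, 0.975),
    eff_rate_mean = colMeans(eff),
    eff_rate_sd = apply(eff, 2L, stats::sd),
    eff_rate_lo = apply(eff, 2L, q, 0.025),
    eff_rate_hi = apply(eff, 2L, q, 0.975),
    accept_frac = as.numeric(raw$accept_frac),
    ess_ln_mult = apply(raw$lnr, 2L, .ess),
    stringsAsFactors = FALSE
  )

  af <- branch_summary$accept_frac
  diag_warnings <- character(0)
  if (config$rate_prior_sd > 0) {
    out_of_band <- mean(af) < 0.1 || mean(af) > 0.6
    if (out_of_band) {
      diag_warnings <- paste0(
        "mean Metropolis acceptance fraction ", round(mean(af), 3),
        " outside [0.1, 0.6]; retune proposal_sd")
      warning(diag_warnings, call. = FALSE)
    }
  }
  diagnostics <- list(
    accept_frac_range = if (config$rate_prior_sd > 0) range(af) else NULL,
    accept_frac_mean = if (config$rate_prior_sd > 0) mean(af) else NULL,
    ess_sigma2 = .ess(raw$sigma2),
    ess_root_state = .ess(st[, n + 1L]),
    n_samples = raw$n_kept,
    warnings = diag_warnings
  )

  structure(list(
    node_summary = node_summary,
    branch_summary = branch_summary,
    sigma2_summary = c(mean = mean(raw$sigma2), sd = stats::sd(raw$sigma2),
                       lo = q(raw$sigma2, 0.025), hi = q(raw$sigma2, 0.975)),
    diagnostics = diagnostics,
    chains = if (config$store_chains) {
      list(states = st, ln_mult = raw$lnr, sigma2 = raw$sigma2,
           log_joint = raw$log_joint)
    } else NULL,
    config = config,
    tree_signature = .tree_signature(phy),
    n_tips = n
  ), class = "mvbm_posterior")
}

# effective sample size by the truncated autocorrelation sum
.ess <- function(x) {
  nx <- length(x)
  if (nx < 3L || stats::sd(x) == 0) return(nx)
  rho <- stats::acf(x, lag.max = min(nx - 1L, 500L), plot = FALSE)$acf[-1L]
  neg <- which(rho < 0)
  if (length(neg) > 0L) rho <- rho[seq_len(neg[1L] - 1L)]
  max(1, nx / (1 + 2 * sum(rho)))
}

.tree_signature <- function(phy) {
  ape::write.tree(ape::reorder.phylo(phy, "cladewise"), digits = 12)
}

#' @export
print.mvbm_posterior <- function(x, ...) {
  cat("mvBM posterior:", x$n_tips, "tips,",
      nrow(x$node_summary), "nodes,", nrow(x$branch_summary), "branches\n")
  cat("  sigma2:", format(x$sigma2_summary["mean"], digits = 4),
      sprintf("[%s, %s]", format(x$sigma2_summary["lo"], digits = 4),
              format(x$sigma2_summary["hi"], digits = 4)), "\n")
  cat("  samples:", x$diagnostics$n_samples,
      " ESS(sigma2):", round(x$diagnostics$ess_sigma2), "\n")
  if (length(x$diagnostics$warnings)) {
    cat("  warnings:", x$diagnostics$warnings, "\n")
  }
  invisible(x)
}

#' Per-node posterior table
#'
#' Joins state and branch-rate summaries into one table keyed by the
#' stable node id, with parent id and branch duration, ready for writing
#' as a delimited file.
#'
#' @param posterior an `mvbm_posterior`.
#' @param phy the tree the posterior was computed on (checked).
#' @return data.frame keyed by `node_id`.
#' @export
posterior_node_table <- function(posterior, phy) {
  stopifnot(inherits(posterior, "mvbm_posterior"))
  if (!identical(posterior$tree_signature, .tree_signature(phy))) {
    stop("tree does not match the one the posterior was computed on")
  }
  tab <- posterior$node_summary
  br <- posterior$branch_summary[, c("node_id", "mult_mean", "mult_lo",
                                     "mult_hi", "eff_rate_mean")]
  merge(tab, br, by = "node_id", all.x = TRUE, sort = TRUE)
}
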