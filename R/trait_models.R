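# Single-trait continuous-evolution models: BM by the pruning algorithm,
# OU and EB by profile likelihood over a transformed covariance.

# Postorder peeling (Felsenstein). Returns the GLS root estimate, its
# residual variance scale, the summed log of the n contrast/root variance
# terms (at unit rate) and the accumulated standardized sum of squares.
.peel_bm <- function(phy, x) {
  n <- length(phy$tip.label)
  ntot <- n + phy$Nnode
  phy <- ape::reorder.phylo(phy, "postorder")
  m <- numeric(ntot); v <- numeric(ntot)
  has <- logical(ntot)
  m[seq_len(n)] <- x[phy$tip.label]
  has[seq_len(n)] <- TRUE
  sum_log_v <- 0
  Q <- 0
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
    V_child <- v[ch] + phy$edge.length[i]
    if (!has[p]) {
      m[p] <- m[ch]; v[p] <- V_child; has[p] <- TRUE
    } else {
      # fold this child into the parent's running estimate: one contrast
      Vs <- v[p] + V_child
      sum_log_v <- sum_log_v + log(Vs)
      Q <- Q + (m[p] - m[ch])^2 / Vs
      m[p] <- (m[p] * V_child + m[ch] * v[p]) / Vs
      v[p] <- v[p] * V_child / Vs
    }
  }
  root <- n + 1L
  list(mu = m[root], v_root = v[root], sum_log_v = sum_log_v, Q = Q, n = n)
}

.check_traits <- function(phy, traits) {
  if (is.null(names(traits))) stop("trait vector must be named by taxon")
  missing <- setdiff(phy$tip.label, names(traits))
  if (length(missing) > 0L) {
    stop("missing trait values for taxa: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- phy$tip.label[!is.finite(traits[phy$tip.label])]
  if (length(bad) > 0L) {
    stop("non-finite trait values for taxa: ", paste(bad, collapse = ", "))
  }
  traits[phy$tip.label]
}

#' Brownian-motion log-likelihood by the pruning algorithm
#'
#' Log density of the tip values under single-rate Brownian motion with
#' fixed root state: multivariate normal with mean `root_state` and
#' covariance `sigma2` times the shared-path-length matrix. Computed in
#' O(n) by postorder peeling, never forming the dense matrix.
#'
#' @param phy a `phylo` object with branch durations in Myr.
#' @param traits named numeric vector of tip values (ln units).
#' @param sigma2 rate, ln-units^2 per Myr; must be > 0.
#' @param root_state state at the root (ln units).
#' @return the log-likelihood (a single number).
#' @export
bm_loglik <- function(phy, traits, sigma2, root_state) {
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
  x <- .check_traits(phy, traits)
  p <- .peel_bm(phy, x)
  Q <- p$Q + (p$mu - root_state)^2 / p$v_root
  slv <- p$sum_log_v + log(p$v_root)
  -p$n / 2 * log(2 * pi * sigma2) - slv / 2 - Q / (2 * sigma2)
}

# unit-rate correlation structure for OU with fixed root at the optimum:
# cov(i,j) = exp(-alpha (T_i + T_j - 2 t_a)) (1 - exp(-2 alpha t_a)) / (2 alpha)
# where t_a is the shared path length from the root. Valid on
# non-ultrametric trees; reduces to the BM matrix as alpha -> 0.
.ou_corr <- function(C, alpha) {
  if (alpha < 1e-12) return(C)
  Td <- diag(C)
  outer_T <- outer(Td, Td, "+")
  exp(-alpha * (outer_T - 2 * C)) * (-expm1(-2 * alpha * C)) / (2 * alpha)
}

# early-burst: rate decays as exp(decay * t); shared-path transform
.eb_corr <- function(C, decay) {
  if (abs(decay) < 1e-12) return(C)
  expm1(decay * C) / decay
}

# GLS profile likelihood for a unit-rate covariance structure W:
# closed-form root and ML sigma2 (divisor n), via Cholesky.
.gls_profile <- function(W, x) {
  n <- length(x)
  R <- chol(W)
  z <- backsolve(R, x, transpose = TRUE)
  o <- backsolve(R, rep(1, n), transpose = TRUE)
  mu <- sum(o * z) / sum(o * o)
  Q <- sum((z - mu * o)^2)
  logdet <- 2 * sum(log(diag(R)))
  sigma2 <- Q / n
  logLik <- if (sigma2 > 0) {
    -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2
  } else NA_real_
  list(mu = mu, sigma2 = sigma2, sigma2_reml = Q / (n - 1),
       logLik = logLik, Q = Q)
}

#' Fit a continuous-trait evolution model by maximum likelihood
#'
#' `BM` uses the closed-form generalized-least-squares root and ML rate
#' (divisor n; the REML value is reported alongside). `OU` (single
#' optimum equal to the root state, fixed root -- the form that remains
#' valid when fossil tips break ultrametricity) and `EB` (exponentially
#' decaying rate) maximize the profile likelihood over their one extra
#' parameter by bounded 1-D optimization, with the GLS closed form nested
#' inside the transformed covariance.
#'
#' @param phy a `phylo` object.
#' @param traits named numeric vector of tip values.
#' @param model one of `"BM"`, `"OU"`, `"EB"`.
#' @param alpha optional fixed OU pull parameter (per Myr); skips
#'   optimization when supplied.
#' @param decay optional fixed EB rate-decay exponent (per Myr, <= 0).
#' @return an object of class `trait_model_fit`: list with elements
#'   `model`, `log_likelihood`, `n_parameters`, `aic`, `aicc`,
#'   `parameters` (sigma2, root_state, sigma2_reml, and alpha or decay),
#'   and `degenerate` (TRUE when the tip values carry no variance and the
#'   rate sits on the sigma2 = 0 boundary).
#' @export
fit_trait_model <- function(phy, traits, model = c("BM", "OU", "EB"),
                            alpha = NULL, decay = NULL) {
  model <- match.arg(model)
  x <- .check_traits(phy, traits)
  n <- length(x)
  if (n < 4L && model != "BM") stop("need >= 4 tips to fit ", model)

  if (model == "BM") {
    p <- .peel_bm(phy, x)
    sigma2 <- p$Q / n
    if (sigma2 <= 0) {
      return(.fit_result("BM", NA_real_, 2L,
                         list(sigma2 = 0, root_state = p$mu,
                              sigma2_reml = 0), n, degenerate = TRUE))
    }
    slv <- p$sum_log_v + log(p$v_root)
    logLik <- -n / 2 * log(2 * pi * sigma2) - slv / 2 - n / 2
    return(.fit_result("BM", logLik, 2L,
                       list(sigma2 = sigma2, root_state = p$mu,
                            sigma2_reml = p$Q / (n - 1)), n))
  }

  C <- ape::vcv(phy)[phy$tip.label, phy$tip.label]
  max_depth <- max(diag(C))
  xv <- as.numeric(x)

  if (model == "OU") {
    obj <- function(a) {
      g <- .gls_profile(.ou_corr(C, a), xv)
      if (!is.finite(g$logLik)) return(1e10)
      -g$logLik
    }
    a_hat <- if (!is.null(alpha)) alpha else {
      opt <- stats::optimize(obj, interval = c(1e-8, max(50 / max_depth, 5)))
      if (!is.finite(opt$objective)) {
        stop("OU optimizer failed to converge; best alpha = ", opt$minimum)
      }
      opt$minimum
    }
    g <- .gls_profile(.ou_corr(C, a_hat), xv)
    if (g$sigma2 <= 0) {
      return(.fit_result("OU", NA_real_, 3L,
                         list(sigma2 = 0, root_state = g$mu,
                              sigma2_reml = 0, alpha = a_hat), n,
                         degenerate = TRUE))
    }
    return(.fit_result("OU", g$logLik, 3L,
                       list(sigma2 = g$sigma2, root_state = g$mu,
                            sigma2_reml = g$sigma2_reml, alpha = a_hat), n))
  }

  # EB
  obj <- function(r) {
    g <- .gls_profile(.eb_corr(C, r), xv)
    if (!is.finite(g$logLik)) return(1e10)
    -g$logLik
  }
  r_hat <- if (!is.null(decay)) decay else {
    opt <- stats::optimize(obj, interval = c(-max(20 / max_depth, 2), 0))
    if (!is.finite(opt$objective)) {
      stop("EB optimizer failed to converge; best decay = ", opt$minimum)
    }
    opt$minimum
  }
  g <- .gls_profile(.eb_corr(C, r_hat), xv)
  if (g$sigma2 <= 0) {
    return(.fit_result("EB", NA_real_, 3L,
                       list(sigma2 = 0, root_state = g$mu,
                            sigma2_reml = 0, decay = r_hat), n,
                       degenerate = TRUE))
  }
  .fit_result("EB", g$logLik, 3L,
              list(sigma2 = g$sigma2, root_state = g$mu,
                   sigma2_reml = g$sigma2_reml, decay = r_hat), n)
}

.fit_result <- function(model, logLik, k, params, n, degenerate = FALSE) {
  aic <- if (is.finite(logLik)) 2 * k - 2 * logLik else NA_real_
  aicc <- if (is.finite(aic) && n - k - 1 > 0) {
    aic + 2 * k * (k + 1) / (n - k - 1)
  } else NA_real_
  structure(
    list(model = model, log_likelihood = logLik, n_parameters = k,
         aic = aic, aicc = aicc, parameters = params, n_tips = n,
         degenerate = degenerate),
    class = "trait_model_fit"
  )
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat(x$model, "fit:", x$n_tips, "tips\n")
  cat("  logLik =", format(x$log_likelihood), " AIC =", format(x$aic), "\n")
  cat("  ", paste(names(x$parameters),
                  vapply(x$parameters, function(p) format(p, digits = 6), ""),
                  sep = " = ", collapse = ", "), "\n")
  if (x$degenerate) cat("  [degenerate: rate on the sigma2 = 0 boundary]\n")
  invisible(x)
}

#' Compare continuous-trait models by AIC
#'
#' Fits each requested model and returns a table sorted ascending by AIC
#' with delta-AIC relative to the best model; AICc is reported alongside.
#'
#' @param phy a `phylo` object.
#' @param traits named numeric vector of tip values.
#' @param models character vector from `c("BM","OU","EB")`.
#' @return data.frame with columns `model`, `k`, `logLik`, `AIC`, `dAIC`,
#'   `AICc`, `sigma2`, `root_state`, `alpha`, `decay`, sorted by AIC; the
#'   fitted objects are attached as attribute `"fits"`.
#' @export
compare_trait_models <- function(phy, traits, models = c("BM", "OU", "EB")) {
  if (length(models) < 1L) stop("at least one model required")
  fits <- lapply(models, function(m) fit_trait_model(phy, traits, m))
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$model, k = f$n_parameters,
               logLik = f$log_likelihood, AIC = f$aic, AICc = f$aicc,
               sigma2 = f$parameters$sigma2,
               root_state = f$parameters$root_state,
               alpha = if (is.null(f$parameters$alpha)) NA_real_ else f$parameters$alpha,
               decay = if (is.null(f$parameters$decay)) NA_real_ else f$parameters$decay,
               stringsAsFactors = FALSE)
  }))
  ord <- order(tab$AIC)
  tab <- tab[ord, , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1L]
  rownames(tab) <- NULL
  tab <- tab[, c("model", "k", "logLik", "AIC", "dAIC", "AICc",
                 "sigma2", "root_state", "alpha", "decay")]
  attr(tab, "fits") <- fits[ord]
  tab
}
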