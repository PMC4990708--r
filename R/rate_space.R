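# Signed two-trait rate space: per-branch rates, RMA line, six-scenario
# tradeoff classification, branch painting.

#' Per-branch signed evolutionary rates for two traits
#'
#' For every non-root node, the change along its subtending branch is the
#' child minus parent posterior-mean state, and the signed rate is that
#' change divided by the branch duration (ln-units per Myr). Sign is kept
#' deliberately: distinguishing increase from decrease is what makes the
#' tradeoff scenarios expressible.
#'
#' @param posterior_rap,posterior_hw `mvbm_posterior` objects for the
#'   two traits, computed on the same tree.
#' @param phy the shared tree.
#' @return data.frame with one row per branch: `node_id`, `parent_id`,
#'   `duration_myr`, `delta_rap`, `delta_hw`, `rate_rap`, `rate_hw`
#'   (scenario is assigned later by [classify_branches()]).
#' @export
branch_rates <- function(posterior_rap, posterior_hw, phy) {
  sig <- .tree_signature(phy)
  if (!identical(posterior_rap$tree_signature, sig) ||
      !identical(posterior_hw$tree_signature, sig)) {
    stop("posteriors were not computed on the supplied tree")
  }
  a <- posterior_rap$node_summary
  b <- posterior_hw$node_summary
  if (!identical(a$node_id, b$node_id)) stop("node sets differ between posteriors")
  nonroot <- which(!is.na(a$parent_id))
  idx <- a$node_id[nonroot]
  pidx <- a$parent_id[nonroot]
  dur <- a$duration_myr[nonroot]
  d_rap <- a$state_mean[match(idx, a$node_id)] - a$state_mean[match(pidx, a$node_id)]
  d_hw <- b$state_mean[match(idx, b$node_id)] - b$state_mean[match(pidx, b$node_id)]
  data.frame(node_id = idx, parent_id = pidx, duration_myr = dur,
             delta_rap = d_rap, delta_hw = d_hw,
             rate_rap = d_rap / dur, rate_hw = d_hw / dur)
}

#' Reduced major axis regression
#'
#' Symmetric line fitting standard in allometry: the slope is the
#' sign-carrying ratio of standard deviations, `sign(r) * sd(y)/sd(x)`,
#' and the line passes through the means.
#'
#' @param x,y numeric vectors of equal length >= 3 with positive sd.
#' @return list of class `rma_fit`: `slope`, `intercept`, `r` (Pearson
#'   correlation), `n`.
#' @export
rma_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 points")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance in x or y: RMA is degenerate")
  r <- stats::cor(x, y)
  slope <- sign(r) * sy / sx
  if (slope == 0) slope <- sy / sx # r exactly 0: keep the magnitude, +ve
  intercept <- mean(y) - slope * mean(x)
  structure(list(slope = slope, intercept = intercept, r = r,
                 n = length(x)), class = "rma_fit")
}

#' @export
print.rma_fit <- function(x, ...) {
  cat(sprintf("RMA fit (n = %d): slope = %.6g, intercept = %.6g, r = %.4f\n",
              x$n, x$slope, x$intercept, x$r))
  invisible(x)
}

#' The six rate-tradeoff scenarios
#'
#' @format character vector of the scenario codes: accelerated increase
#'   (AI), decelerated increase (DI), separation with RAP elongation
#'   (SEP_POS), decelerated decrease (DD), accelerated decrease (AD),
#'   separation with RAP shortening (SEP_NEG), plus the on-line isometry
#'   tie ISO.
#' @export
SCENARIOS <- c("AI", "DI", "SEP_POS", "DD", "AD", "SEP_NEG", "ISO")

#' Classify branches into rate-tradeoff scenarios
#'
#' With `u = rate_hw` (body-size proxy), `v = rate_rap` (bite-force
#' proxy) and `resid = v - (slope*u + intercept)` the vertical offset
#' from the RMA isometry line:
#' both rates positive and above the line -> AI (RAP increasing faster
#' than body size); both positive, below -> DI; RAP increasing while
#' body size non-increasing -> SEP_POS (pure RAP elongation); both
#' negative, above -> DD (RAP decreasing more slowly); both negative,
#' below -> AD; RAP decreasing while body size non-decreasing ->
#' SEP_NEG; within `tolerance` of the line in a same-sign quadrant, or
#' no change at all -> ISO. Every branch receives exactly one label.
#'
#' @param records data.frame from [branch_rates()].
#' @param fit an [rma_fit()] of `rate_rap` on `rate_hw` over the same
#'   records.
#' @param tolerance residual magnitude treated as "on the line"
#'   (ln-units per Myr). Exact ties essentially only occur in
#'   constructed fixtures; the default 1e-9 reflects that.
#' @return `records` with columns `rma_residual` and `scenario` added.
#' @export
classify_branches <- function(records, fit, tolerance = 1e-9) {
  stopifnot(inherits(fit, "rma_fit"))
  u <- records$rate_hw
  v <- records$rate_rap
  resid <- v - (fit$slope * u + fit$intercept)
  scen <- character(length(u))
  for (i in seq_along(u)) {
    scen[i] <-
      if (u[i] == 0 && v[i] == 0) "ISO"
      else if (u[i] <= 0 && v[i] > 0) "SEP_POS"
      else if (u[i] >= 0 && v[i] < 0) "SEP_NEG"
      else if (abs(resid[i]) <= tolerance) "ISO"
      else if (u[i] > 0 && v[i] > 0) { if (resid[i] > 0) "AI" else "DI" }
      else { if (resid[i] > 0) "DD" else "AD" } # u < 0 && v < 0
  }
  records$rma_residual <- resid
  records$scenario <- factor(scen, levels = SCENARIOS)
  records
}

#' Scenario-probability table from posterior draws
#'
#' Propagates the thinned posterior draws of both traits' node states
#' through the rate-space construction, refitting the RMA line per draw,
#' and reports the fraction of draws assigning each branch to each
#' scenario. Complements the single point-estimate label per branch.
#'
#' @param posterior_rap,posterior_hw `mvbm_posterior` objects with
#'   stored chains.
#' @param phy the shared tree.
#' @param tolerance passed to [classify_branches()].
#' @param max_draws cap on the number of draws used.
#' @return data.frame: `node_id` plus one probability column per
#'   scenario.
#' @export
scenario_probabilities <- function(posterior_rap, posterior_hw, phy,
                                   tolerance = 1e-9, max_draws = 500L) {
  if (is.null(posterior_rap$chains) || is.null(posterior_hw$chains)) {
    stop("posteriors must carry stored chains (store_chains = TRUE)")
  }
  phy <- ape::reorder.phylo(phy, "cladewise")
  ndraw <- min(nrow(posterior_rap$chains$states),
               nrow(posterior_hw$chains$states), max_draws)
  ch <- phy$edge[, 2L]; pa <- phy$edge[, 1L]; dur <- phy$edge.length
  counts <- matrix(0L, nrow(phy$edge), length(SCENARIOS),
                   dimnames = list(NULL, SCENARIOS))
  for (s in seq_len(ndraw)) {
    ra <- posterior_rap$chains$states[s, ]
    hw <- posterior_hw$chains$states[s, ]
    u <- (hw[ch] - hw[pa]) / dur
    v <- (ra[ch] - ra[pa]) / dur
    rec <- data.frame(node_id = ch, rate_hw = u, rate_rap = v)
    lab <- classify_branches(rec, rma_fit(u, v), tolerance)$scenario
    counts[cbind(seq_along(lab), as.integer(lab))] <-
      counts[cbind(seq_along(lab), as.integer(lab))] + 1L
  }
  out <- data.frame(node_id = ch, counts / ndraw)
  names(out)[-1L] <- paste0("p_", SCENARIOS)
  out
}

#' Paint scenarios onto the tree
#'
#' Produces (1) an annotated Newick string with each branch's scenario as
#' a `[&scenario=..]` comment after its length, (2) a census of branches
#' per scenario, and (3) for every tip the length of the contiguous run
#' of AI-labeled branches ending at that tip (walking rootward from the
#' tip's own branch) -- the "continuous AI trend" diagnostic -- with the
#' longest run and its tip singled out.
#'
#' @param phy the tree.
#' @param records classified records from [classify_branches()].
#' @return list of class `painted_tree`: `newick`, `census` (named
#'   integer vector over all scenarios), `ai_runs` (named integer vector
#'   per tip), `longest_ai_run`, `longest_ai_tip`.
#' @export
paint_tree <- function(phy, records) {
  if (is.null(records$scenario) || anyNA(records$scenario)) {
    stop("records must be classified before painting")
  }
  phy <- ape::reorder.phylo(phy, "cladewise")
  scen_of <- stats::setNames(as.character(records$scenario), records$node_id)
  if (!setequal(records$node_id, phy$edge[, 2L])) {
    stop("records do not cover the tree's branches")
  }
  n <- length(phy$tip.label)
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  rec <- function(node) {
    inner <- if (node > n) {
      rows <- children[[as.character(node)]]
      paste0("(", paste(vapply(rows, function(r) rec(phy$edge[r, 2L]), ""),
                        collapse = ","), ")")
    } else phy$tip.label[node]
    row <- which(phy$edge[, 2L] == node)
    if (length(row) == 0L) return(inner) # root
    paste0(inner, ":", format(phy$edge.length[row], digits = 12),
           "[&scenario=", scen_of[as.character(node)], "]")
  }
  newick <- paste0(rec(n + 1L), ";")

  census <- table(factor(as.character(records$scenario), levels = SCENARIOS))
  census <- stats::setNames(as.integer(census), SCENARIOS)

  parent_of <- integer(n + phy$Nnode)
  parent_of[phy$edge[, 2L]] <- phy$edge[, 1L]
  ai_runs <- stats::setNames(integer(n), phy$tip.label)
  for (tip in seq_len(n)) {
    node <- tip; run <- 0L
    while (node != n + 1L &&
           identical(unname(scen_of[as.character(node)]), "AI")) {
      run <- run + 1L
      node <- parent_of[node]
    }
    ai_runs[tip] <- run
  }
  best <- which.max(ai_runs)
  structure(list(newick = newick, census = census, ai_runs = ai_runs,
                 longest_ai_run = unname(ai_runs[best]),
                 longest_ai_tip = if (ai_runs[best] > 0L) names(ai_runs)[best] else NA_character_),
            class = "painted_tree")
}

#' @export
print.painted_tree <- function(x, ...) {
  cat("painted tree:", sum(x$census), "branches\n")
  nonzero <- x$census[x$census > 0]
  cat("  census:", paste(names(nonzero), nonzero, sep = "=", collapse = ", "), "\n")
  if (!is.na(x$longest_ai_tip)) {
    cat("  longest AI run:", x$longest_ai_run, "branches, ending at",
        x$longest_ai_tip, "\n")
  } else cat("  no AI branches\n")
  invisible(x)
}
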