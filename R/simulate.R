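# Synthetic-data generators: Yule time trees (optionally with fossil
# tips), traits under single- or multiple-rate Brownian motion with
# recorded truth, and biphasic allometric ontogenetic series. Every
# generator is a pure function of (parameters, seed).

#' Simulate a time-calibrated tree
#'
#' Pure-birth (Yule) tree grown to `n_tips`, branch durations in Myr.
#' With `fossil_fraction > 0`, that fraction of tips (rounded) is
#' truncated at a uniform random height along its terminal branch,
#' producing the non-ultrametric shape typical of phylogenies that mix
#' fossil and extant taxa. The result is returned in canonical node
#' order (see [canonicalize_tree()]).
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per Myr (> 0).
#' @param seed integer seed.
#' @param fossil_fraction fraction of tips truncated into fossils, in
#'   `[0, 1)`.
#' @return a `phylo` object with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 0.1, seed = 1L,
                          fossil_fraction = 0) {
  if (n_tips < 2L) stop("need n_tips >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  if (fossil_fraction < 0 || fossil_fraction >= 1) {
    stop("fossil_fraction must be in [0, 1)")
  }
  set.seed(as.integer(seed))
  phy <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  k <- round(fossil_fraction * n_tips)
  if (k > 0L) {
    fossils <- sample.int(n_tips, k)
    for (tip in fossils) {
      row <- which(phy$edge[, 2L] == tip)
      # truncate at a uniform height within the terminal branch, keeping
      # a strictly positive remainder
      phy$edge.length[row] <- phy$edge.length[row] * stats::runif(1, 0.05, 0.95)
    }
  }
  canonicalize_tree(phy)
}

#' Simulate trait evolution under (multi-rate) Brownian motion
#'
#' Walks the tree root-to-tips adding independent normal increments with
#' variance `sigma2 * r_b * t_b` on each branch, where `r_b` is the
#' branch's rate multiplier. `multipliers = 1` (or any scalar) gives
#' plain Brownian motion; a named vector keyed by child node id sets
#' branch-specific multipliers (unnamed branches default to 1). The full
#' truth -- every node state and every branch multiplier -- is recorded
#' so that estimators can be scored against it.
#'
#' @param phy a `phylo` object (use a canonical tree so node ids are
#'   stable).
#' @param sigma2 base rate, ln-units^2 per Myr (>= 0; 0 gives a constant
#'   trait).
#' @param root_state state at the root.
#' @param multipliers scalar, or numeric vector named by child node id.
#' @param seed integer seed.
#' @return list with `tip_values` (named by tip label), and `truth`:
#'   `node_states` (indexed by node id), `multipliers` (per branch,
#'   named by child node id), `sigma2`, `root_state`, `seed`.
#' @export
simulate_mvbm <- function(phy, sigma2, root_state = 0, multipliers = 1,
                          seed = 1L) {
  validate_time_tree(phy)
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  phy <- ape::reorder.phylo(phy, "cladewise")
  n <- length(phy$tip.label)
  ntot <- n + phy$Nnode
  mult <- rep(1, nrow(phy$edge))
  names(mult) <- phy$edge[, 2L]
  if (length(multipliers) == 1L && is.null(names(multipliers))) {
    mult[] <- multipliers
  } else {
    if (is.null(names(multipliers))) {
      stop("per-branch multipliers must be named by child node id")
    }
    unknown <- setdiff(names(multipliers), names(mult))
    if (length(unknown)) stop("unknown branch ids: ", paste(unknown, collapse = ", "))
    mult[names(multipliers)] <- multipliers
  }
  if (any(mult <= 0)) stop("multipliers must be positive")

  set.seed(as.integer(seed))
  x <- numeric(ntot)
  x[n + 1L] <- root_state
  # cladewise order visits every parent before its children
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
    sd_i <- sqrt(sigma2 * mult[i] * phy$edge.length[i])
    x[ch] <- x[p] + if (sd_i > 0) stats::rnorm(1, 0, sd_i) else 0
  }
  list(
    tip_values = stats::setNames(x[seq_len(n)], phy$tip.label),
    truth = list(node_states = x, multipliers = mult, sigma2 = sigma2,
                 root_state = root_state, seed = as.integer(seed))
  )
}

#' Simulate a biphasic allometric ontogenetic series
#'
#' Emulates a wild developmental series of *Alligator mississippiensis*:
#' head widths on an even grid in ln(mm) across `hw_range_mm`, and RAP
#' length following a continuous two-phase log-log allometry --
#' `ln(rap) = ln(a1) + b1 * ln(hw)` below the breakpoint, continuing
#' with slope `b2` above it -- plus additive normal noise on ln(rap)
#' (multiplicative on the raw scale, the usual error structure for
#' allometric data). The defaults encode strongly positive early
#' allometry (`b1 > 1`) that decelerates to slight negative allometry
#' (`b2 < 1`) at a breakpoint about 30% of the way up the ln(HW) range,
#' the size region where juvenile crocodylians first gain access to
#' robust prey; total length is reported on a 28--364 cm scale mapped
#' log-linearly from head width.
#'
#' @param n number of specimens (default 34).
#' @param hw_range_mm head-width range, mm.
#' @param a1 allometric coefficient of the juvenile phase (raw scale).
#' @param b1 juvenile-phase log-log slope (> 0, default > 1).
#' @param b2 later-phase log-log slope (> 0, default < 1).
#' @param breakpoint_hw_mm head width at the phase change; must lie
#'   inside `hw_range_mm`.
#' @param noise_sd sd of the noise on ln(rap).
#' @param seed integer seed.
#' @return data.frame with columns `specimen`, `total_length_cm`,
#'   `rap_mm`, `hw_mm`.
#' @export
simulate_ontogeny <- function(n = 34L, hw_range_mm = c(15, 260),
                              a1 = 0.12, b1 = 1.35, b2 = 0.95,
                              breakpoint_hw_mm = 35, noise_sd = 0.05,
                              seed = 1L) {
  if (b1 <= 0 || b2 <= 0) stop("allometric slopes must be > 0")
  if (any(hw_range_mm <= 0) || hw_range_mm[2L] <= hw_range_mm[1L]) {
    stop("hw_range_mm must be an increasing positive pair")
  }
  if (breakpoint_hw_mm <= hw_range_mm[1L] ||
      breakpoint_hw_mm >= hw_range_mm[2L]) {
    stop("breakpoint must lie strictly inside hw_range_mm")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  ln_hw <- seq(log(hw_range_mm[1L]), log(hw_range_mm[2L]), length.out = n)
  ln_bp <- log(breakpoint_hw_mm)
  # continuous at the breakpoint: intercept of phase 2 absorbs the kink
  ln_rap <- ifelse(ln_hw <= ln_bp,
                   log(a1) + b1 * ln_hw,
                   log(a1) + (b1 - b2) * ln_bp + b2 * ln_hw)
  if (noise_sd > 0) ln_rap <- ln_rap + stats::rnorm(n, 0, noise_sd)
  lo <- log(hw_range_mm[1L]); hi <- log(hw_range_mm[2L])
  tl <- exp(log(28) + (log(364) - log(28)) * (ln_hw - lo) / (hi - lo))
  data.frame(
    specimen = sprintf("S%02d", seq_len(n)),
    total_length_cm = tl,
    rap_mm = exp(ln_rap),
    hw_mm = exp(ln_hw)
  )
}
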