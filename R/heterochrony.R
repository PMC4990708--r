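# Ten-stage trajectories of the RAP:HW log-ratio, ontogenetic and
# evolutionary, and their comparison.

.stage_ratio <- function(ln_rap, ln_hw, ratio) {
  if (ratio == "log-quotient") {
    if (any(ln_hw == 0)) {
      stop("ln(HW) = 0 (measurement of exactly 1 mm): ",
           "log-quotient ratio undefined", call. = FALSE)
    }
    ln_rap / ln_hw
  } else {
    ln_rap - ln_hw
  }
}

#' Ontogenetic trajectory of the RAP:HW ratio
#'
#' Bins an ontogenetic measurement series into `n_stages` progressive
#' stages over ln(head width) and returns the per-stage mean trait
#' ratio. The default ratio is the quotient of natural logs,
#' `ln(RAP)/ln(HW)`; `ratio = "log-ratio"` switches to `ln(RAP/HW)`.
#' Stages are equal-width intervals in ln(HW) between the series minimum
#' and maximum (`bins = "count"` gives equal-count quantile bins
#' instead).
#'
#' @param series data.frame with columns `rap_mm` and `hw_mm` (e.g. from
#'   [read_ontogeny_series()] or [simulate_ontogeny()]).
#' @param n_stages number of stages (default 10).
#' @param ratio `"log-quotient"` (default) or `"log-ratio"`.
#' @param bins `"width"` (equal width in ln HW, default) or `"count"`.
#' @return object of class `stage_trajectory`: data.frame with columns
#'   `stage`, `mean_ratio` (NA where the bin is empty), `n_in_bin`,
#'   `bin_lo`, `bin_hi`; attribute `kind = "ontogeny"`.
#' @export
ontogeny_trajectory <- function(series, n_stages = 10L,
                                ratio = c("log-quotient", "log-ratio"),
                                bins = c("width", "count")) {
  ratio <- match.arg(ratio); bins <- match.arg(bins)
  if (is.null(series) || nrow(series) == 0L) stop("empty ontogeny series")
  if (any(series$rap_mm <= 0) || any(series$hw_mm <= 0)) {
    stop("measurements must be strictly positive")
  }
  ln_hw <- log(series$hw_mm)
  ln_rap <- log(series$rap_mm)
  vals <- .stage_ratio(ln_rap, ln_hw, ratio)
  edges <- if (bins == "width") {
    seq(min(ln_hw), max(ln_hw), length.out = n_stages + 1L)
  } else {
    unique(stats::quantile(ln_hw, probs = seq(0, 1, length.out = n_stages + 1L),
                           type = 7))
  }
  if (length(edges) < n_stages + 1L) {
    stop("too many tied ln(HW) values for equal-count binning")
  }
  stage <- findInterval(ln_hw, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
  .build_trajectory(vals, stage, n_stages, edges, "ontogeny", ratio)
}

#' Evolutionary trajectory of the RAP:HW ratio along an ancestor chain
#'
#' Maps the `m` ancestor-chain states (root-first, focal tip last) onto
#' `n_stages` sequential stages: entry `k` goes to stage
#' `ceiling(n_stages * k / m)`, so the earliest ancestors land in stage 1
#' and the extant focal taxon in stage `n_stages`. Inputs are the
#' posterior-mean ln states for the two traits at each chain node.
#'
#' @param chain_ln_rap,chain_ln_hw numeric vectors of equal length
#'   `m >= 2`, ordered root-first.
#' @param n_stages number of stages (default 10).
#' @param ratio `"log-quotient"` (default) or `"log-ratio"`.
#' @return object of class `stage_trajectory` with attribute
#'   `kind = "evolution"`; `bin_lo`/`bin_hi` hold the chain positions
#'   mapped into each stage.
#' @export
evolution_trajectory <- function(chain_ln_rap, chain_ln_hw, n_stages = 10L,
                                 ratio = c("log-quotient", "log-ratio")) {
  ratio <- match.arg(ratio)
  m <- length(chain_ln_rap)
  if (length(chain_ln_hw) != m) stop("chain length mismatch between traits")
  if (m < 2L) stop("need at least 2 chain entries")
  vals <- .stage_ratio(chain_ln_rap, chain_ln_hw, ratio)
  stage <- ceiling(n_stages * seq_len(m) / m)
  edges <- NULL
  out <- .build_trajectory(vals, stage, n_stages, NULL, "evolution", ratio)
  # record which chain positions fell in each stage
  out$bin_lo <- vapply(seq_len(n_stages), function(s) {
    w <- which(stage == s); if (length(w)) min(w) else NA_real_
  }, 0)
  out$bin_hi <- vapply(seq_len(n_stages), function(s) {
    w <- which(stage == s); if (length(w)) max(w) else NA_real_
  }, 0)
  out
}

.build_trajectory <- function(vals, stage, n_stages, edges, kind, ratio) {
  mean_ratio <- rep(NA_real_, n_stages)
  n_in_bin <- integer(n_stages)
  for (s in seq_len(n_stages)) {
    w <- which(stage == s)
    n_in_bin[s] <- length(w)
    if (length(w)) mean_ratio[s] <- mean(vals[w])
  }
  out <- data.frame(
    stage = seq_len(n_stages),
    mean_ratio = mean_ratio,
    n_in_bin = n_in_bin,
    bin_lo = if (is.null(edges)) NA_real_ else edges[seq_len(n_stages)],
    bin_hi = if (is.null(edges)) NA_real_ else edges[-1L]
  )
  class(out) <- c("stage_trajectory", "data.frame")
  attr(out, "kind") <- kind
  attr(out, "ratio") <- ratio
  out
}

#' Compare an evolutionary and an ontogenetic stage trajectory
#'
#' Computes the per-stage ratio difference (evolution minus ontogeny)
#' and locates each trajectory's inflection stage as the interior stage
#' (2..n-1) maximizing the absolute second difference of the stage
#' means, ties broken toward the earliest stage. When the largest second
#' difference is below `flatness` the trajectory is treated as having no
#' inflection. The inversion flag is set when the ontogenetic inflection
#' precedes the evolutionary one -- the signature of inverted
#' heterochrony, where a developmental transition that happens early in
#' ontogeny appears late along the evolutionary progression.
#'
#' @param evo,onto `stage_trajectory` objects with the same number of
#'   stages, each with at least 3 nonempty stages.
#' @param flatness second-difference magnitude below which no inflection
#'   is declared (default 1e-6).
#' @return list of class `trajectory_comparison`: `stage_diff`
#'   (data.frame stage, evo, onto, diff), `inflection_evo`,
#'   `inflection_onto` (integer or NA), `inversion_flag`.
#' @export
compare_trajectories <- function(evo, onto, flatness = 1e-6) {
  stopifnot(inherits(evo, "stage_trajectory"),
            inherits(onto, "stage_trajectory"))
  if (nrow(evo) != nrow(onto)) stop("stage counts differ")
  if (sum(!is.na(evo$mean_ratio)) < 3L || sum(!is.na(onto$mean_ratio)) < 3L) {
    stop("need at least 3 nonempty stages in each trajectory")
  }
  infl_evo <- .inflection_stage(evo$mean_ratio, flatness)
  infl_onto <- .inflection_stage(onto$mean_ratio, flatness)
  structure(list(
    stage_diff = data.frame(stage = evo$stage, evo = evo$mean_ratio,
                            onto = onto$mean_ratio,
                            diff = evo$mean_ratio - onto$mean_ratio),
    inflection_evo = infl_evo,
    inflection_onto = infl_onto,
    inversion_flag = !is.na(infl_evo) && !is.na(infl_onto) &&
      infl_onto < infl_evo
  ), class = "trajectory_comparison")
}

# interior stage maximizing |second difference| of the stage means;
# stages with an empty neighbor are skipped (second difference undefined)
.inflection_stage <- function(means, flatness) {
  n <- length(means)
  best <- NA_integer_; best_val <- -Inf
  for (s in 2:(n - 1L)) {
    trio <- means[(s - 1L):(s + 1L)]
    if (anyNA(trio)) next
    d2 <- abs(trio[3L] - 2 * trio[2L] + trio[1L])
    if (d2 > best_val + 0) { # strict: ties keep the earliest stage
      best_val <- d2; best <- s
    }
  }
  if (!is.finite(best_val) || best_val < flatness) return(NA_integer_)
  as.integer(best)
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  cat("trajectory comparison (", nrow(x$stage_diff), "stages )\n")
  cat("  inflection: ontogeny =",
      ifelse(is.na(x$inflection_onto), "none", x$inflection_onto),
      ", evolution =",
      ifelse(is.na(x$inflection_evo), "none", x$inflection_evo), "\n")
  cat("  inverted heterochrony:", x$inversion_flag, "\n")
  invisible(x)
}
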