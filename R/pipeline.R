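# End-to-end pipeline and the command-line surface over it.

#' Run the full analysis pipeline
#'
#' Executes prune -> model comparison -> mvBM (once per trait) ->
#' rate-space classification -> heterochrony comparison, writing every
#' intermediate table plus a JSON run manifest to `out_dir`. All inputs
#' are validated and the entire computation finishes before anything is
#' written, so a failing run leaves no partial tables.
#'
#' @param tree_file Newick tree, durations in Myr.
#' @param traits_file delimited taxon/rap_mm/hw_mm table.
#' @param ontogeny_file delimited ontogeny series (may be NULL to skip
#'   the heterochrony step).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the two MCMC chains (RAP uses `seed`,
#'   HW `seed + 1`).
#' @param iterations,burn_in,thin mvBM sampler settings, see
#'   [mvbm_config()].
#' @param rate_prior_sd prior sd on log branch-rate multipliers.
#' @param n_stages trajectory stages (default 10).
#' @param ratio `"log-quotient"` or `"log-ratio"` trait-ratio convention.
#' @param bins `"width"` or `"count"` ontogeny binning.
#' @param tolerance ISO tolerance for scenario classification.
#' @param focal_tip tip whose ancestor chain forms the evolutionary
#'   trajectory; defaults to the tip with the greatest root-to-tip
#'   duration (the most deeply sampled extant terminal).
#' @param steps subset of `c("models","mvbm","ratespace","heterochrony")`;
#'   later steps pull in the earlier ones they need.
#' @param verbose 0 (quiet), 1 or 2; progress goes to stderr.
#' @return (invisibly) a list with every in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(tree_file, traits_file, ontogeny_file = NULL,
                         out_dir, seed = 1L, iterations = 100000L,
                         burn_in = 0.2, thin = 10L, rate_prior_sd = 1,
                         n_stages = 10L,
                         ratio = c("log-quotient", "log-ratio"),
                         bins = c("width", "count"), tolerance = 1e-9,
                         focal_tip = NULL,
                         steps = c("models", "mvbm", "ratespace",
                                   "heterochrony"),
                         verbose = 0L) {
  ratio <- match.arg(ratio); bins <- match.arg(bins)
  steps <- match.arg(steps, several.ok = TRUE)
  t0 <- Sys.time()
  say <- function(level, ...) {
    if (verbose >= level) message("[bitephylo] ", ...)
  }

  # resolve and validate all inputs up front: no partial outputs
  for (f in c(tree_file, traits_file, ontogeny_file)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  need_onto <- "heterochrony" %in% steps
  if (need_onto && is.null(ontogeny_file)) {
    stop("heterochrony step requires an ontogeny file")
  }

  say(1, "reading inputs")
  tree <- read_time_tree(tree_file)
  traits <- read_trait_table(traits_file)
  onto <- if (!is.null(ontogeny_file)) read_ontogeny_series(ontogeny_file)
  shared <- intersect(tree$tip.label, traits$taxon)
  if (length(shared) < 4L) {
    stop("fewer than 4 taxa shared between tree and trait table")
  }
  tree <- prune_to_taxa(tree, shared)
  ln_rap <- stats::setNames(traits$ln_rap, traits$taxon)[tree$tip.label]
  ln_hw <- stats::setNames(traits$ln_hw, traits$taxon)[tree$tip.label]

  res <- list(tree = tree)
  outputs <- list()

  if (any(c("models", "mvbm", "ratespace", "heterochrony") %in% steps)) {
    say(1, "comparing trait models")
    res$models_rap <- compare_trait_models(tree, ln_rap)
    res$models_hw <- compare_trait_models(tree, ln_hw)
  }

  need_mvbm <- any(c("mvbm", "ratespace", "heterochrony") %in% steps)
  if (need_mvbm) {
    say(1, "running mvBM MCMC (RAP)")
    cfg_rap <- mvbm_config(iterations = iterations, burn_in = burn_in,
                           thin = thin, seed = seed,
                           rate_prior_sd = rate_prior_sd)
    res$posterior_rap <- mvbm_mcmc(tree, ln_rap, cfg_rap)
    say(1, "running mvBM MCMC (HW)")
    cfg_hw <- mvbm_config(iterations = iterations, burn_in = burn_in,
                          thin = thin, seed = seed + 1L,
                          rate_prior_sd = rate_prior_sd)
    res$posterior_hw <- mvbm_mcmc(tree, ln_hw, cfg_hw)
  }

  if (any(c("ratespace", "heterochrony") %in% steps)) {
    say(1, "building rate space")
    recs <- branch_rates(res$posterior_rap, res$posterior_hw, tree)
    res$rma <- rma_fit(recs$rate_hw, recs$rate_rap)
    res$rate_table <- classify_branches(recs, res$rma, tolerance)
    res$painted <- paint_tree(tree, res$rate_table)
  }

  if ("heterochrony" %in% steps) {
    say(1, "building trajectories")
    if (is.null(focal_tip)) {
      focal_tip <- names(which.max(tip_depths(tree)))
    }
    chain <- ancestor_chain(tree, focal_tip)
    ns <- res$posterior_rap$node_summary
    nh <- res$posterior_hw$node_summary
    res$focal_tip <- focal_tip
    res$evo_traj <- evolution_trajectory(
      ns$state_mean[match(chain, ns$node_id)],
      nh$state_mean[match(chain, nh$node_id)],
      n_stages = n_stages, ratio = ratio)
    res$onto_traj <- ontogeny_trajectory(onto, n_stages = n_stages,
                                         ratio = ratio, bins = bins)
    res$comparison <- compare_trajectories(res$evo_traj, res$onto_traj)
  }

  # ---- write everything at once ----
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    outputs[[length(outputs) + 1L]] <<- name
  }
  if (!is.null(res$models_rap)) {
    emit("models_rap.tsv", function(p) write_table(res$models_rap, p))
    emit("models_hw.tsv", function(p) write_table(res$models_hw, p))
  }
  if (!is.null(res$posterior_rap)) {
    emit("nodes_rap.tsv", function(p)
      write_table(posterior_node_table(res$posterior_rap, tree), p))
    emit("nodes_hw.tsv", function(p)
      write_table(posterior_node_table(res$posterior_hw, tree), p))
  }
  if (!is.null(res$rate_table)) {
    emit("rate_space.tsv", function(p) write_table(res$rate_table, p))
    emit("painted_tree.nwk", function(p)
      writeLines(res$painted$newick, p))
  }
  if (!is.null(res$comparison)) {
    emit("trajectory_evolution.tsv", function(p)
      write_table(as.data.frame(res$evo_traj), p))
    emit("trajectory_ontogeny.tsv", function(p)
      write_table(as.data.frame(res$onto_traj), p))
    emit("heterochrony.tsv", function(p)
      write_table(res$comparison$stage_diff, p))
  }

  manifest <- list(
    package = "bitephylo",
    version = as.character(utils::packageVersion("bitephylo")),
    r_version = R.version.string,
    config = list(tree_file = tree_file, traits_file = traits_file,
                  ontogeny_file = ontogeny_file, seed = seed,
                  iterations = iterations, burn_in = burn_in, thin = thin,
                  rate_prior_sd = rate_prior_sd, n_stages = n_stages,
                  ratio = ratio, bins = bins, tolerance = tolerance,
                  focal_tip = res$focal_tip, steps = steps),
    n_taxa = length(tree$tip.label),
    outputs = unlist(outputs),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  say(1, "done: ", length(outputs), " tables + manifest in ", out_dir)
  invisible(res)
}

#' Command-line interface
#'
#' Thin argv-level wrapper around the package functions, used by the
#' `inst/scripts/bitephylo.R` launcher. Subcommands: `simulate`
#' (writes a synthetic tree, trait table and ontogeny series),
#' `fit-models`, `mvbm`, `ratespace`, `heterochrony` and `pipeline`
#' (each running the corresponding prefix of the full pipeline).
#' Options may also come from a flat `key=value` config file via
#' `--config`; explicit flags override file values. Diagnostics go to
#' stderr; numeric outputs only ever land in files.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit status, invisibly (0 on success).
#' @export
bitephylo_cli <- function(argv) {
  status <- tryCatch({
    .cli_run(argv)
    0L
  }, error = function(e) {
    message("bitephylo: error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.cli_run <- function(argv) {
  if (length(argv) == 0L) stop("usage: bitephylo <subcommand> [options]")
  sub <- argv[1L]
  known <- c("simulate", "fit-models", "mvbm", "ratespace", "heterochrony",
             "pipeline")
  if (!sub %in% known) {
    stop("unknown subcommand '", sub, "'; expected one of: ",
         paste(known, collapse = ", "))
  }
  opts <- .parse_flags(argv[-1L])
  if (!is.null(opts$config)) {
    file_opts <- .read_kv_config(opts$config)
    for (k in names(file_opts)) {
      if (is.null(opts[[k]])) opts[[k]] <- file_opts[[k]]
    }
  }
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  int <- function(x, d) if (is.null(x)) d else as.integer(x)
  chr <- function(x, d) if (is.null(x)) d else x
  out <- chr(opts$out, "bitephylo_out")
  seed <- int(opts$seed, 1L)

  if (sub == "simulate") {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    n_tips <- int(opts$`n-tips`, 36L)
    tree <- simulate_tree(n_tips, birth_rate = num(opts$`birth-rate`, 0.1),
                          seed = seed,
                          fossil_fraction = num(opts$`fossil-fraction`, 0.5))
    sim_rap <- simulate_mvbm(tree, sigma2 = 0.01, root_state = 3,
                             seed = seed)
    sim_hw <- simulate_mvbm(tree, sigma2 = 0.01, root_state = 4,
                            seed = seed + 1L)
    write_time_tree(tree, file.path(out, "tree.nwk"))
    write_table(data.frame(taxon = tree$tip.label,
                           rap_mm = exp(sim_rap$tip_values),
                           hw_mm = exp(sim_hw$tip_values)),
                file.path(out, "traits.tsv"))
    write_table(simulate_ontogeny(seed = seed),
                file.path(out, "ontogeny.tsv"))
    message("bitephylo: wrote tree.nwk, traits.tsv, ontogeny.tsv to ", out)
    return(invisible(NULL))
  }

  steps <- switch(sub,
    "fit-models" = "models",
    "mvbm" = c("models", "mvbm"),
    "ratespace" = c("models", "mvbm", "ratespace"),
    "heterochrony" = ,
    "pipeline" = c("models", "mvbm", "ratespace", "heterochrony"))
  run_pipeline(
    tree_file = opts$tree %||% stop("--tree is required"),
    traits_file = opts$traits %||% stop("--traits is required"),
    ontogeny_file = opts$ontogeny,
    out_dir = out, seed = seed,
    iterations = int(opts$iterations, 100000L),
    burn_in = num(opts$`burn-in`, 0.2),
    thin = int(opts$thin, 10L),
    rate_prior_sd = num(opts$`rate-prior-sd`, 1),
    n_stages = int(opts$stages, 10L),
    ratio = chr(opts$ratio, "log-quotient"),
    bins = chr(opts$bins, "width"),
    tolerance = num(opts$tolerance, 1e-9),
    focal_tip = opts$`focal-tip`,
    steps = steps,
    verbose = int(opts$verbose, 0L))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_flags <- function(args) {
  opts <- list(verbose = 0L)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "-v") { opts$verbose <- 1L; i <- i + 1L; next }
    if (a == "-vv") { opts$verbose <- 2L; i <- i + 1L; next }
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (grepl("=", key, fixed = TRUE)) {
      kv <- strsplit(key, "=", fixed = TRUE)[[1L]]
      opts[[kv[1L]]] <- paste(kv[-1L], collapse = "=")
      i <- i + 1L
    } else {
      if (i == length(args)) stop("flag --", key, " needs a value")
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

.read_kv_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("bad config line: ", ln)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    known <- c("tree", "traits", "ontogeny", "out", "seed", "iterations",
               "burn-in", "thin", "stages", "ratio", "bins", "tolerance",
               "focal-tip", "rate-prior-sd", "n-tips", "birth-rate",
               "fossil-fraction", "verbose")
    if (!key %in% known) stop("unknown config key: ", key)
    out[[key]] <- trimws(paste(kv[-1L], collapse = "="))
  }
  out
}
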