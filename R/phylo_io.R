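#' Read a time-calibrated tree from a Newick file
#'
#' Parses a single Newick string with branch lengths in millions of years,
#' validates it (every non-root branch must have a strictly positive
#' duration, tip labels must be unique) and returns the tree in canonical
#' form so that node ids are stable across runs and machines.
#'
#' Canonical form: at every internal node, children are ordered by the
#' lexicographically smallest tip label in their subtree. Node ids are then
#' ape's numbering of that canonical tree -- tips `1..n` in the order they
#' appear, internal nodes `n+1..2n-1` in preorder. The same topology and
#' branch lengths therefore always yield the same ids, which is what makes
#' per-node posterior summaries comparable between analyses.
#'
#' Trees need not be ultrametric: fossil tips simply end before extant ones.
#' Zero-length branches are rejected because under the rate models used
#' here the variance contributed by a branch is rate x duration, and a zero
#' duration makes the branch rate unidentifiable.
#'
#' @param path path to a file containing one Newick string.
#' @param text optional Newick string, used instead of `path` when given.
#' @return an object of class `phylo` in canonical form.
#' @seealso [write_time_tree()], [prune_to_taxa()], [ancestor_chain()]
#' @export
read_time_tree <- function(path, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("tree file not found: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  .check_newick_syntax(text)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy)) stop("Newick parse error: no tree could be read")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  validate_time_tree(phy)
  canonicalize_tree(phy)
}

# Pre-scan of the raw string: balanced parentheses with the offending
# character offset reported, since the downstream parser cannot name it.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unmatched ')' at character offset ", i,
             call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at character offset ",
         length(chars), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate the structural invariants of a time tree
#'
#' Checks that branch lengths exist, are finite and strictly positive for
#' every non-root node, and that tip labels are unique. Called by the
#' reading and simulation functions; exported because user-constructed
#' `phylo` objects should pass through it before analysis.
#'
#' @param phy a `phylo` object.
#' @return `phy`, invisibly, if valid; otherwise an error naming the
#'   offending node(s).
#' @export
validate_time_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object")
  n <- length(phy$tip.label)
  if (n < 2L) stop("tree must have at least 2 tips")
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths; durations in Myr are required")
  }
  bad <- which(!is.finite(phy$edge.length) | phy$edge.length <= 0)
  if (length(bad) > 0L) {
    labs <- vapply(phy$edge[bad, 2L], function(nd) .node_name(phy, nd), "")
    missing <- !is.finite(phy$edge.length[bad])
    msg <- character(0)
    if (any(missing)) {
      msg <- c(msg, paste0("missing branch length for node(s): ",
                           paste(labs[missing], collapse = ", ")))
    }
    if (any(!missing)) {
      msg <- c(msg, paste0("non-positive branch duration for node(s): ",
                           paste(labs[!missing], collapse = ", ")))
    }
    stop(paste(msg, collapse = "; "), call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  invisible(phy)
}

.node_name <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(phy$tip.label[node])
  lab <- phy$node.label[node - n]
  if (!is.null(lab) && length(lab) == 1L && !is.na(lab) && nzchar(lab)) {
    return(lab)
  }
  paste0("#", node)
}

#' Put a tree in canonical child order
#'
#' Reorders children of every internal node by the smallest tip label in
#' their subtree and renumbers nodes accordingly, so that two structurally
#' identical trees get identical node ids regardless of input rotation.
#'
#' @param phy a `phylo` object with branch lengths.
#' @return a `phylo` object in canonical (cladewise) order.
#' @export
canonicalize_tree <- function(phy) {
  n <- length(phy$tip.label)
  phy <- ape::reorder.phylo(phy, "postorder")
  key <- character(n + phy$Nnode)
  key[seq_len(n)] <- phy$tip.label
  # postorder guarantees children are keyed before their parent
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; c_ <- phy$edge[i, 2L]
    key[p] <- if (nzchar(key[p])) min(key[p], key[c_]) else key[c_]
  }
  nwk <- .write_canonical_newick(phy, key)
  out <- ape::read.tree(text = nwk)
  ape::reorder.phylo(out, "cladewise")
}

.root_edge <- function(phy) {
  re <- phy$root.edge
  if (is.null(re) || length(re) != 1L || is.na(re)) 0 else re
}

.write_canonical_newick <- function(phy, key) {
  n <- length(phy$tip.label)
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  root <- n + 1L
  blen <- function(edge_row) {
    format(phy$edge.length[edge_row], digits = 17, scientific = FALSE,
           trim = TRUE)
  }
  rec <- function(node) {
    if (node <= n) return(phy$tip.label[node])
    rows <- children[[as.character(node)]]
    rows <- rows[order(key[phy$edge[rows, 2L]], method = "radix")]
    parts <- vapply(rows, function(r) {
      paste0(rec(phy$edge[r, 2L]), ":", blen(r))
    }, "")
    lab <- .internal_label(phy, node)
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  stem <- if (.root_edge(phy) > 0) {
    paste0(":", format(phy$root.edge, digits = 17, scientific = FALSE,
                       trim = TRUE))
  } else ""
  paste0(rec(root), stem, ";")
}

.internal_label <- function(phy, node) {
  n <- length(phy$tip.label)
  if (is.null(phy$node.label)) return("")
  lab <- phy$node.label[node - n]
  if (is.na(lab) || !nzchar(lab)) "" else lab
}

#' Write a time tree to a Newick file
#'
#' @param phy a `phylo` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_time_tree <- function(phy, path) {
  validate_time_tree(phy)
  ape::write.tree(phy, file = path, digits = 12)
  invisible(path)
}

#' Prune a tree to a set of taxa
#'
#' Drops all tips not in `keep`; degree-2 internal nodes created by the
#' pruning are collapsed with their branch durations summed, so every kept
#' tip retains its root-to-tip path duration exactly. This mirrors the
#' usual comparative-methods step of restricting the phylogeny to taxa
#' with trait data.
#'
#' @param phy a `phylo` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned tree in canonical form.
#' @export
prune_to_taxa <- function(phy, keep) {
  validate_time_tree(phy)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, phy$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown taxa in keep set: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(keep) < 2L) stop("need at least 2 taxa to keep")
  if (length(keep) == length(phy$tip.label)) return(canonicalize_tree(phy))
  # keep the stem from the old root down to the kept taxa's MRCA as a
  # root edge, so root-to-tip path durations are conserved exactly
  pruned <- ape::keep.tip(phy, keep)
  ref <- keep[1L]
  stem <- tip_depths(phy)[[ref]] -
    ape::node.depth.edgelength(pruned)[match(ref, pruned$tip.label)]
  out <- canonicalize_tree(pruned)
  if (stem > 1e-12) out$root.edge <- stem
  out
}

#' Root-to-tip path durations
#'
#' @param phy a `phylo` object.
#' @return named numeric vector of summed branch durations from the root
#'   to each tip (Myr); a stem (`root.edge`) retained by pruning counts
#'   toward every tip.
#' @export
tip_depths <- function(phy) {
  depths <- ape::node.depth.edgelength(phy) + .root_edge(phy)
  stats::setNames(depths[seq_along(phy$tip.label)], phy$tip.label)
}

#' Ancestor chain of a focal tip
#'
#' Returns the node ids on the path from the root to `tip`, root first and
#' tip last; consecutive entries are parent and child. This is the chain
#' of direct ancestors whose reconstructed states form the evolutionary
#' trajectory for the heterochrony comparison.
#'
#' @param phy a `phylo` object.
#' @param tip a tip label.
#' @return integer vector of node ids, root first, tip last.
#' @export
ancestor_chain <- function(phy, tip) {
  idx <- match(tip, phy$tip.label)
  if (is.na(idx)) stop("unknown tip: ", tip, call. = FALSE)
  root <- length(phy$tip.label) + 1L
  as.integer(ape::nodepath(phy, from = root, to = idx))
}

#' Read a per-taxon trait table
#'
#' Reads a delimited text file (comma or tab, autodetected from the
#' header) with columns `taxon`, `rap_mm`, `hw_mm`: retroarticular-process
#' length and head width in millimeters. Natural logs are taken at load,
#' following the convention that all measurements enter the evolutionary
#' models on the ln scale; the fixed mm unit keeps ln-ratios comparable
#' across datasets.
#'
#' @param path delimited text file path.
#' @return data.frame with columns `taxon`, `raw_rap_mm`, `raw_hw_mm`,
#'   `ln_rap`, `ln_hw`.
#' @export
read_trait_table <- function(path) {
  df <- .read_delim(path, c("taxon", "rap_mm", "hw_mm"))
  if (anyDuplicated(df$taxon)) {
    stop("duplicate taxa in trait table: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  }
  if (any(df$rap_mm <= 0) || any(df$hw_mm <= 0)) {
    stop("trait measurements must be strictly positive")
  }
  data.frame(
    taxon = as.character(df$taxon),
    raw_rap_mm = df$rap_mm,
    raw_hw_mm = df$hw_mm,
    ln_rap = log(df$rap_mm),
    ln_hw = log(df$hw_mm),
    stringsAsFactors = FALSE
  )
}

#' Read an ontogenetic measurement series
#'
#' Columns `specimen`, `total_length_cm`, `rap_mm`, `hw_mm`; comma- or
#' tab-delimited with a header row. All measurements must be strictly
#' positive.
#'
#' @param path delimited text file path.
#' @return data.frame with the four columns above.
#' @export
read_ontogeny_series <- function(path) {
  df <- .read_delim(path, c("specimen", "total_length_cm", "rap_mm", "hw_mm"))
  num <- c("total_length_cm", "rap_mm", "hw_mm")
  if (any(as.matrix(df[num]) <= 0)) {
    stop("ontogeny measurements must be strictly positive")
  }
  df$specimen <- as.character(df$specimen)
  df
}

.read_delim <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  df[required]
}

#' Write a delimited table
#'
#' Tab-separated with header, the plain-text interchange format used by
#' all pipeline outputs.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
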