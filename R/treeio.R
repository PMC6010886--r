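#' Read time-calibrated trees from a Newick file
#'
#' Reads one or more rooted, fully bifurcating trees with branch lengths in
#' time units. Every tree is checked for the structural prerequisites of the
#' birth-death likelihood: branch lengths present on all edges, no polytomies,
#' and no negative branch lengths. Ultrametricity is *not* enforced here; use
#' [assert_ultrametric()] before computing branching times.
#'
#' @param path Path to a Newick file. With `multi = TRUE` the file may contain
#'   several `;`-terminated Newick strings (one per line or concatenated).
#' @param multi Logical; if `TRUE` return a list of all trees in the file, if
#'   `FALSE` (default) require exactly one tree.
#' @return A single `phylo` object, or a list of `phylo` objects when
#'   `multi = TRUE`.
#' @seealso [write_newick()], [branching_times()]
#' @export
read_newick <- function(path, multi = FALSE) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  trees <- tryCatch(
    ape::read.tree(path),
    error = function(e) {
      stop("Newick parse failure in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(trees)) {
    stop("Newick parse failure in '", path, "': no tree found", call. = FALSE)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(unclass(trees), function(tr) {
    class(tr) <- "phylo"
    validate_tree(tr)
  })
  if (!multi) {
    if (length(trees) != 1L) {
      stop("expected a single tree but '", path, "' contains ", length(trees),
           "; use multi = TRUE", call. = FALSE)
    }
    return(trees[[1L]])
  }
  trees
}

#' Write trees to a Newick file
#'
#' @param trees A `phylo` object or list of `phylo` objects.
#' @param path Output file path.
#' @param digits Significant digits for branch lengths; the default preserves
#'   lengths to better than 12 significant digits on a round trip.
#' @return `path`, invisibly.
#' @export
write_newick <- function(trees, path, digits = 15) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = path, digits = digits)
  invisible(path)
}

# Structural checks shared by the readers and the simulators: rooted, binary,
# all edge lengths present and non-negative.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stop("not a 'phylo' object", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; time-calibrated branch lengths are required",
         call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    stop("missing branch length on ", sum(is.na(tree$edge.length)),
         " edge(s); every edge must carry a length", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length(s) found; branch lengths must be >= 0",
         call. = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted", call. = FALSE)
  }
  if (!ape::is.binary(tree)) {
    stop("tree contains polytomies; fully bifurcating trees are required ",
         "(the likelihood's ordered-branching-time form assumes binary nodes)",
         call. = FALSE)
  }
  tree
}

# Root-to-tip path lengths for every tip, in tip-index order.
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  d[seq_len(ape::Ntip(tree))]
}

#' Validate that a tree is ultrametric
#'
#' Checks that all root-to-tip path lengths agree within a relative tolerance
#' of the tree depth, as required for trees whose branch lengths represent
#' elapsed time. Empirical chronograms typically carry small rounding noise;
#' the default tolerance absorbs it without accepting genuinely non-clocklike
#' trees.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param rel_tol Maximum allowed (max - min) root-to-tip distance, as a
#'   fraction of the maximum root-to-tip distance. Default `1e-6`.
#' @return The tree, unchanged, invisibly usable in a pipeline.
#' @export
assert_ultrametric <- function(tree, rel_tol = 1e-6) {
  validate_tree(tree)
  d <- tip_depths(tree)
  dev <- max(d) - min(d)
  if (dev > rel_tol * max(d)) {
    worst <- tree$tip.label[c(which.max(d), which.min(d))]
    stop(sprintf(paste0(
      "tree is not ultrametric: root-to-tip depths span %.6g ",
      "(relative deviation %.3g > rel_tol %.3g); extreme tips: %s, %s"),
      dev, dev / max(d), rel_tol, worst[1], worst[2]), call. = FALSE)
  }
  tree
}

#' Reduce an ultrametric tree to its ordered branching times
#'
#' The sufficient statistic of a tree under the constant-rate birth-death
#' model: the tip count N and the ages of the N - 1 internal nodes, measured
#' backward from the present (tips at age 0) and ordered from root to tip
#' (non-increasing). The first entry is the crown age, i.e. the depth of the
#' most recent common ancestor of the tips.
#'
#' @param tree A `phylo` object, or a numeric vector of node ages (already
#'   measured from the present) which is validated and sorted.
#' @param rel_tol Ultrametricity tolerance passed to [assert_ultrametric()].
#' @return An object of class `branching_times`: a list with elements `N`
#'   (integer tip count) and `t` (numeric vector of N - 1 node ages, sorted
#'   non-increasing; `t[1]` is the crown age).
#' @export
branching_times <- function(tree, rel_tol = 1e-6) {
  if (is.numeric(tree)) {
    return(new_branching_times(tree))
  }
  assert_ultrametric(tree, rel_tol = rel_tol)
  n <- ape::Ntip(tree)
  if (n < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  depth_all <- ape::node.depth.edgelength(tree)
  depth <- max(depth_all[seq_len(n)])
  ages <- depth - depth_all[(n + 1L):(2L * n - 1L)]
  # tiny negative ages from float noise on tip depths are clamped
  ages[ages < 0 & ages > -rel_tol * depth] <- 0
  new_branching_times(ages)
}

new_branching_times <- function(ages) {
  ages <- sort(as.numeric(ages), decreasing = TRUE)
  if (length(ages) < 1L) {
    stop("need at least one node age (N >= 2)", call. = FALSE)
  }
  if (any(ages <= 0)) {
    stop("all node ages must be strictly positive; zero internal node ages ",
         "are not supported", call. = FALSE)
  }
  structure(
    list(N = length(ages) + 1L, t = ages),
    class = "branching_times"
  )
}

#' @export
print.branching_times <- function(x, ...) {
  cat("Branching times: N =", x$N, "tips, crown age =",
      format(x$t[1], digits = 6), "\n")
  cat("  t =", paste(format(x$t, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Extract a monophyletic clade as a subtree
#'
#' Returns the subtree spanned by `tip_set`, rooted at the most recent common
#' ancestor of those tips, with branch lengths preserved. The tip set must be
#' exactly the tips descended from that ancestor; otherwise an error lists the
#' intruding tips. This is the helper for analyses that compare well-sampled
#' subtrees of interest embedded in a larger, more sparsely sampled phylogeny.
#'
#' @param tree A rooted `phylo`.
#' @param tip_set Character vector of tip labels (or integer tip indices).
#' @return A `phylo` subtree.
#' @export
extract_clade <- function(tree, tip_set) {
  validate_tree(tree)
  if (is.character(tip_set)) {
    missing <- setdiff(tip_set, tree$tip.label)
    if (length(missing)) {
      stop("tip label(s) not in tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    tips <- match(tip_set, tree$tip.label)
  } else {
    tips <- as.integer(tip_set)
  }
  if (length(tips) < 2L) stop("tip_set must contain at least 2 tips", call. = FALSE)
  if (length(tips) == ape::Ntip(tree)) {
    return(tree)
  }
  mrca <- ape::getMRCA(tree, tips)
  desc <- ape::extract.clade(tree, mrca)
  intruders <- setdiff(desc$tip.label, tree$tip.label[tips])
  if (length(intruders)) {
    stop("tip_set is not monophyletic; clade also contains: ",
         paste(intruders, collapse = ", "), call. = FALSE)
  }
  desc
}
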