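#' Read a rooted species tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the
#' downstream parsimony machinery relies on: the tree must be rooted (a basal
#' trichotomy, ape's convention for unrooted trees, is rejected), tip labels
#' must be unique and nonempty, and every internal node receives a stable
#' label (existing labels are kept; missing ones become `N<node id>`).
#'
#' Branches without lengths are given length 1, so event rates in the
#' simulator are "per branch" unless the input says otherwise.
#'
#' @param path path to a Newick file containing a single rooted tree.
#' @return an object of class `phylo` with unique tip labels and complete
#'   node labels.
#' @export
read_species_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse a tree from ", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_species_tree(tree)
}

#' Validate and normalise a species tree
#'
#' @param tree a `phylo` object.
#' @return the tree, with node labels filled in and branch lengths defaulted
#'   to 1 where absent.
#' @export
validate_species_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 1L) stop("tree has no tips")
  if (anyNA(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("tree tip labels must be nonempty")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (length(tree$tip.label) >= 3L && !ape::is.rooted(tree))
    stop("tree is unrooted (basal polytomy); a rooted species tree is required")
  tree <- label_tree_nodes(tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

#' Fill in missing internal node labels
#'
#' @param tree a `phylo` object.
#' @return the tree with every internal node labelled (`N<node id>` where no
#'   label was present).
#' @export
label_tree_nodes <- function(tree) {
  n_int <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep(NA_character_, n_int)
  fill <- is.na(lab) | !nzchar(lab)
  ids <- length(tree$tip.label) + seq_len(n_int)
  lab[fill] <- paste0("N", ids[fill])
  if (anyDuplicated(c(tree$tip.label, lab)))
    stop("node labels collide with tip labels or each other")
  tree$node.label <- lab
  tree
}

# Precompute the traversal tables used by the simulator and the parsimony DP.
# Nodes are ape ids: tips 1..ntip, root ntip+1. Branches are identified by
# their child node, so `node_name[v]` doubles as the branch name for the edge
# ending in v.
.tree_index <- function(tree, default_length = 1) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  root <- ntip + 1L
  parent <- rep(NA_integer_, n)
  children <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1L]
    v <- tree$edge[i, 2L]
    parent[v] <- u
    children[[u]] <- c(children[[u]], v)
  }
  blen <- rep(default_length, n)
  if (!is.null(tree$edge.length)) blen[tree$edge[, 2L]] <- tree$edge.length
  post <- integer(n)
  k <- 0L
  walk <- function(v) {
    for (w in children[[v]]) walk(w)
    k <<- k + 1L
    post[k] <<- v
  }
  walk(root)
  if (k != n) stop("tree traversal did not reach every node; is the tree connected?")
  node_name <- c(tree$tip.label,
                 if (is.null(tree$node.label)) paste0("N", (ntip + 1L):n) else tree$node.label)
  # descendants (excluding self), bottom-up
  desc <- vector("list", n)
  for (v in post) {
    if (!is.null(children[[v]]))
      desc[[v]] <- unlist(c(children[[v]], desc[children[[v]]]), use.names = FALSE)
    else desc[[v]] <- integer(0)
  }
  list(ntip = ntip, n = n, root = root, parent = parent, children = children,
       blen = blen, post = post, pre = rev(post), node_name = node_name,
       desc = desc, is_tip = seq_len(n) <= ntip)
}

#' Write a tree with per-branch event annotations in Newick form
#'
#' Renders the species tree with each branch labelled by its reconstructed
#' gain/loss ranges, e.g. `Dmel[+0,-3..4]`, mirroring the convention of
#' plotting "+g, -l" along each lineage. Ranges collapse to a single number
#' when min equals max.
#'
#' @param tree a `phylo` object (labelled; see [validate_species_tree()]).
#' @param branch_events data frame with columns `branch`, `gain_min`,
#'   `gain_max`, `loss_min`, `loss_max` (as produced by
#'   [summarize_family()] or [aggregate_families()]).
#' @param path optional file to write to; if `NULL` the Newick string is
#'   returned invisibly only.
#' @return the annotated Newick string, invisibly.
#' @export
write_annotated_tree <- function(tree, branch_events, path = NULL) {
  tree <- validate_species_tree(tree)
  ti <- .tree_index(tree)
  ev <- branch_events
  rng <- function(lo, hi) if (lo == hi) as.character(lo) else paste0(lo, "..", hi)
  tag <- function(name) {
    i <- match(name, ev$branch)
    if (is.na(i)) return("")
    paste0("[+", rng(ev$gain_min[i], ev$gain_max[i]),
           ",-", rng(ev$loss_min[i], ev$loss_max[i]), "]")
  }
  build <- function(v) {
    nm <- ti$node_name[v]
    lab <- if (v == ti$root) nm else paste0(nm, tag(nm))
    if (ti$is_tip[v]) return(lab)
    paste0("(", paste(vapply(ti$children[[v]], build, character(1)), collapse = ","),
           ")", lab)
  }
  nwk <- paste0(build(ti$root), ";")
  if (!is.null(path)) writeLines(nwk, path)
  invisible(nwk)
}

# Run code with a temporary RNG seed, restoring global state afterwards.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
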