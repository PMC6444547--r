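#' Gain/loss cost scheme for splice-site parsimony
#'
#' Unweighted parsimony (`gain_cost = loss_cost = 1`) treats gains and losses
#' agnostically, which is the default for all headline outputs. A Dollo-like
#' analysis (a character may arise once but be lost repeatedly) is
#' approximated by a large `gain_cost`, e.g. `cost_scheme(gain_cost = 100)`.
#'
#' @param gain_cost cost of an absent-to-present transition on a branch
#'   (>= 0).
#' @param loss_cost cost of a present-to-absent transition on a branch
#'   (>= 0).
#' @return a `cost_scheme` object.
#' @export
cost_scheme <- function(gain_cost = 1, loss_cost = 1) {
  stopifnot(is.numeric(gain_cost), is.numeric(loss_cost),
            length(gain_cost) == 1L, length(loss_cost) == 1L,
            gain_cost >= 0, loss_cost >= 0)
  if (gain_cost == 0 && loss_cost == 0)
    stop("gain_cost and loss_cost cannot both be zero")
  structure(list(gain_cost = gain_cost, loss_cost = loss_cost),
            class = "cost_scheme")
}

# States are coded 1 = absent, 2 = present; unknown tips accept either state
# at zero cost (standard missing-data treatment in small parsimony).
.STATE_LEVELS <- c("absent", "present", "unknown")
.BIG <- 1e9

.code_states <- function(states, tip_names) {
  if (is.null(names(states))) {
    if (length(states) != length(tip_names))
      stop("states must be named by tip, or have one entry per tip in tip order")
    names(states) <- tip_names
  }
  missing <- setdiff(tip_names, names(states))
  if (length(missing))
    stop("no state for tip(s): ", paste(missing, collapse = ", "))
  states <- states[tip_names]
  bad <- !(states %in% .STATE_LEVELS)
  if (any(bad))
    stop("invalid state(s): ", paste(unique(states[bad]), collapse = ", "),
         " (use present/absent/unknown)")
  states
}

.trans_matrix <- function(costs) {
  # row = parent state, col = child state (1 absent, 2 present)
  matrix(c(0, costs$loss_cost, costs$gain_cost, 0), 2L, 2L)
}

# Sankoff upward pass. Returns 2 x n matrix of conditional subtree costs.
.sankoff_up <- function(codes, ti, costs) {
  Tm <- .trans_matrix(costs)
  up <- matrix(0, 2L, ti$n)
  for (v in seq_len(ti$ntip)) {
    up[, v] <- switch(codes[v],
                      absent  = c(0, .BIG),
                      present = c(.BIG, 0),
                      unknown = c(0, 0))
  }
  for (v in ti$post) {
    if (ti$is_tip[v]) next
    acc <- c(0, 0)
    for (w in ti$children[[v]]) {
      acc[1L] <- acc[1L] + min(Tm[1L, ] + up[, w])
      acc[2L] <- acc[2L] + min(Tm[2L, ] + up[, w])
    }
    up[, v] <- acc
  }
  up
}

# Downward ("outside") pass: out[s, v] = min cost of the whole tree minus the
# subtree rooted at v, conditional on v having state s. out[, root] = 0.
.sankoff_down <- function(up, ti, costs) {
  Tm <- .trans_matrix(costs)
  out <- matrix(.BIG, 2L, ti$n)
  out[, ti$root] <- 0
  for (u in ti$pre) {
    if (ti$is_tip[u]) next
    for (v in ti$children[[u]]) {
      contrib <- c(min(Tm[1L, ] + up[, v]), min(Tm[2L, ] + up[, v]))
      rest <- out[, u] + up[, u] - contrib  # everything except subtree(v), given u's state
      out[1L, v] <- min(rest + Tm[, 1L])
      out[2L, v] <- min(rest + Tm[, 2L])
    }
  }
  out
}

#' Minimal weighted parsimony score of one splice-site character
#'
#' Computes the small-parsimony (Sankoff) score of a binary
#' presence/absence character on a rooted tree, minimising over both root
#' states. Tips with state `"unknown"` contribute zero cost for either state.
#' With unit costs this equals the Fitch score. Polytomies are handled
#' natively by the dynamic programme.
#'
#' @param states character vector of `"present"`, `"absent"`, `"unknown"`,
#'   named by tip label (or in tip order).
#' @param tree rooted `phylo` tree.
#' @param costs a [cost_scheme()].
#' @return the minimal total cost (numeric). If every tip is unknown the
#'   score is 0 and carries attribute `degenerate = TRUE`.
#' @export
site_score <- function(states, tree, costs = cost_scheme()) {
  tree <- validate_species_tree(tree)
  ti <- .tree_index(tree)
  codes <- .code_states(states, tree$tip.label)
  if (all(codes == "unknown")) {
    return(structure(0, degenerate = TRUE))
  }
  up <- .sankoff_up(codes, ti, costs)
  min(up[, ti$root])
}

# For each edge (identified by child node v), which parent/child state pairs
# occur in at least one most-parsimonious labelling, and which node states
# are optimal at each node. Exact, independent of any enumeration cap.
.edge_supports <- function(up, out, ti, costs) {
  Tm <- .trans_matrix(costs)
  total <- min(up[, ti$root])
  eps <- 1e-7
  node_opt <- matrix(FALSE, 2L, ti$n)
  for (v in seq_len(ti$n)) node_opt[, v] <- (out[, v] + up[, v]) <= total + eps
  pair_opt <- array(FALSE, dim = c(2L, 2L, ti$n))  # [s, t, child v]
  for (u in ti$pre) {
    if (ti$is_tip[u]) next
    for (v in ti$children[[u]]) {
      contrib <- c(min(Tm[1L, ] + up[, v]), min(Tm[2L, ] + up[, v]))
      rest <- out[, u] + up[, u] - contrib
      for (s in 1:2) for (t in 1:2) {
        pair_opt[s, t, v] <- (rest[s] + Tm[s, t] + up[t, v]) <= total + eps
      }
    }
  }
  list(total = total, node_opt = node_opt, pair_opt = pair_opt)
}

#' Enumerate all most-parsimonious scenarios for one character
#'
#' Backtracks the Sankoff dynamic programme to recover every ancestral
#' labelling achieving the minimal score ("we remained agnostic" over ties:
#' all optima are kept, not an arbitrary one). Unknown tips are free nodes
#' and are enumerated alongside internal nodes. The exact number of optima is
#' counted by dynamic programming even when the returned list is truncated at
#' `cap`.
#'
#' @inheritParams site_score
#' @param cap maximum number of labellings materialised (default 10000); the
#'   count and all range statistics remain exact beyond the cap.
#' @return list with elements `score`, `n_scenarios` (exact count),
#'   `truncated`, `labelings` (matrix, one row per scenario, columns named by
#'   node, values 0 = absent / 1 = present), `root_states` (optimal root
#'   states as 0/1), and `events` (list of per-scenario data frames with
#'   columns `branch`, `direction`).
#' @export
enumerate_scenarios <- function(states, tree, costs = cost_scheme(), cap = 10000L) {
  tree <- validate_species_tree(tree)
  ti <- .tree_index(tree)
  codes <- .code_states(states, tree$tip.label)
  if (all(codes == "unknown")) {
    lab <- matrix(0L, 1L, ti$n, dimnames = list(NULL, ti$node_name))
    labs2 <- lab; labs2[] <- 1L
    labelings <- rbind(lab, labs2)
    return(list(score = 0, n_scenarios = 2, truncated = FALSE,
                labelings = labelings, root_states = c(0L, 1L),
                events = lapply(1:2, function(i)
                  data.frame(branch = character(0), direction = character(0)))))
  }
  up <- .sankoff_up(codes, ti, costs)
  Tm <- .trans_matrix(costs)
  eps <- 1e-7
  total <- min(up[, ti$root])

  # exact count of optimal labellings
  cnt <- matrix(0, 2L, ti$n)
  for (v in ti$post) {
    if (ti$is_tip[v]) {
      cnt[, v] <- as.numeric(up[, v] < .BIG / 2)
    } else {
      for (s in 1:2) {
        prod <- 1
        for (w in ti$children[[v]]) {
          best <- min(Tm[s, ] + up[, w])
          opt_t <- which(Tm[s, ] + up[, w] <= best + eps)
          prod <- prod * sum(cnt[opt_t, w])
        }
        cnt[s, v] <- prod
      }
    }
  }
  root_opt <- which(up[, ti$root] <= total + eps)
  n_scen <- sum(cnt[root_opt, ti$root])

  # materialise labellings (subject to cap) by recursive cartesian expansion
  cross <- function(A, B) {
    if (is.null(A)) return(B)
    if (is.null(B)) return(A)
    ia <- rep(seq_len(nrow(A)), each = nrow(B))
    ib <- rep(seq_len(nrow(B)), times = nrow(A))
    M <- A[ia, , drop = FALSE]
    Bb <- B[ib, , drop = FALSE]
    fill <- !is.na(Bb)
    M[fill] <- Bb[fill]
    if (nrow(M) > cap) M <- M[seq_len(cap), , drop = FALSE]
    M
  }
  subtree_labs <- function(v, s) {
    # matrix over all n columns (NA outside subtree), rows = optimal labellings
    M <- matrix(NA_integer_, 1L, ti$n)
    M[1L, v] <- s - 1L
    if (ti$is_tip[v]) return(M)
    for (w in ti$children[[v]]) {
      best <- min(Tm[s, ] + up[, w])
      opt_t <- which(Tm[s, ] + up[, w] <= best + eps)
      W <- NULL
      for (t in opt_t) W <- rbind(W, subtree_labs(w, t))
      if (nrow(W) > cap) W <- W[seq_len(cap), , drop = FALSE]
      M <- cross(M, W)
    }
    M
  }
  labelings <- NULL
  for (s in root_opt) labelings <- rbind(labelings, subtree_labs(ti$root, s))
  truncated <- n_scen > nrow(labelings)
  if (nrow(labelings) > cap) {
    labelings <- labelings[seq_len(cap), , drop = FALSE]
    truncated <- TRUE
  }
  colnames(labelings) <- ti$node_name
  events <- lapply(seq_len(nrow(labelings)), function(i)
    .labeling_events(labelings[i, ], ti))
  list(score = total, n_scenarios = n_scen, truncated = truncated,
       labelings = labelings, root_states = root_opt - 1L, events = events)
}

# Branch events implied by one full labelling (0/1 per node).
.labeling_events <- function(lab, ti) {
  child <- which(!is.na(ti$parent))
  changed <- child[lab[child] != lab[ti$parent[child]]]
  data.frame(branch = ti$node_name[changed],
             direction = ifelse(lab[changed] == 1L, "gain", "loss"),
             stringsAsFactors = FALSE)
}

# TRUE if the changed-edge set of a scenario contains >= 2 pairwise
# independent (neither ancestral to the other) branches with the same
# direction — i.e. the same change happened on independent lineages.
.has_parallel <- function(ev, ti) {
  if (nrow(ev) < 2L) return(FALSE)
  ids <- match(ev$branch, ti$node_name)
  for (dir in unique(ev$direction)) {
    sel <- ids[ev$direction == dir]
    if (length(sel) < 2L) next
    for (i in seq_along(sel)) for (j in seq_along(sel)) {
      if (i >= j) next
      a <- sel[i]; b <- sel[j]
      if (!(a %in% ti$desc[[b]]) && !(b %in% ti$desc[[a]])) return(TRUE)
    }
  }
  FALSE
}

#' Reconstruct gain/loss history for one ortholog family
#'
#' Runs the parsimony machinery over every splice-site character of a
#' [build_site_matrix()] result and aggregates:
#' per-branch gain and loss counts as `[min, max]` ranges over all
#' most-parsimonious scenarios (a range is reported whenever scenarios
#' disagree, rather than picking one), the range of ancestral sites present
#' at the root, the number of ancestral sites retained in all species
#' (present at the root in every optimal scenario and present in every tip
#' with known state), and sites whose every optimal scenario requires the
#' same change on two or more independent branches (parallel events /
#' homoplasy).
#'
#' Branch ranges are computed exactly from per-edge optimal-state membership
#' (which parent/child state pairs occur in at least one optimal labelling),
#' so they do not depend on the enumeration cap; the capped enumeration is
#' used only for scenario counts and parallel-event detection.
#'
#' @param matrix a `site_matrix` (see [build_site_matrix()]).
#' @param tree rooted `phylo`; tips must match the matrix species.
#' @param costs a [cost_scheme()].
#' @param cap enumeration cap per site (see [enumerate_scenarios()]).
#' @return a `family_reconstruction`: list with `family_id`, `sites` (per-site
#'   table), `branch_events` (per-branch range table), `root_present`
#'   (length-2 `[min, max]`), `retained_all`, `retained_with_unknown`,
#'   `parallel_events`, and `totals`.
#' @export
summarize_family <- function(matrix, tree, costs = cost_scheme(), cap = 10000L) {
  stopifnot(inherits(matrix, "site_matrix"))
  tree <- validate_species_tree(tree)
  ti <- .tree_index(tree)
  sp <- rownames(matrix$states)
  if (!setequal(sp, tree$tip.label))
    stop("site matrix species do not match tree tips")
  st <- matrix$states[tree$tip.label, , drop = FALSE]
  nsite <- ncol(st)

  child_nodes <- which(!is.na(ti$parent))
  bn <- ti$node_name[child_nodes]
  gain_min <- gain_max <- loss_min <- loss_max <- stats::setNames(integer(length(bn)), bn)

  site_ids <- colnames(st)
  scores <- numeric(nsite)
  n_scen <- numeric(nsite)
  truncated <- logical(nsite)
  root_min_v <- root_max_v <- integer(nsite)
  retained_v <- logical(nsite)
  retained_unk_v <- logical(nsite)
  parallel_list <- list()

  for (k in seq_len(nsite)) {
    codes <- st[, k]
    known <- codes != "unknown"
    if (!any(known)) {
      scores[k] <- 0; n_scen[k] <- 2; root_min_v[k] <- 0L; root_max_v[k] <- 1L
      next
    }
    up <- .sankoff_up(codes, ti, costs)
    out <- .sankoff_down(up, ti, costs)
    es <- .edge_supports(up, out, ti, costs)
    scores[k] <- es$total

    # per-branch possibility / necessity of each event direction
    for (bi in seq_along(child_nodes)) {
      v <- child_nodes[bi]
      po <- es$pair_opt[, , v]
      gain_possible <- po[1L, 2L]
      loss_possible <- po[2L, 1L]
      gain_forced <- gain_possible && !po[1L, 1L] && !po[2L, 1L] && !po[2L, 2L]
      loss_forced <- loss_possible && !po[1L, 1L] && !po[1L, 2L] && !po[2L, 2L]
      gain_max[bi] <- gain_max[bi] + as.integer(gain_possible)
      gain_min[bi] <- gain_min[bi] + as.integer(gain_forced)
      loss_max[bi] <- loss_max[bi] + as.integer(loss_possible)
      loss_min[bi] <- loss_min[bi] + as.integer(loss_forced)
    }

    root_possible <- es$node_opt[2L, ti$root]
    root_forced <- root_possible && !es$node_opt[1L, ti$root]
    root_min_v[k] <- as.integer(root_forced)
    root_max_v[k] <- as.integer(root_possible)
    all_known_present <- all(codes[known] == "present")
    retained_unk_v[k] <- root_forced && all_known_present
    retained_v[k] <- retained_unk_v[k]

    if (es$total > 0) {
      en <- enumerate_scenarios(codes, tree, costs, cap = cap)
      n_scen[k] <- en$n_scenarios
      truncated[k] <- en$truncated
      par_all <- all(vapply(en$events, .has_parallel, logical(1), ti = ti))
      if (par_all && !en$truncated) {
        # branches changed in every optimal scenario (forced events)
        forced <- Reduce(intersect, lapply(en$events, function(e)
          paste(e$branch, e$direction)))
        parallel_list[[length(parallel_list) + 1L]] <- list(
          site = site_ids[k],
          branches = vapply(strsplit(forced, " "), `[`, character(1), 1L),
          directions = vapply(strsplit(forced, " "), `[`, character(1), 2L))
      }
    } else {
      n_scen[k] <- 1
    }
  }

  sites <- data.frame(site = site_ids,
                      column = matrix$sites$column,
                      phase = matrix$sites$phase,
                      score = scores,
                      n_scenarios = n_scen,
                      truncated = truncated,
                      root_min = root_min_v,
                      root_max = root_max_v,
                      retained = retained_v,
                      stringsAsFactors = FALSE)
  branch_events <- data.frame(branch = bn,
                              parent = ti$node_name[ti$parent[child_nodes]],
                              terminal = ti$is_tip[child_nodes],
                              gain_min = as.integer(gain_min),
                              gain_max = as.integer(gain_max),
                              loss_min = as.integer(loss_min),
                              loss_max = as.integer(loss_max),
                              stringsAsFactors = FALSE)
  structure(list(
    family_id = matrix$family_id,
    sites = sites,
    branch_events = branch_events,
    root_present = c(min = sum(root_min_v), max = sum(root_max_v)),
    retained_all = sum(retained_v),
    retained_with_unknown = sum(retained_unk_v &
                                  apply(st == "unknown", 2L, any)),
    parallel_events = parallel_list,
    totals = list(n_sites = nsite,
                  n_variable_sites = sum(scores > 0),
                  n_changes = sum(scores))
  ), class = "family_reconstruction")
}

#' @export
print.family_reconstruction <- function(x, ...) {
  cat("Family", x$family_id, "—", x$totals$n_sites, "splice-site characters,",
      x$totals$n_variable_sites, "variable,",
      x$totals$n_changes, "changes (min parsimony)\n")
  cat("  root sites present: [", x$root_present["min"], ",",
      x$root_present["max"], "], retained in all species:", x$retained_all, "\n")
  if (length(x$parallel_events))
    cat("  parallel events at", length(x$parallel_events), "site(s)\n")
  invisible(x)
}

#' Aggregate family reconstructions into study-level totals
#'
#' Sums variable-site and change counts across ortholog families, sums the
#' per-branch gain/loss ranges, and tabulates species-specific changes
#' (events on terminal branches).
#'
#' @param reconstructions list of `family_reconstruction` objects sharing one
#'   species tree.
#' @return list with `n_families`, `n_sites`, `n_variable_sites`,
#'   `n_changes`, `root_present`, `retained_all`, `branch_events` (summed
#'   ranges), `species_changes` (terminal-branch ranges per species),
#'   `parallel_events` (flattened with family ids), and `per_family` summary
#'   table.
#' @export
aggregate_families <- function(reconstructions) {
  stopifnot(length(reconstructions) >= 1L)
  ids <- vapply(reconstructions, function(r) r$family_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate family ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bn <- reconstructions[[1L]]$branch_events$branch
  for (r in reconstructions)
    if (!identical(sort(r$branch_events$branch), sort(bn)))
      stop("family reconstructions do not share one species tree")
  acc <- reconstructions[[1L]]$branch_events
  acc <- acc[order(acc$branch), ]
  for (r in reconstructions[-1L]) {
    b <- r$branch_events[order(r$branch_events$branch), ]
    for (col in c("gain_min", "gain_max", "loss_min", "loss_max"))
      acc[[col]] <- acc[[col]] + b[[col]]
  }
  per_family <- data.frame(
    family = ids,
    n_sites = vapply(reconstructions, function(r) r$totals$n_sites, numeric(1)),
    n_variable_sites = vapply(reconstructions, function(r) r$totals$n_variable_sites, numeric(1)),
    n_changes = vapply(reconstructions, function(r) r$totals$n_changes, numeric(1)),
    root_min = vapply(reconstructions, function(r) unname(r$root_present["min"]), numeric(1)),
    root_max = vapply(reconstructions, function(r) unname(r$root_present["max"]), numeric(1)),
    retained_all = vapply(reconstructions, function(r) r$retained_all, numeric(1)),
    stringsAsFactors = FALSE)
  term <- acc[acc$terminal, ]
  species_changes <- data.frame(
    species = term$branch,
    change_min = term$gain_min + term$loss_min,
    change_max = term$gain_max + term$loss_max,
    stringsAsFactors = FALSE)
  par_ev <- list()
  for (r in reconstructions) for (p in r$parallel_events) {
    p$family <- r$family_id
    par_ev[[length(par_ev) + 1L]] <- p
  }
  list(n_families = length(reconstructions),
       n_sites = sum(per_family$n_sites),
       n_variable_sites = sum(per_family$n_variable_sites),
       n_changes = sum(per_family$n_changes),
       root_present = c(min = sum(per_family$root_min), max = sum(per_family$root_max)),
       retained_all = sum(per_family$retained_all),
       branch_events = acc,
       species_changes = species_changes,
       parallel_events = par_ev,
       per_family = per_family)
}

#' Rank correlation between genome size and intron number
#'
#' Spearman rank correlation (average ranks for ties) between per-species
#' intron counts and genome sizes, with an exact permutation p-value for
#' small samples (n <= 10; all n! permutations are evaluated) and the usual
#' t approximation otherwise. Two-sided.
#'
#' @param intron_counts named numeric vector (per species).
#' @param genome_sizes named numeric vector (per species); pairing is by
#'   name, restricted to species present in both.
#' @return list with `estimate` (rho), `p.value`, `n`, `method`, and `table`
#'   (the paired data).
#' @export
genome_size_correlation <- function(intron_counts, genome_sizes) {
  common <- intersect(names(intron_counts), names(genome_sizes))
  if (length(common) < 3L)
    stop("need at least 3 species with both intron counts and genome sizes")
  x <- as.numeric(intron_counts[common])
  y <- as.numeric(genome_sizes[common])
  n <- length(common)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 10L) {
    stat <- function(p) stats::cor(rx, ry[p])
    perms8 <- .permutations(min(n, 8L))
    count <- 0; totalp <- 0
    eval_chunk <- function(P) {
      r <- apply(P, 1L, stat)
      count <<- count + sum(abs(r) >= abs(rho) - 1e-12)
      totalp <<- totalp + nrow(P)
    }
    if (n <= 8L) {
      eval_chunk(perms8)
    } else if (n == 9L) {
      for (i in seq_len(9L)) {
        rest <- setdiff(seq_len(9L), i)
        eval_chunk(cbind(i, matrix(rest[perms8], nrow(perms8), 8L)))
      }
    } else {
      for (i in seq_len(10L)) for (j in setdiff(seq_len(10L), i)) {
        rest <- setdiff(seq_len(10L), c(i, j))
        eval_chunk(cbind(i, j, matrix(rest[perms8], nrow(perms8), 8L)))
      }
    }
    p <- count / totalp
    method <- "Spearman rank correlation, exact permutation p"
  } else {
    tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "Spearman rank correlation, t approximation"
  }
  list(estimate = rho, p.value = min(p, 1), n = n, method = method,
       table = data.frame(species = common, introns = x, genome_size = y,
                          stringsAsFactors = FALSE))
}

# All permutations of 1..n as an n! x n integer matrix (n small).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}
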