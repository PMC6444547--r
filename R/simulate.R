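#' Parameters for the intron presence/absence simulator
#'
#' The generative model: a set of ancestral intron sites at the root of a
#' rooted species tree, then independent gains and losses along each branch.
#' Gains per branch are Poisson with mean `gain_rate * branch_length` and
#' draw a fresh (residue, phase) slot unoccupied on that lineage, phase
#' uniform over {0, 1, 2}; losses are Poisson with mean
#' `loss_rate * n_present * branch_length` and remove uniformly chosen
#' present sites (`loss_rate = Inf` means every present site is lost on
#' every branch). This is the simplest generative counterpart of a
#' parsimony reconstruction target — no substitution model, no rate
#' heterogeneity.
#'
#' @param n_ancestral_sites number of intron sites present at the root.
#' @param gain_rate expected gains per unit branch length (>= 0).
#' @param loss_rate expected losses per present site per unit branch length
#'   (>= 0, may be `Inf`).
#' @param protein_length ancestral protein length in residues (>= 10).
#' @param indel_rate per-residue probability of a whole-codon indel when
#'   emitting divergent orthologs (half deletions, half insertions).
#' @param intron_length emitted intron length in nucleotides (GT...AG).
#' @param seed integer seed; all simulator randomness flows from it.
#' @return a `simulation_params` object.
#' @export
simulation_params <- function(n_ancestral_sites = 10L, gain_rate = 0.5,
                              loss_rate = 0.05, protein_length = 400L,
                              indel_rate = 0, intron_length = 60L,
                              seed = 1L) {
  stopifnot(n_ancestral_sites >= 0, gain_rate >= 0, loss_rate >= 0,
            protein_length >= 10, indel_rate >= 0, indel_rate <= 1,
            intron_length >= 4)
  if (n_ancestral_sites > 3L * protein_length)
    stop("protein_length too small: only ", 3L * protein_length,
         " distinct (residue, phase) slots for ", n_ancestral_sites, " sites")
  structure(list(n_ancestral_sites = as.integer(n_ancestral_sites),
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 protein_length = as.integer(protein_length),
                 indel_rate = indel_rate,
                 intron_length = as.integer(intron_length),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

# slot <-> (residue, phase) encoding; slot in 1..3L
.slot_id <- function(slot) {
  slot <- as.integer(slot)
  sprintf("r%dp%d", (slot - 1L) %/% 3L + 1L, (slot - 1L) %% 3L)
}
.slot_residue <- function(slot) (slot - 1L) %/% 3L + 1L
.slot_phase <- function(slot) (slot - 1L) %% 3L

#' Simulate an intron gain/loss history on a species tree
#'
#' Runs the generative model of [simulation_params()] down the tree from a
#' set of ancestral sites, recording every event. The returned history is
#' self-consistent by construction and re-checked programmatically
#' ([check_history()]) before being returned: applying the event list to the
#' root sites along the tree reproduces the tip presence matrix, no site is
#' gained where present nor lost where absent.
#'
#' @param tree rooted `phylo` species tree (>= 1 tip; branch lengths default
#'   to 1).
#' @param params a [simulation_params()].
#' @return a `true_history`: list with `tree`, `params`, `sites` (registry:
#'   `site`, `residue`, `phase`, `origin`), `root_sites`, `events` (`branch`,
#'   `site`, `direction`, in application order), `tip_matrix` (species x
#'   site logical), and `node_sites` (sites present at every node).
#' @export
simulate_history <- function(tree, params) {
  stopifnot(inherits(params, "simulation_params"))
  tree <- validate_species_tree(tree)
  if (length(tree$tip.label) == 0L) stop("tree has no tips")
  ti <- .tree_index(tree)
  L <- params$protein_length
  nslot <- 3L * L
  .with_seed(params$seed, {
    root_slots <- sort(sample.int(nslot, params$n_ancestral_sites))
    node_slots <- vector("list", ti$n)
    node_slots[[ti$root]] <- root_slots
    events <- list()
    for (v in ti$pre) {
      if (v == ti$root) next
      cur <- node_slots[[ti$parent[v]]]
      t_len <- ti$blen[v]
      bname <- ti$node_name[v]
      n_gain <- stats::rpois(1L, params$gain_rate * t_len)
      if (n_gain > 0L) {
        free <- setdiff(seq_len(nslot), cur)
        if (length(free) < n_gain)
          stop("(residue, phase) slots exhausted on branch ", bname,
               "; increase protein_length")
        gained <- free[sample.int(length(free), n_gain)]
        cur <- c(cur, gained)
        events[[length(events) + 1L]] <-
          data.frame(branch = bname, site = .slot_id(gained),
                     direction = "gain", stringsAsFactors = FALSE)
      }
      n_present <- length(cur)
      if (n_present > 0L) {
        n_loss <- if (is.infinite(params$loss_rate)) n_present
        else min(stats::rpois(1L, params$loss_rate * n_present * t_len), n_present)
        if (n_loss > 0L) {
          lost <- cur[sample.int(n_present, n_loss)]
          cur <- setdiff(cur, lost)
          events[[length(events) + 1L]] <-
            data.frame(branch = bname, site = .slot_id(lost),
                       direction = "loss", stringsAsFactors = FALSE)
        }
      }
      node_slots[[v]] <- sort(cur)
    }
    ev <- if (length(events)) do.call(rbind, events)
    else data.frame(branch = character(0), site = character(0),
                    direction = character(0), stringsAsFactors = FALSE)
    all_slots <- sort(unique(c(root_slots,
                               unlist(node_slots, use.names = FALSE))))
    gained_slots <- setdiff(all_slots, root_slots)
    # registry also includes gained sites later lost everywhere
    ev_gain_slots <- if (nrow(ev)) {
      g <- ev$site[ev$direction == "gain"]
      sort(unique(c(gained_slots, .id_slot(g))))
    } else gained_slots
    all_slots <- sort(unique(c(root_slots, ev_gain_slots)))
    sites <- data.frame(site = .slot_id(all_slots),
                        residue = .slot_residue(all_slots),
                        phase = .slot_phase(all_slots),
                        origin = ifelse(all_slots %in% root_slots, "root", "gain"),
                        stringsAsFactors = FALSE)
    tip_matrix <- matrix(FALSE, ti$ntip, nrow(sites),
                         dimnames = list(tree$tip.label, sites$site))
    for (v in seq_len(ti$ntip))
      tip_matrix[v, .slot_id(node_slots[[v]])] <- TRUE
    hist <- structure(list(tree = tree, params = params, sites = sites,
                           root_sites = sites[sites$origin == "root", , drop = FALSE],
                           events = ev, tip_matrix = tip_matrix,
                           node_sites = stats::setNames(lapply(node_slots, .slot_id),
                                                        ti$node_name)),
                      class = "true_history")
    check_history(hist)
    hist
  })
}

.id_slot <- function(id) {
  m <- regmatches(id, regexec("^r([0-9]+)p([0-2])$", id))
  vapply(m, function(x) (as.integer(x[2L]) - 1L) * 3L + as.integer(x[3L]) + 1L,
         integer(1))
}

#' Construct a history from an explicit event plan
#'
#' Deterministic companion to [simulate_history()]: the caller supplies the
#' root sites and the per-branch events, and the tip matrix is derived by
#' applying them along the tree. Used to build fixtures with known parsimony
#' behaviour (unambiguous single events, ties, parallel changes, studies
#' sized to a target number of sites and changes).
#'
#' @param tree rooted `phylo`.
#' @param params a [simulation_params()] (rates are ignored; protein length
#'   and seed are used for emission).
#' @param root_slots integer slots (`1..3*protein_length`) present at the
#'   root.
#' @param events data frame with columns `branch` (branch name = child node
#'   label), `site` (slot id string like `"r10p0"`), `direction`
#'   (`"gain"`/`"loss"`), applied in row order.
#' @return a `true_history` (see [simulate_history()]).
#' @export
plant_history <- function(tree, params, root_slots, events) {
  tree <- validate_species_tree(tree)
  ti <- .tree_index(tree)
  root_slots <- sort(unique(as.integer(root_slots)))
  stopifnot(all(root_slots >= 1L), all(root_slots <= 3L * params$protein_length))
  if (is.null(events) || nrow(events) == 0L)
    events <- data.frame(branch = character(0), site = character(0),
                         direction = character(0), stringsAsFactors = FALSE)
  node_slots <- vector("list", ti$n)
  node_slots[[ti$root]] <- root_slots
  for (v in ti$pre) {
    if (v == ti$root) next
    cur <- node_slots[[ti$parent[v]]]
    bev <- events[events$branch == ti$node_name[v], , drop = FALSE]
    for (i in seq_len(nrow(bev))) {
      slot <- .id_slot(bev$site[i])
      if (bev$direction[i] == "gain") {
        if (slot %in% cur)
          stop("plant_history: gain of ", bev$site[i], " on branch ",
               bev$branch[i], " where already present")
        cur <- c(cur, slot)
      } else {
        if (!(slot %in% cur))
          stop("plant_history: loss of ", bev$site[i], " on branch ",
               bev$branch[i], " where absent")
        cur <- setdiff(cur, slot)
      }
    }
    node_slots[[v]] <- sort(cur)
  }
  all_slots <- sort(unique(c(root_slots, .id_slot(events$site))))
  sites <- data.frame(site = .slot_id(all_slots),
                      residue = .slot_residue(all_slots),
                      phase = .slot_phase(all_slots),
                      origin = ifelse(all_slots %in% root_slots, "root", "gain"),
                      stringsAsFactors = FALSE)
  tip_matrix <- matrix(FALSE, ti$ntip, nrow(sites),
                       dimnames = list(tree$tip.label, sites$site))
  for (v in seq_len(ti$ntip))
    tip_matrix[v, .slot_id(node_slots[[v]])] <- TRUE
  hist <- structure(list(tree = tree, params = params, sites = sites,
                         root_sites = sites[sites$origin == "root", , drop = FALSE],
                         events = events, tip_matrix = tip_matrix,
                         node_sites = stats::setNames(lapply(node_slots, .slot_id),
                                                      ti$node_name)),
                    class = "true_history")
  check_history(hist)
  hist
}

#' Check the internal consistency of a simulated history
#'
#' Re-applies the event list to the root sites along the tree and verifies
#' that the result equals the recorded tip matrix, and that no event gains a
#' present site or loses an absent one. Called by the simulator on every
#' run; exported so tests and pipelines can re-verify loaded histories.
#'
#' @param history a `true_history`.
#' @return `TRUE` invisibly; stops with a message on any inconsistency.
#' @export
check_history <- function(history) {
  stopifnot(inherits(history, "true_history"))
  ti <- .tree_index(history$tree)
  root <- history$root_sites$site
  node_sets <- vector("list", ti$n)
  node_sets[[ti$root]] <- root
  ev <- history$events
  for (v in ti$pre) {
    if (v == ti$root) next
    cur <- node_sets[[ti$parent[v]]]
    bev <- ev[ev$branch == ti$node_name[v], , drop = FALSE]
    for (i in seq_len(nrow(bev))) {
      if (bev$direction[i] == "gain") {
        if (bev$site[i] %in% cur)
          stop("history inconsistent: gain of present site ", bev$site[i])
        cur <- c(cur, bev$site[i])
      } else {
        if (!(bev$site[i] %in% cur))
          stop("history inconsistent: loss of absent site ", bev$site[i])
        cur <- setdiff(cur, bev$site[i])
      }
    }
    node_sets[[v]] <- cur
  }
  for (v in seq_len(ti$ntip)) {
    expect <- sort(as.character(node_sets[[v]]))
    got <- sort(as.character(colnames(history$tip_matrix)[history$tip_matrix[v, ]]))
    if (!identical(expect, got))
      stop("history inconsistent at tip ", ti$node_name[v],
           ": event replay does not reproduce tip_matrix")
  }
  invisible(TRUE)
}

#' @export
print.true_history <- function(x, ...) {
  cat("Simulated intron history:", nrow(x$sites), "site(s),",
      nrow(x$events), "event(s) on", length(x$tree$tip.label), "tips\n")
  invisible(x)
}

#' Truth totals of a history, on the scale parsimony reports
#'
#' @param history a `true_history`.
#' @return list with `n_changes` (total events), `n_variable_sites` (sites
#'   whose tip pattern is non-constant across species), `n_observed_sites`
#'   (sites present in at least one tip).
#' @export
history_truth_totals <- function(history) {
  tm <- history$tip_matrix
  pres <- colSums(tm)
  list(n_changes = nrow(history$events),
       n_variable_sites = sum(pres > 0 & pres < nrow(tm)),
       n_observed_sites = sum(pres > 0))
}
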