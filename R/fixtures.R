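#' Eight-species insect tree used by the example fixtures
#'
#' A rooted, binary eight-taxon topology shaped like the comparative studies
#' this package targets: four true bugs (milkweed bug Ofas, stink bug Hhal,
#' bed bug Clec, kissing bug Rpro), the pea aphid Apis, a thrips Focc as the
#' remaining hemipteroid, and a beetle/fly pair (Tcas, Dmel) as the
#' holometabolous outgroup. Unit branch lengths.
#'
#' @return a `phylo` object with 8 tips.
#' @export
fixture_tree8 <- function() {
  validate_species_tree(ape::read.tree(text =
    "(((((Ofas:1,Hhal:1):1,(Clec:1,Rpro:1):1):1,Apis:1):1,Focc:1):1,(Tcas:1,Dmel:1):1);"))
}

#' Materialise a documented suite of test fixtures
#'
#' Writes a fixture directory (tree, per-family gene models, alignments,
#' truth JSON) for one of the named configurations:
#'
#' * `"minimal"` — 2-tip tree, 1 simulated family.
#' * `"insect8"` — the 8-tip tree of [fixture_tree8()] with 3 simulated
#'   ortholog families of contrasting size (a large many-intron gene, a
#'   mid-sized gene, and a small intron-poor gene), plus synthetic genome
#'   sizes correlated with the species' true intron counts.
#' * `"cases"` — constructed 4-tip families with known parsimony behaviour:
#'   zero-change, single-gain, single-loss, tie-inducing, parallel-loss and
#'   gap-containing.
#' * `"insect8-scaled"` — a deterministic 8-species study planted to contain
#'   exactly 148 variable splice-site characters and 165 events across 3
#'   families (plus invariant ancestral sites), for a full-pipeline
#'   rehearsal at the scale of a real comparative study.
#'
#' Regenerating with the same seed gives byte-identical files.
#'
#' @param config one of `"minimal"`, `"insect8"`, `"cases"`,
#'   `"insect8-scaled"`.
#' @param dir output directory (created; families under `families/<name>`).
#' @param seed integer seed for all randomness.
#' @return list with `dir`, `tree`, `families` (named list of
#'   `true_history`), `emitted` (named list of [emit_gene_models()] results),
#'   and `genome_sizes` (named vector or NULL).
#' @export
generate_fixture_suite <- function(config = c("insect8", "minimal", "cases",
                                              "insect8-scaled"),
                                   dir, seed = 1L) {
  config <- match.arg(config)
  seed <- as.integer(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(config,
                "minimal" = .suite_minimal(dir, seed),
                "insect8" = .suite_insect8(dir, seed),
                "cases" = .suite_cases(dir, seed),
                "insect8-scaled" = .suite_scaled(dir, seed))
  ape::write.tree(out$tree, file.path(dir, "tree.nwk"))
  if (!is.null(out$genome_sizes)) {
    gs <- data.frame(species = names(out$genome_sizes),
                     genome_size_mb = as.numeric(out$genome_sizes))
    utils::write.table(gs, file.path(dir, "genome_sizes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out$dir <- dir
  out
}

.emit_suite <- function(tree, families, dir) {
  emitted <- list()
  for (nm in names(families)) {
    emitted[[nm]] <- emit_gene_models(families[[nm]],
                                      file.path(dir, "families", nm),
                                      family_id = nm)
  }
  emitted
}

.suite_minimal <- function(dir, seed) {
  tree <- validate_species_tree(ape::read.tree(text = "(A:1,B:1);"))
  fam <- simulate_history(tree, simulation_params(
    n_ancestral_sites = 4L, gain_rate = 0.5, loss_rate = 0.1,
    protein_length = 120L, seed = seed))
  families <- list(fam1 = fam)
  list(tree = tree, families = families,
       emitted = .emit_suite(tree, families, dir), genome_sizes = NULL)
}

.suite_insect8 <- function(dir, seed) {
  tree <- fixture_tree8()
  families <- list(
    hemocytin_like = simulate_history(tree, simulation_params(
      n_ancestral_sites = 40L, gain_rate = 1.2, loss_rate = 0.02,
      protein_length = 800L, seed = seed)),
    tenm_like = simulate_history(tree, simulation_params(
      n_ancestral_sites = 20L, gain_rate = 0.8, loss_rate = 0.02,
      protein_length = 600L, seed = seed + 1L)),
    epimerase_like = simulate_history(tree, simulation_params(
      n_ancestral_sites = 5L, gain_rate = 0.3, loss_rate = 0.02,
      protein_length = 300L, seed = seed + 2L)))
  counts <- Reduce(`+`, lapply(families, function(f) rowSums(f$tip_matrix)))
  # synthetic genome sizes, positively coupled to true intron numbers with
  # mild noise — emulates the observed size/intron-number trend
  gs <- .with_seed(seed + 3L,
                   round(400 + 12 * counts + stats::rnorm(length(counts), 0, 10)))
  names(gs) <- tree$tip.label
  list(tree = tree, families = families,
       emitted = .emit_suite(tree, families, dir), genome_sizes = gs)
}

# Constructed 4-tip cases with known parsimony behaviour.
.suite_cases <- function(dir, seed) {
  tree <- validate_species_tree(ape::read.tree(text = "((A:1,B:1)AB:1,(C:1,D:1)CD:1)R;"))
  p <- function(s) simulation_params(n_ancestral_sites = 0L, gain_rate = 0,
                                     loss_rate = 0, protein_length = 60L,
                                     seed = s)
  ev <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(branch = r[[1]], site = r[[2]], direction = r[[3]],
                 stringsAsFactors = FALSE)))
  }
  sl <- function(r, ph) 3L * (r - 1L) + ph + 1L  # slot of (residue, phase)
  families <- list(
    zero_change = plant_history(tree, p(seed), root_slots = c(30L, 60L, 90L),
                                events = NULL),
    single_gain = plant_history(tree, p(seed + 1L), root_slots = sl(10L, 0L),
                                events = ev(list("AB", "r20p1", "gain"))),
    single_loss = plant_history(tree, p(seed + 2L),
                                root_slots = c(sl(10L, 0L), sl(25L, 0L)),
                                events = ev(list("D", "r25p0", "loss"))),
    # present in A and C only: 2 changes, root state ambiguous (tie)
    tie = plant_history(tree, p(seed + 3L), root_slots = sl(15L, 0L),
                        events = ev(list("B", "r15p0", "loss"),
                                    list("D", "r15p0", "loss"))),
    parallel_loss = plant_history(tree, p(seed + 4L),
                                  root_slots = c(sl(10L, 0L), sl(19L, 0L)),
                                  events = ev(list("A", "r19p0", "loss"),
                                              list("C", "r19p0", "loss"))),
    gap_containing = plant_history(tree, p(seed + 5L), root_slots = sl(12L, 0L),
                                   events = ev(list("C", "r12p0", "loss"),
                                               list("D", "r12p0", "loss"))))
  emitted <- list()
  for (nm in names(families)) {
    emitted[[nm]] <- emit_gene_models(
      families[[nm]], file.path(dir, "families", nm), family_id = nm,
      deletions = if (nm == "gap_containing") list(C = 12L) else NULL)
  }
  list(tree = tree, families = families, emitted = emitted,
       genome_sizes = NULL)
}

# Plant a study with an exact number of variable sites and events:
# single-gain and single-loss sites are unambiguous one-change characters;
# parallel pairs place the same change on two independent terminal branches
# (two changes each, minimal by construction). Invariant ancestral sites are
# added for root-retention reporting and change nothing in the totals.
.plant_study_family <- function(tree, protein_length, n_single_gain,
                                n_single_loss, n_parallel, n_invariant,
                                seed) {
  ti <- .tree_index(tree)
  branches <- ti$node_name[which(!is.na(ti$parent))]
  tips <- tree$tip.label
  # tip pairs from different root subtrees: for such a pair the two terminal
  # changes are the unique optimum (no gain-at-ancestor-plus-loss alternative
  # can reach cost 2), so the planted site is parallel in every MP scenario
  side <- integer(ti$ntip)
  for (ci in seq_along(ti$children[[ti$root]])) {
    sub <- c(ti$children[[ti$root]][ci], ti$desc[[ti$children[[ti$root]][ci]]])
    side[intersect(sub, seq_len(ti$ntip))] <- ci
  }
  pairs <- list()
  for (i in seq_along(tips)) for (j in seq_along(tips)) {
    if (i >= j) next
    if (side[i] != side[j]) pairs[[length(pairs) + 1L]] <- c(tips[i], tips[j])
  }
  .with_seed(seed, {
    nslot <- 3L * protein_length
    need <- n_single_gain + n_single_loss + n_parallel + n_invariant
    slots <- sample.int(nslot, need)
    k <- 0L
    take <- function(n) { s <- slots[(k + 1L):(k + n)]; k <<- k + n; s }
    gain_slots <- if (n_single_gain) take(n_single_gain) else integer(0)
    loss_slots <- if (n_single_loss) take(n_single_loss) else integer(0)
    par_slots <- if (n_parallel) take(n_parallel) else integer(0)
    inv_slots <- if (n_invariant) take(n_invariant) else integer(0)
    rows <- list()
    for (s in gain_slots)
      rows[[length(rows) + 1L]] <- data.frame(
        branch = sample(branches, 1L), site = .slot_id(s),
        direction = "gain", stringsAsFactors = FALSE)
    for (s in loss_slots)
      rows[[length(rows) + 1L]] <- data.frame(
        branch = sample(branches, 1L), site = .slot_id(s),
        direction = "loss", stringsAsFactors = FALSE)
    par_loss <- integer(0)
    for (s in par_slots) {
      pr <- pairs[[sample.int(length(pairs), 1L)]]
      dir <- sample(c("gain", "loss"), 1L)
      if (dir == "loss") par_loss <- c(par_loss, s)
      for (tp in pr)
        rows[[length(rows) + 1L]] <- data.frame(
          branch = tp, site = .slot_id(s), direction = dir,
          stringsAsFactors = FALSE)
    }
    events <- do.call(rbind, c(rows, list(data.frame(
      branch = character(0), site = character(0), direction = character(0),
      stringsAsFactors = FALSE))))
    root <- sort(unique(c(loss_slots, inv_slots, par_loss)))
    params <- simulation_params(n_ancestral_sites = 0L, gain_rate = 0,
                                loss_rate = 0, protein_length = protein_length,
                                seed = seed)
    plant_history(tree, params, root_slots = root, events = events)
  })
}

.suite_scaled <- function(dir, seed) {
  tree <- fixture_tree8()
  # 73 + 45 + 30 = 148 variable sites; 81 + 50 + 34 = 165 events
  families <- list(
    hemocytin_like = .plant_study_family(tree, 900L, n_single_gain = 40L,
                                         n_single_loss = 25L, n_parallel = 8L,
                                         n_invariant = 20L, seed = seed),
    tenm_like = .plant_study_family(tree, 600L, n_single_gain = 25L,
                                    n_single_loss = 15L, n_parallel = 5L,
                                    n_invariant = 10L, seed = seed + 1L),
    epimerase_like = .plant_study_family(tree, 450L, n_single_gain = 15L,
                                         n_single_loss = 11L, n_parallel = 4L,
                                         n_invariant = 4L, seed = seed + 2L))
  counts <- Reduce(`+`, lapply(families, function(f) rowSums(f$tip_matrix)))
  gs <- .with_seed(seed + 3L,
                   round(400 + 12 * counts + stats::rnorm(length(counts), 0, 10)))
  names(gs) <- tree$tip.label
  list(tree = tree, families = families,
       emitted = .emit_suite(tree, families, dir), genome_sizes = gs)
}

#' Parse one emitted family back into a site matrix
#'
#' Convenience wrapper chaining [parse_gene_models()],
#' [derive_intron_sites()], [read_alignment()] and [build_site_matrix()]
#' over a family directory written by [emit_gene_models()] (or any directory
#' with the same layout: `<species>.gff3`, `<species>.genome.fa`, `msa.fa`).
#'
#' @param family_dir the family directory.
#' @param tree rooted `phylo` defining the species set.
#' @param family_id family identifier for the result.
#' @param gap_policy see [build_site_matrix()].
#' @return list with `matrix` (a `site_matrix`), `models`, `sites_by_species`
#'   and `msa`.
#' @export
read_family <- function(family_dir, tree, family_id = basename(family_dir),
                        gap_policy = "unknown") {
  tree <- validate_species_tree(tree)
  models <- list()
  sites_by_species <- list()
  proteins <- character(0)
  for (sp in tree$tip.label) {
    gff <- file.path(family_dir, paste0(sp, ".gff3"))
    gen <- file.path(family_dir, paste0(sp, ".genome.fa"))
    if (!file.exists(gff) || !file.exists(gen)) next
    mods <- parse_gene_models(gff, gen, species = sp)
    if (length(mods) == 0L) next
    m <- mods[[1L]]
    models[[sp]] <- m
    sites_by_species[[sp]] <- derive_intron_sites(m)
    proteins[sp] <- m$protein
  }
  msa <- read_alignment(file.path(family_dir, "msa.fa"), proteins = proteins)
  matrix <- build_site_matrix(sites_by_species, msa, tree,
                              family_id = family_id, gap_policy = gap_policy)
  list(matrix = matrix, models = models,
       sites_by_species = sites_by_species, msa = msa)
}

#' Compare a recovered site matrix against simulated truth
#'
#' Checks that the characters of a `site_matrix` are exactly the simulated
#' sites observable at the tips (present in >= 1 species), at the true
#' alignment columns and phases, and that every non-`unknown` state agrees
#' with the simulated tip presence matrix.
#'
#' @param matrix a `site_matrix` recovered via the parse/derive/map path.
#' @param history the generating `true_history`.
#' @param site_map `site_map` from [emit_gene_models()].
#' @return `TRUE` if everything matches, otherwise a character vector of
#'   discrepancies.
#' @export
matrix_matches_truth <- function(matrix, history, site_map) {
  probs <- character(0)
  tm <- history$tip_matrix
  observable <- colnames(tm)[colSums(tm) > 0]
  sm_key <- paste0("c", matrix$sites$column, "p", matrix$sites$phase)
  truth_key <- paste0("c", site_map$column[match(observable, site_map$site)],
                      "p", site_map$phase[match(observable, site_map$site)])
  if (!setequal(sm_key, truth_key)) {
    probs <- c(probs, paste("character set mismatch: recovered",
                            length(sm_key), "vs true", length(truth_key)))
  } else {
    for (i in seq_along(observable)) {
      k <- which(sm_key == truth_key[i])
      states <- matrix$states[, k]
      truth <- ifelse(tm[rownames(matrix$states), observable[i]],
                      "present", "absent")
      known <- states != "unknown"
      if (!all(states[known] == truth[known]))
        probs <- c(probs, paste("state mismatch at site", observable[i]))
    }
  }
  if (length(probs)) probs else TRUE
}

#' Site matrix directly from a simulated history
#'
#' Builds the splice-site character matrix a perfect alignment of identical
#' proteins would yield: characters are the simulated sites observable in at
#' least one tip, at column = ancestral residue, with states read off the
#' true tip presence matrix. This isolates the inference stages from file
#' IO; the emit/parse path must reproduce exactly this matrix when no
#' indels are simulated.
#'
#' @param history a `true_history`.
#' @param family_id identifier stored in the result.
#' @return a `site_matrix`.
#' @export
history_site_matrix <- function(history, family_id = "truth") {
  tm <- history$tip_matrix
  keep <- colSums(tm) > 0
  sites <- history$sites[match(colnames(tm)[keep], history$sites$site), ,
                         drop = FALSE]
  ids <- sprintf("c%dp%d", sites$residue, sites$phase)
  states <- matrix(ifelse(tm[, keep, drop = FALSE], "present", "absent"),
                   nrow(tm), sum(keep),
                   dimnames = list(rownames(tm), ids))
  structure(list(family_id = family_id,
                 sites = data.frame(site = ids, column = sites$residue,
                                    phase = sites$phase,
                                    stringsAsFactors = FALSE),
                 states = states,
                 provenance = NULL,
                 alignment_width = history$params$protein_length,
                 gap_policy = "unknown",
                 missing_species = character(0)),
            class = "site_matrix")
}
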