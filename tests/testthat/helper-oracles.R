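# Independent oracles and tiny constructors shared across the suite.

# Exhaustive small-parsimony oracle: enumerate every assignment of the free
# nodes (internal nodes and unknown tips), count weighted changes on edges,
# and keep all minimum-cost labellings. Completely independent of the
# package's dynamic programme.
brute_parsimony <- function(states, tree, gain = 1, loss = 1) {
  ti <- intronevo:::.tree_index(tree)
  fixed <- rep(NA_integer_, ti$n)
  for (i in seq_len(ti$ntip)) {
    fixed[i] <- switch(states[[tree$tip.label[i]]],
                       absent = 0L, present = 1L, unknown = NA_integer_)
  }
  free <- sort(c(which(is.na(fixed[seq_len(ti$ntip)])), (ti$ntip + 1L):ti$n))
  grid <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  best <- Inf
  labs <- NULL
  for (g in seq_len(nrow(grid))) {
    lab <- fixed
    lab[free] <- as.integer(grid[g, ])
    cost <- 0
    for (v in seq_len(ti$n)) {
      u <- ti$parent[v]
      if (is.na(u)) next
      if (lab[u] == 0L && lab[v] == 1L) cost <- cost + gain
      if (lab[u] == 1L && lab[v] == 0L) cost <- cost + loss
    }
    if (cost < best - 1e-9) {
      best <- cost
      labs <- matrix(lab, nrow = 1)
    } else if (abs(cost - best) < 1e-9) {
      labs <- rbind(labs, lab)
    }
  }
  colnames(labs) <- ti$node_name
  list(score = best, labs = unique(labs))
}

# Per-branch gain/loss min/max over the oracle's optimal labellings.
brute_branch_ranges <- function(brute, tree) {
  ti <- intronevo:::.tree_index(tree)
  child <- which(!is.na(ti$parent))
  out <- data.frame(branch = ti$node_name[child],
                    gain_min = NA_integer_, gain_max = NA_integer_,
                    loss_min = NA_integer_, loss_max = NA_integer_)
  for (bi in seq_along(child)) {
    v <- child[bi]
    u <- ti$parent[v]
    gains <- brute$labs[, u] == 0L & brute$labs[, v] == 1L
    losses <- brute$labs[, u] == 1L & brute$labs[, v] == 0L
    out$gain_min[bi] <- as.integer(all(gains))
    out$gain_max[bi] <- as.integer(any(gains))
    out$loss_min[bi] <- as.integer(all(losses))
    out$loss_max[bi] <- as.integer(any(losses))
  }
  out
}

# A gene model with given exon lengths in nt (stop codon not included),
# protein made of alanines, consecutive genomic intervals with 100-nt introns.
toy_gene_model <- function(widths, species = "sp", gene_id = "g1",
                           strand = "+") {
  widths <- as.integer(widths)
  stopifnot(sum(widths) %% 3L == 0L)
  starts <- integer(length(widths))
  pos <- 0L
  for (i in seq_along(widths)) {
    starts[i] <- pos + 1L
    pos <- pos + widths[i] + 100L
  }
  exons <- data.frame(start = starts, end = starts + widths - 1L)
  phases <- (3L - (cumsum(c(0L, widths[-length(widths)])) %% 3L)) %% 3L
  gene_model(species = species, gene_id = gene_id, strand = strand,
             exons = exons, phases = phases,
             protein = strrep("A", sum(widths) / 3L),
             stop_included = FALSE)
}

# A site_matrix built directly from a species x site state matrix
# (columns named like "c<column>p<phase>").
toy_site_matrix <- function(states, family_id = "toy") {
  key <- regmatches(colnames(states),
                    regexec("^c([0-9]+)p([0-2])$", colnames(states)))
  sites <- data.frame(site = colnames(states),
                      column = vapply(key, function(k) as.integer(k[2]), integer(1)),
                      phase = vapply(key, function(k) as.integer(k[3]), integer(1)),
                      stringsAsFactors = FALSE)
  structure(list(family_id = family_id, sites = sites, states = states,
                 provenance = NULL, alignment_width = max(sites$column) + 1L,
                 gap_policy = "unknown", missing_species = character(0)),
            class = "site_matrix")
}

tree_quartet <- function() {
  validate_species_tree(ape::read.tree(text = "((A:1,B:1)AB:1,(C:1,D:1)CD:1)R;"))
}

random_rooted_tree <- function(ntip) {
  validate_species_tree(ape::rtree(ntip, rooted = TRUE))
}

# A tiny GFF3 + genome pair written inline: contig of alanine codons so any
# in-frame CDS translates cleanly.
write_toy_gff <- function(dir, cds_rows, contig_nt = strrep("GCT", 400),
                          mrnas = NULL) {
  gff <- file.path(dir, "toy.gff3")
  fa <- file.path(dir, "toy.fa")
  lines <- "##gff-version 3"
  if (is.null(mrnas)) mrnas <- unique(vapply(cds_rows, `[[`, character(1), "tx"))
  for (m in mrnas)
    lines <- c(lines, paste("ctg1", "test", "mRNA", 1, nchar(contig_nt), ".",
                            "+", ".", paste0("ID=", m, ";Parent=g1"), sep = "\t"))
  for (r in cds_rows)
    lines <- c(lines, paste("ctg1", "test", "CDS", r$start, r$end, ".",
                            if (is.null(r$strand)) "+" else r$strand,
                            r$phase, paste0("ID=", r$tx, ":cds;Parent=", r$tx),
                            sep = "\t"))
  writeLines(lines, gff)
  writeLines(c(">ctg1", contig_nt), fa)
  list(gff = gff, fa = fa)
}
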