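# Codon choices per amino acid, from the standard genetic code.
.codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Emit gene models, sequences and alignment for one simulated family
#'
#' Materialises a `true_history` as files a real annotation project would
#' provide: per species a single-contig genome FASTA and a GFF3 gene whose
#' CDS features realise exactly that species' intron set (each intron placed
#' after the coding-nucleotide count implied by its (residue, phase)), a
#' protein FASTA, and the true protein alignment. Nucleotide sequences use
#' one fixed random codon per residue and fixed-length introns with
#' canonical `GT...AG` boundaries; the CDS includes a trailing `TAA` stop
#' codon. Species alternate between + and - strand so both orientations are
#' exercised downstream.
#'
#' Whole-codon indels (probability `indel_rate` per ancestral residue, half
#' deletions and half single-residue insertions) produce divergent orthologs
#' whose emitted alignment still reflects the true homology; a deletion is
#' suppressed when it would remove a residue anchoring an intron of that
#' species, so the event history stays realisable. Extra deletions can be
#' forced via `deletions` to build gap fixtures.
#'
#' @param history a `true_history` from [simulate_history()] or
#'   [plant_history()].
#' @param dir output directory for this family (created).
#' @param family_id family name used in ids.
#' @param deletions optional named list: species -> ancestral residue
#'   indices to delete regardless of `indel_rate`.
#' @param flank length of random flanking sequence on each side of the gene.
#' @return list with `paths` (per-species gff3/genome/protein, plus `msa`
#'   and `truth`), `site_map` (data frame `site`, `residue`, `phase`,
#'   `column`: true alignment column of each site), `msa` (named character),
#'   `proteins`, and `species_sites` (per-species anchor/phase tables in
#'   species protein coordinates).
#' @export
emit_gene_models <- function(history, dir, family_id = "fam1",
                             deletions = NULL, flank = 100L) {
  stopifnot(inherits(history, "true_history"))
  params <- history$params
  tree <- history$tree
  species <- tree$tip.label
  L <- params$protein_length
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aa_letters <- setdiff(Biostrings::AA_STANDARD, character(0))
  cba <- .codons_by_aa()

  .with_seed(params$seed + 7907L, {
    anc_res <- sample(aa_letters, L, replace = TRUE)
    anc_codon <- vapply(anc_res, function(a) sample(cba[[a]], 1L), character(1))

    # per-species indels over ancestral residues
    keep <- list(); ins_res <- list(); ins_codon <- list()
    for (sp in species) {
      anchors <- history$sites$residue[history$tip_matrix[sp, ]]
      kp <- rep(TRUE, L)
      ins <- rep(NA_character_, L)
      if (params$indel_rate > 0) {
        u <- stats::runif(L)
        del <- u < params$indel_rate / 2
        del[anchors] <- FALSE
        kp[del] <- FALSE
        do_ins <- u >= params$indel_rate / 2 & u < params$indel_rate
        ins[do_ins] <- sample(aa_letters, sum(do_ins), replace = TRUE)
      }
      if (!is.null(deletions[[sp]])) {
        forced <- setdiff(as.integer(deletions[[sp]]), anchors)
        kp[forced] <- FALSE
      }
      keep[[sp]] <- kp
      ins_res[[sp]] <- ins
      ins_codon[[sp]] <- vapply(ins, function(a)
        if (is.na(a)) NA_character_ else sample(cba[[a]], 1L), character(1))
    }

    # alignment columns: ancestral column j, then one column per species
    # inserting after j (species order fixed) — truth stays computable
    col_kind <- character(0); col_res <- integer(0); col_sp <- character(0)
    anc_col <- integer(L)
    for (j in seq_len(L)) {
      col_kind <- c(col_kind, "anc"); col_res <- c(col_res, j)
      col_sp <- c(col_sp, NA_character_)
      anc_col[j] <- length(col_kind)
      for (sp in species) {
        if (!is.na(ins_res[[sp]][j])) {
          col_kind <- c(col_kind, "ins"); col_res <- c(col_res, j)
          col_sp <- c(col_sp, sp)
        }
      }
    }
    ncol_msa <- length(col_kind)
    msa <- character(0)
    proteins <- character(0)
    for (sp in species) {
      row <- rep("-", ncol_msa)
      for (k in seq_len(ncol_msa)) {
        j <- col_res[k]
        if (col_kind[k] == "anc") {
          if (keep[[sp]][j]) row[k] <- anc_res[j]
        } else if (identical(col_sp[k], sp)) {
          row[k] <- ins_res[[sp]][j]
        }
      }
      msa[sp] <- paste(row, collapse = "")
      proteins[sp] <- gsub("-", "", msa[sp])
    }

    site_map <- cbind(history$sites[, c("site", "residue", "phase")],
                      column = anc_col[history$sites$residue])

    paths <- list()
    species_sites <- list()
    for (si in seq_along(species)) {
      sp <- species[si]
      strand <- if (si %% 2L == 1L) "+" else "-"
      kp <- keep[[sp]]
      # species residue index of each ancestral residue (NA if deleted)
      sp_index <- rep(NA_integer_, L)
      pos <- 0L
      for (j in seq_len(L)) {
        if (kp[j]) { pos <- pos + 1L; sp_index[j] <- pos }
        if (!is.na(ins_res[[sp]][j])) pos <- pos + 1L
      }
      # codons of the species protein, in order
      codons <- character(0)
      for (j in seq_len(L)) {
        if (kp[j]) codons <- c(codons, anc_codon[j])
        if (!is.na(ins_res[[sp]][j])) codons <- c(codons, ins_codon[[sp]][j])
      }
      stopifnot(length(codons) == nchar(proteins[sp]))

      pres <- history$sites[history$tip_matrix[sp, ], , drop = FALSE]
      anchor_sp <- sp_index[pres$residue]
      stopifnot(!anyNA(anchor_sp))
      coff <- ifelse(pres$phase == 0L, 3L * anchor_sp,
                     3L * (anchor_sp - 1L) + pres$phase)
      o <- order(coff)
      coff <- coff[o]
      if (anyDuplicated(coff))
        stop("two introns at the same (residue, phase) in one gene: ",
             family_id, "/", sp)
      species_sites[[sp]] <- data.frame(anchor = anchor_sp[o],
                                        phase = pres$phase[o],
                                        site = pres$site[o],
                                        stringsAsFactors = FALSE)
      cds_nt <- paste0(paste(codons, collapse = ""), "TAA")
      total_nt <- nchar(cds_nt)
      bounds <- c(0L, coff, total_nt)
      exon_seqs <- substring(cds_nt, bounds[-length(bounds)] + 1L,
                             bounds[-1L])
      introns <- vapply(seq_len(max(length(exon_seqs) - 1L, 0L)), function(i)
        paste0("GT", paste(sample(c("A", "C", "G", "T"),
                                  params$intron_length - 4L,
                                  replace = TRUE), collapse = ""), "AG"),
        character(1))
      gene_id <- paste0(family_id, "_", sp)
      out <- .assemble_contig(exon_seqs, introns, flank, strand, gene_id)
      gff_path <- file.path(dir, paste0(sp, ".gff3"))
      genome_path <- file.path(dir, paste0(sp, ".genome.fa"))
      .write_gff3(out$features, gff_path)
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(stats::setNames(out$contig, out$contig_name)),
        genome_path)
      prot_path <- file.path(dir, paste0(sp, ".protein.fa"))
      Biostrings::writeXStringSet(
        Biostrings::AAStringSet(stats::setNames(proteins[sp], gene_id)),
        prot_path)
      paths[[sp]] <- list(gff3 = gff_path, genome = genome_path,
                          protein = prot_path)
    }
    msa_path <- file.path(dir, "msa.fa")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(msa), msa_path)
    truth_path <- file.path(dir, "truth.json")
    write_history_json(history, truth_path, site_map = site_map)
    list(paths = c(paths, list(msa = msa_path, truth = truth_path)),
         site_map = site_map, msa = msa, proteins = proteins,
         species_sites = species_sites)
  })
}

# Lay the exons and introns onto a contig (plus orientation), then flip the
# whole contig for minus-strand genes. Returns the contig string and a GFF3
# feature table.
.assemble_contig <- function(exon_seqs, introns, flank, strand, gene_id) {
  rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
  left <- rand_nt(flank)
  right <- rand_nt(flank)
  pieces <- character(0)
  starts <- ends <- integer(length(exon_seqs))
  pos <- nchar(left)
  for (i in seq_along(exon_seqs)) {
    starts[i] <- pos + 1L
    pos <- pos + nchar(exon_seqs[i])
    ends[i] <- pos
    pieces <- c(pieces, exon_seqs[i])
    if (i < length(exon_seqs)) {
      pieces <- c(pieces, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  contig <- paste0(left, paste(pieces, collapse = ""), right)
  widths <- nchar(exon_seqs)
  phases <- (3L - (cumsum(c(0L, widths[-length(widths)])) %% 3L)) %% 3L
  contig_name <- paste0("ctg_", gene_id)
  if (strand == "-") {
    len <- nchar(contig)
    contig <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(contig)))
    new_starts <- len - ends + 1L
    new_ends <- len - starts + 1L
    starts <- new_starts
    ends <- new_ends
  }
  feat <- data.frame(start = starts, end = ends, phase = phases,
                     stringsAsFactors = FALSE)  # rows in transcription order
  list(contig = contig, contig_name = contig_name,
       features = list(contig = contig_name, gene_id = gene_id,
                       strand = strand, cds = feat))
}

# Plain GFF3 rendering (version 3 header; gene/mRNA/CDS; 1-based inclusive).
.write_gff3 <- function(features, path) {
  cds <- features$cds
  g0 <- min(cds$start); g1 <- max(cds$end)
  gid <- features$gene_id
  mid <- paste0(gid, "-RA")
  lines <- c("##gff-version 3",
             paste(features$contig, "intronevo", "gene", g0, g1, ".",
                   features$strand, ".", paste0("ID=", gid), sep = "\t"),
             paste(features$contig, "intronevo", "mRNA", g0, g1, ".",
                   features$strand, ".", paste0("ID=", mid, ";Parent=", gid),
                   sep = "\t"))
  o <- order(cds$start)  # GFF3 rows ascending; phase stays with its exon
  for (i in o) {
    lines <- c(lines, paste(features$contig, "intronevo", "CDS",
                            cds$start[i], cds$end[i], ".", features$strand,
                            cds$phase[i],
                            paste0("ID=", mid, ":cds;Parent=", mid),
                            sep = "\t"))
  }
  writeLines(lines, path)
}

#' Serialise a true history (and optional site map) to JSON
#'
#' @param history a `true_history`.
#' @param path output path.
#' @param site_map optional site -> alignment column map from
#'   [emit_gene_models()].
#' @return `path`, invisibly.
#' @export
write_history_json <- function(history, path, site_map = NULL) {
  obj <- list(
    n_tips = length(history$tree$tip.label),
    newick = ape::write.tree(history$tree),
    params = unclass(history$params),
    sites = history$sites,
    events = history$events,
    tip_matrix = as.data.frame(history$tip_matrix))
  if (!is.null(site_map)) obj$site_map <- site_map
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
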