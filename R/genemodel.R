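#' Construct a gene model
#'
#' A gene model is one species' representative isoform of an ortholog: the
#' ordered coding-exon intervals (in transcription order), their GFF3
#' phases, and the translated protein. The constructor checks the structural
#' invariants: non-overlapping exons, total CDS length divisible by 3 (after
#' trimming a trailing stop codon if the annotation includes it), phases
#' consistent with cumulative upstream coding length
#' (`phase_i = (3 - cum_nt_i mod 3) mod 3`), and protein length times three
#' equal to the coding length.
#'
#' @param species species identifier.
#' @param gene_id gene identifier.
#' @param transcript_id selected isoform identifier.
#' @param contig contig/scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame with columns `start`, `end` (1-based inclusive
#'   genomic coordinates), rows in transcription order.
#' @param phases integer vector of per-exon GFF3 phases (same order).
#' @param protein translated amino-acid string (no trailing stop).
#' @param stop_included whether the CDS intervals include the stop codon.
#' @return a `gene_model` object.
#' @export
gene_model <- function(species, gene_id, transcript_id = gene_id, contig = gene_id,
                       strand = "+", exons, phases, protein,
                       stop_included = TRUE) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(exons),
            all(c("start", "end") %in% names(exons)))
  exons <- exons[, c("start", "end")]
  if (any(exons$end < exons$start)) stop("exon with end < start")
  ord <- order(exons$start)
  sorted <- exons[ord, , drop = FALSE]
  if (nrow(sorted) > 1L &&
      any(sorted$start[-1L] <= sorted$end[-nrow(sorted)]))
    stop("overlapping CDS exons in gene ", gene_id)
  widths <- exons$end - exons$start + 1L
  total <- sum(widths)
  coding <- total - if (stop_included) 3L else 0L
  if (coding %% 3L != 0L)
    stop("gene ", gene_id, ": coding length ", coding, " not divisible by 3")
  expected_phase <- (3L - (cumsum(c(0L, widths[-length(widths)])) %% 3L)) %% 3L
  phases <- as.integer(phases)
  if (length(phases) != length(widths) || any(phases != expected_phase))
    stop("gene ", gene_id, ": phases inconsistent with cumulative coding length")
  protein <- as.character(protein)
  if (nchar(protein) * 3L != coding)
    stop("gene ", gene_id, ": protein length ", nchar(protein),
         " inconsistent with coding length ", coding)
  structure(list(species = species, gene_id = gene_id,
                 transcript_id = transcript_id, contig = contig,
                 strand = strand, exons = exons, phases = phases,
                 widths = widths, cds_nt = total, coding_nt = coding,
                 protein = protein, stop_included = stop_included),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model", x$gene_id, "(", x$species, ",", x$strand, "strand):",
      nrow(x$exons), "CDS exon(s),", nchar(x$protein), "aa\n")
  invisible(x)
}

#' Parse gene models from GFF3 and genome FASTA
#'
#' Reads CDS features grouped under mRNA/gene, applies the one-isoform-per-
#' gene policy, re-orders minus-strand CDS into transcription order,
#' translates the spliced CDS from the genome, and validates the phase and
#' length invariants. Genes failing validation are excluded and recorded in
#' the validation report (attribute `"report"`, also returned by
#' [validation_report()]); a missing contig is fatal.
#'
#' @param gff3_path path to a GFF3 file with gene/mRNA/CDS features.
#' @param fasta_path path to the genome FASTA containing the referenced
#'   contigs.
#' @param species species identifier attached to every model.
#' @param isoform_policy `"longest_cds"` (default: keep the isoform with the
#'   longest summed CDS; ties broken by lexicographically smallest
#'   transcript id) or `"first"` (first transcript in file order).
#' @return named list of `gene_model` objects (one per valid gene), with
#'   attribute `report`: data frame (`gene_id`, `status`, `reason`).
#' @export
parse_gene_models <- function(gff3_path, fasta_path, species = "species",
                              isoform_policy = c("longest_cds", "first")) {
  isoform_policy <- match.arg(isoform_policy)
  gff <- rtracklayer::readGFF(gff3_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  first_parent <- function(p) if (length(p)) as.character(p[1L]) else NA_character_
  is_cds <- as.character(gff$type) == "CDS"
  if (!any(is_cds)) stop("no CDS features in ", gff3_path)
  cds <- data.frame(seqid = as.character(gff$seqid)[is_cds],
                    start = gff$start[is_cds], end = gff$end[is_cds],
                    strand = as.character(gff$strand)[is_cds],
                    phase = gff$phase[is_cds],
                    tx = vapply(gff$Parent[is_cds], first_parent, character(1)),
                    stringsAsFactors = FALSE)
  if (anyNA(cds$tx)) stop("CDS feature without Parent in ", gff3_path)
  is_mrna <- as.character(gff$type) %in% c("mRNA", "transcript")
  tx_parent <- stats::setNames(
    vapply(gff$Parent[is_mrna], first_parent, character(1)),
    gff$ID[is_mrna])
  cds_tx <- cds$tx

  report <- data.frame(gene_id = character(0), status = character(0),
                       reason = character(0), stringsAsFactors = FALSE)
  add_report <- function(g, status, reason) {
    report <<- rbind(report, data.frame(gene_id = g, status = status,
                                        reason = reason, stringsAsFactors = FALSE))
  }

  tx_ids <- unique(cds_tx)
  gene_of_tx <- tx_parent[tx_ids]
  gene_of_tx[is.na(gene_of_tx)] <- tx_ids[is.na(gene_of_tx)]  # CDS directly under gene
  models <- list()
  for (g in unique(gene_of_tx)) {
    txs <- tx_ids[gene_of_tx == g]
    cds_len <- vapply(txs, function(tx)
      sum(cds$end[cds_tx == tx] - cds$start[cds_tx == tx] + 1L), numeric(1))
    tx <- if (isoform_policy == "longest_cds") {
      cand <- txs[cds_len == max(cds_len)]
      sort(cand)[1L]
    } else txs[1L]
    feats <- cds[cds_tx == tx, , drop = FALSE]
    contig <- feats$seqid[1L]
    strand <- feats$strand[1L]
    if (!(strand %in% c("+", "-"))) strand <- "+"
    if (!(contig %in% names(genome)))
      stop("contig ", contig, " (gene ", g, ") missing from ", fasta_path)
    o <- order(feats$start)
    if (strand == "-") o <- rev(o)  # transcription order
    feats <- feats[o, , drop = FALSE]
    exons <- data.frame(start = feats$start, end = feats$end)
    phases <- as.integer(feats$phase)
    seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(exons)), function(i)
      Biostrings::subseq(genome[[contig]], exons$start[i], exons$end[i])))
    if (strand == "-") seqs <- Biostrings::reverseComplement(seqs)
    cds_seq <- Biostrings::DNAString(paste(as.character(seqs), collapse = ""))
    model <- tryCatch({
      tr <- .translate_cds(cds_seq, gene_id = g)
      gene_model(species = species, gene_id = g, transcript_id = tx,
                 contig = contig, strand = strand, exons = exons,
                 phases = phases, protein = tr$protein,
                 stop_included = tr$stop_included)
    }, error = function(e) e)
    if (inherits(model, "error")) {
      warning("gene ", g, " invalid: ", conditionMessage(model), call. = FALSE)
      add_report(g, "invalid", conditionMessage(model))
    } else {
      models[[g]] <- model
      add_report(g, "ok", "")
    }
  }
  attr(models, "report") <- report
  models
}

# Translate a spliced CDS, trimming one trailing stop codon if present
# (GFF3 dialects differ on whether the CDS includes the stop).
.translate_cds <- function(cds_seq, gene_id = "?") {
  n <- length(cds_seq)
  if (n %% 3L != 0L)
    stop("CDS length ", n, " not divisible by 3")
  # no.init.codon: translate literally (an alternative initiation codon must
  # not silently become Met, or round trips through emitted models break)
  aa <- as.character(Biostrings::translate(cds_seq, no.init.codon = TRUE))
  stop_included <- endsWith(aa, "*")
  if (stop_included) aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("\\*", aa))
    stop("internal stop codon in CDS of gene ", gene_id)
  list(protein = aa, stop_included = stop_included)
}

#' Validation report of a parsed gene-model set
#'
#' @param models result of [parse_gene_models()].
#' @return data frame with columns `gene_id`, `status`, `reason`.
#' @export
validation_report <- function(models) {
  rep <- attr(models, "report")
  if (is.null(rep))
    rep <- data.frame(gene_id = names(models), status = "ok", reason = "",
                      stringsAsFactors = FALSE)
  rep
}

#' Derive intron positions in protein coordinates
#'
#' For each junction between consecutive coding exons, with `c` coding
#' nucleotides upstream of the intron: phase `p = c mod 3`; anchor residue
#' `r = c/3` when `p = 0` (the residue immediately 5' of the junction),
#' otherwise `floor(c/3) + 1` (the residue whose codon the intron
#' interrupts). Junctions with `c = 0` or `c >=` coding length (introns
#' outside the coding region proper, e.g. within a UTR or interrupting the
#' stop codon) are excluded with a warning.
#'
#' @param gene a `gene_model`.
#' @return data frame with columns `anchor`, `phase`, `coding_offset`, one
#'   row per intron, ordered 5' to 3'.
#' @export
derive_intron_sites <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  w <- gene$widths
  if (length(w) < 2L)
    return(data.frame(anchor = integer(0), phase = integer(0),
                      coding_offset = integer(0)))
  cvals <- cumsum(w[-length(w)])
  keep <- cvals >= 1L & cvals < gene$cds_nt & cvals <= 3L * nchar(gene$protein)
  if (any(!keep))
    warning("gene ", gene$gene_id, ": ", sum(!keep),
            " intron(s) outside the coding region excluded", call. = FALSE)
  cvals <- cvals[keep]
  p <- cvals %% 3L
  r <- ifelse(p == 0L, cvals %/% 3L, cvals %/% 3L + 1L)
  data.frame(anchor = as.integer(r), phase = as.integer(p),
             coding_offset = as.integer(cvals))
}

#' Read a protein multiple sequence alignment
#'
#' Reads an aligned FASTA, checks equal row widths, and (optionally) checks
#' that each row with gaps removed equals the corresponding species'
#' translated protein.
#'
#' @param fasta_path aligned FASTA path (rows named by species).
#' @param proteins optional named character vector of ungapped proteins to
#'   verify against.
#' @return named character vector of aligned rows.
#' @export
read_alignment <- function(fasta_path, proteins = NULL) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  msa <- stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  if (length(unique(nchar(msa))) > 1L)
    stop("alignment rows in ", fasta_path, " have unequal widths")
  if (!is.null(proteins)) {
    for (sp in intersect(names(msa), names(proteins))) {
      ungapped <- gsub("[-.]", "", msa[[sp]])
      if (!identical(ungapped, unname(proteins[[sp]])))
        stop("alignment row for species ", sp,
             " does not match its protein after removing gaps")
    }
  }
  msa
}
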