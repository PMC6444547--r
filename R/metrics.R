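#' Per-exon size table with terminal-exon filtering
#'
#' One record per coding exon of every gene model, with exon size expressed
#' in amino acids (`nt / 3`, fractional values retained since internal exon
#' boundaries need not respect codon boundaries). First and last coding
#' exons smaller than `min_terminal_aa` are dropped — such tiny terminal
#' exons in automated annotations are often UTR fragments or placeholder
#' N-terminal exons rather than real coding exons — while internal exons are
#' never dropped. A single-exon gene's only exon counts as terminal.
#'
#' @param models list of `gene_model` objects (one isoform per gene already
#'   enforced upstream), or a single `gene_model`.
#' @param min_terminal_aa terminal exons smaller than this (in aa) are
#'   excluded (default 10).
#' @return data frame with columns `species`, `gene_id`, `exon_index`,
#'   `exon_aa`, `terminal_flag` (`first`/`last`/`internal`).
#' @export
exon_table <- function(models, min_terminal_aa = 10) {
  if (inherits(models, "gene_model")) models <- list(models)
  recs <- lapply(models, function(m) {
    n <- length(m$widths)
    flag <- rep("internal", n)
    flag[1L] <- "first"
    if (n > 1L) flag[n] <- "last"
    data.frame(species = m$species, gene_id = m$gene_id,
               exon_index = seq_len(n), exon_aa = m$widths / 3,
               terminal_flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(recs, list(data.frame(
    species = character(0), gene_id = character(0), exon_index = integer(0),
    exon_aa = numeric(0), terminal_flag = character(0),
    stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  keep <- out$terminal_flag == "internal" | out$exon_aa >= min_terminal_aa
  out[keep, , drop = FALSE]
}

#' Per-species gene-structure summary
#'
#' Median protein size (aa) and median exon count per gene, plus median,
#' MAD (median of absolute deviations from the median, unscaled) and
#' quartiles (linear interpolation) of exon size over the filtered exon
#' records. Species with fewer than 3 genes are flagged `low_n`.
#'
#' @param records exon records from [exon_table()].
#' @param models the gene models the records came from (protein sizes and
#'   exon counts are computed over genes, unfiltered).
#' @return data frame, one row per species: `species`, `n_genes`, `n_exons`,
#'   `median_protein_aa`, `median_exon_count`, `median_exon_aa`,
#'   `mad_exon_aa`, `q1_exon_aa`, `q3_exon_aa`, `low_n`.
#' @export
species_summary <- function(records, models) {
  if (inherits(models, "gene_model")) models <- list(models)
  gene_tab <- do.call(rbind, lapply(models, function(m)
    data.frame(species = m$species, gene_id = m$gene_id,
               protein_aa = nchar(m$protein), n_exons = length(m$widths),
               stringsAsFactors = FALSE)))
  species <- unique(gene_tab$species)
  rows <- lapply(species, function(sp) {
    g <- gene_tab[gene_tab$species == sp, , drop = FALSE]
    r <- records[records$species == sp, , drop = FALSE]
    x <- r$exon_aa
    med <- if (length(x)) stats::median(x) else NA_real_
    data.frame(
      species = sp,
      n_genes = nrow(g),
      n_exons = nrow(r),
      median_protein_aa = stats::median(g$protein_aa),
      median_exon_count = stats::median(g$n_exons),
      median_exon_aa = med,
      mad_exon_aa = if (length(x)) stats::median(abs(x - med)) else NA_real_,
      q1_exon_aa = if (length(x)) unname(stats::quantile(x, 0.25, type = 7)) else NA_real_,
      q3_exon_aa = if (length(x)) unname(stats::quantile(x, 0.75, type = 7)) else NA_real_,
      low_n = nrow(g) < 3L,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified 1:1:1 sampling of ortholog genes by protein size
#'
#' Splits the reference size distribution (the complete dataset's ortholog
#' sizes, e.g. one reference species' proteins) into three equal-count
#' strata — small, medium, big — by sorted rank, assigns candidate genes to
#' strata by their own size against the stratum boundaries, and samples up
#' to `per_stratum` genes per stratum without replacement (all are taken if
#' fewer are available). Reproducible for a fixed seed.
#'
#' @param reference_sizes numeric vector of ortholog sizes defining the
#'   strata (>= 3 values).
#' @param candidate_genes data frame with columns `gene_id` and `size`.
#' @param per_stratum genes sampled per stratum (default 10).
#' @param seed integer seed.
#' @return the sampled subset of `candidate_genes`, with an added `stratum`
#'   column (`small`/`medium`/`big`), ordered by stratum then size.
#' @export
stratified_sample <- function(reference_sizes, candidate_genes,
                              per_stratum = 10L, seed = 1L) {
  stopifnot(is.numeric(reference_sizes))
  if (length(reference_sizes) < 3L)
    stop("need at least 3 reference genes to define size strata")
  stopifnot(is.data.frame(candidate_genes),
            all(c("gene_id", "size") %in% names(candidate_genes)))
  ref <- sort(reference_sizes)
  n <- length(ref)
  b1 <- ref[ceiling(n / 3)]
  b2 <- ref[ceiling(2 * n / 3)]
  stratum <- ifelse(candidate_genes$size <= b1, "small",
                    ifelse(candidate_genes$size <= b2, "medium", "big"))
  candidate_genes$stratum <- stratum
  .with_seed(seed, {
    picked <- lapply(c("small", "medium", "big"), function(s) {
      pool <- candidate_genes[candidate_genes$stratum == s, , drop = FALSE]
      if (nrow(pool) <= per_stratum) return(pool)
      pool[sort(sample.int(nrow(pool), per_stratum)), , drop = FALSE]
    })
    out <- do.call(rbind, picked)
    out <- out[order(match(out$stratum, c("small", "medium", "big")), out$size), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
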