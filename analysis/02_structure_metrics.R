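#!/usr/bin/env Rscript
# Step 2 — comparative gene-structure metrics.
#
# Parses every emitted gene model of the insect8 study, builds the exon
# table (terminal exons < 10 aa excluded), and writes per-species medians of
# protein size, exon count and exon size with MAD and quartiles. Also
# demonstrates the 1:1:1 stratified ortholog sampling against a reference
# size distribution. Requires 01_simulate.R to have run.

suppressPackageStartupMessages(library(intronevo))

study <- "results/studies/insect8"
out <- "results/metrics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
tree <- read_species_tree(file.path(study, "tree.nwk"))

fams <- list.dirs(file.path(study, "families"), recursive = FALSE)
models <- list()
for (fd in fams) {
  fr <- read_family(fd, tree)
  models <- c(models, setNames(fr$models,
                               paste0(basename(fd), ".", names(fr$models))))
}
message("Parsed ", length(models), " gene models from ", length(fams),
        " families x ", length(tree$tip.label), " species")

records <- exon_table(models, min_terminal_aa = 10)
summary_tab <- species_summary(records, models)
write.table(records, file.path(out, "exon_records.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(summary_tab, file.path(out, "species_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Per-species summary (exon size in aa):")
print(summary_tab[, c("species", "n_genes", "median_protein_aa",
                      "median_exon_count", "median_exon_aa", "mad_exon_aa")],
      row.names = FALSE)

# stratified 1:1:1 sampling: reference sizes from the first species' genes
ref_sp <- tree$tip.label[1L]
sizes <- vapply(models, function(m) nchar(m$protein), numeric(1))
ref <- sizes[grepl(paste0("\\.", ref_sp, "$"), names(sizes))]
cand <- data.frame(gene_id = names(sizes), size = unname(sizes))
picked <- stratified_sample(ref, cand, per_stratum = 10, seed = 1)
write.table(picked, file.path(out, "stratified_sample.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Stratified sample: ", nrow(picked), " genes (",
        paste(capture.output(print(table(picked$stratum)))[2], collapse = ""),
        ")")
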