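test_that("cumulative coding length and phases follow the plus-strand example", {
  d <- withr::local_tempdir()
  # CDS intervals 101-130 and 191-250: 30 then 60 nt, phases 0 then 0
  p <- write_toy_gff(d, list(list(tx = "t1", start = 101, end = 130, phase = 0),
                             list(tx = "t1", start = 191, end = 250, phase = 0)))
  models <- parse_gene_models(p$gff, p$fa, species = "toy")
  expect_length(models, 1L)
  m <- models[[1L]]
  expect_identical(m$widths, c(30L, 60L))
  expect_identical(cumsum(m$widths), c(30L, 90L))
  expect_identical(nchar(m$protein), 30L)  # no stop codon in this CDS
})

test_that("longest-CDS isoform wins, ties break lexicographically", {
  d <- withr::local_tempdir()
  p <- write_toy_gff(d, list(
    list(tx = "t1", start = 1, end = 300, phase = 0),
    list(tx = "t2", start = 1, end = 270, phase = 0)))
  models <- parse_gene_models(p$gff, p$fa, species = "toy")
  expect_identical(models[[1L]]$transcript_id, "t1")
  expect_identical(models[[1L]]$coding_nt, 300L)

  p2 <- write_toy_gff(d, list(
    list(tx = "tB", start = 1, end = 270, phase = 0),
    list(tx = "tA", start = 31, end = 300, phase = 0)))
  models2 <- parse_gene_models(p2$gff, p2$fa, species = "toy")
  expect_identical(models2[[1L]]$transcript_id, "tA")
})

test_that("phase inconsistency flags the gene invalid; missing contig is fatal", {
  d <- withr::local_tempdir()
  p <- write_toy_gff(d, list(list(tx = "t1", start = 101, end = 130, phase = 0),
                             list(tx = "t1", start = 191, end = 250, phase = 1)))
  expect_warning(models <- parse_gene_models(p$gff, p$fa, species = "toy"),
                 "invalid")
  expect_length(models, 0L)
  rep <- validation_report(models)
  expect_identical(rep$status, "invalid")
  expect_match(rep$reason, "phase")

  gff2 <- file.path(d, "bad.gff3")
  writeLines(c("##gff-version 3",
               paste("nope", "t", "mRNA", 1, 30, ".", "+", ".",
                     "ID=t9;Parent=g9", sep = "\t"),
               paste("nope", "t", "CDS", 1, 30, ".", "+", 0,
                     "ID=t9:c;Parent=t9", sep = "\t")), gff2)
  expect_error(parse_gene_models(gff2, p$fa), "missing")
})

test_that("minus-strand CDS are re-ordered into transcription order", {
  # emitted fixtures alternate strands: second species is minus-strand
  tree <- validate_species_tree(ape::read.tree(text = "(A:1,B:1);"))
  h <- plant_history(tree,
                     simulation_params(n_ancestral_sites = 0L, gain_rate = 0,
                                       loss_rate = 0, protein_length = 50L,
                                       seed = 4),
                     root_slots = c(30L, 60L), events = NULL)
  d <- withr::local_tempdir()
  em <- emit_gene_models(h, d, family_id = "f")
  mB <- parse_gene_models(file.path(d, "B.gff3"), file.path(d, "B.genome.fa"),
                          species = "B")[[1L]]
  expect_identical(mB$strand, "-")
  expect_identical(nrow(mB$exons), 3L)
  # transcription order on the minus strand runs right to left
  expect_true(all(diff(mB$exons$start) < 0))
  expect_identical(derive_intron_sites(mB)[, c("anchor", "phase")],
                   em$species_sites$B[, c("anchor", "phase")])
  # and the same sites come out of the plus-strand copy
  mA <- parse_gene_models(file.path(d, "A.gff3"), file.path(d, "A.genome.fa"),
                          species = "A")[[1L]]
  expect_identical(derive_intron_sites(mA)[, c("anchor", "phase")],
                   derive_intron_sites(mB)[, c("anchor", "phase")])
})

test_that("intron sites follow the coding-offset arithmetic", {
  # c = 30 -> (10, 0); c = 31 -> (11, 1); c = 32 -> (11, 2)
  for (case in list(list(w = c(30L, 60L), site = c(10L, 0L)),
                    list(w = c(31L, 59L), site = c(11L, 1L)),
                    list(w = c(32L, 58L), site = c(11L, 2L)))) {
    g <- toy_gene_model(case$w)
    s <- derive_intron_sites(g)
    expect_identical(c(s$anchor, s$phase), case$site)
  }
})

test_that("a 47-exon gene yields 46 intron sites", {
  g <- toy_gene_model(rep(30L, 47L))
  expect_identical(nrow(derive_intron_sites(g)), 46L)
})

test_that("phase-0 sites are exactly those with coding offset divisible by 3", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    w <- sample(3:90, n, replace = TRUE)
    w[n] <- w[n] + (3L - sum(w) %% 3L) %% 3L  # pad to frame
    g <- toy_gene_model(w)
    s <- derive_intron_sites(g)
    expect_identical(s$phase == 0L, s$coding_offset %% 3L == 0L)
    expect_identical(s$coding_offset, cumsum(w[-n]))
    # anchors within protein, strictly increasing offsets, no duplicates
    expect_true(all(s$anchor >= 1 & s$anchor <= nchar(g$protein)))
    expect_true(all(diff(s$coding_offset) > 0))
    expect_false(anyDuplicated(paste(s$anchor, s$phase)) > 0)
  }
})

test_that("a zero-site gene is a single CDS translating to the full protein", {
  tree <- validate_species_tree(ape::read.tree(text = "(A:1,B:1);"))
  h <- plant_history(tree,
                     simulation_params(n_ancestral_sites = 0L, gain_rate = 0,
                                       loss_rate = 0, protein_length = 80L,
                                       seed = 9),
                     root_slots = integer(0), events = NULL)
  d <- withr::local_tempdir()
  emit_gene_models(h, d, family_id = "f")
  m <- parse_gene_models(file.path(d, "A.gff3"), file.path(d, "A.genome.fa"),
                         species = "A")[[1L]]
  expect_identical(nrow(m$exons), 1L)
  expect_identical(nchar(m$protein), 80L)
  expect_identical(nrow(derive_intron_sites(m)), 0L)
})

test_that("a site at (10, 0) puts 30 coding nt upstream of the first intron", {
  tree <- validate_species_tree(ape::read.tree(text = "(A:1,B:1);"))
  h <- plant_history(tree,
                     simulation_params(n_ancestral_sites = 0L, gain_rate = 0,
                                       loss_rate = 0, protein_length = 100L,
                                       seed = 3),
                     root_slots = 3L * 9L + 0L + 1L,  # slot of (10, 0)
                     events = NULL)
  d <- withr::local_tempdir()
  emit_gene_models(h, d, family_id = "f")
  m <- parse_gene_models(file.path(d, "A.gff3"), file.path(d, "A.genome.fa"),
                         species = "A")[[1L]]
  expect_identical(nrow(m$exons), 2L)
  expect_identical(m$widths[1L], 30L)
})

test_that("alignment reading validates widths and protein consistency", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "msa.fa")
  writeLines(c(">A", "AC-DE", ">B", "ACFDE"), fa)
  msa <- read_alignment(fa)
  expect_identical(unname(msa["A"]), "AC-DE")
  expect_silent(read_alignment(fa, proteins = c(A = "ACDE", B = "ACFDE")))
  expect_error(read_alignment(fa, proteins = c(A = "ACDX", B = "ACFDE")), "A")

  writeLines(c(">A", "AC-DE", ">B", "ACFD"), fa)
  expect_error(read_alignment(fa), "widths")
})
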