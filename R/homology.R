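#' Map an intron site from protein to alignment coordinates
#'
#' Returns the alignment column occupied by the anchor residue of an intron
#' site in one species' aligned row. The anchor always exists in its own row
#' (its coordinates were derived from that protein), so the map is total.
#'
#' @param site list or data frame row with `anchor` (1-based residue index)
#'   and `phase` (0/1/2).
#' @param aligned_row single aligned sequence (character scalar, gaps `-`).
#' @return 1-based alignment column (integer).
#' @export
map_site_to_column <- function(site, aligned_row) {
  anchor <- as.integer(site$anchor)
  chars <- strsplit(as.character(aligned_row), "")[[1L]]
  res_cols <- which(chars != "-" & chars != ".")
  if (anchor < 1L || anchor > length(res_cols))
    stop("anchor ", anchor, " beyond ungapped length ", length(res_cols),
         " of aligned row")
  res_cols[anchor]
}

#' Build homologous splice-site characters for one ortholog family
#'
#' Projects each species' intron sites onto the family protein alignment and
#' merges them into discrete splice-site characters identified by
#' (alignment column, phase) — phase is part of site identity, so an intron
#' interrupting the same column after 1 versus 2 nucleotides gives two
#' distinct characters. Each species is scored `present` (it has an intron
#' at that column and phase), `unknown` (its row is gapped at that column,
#' i.e. the region is not alignable, or the species has no data), or
#' `absent` otherwise.
#'
#' @param sites_by_species named list (one entry per species) of data frames
#'   with columns `anchor`, `phase` (as from [derive_intron_sites()]);
#'   species in `tree` but absent from the list or from the alignment get an
#'   all-`unknown` row (reported in the `missing_species` field).
#' @param msa named character vector or [Biostrings::AAStringSet] of aligned
#'   rows (equal width), names = species.
#' @param tree rooted `phylo`; its tips define the species set.
#' @param family_id identifier stored in the result.
#' @param gap_policy state assigned when a species' row is gapped at a site's
#'   column: `"unknown"` (default; missing data, costless in parsimony) or
#'   `"absent"`.
#' @return a `site_matrix`: list with `family_id`, `sites` (data frame
#'   `site`, `column`, `phase`), `states` (species x site character matrix),
#'   `provenance` (per present state, the originating residue index), and
#'   `missing_species`.
#' @export
build_site_matrix <- function(sites_by_species, msa, tree,
                              family_id = "family",
                              gap_policy = c("unknown", "absent")) {
  gap_policy <- match.arg(gap_policy)
  tree <- validate_species_tree(tree)
  species <- tree$tip.label
  if (inherits(msa, "XStringSet")) msa <- as.character(msa)
  msa <- vapply(msa, as.character, character(1))
  if (length(unique(nchar(msa))) > 1L)
    stop("alignment rows have unequal widths")
  width <- nchar(msa[1L])
  msa_chars <- lapply(msa, function(s) strsplit(s, "")[[1L]])

  missing_species <- species[!(species %in% names(msa))]
  observed <- list()  # per species: data.frame(column, phase, anchor)
  for (sp in setdiff(species, missing_species)) {
    df <- sites_by_species[[sp]]
    if (is.null(df) || nrow(df) == 0L) {
      observed[[sp]] <- data.frame(column = integer(0), phase = integer(0),
                                   anchor = integer(0))
      next
    }
    cols <- vapply(seq_len(nrow(df)), function(i)
      map_site_to_column(df[i, , drop = FALSE], msa[[sp]]), integer(1))
    key <- paste(cols, df$phase)
    if (anyDuplicated(key))
      stop("species ", sp, ": two introns map to the same (column, phase); ",
           "gene-model invariant violated")
    observed[[sp]] <- data.frame(column = cols, phase = as.integer(df$phase),
                                 anchor = as.integer(df$anchor))
  }

  all_sites <- unique(do.call(rbind, c(list(data.frame(column = integer(0),
                                                       phase = integer(0))),
                                       lapply(observed, function(o)
                                         o[, c("column", "phase")]))))
  all_sites <- all_sites[order(all_sites$column, all_sites$phase), , drop = FALSE]
  rownames(all_sites) <- NULL
  site_ids <- if (nrow(all_sites)) paste0("c", all_sites$column, "p", all_sites$phase) else character(0)

  states <- matrix("absent", length(species), nrow(all_sites),
                   dimnames = list(species, site_ids))
  prov <- matrix(NA_integer_, length(species), nrow(all_sites),
                 dimnames = list(species, site_ids))
  for (sp in species) {
    if (sp %in% missing_species) {
      states[sp, ] <- "unknown"
      next
    }
    obs <- observed[[sp]]
    for (k in seq_len(nrow(all_sites))) {
      col <- all_sites$column[k]
      hit <- which(obs$column == col & obs$phase == all_sites$phase[k])
      if (length(hit)) {
        if (msa_chars[[sp]][col] %in% c("-", "."))
          stop("species ", sp, " marked present at gapped column ", col)
        states[sp, k] <- "present"
        prov[sp, k] <- obs$anchor[hit]
      } else if (msa_chars[[sp]][col] %in% c("-", ".")) {
        states[sp, k] <- gap_policy
      }
    }
  }
  structure(list(family_id = family_id,
                 sites = cbind(data.frame(site = site_ids,
                                          stringsAsFactors = FALSE), all_sites),
                 states = states,
                 provenance = prov,
                 alignment_width = width,
                 gap_policy = gap_policy,
                 missing_species = missing_species),
            class = "site_matrix")
}

#' @export
print.site_matrix <- function(x, ...) {
  cat("Site matrix for family", x$family_id, "—", ncol(x$states),
      "splice-site characters x", nrow(x$states), "species\n")
  if (length(x$missing_species))
    cat("  species with no data:", paste(x$missing_species, collapse = ", "), "\n")
  invisible(x)
}

#' Write the per-family character table
#'
#' @param matrix a `site_matrix`.
#' @param path TSV output path.
#' @return the table written, invisibly.
#' @export
write_site_table <- function(matrix, path) {
  tab <- cbind(data.frame(family = matrix$family_id, stringsAsFactors = FALSE),
               matrix$sites,
               as.data.frame(t(matrix$states), stringsAsFactors = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Render an alignment with splice-site markers
#'
#' Text rendering of the family alignment with a `|` inserted after the
#' anchor column of each splice site a species carries (the display
#' convention for showing splice sites inside a curated protein alignment).
#' Phase is appended as a digit marker line below each block.
#'
#' @param matrix a `site_matrix`.
#' @param msa the family alignment used to build it.
#' @param path optional file to write to.
#' @param block width of alignment blocks (columns per line).
#' @return character vector of rendered lines, invisibly.
#' @export
render_annotated_alignment <- function(matrix, msa, path = NULL, block = 60L) {
  if (inherits(msa, "XStringSet")) msa <- as.character(msa)
  species <- rownames(matrix$states)
  lines <- character(0)
  width <- matrix$alignment_width
  starts <- seq(1L, max(width, 1L), by = block)
  pad <- max(nchar(species))
  for (s in starts) {
    e <- min(s + block - 1L, width)
    for (sp in species) {
      if (!(sp %in% names(msa))) next
      chars <- strsplit(substr(msa[[sp]], s, e), "")[[1L]]
      here <- matrix$sites$column >= s & matrix$sites$column <= e &
        matrix$states[sp, ] == "present"
      out <- character(0)
      for (i in seq_along(chars)) {
        out <- c(out, chars[i])
        col <- s + i - 1L
        k <- which(matrix$sites$column == col & here)
        if (length(k)) out <- c(out, paste0("|", matrix$sites$phase[k[1L]]))
      }
      lines <- c(lines, paste0(formatC(sp, width = pad, flag = "-"), "  ",
                               paste(out, collapse = "")))
    }
    lines <- c(lines, "")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Per-species intron counts from site matrices
#'
#' Counts `present` states per species, summed over families; the intron
#' number used for the genome-size correlation.
#'
#' @param matrices list of `site_matrix` objects.
#' @return named integer vector, one entry per species.
#' @export
species_intron_counts <- function(matrices) {
  if (inherits(matrices, "site_matrix")) matrices <- list(matrices)
  species <- rownames(matrices[[1L]]$states)
  counts <- stats::setNames(integer(length(species)), species)
  for (m in matrices) {
    pres <- rowSums(m$states == "present")
    counts[names(pres)] <- counts[names(pres)] + pres
  }
  counts
}
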