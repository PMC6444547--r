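---
title: "Methods: splice-site homology and intron gain/loss parsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splice-site homology and intron gain/loss parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronevo)
```

## The problem

Orthologous proteins in different insect lineages are often near-identical
in length yet dramatically different in gene structure: hemipteroid genomes
tend to carry many small coding exons where flies and beetles carry few
large ones. To ask *when* those introns arrived or disappeared, one needs
three things: intron positions expressed in protein coordinates (so they
can be compared across species), a homology relation between splice sites
of different orthologs, and a reconstruction of gains and losses on a
species tree. This vignette documents the models, conventions and numerical
choices behind each stage, and what the test suite does and does not
establish.

## Intron positions in protein coordinates

For a junction between consecutive coding exons, let `c` be the number of
coding nucleotides 5′ of the intron. The phase is `p = c mod 3` (0 between
codons, 1 or 2 inside a codon) and the anchor residue is

* `r = c / 3` for `p = 0` — the residue immediately 5′ of the junction;
* `r = ⌊c/3⌋ + 1` for `p > 0` — the residue whose codon the intron
  interrupts.

The anchor convention for phase-0 sites is genuinely open (the residue
before or after the junction would both be defensible); we fix the 5′
residue globally and apply it identically in simulation and inference, so
every downstream comparison is convention-invariant. Junctions with `c = 0`
or `c` at/after the end of the coding region (UTR introns, introns inside
the stop codon) are excluded — they have no protein-coordinate identity.

GFF3 handling: phases must satisfy `phase_i = (3 − cum_nt_i mod 3) mod 3`;
violations flag the gene invalid (excluded, counted in the validation
report) rather than being repaired. A trailing stop codon is trimmed before
the divisible-by-three check because annotation dialects differ on whether
the CDS includes it. Where a gene has several isoforms we keep the one with
the longest summed CDS, ties broken by smallest transcript id — the
"one isoform per gene" rule needs *some* deterministic refinement and
longest-CDS retains the most splice junctions; the policy is configurable
and recorded in every report.

## Splice-site homology

A site maps to the alignment column occupied by its anchor residue in its
own species' row; the distinct `(column, phase)` pairs observed in at least
one species become the family's characters. Phase is part of site identity:
an intron after nucleotide 1 of a codon is *not* the same character as one
after nucleotide 2 in the same column.

Two policies deserve emphasis:

* **Gap policy.** If a species' row is gapped at a character's column, the
  region is not alignable for that species and the state is `unknown`
  (missing data — costless for either state in the parsimony step). The
  alternative, scoring it `absent`, is available by flag but conflates
  "no intron" with "no homologous position". Species missing from a family
  entirely get an all-`unknown` row.
* **No tolerance window.** Characters are homologous only at *identical*
  `(column, phase)`. Splice sites that drift by a column in imperfect
  alignments will appear as two characters; we deliberately do not merge
  near-misses, because a ±k-column window invents homology that the
  alignment does not support. Curated alignments are the user's
  responsibility (alignment computation is out of scope); on real data an
  exact-match tally may therefore differ slightly from a manually merged
  one.

## Parsimony with all optima

Each character is a binary presence/absence trait at the tips of a rooted
tree (polytomies handled natively). A Sankoff dynamic programme with costs
`gain_cost`/`loss_cost` (default 1/1 — agnostic between directions; a
Dollo-like regime is available via a large gain cost but is not used for
headline outputs) gives the minimal total cost, minimising over both root
states. `unknown` tips contribute zero cost to either state.

Ties are first-class: rather than choosing one optimal labelling, the
package reports, per branch, the `[min, max]` number of gains and losses
over *all* most-parsimonious scenarios, and likewise a range for the number
of sites present at the root. These ranges are computed exactly from
per-edge optimal-state membership (an outside/inside decomposition of the
DP), so they are correct even when the number of optimal labellings exceeds
the enumeration cap (default 10,000; the exact count is still reported by a
counting DP, and truncation is flagged). The capped enumeration itself is
used only where the full scenario list is needed:

* **Parallel events.** A site is reported as a parallel (homoplastic)
  change when *every* optimal scenario contains at least two changes of the
  same direction on branches neither of which is ancestral to the other.
  Requiring the same direction matches the intended reading — the same
  site lost (or gained) independently on two lineages; a gain on one branch
  plus a loss elsewhere is a different phenomenon. Requiring it in every
  scenario keeps the call agnostic: ambiguous sites are not counted.
* **Retention.** A site counts as "retained in all species" when the root
  state is present in every optimal scenario *and* every tip with known
  state carries it; `unknown` tips do not veto retention but the number of
  such sites is reported separately.

Scores are exact integers under unit costs; all floating-point comparisons
in the DP use an absolute tolerance of 1e-7 against costs of order 1, and
fixed-state tips are encoded with a large finite cost (1e9) rather than
infinity to keep the outside pass free of `Inf − Inf`.

The genome-size relation uses Spearman rank correlation with average ranks
for ties. For n ≤ 10 species the two-sided p-value is an exact permutation
p over all n! pairings (enumerated in chunks); beyond that the usual t
approximation applies. With the eight species typical here, the smallest
achievable two-sided p is 2/8! ≈ 5·10⁻⁵.

## Exon and protein-size metrics

Exon sizes are `nt/3` with fractional values retained — internal exon
boundaries need not respect codon boundaries, and rounding would bias
small-exon species. First and last coding exons shorter than 10 aa are
excluded (tiny terminal "exons" in automated annotations are usually UTR
fragments or placeholder N-terminal stubs); internal exons are never
excluded. Summaries are medians, the unscaled MAD (median absolute
deviation from the median), and type-7 (linear interpolation) quartiles.
Box-plot whisker conventions vary between publications and are cosmetic
here; the tested surface is the numeric summary table. The stratified
ortholog sampler splits a reference size distribution into terciles by
sorted rank — not fixed aa thresholds — and samples up to 10 genes per
stratum without replacement, seeded.

## The simulator: what it emulates, and what it does not

The generative model is deliberately the simplest process for which
parsimony is a meaningful estimator: sites at the root (uniform over
`(residue, phase)` slots), then independently per branch, Poisson gains
(`gain_rate × branch length`, fresh unoccupied slots, phase uniform — no
phase bias is asserted) and Poisson losses
(`loss_rate × sites present × branch length`, uniform over present sites;
`loss_rate = Inf` gives the absorbing limit). Defaults in the example
studies — three families of contrasting size (protein lengths 800/600/300,
ancestral site counts 40/20/5, gains 1.2/0.8/0.3 per branch, losses 0.02
per site per branch) — were chosen once to produce families resembling a
large many-intron gene, a mid-sized gene, and a small intron-poor gene on
an eight-species tree.

Emission realises a history as files: one random codon per residue (fixed
by seed, shared across species so that the no-indel alignment is exact),
fixed-length 60-nt introns with canonical `GT…AG` boundaries, a trailing
`TAA` stop, alternating +/− strand across species, and a GFF3 whose CDS
features place each intron after exactly the coding-nucleotide count its
`(residue, phase)` implies. Optional whole-codon indels (half deletions,
half insertions per the indel rate; deletions never remove a residue that
anchors an intron of that species) produce divergent orthologs whose
emitted alignment still encodes the true homology, so gap handling can be
tested against truth.

What the simulator does **not** emulate: substitution processes, rate
heterogeneity across sites or lineages, alignment error (the emitted MSA is
the true homology), genome-size evolution (the synthetic genome sizes in
the example studies are generated as an affine function of each species'
true intron count plus Gaussian noise, to exercise the correlation
machinery — they are labelled synthetic and carry no biological content),
intron-length variation, or annotation error beyond what the validation
path is tested with. Passing round-trip and recovery tests therefore shows
the *machinery* is correct, not that real curated data would be recovered
at the same rates: real alignments drift, real annotations split genes
across scaffolds, and real site identity sometimes needs manual merging of
neighbouring columns.

## Test design and problem sizes

The suite verifies the parsimony engine against an exhaustive oracle
(every ancestral labelling) on all 105 rooted binary topologies with five
tips crossed with all 32 tip patterns, plus 200 random 6–8-tip cases with
unknowns; file round trips (emit → parse → derive → map → exact tip-matrix
match) on 100 simulated eight-species histories under mixed rates; exact
recovery of totals on 200 homoplasy-free families and the lower-bound
inequality on 200 high-rate families; tie and parallel fixtures checked
character-by-character against brute force; and a planted eight-species
study containing exactly 148 variable characters and 165 events, pushed
through the complete pipeline. These sizes keep the full suite in the
low minutes on a single core while leaving each property with a
comfortable margin of cases. Event "recovery" in the low-rate study is
defined as the true branch and direction lying within the inferred
per-branch range — under ties (for instance an event on one of the two
branches below the root, where direction and placement trade off) no
method could pin the event to a single branch, and the agnostic range is
exactly the honest answer.

## Repository shape

The deliverable is organised as an analysis workflow — numbered scripts
under `analysis/` that narrate simulate → metrics → infer → rehearse and
write tables under `results/` — over a conventional R package in `R/`
where every computation lives and is unit-tested. `run_pipeline()` plus
those scripts are the orchestration surface; there is no separate shell
CLI, as the intended users drive the analysis from R.

## Known limitations

* Exact `(column, phase)` identity makes the site tally sensitive to
  alignment quality; no fuzzy merging is offered by design.
* Parsimony underestimates change counts when the same site changes
  repeatedly; branch-length-aware probabilistic models are out of scope.
* UTR introns have no protein-coordinate identity and are excluded.
* The exact permutation p-value enumerates up to 10! pairings; larger
  studies fall back to the t approximation.
* Gene models split across scaffolds or requiring frame repair must be
  resolved upstream; the parser validates, it does not cure.
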