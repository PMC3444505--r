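---
title: "Marker-gene ANI screening and bacterial species delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-gene ANI screening and bacterial species delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aniscreen)
library(dplyr)
```

## The problem

Whole-genome average nucleotide identity (ANIm) with a 95% same-species
boundary is the operational replacement for DNA-DNA hybridization in
prokaryotic taxonomy, but it needs genome sequences for every strain.
For routine surveys it is far cheaper to sequence a few housekeeping genes.
The catch is that most genes drift away from the genome-wide signal: their
rates differ, and recombination can decouple a locus from the organismal
history entirely. `aniscreen` implements the workflow that addresses this
for rhizobia and similar clades:

1. **Screen** a set of core genes for markers whose per-gene ANI (ANIg,
   derived from a simple difference count) reproduces the species
   partition given by genomic ANI at a fixed boundary (95% or 96%).
2. **Concatenate** the selected markers (for rhizobia, the
   *SMc00019*-*truA*-*thrA* set, whose concatenate ANI we call ANIstt) and
   read species membership off the concatenate: pairs at or above 96% are
   conspecific, pairs at or below 94% are different species, and the open
   interval (94, 96) is an intermediate zone interpreted as a genetic
   continuum or ongoing speciation.
3. **Audit** existing taxonomies: type-strain pairs above the intraspecies
   floor flag candidate synonyms to merge; query strains whose best
   type-strain score falls below the interspecies ceiling are candidate
   novel species.

## Models and statistics

### Gene-level ANI

For two aligned rows, a column is *compared* iff both rows carry an
unambiguous A/C/G/T (pairwise deletion; gaps and IUPAC ambiguity codes are
excluded). With `d` differing columns among `s` compared columns,
`ANI = 100 (1 - d/s)`. The concatenate ANI pools `d` and `s` across genes,
i.e. it is the length-weighted combination, identical to counting on the
concatenated rows — not the unweighted mean of per-gene ANIg values. We
chose pairwise deletion (per pair of rows) rather than complete deletion
(per alignment) because amplicon data often carry scattered ambiguity
codes and complete deletion would discard those columns for all pairs;
the difference on clean alignments is nil, and on ambiguous data it is a
fraction of a percent.

### Genome-level ANI

Genomic ANI is computed by a self-contained fragment algorithm rather than
an external aligner. The query genome is cut into consecutive
non-overlapping 1020 bp fragments. Each fragment is seeded by exact 15-mers
(every 16 bp) against a k-mer index of the subject and of its reverse
complement; the best-supported diagonal (most seed votes; ties to the
forward strand and smaller offset) defines a window, and the fragment is
aligned by a banded global alignment (half-width 32) in which the fragment
is fully consumed and leading/trailing subject gaps are free. Fragments
passing the classical filters — at least 30% identity over at least 70% of
their length — contribute an aligned-length-weighted identity; the result
is symmetrized as the mean of the two directions. When no fragment
qualifies the result is "no homology detected", deliberately distinct from
ANI 0. On indel-free simulated pairs this recovers the realized divergence
to within a few hundredths of a percentage point for divergences up to at
least 10% (the acceptance suite requires ±0.3).

Parameter defaults (fragment 1020 bp, 15-mer seeds, 30%/70% filters, both
strands) follow common fragment-ANI practice; all are adjustable through
`ani_params()`. The seed length bounds the detectable divergence: an exact
15-mer survives at rate `(1-d)^15`, so at `d = 0.3` roughly one seed in
200 survives — still several per fragment at the default seed spacing.

### Screening statistics

For a candidate gene and a genome table over the same pairs:

* the **gap statistic** is `min(intra ANI) - max(inter ANI)` with respect
  to the species labels, plus the list of pairs violating the configured
  boundaries (intraspecies pairs under 96, interspecies pairs over 94);
* **boundary concordance** asks whether some candidate boundary
  `t ∈ {95, 96}` makes `ANIg >= t` agree with the genome call
  (`ANIm >= 95`, closed at the boundary) for *every* pair. The chosen
  boundary is the smallest satisfying `t`, which is conservative toward
  lumping; when none works the mismatching pairs at the best candidate are
  reported.
* genes are ranked by concordance, then descending gap, then ascending
  Robinson-Foulds distance of their neighbor-joining tree to a reference
  tree (when one is supplied), then ascending gene length, with the gene
  name as a deterministic final tie-break. The length criterion mirrors
  the practical preference for amplifiable markers under 1.5 kb.

The reference-tree criterion is optional because a trustworthy species
tree is not always available; with no reference tree the RF column is
omitted from the ranking. NJ + RF is used as the congruence measure — a
likelihood-based topology test would need full ML machinery and adds
nothing for a screening rank.

### Concordance statistics

Agreement between ANIm and a marker ANI table over the same pairs is
summarized by Pearson and Spearman correlations (average ranks for ties,
matching common statistical software), ordinary least-squares linear and
quadratic fits, and the extra sum-of-squares F test
`F = (SSE_lin - SSE_quad) / (SSE_quad / (n - 3))` on `(1, n-3)` degrees of
freedom. A quadratic SSE within floating-point noise of zero is reported
as infinite F with p = 0 and flagged degenerate. Printed p-values below
1e-4 are shown as "< 1e-04"; the numeric value is always carried in the
result. The two-dimensional scatter is tallied into an interspecies region
(ANIm < 93 and ANIstt < 94), an intraspecies region (ANIm > 95 and
ANIstt > 96) and the remainder; the inequalities are strict, so pairs on a
region edge count as "between".

### Classification conventions

The classifier is a total function of ANIstt: intra iff `>= 96.00`, inter
iff `<= 94.00`, intermediate otherwise. The boundaries are closed on the
observed extremes because they come from observed data (the highest
interspecies and lowest intraspecies values), and ties at exactly 94 or 96
are resolved toward the category that produced the boundary. All four
constants (93/94/95/96) are configurable via `threshold_config()`. The
audit reports support counts under both readings of "supported" —
strictly below the 94 ceiling and below the 96 floor — because the two
are genuinely different claims; merge candidates are connected components
of the graph joining species whose type strains reach ANIstt >= 96.
Which name survives a merge is nomenclature, not computation, so the tool
only flags the component.

### PHI recombination test

A marker is only useful if its history matches the organismal history, so
candidate concatenates are screened for recombination with a pairwise
homoplasy test. For two alignment columns the *refined incompatibility*
is the cycle rank `E - V + C` of the bipartite graph whose nodes are the
states observed at each site and whose edges are the observed joint
states; it is zero exactly when the pair of sites is compatible with some
tree, and generalizes the four-gamete test to multistate characters
(validated in the tests against an exhaustive minimal-homoplasy oracle on
up to six taxa). The PHI statistic is the mean incompatibility over pairs
of parsimony-informative sites within a window (default 100, counted in
informative-site index space). Recombination concentrates compatibility
locally, so the observed statistic is compared against a null obtained by
permuting the order of informative sites, with
`p = (r + 1) / (n_permutations + 1)` where `r` counts permutations with a
statistic at most the observed one. On a homoplasy-free alignment every
pair score is zero and p is exactly 1. The add-one correction means p can
never be 0; results below the permutation resolution print as a floor.

## The simulator and what it does (not) show

`simulate_panel()` generates the study conditions the rest of the package
is tested under: a star species tree whose species ancestors sit at depths
drawn from half the interspecies pairwise-divergence range (default
0.06-0.20, matching the 80-94% interspecies ANI span seen in rhizobia),
strains at depths from half the intraspecies range (default 0.00-0.03),
uniform Jukes-Cantor-like substitution, per-gene rate multipliers,
optional interspecies gene transfer (the recipient's copy is replaced by
the donor's), and neutral intergenic filler. Defaults of 5 species × 3
strains echo a small survey panel. No indels are simulated, which keeps
alignment trivial and lets the generator log *realized* divergences from
the final sequences — `expected_ani()` is therefore exact, not
distributional, and acceptance checks compare against it rather than
against nominal rates.

What passing tests on these panels do **not** show: real amplicons carry
indels, alignment error, primer bias and within-genome rate heterogeneity;
real species boundaries are not a clean uniform gap; and the star species
tree carries no deep phylogenetic structure, so tree-congruence numbers on
simulated panels mostly measure how two estimates resolve noise, not
recovery of true resolution. The package's claims about real data rest on
the method, not on the simulator.

## Numerical choices and degenerate inputs

* ANI values are carried at full double precision and only rounded for
  display; TSV matrices round-trip at full precision.
* Pairs with zero compared sites are errors for a single comparison but
  are collected as `NA` rows in whole-table computations, so one
  gap-saturated strain cannot abort a panel.
* A gene whose statistics cannot be computed is reported by the screen as
  screened-out with its reason, never silently dropped.
* NJ input must be symmetric to 1e-9 with a zero diagonal; RF requires at
  least four shared leaves.
* Problem sizes in the test-suite simulations (e.g. 50 screening panels of
  5×3 strains and 20 genes; 200 clonal and 50 recombinant PHI replicates
  at 199 permutations; a 10-species panel in the acceptance script) were
  chosen to give stable rates at interactive runtimes; the PHI window of
  40 used in simulations keeps most in-window pairs within one gene, which
  is the regime where the test has power.

## Known limitations

* The fragment engine approximates alignment-based ANIm; it is validated
  by property tests (recovery of known divergence, strand handling,
  symmetry), not by bit-compatibility with any external tool, and printed
  values on real data may differ from other implementations by a few
  tenths of a percent depending on alignment choices.
* Gap treatment (pairwise vs complete deletion) and aligner scoring are
  normative choices; published concatenate ANI values can shift by
  ~0.1-0.3 points under different choices.
* The 94/96 boundaries are the clade-specific observation for rhizobia;
  other groups should re-derive them via `screen_markers()` and
  `gap_statistic()` before trusting the classifier's defaults.

## A worked mini-study

```{r pipeline}
sim <- simulate_panel(sim_config(n_species = 5, strains_per_species = 3,
                                 n_genes = 6,
                                 gene_rate_multipliers = c(1, 1, 1, 3, 0.3, 1),
                                 n_transfer_events = 2, transfer_genes = 6L,
                                 genome_filler_bp = 5000, seed = 101))
genome_tab <- truth_ani_table(sim$truth)
screen_markers(sim$panel, genome_tab)
```

```{r concordance}
stt <- anistt(sim$panel, genes = c("gene01", "gene02", "gene03"))
key <- function(t) paste(t$id_a, t$id_b)
pairs <- tibble::tibble(anim = genome_tab$ani[match(key(stt), key(genome_tab))],
                        anistt = stt$ani)
conc <- ani_concordance(pairs)
conc
```

```{r plot, fig.width = 6, fig.height = 4}
ggplot2::autoplot(conc)
```

```{r classify}
classify_pairs(dplyr::bind_cols(stt[, c("id_a", "id_b")],
                                anistt = stt$ani, anim = pairs$anim)) |>
  dplyr::count(category, region_2d)
```
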