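# aniscreen

Marker-gene screening and bacterial species delimitation by average
nucleotide identity (ANI).

## The problem

Genomic ANI (ANIm) with a ~95% same-species boundary has replaced DNA-DNA
hybridization for deciding whether two prokaryotic strains belong to the
same species — but it needs genome sequences. `aniscreen` is for
taxonomists and microbial ecologists who want genome-grade species calls
from a few sequenced housekeeping genes. It implements the full workflow:

* **Screen** core genes for taxonomic markers: a gene passes when its
  per-gene ANI (**ANIg**, from a pairwise difference count under pairwise
  deletion) reproduces the genomic species partition at a fixed boundary
  (95% or 96%), quantified by the **ANI gap** statistic
  `min(intra ANI) − max(inter ANI)` and ranked together with tree
  congruence (NJ + Robinson–Foulds) and gene length (< 1.5 kb preferred
  for amplicon work).
* **Delimit** species from a marker concatenate (for rhizobia,
  *SMc00019*-*truA*-*thrA*, whose concatenate ANI is called **ANIstt**):
  pairs with ANIstt ≥ 96 are conspecific, ≤ 94 are different species, and
  the open zone (94, 96) marks a genetic continuum / ongoing speciation.
* **Audit** a taxonomy: type-strain pairs above the 96 floor are
  later-synonym candidates (merge components), queries whose best
  type-strain ANIstt is ≤ 94 are novel-species candidates.
* Supporting machinery: a self-contained fragment-seeded genome ANI
  engine (1020 bp fragments, exact 15-mer seeds on both strands, banded
  global extension, Goris-style 30% identity / 70% coverage filters),
  concordance statistics (Pearson/Spearman, linear vs quadratic curve
  fits with the extra sum-of-squares F test, 2-D scatter-region tallies),
  a PHI recombination permutation test, and a panel simulator with exact
  realized-divergence ground truth.

## Worked example

Simulate a 5-species panel (3 strains each) with six genes — three
clock-like, one fast, one slow, one horizontally transferred — then screen
the genes against the genomic ANI table:

```r
library(aniscreen)
sim <- simulate_panel(sim_config(n_species = 5, strains_per_species = 3,
                                 n_genes = 6,
                                 gene_rate_multipliers = c(1, 1, 1, 3, 0.3, 1),
                                 n_transfer_events = 2, transfer_genes = 6L,
                                 genome_filler_bp = 5000, seed = 101))
genome_tab <- truth_ani_table(sim$truth)
screen_markers(sim$panel, genome_tab)
#> # A tibble: 6 × 12
#>   gene   length_bp len_ok concordant chosen_boundary min_intra max_inter    gap
#> 1 gene03      1084 TRUE   TRUE                    95      97.0      88.0   9.04
#> 2 gene02       818 TRUE   TRUE                    95      97.2      88.4   8.80
#> 3 gene01       949 TRUE   TRUE                    95      96.6      88.1   8.54
#> 4 gene04      1063 TRUE   FALSE                   NA      92.1      67.6  24.5
#> 5 gene05       900 TRUE   FALSE                   NA      98.8      96.3   2.44
#> 6 gene06       920 TRUE   FALSE                   NA      83.6     100   -16.4
```

The three clock-like genes are the only concordant ones and take ranks
1–3: each separates species at the 95% boundary exactly as the genome
table does. The fast gene (`gene04`) pushes intraspecies pairs below the
boundary, the slow gene (`gene05`) pulls interspecies pairs above it, and
the transferred gene (`gene06`) has an interspecies pair at ANI 100, hence
a negative gap.

Concatenate the markers and check concordance with the genome signal:

```r
stt <- anistt(sim$panel, genes = c("gene01", "gene02", "gene03"))
gap_statistic(stt, sim$panel$strains)
#> <gap_report> source: concatenate:gene01-gene02-gene03
#>   min intra ANI: 97.2641  max inter ANI: 87.6885  gap: 9.57559
#>   0 boundary-violating pair(s)

key <- function(t) paste(t$id_a, t$id_b)
pairs <- tibble::tibble(anim = genome_tab$ani[match(key(stt), key(genome_tab))],
                        anistt = stt$ani)
ani_concordance(pairs)
#> <ani_concordance> n = 105 pairs
#>   Pearson r = 0.991  Spearman rho = 0.931
#>   linear    R^2 = 0.982
#>   quadratic R^2 = 0.986
#>   extra-SS F(1,102) = 23.46704, P < 1e-04 -> quadratic
#>   regions: intra 15 | inter 90 | between 0
```

The intraspecies gap is 9.6 percentage points (≥ 2 is the working
criterion), both correlations are high, the quadratic curve fits better
than the linear one, and every pair falls cleanly into the intraspecies
(ANIm > 95, ANIstt > 96) or interspecies (ANIm < 93, ANIstt < 94) region —
classification by the 94/96 rule is therefore exact on this panel:

```r
classify_pairs(dplyr::bind_cols(stt[, c("id_a", "id_b")],
                                anistt = stt$ani, anim = pairs$anim)) |>
  dplyr::count(category, region_2d)
#>   category region_2d        n
#> 1 inter    inter-region    90
#> 2 intra    intra-region    15
```

`autoplot(ani_concordance(pairs))` draws the ANIstt-vs-ANIm scatter with
the two species regions shaded and the quadratic fit overlaid; fitted
objects support `broom::tidy()` and `broom::glance()`.

A thin command-line wrapper covering the same workflow (subcommands
`simulate`, `ani`, `gene`, `stt`, `screen`, `classify`, `assign`, `audit`,
`concordance`, `phi`, `njtree`, `rf`) is installed at
`system.file("scripts", "aniscreen", package = "aniscreen")`; see
`?ani_cli`.

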