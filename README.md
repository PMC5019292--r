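# karyobarcode

Desk tools for the two classic analyses of a fish
cytogenetics-and-DNA-barcoding study, aimed at cytogeneticists and
barcoding practitioners who have (a) per-chromosome arm measurements
from metaphase spreads and/or (b) an aligned set of COI barcode
sequences, and want the standard summaries with every step explicit,
deterministic and tested.

**Cytogenetic track.** From long/short arm lengths (µm) per chromosome
pair it computes the arm ratio *r = LA/SA*, the centromeric index
*CI = SA/(LA+SA)*, Levan-style morphology classes
(m: 1 ≤ r ≤ 1.7, sm: 1.7 < r ≤ 3, st: 3 < r ≤ 7, t: r > 7, boundaries
to the lower class), the diploid number 2n, the canonical karyotype
formula (e.g. `4m+40sm+6st`), the fundamental number
*NF = 2(m+sm) + (st+t)*, and a haploid idiogram (SVG or base
graphics). A cleaned transcription of a published 25-pair loach
measurement table for three species is bundled, with every
transcription edit logged (`inst/extdata/PROVENANCE.md`).

**Molecular track.** From an aligned FASTA plus a taxon→species map it
computes pairwise p, Kimura two-parameter
(*d = −½ ln[(1−2P−Q)√(1−2Q)]*) and Tamura–Nei (TN93) distances with
optional discrete-gamma rate correction (each −ln x replaced by
α(x^(−1/α)−1)), between-species mean divergences, neighbor-joining
trees with nonparametric bootstrap supports, and outgroup-rooted
species-monophyly tests. A simulation module generates measurement
tables and gamma-heterogeneous TN93 alignments with known ground truth,
including a ready-made three-species-plus-outgroup barcoding scenario.

## Worked example

Karyotype summary of the bundled *Cobitis linea* table, classifying
from the table's printed arm-ratio column:

```r
library(karyobarcode)
tab <- read_measurements(system.file("extdata", "cobitis_linea.tsv",
                                     package = "karyobarcode"))
k <- karyotype(tab, "Cobitis linea", use_printed_ar = TRUE)
k
#> Karyotype of Cobitis linea
#>   chromosome pairs: 25   2n = 50
#>   formula: 4m+40sm+6st    NF = 94
#>   classified from: printed_ar
```

So the 25 pairs classify to 2 metacentric, 20 submetacentric and 3
subtelocentric pairs, giving the diploid complement 4m + 40sm + 6st
with 50 chromosomes and 94 chromosome arms. `summary(k)` prints the
per-chromosome metrics at the conventional 2-decimal presentation
(pair 1: arm ratio 2.43, centromeric index 0.29), and `plot(k)` draws
the idiogram.

The molecular pipeline on the simulated three-species scenario:

```r
sc  <- kor_scenario()
aln <- simulate_alignment(sc$tree, sc$length, sc$model, seed = 1)
d   <- pairwise_distances(aln, model = "k2p")
round(group_mean_distance(d, sc$species_map, percent = TRUE), 1)
#>                            Cobitis linea Oxynoemacheilus persa Oxynoemacheilus tongiorgii Misgurnus
#> Cobitis linea                        0.7                  26.9                       26.2      33.0
#> Oxynoemacheilus persa               26.9                   0.4                        6.4      30.8
#> Oxynoemacheilus tongiorgii          26.2                   6.4                        0.3      29.1
#> Misgurnus                           33.0                  30.8                       29.1        NA

tr <- bootstrap_support(aln, replicates = 100, seed = 1)
is_monophyletic(tr, sc$species_map, outgroup = sc$outgroup)
#>              Cobitis linea      Oxynoemacheilus persa Oxynoemacheilus tongiorgii
#>                       TRUE                       TRUE                       TRUE
```

Off-diagonal cells are between-species mean K2P distances in percent;
the diagonal holds within-species means. Note the plain K2P values
undershoot the generating divergences (0.103 and 0.40
substitutions/site) because the scenario simulates strong among-site
rate heterogeneity (gamma shape 0.4292); passing
`gamma_shape = sc$model$gamma_shape` to `pairwise_distances()`
corrects for it. All three species come out monophyletic on the
bootstrapped NJ tree. A thin command-line interface over the same
functions lives at `inst/cli/karyobarcode.R`
(`karyotype | idiogram | dist | njtree | monophyly | simulate-karyo |
simulate-seqs`).

To run the same analysis on the real barcodes, download GenBank
accessions KP050529–KP050540 as an aligned FASTA and supply a
two-column taxon→species TSV; the pipeline is identical.

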