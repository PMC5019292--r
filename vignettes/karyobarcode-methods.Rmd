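---
title: "Methods: karyotype metrics, barcode distances, and the simulation design"
author: "karyobarcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: karyotype metrics, barcode distances, and the simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyobarcode)
```

This vignette documents the models and procedures behind the package, the
parameters a user may want to change, the design choices that were
genuinely open, and what the simulation-based tests do and do not
demonstrate about real data.

## The cytogenetic track

### Metrics

Each chromosome pair contributes a long-arm length $LA$ and short-arm
length $SA$ (µm), measured on a metaphase spread. From these the package
derives

* total length $TA = LA + SA$,
* arm ratio $r = LA / SA \ge 1$,
* centromeric index $CI = SA / (LA + SA) \in (0, 0.5]$.

$r$ and $CI$ carry the same information, tied by $CI = 1/(1+r)$; the
package computes both and a property-style test checks the identity to
$10^{-12}$ on random measurements. All internal arithmetic is at full
double precision. Rounding happens only at the reporting layer, to 2
decimals with half-up ties, because that is how cytogenetic tables are
conventionally printed and it is the only rounding rule that reproduces
published example rows (e.g. $6.53/2.69 = 2.4275 \to 2.43$).

### Morphology classes

Chromosomes are classified by arm ratio into the four classes of the
Levan tradition:

| class | meaning        | interval          |
|-------|----------------|-------------------|
| m     | metacentric    | $1 \le r \le 1.7$ |
| sm    | submetacentric | $1.7 < r \le 3$   |
| st    | subtelocentric | $3 < r \le 7$     |
| t     | telocentric    | $r > 7$           |

Published applications of these criteria differ in how they treat the
boundary values. This package assigns boundaries to the lower (more
metacentric) class. That choice is not arbitrary: on the bundled
25-pair *Cobitis linea* table it reproduces the published type call of
every row, including the boundary row with $r = 1.69$ called
metacentric, 25 out of 25.

### Karyotype summary, formula and fundamental number

With $2n$ chromosomes in $n$ pairs, class counts are reported as
chromosome counts (twice the pair counts). The karyotype formula
concatenates nonzero classes in the fixed order m, sm, st, t
(`"4m+40sm+6st"`). The fundamental number (arm count) uses

$$NF = 2(m + sm) + (st + t),$$

i.e. bi-armed chromosomes contribute two arms and subtelocentric or
telocentric chromosomes one. Authors differ on whether subtelocentrics
count one or two arms; the one-arm rule is adopted here because it is
the only rule consistent with the published compositions the fixtures
derive from (4m+40sm+6st giving 94 and 18m+24sm+8st giving 92). Note
that no standard rule reproduces every published arm number for every
species: one of the three fixture species has mutually inconsistent
published compositions, which is why the summary functions always
recompute NF from the classified counts rather than accepting one.

### Classifying from printed versus recomputed arm ratios

Published tables round to two decimals and occasionally contain
internally inconsistent rows (the bundled table has exactly one, where
$LA/SA$ implies $r \approx 3.08$ but the printed ratio is 1.63). The
reader therefore keeps both: `karyotype(..., use_printed_ar = TRUE)`
classifies from the table's own ratio column, which is the right mode
for reproducing a published summary; the default recomputes $r$ from
the arm lengths, the right mode for new measurements. Every cleaning
edit applied to the bundled fixtures is listed in
`inst/extdata/PROVENANCE.md`; user data are never silently edited.

### Idiogram

The haploid idiogram draws one glyph per pair (a diploid flag doubles
them), ordered by decreasing total length, with the short arm above the
centromere so the centromere sits at a fraction $CI$ from the top. The
source figures state no tie-break or normalization rule, so the package
declares its own: ties in length are broken by higher $CI$, then by
pair id, and heights are normalized to the largest chromosome. SVG
output is a pure function of layout and style — re-rendering identical
input is byte-identical, which the tests assert.

## The molecular track

### Distances

For two aligned sequences the package counts, over sites where both
sequences have an unambiguous base, the proportions of purine
transitions $P_1$ (A↔G), pyrimidine transitions $P_2$ (C↔T) and
transversions $Q$. Sites with a gap or any ambiguity code (everything
outside A, C, G, T is treated as N) are excluded per pair ("pairwise
deletion", the default); complete-deletion and a site-coverage
threshold mode are available for users who want a common site set
across all pairs. The Kimura two-parameter distance is

$$\hat d = -\tfrac12 \ln\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right],
  \qquad P = P_1 + P_2,$$

and the Tamura–Nei (TN93) distance is the standard closed form with
empirical base frequencies pooled over the pair, distinguishing the two
transition types. With uniform frequencies and $P_1 = P_2$ TN93 reduces
to K2P; the tests check this reduction to $10^{-9}$ and check both
distances against an independent implementation (`ape::dist.dna`) to
$10^{-9}$ on simulated pairs.

Rate heterogeneity across sites is accommodated by the usual gamma
correction: every $-\ln x$ in a distance formula is replaced by
$\alpha(x^{-1/\alpha} - 1)$ with shape $\alpha$. As $\alpha \to \infty$
the correction vanishes (tested at $\alpha = 10^6$ against the
uncorrected value at $10^{-4}$). The default shape offered throughout
the package is 0.4292 with 5 categories, the published model fit for
the COI alignment this package's molecular track re-analyzes.

Pairs past saturation (where a logarithm's argument is nonpositive) are
flagged as undefined `NA` cells rather than raising errors, so a large
matrix with a few bad pairs remains usable; functions that cannot
tolerate undefined cells (tree building, group means) refuse them
loudly, naming the offending pairs.

Distances are substitutions/site internally everywhere; percentages
appear only in reporting (`percent = TRUE`), matching how barcoding
papers print values like "10.3 %".

### Between-species means

The between-species summary is the arithmetic mean of all cross-species
taxon pairs, the conventional barcoding between-group distance; the
within-species mean occupies the diagonal. Whether a published
between-species value is a group mean or a single representative pair
is often unstated; the group mean is adopted as the standard summary.

### Neighbor joining

Tree building is the Saitou–Nei neighbor-joining agglomeration with the
Studier–Keppler criterion
$Q_{ij} = (n-2)d_{ij} - \sum_k d_{ik} - \sum_k d_{jk}$. Three
numerical choices are declared:

* **Ties** in $Q$ are broken by the lowest index pair, so degenerate
  inputs (equidistant matrices, identical sequences) give a
  deterministic tree.
* **Negative branch estimates** are clamped to zero with the deficit
  transferred to the sister branch, keeping the joined pair's path
  length intact and all reported lengths interpretable.
* Two taxa yield the single split with the distance shared equally.

NJ is exact on additive matrices: the tests enumerate *all* labelled
unrooted topologies on 4 and 5 taxa (3 and 15 trees, generated from
their closed-form shapes), assign random branch lengths, and require
exact topology recovery and path-length reproduction to $10^{-9}$.

### Bootstrap and monophyly

Bootstrap supports resample alignment columns with replacement,
recompute the distance matrix and NJ tree per replicate, and score each
bipartition of the point-estimate tree by the percentage of replicate
trees containing it (supports annotate the point tree, not a
consensus). A replicate that produces a saturated distance is redrawn
up to a bounded retry budget. The whole procedure is deterministic
given the seed. Species monophyly is judged after rooting on a
user-supplied outgroup: a species is monophyletic when the smallest
clade containing all its members contains nothing else;
single-member species are monophyletic by definition. Rooting fails
loudly when the outgroup taxa are absent or not themselves
monophyletic.

## The simulation module

### What it emulates

The measurement generator emulates the structure of a published
karyotype table: per pair, a total length uniform on a range (default
1.5–9.5 µm, the scale of small loach chromosomes), an arm ratio uniform
within the class interval, arms derived from the two, and independent
multiplicative Gaussian measurement noise on each arm (default relative
sd 2%, a plausible scale for repeated length measurements on metaphase
photographs). Sampling intervals are shrunk 0.15 away from class
boundaries by default so that noisy ratios usually stay classifiable;
with zero noise, classification recovers the generating labels exactly,
and at the default noise and margin the per-chromosome label recovery
is at least 95% — both are tested.

The sequence generator evolves gap-free alignments down a tree under a
TN93 process: root drawn from the stationary frequencies, per-branch
transition probabilities from the eigendecomposition of the scaled rate
matrix, and discrete-gamma rate heterogeneity with `categories`
equal-probability categories represented by their conditional means
(5 by default). Branch lengths are expected substitutions per site.

The bundled three-species scenario (`kor_scenario()`) mirrors the
structure of a sympatric loach barcoding study: two congeners at 0.103
substitutions/site between-species divergence, a third species of
another genus at 0.400 from both, one outgroup taxon, within-species
divergence 0.005 (a free choice — the source study prints no
intraspecific distances — at the low end of typical COI intraspecific
variation), 2/4/6 taxa per species matching the study's sample sizes,
600 sites (the COI barcode scale), an AT-rich base composition typical
of fish mitochondrial COI, transition bias, and gamma shape 0.4292
with 5 categories.

### What the tests do and do not show

Simulation-recovery tests match the estimator to the generating
process. Unbiasedness of the K2P estimator is checked on K2P-generated
data (two taxa, 600 sites, 200 replicates, divergences 0.05, 0.103 and
0.40; the mean estimate must fall within two Monte-Carlo standard
errors of the truth). Group-mean recovery on the three-species scenario
is checked with the gamma-corrected TN93 estimator at the generating
shape, averaging 20 replicate alignments. Monophyly recovery runs the
full pipeline (simulate, K2P distances, NJ, outgroup rooting) 100 times
with distinct seeds and requires all three species monophyletic in at
least 95 runs.

These checks validate internal consistency, not realism: the generator
produces gap-free alignments without indels, no saturation beyond the
model, no alignment error, no numts, and i.i.d. sites. Passing them
says the estimators and tree machinery do what their formulas promise
under the stated model; it does not certify performance on real
barcodes, where a plain K2P distance on strongly rate-heterogeneous
deep divergences is known to underestimate (visibly so at the 0.40
scenario depth — the gamma-corrected estimator is provided for exactly
that reason, and its nonlinearity in turn inflates variance and adds a
small convex bias at depth).

The problem sizes above (600 sites, 200 recovery replicates, 100
pipeline runs, 20 group-mean replicates) were chosen as the smallest
sets at which the Monte-Carlo standard errors make the checks
informative; they run in seconds to a couple of minutes on one core.

## Configuration, formats, provenance

Tabular measurements are TSV/CSV with headers; alignments are FASTA
(wrapped at 70 columns on output); distance matrices round-trip through
square PHYLIP and TSV; trees round-trip through newick with branch
lengths and integer supports as internal node labels. The command-line
entry point (`inst/cli/karyobarcode.R`) exposes each stage as a
subcommand, writes a provenance record (package version, subcommand,
options, seed) next to every output, and reads an optional YAML
configuration file whose values are overridden by explicit flags. YAML
was chosen as the configuration format because it is the established
configuration grammar in the R ecosystem with a mature parser.

## Known limitations

* Classification thresholds are fixed; users wanting other published
  threshold variants must classify from the metrics themselves.
* The molecular track consumes aligned sequences; it does not align,
  select models, or compute likelihood-based trees. NJ on good
  distances recovers well-separated species reliably (and is exact on
  additive inputs) but is not a substitute for likelihood methods on
  hard topologies.
* The gamma correction assumes the shape is known; it is not estimated
  from the data.
* Ambiguity codes other than N are not partially matched — any non-ACGT
  symbol is excluded like N, a deliberate simplification.
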