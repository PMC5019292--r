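# Fixture provenance

The three TSV files in this directory are cleaned transcriptions of the
published per-chromosome measurement table for *Cobitis linea*,
*Oxynoemacheilus persa* and *Oxynoemacheilus tongiorgii* (25 chromosome
pairs each; long/short arm lengths in µm, printed total length, arm ratio,
centromeric index and chromosome-type call). Every departure from the
printed table is listed here; the reader applies no silent cleaning to user
data.

## Schema normalisation

- Common schema for all three blocks:
  `pair_id, long_arm, short_arm, printed_ta, printed_ar, printed_ci, printed_ct`.
- The *O. tongiorgii* block is printed with its CT column before the numeric
  columns; it is re-ordered here to the common schema. Values unchanged.
- Printed CT calls `M`/`Sm`/`St` are lower-cased to `m`/`sm`/`st`.
- Centromeric indices printed without a leading zero (`.30`) are stored as
  decimals (`0.30`).

## Value edits (typo repairs)

- *C. linea* pair 1: printed CI `29` stored as `0.29` (dropped decimal
  point; 2.69/9.22 = 0.29 confirms).
- *C. linea* pair 25: printed SA `99` stored as `0.99` (dropped decimal
  point; 4.07 + 0.99 = 5.06 = printed TA confirms).

## Known internal inconsistencies (left as printed, flagged)

- *C. linea* pair 9: LA 4.86 / SA 1.58 imply AR ≈ 3.08 and CI ≈ 0.25, but
  the printed AR is 1.63, printed CI 0.28 and printed CT `m`. Which figures
  are mistyped cannot be decided from the publication. This is the only
  *C. linea* row whose CI recomputed from LA/SA differs from the printed CI
  by more than 0.01; consistency checks exclude it.
- *O. persa* pair 18: printed AR 1.69 falls in the metacentric interval of
  the adopted thresholds but the printed CT is `Sm`. The *O. persa* block is
  not used for classification checks (its published karyotype formula is
  also printed three mutually inconsistent ways, and no formula reproduces
  the published arm number 90).
- Printed TA occasionally differs from LA + SA by 0.01 (rounding of the
  source measurements); derived quantities here always use LA + SA.
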