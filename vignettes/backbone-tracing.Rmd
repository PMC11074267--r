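---
title: "From density voxels to backbone models: the cryoforge methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From density voxels to backbone models: the cryoforge methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoforge)
```

cryoforge turns cryo-EM density volumes and atomic models into
voxel-labeled training data, and per-voxel probability volumes plus a
protein sequence into a traced Cα backbone. This vignette is the package's
account of the methods: the models and their assumptions, the parameters
that matter, the numerical choices, and what the synthetic fixtures do and
do not establish about real data.

## Grid model and MRC handling

A `density_grid` holds a 3D scalar field with per-axis voxel sizes and an
origin in Å; the voxel with zero-based index `(m_x, m_y, m_z)` is centered
at `origin + m * voxel`. Files are MRC2014. Three handling rules keep the
rest of the package free of format dialects:

- **Axis normalization on read.** The MRC header permits any permutation
  of (x, y, z) across (columns, rows, sections); `read_mrc()` undoes the
  permutation so in-memory arrays are always x-fastest. Files are written
  with the identity mapping.
- **Origin fallback.** Deposited maps record the origin either in the
  `origin` fields or as `nstart` voxel offsets; when the former is all
  zero and the latter is not, `nstart * voxel` is used.
- **Single output mode.** Everything is written as mode 2 (32-bit reals),
  including integer label masks: label values are ≤ 20 and are exactly
  representable, and one code path keeps the writer simple.

`validate_mrc()` runs the standard battery of header checks (id string,
machine stamp, mode, dimensions, axis mapping, volume-stack divisibility,
labels, version, extended-header type, statistics, file size) and the
package maintains the invariant — tested end to end — that every MRC file
it writes passes all of them. The statistics check accepts the MRC
"undetermined" convention (`dmax < dmin`), and compares recorded against
recomputed values with tolerance `1e-4 * (max − min)` to absorb float32
storage rounding. For modes 4 and 12 (complex, half floats) the statistics
are not recomputed — base R cannot decode those payloads — and the check
reports a pass with an explanatory note; all files this package itself
produces are mode 2. Either compliant `nversion` (20140, 20141) is
accepted on read; 20141 is written.

## Preprocessing

`resample_grid()` brings a map to a uniform voxel size (default 1 Å, the
standardized training grid) by trilinear interpolation, covering the full
input bounding box (`ceiling(extent / target)` voxels per axis) and
padding with 0 beyond the input support. Trilinear interpolation is the
standard meaning of volume resampling here and has the virtue of being
exactly testable: it reproduces constant and affine fields to machine
precision, which the suite exploits. A nearest-neighbor mode exists for
masks, where interpolation would invent fractional classes.

`normalize_grid()` divides by the 95th percentile of the *strictly
positive* densities and clips to [0, 1]. Positive values are where protein
signal lives; the percentile (rather than the maximum) makes the scale
robust to a handful of extreme voxels. The percentile estimator is linear
interpolation between order statistics — the most common convention, and
pinned by a test against an explicit order-statistic oracle so the
normalization is reproducible to the digit. Maps with no positive values
are degenerate and rejected.

## Voxel labeling

`parse_structure()` reads PDB models via bio3d, keeping one row per
residue carrying any of Cα/N/C, the first alternate-location conformer
only, and insertion codes as part of residue identity. Amino types use a
fixed alphabetical coding (ALA = 1 … VAL = 20; 0 for non-standard
residues such as MSE). Secondary structure comes from HELIX/SHEET header
records (helix = 2, strand = 3, coil = 1 wherever backbone exists) rather
than being recomputed; an `ss_table` argument accepts an external
per-residue assignment for models whose headers are absent or untrusted.

Two index-assignment conventions are implemented:

- `nearest` (default): round `(coord − origin) / voxel` to the nearest
  integer, ties toward +∞. Round-trip error is ≤ half a voxel per axis —
  at 1 Å voxels, ≤ 0.5 Å.
- `eq1`: the literal floor-then-ceiling formula
  `i = ⌈⌊z − origin_z⌋ / voxel_z⌉`. Its round-trip error approaches a
  full voxel; it is retained because the convention exists in the wild
  and the two modes make the difference measurable (`verify_labels()`
  reports the max per-axis deviation under either).

`make_masks()` produces the four schemes (backbone-atom 1/2/3, Cα 0/1,
amino 0–20, secondary structure 0–3) on the map's geometry. Atoms outside
the grid are counted and skipped, not errors: cropped deposited maps do
cut models. Voxel collisions resolve by priority Cα > N > C with first
writer winning within a class, so the Cα-derived labels that feed three of
the four schemes are never destroyed by a later N or C atom.

## Tiling

`divide_grid()` cuts volumes into `tile_size`³ cubes (default 32) with
`overlap` voxels (default 6) of context on each face, so cores of
`tile_size − 2·overlap` = 20 voxels partition the volume exactly once;
`stitch_grid()` reassembles predictions from those central cores, which
avoids the boundary artifacts of predicting voxels whose neighborhood was
cut off. Edge policy, which the core/overlap numbers alone do not fix: the
first core starts at parent index 0 (leading overlap of boundary tiles is
zero-padding) and trailing partial cores are clipped to the volume. This
is the unique choice that keeps the exactly-once core cover for every
volume shape, and the round-trip identity is property-tested over random
shapes from 1³ to 70³.

## The tracing HMM

States are candidate Cα voxels: every voxel whose predicted Cα probability
reaches the threshold (default 0.5), with coordinates at voxel centers and
amino distributions renormalized over the 20 residue classes (mass on the
background/unknown class is discarded — it says "no residue here", which
the candidate threshold already adjudicated).

- **Emissions** are normalized geometric means
  `e_s(a) ∝ √(p_s(a)·bg(a))` of predicted amino probabilities and
  background frequencies. Background defaults to uniform 1/20 and is
  user-overridable from any frequency table; the synthetic generator
  draws sequences from the same table so emission tests are
  self-consistent.
- **Transitions** weight a step between states at distance `x` by a
  Gaussian with mean μ = 3.8047 Å — the consecutive-Cα spacing — and
  standard deviation σ·Λ = 0.036 × 10 = 0.36 Å. The stated σ of 0.036 Å
  is read as a base value carrying a tunable scale Λ; both are arguments,
  and their product is what the math uses. Support is restricted to
  neighbors within [2, 6] Å: below 2 Å two Cα cannot coexist, above 6 Å
  the Gaussian mass is negligible (≈ 10⁻⁹ relative), and the restriction
  turns a quadratic transition matrix into a sparse neighbor structure.
  Weights are normalized per state over its neighbor set.
- **Initial probabilities** for a chain renormalize the first residue's
  emissions over the currently free states, since any Cα may start a
  chain.

**Injective decoding.** The no-reuse constraint (one voxel hosts one
residue) breaks the independence structure ordinary Viterbi relies on;
exact decoding is combinatorial. cryoforge uses a beam search over partial
injective paths (default beam 32): extend each retained path to every
free neighbor of its last state, score in log domain, keep the top beam.
Ties break toward the lexicographically smaller state path, making
decoding deterministic without any RNG. With a beam at least the number
of injective paths the search is exhaustive, and the suite verifies
equality with brute-force enumeration over hundreds of random ≤ 6-state
models. Multiple chains are decoded longest first — the most constrained
alignment claims states before easier ones — consuming states globally.
All scoring is in log space; 400-residue chains decode with finite scores
and no underflow.

The beam is a heuristic for large candidate sets: a narrow beam can
dead-end (reported as an error naming the residue index) or return a
suboptimal path. Raising `beam_width` trades time for optimality.

## Evaluation

`chain_compare()` matches model to reference Cα atoms one-to-one, globally
nearest pair first, accepting pairs within 3 Å (the conventional
chain-comparison cutoff; configurable). Greedy nearest-first is stated
explicitly because published comparison tools do not document their exact
matching; whatever they do, the greedy rule is deterministic and
reproducible here. Reported: RMSD over matched pairs, matching % of
reference residues, sequence identity % among matches. `voxel_f1()`
scores voxel predictions with precision/recall/F1 — the balanced choice
when positive voxels are a sliver of the volume. `dataset_stats()` and
`split_dataset()` handle resolution-bin summaries (half-up rounding to 2
decimals) and seeded 90/10 splits, optionally stratified by resolution
bin so both sets share the resolution distribution.

## Synthetic data: what it emulates, and what it does not

The generator exists so every stage is testable without experimental maps
or a trained predictor. `make_backbone()` builds chains with consecutive
Cα spacing inside 3.8 ± 0.05 Å: ideal-helix parameterization (radius
2.3 Å, rise 1.5 Å, twist 100°, giving 3.83 Å chords) for helix spans, a
flat 3.80 Å zigzag for strands, a self-avoiding 3.8 Å random walk for
coil, with non-adjacent residues kept ≥ 3 Å apart and bounded retries.
N and C atoms sit on the Cα–Cα segments at roughly bonded distances.
`simulate_map()` sums isotropic Gaussian blobs (default σ = 1 Å at 1 Å
voxels — resolvable but overlapping, in the spirit of 2–4 Å maps) plus
Gaussian noise, with a ≥ 5 Å margin. `simulate_predictions()` emulates a
per-voxel classifier of tunable quality: the true class receives
probability `fidelity` everywhere, the remainder spread uniformly — at
fidelity 1 the argmax reproduces the masks exactly. The construction is
deterministic given masks and fidelity; the `seed` argument is accepted
for interface stability (randomness enters through backbone generation
and map noise, not through the oracle).

Default study conditions used by the tests: 30-residue helical backbones,
1 Å voxels, blob σ 1 Å, noise σ 0.05, prediction fidelity 0.9 over ten
seeds for the end-to-end recovery property (traced matching = 100 % at
3 Å, sequence identity ≥ 90 %). These sizes keep the whole suite in the
seconds range while leaving every algorithmic branch exercised — beam
decoding depth is covered separately by a 400-residue mixed-motif chain.

What passing these tests does **not** show: real maps have non-Gaussian,
resolution-dependent point-spread, anisotropy, solvent and ligand
density, model-map misalignment, and predictors whose errors are spatially
correlated rather than uniform. Synthetic recovery is a correctness
statement about the pipeline, not a performance claim about experimental
data — benchmark-level performance on deposited maps is the business of
the predictor, which this package deliberately does not include.

## Numerical choices and degenerate inputs

- Percentile: linear interpolation between order statistics; maps without
  positive values are rejected.
- Statistics tolerance in MRC validation: `1e-4 · (max − min)` with a
  1e-6 floor for constant maps.
- Interpolation outside input support: 0 (the background convention used
  by masks and padding alike).
- Emission/initial normalizations reject all-zero numerators
  (degenerate-emission / degenerate-start errors) instead of silently
  renormalizing noise.
- Beam ties: lexicographic state order; no RNG anywhere in decoding.
- `fidelity = 1/k` on k classes makes the oracle uniform; argmax ties
  then resolve by class index, which is why tests pin fidelity away from
  the uniform point.
- Split sizes use `floor(fraction · n)` for the training side, so a 90 %
  split of 7,392 ids gives exactly 6,652 / 740.

## Known limitations

- The injective decoder is exact only in the exhaustive-beam regime;
  production-size candidate sets rely on the beam heuristic.
- Secondary structure mirrors the model's header records; models without
  HELIX/SHEET records label everything coil unless an external table is
  supplied.
- MRC modes 4 and 12 are recognized by the validator but their payloads
  are not decoded.
- The command-line wrapper is a thin convenience over the exported
  functions; programmatic use through `run_pipeline()` is the primary
  interface.
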