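---
title: "Methods: models, cutoffs and design choices in nuprtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, cutoffs and design choices in nuprtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuprtools)
```

`nuprtools` is an analysis layer for small helix-loop-helix chromatin
proteins of the NUPR1/HMGA type: consensus quality assessment of candidate
structural models, secondary-structure and turn assignment, protein-DNA
interface analysis, rigid docking onto ideal B-DNA, conformational-ensemble
order/disorder analytics, and sequence-level motif and modification-site
scoring. This vignette records the models each stage assumes, the tunable
parameters and their defaults, what the synthetic generators do and do not
emulate, and the design choices made where the design was genuinely open.

## Structure model and input conventions

Structures are flat atom tables (model, chain, residue number, residue
name, atom name, element, x/y/z in Angstrom). Residue numbering is 1-based
and spans are inclusive on both ends, so a helix from residue 20 to 33 has
length 14. All distances are in Angstrom and all angles in degrees.
Hydrogens are first-class atoms; no hydrogens are ever inferred at the I/O
layer. The PDB reader keeps the first alternate location with a warning and
ignores insertion codes (with a warning); DNA residues may arrive as
`A/T/G/C` or `DA/DT/DG/DC` and are stored canonically in the two-letter
form. Phosphate-oxygen naming is normalized from the older `O1P/O2P`
dialect to `OP1/OP2`; normalization is idempotent and touches nothing else.

## Consensus model evaluation

Superposition is the closed-form least-squares rigid fit (Kabsch algorithm
via a 3x3 SVD) over the C-alpha atoms common to both structures, matched by
chain and residue number; a residue-identity mismatch is an error naming
the first offending residue, and reflections are excluded by the usual
determinant correction. All-atom selection is available behind a flag, but
RMSD is reported over C-alpha only by default, which is how such model
comparisons are usually tabulated.

The alignment Z-score uses the statistic S = number of matched C-alpha
pairs within 4 Angstrom after optimal superposition. The null distribution
is a desk-scale stand-in for a random comparison of structures: S is
recomputed against seeded, length-matched random-coil decoys (default
`null_size = 200`), and `z = (S_obs - mean(S_null)) / sd(S_null)`. A
permutation null (shuffling the residue correspondence) was evaluated and
rejected: sequential correspondence retains chain locality that shuffles
destroy, so even unrelated folds score systematically positive against it,
and for fully extended chains the statistic is identically zero with zero
null variance. Against the random-coil null, identical structures score
far above 3 and unrelated random folds average |z| below 1. A zero-variance
null raises an error advising a larger `null_size`.

Aggregation over a model set treats one designated label as the negative
control (an unrelated fold included to calibrate dissimilarity). Per
candidate: mean RMSD and population standard deviation over the *other
candidates* (control excluded), mean Z over the other candidates *plus*
the control, and the Pearson correlation between the candidate's
off-diagonal RMSD and Z entries. The correlation is reported descriptively
only and is `NA` when either vector is constant. Ranking is a total order:
ascending mean RMSD, ties broken by descending mean Z, then input order;
the control is never ranked. This combination of exclusion rules
reproduces the published aggregate statistics of the best-scoring
reference model exactly (mean 4.77, SD 0.38 from the bundled matrices).

Ramachandran classification uses a three-level rectangular-basin map:
favored boxes for the right-handed alpha basin (phi in [-100, -40], psi in
[-70, -10]), the beta/extended basin (phi in [-170, -50], psi in
[100, 180] or [-180, -160]) and the left-handed alpha basin (phi in
[40, 90], psi in [0, 70]); "allowed" is within 20 degrees (Chebyshev) of a
favored box, everything else is disallowed. The map is deliberately simple:
the properties downstream code relies on are topological (the ideal helix
point (-57, -47) is favored, (0, 0) is disallowed), not the exact
percentages a specific published grid would give. Chain termini and
residues with incomplete backbones are skipped (the latter with a
warning), and percentages are over classified residues and sum to 100.

## Secondary structure, turns, accessibility

Helix assignment is dihedral-window based: a residue is helical when
(phi, psi) fall within +-35 degrees of (-57, -47), and maximal runs of at
least 4 helical residues become spans. A dihedral window rather than a
hydrogen-bond (DSSP-style) rule keeps the assigner exactly inverse to the
dihedral-level builder used for fixtures and ensembles, and +-35 degrees
covers the regular alpha range without admitting the beta basin.

Beta-turns are windows of 4 consecutive residues, all outside helix spans,
with Calpha(i)-Calpha(i+3) strictly below 7 Angstrom. Gamma-turns are
windows of 3 consecutive residues with an O(i)...H-N(i+2) contact at most
2.5 Angstrom (the module-wide hydrogen-bond rule; heavy-atom fallback 3.5
Angstrom when the structure carries no hydrogens), flagged *classic* when
the central residue is within +-30 degrees of (75, -64). Both detectors
report maximal non-overlapping windows scanning N- to C-terminus, which is
how turn counts are conventionally summarized.

Accessibility is Shrake-Rupley sphere sampling with a deterministic
Fibonacci lattice (default 960 points per atom, probe 1.4 Angstrom) and
the standard van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80, P 1.80,
H 1.20. The deterministic lattice makes ASA reproducible bit-for-bit and
additively exact for non-overlapping atoms; its accuracy is checked
against the analytic isolated-atom sphere (within 2 %) and a 10x-denser
sampling oracle (within 3 %). Relative ASA divides by Gly-X-Gly maximal
exposures, and residues with relative ASA strictly below 0.25 are labeled
buried (`b`), otherwise exposed (`e`). The 0.25 threshold is this
package's declared choice; the upstream tools that print such labels do
not document theirs.

## Protein-DNA interface rules

All cutoffs are inclusive (a pair exactly at the cutoff is reported) and
exposed in the pipeline configuration:

| category | rule | cutoff (A) |
|---|---|---|
| salt bridge | charged N atom to charged O atom | 5.0 |
| hydrogen bond | polar H to O/N acceptor | 2.5 (heavy fallback 3.5) |
| attractive charge | opposite formal charges | 5.6 |
| pi-pi stacking | ring centroid to ring centroid | 5.5 |
| alkyl | aliphatic group centroid pair | 5.5 |
| pi-alkyl | ring centroid to aliphatic centroid | 6.0 |

Salt bridges are measured atom-pairwise (reports list atom pairs such as
`A:Lys65:NZ` to `C:A7:OP2`), not group-centroid-wise. Positive groups are
Lys NZ, Arg NH1/NH2/NE and (configurably) His ND1/NE2; negative groups are
Asp OD1/OD2, Glu OE1/OE2, DNA OP1/OP2 and C-terminal OXT. The
electrostatic and hydrophobic cutoffs are not published by the commercial
tool that defined these report categories; the values above were chosen to
bracket every distance such reports print (the largest published
attractive-charge distance is 5.53 Angstrom, hence 5.6). A pair that
qualifies as a salt bridge is not repeated as an attractive-charge record.
Thymine's C7 methyl counts as an aliphatic group on the DNA side, so every
category can span a protein-DNA interface. Hydrogen-bond detection
requires a hydrogen covalently close (within 1.25 Angstrom) to an N/O
donor; carbon-bound hydrogens never donate.

In-silico mutagenesis (supported targets Glu, Asp, Lys, Arg, Ala) keeps
the backbone and CB and rebuilds an idealized side chain along the
original CA-to-CB direction. This is a sign-flip device for rewiring
analyses — which contacts are lost and gained, keyed by category and
residue pair — not a geometry prediction; relaxed mutant distances are out
of scope. A Gly target is an error (no CB to build from).

Docking is deliberately minimal: seeded uniform random orientations with
the protein centroid placed just outside the phosphate cylinder at random
height and azimuth, scored as `w_attr * (attractive pairs <= 5.6 A) -
w_clash * (heavy clashes < 2.5 A)` with unit default weights, greedy
clustering at 3 Angstrom interface RMSD (computed in the fixed DNA frame),
clusters ranked by best member. It is an enrichment machine — a
cationic-patch binder must reliably outrank a neutral control — not a
physics-based pose predictor. DNA stays rigid; bending is not modeled.

The B-DNA duplex is a rigid fiber model (twist 36 degrees per base pair,
rise 3.38 Angstrom per base pair, schematic cylindrical backbone
template). Groove assignment classifies a point as distal (> 10 Angstrom
from the nearest DNA atom), backbone (nearest atom is a phosphate/sugar
atom within 4 Angstrom), else minor or major by the angular sector around
the helical axis relative to the dyad direction of the nearest base pair,
which in this fiber model bisects the glycosidic bonds and points into the
minor groove.

## Ensembles and disorder

Ensembles are multi-model structures sharing one topology. Frame
subsampling is evenly spaced including both endpoints when unseeded
(`ceiling(k (N-1)/(n-1))`, 0-based), or a seeded uniform subset — both
modes exist because sampling protocols in the literature rarely state
which was used. RMSF superposes every frame on an iteratively refined mean
structure (two passes), removing the bias of fitting to an arbitrary first
frame. Helix persistence counts a frame when a *single* assigned helix
covers at least 75 % of the span (the coverage fraction is configurable;
"helix present in a frame" has no standard definition). Disorder consensus
applies the strict rule "disordered iff probability > 0.5" per predictor
with a majority vote and reports the agreement fraction.

## Sequence-level scans and scores

Motif positions are 1-based and inclusive. The NLS scanner matches the
bipartite core `K-(K/R)-X-(K/R)`; a second basic cluster (at least 2 of
K/R within a 4-residue window, extended through any contiguous basic run)
starting 8-14 residues downstream of the core start produces a bipartite
hit — this spacer rule is a reconstruction calibrated so a core at 82 with
a cluster at 93-96 yields the canonical 16-residue span 82-96, and the
bounds are configurable in source. The NES pattern is
`L-x(3)-L-x(2)-L-x-L` with strict leucine anchors (a widened
hydrophobic-anchor mode exists but is off by default). AT-hook-like cores
are windows (default 7) whose G/R/K fraction reaches 0.7; overlapping
qualifying windows are merged and trimmed to their G/R/K edges, so a
planted `RKGRTKR` is recovered at exactly its planted position with score
6/7; two cores separated by a 10-40 residue gap pair into a bipartite hit.

Physicochemical summaries use the Kyte-Doolittle scale (centered window,
odd length, ends truncated), average residue masses plus one water for
molecular weight, and a bisection pI on the Henderson-Hasselbalch
net-charge function with the EMBOSS pKa set (N-terminus 8.6, C-terminus
3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1); 100 bisection
steps on [0, 14] put the net charge at the returned pI below 1e-3 charges.
Alignment identity excludes gap-gap columns from the denominator;
conservation is the percent of rows sharing the reference letter, binned
linearly into grades 1-9.

The PTM meta-score reads "predicted" strictly: a program calls a site iff
its raw score exceeds its own cutoff. The meta-score is the fraction of
programs registered for that modification class that call the site, so a
unanimous site scores exactly 1. Two genuinely open readings were settled
here: scores are *unweighted* fractions (per-program weighting schemes are
rejected for reproducibility), and program totals are *per class* rather
than shared across classes, since different classes are served by
different program panels. Sites with zero predicting programs are omitted
from reports but retrievable.

## Synthetic data: what it emulates, what it does not

The generators produce every input the pipeline consumes: ideal-backbone
protein models (N, CA, C, O, amide H, CB; bond lengths 1.458/1.525/1.329
Angstrom and standard angles; helical spans at (-57, -47), extended
elsewhere; seeded Gaussian coordinate noise), fiber-model B-DNA duplexes,
conformational ensembles driven by a per-span order schedule, per-program
prediction tables with a controllable agreement level, and
motif-embedded sequences over a background alphabet that excludes the
scanned anchor letters (K, R, L, G) so planted motifs are unambiguous.

Ensemble frames re-dihedralize a span to random coil (phi uniform in
[-170, -60], psi uniform in [60, 175] — generously allowed and
unambiguously non-helical) with probability 1 minus the span's order
probability; everything outside scheduled spans stays extended. Default
frame noise is 0.05 Angstrom per coordinate: large enough that no two
frames are identical, small enough (about 7 degrees of dihedral jitter)
that a built helix is never mis-assigned, so a span with order probability
1 has persistence exactly 1. The reference study conditions are used
throughout the checks: spans (20, 33), (65, 72), (80, 98) on a 100-residue
chain, order probabilities (1.0, 0.15, 0.5) — helix 1 persistently folded,
helix 2 almost always disordered, helix 3 intermediate — and ensembles of
120 frames for pipeline demonstrations or 400 frames for parameter
recovery, where each probability is recovered within three binomial
standard errors.

Two honest limitations of this emulation. First, only scheduled spans move;
loops never re-randomize, so absolute RMSF values are dominated by
lever-arm geometry rather than local wiggling, and the meaningful RMSF
property is the contrast "always-ordered span fluctuates less than the
rest of the chain", which holds robustly, rather than span-versus-adjacent-
loop comparisons, which depend on where a rigid block's pivot sits. Second,
the synthetic structures carry ideal geometry — passing tests demonstrate
that the analysis rules are implemented correctly and are mutually
consistent, not that they would reproduce numbers derived from relaxed,
force-field-sampled models, which were never deposited for this protein
family. Interface distances printed in the original reports are therefore
checked as *rule behavior* (boundary tests at cutoff +- 0.01 Angstrom, one
engineered contact per category) rather than as numeric targets.

## Numerical choices and degenerate inputs

* Superposition requires at least 3 matched atoms; its correctness is
  checked against a brute-force hierarchical rotation-grid oracle
  (agreement within 1e-3 Angstrom on random 6-point sets, typically 1e-6).
* Score matrices must be symmetric within 1e-6 with a zero RMSD diagonal;
  rotation determinants are +1 within 1e-6.
* Population (not sample) SD is used in the consensus table, matching the
  published aggregation.
* Ranking tie-breaks: mean Z descending, then input order — a total order.
* `sample_frames` with one frame returns the first frame; requesting more
  frames than exist is an error.
* Docking with a chargeless protein yields scores that never exceed zero;
  the zero-variance Z-score null is an error rather than an Inf.
* Problem sizes used by the checks — 400-frame ensembles, 500 poses x 20
  seeds for docking enrichment, 100 oracle trials, 960 sphere points — are
  the package's own balance of statistical resolution against a
  single-CPU run of a few minutes.

## Known limitations

Helix-helix packing analysis, DSSP-grade secondary structure, physics
energy functions, DNA flexibility, reproduction of relaxed mutant contact
distances, and the external predictors whose score tables this package
consumes are all out of scope. The fiber-model DNA is schematic: its
backbone and base templates have plausible radii and stacking distances,
but base-pair hydrogen-bond geometry is not modeled, and groove assignment
is only meaningful for duplexes built by `build_bdna()` in their
construction frame.
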