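---
title: "Methods behind fcmurkit: sequence numbering, melting criteria, interface constraints and the MFI index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind fcmurkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmurkit)
```

`fcmurkit` packages the computational workflow of an interspecies
mutational and structural study of the IgM Fc receptor (FcµR): comparing
the human and mouse Ig-like ligand-binding domains, estimating domain
stability from heating trajectories, screening docked receptor poses
against interface constraints on the IgM-Fc pentamer, and quantifying
flow-cytometry binding screens. This vignette explains the models and
conventions each module uses, why the defaults are what they are, and
what the synthetic-data tests do and do not establish.

## Sequence numbering and alignment

The unit of analysis is the V-set Ig-like domain, but all residue
reporting uses *full-length* numbering counted from the initiator Met of
the complete receptor, because that is how mutants are named in the
experimental literature (E41Q, N66-, N109K, ...). A `protein_seq` stores
the domain residues plus a `numbering_offset`; `anchor_numbering()` sets
the offset from a single unique motif. For the human domain the `KVEG`
A-strand motif anchored at 24–27 fixes the offset at 17, and one anchor
then has to place *every* other landmark correctly — E41/M42, N66,
K79–R83, Y81, N109, the four bridge cysteines 37/49/58/104 and the
R75/D98 salt bridge. The test suite asserts all of these simultaneously:
a single off-by-one anywhere would break the whole set, which makes the
anchor a strong self-check on the parsed sequence.

The printed domain sequences contain typesetting hyphens;
`parse_domain_sequence()` strips hyphens, whitespace and digits. The
resulting lengths (human 108, mouse 107) differ by exactly the known
single-residue deletion in the mouse domain, which is the evidence that
the stripping rule is right.

Alignment is classical global Needleman–Wunsch with Gotoh's affine-gap
recursion, written out in the package rather than delegated, for one
reason: determinism. Substitution scores are BLOSUM62 (taken from
Biostrings), gaps cost `10 + 0.5·L`, and ties in the dynamic program are
broken in a fixed order — diagonal over up over left, match state
preferred — so the emitted alignment is unique and regression-testable.
On sequences of length ≤ 5 the DP is checked against exhaustive
enumeration of all alignments; on the real domain pair the score is
cross-checked against `Biostrings::pairwiseAlignment()` under the same
parameters. Under these defaults the human/mouse domain alignment has
exactly one gap, in the mouse row, at the human-66 column (the missing
mouse CDR2 residue), and 70/108 = 64.8 % column identity — consistent
with the published domain identity of 64 %. Exact reproduction of that
printed figure is not guaranteed, because published per-region
identities use exon-delimited boundaries that may differ from the
modelling sequences by a few flanking residues and the rounding
convention is unstated; `percent_identity()` therefore reports the
unrounded value together with round-half-up and truncated forms, and
the package asserts only the interval [63, 66].

Cysteine classification maps each cysteine of a query sequence through
the alignment to an annotated reference. For the mouse domain against
the human reference this yields four bridged cysteines (the conserved
C37–C104 and C49–C58 bridges) and one free cysteine. Its position is 80
in the mouse receptor's own numbering but 81 in human-aligned column
numbering; both conventions appear in the literature, and the module
reports both (`pos_seq` and `pos_ref`), with human-aligned numbering as
the default reporting convention for cross-species comparison.

CDR boundaries are not precisely defined by sequence alone (CDR1 is
"about five residues"), so `fcmur_regions()` ships configurable ranges
(CDR1 38–42, CDR2 65–66, CDR3 105–110, A strand 24–27, DE loop 79–83)
and refuses configurations that exclude the residues known to matter.

## Melting-temperature estimation

A heating trajectory is an F × 3N coordinate matrix with frame times and
a piecewise-linear `temperature_schedule`. The built-in schedule heats
from −273 °C to −73 °C in 4 ns and then to 127 °C over 200 ns, holding
afterwards; temperatures are carried in kelvin (°C + 273.15, so the
start maps to 0.15 K exactly) and reported in both units.

Two order parameters are computed per frame:

- **Native-contact fraction Q.** The native set is every atom pair
  within a cutoff in the folded reference with at least
  `min_seq_separation = 4` residues between them; the default cutoff is
  4.5 Å for all-heavy-atom models and 8 Å for Cα-only models. A contact
  "remains" while its current distance stays within the cutoff; a
  `λ·reference_distance` retention mode (λ = 1.2) is available because
  conventions differ between analysis packages. The contact definition
  itself is a free parameter of this kind of analysis — published Tm
  tables computed with unstated contact definitions are therefore
  context for this module, not reproduction targets.
- **Radius of gyration.** Unweighted RMS distance to the centroid by
  default (mass weighting optional).

Both profiles are smoothed with a centered moving mean (default 51
frames, shrinking symmetrically at the edges), and Tm is the temperature
at the first crossing — Q falling through 0.8, or Rg rising through
14 Å — with the crossing time interpolated linearly between the
bracketing frames. Whether the threshold is applied to the raw or the
smoothed series is a genuine choice; the smoothed series is used, since
the smoothing exists precisely to suppress single-frame fluctuations
through the threshold. Every estimate reports the temperature span of
one smoothing window at the crossing, which is the natural resolution
limit of the method; crossings after the ramp report the hold
temperature and a `post_ramp` flag. Repeats with no crossing are
*censored*: excluded from the mean/SD but counted, because there is no
principled way to impute a Tm for a run that never melted.

Group contrasts use the two-sided pooled-variance Student's t-test, with
a summary-statistic entry point so published mean/SD/n rows can be
compared directly: human WT 336 ± 5.7 K vs mouse WT 327 ± 5.8 K (n = 5,
native-contacts criterion) gives t = 2.47, df = 8, p ≈ 0.038 — the
marginally significant species difference.

### What the synthetic trajectories establish

`gen_heating_trajectory()` emulates a two-state transition on a
30-residue Cα helix (rise 1.5 Å, twist 100°, radius 2.3 Å). The helix
was chosen because it guarantees a rich i/i+4 contact set at the 8 Å Cα
cutoff, and 30 residues put the folded Rg at ≈ 13.2 Å — below the 14 Å
criterion with margin. Below the programmed `t_melt` frames fluctuate
about the reference with 0.3 Å Gaussian noise; at `t_melt` the model
expands abruptly (programmed Rg jump of +5 Å, i.e. to ≈ 18.2 Å) and then
drifts at 0.05 Å/K, so both criteria cross at the programmed temperature.
Defaults use 2000 frames over the 204 ns ramp, making one smoothing
window span ≈ 5.1 K; recovery tests over seeds 1–20 and programmed
transitions at 320/350/380 K require the median |Tm − T*| within that
span for both criteria (observed ≈ 1.5–1.8 K). This validates the
estimator's bookkeeping — smoothing, crossing detection, time-to-
temperature conversion, censoring — not the physics of any force field:
real unfolding is gradual, partially reversible and pathway-dependent,
and nothing here speaks to whether a particular MD protocol's Tm values
are accurate.

## Docking-pose geometry

Structures are plain atom tables (chain, residue, atom name, element,
coordinates) in the bio3d column dialect, read and written through
bio3d. Interface analysis is residue-granular: residues are in contact
when any heavy-atom pair across the two selections is within the cutoff
(default 5 Å — a surrogate for the interactive visual inspection such
studies typically use, and configurable for that reason).

`check_constraints()` is a gatekeeper for externally produced docking
poses, encoding the constraint vocabulary of the FcµR/IgM-Fc system:
required interface residues (receptor N66, R83, N109; ligand Q510),
forbidden interface residues (E41, M42, Y81), and excluded chains (the
adjacent subunits' chains must contribute no contacts).
`domain_contact_fraction()` implements the "most contacts with Cµ4"
filter as *strictly* greater than 0.75 at residue-pair granularity — a
pose with exactly 75 % Cµ4 contacts fails, which the tests pin down as
the boundary semantics. The glycan filter places a pseudo-glycan sphere
(default 6 Å) at the side-chain tip of the N402-analog site; the
C-terminus filter requires clearance (default 8 Å) plus a half-space
test that the terminal Cα lies on the membrane-facing side of the
receptor, away from the ligand centroid. Clash testing uses a 2.5 Å
heavy-atom threshold. All three thresholds are explicit surrogates for
visual criteria that are never stated numerically in this literature;
they are parameters, not claims.

Pentamer tiling reproduces the superposition argument for site
multiplicity: given a docked receptor pair on one two-chain subunit,
superpose that subunit's Cα set onto each of the other four subunits
(Kabsch least-squares, proper rotations only — reflections are
structurally meaningless and explicitly excluded) and carry the
receptors along, giving 10 placements, each scored for clash and
C-terminus accessibility. On the C5-symmetric synthetic pentamer all 10
are accessible — the "up to ten binding sites" count. The real IgM
pentamer is an asymmetric hexagon with a missing segment; the synthetic
disc is exactly symmetric because symmetry is what makes the placement
count and the sub-1e-6 tiling-consistency invariant exactly checkable.
Asymmetry would add realism but nothing testable.

The affinity calibration is an ordinary least-squares line of log10(Ka)
on docking score, reflecting the approximately linear score–affinity
relationship such docking servers exhibit over Ka ≈ 10⁴–10¹⁰ M⁻¹; it is
generic by necessity, since the identity of any particular calibration
set is not public. The package does not dock: poses, scores and the
pentamer structure are inputs.

## The MFI index

Binding screens mix a GFP⁺ transductant population with GFP⁻ control
cells, stain with a PE-developed probe, and summarise each channel by
its mean fluorescence intensity. The index

$$\mathrm{index} = \frac{\mathrm{PE}_t - \mathrm{PE}_c}{\mathrm{GFP}_t - \mathrm{GFP}_c}$$

subtracts the shared staining background (numerator) and normalises to
transgene expression (denominator). It is invariant to additive
background on either channel and to a common rescaling of all four
MFIs. A non-positive GFP difference means the gate failed to separate
the populations, and the index is deliberately an error rather than a
number. MFIs are arithmetic means by default ("mean fluorescence
intensity" read literally), with a geometric-mean mode because cytometry
practice varies; inputs are assumed compensated, and gating is an input
label, not an algorithm. Replicate indices are summarised as mean ±
sample SD and compared to wild type with the unpaired pooled-variance
Student's t-test (Welch behind a flag), tiered at p < 0.05/0.01/0.001.

The synthetic panel programs index multipliers per construct (defaults:
wild type 1.0; reduced constructs 0.2; the enhanced CDR1 double mutant
2.0; 10 % replicate CV, three replicates — the design scale of such
experiments) and builds records whose expected index equals the
programmed value exactly; at zero CV the identity is exact, which
separates arithmetic errors from Monte-Carlo noise in the tests. Null
panels over 20 seeds check that the t-test's type-I error stays near the
nominal 5 %. What these tests establish is the statistic and its
calibration under the generator's assumptions (log-normal events,
Gaussian replicate effects); real cytometry data add spillover,
autofluorescence and gating ambiguity that the generator deliberately
omits, so passing tests validate the computation, not instrument-level
robustness.

## Numerical and design notes

- Alignment DP ties: diagonal > up > left, match state preferred — the
  published-sequence alignment is pinned as a regression test.
- Gap cost convention: a length-L gap costs `open + ext·L`
  (10 + 0.5·L), matching the Biostrings parameterisation used for the
  cross-check.
- Tm crossing: first smoothed crossing only; later re-entries are
  ignored. Degenerate zero-variance t-tests return p = 1 (equal means)
  or p = 0 with a `degenerate` flag.
- Kabsch degeneracy: fewer than 3 points, or collinear/coincident point
  sets, are errors rather than silently unstable fits.
- Insertion codes in residue references are unsupported (not needed for
  any fixture here); documented limitation.
- All generators require an explicit seed, restore the caller's RNG
  state, and are bit-reproducible; their ground-truth records carry
  everything needed to re-derive expected downstream values without
  rerunning them.
- Problem sizes in the shipped tests (30-residue Cα models, 2000-frame
  trajectories, 20-seed recovery grids, 5000-event tables) were chosen
  as the smallest scales at which every property being asserted is
  comfortably resolved; all scale parameters are arguments.

## Known limitations

- The package evaluates docking poses; it cannot generate them, so its
  verdicts inherit whatever search bias produced the input poses.
- Published Tm tables from MD heating runs depend on force field and
  contact definition; this module reproduces the estimator, not those
  numbers.
- Region identity percentages depend on unpublished exon boundaries;
  only the domain-level identity interval is asserted.
- Cα-only fixtures exercise all geometric operators, but heavy-atom
  behaviour (e.g. side-chain-tip glycan spheres) is only partially
  covered by them; the glycan filter falls back to Cα with a warning on
  such models.
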