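---
title: "Methods: ensemble probes, reweighting and synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble probes, reweighting and synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepensemble)
```

# Scope and model of the data

`pepensemble` treats a peptide conformational ensemble as an ordered set of
frames, each a single chain of residues carrying backbone atoms (N, H, CA,
C, O) and side-chain heavy atoms (or a single centroid proxy). Frames are
assumed to be an equilibrium sample: all ensemble quantities are weighted
averages over frames, with weights either uniform or supplied by WHAM
reweighting of replica-exchange energy records. No kinetic information is
used anywhere.

Residue numbering is preserved from the input (the bundled fixture peptide,
the amino-truncated amyloid-β fragment, uses 10..40), and every sequence
separation |j − i| is computed on these numbers, never on array positions.
Coordinates are in Ångström throughout; angles are degrees in (−180, 180].

# Secondary-structure assignment

External assignment programs are replaced by an in-package
hydrogen-bond-pattern assigner:

1. **H-bond energy.** The Kabsch–Sander electrostatic form
   E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol between an
   amide donor N–H and a carbonyl acceptor C=O, for |i − j| ≥ 2. A bond is
   declared when E < −0.5 kcal/mol; any interatomic distance below 0.5 Å
   clamps E to −9.9 (the conventional floor). Missing amide hydrogens are
   reconstructed at 1.01 Å from N along the direction opposing the bisector
   of C(i−1)→N and CA→N, in the C(i−1)–N–CA plane; the first residue has no
   preceding carbonyl and keeps no reconstructed H.
2. **One bond per donor.** An amide proton donates a single hydrogen bond,
   so each donor keeps only its lowest-energy acceptor. Without this
   constraint, compact random-coil frames accumulate spurious bifurcated
   bonds that inflate helix-like patterns.
3. **Pattern rules.** Two consecutive i→i+4 turns make an α run (residues
   i+1..i+4), i→i+3 a 3₁₀ run, i→i+5 a π run, with priority α > 3₁₀ > π;
   parallel/antiparallel bridge patterns (the standard DSSP conditions, for
   |i − j| ≥ 3) give isolated bridges, and adjacent bridges an extended
   strand. The two chain-terminal residues on each side are never helix —
   the pattern context is insufficient there, matching the edge behavior of
   the classic assigners.
4. **Turns.** Residues covered by an H-bonded 3- or 4-turn, or whose (φ, ψ)
   fall in a declared turn region — φ < 0 with ψ ∈ (−120°, 60°), or φ > 0
   with ψ ∈ (−60°, 90°) — and not already helix or strand, are turns;
   everything else is coil. The dihedral fallback is deliberate: turn
   assignment in the reference programs is generous, and a purely H-bonded
   definition would miss open turns entirely.

The four-state reduction H ∈ {α, 3₁₀, π}, S ∈ {extended, bridge},
T ∈ {turn}, RC ∈ {coil} is what all downstream propensity tables use; the
sub-labels remain available via `assign_states(conf, detail = TRUE)`.

This assigner is a documented approximation, validated on canonical
geometries (ideal α-helix interiors, registered antiparallel strands,
isolated extended chains) rather than against the empirical torsional
potentials of any specific external program.

# Tertiary structure and compactness

A **contact** forms when the geometric centers of two side chains' heavy
atoms (CA for glycine, which has none — a deliberate fallback so the
contact criterion remains total over residues) lie strictly within 6.5 Å,
the approximate onset of side-chain hydration. Contacts with |j − i| ≥ 5
are long-range. The minimum sequence separation for counting contacts is 2:
|j − i| = 1 neighbors are bonded and trivially within cutoff, and no
meaningful contact table lists them. Both cutoff and separation are
configurable. "Stable" contacts use a strict ⟨C(i,j)⟩ > 0.35. The mean
contact count ⟨C⟩ is the weighted mean per-frame count, which equals the
sum of occupancies over i < j.

The **radius of gyration** uses the point set {side-chain mass centers} ∪
{Cα atoms}, unweighted RMS about its mean — note the deliberate asymmetry
with contacts: contacts use geometric centers, R_g uses mass-weighted
centers, because the two probes serve different purposes (packing versus
mass distribution). End-to-end distance is Cα(first)–Cα(last); P(R_g) is a
weighted histogram with 0.5 Å bins, normalized to integrate to 1.

# Backbone dihedral fluctuations

δφ(i) and δψ(i) are circular RMS fluctuations: the weighted circular mean
is taken via the resultant vector, each deviation is wrapped into
(−180, 180], and the weighted RMS of wrapped deviations is returned. This
is a bounded, degree-valued dispersion: it recovers the generating spread
for narrow wrapped normals and tends to 180/√3 ≈ 103.9° for a uniform
circle. The alternative −2·ln(R) circular variance was rejected because it
is unbounded and not in degrees, which would make sequence-averaged values
such as ⟨δψ⟩ ≈ 80–90° impossible to express. Undefined terminal angles
(φ of the first residue, ψ of the last) are excluded from sequence
averages.

# NMR observables

**³J(HN-Hα)** couplings follow the Karplus relation
J = A·cos²(φ − 60°) + B·cos(φ − 60°) + C with three built-in coefficient
sets (Pardi 6.4/−1.4/1.9; Brueschweiler 9.5/−1.4/0.3; Vuister
6.51/−1.76/1.60 Hz). J is averaged per frame, then over frames — not
evaluated at the average φ, which would be wrong for a multimodal
disordered ensemble. The N-terminal residue is excluded: its φ is undefined
in an uncapped chain and distorted by capping groups in a capped one. No
refitting of Karplus coefficients against experiment is performed; the
built-in sets are used as published.

**RDCs** use a steric-obstruction alignment model. The molecule sits
between two parallel obstructing plates at spacing L; for each plate-normal
direction u the accessible fraction is max(0, 1 − h(u)/L), where h(u) is
the molecular extent along u. The alignment tensor is the
accessible-fraction-weighted average of (3·u·uᵀ − I)/2, symmetric and
traceless by construction. Because the steric weight is invariant under
rotation about the plate normal, the full orientation average over SO(3)
reduces exactly to a spherical average: the implementation therefore uses a
deterministic Fibonacci grid of 1152 directions (configurable), and the
rotation-equivariance of the tensor holds to within grid discretization
error (a few × 10⁻³ at 1152 points). Plate spacing defaults to 1.2× the
maximal molecular extent, keeping every orientation partially accessible
while still discriminating shape. The unscaled coupling of a backbone N–H
unit vector e is eᵀ·A·e; the physical prefactor (gyromagnetic ratios, bond
length, alignment strength) is absorbed by the closed-form least-squares
scale s = Σ D_comp·D_exp / Σ D_comp² fitted against experiment, so only the
tensor's shape and orientation matter. The tensor is computed per
conformer and couplings averaged across frames ("global" whole-molecule
alignment per frame); a common-tensor alternative was considered and
rejected as less appropriate for a disordered ensemble whose shape varies
frame to frame.

Agreement metrics — RMSD, Pearson correlation, and Q = √[Σ(D_comp −
D_exp)²/ΣD_exp²] — are evaluated on the shared residue support only;
residues lacking an experimental value are excluded pairwise. For
J-couplings, all combinations of experimental table × Karplus set are
evaluated and summarized as mean ± sd across combinations.

# WHAM reweighting

The binless (sample-based) form of the multi-state reweighting equations is
iterated to self-consistency over the pooled samples:

f_k ← −log Σ_n exp(−β_k E_n) / Σ_m N_m exp(f_m − β_m E_n),

anchored at f_1 = 0, with log-sum-exp stabilization throughout, until
max |Δf_k| < 10⁻⁷ (non-convergence at 10⁵ iterations is an error carrying
the final residual). Binless WHAM was chosen over histogram WHAM because it
has no bin-width hyperparameter and is exact in the zero-width limit.
Weights at a target temperature T are w_n ∝ exp(−β_T E_n)/Σ_m N_m
exp(f_m − β_m E_n), normalized; at a single simulated temperature they
reduce exactly to uniform. k_B = 0.0019872041 kcal/(mol·K). Structural
observables default to 330 K and J/RDC observables to 300 K, the
temperature closest to typical experimental conditions.

Error bars are standard errors across independent trajectories (the
generating protocol provides four); a leave-one-out jackknife alternative
is available. Within a single trajectory, block standard errors over four
contiguous frame blocks stand in for trajectory errors. No
autocorrelation correction is applied — synthetic frames are independent
by construction.

# The synthetic-data generator: what it emulates, and what it does not

The generator stands in for the conformational preferences a force field
would impose, without any physical energy function:

- **Backbones** are built by sequential internal-coordinate (NeRF)
  placement with ideal Engh–Huber-style constants (N–CA 1.458, CA–C 1.525,
  C–N 1.329, C=O 1.231 Å; N-CA-C 111.2°, CA-C-N 116.2°, C-N-CA 121.7°),
  ω fixed at 180° (the fixture peptide contains no proline, so cis peptide
  bonds are not modeled). Rebuilding torsions from the coordinates returns
  the inputs to 10⁻⁶ degrees.
- **Dihedrals** are drawn per residue from a weighted mixture of
  Ramachandran basins (helix −57/−47; strand −135/135; polyproline-II
  −75/145; left-handed turn 60/30) with wrapped-normal spreads. The coil
  preset uses strand 0.35 / ppII 0.45 / turn-L 0.20 at 20° spread. The
  turn-L weight is deliberately the smallest: runs of consecutive
  left-handed draws read as 3₁₀ helix to any pattern assigner, and a
  mixture emulating a genuine random coil must keep such runs rare (the
  preset yields ⟨H⟩ ≈ 0.02, comfortably in the random-coil regime).
- **Side chains** in generated data are a single pseudo-centroid placed
  2.4 Å from CA along the CB direction (L-chirality; omitted for glycine).
  Real PDB inputs keep their full side chains. The contact and R_g
  operations consume only centroids/mass-centers, so this proxy is
  sufficient for them; it is *not* a model of side-chain packing,
  rotamers, or salt-bridge geometry.
- **Contact bias**: frames can be rejection-sampled until a named residue
  pair's centroids fall within the cutoff, with a stated probability per
  frame, enabling contact-recovery tests with a known ground truth.
- **Replica energies** are Gaussian draws per temperature. The default
  pipeline model uses d⟨E⟩/dT = 0.5 kcal/mol/K with sd 16 kcal/mol so that
  adjacent distributions on a four-temperature 300–440 K exponential
  ladder overlap (separation ≈ 1.3 sd), emulating the ~27–29% exchange
  acceptance of a production replica-exchange setup; without overlap WHAM
  is ill-conditioned, exactly as it would be for a real ladder with
  rejected exchanges. For oracle tests, the Gaussian density-of-states
  model g(E) ∝ exp(aE − E²/2s²) gives exact closed forms: E|β ~
  N((a − β)s², s²) and f(β) = −s²(a − β)²/2 + const.
- **Synthetic experiments** compute the observable from a reference
  ensemble via the package's own forward models and add i.i.d. Gaussian
  noise. At zero noise the recovery loop is exact by construction (Q = 0,
  PCC = 1); this validates the plumbing and the scale fit, not the forward
  model's physical accuracy.

Because frames are independent draws, passing tests demonstrate correct
*statistics* (averaging, reweighting, error propagation, pattern
recognition on canonical geometries) — they do not demonstrate that any
real force field's ensemble is reproduced, nor do they validate kinetics,
solvent effects, or side-chain detail absent from the generator.

# Numerical choices and degenerate inputs

- Angles wrap into (−180, 180]; the torsion of collinear points is an
  error, as is an alignment tensor of collinear coordinates.
- Contact and stability comparisons are strict inequalities (< 6.5 Å,
  > 0.35), following the probes' definitions.
- Tie-breaks in contact ranking: equal occupancies order by ascending
  (i, then j).
- PDB coordinates round to 10⁻³ Å (format precision); the writer/reader
  round-trip is tested at that tolerance.
- The similarity ranking between analyzed runs min–max-normalizes each
  RMSD column (helix, turn, δφ, δψ, contact map) across runs and averages
  them; this aggregate is an artifact of the report, kept separate from
  the per-metric outputs, and a zero range in a column contributes zero
  for all runs.
- Degenerate weights (single frame, one-hot) are valid everywhere; block
  error estimates return NA when fewer than two blocks exist.

# Problem sizes

The test suite and the acceptance script use deliberately modest sizes
chosen to exercise every code path with stable statistics: 31-residue
chains, 100–500 frames per ensemble, four replica temperatures, 5000
energy samples per replica for the WHAM oracle, and a 1152-direction
orientation grid. Headline ensemble statistics from microsecond-scale
simulations are not reproducible at these sizes and are not targeted;
the package's claims are the property-based ones listed above.

# Known limitations

- Single chain only; no mmCIF or binary trajectory formats (multi-model
  PDB and plain-text tables are the interchange formats).
- The secondary-structure assigner approximates, but is not, any specific
  external program; empirical torsional-propensity energies and π-bulge
  refinements are out of scope.
- The steric alignment model is purely obstructive: no electrostatic
  (charged-medium) alignment, no dynamic scaling by order parameters.
- WHAM assumes independent frames; no autocorrelation or effective-sample
  -size correction, and no MBAR-style covariance estimates.
- No statistical significance testing between runs in the comparison
  report.
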