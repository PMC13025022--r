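---
title: "Frequency-resolved anharmonic mode analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-resolved anharmonic mode analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freseanr)
```

# The problem

Protein function frequently involves reversible transitions between
conformational states. The collective motions that carry such transitions
live at very low vibrational frequencies — tens of wavenumbers and below —
where the dynamics is diffusive and anharmonic, so harmonic normal modes
(curvature of a single minimum) and quasiharmonic/PCA modes (eigenvectors
of a displacement covariance matrix) are poor descriptors: the former
assume a linear restoring force that does not exist at zero frequency, the
latter converge only when the slow motions they try to describe have been
sampled many times over.

FRESEAN (frequency-selective anharmonic) mode analysis takes a different
route. It asks, *at a chosen frequency*, which collective degrees of
freedom contribute most to the vibrational density of states (VDoS), using
only short-time velocity correlations. At zero frequency the leading six
eigenvectors are rigid-body translation and rotation of the whole
molecule; the following modes are the anharmonic low-frequency vibrations,
ranked by their zero-frequency spectral power. Because the estimate
averages over thousands of fast oscillations rather than waiting for rare
excursions, it is reproducible from nanosecond-scale trajectories — which
is what makes these modes usable as collective variables (CVs) for
enhanced sampling.

# The pipeline

## Coarse-graining and alignment

Spectral analysis operates on a reduced representation: one bead for each
glycine and two beads (backbone / sidechain) for every other residue.
Bead positions and velocities are mass-weighted means of the member atoms,
so bead mass, total mass and total momentum are conserved exactly. The
exact atom partition is a convention the literature leaves open; the
default backbone set is N, CA, C, O with their hydrogens and terminal
oxygens, and the mapping is configurable (`cg_mapping()`).

Each frame is then rotated into a reference coordinate system by weighted
Kabsch superposition (weights default to bead masses), and **velocities
are rotated by the same rotation**. Two consequences of this convention
are worth stating explicitly:

* aligned positions satisfy the rotational Eckart condition exactly
  (the mass-weighted torque of the displacement field about the reference
  vanishes frame by frame) — this is what Kabsch optimality guarantees,
  and it pins the rigid-body subspace of the spectral matrix to the
  reference geometry;
* velocity *angular momentum* is not removed by the rotation (a rotation
  preserves its magnitude). Rigid rotational motion therefore appears,
  correctly, as zero-frequency spectral power inside the six-dimensional
  rigid subspace of the reference geometry rather than being silently
  discarded.

## Velocity cross-correlation and the spectral matrix

For the 3n coarse-grained degrees of freedom the package forms the
mass-weighted velocity cross-correlation matrix

$$C_{ij}(t) = \langle \sqrt{m_i m_j}\; v_i(t_0)\, v_j(t_0+t) \rangle,$$

averaged densely over time origins up to a maximum lag of 2 ps (the
default; at the default 20 fs sampling this is 101 lags), then
time-symmetrized, $C(t) \leftarrow \tfrac12 (C(t) + C(t)^\top)$. Entries
are in amu nm²/ps² = kJ/mol, so at equipartition the diagonal of $C(0)$
is $k_B T$ per degree of freedom — a built-in sanity check used
throughout the tests.

The frequency-domain matrices are computed with a cosine transform of the
symmetrized correlation, tapered by a time-domain Gaussian chosen so that
the implied spectral resolution is a Gaussian window of 10 cm⁻¹ FWHM
(configurable; FWHM rather than σ is the documented choice). The
normalization is one-sided per cm⁻¹:

$$\tilde C(\nu) = 2 c\, \Delta t \Big( C(0) + 2 \sum_{j \ge 1} w_j\,
C(j\Delta t) \cos(2\pi c \nu\, j \Delta t) \Big),$$

with $c$ the speed of light in cm/ps. Under trapezoidal quadrature over
the frequency grid this convention is exactly Parseval-consistent:
integrating a diagonal element over $[0, \nu_{\mathrm{Nyq}}]$ recovers
$C_{ii}(0)$ to machine precision (`spectrum_integral()`), and in the
tests to better than 1% for finite grids. The frequency grid places
$\nu = 0$ on a grid point exactly and refines the grid four-fold relative
to the lag count by default.

Only relative spectral intensities matter for mode ranking, so the
normalization choice does not affect which modes are selected — but it is
documented and checkable, which is why it was chosen.

## Modes, classification, reproducibility

`fresean_modes()` diagonalizes the (real, symmetric) spectral matrix at a
chosen frequency; eigenvalues are each mode's VDoS contribution there and
are sorted descending, with eigenvector signs fixed by making the
largest-magnitude component positive so replicas can be compared
directly. `classify_rigid_modes()` projects each mode onto the analytic
six-dimensional mass-weighted translation/rotation basis at the reference
geometry (rotations built as $r \times \hat e_\alpha$ and Gram–Schmidt
orthonormalized against translations) and flags overlaps above 0.8.

Mode similarity across replicas uses the absolute inner product for
single modes and RMSIP, $\sqrt{\tfrac1k \sum_{ij} (a_i \cdot b_j)^2}$,
for subspaces. RMSIP is invariant to any orthogonal remixing within
either set — deliberately, because near-degenerate modes (typically 8 and
9) mix freely between replicas without changing the physical subspace.
Both statistics operate in mass-weighted space, consistent with the
eigenproblem; a plain-Cartesian option exists for comparison with
external tools.

## Collective variables and PLUMED export

A mode CV is evaluated in four steps: align the frame to the reference,
coarse-grain, form displacements relative to the reference, project onto
the mode. The projection is mass-weighted by default
($\sum_i \sqrt{m_i}\, \Delta r_i \cdot e_i$, units nm·amu^½), consistent
with the space the eigenvectors live in. Two exact properties make these
CVs usable for biasing, and both are enforced by tests: invariance under
rigid motion of the input frame (the alignment absorbs it), and exact
linearity along the mode direction — exact because modes orthogonal to
the rigid subspace leave the Kabsch rotation at identity for displaced
frames (the cross-covariance stays symmetric).

`write_plumed_input()` emits one *valid realization* of this CV for
PLUMED: `FIT_TO_TEMPLATE` (OPTIMAL) alignment against an emitted
reference PDB, per-bead `CENTER`/`POSITION` actions and a `COMBINE`
projection whose coefficients are written at full precision, plus a
`METAD` action over the two CVs. The mechanism used by production
simulations is not prescribed by the method; this realization was chosen
because every coefficient survives the text round-trip, so the package
can re-parse its own output and verify agreement with the internal
evaluator to 1e-6 (in practice, exactly). Computing bias forces through
the alignment Jacobian is the external engine's responsibility.

## Metadynamics post-processing

The post-processing side consumes PLUMED-dialect COLVAR/HILLS text files.
Reweighting to the unbiased ensemble defaults to the final-bias
estimator, $w_i \propto \exp(+V_{\mathrm{bias}}(s_i,
t_{\mathrm{end}})/k_BT)$, discarding the first 20% of the deposition time
as a transient; a Tiwary–Parrinello-style time-dependent estimator (with
the $c(t)$ offset evaluated on a CV grid) is selectable. Both recover an
analytic double-well free energy to well within 1 $k_BT$ in the tests;
the final-bias scheme is the default because it is simpler and its error
on the toy systems is smaller than the sampling noise.

Free-energy surfaces are weighted histograms, $F = -k_BT \ln P$, gauge-
fixed to min 0. Binning defaults to 50 bins per dimension over the
data range padded 5%; bins with fewer than 5 *effective* samples (Kish
effective sample size of the weights in the bin) are masked in $F$ and
excluded from entropy calculations, while the probability array keeps
raw values so replica averaging stays unbiased. Replica averaging
averages probabilities — not free energies — and reports per-bin
standard deviations of gauge-fixed replica surfaces (the uncertainty of
a single run) and SEM = std/√R.

Information metrics follow the standard definitions: Shannon entropy
$S_2 = -\sum p \log_2 p$ in bits over occupied bins (renormalized), and
the Bhattacharyya coefficient $\sum \sqrt{p_a p_b}$; both are validated
against closed forms (8.000 bits for uniform-256; $e^{-1/2} \approx
0.6065$ for unit Gaussians two standard deviations apart). The
minimum free-energy path is the lowest-maximum (minimax) path on the
8-connected grid graph, found by a Dijkstra-style search with cumulative
free energy as tie-break; a steepest-descent string method is a
deliberate non-goal.

# The synthetic-data generators

Every stage above is validated against generators with analytic ground
truth, integrated with a BAOAB Langevin splitting (stable configurational
sampling at moderate steps; exact Ornstein–Uhlenbeck velocity update).
Units are GROMACS-style throughout (nm, ps, amu, kJ/mol, K;
$k_B = 0.0083144621$), and all randomness flows from one explicit seed.

* **Harmonic bead–spring networks** — distance springs whose rest lengths
  default to the input geometry (elastic-network convention), with
  analytic Hessian and normal modes. These are the oracle for the
  spectral pipeline: resonance-frequency FRESEAN modes must match the
  analytic eigenvectors.
* **Rigid-body diffusion** — OU-process centre-of-mass and body-frame
  angular velocities with equipartition variances; orientations
  propagated by exact rotation maps, so intra-body distances are
  conserved to round-off. Euler coupling between principal axes is
  neglected (the generator emulates thermal diffusion, not gyroscopic
  dynamics). This is the oracle behind the six-rigid-mode count.
* **Two-state systems** — a tethered bead cloud with a symmetric quartic
  double well of configurable barrier (in $k_BT$) along one declared
  collective direction; at zero barrier the well degenerates to a
  unimodal quartic. The declared direction is exactly the displacement
  between the minima.
* **Toy well-tempered metadynamics** — Langevin dynamics on analytic 1D/2D
  potentials with grid-accumulated Gaussian bias and well-tempered height
  scaling $h\,e^{-V/(\gamma-1)k_BT}$, emitting COLVAR/HILLS in the PLUMED
  dialect. With zero height it reduces to unbiased sampling whose CV
  histogram matches direct Boltzmann integration (KS < 0.05 at 10⁵
  samples); at long times the deposited bias converges to
  $-(1-1/\gamma)F + \mathrm{const}$.

What these generators do *not* emulate about real proteins: solvent
friction memory (the noise is Markovian), chemical detail in the
coarse-grained beads, rugged multi-minimum landscapes, and the broad
near-degenerate low-frequency spectrum of a large protein. Passing tests
therefore demonstrate correctness of the estimators and transforms under
controlled conditions, not that any particular protein's modes are
converged.

# Problem sizes and numerical choices

The validation suite uses desk-scale systems chosen so each property is
measured in seconds to a couple of minutes: 2–10 beads; 10⁵–10⁶ Langevin
steps; replica-reproducibility runs covering ≥ 2000 oscillation periods
of the slowest designed mode; five replicas for surface averaging. These
sizes give sampling noise comfortably below each asserted tolerance
(e.g. per-dof kinetic energy within 3% needs a few thousand effective
samples per dof).

Numerical conventions worth knowing:

* eigen-decompositions use symmetrized inputs and a deterministic sign
  convention; ties in eigenvalue sorting are stable;
* the zero-barrier and zero-temperature edge cases of the generators are
  defined (unimodal quartic; static trajectory) rather than errors;
* degenerate geometries (collinear references) are rejected early, since
  rotations are undefined there;
* text formats (trajectory container, mode files, FES grids) write 17
  significant digits and round-trip bit-exactly; mode files carry a
  version tag and checksum;
* the TRR reader/writer implements the GROMACS big-endian layout with
  single/double precision autodetected from block sizes.

# Known limitations

* All-atom FRESEAN analysis at protein scale is out of scope; the
  implementation is exact but tuned for coarse-grained degrees of
  freedom (the spectral matrix is dense, 3n × 3n per frequency).
* The quasiharmonic/PCA comparison mirrors the method's qualitative
  claim — covariance eigenvectors depend on rare events and reproduce
  worse across replicas — on a synthetic diffusive system with a
  rare-event coordinate; the margin of that ordering depends on the rare
  event statistics and is asserted only as an ordering.
* Reweighting variance grows with bias roughness; the final-bias scheme
  assumes the late-time bias is quasi-static, which the well-tempered
  protocol provides but plain metadynamics would not.
* Multi-walker runs, block-averaging error analysis and surfaces above
  2D are not implemented.
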