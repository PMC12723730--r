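---
title: "Multi-tensor SVD fitting of residual dipolar couplings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-tensor SVD fitting of residual dipolar couplings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Residual dipolar couplings (RDCs) measured on a weakly aligned protein
report on the orientation of internuclear vectors relative to the molecular
alignment frame. For a rigid molecule the coupling between nuclei p and q is

    D_pq = C_pq * sum_ij S_ij cos(a_i) cos(a_j),

with S the symmetric, traceless 3x3 Saupe (alignment) matrix — five
independent elements — and cos(a_i) the direction cosines of the p-q vector.
Given six or more couplings on known coordinates, S is the least-squares
solution of an overdetermined linear system, conventionally solved by
singular value decomposition (SVD).

Multi-domain proteins complicate this picture: when a mobile domain
exchanges between two orientations faster than the alignment timescale but
slower than overall tumbling, the measured couplings are population-weighted
averages over the two conformers. The central estimator of this package,
`rdc_fit()`, therefore accepts either one bond-vector set (classic 5-element
fit) or two matched sets, in which case it solves the stacked N x 10 system
for two population-weighted tensors S'_1 and S'_2 simultaneously. All the
machinery around that estimator — invariant-domain identification across
crystal structures, bond-vector orientation averaging, tensor comparison and
co-alignment, a two-state rotation grid search, quality-factor
cross-validation, pose decomposition, and a noise simulator — is organized
so a two-state interdomain equilibrium can be detected and quantified from
RDCs alone.

## Normalization, weighting and quality factors

Different coupling types have very different intrinsic dipolar strengths.
Before a joint fit, C'N couplings are upscaled eight-fold and CaC' couplings
five-fold (N-H unscaled), bringing all types onto the N-H coupling scale;
the same scales stand in for the dipolar constants in the design matrix
(`design_matrix()` builds rows as scale x geometry / uncertainty). The
effective weight of each equation on the normalized scale is
scale / uncertainty, so precisely measured weak couplings contribute with
appropriately high weight. The fitted tensor is expressed in normalized
coupling units (Hz); `Da = Szz/2` and `Rh = (2/3)(Sxx - Syy)/Szz` follow
the eigenvalue convention `|Szz| >= |Syy| >= |Sxx|`, which keeps the
rhombicity in [0, 2/3].

Fit quality is summarized by

    Q = sqrt( sum(resid^2) / (N Da^2 (4 + 3 Rh^2) / 5) ),

computed on normalized couplings. For two-tensor fits this denominator is
meaningless — the two fitted tensors can be large and nearly opposing while
the couplings stay small — so the RMS-coupling form
`Q_rms = sqrt(sum(resid^2) / sum(D^2))` is used instead (`q_rms` on every
fit object). We read the replacement denominator as staying inside the
square root; the alternative reading (N x RMS as a plain factor) would break
the N-scaling of Q and make values incomparable across data set sizes.

Because a two-tensor fit has ten adjustable parameters, overfitting is
policed by the jackknifed factor `Q_jk`: the fit is repeated N times, each
time omitting one coupling whose deviation is then measured against its
prediction from the remaining data. For linear least squares the
leave-one-out predictions follow exactly from the hat-matrix identity
`resid_loo = resid / (1 - h)`, which depends only on the fitted column
space; the package uses this identity (it is exact, not an approximation,
and is verified against explicit refit loops in the test suite), falling
back to explicit refits at leverages near one. A two-tensor jackknife needs
at least 11 couplings.

## Identifiability of same-axis conformer grids

One structural result shaped several design choices and deserves a full
statement. Suppose the two conformers offered to the two-tensor fit share
one domain's vectors exactly and differ by a rigid rotation of the other
domain's vectors about a single axis — precisely how a rotation grid search
builds its conformer pairs, with the major conformer rotated by R_major and
the minor by R_minor about the tensor co-alignment axis.

Decompose tensor space under rotations about that axis into its m = 0
(axial), |m| = 1 and |m| = 2 blocks. The shared-domain rows constrain
S'_1 + S'_2; the mobile-domain rows constrain S'_1 and S'_2 only through
the rotated combination, and a rotation by an angle r acts on the m-blocks
as a phase m*r. Two consequences follow:

1. **An axial gauge freedom.** The component of the tensors axially
   symmetric about the rotation axis can be moved between the two conformers
   without changing any predicted coupling, so the N x 10 system has rank 9,
   not 10. The minimum-norm SVD solution fixes this gauge by equalizing the
   two axial components (in the element coordinates the solver works in).
   `rdc_fit()` truncates singular values below 1e-8 of the largest, treats
   rank 9 as the expected rank for such pairs, and flags rank below 9
   (e.g. strictly identical conformers) as degenerate.

2. **A flat grid landscape.** For any pair of distinct node rotations the
   block phases are invertible, so every non-degenerate grid node spans the
   *same* nine-dimensional prediction space: the model is a reparametrization
   of "independent tensors for the two domains, constrained to share their
   axial component". Residuals, `q2`, and the jackknifed `q2_jk` (whose hat
   matrix depends only on that space) are therefore node-independent to
   machine precision — a property the test suite asserts directly. The grid
   location (R_major, R_minor) and the populations are not identifiable from
   the couplings alone in this exactly-rigid setting; what varies across the
   grid, and is reported, is the *conditional* decomposition: the population
   map and the degeneracy mask. Structural noise or domain non-rigidity
   breaks the exact equivalence, which is why grids over real crystal-derived
   conformers can show ridge structure that ideal fixtures cannot.

The fixture generator confronts the gauge squarely: `make_fixture()`
defaults its interdomain rotation axis to the *gauge-neutral* axis of its
two ground-truth tensors (`gauge_neutral_axis()`), along which both tensors
have zero axial component in the solver's element metric. With that choice
the minimum-norm solution coincides with the ground truth, and zero-noise
recovery of tensors and populations is exact for every mixing fraction —
the regime the recovery claims refer to. For any other axis the recovered
tensors are exact up to the (physically undetermined) axial trade, and
populations inherit a corresponding small offset.

## Populations and the degeneracy guard

The fractional population of each state is not separately observable: it is
absorbed into the magnitude of each population-weighted tensor. Populations
are therefore apportioned by the generalized degree of order (Frobenius
magnitude) of the two fitted tensors, `p_h = G_h / (G_1 + G_2)`, valid
under the assumption that both states align with equal intrinsic strength
when fully populated. The fixture enforces this assumption in its ground
truth by rescaling its second reference tensor to the first one's
generalized magnitude.

When the two conformers are too similar, the fit compensates with huge,
nearly opposing tensors. Such solutions are rejected by a closed threshold
on the summed alignment magnitudes, `|Da_1| + |Da_2| >= 2 |Da_ref|`, with
`Da_ref` from the single-tensor fit of the same couplings; grid nodes
failing the guard are masked, and a wholly masked grid is an error.

Model selection between one and two states uses the nested
extra-sum-of-squares F-test with (5, N - 10) degrees of freedom and the
Akaike information criterion `N log(RSS/N) + 2k` with k = 5 and 10
(`model_selection()`); a positive AIC difference favors the two-state model.

## Domain identification and vector averaging

`find_invariant_core()` implements a deterministic shrink-and-readmit
variant of largest-common-substructure selection: superpose all structures
on the current residue set's backbone (N, CA, C), drop the residue whose CA
deviates most from the across-structure mean when above the cutoff
(default 0.5 Angstrom), iterate to stability, then re-admit excluded
residues that satisfy the cutoff under the final superposition. The
procedure uses no random numbers, so results are exactly reproducible and
invariant to pre-rotations of the inputs. Two caveats found while testing
on synthetic hinges are worth knowing: residues near the hinge axis of a
pure rotation move little and can legitimately satisfy the cutoff, and
short stretches of a moved domain can be absorbed by a compensating
superposition — both are properties of the selection criterion itself, not
of this implementation, and both disappear when the interdomain
displacement is large compared with the cutoff everywhere.

`prune_by_vector_angle()` applies the second, stricter filter: a peptide
plane is retained only if its N-H, C'-N and CA-C' unit vectors deviate from
their across-structure normalized-mean orientations by a pooled RMS of at
most 5 degrees. We pool over structures *and* vector types; pooling over
structures only would make the threshold depend on how many of the three
vector types carry data for a given plane.

`average_vector_orientations()` then builds the averaged-orientation
reference: every C' of the base structure stays fixed; CA(i-1) and N(i) are
re-positioned along the averaged CA(i-1)-C'(i-1) and C'(i-1)-N(i)
directions from the fixed C'(i-1) at the base's bond lengths, and the amide
H moves with its averaged N-H direction from the new N. Only planes passing
the angular filter are modified. Amide hydrogens themselves are placed by
the standard in-plane bisector construction (`add_amide_hydrogens()`), with
a configurable N-H bond length defaulting to 1.02 Angstrom.

## Pose decomposition

Interdomain pose is reported as closure/twist/bend angles in a fixed
analysis frame (`define_ctb_axes()`): twist along the line of domain
centers of mass, closure the perpendicular component of the axis that
rotates the reference's mobile domain onto the closed reference's (so that
closing motions are positive), bend their cross product. A target's
mobile-domain rotation — extracted by two least-squares superpositions
(Kabsch, proper rotations only) — is factored as sequential rotations about
closure, then twist, then bend (`pose_ctb()`, bend applied first). The
composition order is a convention; it is pinned down operationally by the
package's own round-trip property (construct a pose from three angles,
decompose, recover the angles to 0.02 degrees over the +/-40 degree range)
rather than by an external reference. Near twist = +/-90 degrees the outer
angles merge (gimbal lock); the sum is then reported as closure with a
warning. Note the stated axes make (closure, twist, bend) a left-handed
triple; the factorization works in the right-handed companion basis and
negates the third angle, so all reported angles are rotations about the
stated axes.

## The simulator and what passing tests show

`synth_rdcs()` generates population-weighted couplings with Gaussian noise
of standard deviation sigma_RDC added on the normalized scale;
`cone_noise()` perturbs bond vectors by a tilt drawn from the density
sin(b) exp(-b^2/sigma_cone^2) with uniform azimuth, via a tabulated
1000-point inverse CDF over the effective support (deterministic draw count
per seed). `recovery_study()` sweeps mixing fraction and both noise sources,
refits, and tabulates recovered populations, tensor similarity
P(S_fit, S_ref) and fit quality; degenerate fits are flagged and excluded
from summaries. Structural noise is applied to the *fitting* coordinates,
i.e. it models errors in the reference structures rather than in the data.

Default conditions: 100 bond vectors per domain (coupling types cycling
NH, C'N, CaC'), a 30-degree interdomain rotation, and the shipped reference
tensors for the open and closed states of maltose-binding protein
(dimensionless elements of order 1e-3, printed layout
[Szz, Sxx-Syy, Sxy, Sxz, Syz]); for simulation in physical units they are
multiplied by the N-H dipolar constant (21.7 kHz), giving alignment
magnitudes near 10-20 Hz, typical of weak steric alignment. Noise levels
sigma_RDC in {0, 0.5, 1} Hz bracket realistic measurement error for
normalized backbone RDCs, and sigma_cone in {0, 4, 8} degrees brackets the
bond-vector orientation error of good crystal structures. Acceptance-scale
runs use 20 trials per cell and N = 800 couplings for the jackknife
convergence check; these sizes were chosen so the full suite exercises
every stochastic claim at useful power while remaining desk-scale.

What the fixture does *not* emulate: real peptide-plane geometry and its
correlated vector orientations within a plane, linker residues whose bond
vectors straddle domains (those are pivot-dependent and are excluded from
rigid-rotation reasoning), per-residue variation in measurement error, and
any deviation of the two states' intrinsic alignment magnitudes from
equality. Passing tests therefore demonstrate the estimator's correctness
and its noise response under the stated model, not the accuracy of any
particular experimental analysis.

## Numerical choices

* Minimum-norm SVD least squares with relative singular-value cutoff 1e-8;
  rank and condition number are reported on every fit.
* Eigenframe sign convention: largest-magnitude component positive on the z
  and y eigenvectors, x = y cross z — keeps Monte-Carlo eigenframe
  comparisons free of spurious 180-degree jumps.
* Tensor co-alignment (`coalign_domain()`) minimizes the 5D angle between
  tensors by Nelder-Mead over (Rx, Ry, Rz), started at zero, tolerance
  0.01 degrees; RDC fits see only orientations, so no pivot enters.
* The axis-angle extraction uses the antisymmetric part away from 180
  degrees and the symmetric-part eigenvector at 180; the identity reports
  +z with angle 0.
* Grid defaults: R_major step 0.5 degrees, R_minor step 2.5 degrees;
  sigma(delta Q) by delete-one jackknife using the exact RSS downdate.
* Every stochastic operation takes an explicit integer seed.

## Limitations

Three-or-more-conformer fitting is deliberately not exposed: the linear
algebra generalizes, but backbone RDC data rarely determine more than two
states, and the gauge analysis above only sharpens that caution. Absolute
populations require the equal-intrinsic-alignment assumption (or external
knowledge of the 100%-state tensors). The grid search's node selection is
meaningful only insofar as non-rigidity breaks the same-axis equivalence;
on ideally rigid synthetic input its delta-Q surface is flat by theorem,
and the package reports it as such rather than manufacturing an optimum.
mmCIF input, sequence alignment across differently numbered constructs,
and ensemble rebuilding of linkers are out of scope.
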