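# rdcsvd

Multi-tensor SVD fitting of residual dipolar couplings (RDCs) for
quantifying protein domain motion.

RDCs measured on a weakly aligned protein constrain the orientations of
internuclear vectors through the Saupe alignment tensor **S** — a symmetric,
traceless 3x3 matrix with five independent elements:

    D_pq = C_pq * sum_ij S_ij cos(a_i) cos(a_j)

For a rigid structure, **S** is the least-squares solution of an
overdetermined linear system (one row per coupling), solved here by
minimum-norm SVD. For a multi-domain protein exchanging rapidly between two
conformations, measured couplings are population-weighted averages; the same
linear machinery then solves an N x 10 system for two population-weighted
tensors **S**'_1, **S**'_2 at once. From their generalized magnitudes the
state populations follow (under an equal-intrinsic-alignment assumption),
and a rotation grid search over candidate conformer pairs — guarded against
degenerate solutions by a threshold on the summed tensor magnitudes — maps
out a two-state interdomain equilibrium, such as the minor partially closed
state of apo maltose-binding protein.

The package is organized around one fitting function, `rdc_fit()`, which
returns a classed object with `print`, `summary`, `coef`, `predict`,
`residuals`, `plot` and `simulate` methods. Around it:

* `read_pdb()`, `write_pdb()`, `add_amide_hydrogens()`,
  `extract_bond_vectors()`, `read_rdc_table()` — structure and coupling I/O
  (PDB parsing through bio3d), amide proton placement, unit bond vectors.
* `find_invariant_core()`, `prune_by_vector_angle()`,
  `average_vector_orientations()` — rigid-domain identification across
  crystal structures and structural-noise reduction by orientation
  averaging.
* `q_factor()`, `q_jackknife()` — quality factors, including the
  cross-validated Q_jk computed by the exact leave-one-out identity.
* `compare_tensors()`, `coalign_domain()`, `rotation_grid_q()`,
  `tensor_orientation_uncertainty()` — alignment-frame comparison (5D
  angle), co-alignment of a mobile domain, and Monte-Carlo frame
  uncertainty.
* `grid_search_two_state()`, `model_selection()`, `degeneracy_guard()` —
  the two-state (R_major, R_minor) grid search with masking, F-test and AIC
  model comparison.
* `superpose()`, `define_ctb_axes()`, `pose_ctb()`, `rotate_domain()` —
  Kabsch superposition and the closure/twist/bend decomposition of
  interdomain pose.
* `make_fixture()`, `synth_rdcs()`, `cone_noise()`, `recovery_study()` —
  a fully synthetic two-domain fixture and the noise-sensitivity simulator
  (Gaussian coupling noise, cone-distributed bond-vector noise).

A thin command-line wrapper with `fit`, `fit2`, `domains`, `pose`, `grid`
and `simulate` subcommands ships at `inst/cli/rdcsvd.R`.

## Worked example

Simulate a two-domain protein whose minor (16%) conformer differs by a
30-degree domain rotation, with 0.5 Hz measurement noise, then compare a
single-tensor and a two-tensor fit:

```r
library(rdcsvd)

fx <- make_fixture(seed = 1)                    # 100 + 100 bond vectors
rd <- synth_rdcs(fx$conformer1, fx$conformer2, fx$tensors,
                 p_minor = 0.16, sigma_rdc = 0.5, seed = 2)

single <- rdc_fit(rd, fx$conformer1)
single
#> Single-tensor RDC fit: N = 200 couplings
#>   Q = 0.0657   Q_jk = 0.0675   Q_rms = 0.0654
#>   tensor 1: Da = 16.614, Rh = 0.1222

two <- rdc_fit(rd, list(fx$conformer1, fx$conformer2))
two
#> Two-tensor RDC fit: N = 200 couplings
#>   Q = 0.0360   Q_jk = 0.0378   Q_rms = 0.0360
#>   tensor 1: Da = 14.664, Rh = 0.0610
#>   tensor 2: Da = 2.6048, Rh = 0.4269
#>   populations (equal-alignment assumption): 0.841 / 0.159

model_selection(single, two)
#> F = 87.24 on (5, N-10) df, one-sided significance 2.59e-47
#> AIC(single) = 2.752, AIC(two-state) = -225.773, delta = 228.524
#> preferred model: two-state
```

The single-tensor fit leaves structured residuals (Q = 0.066, against a
noise floor near 0.03); the two-tensor fit reaches that floor, recovers the
minor-state population (15.9% fitted vs 16% simulated), and both the F-test
and AIC prefer the two-state model. The major-state tensor's
`Da = 14.7 Hz, Rh = 0.06` matches the 84%-weighted reference alignment, and
the jackknifed Q_jk staying close to Q shows the ten-parameter fit is not
overfitting these 200 couplings.

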