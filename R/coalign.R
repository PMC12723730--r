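# Alignment-frame co-alignment of a mobile domain, the rotation grid check,
# and the Monte-Carlo tensor-orientation uncertainty.

#' Co-align a mobile domain's alignment frame with a reference tensor
#'
#' Finds small Cartesian rotations (Rx, Ry, Rz), applied to the mobile
#' domain's bond vectors, that minimize the five-dimensional angle between
#' the alignment tensor refitted from the rotated domain's couplings and a
#' reference tensor (typically the other domain's fit). RDC fits depend only
#' on orientations, so the rotation pivot is irrelevant. The optimizer is a
#' derivative-free Nelder-Mead simplex started at (0, 0, 0).
#'
#' @param rdcs `rdc_table`; only couplings of `mobile_residues` enter the
#'   refits.
#' @param vectors `bond_vector` table for the whole structure.
#' @param mobile_residues residues of the mobile domain.
#' @param reference_tensor `saupe_tensor` to co-align with.
#' @param tol convergence tolerance on the 5D angle, degrees (default 0.01).
#' @return list: `rotation_xyz` (degrees about x, y, z), `rotation` (3x3),
#'   `axis`, `angle`, `phi`, `psi` (single equivalent axis-angle),
#'   `angle_5d` (residual 5D angle, degrees), `vectors` (the co-aligned
#'   bond-vector table), `fit` (mobile-domain fit after rotation).
#' @export
coalign_domain <- function(rdcs, vectors, mobile_residues, reference_tensor,
                           tol = 0.01) {
  sub_rdc <- rdcs[rdcs$resno %in% mobile_residues, , drop = FALSE]
  sub_vec <- vectors[vectors$resno %in% mobile_residues, , drop = FALSE]
  obj <- function(ang) {
    v <- rotate_vectors(sub_vec, rotation_xyz(ang[1], ang[2], ang[3]))
    f <- rdc_fit(sub_rdc, v, jackknife = FALSE)
    compare_tensors(f$tensors[[1]], reference_tensor)$angle_5d
  }
  opt <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 2000))
  if (opt$convergence != 0 && opt$value > tol)
    warning("co-alignment did not converge below ", tol,
            " deg; residual 5D angle ", format(opt$value))
  R <- rotation_xyz(opt$par[1], opt$par[2], opt$par[3])
  aa <- axis_angle(R)
  out_vec <- rotate_vectors(vectors, R, residues = mobile_residues)
  fit <- rdc_fit(sub_rdc,
                 out_vec[out_vec$resno %in% mobile_residues, , drop = FALSE],
                 jackknife = FALSE)
  list(rotation_xyz = opt$par, rotation = R, axis = aa$axis,
       angle = aa$angle, phi = aa$phi, psi = aa$psi,
       angle_5d = opt$value, vectors = out_vec, fit = fit)
}

#' Single-tensor Q over a grid of mobile-domain rotations
#'
#' Systematic check that a co-aligned reference structure is optimal: the
#' mobile domain is rotated over a 3D grid of x, y, z rotations and the
#' single-tensor Q of the full coupling set recorded at each node.
#'
#' @param rdcs `rdc_table`.
#' @param vectors co-aligned `bond_vector` table.
#' @param mobile_residues residues of the mobile domain.
#' @param half_range half-width of the grid in degrees (default 5).
#' @param step grid step in degrees (default 1).
#' @return data.frame `rx, ry, rz, q` with attribute `"argmin"` (the row of
#'   the minimum).
#' @export
rotation_grid_q <- function(rdcs, vectors, mobile_residues,
                            half_range = 5, step = 1) {
  g <- seq(-half_range, half_range, by = step)
  grid <- expand.grid(rx = g, ry = g, rz = g, KEEP.OUT.ATTRS = FALSE)
  grid$q <- vapply(seq_len(nrow(grid)), function(i) {
    v <- rotate_vectors(vectors,
                        rotation_xyz(grid$rx[i], grid$ry[i], grid$rz[i]),
                        residues = mobile_residues)
    rdc_fit(rdcs, v, jackknife = FALSE)$q
  }, 0)
  attr(grid, "argmin") <- grid[which.min(grid$q), ]
  grid
}

#' Monte-Carlo uncertainty of the alignment-frame orientation
#'
#' Adds Gaussian noise at the per-coupling uncertainty (on the normalized
#' scale; the residual RMS when uncertainties are absent or uniform at 1) to
#' the measured couplings, refits the tensor, and measures the rotation
#' angle between the perturbed and unperturbed eigenframes. The RMS angle
#' over trials estimates the orientational uncertainty of the alignment
#' frame.
#'
#' @param rdcs `rdc_table`.
#' @param vectors `bond_vector` table.
#' @param n_trials number of Monte-Carlo trials (>= 10).
#' @param seed integer seed.
#' @return RMS eigenframe rotation angle in degrees; attribute `"angles"`
#'   carries the per-trial angles.
#' @export
tensor_orientation_uncertainty <- function(rdcs, vectors, n_trials = 100,
                                           seed = 0) {
  if (n_trials < 10) stop("need at least 10 trials")
  set.seed(seed)
  fit0 <- rdc_fit(rdcs, vectors, jackknife = FALSE)
  sd_norm <- rdcs$scale * rdcs$uncertainty
  if (all(rdcs$uncertainty == 1))
    sd_norm <- rep(sqrt(mean(fit0$residuals^2)), nrow(rdcs))
  angles <- vapply(seq_len(n_trials), function(k) {
    r2 <- rdcs
    noise <- stats::rnorm(nrow(rdcs), sd = sd_norm)
    r2$value <- r2$value + noise / r2$scale
    f <- rdc_fit(r2, vectors, jackknife = FALSE)
    dR <- t(fit0$tensors[[1]]$eigenframe) %*% f$tensors[[1]]$eigenframe
    axis_angle(dR)$angle
  }, 0)
  out <- sqrt(mean(angles^2))
  attr(out, "angles") <- angles
  out
}
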