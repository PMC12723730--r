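# Two-conformer model assessment: populations, degeneracy guard, nested
# F-test / AIC model selection, and the (R_major, R_minor) rotation grid
# search for a two-state interdomain equilibrium.

#' Populations from a pair of fitted conformer tensors
#'
#' Apportions fractional populations by the generalized degree of order of
#' the two population-weighted tensors, `p_h = G_h / (G_1 + G_2)`. Valid
#' only under the assumption that both states align with roughly equal
#' intrinsic strength when fully populated; the returned vector carries
#' this as attribute `"assumes_equal_alignment"`.
#'
#' @param fit an `rdc_fit2` (or list of two `saupe_tensor`s).
#' @return length-2 numeric vector summing to 1.
#' @export
tensor_populations <- function(fit) {
  tensors <- if (inherits(fit, "rdc_fit")) fit$tensors else fit
  g <- vapply(tensors, generalized_order, 0)
  if (sum(g) == 0) stop("both tensors are zero; populations undefined")
  out <- g / sum(g)
  attr(out, "assumes_equal_alignment") <- TRUE
  out
}

#' Degeneracy guard for a two-tensor fit
#'
#' A two-tensor fit of conformers that are too similar is ill-posed: the
#' solver compensates with very large, nearly opposing tensors. The guard
#' rejects (returns TRUE) whenever the summed alignment magnitudes reach
#' twice the reference single-tensor magnitude:
#' `|Da_1| + |Da_2| >= 2 |Da_ref|` (closed threshold).
#'
#' @param fit an `rdc_fit2`.
#' @param reference_da single-tensor reference alignment magnitude
#'   (default: the one stored in the fit).
#' @return logical flag; TRUE means reject.
#' @export
degeneracy_guard <- function(fit, reference_da = fit$reference_da) {
  das <- vapply(fit$tensors, function(t) abs(t$da), 0)
  sum(das) >= 2 * abs(reference_da)
}

#' Single- versus two-conformer model selection
#'
#' Nested extra-sum-of-squares F-test (5 extra parameters, N - 10 residual
#' degrees of freedom) and Akaike information criterion comparison of a
#' single-tensor and a two-tensor fit of the same couplings. AIC is
#' `N log(RSS / N) + 2k` with k = 5 and 10; `aic_delta = AIC_single -
#' AIC_two`, positive when the two-state model is preferred.
#'
#' @param single an `rdc_fit` (one conformer).
#' @param two an `rdc_fit2` on the identical coupling set.
#' @return object of class `rdc_model_selection`: `f_statistic`,
#'   `f_significance` (one-sided p-value), `aic_single`, `aic_two`,
#'   `aic_delta`, `preferred`.
#' @export
model_selection <- function(single, two) {
  if (single$n_rdc != two$n_rdc ||
      !isTRUE(all.equal(single$measured, two$measured)))
    stop("model selection requires identical coupling sets")
  n <- single$n_rdc
  if (n <= 10) stop("need more than 10 couplings")
  rss1 <- sum(single$residuals^2)
  rss2 <- sum(two$residuals^2)
  f <- ((rss1 - rss2) / 5) / (rss2 / (n - 10))
  sig <- stats::pf(f, 5, n - 10, lower.tail = FALSE)
  aic1 <- n * log(rss1 / n) + 2 * 5
  aic2 <- n * log(rss2 / n) + 2 * 10
  out <- list(f_statistic = f, f_significance = sig,
              aic_single = aic1, aic_two = aic2,
              aic_delta = aic1 - aic2,
              preferred = if (aic1 - aic2 > 0) "two-state" else "single")
  class(out) <- "rdc_model_selection"
  out
}

#' @export
print.rdc_model_selection <- function(x, ...) {
  cat(sprintf("F = %.4g on (5, N-10) df, one-sided significance %.3g\n",
              x$f_statistic, x$f_significance))
  cat(sprintf("AIC(single) = %.3f, AIC(two-state) = %.3f, delta = %.3f\n",
              x$aic_single, x$aic_two, x$aic_delta))
  cat("preferred model:", x$preferred, "\n")
  invisible(x)
}

# delta-Q jackknife: delete-one residual sums of squares for both models
# via the exact downdate RSS_(-i) = RSS - e_i^2 / (1 - h_i) (weighted
# residuals e and leverages h), giving the jackknife standard error of
# (Q_rms_single - Q_rms_two) in O(N) after two SVDs
delta_q_jackknife_se <- function(rdcs, vectors1, vectors2) {
  mt <- match_rdc_vectors(rdcs, list(vectors1, vectors2))
  d <- mt$rdcs
  n <- nrow(d)
  w <- d$scale / d$uncertainty
  dnorm <- d$scale * d$value
  b <- w * dnorm
  G1 <- design_geometry(mt$dirs[[1]])
  G12 <- cbind(G1, design_geometry(mt$dirs[[2]]))
  # exact delete-one refit residuals at every row from the projection
  # downdate: with weighted hat H and weighted residual e = -w r,
  # r_j^(-i) = r_j + H[j, i] w_i r_i / ((1 - h_i) w_j); valid for
  # minimum-norm (rank-deficient) fits since only the column space enters
  unw_rss_loo <- function(G) {
    A <- G * w
    sv <- svd(A)
    keep <- sv$d > 1e-8 * max(sv$d)
    U <- sv$u[, keep, drop = FALSE]
    x <- sv$v[, keep, drop = FALSE] %*% ((t(U) %*% b) / sv$d[keep])
    r <- drop(G %*% x) - dnorm
    H <- tcrossprod(U)
    h <- pmin(diag(H), 1 - 1e-12)
    Rloo <- r + H * rep(w * r / (1 - h), each = n) / w
    colSums(Rloo^2) - diag(Rloo)^2       # sum over j != i
  }
  den_i <- sum(dnorm^2) - dnorm^2
  dq_i <- sqrt(pmax(unw_rss_loo(G1), 0) / den_i) -
    sqrt(pmax(unw_rss_loo(G12), 0) / den_i)
  sqrt((n - 1) / n * sum((dq_i - mean(dq_i))^2))
}

#' Two-state rotation grid search
#'
#' Searches a 2D grid of conformer pairs for the two-state interdomain
#' equilibrium best fitting the couplings. The major conformer rotates the
#' mobile domain's bond vectors by `r_major` degrees about `axis` (the
#' tensor co-alignment axis); the minor conformer by `r_minor`. At each
#' grid node a two-tensor fit is performed and its RMS-normalized quality
#' factor `q2`, the drop `delta_q` relative to the single-tensor fit of the
#' unrotated reference, the minor-state population, and the degeneracy flag
#' are recorded. Degenerate nodes (summed tensor magnitudes at least twice
#' the reference, or rank deficiency when the two rotations coincide) are
#' masked and excluded from the optimum, which is the unmasked node with
#' the largest `delta_q`; ties within `1e-10` of the maximum are broken by
#' smaller `q2_jk`, then smaller `sum_da_ratio`, then smaller `r_minor`.
#' The jackknife uncertainty `sigma(delta_q)` is computed at the optimum
#' (and for all nodes when `sigma_all = TRUE`).
#'
#' An identifiability caveat applies to exactly rigid inputs: when both
#' conformers at every node are rotations of one common vector set about
#' one common axis, all non-degenerate nodes span the same prediction
#' space, so `q2`, `q2_jk` and `delta_q` are node-independent and the grid
#' location is determined only up to that equivalence — the landscape is
#' flat and the informative outputs are the population map and the
#' degeneracy mask. Structural noise or domain non-rigidity breaks the
#' equivalence; see the package vignette for the full argument.
#'
#' @param rdcs `rdc_table`.
#' @param vectors co-aligned reference `bond_vector` table.
#' @param mobile_residues residues of the mobile (rotated) domain.
#' @param axis unit rotation axis (length-3).
#' @param major_range length-2 range of `r_major` in degrees.
#' @param minor_range length-2 range of `r_minor` in degrees.
#' @param major_step,minor_step grid steps in degrees (defaults 0.5, 2.5).
#' @param sigma_all compute the jackknife `sigma(delta_q)` at every node
#'   (costly) instead of only at the optimum.
#' @return object of class `rdc_grid`: `grid` data.frame
#'   (`r_major, r_minor, q2, delta_q, delta_q_sigma, delta_q_norm,
#'   p_minor, sum_da_ratio, degenerate`), `optimum` (one row, plus the
#'   optimum's `fit`), `q_single` (reference single-tensor fit q_rms),
#'   `reference_fit`.
#' @export
grid_search_two_state <- function(rdcs, vectors, mobile_residues, axis,
                                  major_range = c(-3, 2),
                                  minor_range = c(5, 90),
                                  major_step = 0.5, minor_step = 2.5,
                                  sigma_all = FALSE) {
  ref_fit <- rdc_fit(rdcs, vectors, jackknife = FALSE)
  q_single <- ref_fit$q_rms
  ref_da <- ref_fit$tensors[[1]]$da
  majors <- seq(major_range[1], major_range[2], by = major_step)
  minors <- seq(minor_range[1], minor_range[2], by = minor_step)
  grid <- expand.grid(r_major = majors, r_minor = minors,
                      KEEP.OUT.ATTRS = FALSE)
  rotated <- function(angle) {
    if (angle == 0) vectors
    else rotate_vectors(vectors, rotation_about_axis(axis, angle),
                        residues = mobile_residues)
  }
  cache <- new.env(parent = emptyenv())
  get_rot <- function(angle) {
    key <- format(angle, digits = 12)
    if (is.null(cache[[key]])) cache[[key]] <- rotated(angle)
    cache[[key]]
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    v1 <- get_rot(grid$r_major[i])
    v2 <- get_rot(grid$r_minor[i])
    if (abs(grid$r_major[i] - grid$r_minor[i]) < 1e-9)
      return(list(q2 = NA_real_, q2_jk = NA_real_, p_minor = NA_real_,
                  sum_da_ratio = NA_real_, degenerate = TRUE, fit = NULL))
    f <- suppressWarnings(rdc_fit(rdcs, list(v1, v2), jackknife = TRUE,
                                  reference_da = ref_da))
    list(q2 = f$q_rms, q2_jk = f$q_jk, p_minor = f$populations[2],
         sum_da_ratio = f$sum_da_ratio, degenerate = f$degenerate, fit = f)
  })
  grid$q2 <- vapply(res, `[[`, 0, "q2")
  grid$q2_jk <- vapply(res, `[[`, 0, "q2_jk")
  grid$delta_q <- q_single - grid$q2
  grid$p_minor <- vapply(res, `[[`, 0, "p_minor")
  grid$sum_da_ratio <- vapply(res, `[[`, 0, "sum_da_ratio")
  grid$degenerate <- vapply(res, `[[`, TRUE, "degenerate")
  ok <- which(!grid$degenerate)
  if (length(ok) == 0)
    stop("no resolvable two-state region: entire grid is degenerate")
  grid$delta_q_sigma <- NA_real_
  sigma_at <- function(i) {
    delta_q_jackknife_se(rdcs, get_rot(grid$r_major[i]),
                         get_rot(grid$r_minor[i]))
  }
  if (sigma_all)
    grid$delta_q_sigma[ok] <- vapply(ok, sigma_at, 0)
  best <- max(grid$delta_q[ok])
  tied <- ok[grid$delta_q[ok] >= best - 1e-10]
  o <- order(grid$q2_jk[tied], grid$sum_da_ratio[tied],
             grid$r_minor[tied])
  opt_i <- tied[o[1]]
  if (is.na(grid$delta_q_sigma[opt_i]))
    grid$delta_q_sigma[opt_i] <- sigma_at(opt_i)
  grid$delta_q_norm <- grid$delta_q / grid$delta_q_sigma
  out <- list(grid = grid, optimum = grid[opt_i, , drop = FALSE],
              optimum_fit = res[[opt_i]]$fit, q_single = q_single,
              reference_fit = ref_fit, axis = axis,
              mobile_residues = mobile_residues)
  class(out) <- "rdc_grid"
  out
}

#' @export
print.rdc_grid <- function(x, ...) {
  o <- x$optimum
  cat(sprintf("Two-state grid search: %d nodes (%d degenerate/masked)\n",
              nrow(x$grid), sum(x$grid$degenerate)))
  cat(sprintf("single-tensor reference Q_rms = %.4f\n", x$q_single))
  cat(sprintf(
    "optimum: R_major = %g, R_minor = %g deg, Q2 = %.4f, delta Q = %.4f\n",
    o$r_major, o$r_minor, o$q2, o$delta_q))
  cat(sprintf("         minor population = %.1f%%, delta Q / sigma = %.2f\n",
              100 * o$p_minor, o$delta_q_norm))
  invisible(x)
}

#' Heat-map of a two-state grid search
#'
#' @param x an `rdc_grid`.
#' @param what column to map (default `"delta_q"`).
#' @param ... passed to `image`.
#' @export
plot.rdc_grid <- function(x, what = "delta_q", ...) {
  g <- x$grid
  majors <- sort(unique(g$r_major))
  minors <- sort(unique(g$r_minor))
  z <- matrix(NA_real_, length(majors), length(minors))
  z[cbind(match(g$r_major, majors), match(g$r_minor, minors))] <-
    ifelse(g$degenerate, NA, g[[what]])
  graphics::image(majors, minors, z, xlab = "R_major (deg)",
                  ylab = "R_minor (deg)", main = what,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::points(x$optimum$r_major, x$optimum$r_minor, pch = 1, cex = 2,
                   col = "magenta", lwd = 2)
  invisible(x)
}
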