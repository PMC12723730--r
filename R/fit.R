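# Saupe-tensor SVD fitting of residual dipolar couplings.
#
# Model (normalized couplings): for a unit internuclear vector with direction
# cosines (cx, cy, cz) and tensor elements S = (Syy, Szz, Sxy, Sxz, Syz),
#   d = Syy (cy^2 - cx^2) + Szz (cz^2 - cx^2)
#       + 2 Sxy cx cy + 2 Sxz cx cz + 2 Syz cy cz,
# where d = scale * value is the measured coupling brought onto the N-H
# scale. For a fast-exchanging two-state ensemble the observed coupling is
# the sum of two such terms, one per conformer, with population-weighted
# tensors S'_h: ten unknowns in place of five.

# geometry part of the design row (no scale, no uncertainty)
design_geometry <- function(dirs) {
  cx <- dirs[, 1]; cy <- dirs[, 2]; cz <- dirs[, 3]
  cbind(cy^2 - cx^2, cz^2 - cx^2, 2 * cx * cy, 2 * cx * cz, 2 * cy * cz)
}

#' Design matrix rows for an RDC fit
#'
#' One row per coupling: the five direction-cosine terms multiplied by the
#' per-type normalization scale (standing in for the dipolar interaction
#' constant) and divided by the measurement uncertainty. Dotted with the
#' tensor element vector `(Syy, Szz, Sxy, Sxz, Syz)` a row reproduces the
#' scaled, uncertainty-weighted coupling.
#'
#' @param vectors `bond_vector` table (directions must be unit length).
#' @param scale per-row normalization scale (recycled).
#' @param uncertainty per-row positive uncertainty in Hz (recycled).
#' @return numeric matrix with 5 columns.
#' @export
design_matrix <- function(vectors, scale = 1, uncertainty = 1) {
  dirs <- vector_dirs(vectors)
  nrm <- sqrt(rowSums(dirs^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("bond vectors must be unit length")
  if (any(uncertainty <= 0)) stop("uncertainties must be positive")
  design_geometry(dirs) * (rep_len(scale, nrow(dirs)) /
                           rep_len(uncertainty, nrow(dirs)))
}

#' Back-calculate normalized couplings from a tensor
#'
#' @param vectors `bond_vector` table.
#' @param tensor `saupe_tensor`.
#' @return numeric vector of normalized couplings (units of the tensor).
#' @export
predict_rdc <- function(vectors, tensor) {
  drop(design_geometry(vector_dirs(vectors)) %*%
         as_saupe_tensor(tensor)$elements)
}

# minimum-norm least squares by SVD; returns x, rank, condition number and
# the pieces needed for the exact leave-one-out identity. Singular values
# below tol_rel * max(d) are truncated: this fixes the gauge of exactly
# rank-deficient two-conformer systems (see gauge_neutral_axis) while
# leaving well-determined directions untouched.
svd_lsq <- function(A, b, tol_rel = 1e-8) {
  sv <- svd(A)
  tol <- tol_rel * max(sv$d)
  pos <- sv$d > tol
  dinv <- ifelse(pos, 1 / sv$d, 0)
  P <- sv$v %*% (dinv * t(sv$u))          # pseudo-inverse, p x N
  x <- drop(P %*% b)
  list(x = x, rank = sum(pos),
       condition = if (all(pos)) max(sv$d) / min(sv$d) else Inf,
       pinv = P)
}

#' Quality factor of an RDC fit
#'
#' `Q = sqrt(sum(resid^2) / (N Da^2 (4 + 3 Rh^2) / 5))`, computed on
#' normalized couplings.
#'
#' @param residuals predicted minus measured normalized couplings.
#' @param da alignment magnitude (same units as the residuals).
#' @param rhombicity tensor rhombicity.
#' @return non-negative scalar.
#' @export
q_factor <- function(residuals, da, rhombicity) {
  n <- length(residuals)
  if (n < 1) stop("need at least one residual")
  if (da == 0) stop("q_factor undefined for zero alignment magnitude (Da = 0)")
  sqrt(sum(residuals^2) / (n * da^2 * (4 + 3 * rhombicity^2) / 5))
}

# exact delete-one coefficient vectors for a full-rank weighted LS fit;
# falls back to explicit refits when rank-deficient or a leverage is ~1
loo_coefficients <- function(A, b, sol) {
  n <- nrow(A); p <- ncol(A)
  out <- matrix(NA_real_, n, p)
  ew <- b - drop(A %*% sol$x)
  if (sol$rank == p) {
    h <- rowSums(A * t(sol$pinv))         # diag of A %*% pinv
    for (i in seq_len(n)) {
      if (1 - h[i] > 1e-8) {
        out[i, ] <- sol$x - sol$pinv[, i] * ew[i] / (1 - h[i])
      } else {
        out[i, ] <- svd_lsq(A[-i, , drop = FALSE], b[-i])$x
      }
    }
  } else {
    for (i in seq_len(n))
      out[i, ] <- svd_lsq(A[-i, , drop = FALSE], b[-i])$x
  }
  out
}

#' Fit Saupe alignment tensors to residual dipolar couplings
#'
#' The central estimator. With a single bond-vector set, solves the
#' overdetermined N x 5 linear system for the alignment tensor by
#' minimum-norm SVD least squares; with a list of two vector sets (one per
#' conformer of a fast-exchanging two-state ensemble), solves the N x 10
#' system for the pair of population-weighted tensors. Rows are weighted by
#' `scale / uncertainty`. Couplings and vectors are matched by
#' (residue, type).
#'
#' For single-tensor fits the quality factor `q` follows the
#' `Da^2 (4 + 3 Rh^2)` normalization (see [q_factor()]) and `q_rms` the
#' RMS-coupling normalization `sqrt(sum(resid^2) / sum(d^2))`. For
#' two-tensor fits the generalized tensor magnitude is no longer a
#' meaningful yardstick (the two tensors may nearly cancel), so `q` equals
#' `q_rms`. The jackknifed factor `q_jk` repeats the fit N times, each time
#' omitting one coupling and predicting it from the remainder; for
#' two-tensor fits a minimum of 11 couplings is required.
#'
#' Two-tensor fits carry a degeneracy guard: when the summed alignment
#' magnitudes reach twice the single-tensor reference magnitude
#' (`sum(|Da|) >= 2 |Da_ref|`), or the system is rank-deficient (e.g.
#' identical conformers), the fit is flagged `degenerate` and its
#' populations are not to be interpreted. Populations are apportioned by
#' the generalized degree of order of the two fitted tensors, valid under
#' the assumption that both states align with equal intrinsic strength.
#'
#' @param rdcs `rdc_table` of measured couplings.
#' @param vectors `bond_vector` table, or list of two such tables for a
#'   two-conformer fit.
#' @param jackknife compute `q_jk` (default TRUE).
#' @param reference_da single-tensor alignment magnitude used by the
#'   degeneracy guard of two-tensor fits; when NULL it is computed from a
#'   single-tensor fit to the first conformer's vectors.
#' @return object of class `rdc_fit` (two-conformer fits additionally
#'   `rdc_fit2`): tensors, populations, quality factors, residuals
#'   (normalized, predicted minus measured), rank and condition number.
#' @export
rdc_fit <- function(rdcs, vectors, jackknife = TRUE, reference_da = NULL) {
  two <- is.list(vectors) && !is.data.frame(vectors)
  if (two && length(vectors) != 2)
    stop("supply one bond-vector table or a list of two (one per conformer)")
  mt <- match_rdc_vectors(rdcs, vectors)
  d <- mt$rdcs
  n <- nrow(d)
  p <- if (two) 10L else 5L
  if (n < p + 1)
    stop("need at least ", p + 1, " matched couplings for a ",
         if (two) "two-tensor" else "single-tensor", " fit; got ", n)
  w <- d$scale / d$uncertainty
  dnorm <- d$scale * d$value
  G <- lapply(mt$dirs, design_geometry)
  A <- do.call(cbind, G) * w
  b <- w * dnorm
  sol <- svd_lsq(A, b)
  # a two-conformer pair differing by a rigid one-axis rotation of one
  # domain has expected rank 9 (axial gauge freedom, resolved minimum-norm)
  min_rank <- if (two) 9L else 5L
  if (sol$rank < min_rank)
    warning("rank-deficient system (rank ", sol$rank, " < ", min_rank,
            "); condition number ", format(sol$condition))
  fitted <- drop(do.call(cbind, G) %*% sol$x)
  resid <- fitted - dnorm
  fit <- list(n_conformers = if (two) 2L else 1L, n_rdc = n,
              data = d, dirs = mt$dirs,
              fitted = fitted, measured = dnorm, residuals = resid,
              weights = w, rank = sol$rank,
              condition_number = sol$condition,
              coefficients = sol$x,
              q_rms = sqrt(sum(resid^2) / sum(dnorm^2)),
              call = match.call())
  if (!two) {
    fit$tensors <- list(saupe_tensor(sol$x))
    fit$q <- q_factor(resid, fit$tensors[[1]]$da,
                      fit$tensors[[1]]$rhombicity)
  } else {
    fit$tensors <- list(saupe_tensor(sol$x[1:5]), saupe_tensor(sol$x[6:10]))
    fit$q <- fit$q_rms
    if (is.null(reference_da)) {
      ref <- svd_lsq(G[[1]] * w, b)
      reference_da <- saupe_tensor(ref$x)$da
    }
    fit$reference_da <- reference_da
    g <- vapply(fit$tensors, generalized_order, 0)
    fit$populations <- if (sum(g) > 0) g / sum(g) else c(NA_real_, NA_real_)
    fit$sum_da_ratio <- sum(abs(vapply(fit$tensors, function(t) t$da, 0))) /
      abs(reference_da)
    fit$degenerate <- fit$sum_da_ratio >= 2 || sol$rank < 9
  }
  class(fit) <- c(if (two) "rdc_fit2", "rdc_fit")
  if (jackknife) fit$q_jk <- q_jackknife_fit(fit, A, b)
  fit
}

# leverages (diagonal of the projection onto the kept column space);
# rank-agnostic, so valid for gauge-deficient two-conformer systems
leverages <- function(A, tol_rel = 1e-8) {
  sv <- svd(A)
  keep <- sv$d > tol_rel * max(sv$d)
  rowSums(sv$u[, keep, drop = FALSE]^2)
}

# Q_jk for a fitted system; A, b are the weighted design and rhs.
# Leave-one-out predictions come from the exact linear identity
# pred_loo_i - d_i = resid_i / (1 - h_i); the identity needs only the hat
# diagonal, which depends on the column space alone, so it holds for
# rank-deficient (minimum-norm) fits as well. The per-omission tensors
# needed for the single-tensor denominator use the coefficient downdate.
q_jackknife_fit <- function(fit, A, b) {
  n <- nrow(A); p <- ncol(A)
  if (n <= p)
    stop("jackknife requires N > parameters (N = ", n, ", parameters = ",
         p, ")")
  h <- leverages(A)
  ok <- 1 - h > 1e-8
  r <- fit$residuals / (1 - h)
  if (any(!ok)) {            # leverage ~ 1: prediction requires explicit refit
    Gall <- do.call(cbind, lapply(fit$dirs, design_geometry))
    for (i in which(!ok)) {
      xi <- svd_lsq(A[-i, , drop = FALSE], b[-i])$x
      r[i] <- drop(Gall[i, , drop = FALSE] %*% xi) - fit$measured[i]
    }
  }
  if (p == 5) {
    sol <- svd_lsq(A, b)
    cf <- loo_coefficients(A, b, sol)
    denom <- vapply(seq_len(n), function(i) {
      t_i <- saupe_tensor(cf[i, ])
      t_i$da^2 * (4 + 3 * t_i$rhombicity^2) / 5
    }, 0)
    sqrt(sum(r^2) / sum(denom))
  } else {
    sqrt(sum(r^2) / sum(fit$measured^2))
  }
}

#' Jackknifed quality factor
#'
#' Standalone cross-validated Q: the fit is repeated N times, each omitting
#' one coupling whose deviation is then measured against its prediction from
#' the remaining data. For single-tensor fits the denominator aggregates the
#' per-omission `Da_i` and `Rh_i`; for two-tensor fits it uses the mean
#' square of the measured couplings.
#'
#' @inheritParams rdc_fit
#' @return scalar `q_jk`.
#' @export
q_jackknife <- function(rdcs, vectors) {
  rdc_fit(rdcs, vectors, jackknife = TRUE)$q_jk
}

#' @export
coef.rdc_fit <- function(object, ...) {
  unlist(lapply(object$tensors, function(t) t$elements), use.names = TRUE)
}

#' @export
residuals.rdc_fit <- function(object, ...) object$residuals

#' @export
fitted.rdc_fit <- function(object, ...) object$fitted

#' Back-calculate couplings from a fitted model
#'
#' @param object an `rdc_fit`.
#' @param vectors optional new bond-vector table (or list of two for a
#'   two-conformer fit); defaults to the fitted data.
#' @param ... unused.
#' @return numeric vector of normalized couplings.
#' @export
predict.rdc_fit <- function(object, vectors = NULL, ...) {
  if (is.null(vectors)) return(object$fitted)
  if (is.data.frame(vectors)) vectors <- list(vectors)
  if (length(vectors) != object$n_conformers)
    stop("need one vector set per fitted conformer")
  Reduce(`+`, Map(function(v, t) predict_rdc(v, t), vectors, object$tensors))
}

#' Simulate coupling replicates from a fitted model
#'
#' Draws Gaussian noise around the back-calculated couplings at the
#' measurement uncertainties (scaled to the normalized coupling units) and
#' returns replicate RDC tables on the raw scale.
#'
#' @param object an `rdc_fit`.
#' @param nsim number of replicate tables.
#' @param seed integer seed, or NULL.
#' @param ... unused.
#' @return list of `rdc_table` objects.
#' @export
simulate.rdc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  lapply(seq_len(nsim), function(k) {
    dn <- object$fitted + stats::rnorm(object$n_rdc,
                                       sd = d$scale * d$uncertainty)
    rdc_table(d$resno, d$type, dn / d$scale, d$uncertainty)
  })
}

#' @export
print.rdc_fit <- function(x, ...) {
  cat(sprintf("%s-tensor RDC fit: N = %d couplings\n",
              if (x$n_conformers == 2) "Two" else "Single", x$n_rdc))
  cat(sprintf("  Q = %.4f", x$q))
  if (!is.null(x$q_jk)) cat(sprintf("   Q_jk = %.4f", x$q_jk))
  cat(sprintf("   Q_rms = %.4f\n", x$q_rms))
  for (h in seq_along(x$tensors))
    cat(sprintf("  tensor %d: Da = %.5g, Rh = %.4f\n",
                h, x$tensors[[h]]$da, x$tensors[[h]]$rhombicity))
  if (!is.null(x$populations))
    cat(sprintf("  populations (equal-alignment assumption): %.3f / %.3f%s\n",
                x$populations[1], x$populations[2],
                if (isTRUE(x$degenerate)) "  [DEGENERATE - do not interpret]"
                else ""))
  invisible(x)
}

#' @export
summary.rdc_fit <- function(object, ...) {
  out <- list(fit = object,
              rms_residual = sqrt(mean(object$residuals^2)),
              by_type = tapply(object$residuals, object$data$type,
                               function(r) sqrt(mean(r^2))))
  class(out) <- "summary.rdc_fit"
  out
}

#' @export
print.summary.rdc_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  RMS residual (normalized Hz): %.4g\n", x$rms_residual))
  cat("  by type:",
      paste(names(x$by_type), signif(x$by_type, 4), sep = " = ",
            collapse = ", "), "\n")
  cat(sprintf("  rank = %d, condition number = %.3g\n",
              x$fit$rank, x$fit$condition_number))
  invisible(x)
}

#' Correlation plot of measured versus back-calculated couplings
#'
#' @param x an `rdc_fit`.
#' @param ... passed to `plot`.
#' @export
plot.rdc_fit <- function(x, ...) {
  types <- unique(x$data$type)
  col <- stats::setNames(grDevices::hcl.colors(max(3, length(types)),
                                               "Dark 3")[seq_along(types)],
                         types)
  graphics::plot(x$measured, x$fitted, col = col[x$data$type], pch = 16,
                 xlab = "measured (normalized Hz)",
                 ylab = "back-calculated (normalized Hz)", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = names(col), col = col, pch = 16,
                   bty = "n")
  invisible(x)
}
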