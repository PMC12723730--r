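# Rigid-body superposition and the closure/twist/bend decomposition of
# relative domain orientation.

#' Least-squares superposition of two point sets
#'
#' Kabsch algorithm: the proper rotation and translation minimizing the
#' RMSD between matched point sets (`rotation %*% mobile + translation`
#' onto `target`). Reflections are never returned; a reflection-requiring
#' correspondence yields the best proper rotation with nonzero RMSD.
#'
#' @param mobile,target n x 3 coordinate matrices, matched row-wise,
#'   n >= 3 and not collinear.
#' @return list of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom), `atom_count`.
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3, all(dim(mobile) == dim(target)))
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  H <- crossprod(P, Q)
  sv <- svd(H)
  if (min(sv$d) < 1e-10 && sum(sv$d > 1e-10) < 2)
    stop("degenerate (collinear) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rot <- sweep(P %*% t(R), 2, ct, "+")
  out <- list(rotation = R, translation = ct - drop(R %*% cm),
              rmsd = sqrt(mean(rowSums((rot - target)^2))),
              atom_count = n)
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition of %d atoms, RMSD = %.4f A\n",
              x$atom_count, x$rmsd))
  invisible(x)
}

apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, "+")
}

# matched backbone coordinates of `residues` present in every model
backbone_coords <- function(model, residues, atoms = c("N", "CA", "C")) {
  a <- model$atoms
  sel <- a$resno %in% residues & a$elety %in% atoms
  b <- a[sel, , drop = FALSE]
  b <- b[order(b$resno, match(b$elety, atoms)), , drop = FALSE]
  list(xyz = as.matrix(b[, c("x", "y", "z")]),
       key = paste(b$resno, b$elety))
}

shared_backbone <- function(models, residues, atoms = c("N", "CA", "C")) {
  bs <- lapply(models, backbone_coords, residues = residues, atoms = atoms)
  keys <- Reduce(intersect, lapply(bs, `[[`, "key"))
  lapply(bs, function(b) b$xyz[match(keys, b$key), , drop = FALSE])
}

#' Superpose one structure onto another over a residue set
#'
#' @param mobile,target `structure_model`s sharing residue numbering.
#' @param residues residues to superpose on.
#' @param atoms backbone atom names used (default N, CA, C).
#' @return list: `model` (transformed copy of `mobile`), `superposition`.
#' @export
superpose_structures <- function(mobile, target, residues,
                                 atoms = c("N", "CA", "C")) {
  xy <- shared_backbone(list(mobile, target), residues, atoms)
  sp <- superpose(xy[[1]], xy[[2]])
  m <- mobile
  m$atoms[, c("x", "y", "z")] <-
    apply_superposition(m$atoms[, c("x", "y", "z")], sp)
  list(model = m, superposition = sp)
}

domain_com <- function(model, residues, atoms = c("N", "CA", "C")) {
  colMeans(backbone_coords(model, residues, atoms)$xyz)
}

#' Rotate a domain of a structure about an axis
#'
#' Only atoms of the given residues are transformed; the pivot defaults to
#' the domain's backbone center of mass. Couplings depend only on bond
#' orientations, so downstream RDC fits are pivot-invariant.
#'
#' @param model a `structure_model`.
#' @param residues residues of the domain.
#' @param axis rotation axis (unit length).
#' @param angle rotation angle in degrees.
#' @param pivot rotation pivot (default domain backbone COM).
#' @return transformed `structure_model`.
#' @export
rotate_domain <- function(model, residues, axis, angle, pivot = NULL) {
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-8) stop("axis must be unit length")
  if (is.null(pivot)) pivot <- domain_com(model, residues)
  R <- rotation_about_axis(axis, angle)
  sel <- model$atoms$resno %in% residues
  xyz <- as.matrix(model$atoms[sel, c("x", "y", "z")])
  model$atoms[sel, c("x", "y", "z")] <-
    sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, "+")
  model
}

#' Closure, twist and bend axes of a two-domain system
#'
#' Fixed analysis frame for interdomain pose: the twist axis is the unit
#' vector from the reference structure's first-domain center of mass to its
#' second-domain center of mass; the closure axis is the unit component,
#' orthogonal to twist, of the rotation axis carrying the reference's
#' mobile domain onto the closed reference's (so that closing motions are
#' positive closure); the bend axis is the cross product twist x closure.
#' Both structures are superposed on the first domain internally.
#'
#' @param reference `structure_model` of the open reference state.
#' @param ntd,ctd `domain_definition`s (or residue vectors) of the fixed
#'   and mobile domains.
#' @param closed_reference `structure_model` of the closed state.
#' @return 3x3 matrix with unit columns `closure`, `twist`, `bend`.
#' @export
define_ctb_axes <- function(reference, ntd, ctd, closed_reference) {
  ntd <- domain_residues(ntd); ctd <- domain_residues(ctd)
  cl <- superpose_structures(closed_reference, reference, ntd)$model
  twist <- domain_com(reference, ctd) - domain_com(reference, ntd)
  twist <- twist / sqrt(sum(twist^2))
  # rotation carrying the reference CTD onto the closed CTD
  xy <- shared_backbone(list(reference, cl), ctd)
  R <- superpose(xy[[1]], xy[[2]])$rotation
  aa <- axis_angle(R)
  perp <- aa$axis - sum(aa$axis * twist) * twist
  np <- sqrt(sum(perp^2))
  if (np < 1e-6) stop("closure axis degenerate: rotation axis parallel to twist")
  closure <- perp / np
  bend <- c(twist[2] * closure[3] - twist[3] * closure[2],
            twist[3] * closure[1] - twist[1] * closure[3],
            twist[1] * closure[2] - twist[2] * closure[1])
  axes <- cbind(closure = closure, twist = twist, bend = bend)
  axes
}

domain_residues <- function(x) {
  if (inherits(x, "domain_definition")) x$residues else as.integer(x)
}

#' Closure/twist/bend pose of a mobile domain
#'
#' Measures the orientation of a target structure's mobile domain relative
#' to the reference: the target is superposed on the reference by the first
#' domain, the mobile-domain rotation is extracted by domain-on-domain
#' superposition, and that rotation is factored into sequential rotations
#' about the closure, twist and bend axes (bend applied first). Identity
#' pose reports 0/0/0. Near gimbal lock (twist within 0.1 degree of
#' +/-90) closure and bend are not separable and their sum is reported as
#' closure, with a warning.
#'
#' @param reference,target `structure_model`s sharing numbering.
#' @param ntd,ctd domain definitions or residue vectors.
#' @param axes 3x3 closure/twist/bend axis matrix from [define_ctb_axes()].
#' @return object of class `domain_pose`: `closure`, `twist`, `bend`
#'   (degrees), `rotation` (3x3), `reference_label`.
#' @export
pose_ctb <- function(reference, target, ntd, ctd, axes) {
  ntd <- domain_residues(ntd); ctd <- domain_residues(ctd)
  tg <- superpose_structures(target, reference, ntd)$model
  xy <- shared_backbone(list(reference, tg), ctd)
  R <- superpose(xy[[1]], xy[[2]])$rotation
  ang <- factor_rotation(R, axes)
  out <- list(closure = ang[1], twist = ang[2], bend = ang[3],
              gimbal = isTRUE(attr(ang, "gimbal")),
              rotation = R, reference_label = reference$label)
  class(out) <- "domain_pose"
  out
}

#' @export
print.domain_pose <- function(x, ...) {
  cat(sprintf("closure/twist/bend = %.1f/%.1f/%.1f deg (vs %s)%s\n",
              x$closure, x$twist, x$bend, x$reference_label,
              if (x$gimbal) "  [gimbal: closure+bend merged]" else ""))
  invisible(x)
}
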