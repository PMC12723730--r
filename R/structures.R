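# Structure model and PDB input/output. A structure_model is a light wrapper
# around an atom table (one row per atom): chain, resno, resid (3-letter),
# elety (PDB atom name), x, y, z. PDB parsing and writing go through bio3d.

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @param label free-text label (e.g. PDB id + chain).
#' @param resolution resolution in Angstrom, or NA.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, label = "", resolution = NA_real_) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atom table must have columns ", paste(need, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom positions must be finite")
  if (any(atoms$elety == "" | is.na(atoms$elety)))
    stop("atom names must be non-empty")
  dup <- duplicated(atoms[, c("chain", "resno", "elety")])
  if (any(dup))
    stop("duplicate atoms for (chain, residue, atom name): ",
         paste(unique(paste0(atoms$chain[dup], ":", atoms$resno[dup], ":",
                             atoms$elety[dup])),
               collapse = ", "))
  structure(list(atoms = atoms, label = label, resolution = resolution),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d atoms, %d residues\n",
              x$label, nrow(x$atoms), length(unique(x$atoms$resno))))
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Reads ATOM records of the first MODEL of a PDB file. Alternate locations
#' are resolved to the highest occupancy (ties to the first listed);
#' insertion-coded residues are dropped.
#'
#' @param path PDB file path.
#' @param chain chain identifier, or NULL for all chains.
#' @return a `structure_model`.
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  if (!is.null(chain)) {
    at <- at[!is.na(at$chain) & at$chain == chain, , drop = FALSE]
    if (nrow(at) == 0) stop("no ATOM records for chain ", chain, " in ", path)
  }
  if ("insert" %in% names(at))
    at <- at[is.na(at$insert) | at$insert == "", , drop = FALSE]
  # altloc: keep highest occupancy per (chain, resno, elety), ties first listed
  if ("alt" %in% names(at)) {
    key <- paste(at$chain, at$resno, at$elety, sep = "\r")
    occ <- if ("o" %in% names(at)) ifelse(is.na(at$o), 1, at$o) else rep(1, nrow(at))
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      best <- idx[which.max(occ[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
    at <- at[keep, , drop = FALSE]
  }
  label <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path))
  if (!is.null(chain)) label <- paste0(label, "_", chain)
  structure_model(data.frame(chain = at$chain, resno = at$resno,
                             resid = at$resid, elety = at$elety,
                             x = at$x, y = at$y, z = at$z,
                             stringsAsFactors = FALSE),
                  label = label)
}

#' Write a structure model to a PDB file
#'
#' Coordinates are written with the standard 3-decimal PDB convention.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain)
  invisible(path)
}

atom_xyz <- function(model, resno, elety) {
  a <- model$atoms
  i <- which(a$resno == resno & a$elety == elety)
  if (length(i) == 0) return(NULL)
  as.numeric(a[i[1], c("x", "y", "z")])
}

#' Place backbone amide hydrogens
#'
#' Adds (or replaces) the amide H of every residue i >= 2 with C'(i-1), N(i)
#' and CA(i) present, under standard in-peptide-plane geometry: H lies in the
#' C'(i-1)-N(i)-CA(i) plane, on the side opposite the C'/CA bisector, at
#' `nh_bond_length` from N. Prolines and residues with missing flanking heavy
#' atoms are skipped (the latter with a warning).
#'
#' @param model a `structure_model`.
#' @param nh_bond_length N-H bond length in Angstrom (default 1.02).
#' @return a `structure_model` with H atoms placed.
#' @export
add_amide_hydrogens <- function(model, nh_bond_length = 1.02) {
  a <- model$atoms
  a <- a[a$elety != "H", , drop = FALSE]   # replace any existing amide H
  resnos <- sort(unique(a$resno))
  m <- structure(list(atoms = a, label = model$label,
                      resolution = model$resolution),
                 class = "structure_model")
  newrows <- list()
  skipped <- integer(0)
  for (r in resnos[-1]) {
    row <- which(a$resno == r)[1]
    if (a$resid[row] == "PRO") next
    n <- atom_xyz(m, r, "N"); ca <- atom_xyz(m, r, "CA")
    cp <- atom_xyz(m, r - 1, "C")
    if (is.null(n) || is.null(ca) || is.null(cp)) {
      if (!is.null(n)) skipped <- c(skipped, r)
      next
    }
    u1 <- cp - n; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- ca - n; u2 <- u2 / sqrt(sum(u2^2))
    b <- u1 + u2
    nb <- sqrt(sum(b^2))
    if (nb < 1e-8) { skipped <- c(skipped, r); next }
    h <- n - nh_bond_length * b / nb      # anti-bisector, in plane
    newrows[[length(newrows) + 1]] <-
      data.frame(chain = a$chain[row], resno = r, resid = a$resid[row],
                 elety = "H", x = h[1], y = h[2], z = h[3],
                 stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("amide H skipped for residues with missing heavy atoms: ",
            paste(skipped, collapse = ", "))
  atoms <- rbind(a, do.call(rbind, newrows))
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = model$label,
                 resolution = model$resolution),
            class = "structure_model")
}

#' Extract internuclear bond vectors
#'
#' Extracts unit bond vectors for the coupling types supported by the
#' fitting machinery: `NH` is N(i) to H(i); `C'N` is C'(i-1) to N(i),
#' attributed to residue i; `CaC'` is CA(i) to C'(i). Pairs with a missing
#' atom are silently omitted.
#'
#' @param model a `structure_model`.
#' @param types character subset of `c("NH", "C'N", "CaC'")`.
#' @return `bond_vector` data.frame: `resno`, `type`, direction `x,y,z`
#'   (unit), origin `ox,oy,oz` (Angstrom).
#' @export
extract_bond_vectors <- function(model, types = c("NH", "C'N", "CaC'")) {
  types <- match.arg(types, c("NH", "C'N", "CaC'"), several.ok = TRUE)
  rows <- list()
  for (r in sort(unique(model$atoms$resno))) {
    for (tp in types) {
      if (tp == "NH") {
        from <- atom_xyz(model, r, "N"); to <- atom_xyz(model, r, "H")
      } else if (tp == "C'N") {
        from <- atom_xyz(model, r - 1, "C"); to <- atom_xyz(model, r, "N")
      } else {
        from <- atom_xyz(model, r, "CA"); to <- atom_xyz(model, r, "C")
      }
      if (is.null(from) || is.null(to)) next
      d <- to - from
      nd <- sqrt(sum(d^2))
      if (nd < 1e-8) next
      d <- d / nd
      rows[[length(rows) + 1]] <-
        data.frame(resno = r, type = tp, x = d[1], y = d[2], z = d[3],
                   ox = from[1], oy = from[2], oz = from[3],
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(resno = integer(0), type = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      ox = numeric(0), oy = numeric(0), oz = numeric(0))
  class(out) <- c("bond_vector", "data.frame")
  out
}

#' Build a bond-vector table from raw directions
#'
#' @param resno integer residue numbers.
#' @param type coupling types.
#' @param dirs n x 3 matrix of directions (normalized internally).
#' @param origins optional n x 3 matrix of origins (default 0).
#' @return `bond_vector` data.frame.
#' @export
bond_vectors <- function(resno, type, dirs, origins = NULL) {
  dirs <- as.matrix(dirs)
  stopifnot(ncol(dirs) == 3, nrow(dirs) == length(resno),
            length(type) %in% c(1L, length(resno)))
  nrm <- sqrt(rowSums(dirs^2))
  if (any(nrm < 1e-12)) stop("zero-length direction")
  dirs <- dirs / nrm
  if (is.null(origins)) origins <- matrix(0, nrow(dirs), 3)
  out <- data.frame(resno = as.integer(resno),
                    type = rep_len(as.character(type), length(resno)),
                    x = dirs[, 1], y = dirs[, 2], z = dirs[, 3],
                    ox = origins[, 1], oy = origins[, 2], oz = origins[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("bond_vector", "data.frame")
  out
}

vector_dirs <- function(vectors) as.matrix(vectors[, c("x", "y", "z")])

#' Rotate bond vectors
#'
#' Applies a rotation to the directions (and origins) of a bond-vector
#' table, optionally restricted to a residue subset.
#'
#' @param vectors `bond_vector` table.
#' @param rotation 3x3 rotation.
#' @param residues residues to rotate (default all).
#' @param pivot origin-rotation pivot (default c(0,0,0)); directions are
#'   pivot-independent.
#' @return rotated `bond_vector` table.
#' @export
rotate_vectors <- function(vectors, rotation, residues = NULL,
                           pivot = c(0, 0, 0)) {
  sel <- if (is.null(residues)) rep(TRUE, nrow(vectors))
         else vectors$resno %in% residues
  d <- vector_dirs(vectors)[sel, , drop = FALSE] %*% t(rotation)
  vectors[sel, c("x", "y", "z")] <- d
  o <- as.matrix(vectors[sel, c("ox", "oy", "oz")])
  o <- sweep(sweep(o, 2, pivot) %*% t(rotation), 2, pivot, "+")
  vectors[sel, c("ox", "oy", "oz")] <- o
  vectors
}
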