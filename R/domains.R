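# Invariant-domain identification across crystal structures, peptide-plane
# pruning by bond-vector consistency, and averaged-orientation reference
# construction.

#' Domain definition
#'
#' @param name domain name (e.g. "NTD").
#' @param residues ordered integer residue set.
#' @param invariant_planes subset of residues passing the angular filter
#'   (defaults to all residues).
#' @return object of class `domain_definition`.
#' @export
domain_definition <- function(name, residues,
                              invariant_planes = residues) {
  residues <- sort(unique(as.integer(residues)))
  invariant_planes <- sort(unique(as.integer(invariant_planes)))
  if (!all(invariant_planes %in% residues))
    stop("invariant_planes must be a subset of residues")
  structure(list(name = name, residues = residues,
                 invariant_planes = invariant_planes),
            class = "domain_definition")
}

#' @export
print.domain_definition <- function(x, ...) {
  cat(sprintf("domain '%s': %d residues, %d invariant planes\n",
              x$name, length(x$residues), length(x$invariant_planes)))
  invisible(x)
}

# generalized Procrustes: superpose all coordinate sets onto their evolving
# mean (seeded from the first set); returns superpositions and the mean
procrustes_mean <- function(xyz_list, max_iter = 100, tol = 1e-10) {
  ref <- xyz_list[[1]]
  sps <- NULL
  for (it in seq_len(max_iter)) {
    sps <- lapply(xyz_list, superpose, target = ref)
    pos <- Map(apply_superposition, xyz_list, sps)
    new_ref <- Reduce(`+`, pos) / length(pos)
    if (max(abs(new_ref - ref)) < tol) { ref <- new_ref; break }
    ref <- new_ref
  }
  list(superpositions = sps, mean = ref, positions = pos)
}

#' Identify the invariant core of a region across structures
#'
#' Finds the largest residue subset of `region` whose backbone conformation
#' is shared by all structures: after least-squares superposition of every
#' structure on the current subset's backbone (N, CA, C) atoms, each
#' retained residue's CA RMSD from the across-structure mean must not
#' exceed `distance_cutoff`. The iteration is a deterministic greedy
#' shrink seeded from the full region (superpose, drop the worst residue
#' above the cutoff, re-superpose), followed by re-admission passes for
#' excluded residues that satisfy the cutoff under the final superposition.
#'
#' @param structures list of >= 2 `structure_model`s sharing numbering.
#' @param region integer residues to search within.
#' @param distance_cutoff CA deviation cutoff in Angstrom (default 0.5).
#' @param name name for the resulting domain.
#' @return list: `domain` (a `domain_definition`), `superpositions`
#'   (per-structure `superposition` onto the mean of the final core).
#' @export
find_invariant_core <- function(structures, region, distance_cutoff = 0.5,
                                name = "domain") {
  stopifnot(length(structures) >= 2)
  # residues with full backbone in every structure
  usable <- Reduce(intersect, lapply(structures, function(m) {
    a <- m$atoms
    r <- intersect(region, a$resno)
    r[vapply(r, function(q)
      all(c("N", "CA", "C") %in% a$elety[a$resno == q]), TRUE)]
  }))
  usable <- sort(usable)
  current <- usable
  ca_dev <- function(core) {
    bb <- shared_backbone(structures, core)
    pm <- procrustes_mean(bb)
    # CA rows are every 2nd of (N, CA, C) triplets
    ca_idx <- seq(2, nrow(bb[[1]]), by = 3)
    devs <- sqrt(Reduce(`+`, lapply(pm$positions, function(p)
      rowSums((p[ca_idx, , drop = FALSE] -
               pm$mean[ca_idx, , drop = FALSE])^2))) / length(structures))
    names(devs) <- as.character(core)
    list(devs = devs, pm = pm)
  }
  repeat {
    if (length(current) < 4) stop("degenerate core: fewer than 4 residues")
    cd <- ca_dev(current)
    if (max(cd$devs) > distance_cutoff) {
      worst <- current[which.max(cd$devs)]
      current <- setdiff(current, worst)
      next
    }
    # re-admission: excluded residues satisfying the cutoff under the
    # current superposition
    excl <- setdiff(usable, current)
    if (length(excl) == 0) break
    pos_ca <- lapply(seq_along(structures), function(s) {
      xyz <- backbone_coords(structures[[s]], excl, atoms = "CA")
      list(key = xyz$key,
           xyz = apply_superposition(xyz$xyz, cd$pm$superpositions[[s]]))
    })
    keys <- Reduce(intersect, lapply(pos_ca, `[[`, "key"))
    if (length(keys) == 0) break
    mats <- lapply(pos_ca, function(p) p$xyz[match(keys, p$key), , drop = FALSE])
    mn <- Reduce(`+`, mats) / length(mats)
    dev <- sqrt(Reduce(`+`, lapply(mats, function(m)
      rowSums((m - mn)^2))) / length(mats))
    readmit <- as.integer(sub(" CA$", "", keys))[dev <= distance_cutoff]
    if (length(readmit) == 0) break
    current <- sort(c(current, readmit))
  }
  cd <- ca_dev(current)
  list(domain = domain_definition(name, current),
       superpositions = cd$pm$superpositions)
}

# vectors of the requested types for one residue, per structure model
plane_vectors <- function(model, resno, types) {
  v <- extract_bond_vectors(model, types)
  v[v$resno == resno, , drop = FALSE]
}

#' Prune peptide planes by bond-vector orientation consistency
#'
#' Within a superposed set of structures, retains only those peptide planes
#' of a domain whose bond vectors (by default N-H, C'-N and CA-C') deviate
#' from their across-structure averaged orientation by an RMS angle, pooled
#' over structures and vector types, of at most `angle_threshold` degrees.
#' Structures are superposed internally on the domain's backbone.
#'
#' @param structures list of `structure_model`s (with amide hydrogens when
#'   NH vectors are requested).
#' @param domain a `domain_definition`.
#' @param angle_threshold RMS angle cutoff in degrees (default 5).
#' @param types vector types entering the filter.
#' @return the `domain_definition` with updated `invariant_planes`;
#'   attribute `"rms_angle"` carries the per-plane pooled RMS (degrees).
#' @export
prune_by_vector_angle <- function(structures, domain, angle_threshold = 5,
                                  types = c("NH", "C'N", "CaC'")) {
  bb <- shared_backbone(structures, domain$residues)
  pm <- procrustes_mean(bb)
  sup <- lapply(seq_along(structures), function(s) {
    m <- structures[[s]]
    m$atoms[, c("x", "y", "z")] <-
      apply_superposition(m$atoms[, c("x", "y", "z")],
                          pm$superpositions[[s]])
    m
  })
  vecs <- lapply(sup, extract_bond_vectors, types = types)
  rms <- vapply(domain$residues, function(r) {
    sq <- c()
    for (tp in types) {
      dirs <- do.call(rbind, lapply(vecs, function(v)
        as.matrix(v[v$resno == r & v$type == tp, c("x", "y", "z")])))
      if (is.null(dirs) || nrow(dirs) < length(structures)) next
      mn <- colMeans(dirs)
      nm <- sqrt(sum(mn^2))
      if (nm < 1e-8) return(Inf)
      mn <- mn / nm
      ang <- acos(pmax(-1, pmin(1, drop(dirs %*% mn))))
      sq <- c(sq, ang^2)
    }
    if (length(sq) == 0) NA_real_ else rad2deg(sqrt(mean(sq)))
  }, 0)
  keep <- domain$residues[!is.na(rms) & rms <= angle_threshold]
  out <- domain_definition(domain$name, domain$residues, keep)
  attr(out, "rms_angle") <- stats::setNames(rms, domain$residues)
  out
}

#' Replace bond-vector orientations by their across-structure averages
#'
#' Builds an averaged-orientation reference: structures are superposed on
#' the base over the domain's residues; for every invariant plane i the
#' base's C' atoms stay fixed while CA(i-1) and N(i) are re-positioned
#' along the averaged CA(i-1)-C'(i-1) and C'(i-1)-N(i) directions from the
#' fixed C'(i-1), preserving the base's bond lengths, and the amide H(i)
#' is placed along the averaged N(i)-H(i) direction from the new N(i).
#'
#' @param structures list of `structure_model`s (hydrogens present); must
#'   include `base`.
#' @param base the `structure_model` whose coordinates anchor the output.
#' @param domain a `domain_definition`; only its `invariant_planes` are
#'   modified.
#' @return list of class `averaged_reference`: `model` (modified base),
#'   `replaced_vectors` (`bond_vector` table of the averaged directions),
#'   `provenance` (source labels).
#' @export
average_vector_orientations <- function(structures, base, domain) {
  labs <- vapply(structures, `[[`, "", "label")
  if (!base$label %in% labs)
    stop("base structure must be part of the superposed collection")
  bb <- shared_backbone(structures, domain$residues)
  pm <- procrustes_mean(bb)
  # re-superpose everything onto the base's original frame
  base_i <- which(labs == base$label)[1]
  to_base <- superpose(
    apply_superposition(bb[[base_i]], pm$superpositions[[base_i]]),
    bb[[base_i]])
  sup <- lapply(seq_along(structures), function(s) {
    m <- structures[[s]]
    xyz <- apply_superposition(m$atoms[, c("x", "y", "z")],
                               pm$superpositions[[s]])
    m$atoms[, c("x", "y", "z")] <- apply_superposition(xyz, to_base)
    m
  })
  vecs <- lapply(sup, extract_bond_vectors)
  mean_dir <- function(r, tp) {
    dirs <- do.call(rbind, lapply(vecs, function(v)
      as.matrix(v[v$resno == r & v$type == tp, c("x", "y", "z")])))
    if (is.null(dirs) || nrow(dirs) < length(structures)) return(NULL)
    mn <- colMeans(dirs)
    mn / sqrt(sum(mn^2))
  }
  out <- base
  repl <- list()
  for (r in domain$invariant_planes) {
    cp <- atom_xyz(base, r - 1, "C")
    if (is.null(cp)) next
    dcc <- mean_dir(r - 1, "CaC'")          # CA(i-1) -> C'(i-1)
    ca_prev <- atom_xyz(base, r - 1, "CA")
    if (!is.null(dcc) && !is.null(ca_prev)) {
      len <- sqrt(sum((cp - ca_prev)^2))
      newca <- cp - len * dcc
      out$atoms[out$atoms$resno == r - 1 & out$atoms$elety == "CA",
                c("x", "y", "z")] <- rbind(newca)
      repl[[length(repl) + 1]] <-
        data.frame(resno = r - 1, type = "CaC'", x = dcc[1], y = dcc[2],
                   z = dcc[3], ox = newca[1], oy = newca[2], oz = newca[3])
    }
    dcn <- mean_dir(r, "C'N")               # C'(i-1) -> N(i)
    n_old <- atom_xyz(base, r, "N")
    if (!is.null(dcn) && !is.null(n_old)) {
      len <- sqrt(sum((n_old - cp)^2))
      newn <- cp + len * dcn
      out$atoms[out$atoms$resno == r & out$atoms$elety == "N",
                c("x", "y", "z")] <- rbind(newn)
      repl[[length(repl) + 1]] <-
        data.frame(resno = r, type = "C'N", x = dcn[1], y = dcn[2],
                   z = dcn[3], ox = cp[1], oy = cp[2], oz = cp[3])
      dnh <- mean_dir(r, "NH")
      h_old <- atom_xyz(base, r, "H")
      if (!is.null(dnh) && !is.null(h_old)) {
        len_h <- sqrt(sum((h_old - n_old)^2))
        newh <- newn + len_h * dnh
        out$atoms[out$atoms$resno == r & out$atoms$elety == "H",
                  c("x", "y", "z")] <- rbind(newh)
        repl[[length(repl) + 1]] <-
          data.frame(resno = r, type = "NH", x = dnh[1], y = dnh[2],
                     z = dnh[3], ox = newn[1], oy = newn[2], oz = newn[3])
      }
    }
  }
  rv <- do.call(rbind, repl)
  if (!is.null(rv)) class(rv) <- c("bond_vector", "data.frame")
  structure(list(model = out, replaced_vectors = rv, provenance = labs),
            class = "averaged_reference")
}

#' @export
print.averaged_reference <- function(x, ...) {
  cat(sprintf("averaged reference over %d structures: %d vectors replaced\n",
              length(x$provenance),
              if (is.null(x$replaced_vectors)) 0L
              else nrow(x$replaced_vectors)))
  invisible(x)
}
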