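# Programmatic fixtures: synthetic backbones, two-domain structure pairs and
# random tensors. Everything is generated in code at test time.

# synthetic backbone with N, CA, C atoms along a gently curving chain;
# geometry is plausible (1.33/1.46/1.52 A bonds, non-collinear) but makes no
# claim to ideal peptide stereochemistry
make_backbone <- function(n_res, seed = 0, chain = "A", label = "synth") {
  set.seed(seed)
  rows <- list()
  # local frames follow a coarse helical path
  t <- seq_len(n_res)
  path <- cbind(4 * cos(t / 3), 4 * sin(t / 3), 1.6 * t)
  # aperiodic wobble so that no two chain segments are alike
  path <- path + matrix(rnorm(3 * n_res, sd = 0.35), n_res, 3)
  for (i in t) {
    tang <- if (i < n_res) path[min(i + 1, n_res), ] - path[i, ]
            else path[i, ] - path[i - 1, ]
    tang <- tang / sqrt(sum(tang^2))
    up <- c(0, 0, 1) - tang[3] * tang
    up <- up / sqrt(sum(up^2))
    side <- c(tang[2] * up[3] - tang[3] * up[2],
              tang[3] * up[1] - tang[1] * up[3],
              tang[1] * up[2] - tang[2] * up[1])
    npos <- path[i, ]
    ca <- npos + 1.46 * (0.8 * tang + 0.6 * up)
    cc <- ca + 1.52 * (0.85 * tang - 0.52 * side)
    rows[[i]] <- data.frame(
      chain = chain, resno = i, resid = "ALA",
      elety = c("N", "CA", "C"),
      x = c(npos[1], ca[1], cc[1]),
      y = c(npos[2], ca[2], cc[2]),
      z = c(npos[3], ca[3], cc[3]),
      stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, rows), label = label)
}

# pair (or more) of structures sharing a backbone, with residues of
# `moved_residues` rigidly displaced/rotated in the copies and optional
# per-atom Gaussian jitter
make_structure_pair <- function(n_res = 30, moved_residues = integer(0),
                                shift = c(0, 0, 0), axis = c(0, 0, 1),
                                angle = 0, jitter = 0, seed = 0,
                                labels = c("m1", "m2")) {
  base <- make_backbone(n_res, seed = seed, label = labels[1])
  m2 <- base
  m2$label <- labels[2]
  if (length(moved_residues)) {
    if (angle != 0)
      m2 <- rotate_domain(m2, moved_residues, axis / sqrt(sum(axis^2)), angle)
    sel <- m2$atoms$resno %in% moved_residues
    m2$atoms[sel, c("x", "y", "z")] <-
      sweep(as.matrix(m2$atoms[sel, c("x", "y", "z")]), 2, shift, "+")
  }
  if (jitter > 0) {
    set.seed(seed + 1)
    m2$atoms[, c("x", "y", "z")] <-
      as.matrix(m2$atoms[, c("x", "y", "z")]) +
      matrix(rnorm(3 * nrow(m2$atoms), sd = jitter), ncol = 3)
  }
  list(base, m2)
}

random_tensor <- function(seed = 0, scale = 1) {
  set.seed(seed)
  saupe_tensor(scale * runif(5, -1, 1))
}

random_unit <- function(seed = 0) {
  set.seed(seed)
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# direct double-sum evaluation of the coupling for one vector and tensor:
# D = C * sum_ij S_ij cos(a_i) cos(a_j); independent of the design-row path
coupling_double_sum <- function(dir, tensor, scale = 1) {
  S <- as_saupe_tensor(tensor)$matrix
  scale * drop(t(dir) %*% S %*% dir)
}
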