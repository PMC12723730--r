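test_that("PDB writer/reader round trip preserves coordinates to 3 decimals", {
  m <- make_backbone(5, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  back <- read_pdb(path)
  expect_equal(nrow(back$atoms), nrow(m$atoms))
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               round(as.matrix(m$atoms[, c("x", "y", "z")]), 3),
               ignore_attr = TRUE)
})

test_that("read_pdb selects chains and rejects structures without ATOM records", {
  m <- make_backbone(4, seed = 3, chain = "A")
  m2 <- make_backbone(4, seed = 4, chain = "B", label = "synthB")
  path <- withr::local_tempfile(fileext = ".pdb")
  pa <- withr::local_tempfile(fileext = ".pdb")
  pb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, pa)
  write_pdb(m2, pb)
  atom_lines <- function(p) grep("^ATOM", readLines(p), value = TRUE)
  writeLines(c(atom_lines(pa), atom_lines(pb), "END"), path)
  mA <- suppressWarnings(read_pdb(path, chain = "A"))
  mB <- suppressWarnings(read_pdb(path, chain = "B"))
  expect_equal(sort(unique(mA$atoms$chain)), "A")
  expect_equal(nrow(mB$atoms), 12)
  expect_match(mA$label, "_A$")

  het <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00",
    "END"), het)
  expect_error(read_pdb(het))
  expect_error(read_pdb("/nonexistent/file.pdb"), "cannot read")
})

test_that("amide hydrogen placement is planar, bisecting and idempotent", {
  m <- make_backbone(6, seed = 5)
  mh <- add_amide_hydrogens(m, nh_bond_length = 1.02)
  for (r in 2:6) {
    h <- as.numeric(mh$atoms[mh$atoms$resno == r & mh$atoms$elety == "H",
                             c("x", "y", "z")])
    n <- as.numeric(mh$atoms[mh$atoms$resno == r & mh$atoms$elety == "N",
                             c("x", "y", "z")])
    ca <- as.numeric(mh$atoms[mh$atoms$resno == r & mh$atoms$elety == "CA",
                              c("x", "y", "z")])
    cp <- as.numeric(mh$atoms[mh$atoms$resno == r - 1 & mh$atoms$elety == "C",
                              c("x", "y", "z")])
    expect_equal(sqrt(sum((h - n)^2)), 1.02, tolerance = 1e-10)
    # H in the C'-N-CA plane
    nrm <- c((cp - n)[2] * (ca - n)[3] - (cp - n)[3] * (ca - n)[2],
             (cp - n)[3] * (ca - n)[1] - (cp - n)[1] * (ca - n)[3],
             (cp - n)[1] * (ca - n)[2] - (cp - n)[2] * (ca - n)[1])
    expect_equal(sum((h - n) * nrm) / sqrt(sum(nrm^2)), 0, tolerance = 1e-9)
    # equal angles to both heavy-atom bonds
    angto <- function(v) acos(sum((h - n) * v) / sqrt(sum((h - n)^2) * sum(v^2)))
    expect_equal(angto(cp - n), angto(ca - n), tolerance = 1e-6)
  }
  # idempotence after perturbing H
  pert <- mh
  sel <- pert$atoms$elety == "H"
  pert$atoms[sel, "x"] <- pert$atoms[sel, "x"] + 0.3
  again <- add_amide_hydrogens(pert, nh_bond_length = 1.02)
  expect_equal(again$atoms, mh$atoms, tolerance = 1e-12)
})

test_that("bond vector extraction counts, normalizes and is equivariant", {
  m <- add_amide_hydrogens(make_backbone(8, seed = 6))
  v <- extract_bond_vectors(m)
  # complete n-residue chain: 3n - 1 vectors minus the n with no H (res 1)
  # here: NH for 2..8 (7), C'N for 2..8 (7), CaC' for 1..8 (8) = 22 = 3n - 2
  expect_equal(nrow(v), 3 * 8 - 2)
  expect_equal(sqrt(rowSums(as.matrix(v[, c("x", "y", "z")])^2)),
               rep(1, nrow(v)), tolerance = 1e-10)
  # translation leaves directions unchanged
  mt <- m
  mt$atoms[, c("x", "y", "z")] <- mt$atoms[, c("x", "y", "z")] + 100
  vt <- extract_bond_vectors(mt)
  expect_equal(vt[, c("x", "y", "z")], v[, c("x", "y", "z")], tolerance = 1e-10)
  # rotation equivariance
  R <- rotation_about_axis(random_unit(9), 40)
  mr <- m
  mr$atoms[, c("x", "y", "z")] <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  vr <- extract_bond_vectors(mr)
  expect_equal(as.matrix(vr[, c("x", "y", "z")]),
               as.matrix(v[, c("x", "y", "z")]) %*% t(R), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("NH vector points from N to H and C'N is attributed to residue i", {
  atoms <- data.frame(
    chain = "A", resno = c(1, 1, 1, 2, 2, 2, 2),
    resid = "ALA",
    elety = c("N", "CA", "C", "N", "H", "CA", "C"),
    x = c(0, 1.4, 2.4, 3.0, 3.0, 4.4, 5.4),
    y = c(0, 0.3, 0.1, 0.9, 0.9, 1.2, 1.0),
    z = c(0, 0, 1.0, 1.5, 2.52, 1.8, 2.8))
  m <- structure_model(atoms)
  v <- extract_bond_vectors(m)
  nh <- v[v$type == "NH" & v$resno == 2, ]
  expect_equal(as.numeric(nh[, c("x", "y", "z")]), c(0, 0, 1))
  cn <- v[v$type == "C'N", ]
  expect_equal(cn$resno, 2)   # C'(1)-N(2) belongs to residue 2
  d <- c(3.0 - 2.4, 0.9 - 0.1, 1.5 - 1.0)
  expect_equal(as.numeric(cn[, c("x", "y", "z")]), d / sqrt(sum(d^2)),
               tolerance = 1e-12)
})

test_that("RDC tables parse, assign scales by type and reject bad input", {
  path <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c("# residue type value uncertainty",
               "42 NH 11.3 0.3",
               "42 C'N -0.9 0.1",
               "43 CaC' 2.1 0.2",
               "44 NH -3.2"), path)
  tbl <- read_rdc_table(path, default_uncertainty = 0.5)
  expect_s3_class(tbl, "rdc_table")
  expect_equal(nrow(tbl), 4)
  expect_equal(tbl$scale[tbl$resno == 42 & tbl$type == "NH"], 1)
  expect_equal(tbl$scale[tbl$type == "C'N"], 8)
  expect_equal(tbl$scale[tbl$type == "CaC'"], 5)
  expect_equal(tbl$value[tbl$resno == 42 & tbl$type == "NH"], 11.3)
  expect_equal(tbl$uncertainty[tbl$resno == 44], 0.5)

  bad <- withr::local_tempfile(fileext = ".tbl")
  writeLines("42 XY 1.0 0.1", bad)
  expect_error(read_rdc_table(bad), "line 1.*unknown coupling type")
  expect_error(rdc_table(c(1, 1), c("NH", "NH"), c(1, 2)), "duplicate")
  expect_error(rdc_table(1, "NH", 1, uncertainty = 0), "positive")
})
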