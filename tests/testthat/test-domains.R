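test_that("identical structures keep every residue with zero deviation", {
  m <- make_backbone(20, seed = 1)
  m2 <- m; m2$label <- "copy"
  res <- find_invariant_core(list(m, m2), region = 1:20)
  expect_equal(res$domain$residues, 1:20)
  expect_lt(max(vapply(res$superpositions, function(s) s$rmsd, 0)), 1e-9)
})

test_that("rigidly displaced residues are excluded, the rest retained", {
  pair <- make_structure_pair(n_res = 30, moved_residues = 10:20,
                              shift = c(2, 0, 0), seed = 2)
  res <- find_invariant_core(pair, region = 1:30, distance_cutoff = 0.5)
  expect_equal(res$domain$residues, setdiff(1:30, 10:20))
})

test_that("greedy core search agrees with brute-force subset search on a toy case", {
  # 10 residues, three perturbed by varied amounts; brute force = for each
  # candidate subset size, check the cutoff criterion on the greedy result
  # against exhaustive enumeration of which residues can co-exist
  pair <- make_structure_pair(n_res = 10, moved_residues = c(3, 6, 9),
                              shift = c(2, 0, 0), seed = 3)
  res <- find_invariant_core(pair, region = 1:10, distance_cutoff = 0.4)
  # brute force over all subsets of size >= 4 (1013 subsets)
  dev_of <- function(sub) {
    bb <- rdcsvd:::shared_backbone(pair, sub)
    pm <- rdcsvd:::procrustes_mean(bb)
    ca <- seq(2, nrow(bb[[1]]), by = 3)
    max(sqrt(Reduce(`+`, lapply(pm$positions, function(p)
      rowSums((p[ca, , drop = FALSE] - pm$mean[ca, , drop = FALSE])^2))) /
        length(pair)))
  }
  best <- integer(0)
  for (size in 10:4) {
    combs <- utils::combn(10, size)
    ok_sizes <- apply(combs, 2, function(sub) dev_of(sub) <= 0.4)
    if (any(ok_sizes)) { best <- combs[, which(ok_sizes)[1]]; break }
  }
  expect_equal(length(res$domain$residues), length(best))
  expect_equal(res$domain$residues, sort(setdiff(1:10, c(3, 6, 9))))
})

test_that("core search is invariant to pre-rotating an input structure", {
  pair <- make_structure_pair(n_res = 25, moved_residues = 5:8,
                              shift = c(1.5, 0.5, 0), seed = 4)
  res1 <- find_invariant_core(pair, region = 1:25)
  rot <- pair
  R <- rotation_about_axis(random_unit(5), 63)
  rot[[2]]$atoms[, c("x", "y", "z")] <-
    as.matrix(rot[[2]]$atoms[, c("x", "y", "z")]) %*% t(R) + 5
  res2 <- find_invariant_core(rot, region = 1:25)
  expect_equal(res1$domain$residues, res2$domain$residues)
  expect_equal(vapply(res1$superpositions, function(s) s$rmsd, 0),
               vapply(res2$superpositions, function(s) s$rmsd, 0),
               tolerance = 1e-8)
})

test_that("raising the distance cutoff never shrinks the core", {
  pair <- make_structure_pair(n_res = 20, moved_residues = c(4, 9, 15),
                              shift = c(0.8, 0, 0), jitter = 0.05, seed = 6)
  sizes <- vapply(c(0.2, 0.5, 1.0, 3), function(cut)
    length(find_invariant_core(pair, 1:20, cut)$domain$residues), 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("degenerate cores raise an error", {
  pair <- make_structure_pair(n_res = 6, moved_residues = 1:6,
                              jitter = 3, seed = 7)
  expect_error(find_invariant_core(pair, 1:6, distance_cutoff = 0.05),
               "degenerate core")
})

test_that("vector-angle pruning retains consistent planes and matches hand-computed RMS", {
  m1 <- add_amide_hydrogens(make_backbone(12, seed = 8))
  m2 <- m1; m2$label <- "c2"
  m3 <- m1; m3$label <- "c3"
  # tilt residue 7's N-H by 12 degrees in one of three structures
  k <- 7
  n <- as.numeric(m2$atoms[m2$atoms$resno == k & m2$atoms$elety == "N",
                           c("x", "y", "z")])
  h <- as.numeric(m2$atoms[m2$atoms$resno == k & m2$atoms$elety == "H",
                           c("x", "y", "z")])
  v <- h - n
  perp <- c(v[2], -v[1], 0); perp <- perp / sqrt(sum(perp^2))
  tilt <- rotation_about_axis(perp, 12)
  m2$atoms[m2$atoms$resno == k & m2$atoms$elety == "H", c("x", "y", "z")] <-
    rbind(n + drop(tilt %*% v))
  dom <- domain_definition("D", 2:12)
  pruned <- prune_by_vector_angle(list(m1, m2, m3), dom, angle_threshold = 5)
  # hand-computed: one vector of nine (3 structures x 3 types) deviates;
  # mean dir pulls back ~4 deg toward the tilted copy; RMS over the three
  # structures and three types for plane k:
  rms <- attr(pruned, "rms_angle")[as.character(k)]
  # oracle: direct arithmetic on the three N-H directions + identical others
  d0 <- v / sqrt(sum(v^2)); d1 <- drop(tilt %*% v); d1 <- d1 / sqrt(sum(d1^2))
  mn <- (2 * d0 + d1); mn <- mn / sqrt(sum(mn^2))
  angs <- acos(pmin(1, c(sum(d0 * mn), sum(d1 * mn), sum(d0 * mn)))) * 180 / pi
  expect_equal(unname(rms), sqrt(mean(c(angs^2, rep(0, 6)))), tolerance = 1e-6)
  # pooled over 9 vectors the 12-degree single-vector tilt stays under 5
  expect_lt(rms, 5)
  expect_true(k %in% pruned$invariant_planes)
  expect_true(all(setdiff(3:12, k) %in% pruned$invariant_planes))
  # a 40-degree tilt pushes the pooled RMS over the threshold
  m2b <- m1
  vv <- as.numeric(m2b$atoms[m2b$atoms$resno == k & m2b$atoms$elety == "H",
                             c("x", "y", "z")]) -
    as.numeric(m2b$atoms[m2b$atoms$resno == k & m2b$atoms$elety == "N",
                         c("x", "y", "z")])
  pp <- c(vv[2], -vv[1], 0); pp <- pp / sqrt(sum(pp^2))
  m2b$atoms[m2b$atoms$resno == k & m2b$atoms$elety == "H", c("x", "y", "z")] <-
    rbind(as.numeric(m2b$atoms[m2b$atoms$resno == k & m2b$atoms$elety == "N",
                               c("x", "y", "z")]) +
            drop(rotation_about_axis(pp, 40) %*% vv))
  m2b$label <- "c2b"
  pruned2 <- prune_by_vector_angle(list(m1, m2b, m3), dom,
                                   angle_threshold = 5)
  expect_false(k %in% pruned2$invariant_planes)
  # identical structures: everything retained at RMS 0
  all_same <- prune_by_vector_angle(list(m1, m1, m1), dom)
  expect_equal(all_same$invariant_planes, dom$residues)
})

test_that("vector averaging preserves bond lengths and reduces to the base", {
  m1 <- add_amide_hydrogens(make_backbone(10, seed = 9))
  dom <- domain_definition("D", 2:10)
  # single structure: output equals base
  one <- average_vector_orientations(list(m1), m1, dom)
  expect_equal(one$model$atoms, m1$atoms, tolerance = 1e-9)
  # symmetric +/- tilt: averaged N-H equals the base direction
  tilt_nh <- function(m, k, ang) {
    n <- as.numeric(m$atoms[m$atoms$resno == k & m$atoms$elety == "N",
                            c("x", "y", "z")])
    h <- as.numeric(m$atoms[m$atoms$resno == k & m$atoms$elety == "H",
                            c("x", "y", "z")])
    v <- h - n
    perp <- c(v[2], -v[1], 0); perp <- perp / sqrt(sum(perp^2))
    m$atoms[m$atoms$resno == k & m$atoms$elety == "H", c("x", "y", "z")] <-
      rbind(n + drop(rotation_about_axis(perp, ang) %*% v))
    m
  }
  m2 <- tilt_nh(m1, 5, 8);  m2$label <- "p"
  m3 <- tilt_nh(m1, 5, -8); m3$label <- "m"
  avg <- average_vector_orientations(list(m1, m2, m3), m1, dom)
  v_base <- extract_bond_vectors(m1)
  v_avg <- extract_bond_vectors(avg$model)
  nh_b <- as.numeric(v_base[v_base$resno == 5 & v_base$type == "NH",
                            c("x", "y", "z")])
  nh_a <- as.numeric(v_avg[v_avg$resno == 5 & v_avg$type == "NH",
                           c("x", "y", "z")])
  expect_equal(nh_a, nh_b, tolerance = 1e-6)
  # bond lengths preserved for repositioned atoms
  for (r in 3:9) {
    for (pair in list(c("N", "H"))) {
      b0 <- sqrt(sum((as.numeric(m1$atoms[m1$atoms$resno == r &
                                            m1$atoms$elety == pair[2],
                                          c("x", "y", "z")]) -
                        as.numeric(m1$atoms[m1$atoms$resno == r &
                                              m1$atoms$elety == pair[1],
                                            c("x", "y", "z")]))^2))
      b1 <- sqrt(sum((as.numeric(avg$model$atoms[avg$model$atoms$resno == r &
                                                   avg$model$atoms$elety == pair[2],
                                                 c("x", "y", "z")]) -
                        as.numeric(avg$model$atoms[avg$model$atoms$resno == r &
                                                     avg$model$atoms$elety == pair[1],
                                                   c("x", "y", "z")]))^2))
      expect_equal(b1, b0, tolerance = 1e-9)
    }
  }
  expect_error(average_vector_orientations(list(m2, m3), m1, dom), "base")
})

test_that("two-domain hinge fixture recovers the generating partition", {
  # shift along the rotation axis: a screw motion with nonzero advance
  # displaces every moved atom by at least the advance, so no spurious
  # cross-domain consistency is possible
  pair <- make_structure_pair(n_res = 30, moved_residues = 16:30,
                              axis = c(0, 1, 0), angle = 40,
                              shift = c(0, 6, 0), seed = 10)
  d1 <- find_invariant_core(pair, region = 1:30, name = "A")
  expect_equal(d1$domain$residues, 1:15)
  remaining <- setdiff(1:30, d1$domain$residues)
  d2 <- find_invariant_core(pair, region = remaining, name = "B")
  expect_equal(d2$domain$residues, 16:30)
})
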