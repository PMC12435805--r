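test_that("axis vectors run from the centre of mass to C-alpha(12)", {
  gb <- make_toy_gb(3)
  v <- axis_vector(gb$atoms, gb$ann)
  expect_equal(v$D, v$tip - v$origin)
  expect_gt(vec_norm_for_test(v$D), 0)
  # translation leaves D unchanged
  moved <- apply_transform(gb$atoms, rigid_transform(diag(3), c(7, -3, 2)))
  v2 <- axis_vector(moved, gb$ann)
  expect_equal(v2$D, v$D, tolerance = 1e-12)
  expect_equal(v2$origin, v$origin + c(7, -3, 2), tolerance = 1e-12)
  # mass vs uniform weighting shifts the origin by the hand-computed amount
  co <- points_atom_set(rbind(c(0, 0, 0), c(1, 0, 0)), element = c("C", "O"))
  ann <- gb$ann
  expect_equal(center_of_mass(co)[1] - center_of_mass(co, "uniform")[1],
               15.999 / (12.011 + 15.999) - 0.5, tolerance = 1e-12)
})


test_that("missing C-alpha(12) raises an error naming the position", {
  gb <- make_toy_gb(4)
  key12 <- gb$ann$imgt_resno[["12"]]
  resno12 <- as.integer(strsplit(key12, "|", fixed = TRUE)[[1]][1])
  pruned <- gb$atoms[!(gb$atoms$resno == resno12 & gb$atoms$elety == "CA"), ]
  class(pruned) <- c("atom_set", "data.frame")
  expect_error(axis_vector(pruned, gb$ann), "12")
})

test_that("intra-DiGb angles follow the vector geometry", {
  expect_equal(intra_digb_angle(c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(intra_digb_angle(c(1, 0, 0), c(0, 3, 0)), 90)
  expect_equal(intra_digb_angle(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_error(intra_digb_angle(c(0, 0, 0), c(1, 0, 0)), "zero-length")
  gb <- make_toy_gb(5)
  for (ang in c(71.3, 85, 100.7)) {
    sc <- assemble_digb(gb, ang)
    g <- digb_geometry(sc$atoms, sc$ann_a, sc$ann_b)
    expect_equal(g$intra_digb_angle, ang, tolerance = 0.1)
    expect_equal(g$c12_separation, 6, tolerance = 0.01)
  }
})

test_that("identical frames give zero wobble and exact mean decomposition", {
  gb <- make_toy_gb(6)
  sc <- assemble_digb(gb, 85)
  frames <- list(sc$atoms, sc$atoms, sc$atoms)
  gs <- wobble_series(frames, sc$ann_a, sc$ann_b)
  expect_lte(max(gs$beta), 1e-6)
  expect_equal(colSums(sweep(gs$D_mobile, 2, gs$D_a_mobile)), c(0, 0, 0),
               tolerance = 1e-9)
})

test_that("a symmetric two-frame series splits the angle evenly", {
  gb <- make_toy_gb(6)
  sc <- assemble_digb(gb, 90)
  # two frames with the mobile Gb tilted +10 and -10 degrees about the hinge
  ws <- make_wobble_series(sc, amplitude = 10, n_frames = 2, seed = 1)
  gs <- wobble_series(ws$frames, ws$ann_a, ws$ann_b)
  expect_equal(gs$beta, c(10, 10), tolerance = 1e-6)
})

test_that("wobble angles equal a direct recomputation from stored vectors", {
  gb <- make_toy_gb(7)
  sc <- assemble_digb(gb, 85)
  ws <- make_wobble_series(sc, amplitude = 3, n_frames = 60, seed = 13)
  gs <- wobble_series(ws$frames, ws$ann_a, ws$ann_b)
  Da <- colMeans(gs$D_mobile)
  beta_direct <- vapply(seq_len(60), function(i) {
    d <- gs$D_mobile[i, ]
    cosv <- sum(Da * d) / (sqrt(sum(Da^2)) * sqrt(sum(d^2)))
    acos(max(-1, min(1, cosv))) * 180 / pi
  }, numeric(1))
  expect_equal(gs$beta, beta_direct, tolerance = 1e-6)
  expect_equal(max(gs$beta), max(beta_direct))
})

test_that("angle outputs are invariant under global rigid motion of a series", {
  gb <- make_toy_gb(8)
  sc <- assemble_digb(gb, 80)
  ws <- make_wobble_series(sc, amplitude = 5, n_frames = 8, seed = 3)
  base <- wobble_series(ws$frames, ws$ann_a, ws$ann_b)
  set.seed(4)
  G <- rigid_transform(random_rotation(), rnorm(3, sd = 25))
  moved <- lapply(ws$frames, apply_transform, transform = G)
  gs <- wobble_series(moved, ws$ann_a, ws$ann_b)
  expect_equal(gs$beta, base$beta, tolerance = 1e-6)
  expect_equal(gs$intra_digb_angle, base$intra_digb_angle, tolerance = 1e-6)
})

test_that("residue minimum distances use heavy atoms only", {
  a <- points_atom_set(c(0, 0, 0))
  b <- points_atom_set(c(2.5, 0, 0))
  expect_equal(residue_min_distance(a, b), 2.5)
  expect_equal(residue_min_distance(b, a), 2.5)
  # a nearer hydrogen is ignored
  bh <- points_atom_set(rbind(c(1.0, 0, 0), c(2.5, 0, 0)),
                        element = c("H", "O"))
  expect_equal(residue_min_distance(a, bh), 2.5)
  h_only <- points_atom_set(c(1, 0, 0), element = "H")
  expect_error(residue_min_distance(a, h_only), "heavy")
  set.seed(12)
  for (rep in 1:5) {
    A <- matrix(rnorm(24, sd = 3), ncol = 3)
    B <- matrix(rnorm(24, sd = 3) + 2, ncol = 3)
    expect_equal(residue_min_distance(points_atom_set(A), points_atom_set(B)),
                 brute_min_distance(A, B), tolerance = 1e-12)
  }
})

test_that("interface contacts flag close N/O pairs as hydrogen bonds", {
  gb <- make_toy_gb(9, n_res = 30)
  far <- assemble_digb(gb, 85)
  # push the copies far apart: no contacts at all
  b <- far$atoms
  bsel <- b$chain == "B"
  b$x[bsel] <- b$x[bsel] + 100
  class(b) <- c("atom_set", "data.frame")
  expect_equal(nrow(interface_contacts(b, far$ann_a, far$ann_b)), 0)
  # constructed interface: backbone N--O pair at 2.9 A
  two <- atom_set(data.frame(
    chain = c("A", "B"), resno = c(1, 1), resid = "GLY",
    elety = c("N", "O"), element = c("N", "O"),
    x = c(0, 2.9), y = 0, z = 0))
  ann_a <- far$ann_a; ann_a$imgt_resno <- c(`12` = "1|")
  ann_b <- far$ann_b; ann_b$imgt_resno <- c(`12` = "1|")
  ct <- interface_contacts(two, ann_a, ann_b)
  expect_equal(nrow(ct), 1)
  expect_true(ct$is_hbond)
  expect_equal(ct$min_heavy_distance, 2.9, tolerance = 1e-9)
  expect_identical(ct$hbond_atoms, "N--O")
  # a 3.8 A carbon pair is a contact but not a hydrogen bond
  two$elety <- c("CA", "CA"); two$element <- c("C", "C"); two$x <- c(0, 3.8)
  ct2 <- interface_contacts(two, ann_a, ann_b)
  expect_equal(nrow(ct2), 1)
  expect_false(ct2$is_hbond)
})

test_that("contacts appear at the assembled DiGb interface near residue 12", {
  gb <- make_toy_gb(10)
  sc <- assemble_digb(gb, 85, c12_separation = 4)
  ct <- interface_contacts(sc$atoms, sc$ann_a, sc$ann_b, contact_cutoff = 4.5)
  expect_gt(nrow(ct), 0)
  expect_true("12" %in% c(ct$imgt_a, ct$imgt_b))
})
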