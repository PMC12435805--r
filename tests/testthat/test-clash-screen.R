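test_that("the 4 A sphere boundary is inclusive", {
  probe <- points_atom_set(c(0, 0, 0))
  expect_equal(count_clash_atoms(probe, points_atom_set(c(5, 0, 0)), 4), 0)
  expect_equal(count_clash_atoms(probe, points_atom_set(c(3.9, 0, 0)), 4), 1)
  expect_equal(count_clash_atoms(probe, points_atom_set(c(4.0, 0, 0)), 4), 1)
  expect_error(count_clash_atoms(probe, probe, 0), "positive")
})

test_that("cell-list counting equals the all-pairs oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    P <- matrix(runif(3 * sample(50:200, 1), 0, 20), ncol = 3)
    E <- matrix(runif(3 * sample(50:200, 1), 0, 20), ncol = 3)
    cutoff <- runif(1, 1, 5)
    expect_identical(count_clash_atoms(points_atom_set(P), points_atom_set(E), cutoff),
                     brute_clash_count(P, E, cutoff))
  }
})

test_that("clash counts are monotone in the cutoff and ignore hydrogens", {
  set.seed(9)
  P <- points_atom_set(matrix(runif(300, 0, 15), ncol = 3))
  E <- points_atom_set(matrix(runif(300, 0, 15), ncol = 3))
  counts <- vapply(c(1, 2, 3, 4, 6, 9), function(cf)
    count_clash_atoms(P, E, cf), integer(1))
  expect_false(is.unsorted(counts))
  # a hydrogen sitting inside the cutoff contributes nothing
  Eh <- points_atom_set(rbind(c(50, 0, 0), c(70, 0, 0)), element = c("H", "C"))
  expect_equal(count_clash_atoms(points_atom_set(c(50, 0, 1)), Eh, 4), 0L)
})

test_that("clash reports classify against the 5% threshold", {
  expect_identical(clash_report(0, 200)$classification, "no_clash")
  expect_identical(clash_report(6, 200)$classification, "under_5pct")
  expect_identical(clash_report(10, 200)$classification, "over_5pct")
  expect_equal(clash_report(6, 200)$score, 0.03)
  expect_error(clash_report(10, 5), ">=|not")
})

scaffold_fixture <- local({
  gb <- make_toy_gb(21)
  assemble_digb(gb, 85)
})

test_that("screening recovers planted clash fractions through placement", {
  sc <- scaffold_fixture
  ann <- list(sc$ann_a, sc$ann_b)
  clean <- make_survey_entry(sc, 0, seed = 31)
  rep0 <- screen_on_scaffold(clean$atoms, sc$atoms, complex_ann = clean$ann,
                             scaffold_ann = ann)
  expect_equal(rep0$n_clash, 0L)
  expect_identical(rep0$classification, "no_clash")
  expect_lte(max(rep0$placement_rmsd), 1e-6)
  planted <- make_survey_entry(sc, 0.03, seed = 32)
  rep3 <- screen_on_scaffold(planted$atoms, sc$atoms, complex_ann = planted$ann,
                             scaffold_ann = ann)
  expect_equal(rep3$score, 0.03)
  expect_identical(rep3$classification, "under_5pct")
})

test_that("a degenerate scaffold with coincident Gb copies scores 1", {
  sc <- scaffold_fixture
  # both placements identical: copy B lands exactly on copy A
  degenerate_ann <- list(sc$ann_a, sc$ann_a)
  entry <- make_survey_entry(sc, 0, seed = 33)
  rep <- screen_on_scaffold(entry$atoms, sc$atoms, complex_ann = entry$ann,
                            scaffold_ann = degenerate_ann)
  expect_equal(rep$score, 1.0)
})

test_that("clash reports are invariant under a global rigid motion", {
  sc <- scaffold_fixture
  ann <- list(sc$ann_a, sc$ann_b)
  entry <- make_survey_entry(sc, 0.1, seed = 34)
  base <- screen_on_scaffold(entry$atoms, sc$atoms, complex_ann = entry$ann,
                             scaffold_ann = ann)
  set.seed(35)
  G <- rigid_transform(random_rotation(), rnorm(3, sd = 20))
  moved_complex <- apply_transform(entry$atoms, G)
  moved_scaffold <- apply_transform(sc$atoms, G)
  rep <- screen_on_scaffold(moved_complex, moved_scaffold,
                            complex_ann = entry$ann, scaffold_ann = ann)
  expect_equal(rep$n_clash, base$n_clash)
  expect_equal(rep$score, base$score)
})

test_that("library surveys aggregate planted classes and skip failures", {
  sc <- scaffold_fixture
  ann <- list(sc$ann_a, sc$ann_b)
  fracs <- c(0, 0, 0, 0, 0.03, 0.03, 0.03, 0.1, 0.1, 0.1)
  entries <- lapply(seq_along(fracs), function(i) {
    e <- make_survey_entry(sc, fracs[i], seed = 40 + i)
    list(atoms = e$atoms, ann = e$ann)
  })
  names(entries) <- sprintf("entry%02d", seq_along(entries))
  sv <- survey_library(entries, sc$atoms, scaffold_ann = ann)
  expect_equal(sv$fraction_no_clash, 0.4)
  expect_equal(sv$fraction_under_threshold, 0.7)
  expect_equal(sv$n_screened, 10)
  # an unusable entry is skipped with a reason, not fatal
  entries$broken <- list(atoms = points_atom_set(matrix(runif(30), ncol = 3),
                                                 chain = "T"),
                         ann = NULL)
  sv2 <- survey_library(entries, sc$atoms, scaffold_ann = ann)
  expect_equal(sv2$n_screened, 10)
  expect_length(sv2$skipped, 1)
  expect_match(names(sv2$skipped), "broken")
})
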