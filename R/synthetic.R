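# Deterministic synthetic-structure generators with planted ground truth.
#
# The toy folds are rigid, chirality-bearing backbones with IMGT-labelled
# residues, not physically realistic immunoglobulin domains: every in-scope
# computation (superposition, clash counting, axis-vector geometry) is
# purely geometric and needs only labelled rigid bodies of non-degenerate
# shape. All randomness flows through an explicit seed via a private RNG
# stream, so generation never touches the caller's RNG state and the same
# (seed, parameters) always reproduces bit-identical output.

with_private_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a toy Gb body with IMGT-labelled residues
#'
#' Builds a rigid backbone (N, CA, C, O per residue) along an irregular
#' helical curve with seeded jitter, giving an asymmetric, chirality-bearing
#' body. Residues are labelled with IMGT framework positions taken from the
#' embedded reference: the interface-critical positions (7, 12, 14, 44, 46,
#' 47, 84, 120, 123, 125) are always included and the rest of the framework
#' fills the remaining residues in increasing IMGT order. The sequence
#' carries the core Gb substitutions (N7, C12, K14, M125), so residue 12 is
#' the cysteine that hinges the dimer.
#'
#' @param seed integer seed; the same seed reproduces the body bit-exactly.
#' @param n_res number of residues, between 30 and 140 (default 90; at most
#'   91 residues receive framework labels).
#' @return list (class `toy_gb`) with `atoms` (an `atom_set`, chain `"A"`),
#'   `ann` (a `chain_annotation`) and `imgt` (per-residue labels).
#' @export
make_toy_gb <- function(seed, n_res = 90) {
  if (!is.numeric(n_res) || n_res < 30 || n_res > 140)
    stop("n_res must lie in [30, 140]", call. = FALSE)
  n_res <- as.integer(n_res)
  ref <- gb_reference()
  fw <- ref[ref$region == "FR", , drop = FALSE]
  required <- c(7, 12, 14, 44, 46, 47, 84, 120, 123, 125)
  n_label <- min(n_res, nrow(fw))
  extra <- setdiff(fw$imgt, required)
  take <- sort(c(required,
                 extra[unique(round(seq(1, length(extra),
                                        length.out = n_label - length(required))))]))
  take <- take[seq_len(min(length(take), n_label))]
  res1 <- fw$res[match(take, fw$imgt)]
  core <- c(`7` = "N", `12` = "C", `14` = "K", `125` = "M")
  hit <- as.character(take) %in% names(core)
  res1[hit] <- core[as.character(take[hit])]
  # unlabeled spacer residues (only when n_res > labelled framework): glycines
  n_spacer <- n_res - length(take)
  seq1 <- c(res1, rep("G", n_spacer))

  xyz <- with_private_seed(seed, {
    i <- seq_len(n_res)
    radius <- 8 + 3 * sin(i / 11)
    ca <- cbind(radius * cos(i * 100 * pi / 180),
                radius * sin(i * 100 * pi / 180),
                1.6 * i + 2 * cos(i / 7))
    ca <- ca + matrix(stats::runif(3 * n_res, -0.8, 0.8), ncol = 3)
    list(ca = ca,
         wob = matrix(stats::runif(3 * n_res, -0.15, 0.15), ncol = 3))
  })
  ca <- xyz$ca
  # backbone satellites at fixed chiral offsets from CA, with small jitter
  off_n <- c(-1.20, 0.45, 0.30); off_c <- c(1.15, 0.50, -0.25); off_o <- c(1.90, 1.55, -0.35)
  per_res <- function(k) {
    r3 <- bio3d::aa123(seq1[k])
    data.frame(chain = "A", resno = k, insert = "",
               resid = r3,
               elety = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               x = ca[k, 1] + c(off_n[1], 0, off_c[1], off_o[1]) + xyz$wob[k, 1],
               y = ca[k, 2] + c(off_n[2], 0, off_c[2], off_o[2]) + xyz$wob[k, 2],
               z = ca[k, 3] + c(off_n[3], 0, off_c[3], off_o[3]) + xyz$wob[k, 3],
               o = 1, alt = "", is_h = FALSE, stringsAsFactors = FALSE)
  }
  atoms <- atom_set(do.call(rbind, lapply(seq_len(n_res), per_res)),
                    source = sprintf("make_toy_gb(seed=%d, n_res=%d)", seed, n_res))
  map_tab <- data.frame(query_index = seq_along(take),
                        residue = res1,
                        imgt = as.character(take),
                        region = "FR", stringsAsFactors = FALSE)
  map <- structure(list(query = paste(seq1, collapse = ""), table = map_tab,
                        cdr_spans = .imgt_cdr_spans, framework_identity = 1,
                        alignment_score = NA_real_),
                   class = "framework_map")
  ann <- chain_annotation_direct("A", map, resno = seq_along(take))
  structure(list(atoms = atoms, ann = ann, imgt = take, seed = seed),
            class = "toy_gb")
}

#' @export
print.toy_gb <- function(x, ...) {
  cat(sprintf("<toy_gb> %d residues, %d IMGT-labelled (seed %d)\n",
              max(x$atoms$resno), length(x$imgt), x$seed))
  invisible(x)
}

relabel_chain <- function(atoms, chain) { atoms$chain <- chain; atoms }

reannotate <- function(ann, chain) {
  out <- ann; out$chain <- chain; out
}

#' Assemble a synthetic DiGb dimer at a requested intra-DiGb angle
#'
#' The second copy is generated by rotating the body about an axis
#' perpendicular to its axis vector, centred at the C-alpha of residue 12,
#' then translating along that rotation axis. Because the rotation axis is
#' perpendicular to `D`, the rotation changes the axis direction by exactly
#' the requested angle, and because the translation is along the axis
#' through C-alpha(12), the C12--C12 separation equals the requested span
#' exactly. The generating screw transform is stored as ground truth.
#'
#' @param gb a `toy_gb` (or list with `atoms` and `ann`).
#' @param intra_angle requested intra-DiGb angle in degrees, (0, 180\].
#' @param c12_separation requested C-alpha(12) separation in Angstroms,
#'   within the disulfide-like span \[4, 8\] (default 6).
#' @return a `synthetic_scene` with `atoms` (chains `"A"` and `"B"`),
#'   annotations for both chains, the generating `transform`, and `truth`
#'   (`intra_angle`, `c12_separation`, plus the measured closure values).
#' @export
assemble_digb <- function(gb, intra_angle, c12_separation = 6) {
  if (!is.numeric(intra_angle) || intra_angle <= 0 || intra_angle > 180)
    stop("intra_angle must lie in (0, 180] degrees", call. = FALSE)
  if (!is.numeric(c12_separation) || c12_separation < 4 || c12_separation > 8)
    stop("c12_separation must lie in [4, 8] Angstroms", call. = FALSE)
  atoms_a <- gb$atoms; ann_a <- gb$ann
  va <- axis_vector(atoms_a, ann_a)
  axis <- perpendicular_unit(va$D)
  R <- rotation_about_axis(axis, intra_angle)
  tip <- va$tip
  # screw motion: rotate about the axis line through C-alpha(12), then
  # slide along the same axis
  M <- rigid_transform(R, tip - as.numeric(R %*% tip) + c12_separation * axis)
  atoms_b <- relabel_chain(apply_transform(atoms_a, M), "B")
  ann_b <- reannotate(ann_a, "B")
  combined <- rbind(atoms_a, atoms_b)
  geom <- digb_geometry(combined, ann_a, ann_b)
  if (abs(geom$intra_digb_angle - intra_angle) > 0.1 ||
      abs(geom$c12_separation - c12_separation) > 0.01)
    stop("assembly closure failed: measured ",
         sprintf("%.3f deg / %.3f A", geom$intra_digb_angle, geom$c12_separation),
         call. = FALSE)
  structure(list(atoms = combined, ann_a = ann_a, ann_b = ann_b,
                 transform = M, axis = axis, tip = tip,
                 truth = list(intra_angle = intra_angle,
                              c12_separation = c12_separation,
                              measured_angle = geom$intra_digb_angle,
                              measured_separation = geom$c12_separation),
                 seed = gb$seed, generator = "assemble_digb"),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %s; truth: %s\n", x$generator,
              paste(names(x$truth), vapply(x$truth, function(v)
                paste(signif(unlist(v), 4), collapse = ","), ""),
                sep = "=", collapse = ", ")))
  invisible(x)
}

#' Generate a wobble series of DiGb frames with planted amplitude
#'
#' Each frame re-orients the mobile Gb (chain B) by a rotation about its
#' hinge (the C-alpha of residue 12) about a per-frame axis perpendicular to
#' its axis vector. Tilt magnitudes are drawn in azimuth-opposed pairs, so
#' the frame-average axis direction equals the unwobbled one exactly and the
#' planted per-frame tilts are exactly the wobble angles beta_i the analysis
#' should recover; the maximum tilt equals `amplitude` by construction.
#' Every frame additionally receives a random global rigid motion, which the
#' analysis must undo by superposing on the static Gb.
#'
#' @param digb a `synthetic_scene` from [assemble_digb()].
#' @param amplitude maximum wobble angle in degrees (>= 0).
#' @param n_frames number of frames (default 60, the usual length of a 3D
#'   variability model series).
#' @param seed integer seed.
#' @return a `synthetic_scene` whose `frames` field is a list of `atom_set`s
#'   and whose `truth` records `amplitude` and the per-frame `tilts`.
#' @export
make_wobble_series <- function(digb, amplitude, n_frames = 60, seed = 1) {
  stopifnot(inherits(digb, "synthetic_scene"))
  if (!is.numeric(amplitude) || amplitude < 0)
    stop("amplitude must be >= 0", call. = FALSE)
  if (n_frames < 2) stop("need n_frames >= 2", call. = FALSE)
  atoms <- digb$atoms
  ann_b <- digb$ann_b
  vb <- axis_vector(atoms, ann_b)
  e1 <- perpendicular_unit(vb$D)
  e2 <- unit_vec(cross3(unit_vec(vb$D), e1))
  n_pairs <- n_frames %/% 2L
  sim <- with_private_seed(seed, {
    tilt_p <- if (n_pairs >= 1)
      c(amplitude, if (n_pairs > 1) stats::runif(n_pairs - 1, 0, amplitude))
    else numeric()
    phi_p <- stats::runif(max(n_pairs, 1), 0, 2 * pi)[seq_len(n_pairs)]
    glob <- lapply(seq_len(n_frames), function(i)
      list(ax = stats::rnorm(3), ang = stats::runif(1, 0, 360),
           tr = stats::runif(3, -20, 20)))
    list(tilt_p = tilt_p, phi_p = phi_p, glob = glob)
  })
  tilts <- numeric(n_frames); phis <- numeric(n_frames)
  for (j in seq_len(n_pairs)) {
    tilts[2 * j - 1] <- sim$tilt_p[j]; phis[2 * j - 1] <- sim$phi_p[j]
    tilts[2 * j] <- sim$tilt_p[j]; phis[2 * j] <- sim$phi_p[j] + pi
  }
  # odd frame count: one exactly-average frame (zero tilt)
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    w <- cos(phis[i]) * e1 + sin(phis[i]) * e2
    Rw <- rotation_about_axis(w, tilts[i])
    hinge <- rigid_transform(Rw, vb$tip - as.numeric(Rw %*% vb$tip))
    fr <- atoms
    bsel <- fr$chain == "B"
    bxyz <- apply_transform(coords(fr)[bsel, , drop = FALSE], hinge)
    fr$x[bsel] <- bxyz[, 1]; fr$y[bsel] <- bxyz[, 2]; fr$z[bsel] <- bxyz[, 3]
    g <- sim$glob[[i]]
    G <- rigid_transform(rotation_about_axis(g$ax, g$ang), g$tr)
    frames[[i]] <- apply_transform(fr, G)
  }
  structure(list(frames = frames, ann_a = digb$ann_a, ann_b = ann_b,
                 truth = list(amplitude = amplitude, tilts = tilts,
                              intra_angle = digb$truth$intra_angle),
                 seed = seed, generator = "make_wobble_series"),
            class = "synthetic_scene")
}

#' Generate two atom sets with an exact planted clash count
#'
#' Places `n_atoms` probe atoms against a compact random environment cloud:
#' exactly `k_clash` probes are put within `cutoff` of an environment atom
#' and the remainder on a far-away lattice, strictly farther than
#' `cutoff + 1` from every environment atom. The construction is verified
#' against an all-pairs distance check before returning.
#'
#' @param n_atoms number of probe atoms.
#' @param k_clash planted number of clashing probes, `0 <= k <= n`.
#' @param cutoff clash distance (default 4.0).
#' @param seed integer seed.
#' @return a `synthetic_scene` with `probe` and `environment` `atom_set`s
#'   and `truth$n_clash = k_clash`.
#' @export
make_clash_scene <- function(n_atoms, k_clash, cutoff = 4.0, seed = 1) {
  if (k_clash < 0 || k_clash > n_atoms)
    stop("need 0 <= k_clash <= n_atoms", call. = FALSE)
  n_env <- 40L
  sim <- with_private_seed(seed, {
    env <- matrix(stats::runif(3 * n_env, -8, 8), ncol = 3)
    anchor <- sample.int(n_env, k_clash, replace = TRUE)
    dirs <- matrix(stats::rnorm(3 * max(k_clash, 1)), ncol = 3)[seq_len(k_clash), , drop = FALSE]
    dist <- stats::runif(k_clash, 0.35 * cutoff, 0.95 * cutoff)
    jit <- matrix(stats::runif(3 * n_atoms, -0.3, 0.3), ncol = 3)
    list(env = env, anchor = anchor, dirs = dirs, dist = dist, jit = jit)
  })
  env <- sim$env
  probes <- matrix(NA_real_, n_atoms, 3)
  if (k_clash > 0) {
    u <- sim$dirs / sqrt(rowSums(sim$dirs^2))
    probes[seq_len(k_clash), ] <- env[sim$anchor, , drop = FALSE] + u * sim$dist
  }
  n_far <- n_atoms - k_clash
  if (n_far > 0) {
    far_x <- 60 + (cutoff + 6) * seq_len(n_far)
    probes[k_clash + seq_len(n_far), ] <-
      cbind(far_x, 0, 0) + sim$jit[k_clash + seq_len(n_far), , drop = FALSE]
  }
  # all-pairs verification of the planted truth
  d2 <- outer(rowSums(probes^2), rowSums(env^2), "+") - 2 * probes %*% t(env)
  near <- apply(d2 <= cutoff^2, 1, any)
  dmin <- sqrt(pmax(0, apply(d2, 1, min)))
  if (sum(near) != k_clash ||
      (n_far > 0 && any(dmin[k_clash + seq_len(n_far)] <= cutoff + 1)))
    stop("infeasible packing for the requested clash scene", call. = FALSE)
  mk <- function(xyz, chain) atom_set(data.frame(
    chain = chain, resno = seq_len(nrow(xyz)), resid = "GLY", elety = "CA",
    element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE), source = "make_clash_scene")
  structure(list(probe = mk(probes, "P"), environment = mk(env, "E"),
                 truth = list(n_clash = as.integer(k_clash), cutoff = cutoff),
                 seed = seed, generator = "make_clash_scene"),
            class = "synthetic_scene")
}

#' Synthetic target:nanobody complex with a planted clash fraction
#'
#' Builds a screening entry for a given synthetic DiGb scaffold: the
#' complex's nanobody chain is a copy of the scaffold's first Gb, and the
#' target chain is laid out along the scaffold's screw axis so that, after
#' the two copies are placed on the scaffold, an exact planted fraction of
#' the target heavy atoms fall within the clash cutoff of the other copy.
#' Each planted pair contributes one clashing target atom per copy, so the
#' resulting clash score equals `round(clash_fraction * n_target) /
#' n_target` exactly. The whole complex is then moved by a random global
#' rigid transform, which screening must undo.
#'
#' @param scaffold a `synthetic_scene` from [assemble_digb()].
#' @param clash_fraction planted fraction of clashing target atoms, in
#'   \[0, 0.5\] (each planted pair consumes two target atoms).
#' @param n_target number of target atoms (default 100).
#' @param cutoff clash cutoff the fraction is planted for (default 4.0).
#' @param seed integer seed.
#' @return a `synthetic_scene` with `atoms` (chains `"N"` nanobody, `"T"`
#'   target), `ann` for the nanobody chain and `truth` (`score`,
#'   `n_clash`, `classification`).
#' @export
make_survey_entry <- function(scaffold, clash_fraction, n_target = 100,
                              cutoff = 4.0, seed = 1) {
  stopifnot(inherits(scaffold, "synthetic_scene"))
  if (clash_fraction < 0 || clash_fraction > 0.5)
    stop("clash_fraction must lie in [0, 0.5]", call. = FALSE)
  p <- round(clash_fraction * n_target)
  M <- scaffold$transform
  axis <- scaffold$axis; tip <- scaffold$tip
  s <- scaffold$truth$c12_separation
  body <- coords(scaffold$atoms)
  rel <- sweep(body, 2, tip)
  proj <- as.numeric(rel %*% axis)
  radial <- sqrt(pmax(0, rowSums(rel^2) - proj^2))
  L0 <- max(abs(proj)) + 25
  pos <- matrix(NA_real_, n_target, 3)
  Minv <- invert_transform(M)
  k <- 0L
  for (j in seq_len(p)) {           # planted pair: t1 and the pre-image of t1 + 1A
    k <- k + 1L; t1 <- tip + (L0 + 20 * j) * axis
    k <- k + 1L
    t2 <- apply_transform(rbind(t1 + 1.0 * axis), Minv)[1, ]
    pos[k - 1L, ] <- t1; pos[k, ] <- t2
  }
  # non-clashing targets on a cylindrical lattice about the screw axis:
  # images are carried to the same radius, rotated, and shifted axially by
  # the full C12 separation, so any lattice with >= 12 A axial/radial
  # spacing stays strictly clear of the cutoff + 1 A margin
  e1 <- perpendicular_unit(axis); e2 <- unit_vec(cross3(axis, e1))
  r_far <- max(radial) + 20
  z_far0 <- L0 + 20 * (p + 2)
  n_far <- n_target - 2L * p
  for (j in seq_len(n_far)) {
    k <- k + 1L
    layer <- (j - 1L) %/% 8L; spoke <- (j - 1L) %% 8L
    psi <- 2 * pi * spoke / 8
    pos[k, ] <- tip + (z_far0 + 12 * layer) * axis +
      r_far * (cos(psi) * e1 + sin(psi) * e2)
  }
  nb <- relabel_chain(scaffold$atoms[scaffold$atoms$chain == "A", , drop = FALSE], "N")
  class(nb) <- c("atom_set", "data.frame")
  # all-pairs verification of the planted truth before any transform
  all_xyz <- rbind(coords(nb), pos)
  img_xyz <- apply_transform(all_xyz, M)
  near <- function(X, Y) {
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
    apply(d2 <= cutoff^2, 1, any)
  }
  n_check <- sum(near(pos, img_xyz)) + sum(near(apply_transform(pos, M), all_xyz))
  if (n_check != 2L * p)
    stop("planted clash construction failed verification (", n_check,
         " != ", 2L * p, ")", call. = FALSE)
  target <- atom_set(data.frame(chain = "T", resno = seq_len(n_target),
                                resid = "GLY", elety = "CA", element = "C",
                                x = pos[, 1], y = pos[, 2], z = pos[, 3],
                                stringsAsFactors = FALSE),
                     source = "make_survey_entry")
  complex <- rbind(nb, target)
  g <- with_private_seed(seed, list(ax = stats::rnorm(3),
                                    ang = stats::runif(1, 0, 360),
                                    tr = stats::runif(3, -30, 30)))
  G <- rigid_transform(rotation_about_axis(g$ax, g$ang), g$tr)
  complex <- apply_transform(complex, G)
  n_clash <- 2L * p
  n_total <- 2L * n_target
  structure(list(atoms = complex, ann = reannotate(scaffold$ann_a, "N"),
                 truth = list(score = n_clash / n_total,
                              n_clash = n_clash, n_total = n_total,
                              classification = if (p == 0) "no_clash"
                              else if (n_clash / n_total < 0.05) "under_5pct"
                              else "over_5pct",
                              cutoff = cutoff),
                 seed = seed, generator = "make_survey_entry"),
            class = "synthetic_scene")
}
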