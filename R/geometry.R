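#' Gb axis vector
#'
#' The orientation of a Gb is summarised by the vector from its heavy-atom
#' centre of mass to the C-alpha of IMGT residue 12 (the disulfide site at
#' the dimer interface): `D = tip - origin`.
#'
#' @param atoms `atom_set` containing the Gb chain.
#' @param ann the chain's `chain_annotation`.
#' @param weighting centre-of-mass weighting, `"atomic_mass"` (default) or
#'   `"uniform"`.
#' @return an `axis_vector`: list with `origin`, `tip`, `D` (3-vectors,
#'   Angstroms).
#' @export
axis_vector <- function(atoms, ann, weighting = c("atomic_mass", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(ann, "chain_annotation"))
  gb <- select_atoms(atoms, chain = ann$chain)
  ca12 <- atoms_at_imgt(gb, ann, 12, elety = "CA")
  if (nrow(ca12) == 0)
    stop("no C-alpha at IMGT position 12 in chain ", ann$chain, call. = FALSE)
  origin <- center_of_mass(gb, weighting)
  tip <- as.numeric(unlist(ca12[1, c("x", "y", "z")]))
  D <- tip - origin
  if (vec_norm(D) == 0)
    stop("degenerate axis: centre of mass coincides with C-alpha(12)", call. = FALSE)
  structure(list(origin = origin, tip = tip, D = D), class = "axis_vector")
}

#' @export
print.axis_vector <- function(x, ...) {
  cat(sprintf("<axis_vector> |D| = %.2f A, direction (%.3f, %.3f, %.3f)\n",
              vec_norm(x$D), x$D[1] / vec_norm(x$D), x$D[2] / vec_norm(x$D),
              x$D[3] / vec_norm(x$D)))
  invisible(x)
}

as_D <- function(x) {
  if (inherits(x, "axis_vector")) x$D
  else if (is.numeric(x) && length(x) == 3) as.numeric(x)
  else stop("expected an axis_vector or a numeric 3-vector", call. = FALSE)
}

#' Intra-DiGb angle
#'
#' The angle between the two Gbs' axis vectors (or between their
#' series-average vectors), in degrees in \[0, 180\]. The tip-minus-origin
#' orientation of [axis_vector()] is used throughout, so parallel axes give
#' 0 and antiparallel axes 180.
#'
#' @param static_D,mobile_D `axis_vector`s or numeric 3-vectors.
#' @return angle in degrees.
#' @export
intra_digb_angle <- function(static_D, mobile_D) {
  angle_between(as_D(static_D), as_D(mobile_D))
}

#' Wobble-angle series over docked models
#'
#' Implements the interface-dynamics analysis: every frame is first
#' superposed on the static Gb of the reference frame (framework C-alpha
#' correspondence), axis vectors `D_i` are extracted for the static and
#' mobile Gb of each aligned frame, the average `D_a = sum(D_i) / n` is
#' taken per Gb (unnormalised mean, exactly as defined), and the per-frame
#' wobble is `beta_i = arccos(D_a . D_i / (|D_a| |D_i|))` for the mobile Gb,
#' with the cosine clamped to \[-1, 1\]. The intra-DiGb angle is the angle
#' between the static and mobile `D_a`.
#'
#' @param frames list (length >= 2) of `atom_set`s, one docked model per
#'   frame, each containing the static and mobile Gb chains.
#' @param static_ann,mobile_ann `chain_annotation`s for the two chains
#'   (shared across frames).
#' @param weighting centre-of-mass weighting for the axis vectors.
#' @return a `geometry_series`: list with `n_frames`, `beta` (degrees, one
#'   per frame), `D_static`, `D_mobile` (n x 3 matrices of per-frame axis
#'   vectors), `D_a_static`, `D_a_mobile`, `intra_digb_angle`, `max_beta`
#'   and `wobble_range` (`max(beta) - min(beta)`).
#' @export
wobble_series <- function(frames, static_ann, mobile_ann,
                          weighting = c("atomic_mass", "uniform")) {
  weighting <- match.arg(weighting)
  if (!is.list(frames) || length(frames) < 2)
    stop("need at least 2 frames", call. = FALSE)
  ref <- frames[[1]]
  Ds <- matrix(NA_real_, length(frames), 3)
  Dm <- matrix(NA_real_, length(frames), 3)
  bad <- character()
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (!inherits(fr, "atom_set")) stop("frame ", i, " is not an atom_set", call. = FALSE)
    if (!mobile_ann$chain %in% fr$chain) { bad <- c(bad, i); next }
    tf <- superpose_chains(fr, static_ann, ref, static_ann)
    aligned <- apply_transform(fr, tf)
    Ds[i, ] <- axis_vector(aligned, static_ann, weighting)$D
    Dm[i, ] <- axis_vector(aligned, mobile_ann, weighting)$D
  }
  if (length(bad))
    stop("frames missing the mobile Gb chain '", mobile_ann$chain, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  Da_s <- colMeans(Ds)
  Da_m <- colMeans(Dm)
  beta <- vapply(seq_len(nrow(Dm)), function(i) angle_between(Da_m, Dm[i, ]), 0)
  out <- list(n_frames = length(frames), beta = beta,
              D_static = Ds, D_mobile = Dm,
              D_a_static = Da_s, D_a_mobile = Da_m,
              intra_digb_angle = angle_between(Da_s, Da_m),
              max_beta = max(beta),
              wobble_range = max(beta) - min(beta),
              weighting = weighting)
  class(out) <- "geometry_series"
  out
}

#' @export
print.geometry_series <- function(x, ...) {
  cat(sprintf("<geometry_series> %d frames: intra-DiGb angle %.1f deg, max wobble %.1f deg (range %.1f deg)\n",
              x$n_frames, x$intra_digb_angle, x$max_beta, x$wobble_range))
  invisible(x)
}

#' Minimum heavy-atom distance between two residues
#'
#' Hydrogens are ignored; the minimum is over all heavy-atom pairs.
#'
#' @param res_a,res_b `atom_set`s holding one residue each (any atom subset
#'   works; each must contain at least one heavy atom).
#' @return distance in Angstroms.
#' @export
residue_min_distance <- function(res_a, res_b) {
  A <- coords(res_a[!res_a$is_h, , drop = FALSE])
  B <- coords(res_b[!res_b$is_h, , drop = FALSE])
  if (nrow(A) == 0 || nrow(B) == 0)
    stop("each residue needs at least one heavy atom", call. = FALSE)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Residue contacts across a DiGb interface
#'
#' Lists all residue pairs between two chains whose minimum heavy-atom
#' distance is within `contact_cutoff`. A contact is flagged as a hydrogen
#' bond when some N/O--N/O atom pair is within `hbond_cutoff`; with the
#' (typical) hydrogen-free cryo-EM models this is a distance-only criterion.
#' Residues are reported with their IMGT labels where annotated.
#'
#' @param atoms `atom_set` containing both chains.
#' @param ann_a,ann_b `chain_annotation`s of the two chains.
#' @param contact_cutoff residue contact distance (default 4.0 Angstroms).
#' @param hbond_cutoff donor--acceptor distance (default 3.5 Angstroms).
#' @return data frame (class `contact_table`) with one row per contacting
#'   residue pair: chain/resno/residue/IMGT label for both sides,
#'   `min_heavy_distance`, `is_hbond` and the closest N/O atom-name pair
#'   when flagged.
#' @export
interface_contacts <- function(atoms, ann_a, ann_b, contact_cutoff = 4.0,
                               hbond_cutoff = 3.5) {
  a <- select_atoms(atoms, chain = ann_a$chain, heavy_only = TRUE)
  b <- select_atoms(atoms, chain = ann_b$chain, heavy_only = TRUE)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty chain selection", call. = FALSE)
  imgt_of <- function(ann) {
    inv <- stats::setNames(names(ann$imgt_resno), ann$imgt_resno)
    function(resno, insert) {
      v <- inv[paste(resno, insert, sep = "|")]
      ifelse(is.na(v), "", v)
    }
  }
  imgt_a <- imgt_of(ann_a); imgt_b <- imgt_of(ann_b)
  res_a <- split(seq_len(nrow(a)), paste(a$resno, a$insert, sep = "|"))
  res_b <- split(seq_len(nrow(b)), paste(b$resno, b$insert, sep = "|"))
  A <- coords(a); B <- coords(b)
  rows <- list()
  for (ka in names(res_a)) {
    ia <- res_a[[ka]]
    for (kb in names(res_b)) {
      ib <- res_b[[kb]]
      d2 <- outer(rowSums(A[ia, , drop = FALSE]^2),
                  rowSums(B[ib, , drop = FALSE]^2), "+") -
        2 * A[ia, , drop = FALSE] %*% t(B[ib, , drop = FALSE])
      dmin <- sqrt(max(0, min(d2)))
      if (dmin > contact_cutoff) next
      no_a <- toupper(a$element[ia]) %in% c("N", "O")
      no_b <- toupper(b$element[ib]) %in% c("N", "O")
      is_hb <- FALSE; hb_atoms <- ""
      if (any(no_a) && any(no_b)) {
        dno <- d2[no_a, no_b, drop = FALSE]
        if (min(dno) <= hbond_cutoff^2) {
          is_hb <- TRUE
          idx <- which(dno == min(dno), arr.ind = TRUE)[1, ]
          hb_atoms <- paste(a$elety[ia[no_a][idx[1]]],
                            b$elety[ib[no_b][idx[2]]], sep = "--")
        }
      }
      pa <- strsplit(ka, "|", fixed = TRUE)[[1]]; pa <- c(pa, "")[1:2]
      pb <- strsplit(kb, "|", fixed = TRUE)[[1]]; pb <- c(pb, "")[1:2]
      rows[[length(rows) + 1L]] <- data.frame(
        chain_a = ann_a$chain, resno_a = as.integer(pa[1]),
        resid_a = a$resid[ia[1]], imgt_a = unname(imgt_a(pa[1], pa[2])),
        chain_b = ann_b$chain, resno_b = as.integer(pb[1]),
        resid_b = b$resid[ib[1]], imgt_b = unname(imgt_b(pb[1], pb[2])),
        min_heavy_distance = dmin, is_hbond = is_hb, hbond_atoms = hb_atoms,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain_a = character(), resno_a = integer(), resid_a = character(),
               imgt_a = character(), chain_b = character(), resno_b = integer(),
               resid_b = character(), imgt_b = character(),
               min_heavy_distance = numeric(), is_hbond = logical(),
               hbond_atoms = character(), stringsAsFactors = FALSE)
  out <- out[order(out$min_heavy_distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Single-model DiGb geometry
#'
#' Axis vectors, intra-DiGb angle and the C-alpha(12)--C-alpha(12) disulfide
#' span measured on one DiGb model (the consensus-model entry point; use
#' [wobble_series()] for a docked model series).
#'
#' @param atoms `atom_set` with both Gb chains.
#' @param ann_a,ann_b `chain_annotation`s of the two Gbs.
#' @param weighting centre-of-mass weighting.
#' @return list with `axis_a`, `axis_b`, `intra_digb_angle` (degrees) and
#'   `c12_separation` (Angstroms).
#' @export
digb_geometry <- function(atoms, ann_a, ann_b,
                          weighting = c("atomic_mass", "uniform")) {
  weighting <- match.arg(weighting)
  va <- axis_vector(atoms, ann_a, weighting)
  vb <- axis_vector(atoms, ann_b, weighting)
  list(axis_a = va, axis_b = vb,
       intra_digb_angle = intra_digb_angle(va, vb),
       c12_separation = vec_norm(va$tip - vb$tip))
}
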