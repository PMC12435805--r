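#' Rigid transforms
#'
#' A `rigid_transform` holds a proper rotation `R` (3x3, det +1), a
#' translation `t` (Angstroms) and the `rmsd` of the fit that produced it.
#' Applying it maps a coordinate `x` to `R x + t`.
#'
#' @param R 3x3 rotation matrix.
#' @param t numeric 3-vector.
#' @param rmsd non-negative fit RMSD (Angstroms).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(R, t = c(0, 0, 0), rmsd = 0) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("R is not orthonormal", call. = FALSE)
  if (abs(det(R) - 1) > 1e-6)
    stop("R is not a proper rotation (det != +1)", call. = FALSE)
  structure(list(R = R, t = as.numeric(t), rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- deg(acos(max(-1, min(1, (sum(diag(x$R)) - 1) / 2))))
  cat(sprintf("<rigid_transform> rotation %.2f deg, |t| = %.2f A, fit rmsd %.4f A\n",
              ang, vec_norm(x$t), x$rmsd))
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of `mobile`
#' onto `fixed` over paired points, via SVD of the covariance matrix with the
#' usual determinant correction that excludes reflections.
#'
#' @param mobile,fixed n x 3 coordinate matrices (n >= 3, equal n, not
#'   collinear).
#' @return a [rigid_transform()] such that `R %*% x + t` maps mobile points
#'   onto fixed.
#' @export
kabsch_superpose <- function(mobile, fixed) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  if (!all(dim(mobile) == dim(fixed)) || ncol(mobile) != 3)
    stop("mobile and fixed must be equal-size n x 3 matrices", call. = FALSE)
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 paired points", call. = FALSE)
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  # collinearity check: second singular value of the centred cloud ~ 0
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate geometry: points are (near-)collinear", call. = FALSE)
  H <- crossprod(A, B)            # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cf - as.numeric(R %*% cm)
  moved <- sweep(tcrossprod(A, R), 2, cf, "+")
  rigid_transform(R, t, rmsd = rmsd_xyz(moved, fixed))
}

#' Apply a rigid transform to coordinates
#'
#' @param atoms an `atom_set` or an n x 3 coordinate matrix.
#' @param transform a `rigid_transform`.
#' @return the same kind of object with every coordinate replaced by
#'   `R x + t`; all atom labels are preserved.
#' @export
apply_transform <- function(atoms, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(atoms, "atom_set")) {
    xyz <- coords(atoms)
    set_coords(atoms, sweep(tcrossprod(xyz, transform$R), 2, transform$t, "+"))
  } else {
    sweep(tcrossprod(as.matrix(atoms), transform$R), 2, transform$t, "+")
  }
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$R)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$t), rmsd = transform$rmsd)
}

compose_transform <- function(outer, inner) {
  # (outer o inner)(x) = R_o (R_i x + t_i) + t_o
  rigid_transform(outer$R %*% inner$R,
                  as.numeric(outer$R %*% inner$t) + outer$t)
}

#' Paired framework C-alpha coordinates of two annotated chains
#'
#' Collects the C-alpha atoms at IMGT framework positions shared by both
#' chains (CDRs excluded: their conformations differ between a target-bound
#' nanobody and a scaffold Gb, while framework regions deviate by only about
#' 1 Angstrom across nanobodies). Positions lacking a C-alpha in either
#' chain are simply absent from the pairing.
#'
#' @param atoms_a,atoms_b `atom_set`s containing the two chains.
#' @param ann_a,ann_b matching `chain_annotation`s.
#' @param min_pairs minimum number of shared positions (default 20).
#' @return list with `xyz_a`, `xyz_b` (n x 3 matrices, row-paired) and
#'   `imgt` (the shared position labels).
#' @export
match_framework_atoms <- function(atoms_a, ann_a, atoms_b, ann_b,
                                  min_pairs = 20) {
  stopifnot(inherits(ann_a, "chain_annotation"),
            inherits(ann_b, "chain_annotation"))
  fw_a <- ann_a$map$table$imgt[ann_a$map$table$region == "FR"]
  fw_b <- ann_b$map$table$imgt[ann_b$map$table$region == "FR"]
  shared <- intersect(fw_a, fw_b)
  grab <- function(atoms, ann, pos) {
    ca <- atoms_at_imgt(atoms, ann, pos, elety = "CA")
    if (nrow(ca) >= 1) as.numeric(unlist(ca[1, c("x", "y", "z")])) else NULL
  }
  xa <- list(); xb <- list(); keep <- character()
  for (p in shared) {
    a <- grab(atoms_a, ann_a, p); b <- grab(atoms_b, ann_b, p)
    if (is.null(a) || is.null(b)) next
    xa[[length(xa) + 1L]] <- a; xb[[length(xb) + 1L]] <- b
    keep <- c(keep, p)
  }
  if (length(keep) < min_pairs)
    stop("only ", length(keep), " shared framework C-alpha positions (need >= ",
         min_pairs, ")", call. = FALSE)
  list(xyz_a = do.call(rbind, xa), xyz_b = do.call(rbind, xb), imgt = keep)
}

#' Superpose one annotated chain onto another
#'
#' Convenience wrapper: pairs framework C-alphas with
#' [match_framework_atoms()] and fits them with [kabsch_superpose()].
#'
#' @inheritParams match_framework_atoms
#' @return a `rigid_transform` mapping chain-a coordinates onto chain b.
#' @export
superpose_chains <- function(atoms_a, ann_a, atoms_b, ann_b, min_pairs = 20) {
  pairs <- match_framework_atoms(atoms_a, ann_a, atoms_b, ann_b,
                                 min_pairs = min_pairs)
  kabsch_superpose(pairs$xyz_a, pairs$xyz_b)
}

#' Serialize / read a rigid transform as 12 plain-text numbers
#'
#' Row-major rotation first, then the translation.
#' @param transform a `rigid_transform`.
#' @param path output (input) file.
#' @return `path` invisibly; `read_transform()` returns the
#'   `rigid_transform`.
#' @export
write_transform <- function(transform, path) {
  vals <- c(t(transform$R), transform$t)
  writeLines(format(vals, digits = 17), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  vals <- as.numeric(readLines(path, warn = FALSE))
  if (length(vals) != 12 || any(!is.finite(vals)))
    stop("expected 12 finite numbers in '", path, "'", call. = FALSE)
  rigid_transform(matrix(vals[1:9], 3, 3, byrow = TRUE), vals[10:12])
}
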