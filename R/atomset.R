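#' Atom sets
#'
#' An `atom_set` is the coordinate container used throughout the package: a
#' data frame with one row per atom and columns `chain`, `resno`, `insert`,
#' `resid` (3-letter residue code), `elety` (atom name), `element`, `x`, `y`,
#' `z` (Angstroms), `o` (occupancy), `alt` (alternate-location id, `""` when
#' none) and `is_h` (`TRUE` for hydrogen/deuterium). Geometry defaults work on
#' heavy atoms only; hydrogens are retained on read and can be re-enabled
#' explicitly where a function offers the choice.
#'
#' @param df data frame carrying the columns above (missing `insert`, `alt`,
#'   `o`, `element`, `is_h` are filled with defaults).
#' @param source character scratch note on where the atoms came from.
#' @return an object of class `atom_set` (also a `data.frame`).
#' @examples
#' a <- atom_set(data.frame(chain = "A", resno = 1, resid = "GLY",
#'                          elety = "CA", element = "C", x = 0, y = 0, z = 0))
#' center_of_mass(a)
#' @export
atom_set <- function(df, source = "constructed") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("atom_set is missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (is.null(df$insert)) df$insert <- ""
  if (is.null(df$alt)) df$alt <- ""
  if (is.null(df$o)) df$o <- 1
  if (is.null(df$element)) df$element <- guess_element(df$elety)
  if (is.null(df$is_h)) df$is_h <- toupper(df$element) %in% c("H", "D")
  df$insert[is.na(df$insert)] <- ""
  df$alt[is.na(df$alt)] <- ""
  df$resno <- as.integer(df$resno)
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("atom coordinates must be finite", call. = FALSE)
  if (any(df$o < 0 | df$o > 1, na.rm = TRUE))
    stop("occupancy must lie in [0, 1]", call. = FALSE)
  df <- df[, c("chain", "resno", "insert", "resid", "elety", "element",
               "x", "y", "z", "o", "alt", "is_h")]
  class(df) <- c("atom_set", "data.frame")
  attr(df, "source") <- source
  df
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("<atom_set> %d atoms (%d heavy), chains: %s\n",
              nrow(x), sum(!x$is_h), paste(unique(x$chain), collapse = " ")))
  invisible(x)
}

# Element symbol from a PDB atom name when the element column is absent:
# strip digits/primes, take the leading letter(s); two-letter elements are
# only trusted when they name a common hetero element.
guess_element <- function(elety) {
  nm <- gsub("[^A-Za-z]", "", elety)
  first <- toupper(substr(nm, 1, 1))
  two <- toupper(substr(nm, 1, 2))
  known2 <- c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA", "CA", "CU", "NI", "CO")
  ifelse(two %in% setdiff(known2, c("CA", "NA")) , two, first)
}

# Average atomic masses (Da) for elements seen in protein models.
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  MN = 54.938, CU = 63.546, `NA` = 22.990, K = 39.098, CA = 40.078,
  CL = 35.45, BR = 79.904, F = 18.998, I = 126.904, NI = 58.693, CO = 58.933
)

atomic_mass <- function(element) {
  m <- .atomic_masses[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Coordinates of an atom set as a matrix
#' @param atoms an `atom_set`.
#' @return numeric matrix with `nrow(atoms)` rows and columns x, y, z.
#' @export
coords <- function(atoms) {
  as.matrix(as.data.frame(atoms)[, c("x", "y", "z")])
}

set_coords <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' Select atoms by chain, residue range and atom class
#'
#' Filters are conjunctive. `polymer_only = TRUE` drops waters and other
#' non-polymer heteroatoms (anything whose residue name is not a standard
#' amino acid or nucleotide). An empty selection is returned, not an error.
#'
#' @param atoms an `atom_set`.
#' @param chain chain id(s), or `NULL` for any.
#' @param residue_range `NULL`, or a length-2 numeric `c(from, to)` interval
#'   of author residue numbers (inclusive).
#' @param heavy_only drop hydrogens (default `FALSE`).
#' @param polymer_only drop waters/non-polymer heteroatoms (default `FALSE`).
#' @param elety atom name(s) to keep, or `NULL` for any.
#' @return an `atom_set` (possibly with zero rows).
#' @export
select_atoms <- function(atoms, chain = NULL, residue_range = NULL,
                         heavy_only = FALSE, polymer_only = FALSE,
                         elety = NULL) {
  stopifnot(inherits(atoms, "atom_set"))
  if (nrow(atoms) == 0) stop("cannot select from an empty atom_set", call. = FALSE)
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(residue_range)) {
    if (length(residue_range) != 2 || !is.numeric(residue_range) ||
        any(!is.finite(residue_range)) || residue_range[1] > residue_range[2])
      stop("residue_range must be a finite numeric interval c(from, to)", call. = FALSE)
    keep <- keep & atoms$resno >= residue_range[1] & atoms$resno <= residue_range[2]
  }
  if (heavy_only) keep <- keep & !atoms$is_h
  if (polymer_only) keep <- keep & atoms$resid %in% .polymer_resids
  if (!is.null(elety)) keep <- keep & atoms$elety %in% elety
  out <- atoms[keep, , drop = FALSE]
  class(out) <- c("atom_set", "data.frame")
  attr(out, "source") <- attr(atoms, "source")
  out
}

.polymer_resids <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL",
  "DA", "DC", "DG", "DT", "A", "C", "G", "U"
)

#' Centre of mass of an atom set
#'
#' The weighted mean of the heavy-atom coordinates. Hydrogens are excluded
#' regardless of the weighting mode; `weighting = "uniform"` gives every heavy
#' atom equal weight, `"atomic_mass"` (the default) weights by average atomic
#' mass. This is the origin of the DiGb axis vector (see [axis_vector()]).
#'
#' @param atoms an `atom_set` with at least one heavy atom.
#' @param weighting `"atomic_mass"` or `"uniform"`.
#' @return numeric 3-vector (Angstroms).
#' @export
center_of_mass <- function(atoms, weighting = c("atomic_mass", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(atoms, "atom_set"))
  heavy <- atoms[!atoms$is_h, , drop = FALSE]
  if (nrow(heavy) == 0) stop("center_of_mass needs at least one heavy atom", call. = FALSE)
  w <- if (weighting == "atomic_mass") atomic_mass(heavy$element) else rep(1, nrow(heavy))
  xyz <- as.matrix(as.data.frame(heavy)[, c("x", "y", "z")])
  as.numeric(colSums(xyz * w) / sum(w))
}

# Combine atom sets (e.g. two chains into one model).
#' @export
rbind.atom_set <- function(..., deparse.level = 1) {
  parts <- list(...)
  out <- do.call(rbind.data.frame, lapply(parts, as.data.frame))
  atom_set(out, source = "combined")
}
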