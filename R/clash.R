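#' Count probe atoms clashing with an environment
#'
#' A probe atom is scored as clashed when at least one environment atom lies
#' within `cutoff` Angstroms of it (inclusive at exactly the cutoff). Both
#' sets are reduced to heavy atoms first. The implementation bins the
#' environment into cutoff-sized cells and visits only neighbouring cells,
#' but is exact: it equals the all-pairs count by construction.
#'
#' @param probe,environment nonempty `atom_set`s.
#' @param cutoff contact distance in Angstroms (default 4.0, the sphere used
#'   for scaffold applicability screening).
#' @return integer count of clashing probe atoms.
#' @export
count_clash_atoms <- function(probe, environment, cutoff = 4.0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff) || cutoff <= 0)
    stop("cutoff must be a positive number", call. = FALSE)
  stopifnot(inherits(probe, "atom_set"), inherits(environment, "atom_set"))
  P <- coords(probe[!probe$is_h, , drop = FALSE])
  E <- coords(environment[!environment$is_h, , drop = FALSE])
  if (nrow(P) == 0 || nrow(E) == 0)
    stop("probe and environment must each contain heavy atoms", call. = FALSE)
  sum(clashing_mask(P, E, cutoff))
}

# Logical vector over probe rows: TRUE when any environment atom is within
# cutoff. Cell-list neighbour search on the environment.
clashing_mask <- function(P, E, cutoff) {
  cell_of <- function(X) {
    k <- floor(X / cutoff)
    paste(k[, 1], k[, 2], k[, 3], sep = ",")
  }
  ekey <- cell_of(E)
  ecell <- split(seq_len(nrow(E)), ekey)
  pk <- floor(P / cutoff)
  pkey <- paste(pk[, 1], pk[, 2], pk[, 3], sep = ",")
  out <- logical(nrow(P))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cut2 <- cutoff^2
  for (key in unique(pkey)) {
    rows <- which(pkey == key)
    base <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    nb <- sweep(off, 2, base, "+")
    nbkeys <- paste(nb[, 1], nb[, 2], nb[, 3], sep = ",")
    cand <- unlist(ecell[nbkeys], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    Ec <- E[cand, , drop = FALSE]
    # squared distances, probe rows x candidate env atoms
    d2 <- outer(rowSums(P[rows, , drop = FALSE]^2), rowSums(Ec^2), "+") -
      2 * P[rows, , drop = FALSE] %*% t(Ec)
    out[rows] <- apply(d2 <= cut2, 1, any)
  }
  out
}

#' Clash report for a complex placed on a two-copy scaffold
#'
#' Builds the report object: `score = n_clash / n_total`, where `n_total` is
#' the number of target heavy atoms across both placed copies (the "maximal
#' clash" normaliser: every target atom clashing gives score 1) and the
#' classification thresholds at a fraction of that maximum (default 5%).
#'
#' @param n_clash,n_total atom counts.
#' @param cutoff contact cutoff used (Angstroms).
#' @param threshold classification threshold on the score (default 0.05).
#' @param placement_rmsd optional numeric vector of placement fit RMSDs.
#' @return object of class `clash_report` with fields `n_clash`, `n_total`,
#'   `score`, `cutoff`, `threshold`, `classification` (`no_clash`,
#'   `under_5pct`, `over_5pct`) and `placement_rmsd`.
#' @export
clash_report <- function(n_clash, n_total, cutoff = 4.0, threshold = 0.05,
                         placement_rmsd = numeric()) {
  stopifnot(n_clash >= 0, n_clash <= n_total, n_total > 0)
  score <- n_clash / n_total
  classification <- if (n_clash == 0) "no_clash"
  else if (score < threshold) "under_5pct"
  else "over_5pct"
  structure(list(n_clash = as.integer(n_clash), n_total = as.integer(n_total),
                 score = score, cutoff = cutoff, threshold = threshold,
                 classification = classification,
                 placement_rmsd = placement_rmsd),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("<clash_report> %d / %d target heavy atoms within %.1f A (score %.4f): %s\n",
              x$n_clash, x$n_total, x$cutoff, x$score, x$classification))
  invisible(x)
}

#' Screen a target:nanobody complex on a two-copy DiGb scaffold
#'
#' Places two copies of the complex onto the scaffold: copy A is superposed
#' via its nanobody's framework C-alphas onto the first scaffold Gb chain,
#' copy B onto the second. Target heavy atoms of each copy lying within
#' `cutoff` of any heavy atom of the other placed copy (target and nanobody
#' alike) are scored as clashed; the score normalises by the total number of
#' target heavy atoms over both copies.
#'
#' @param complex `atom_set` with one nanobody chain and at least one target
#'   chain.
#' @param scaffold `atom_set` with two Gb chains.
#' @param nb_chain nanobody chain id in `complex`; `NULL` to auto-detect as
#'   the chain with the highest framework identity.
#' @param scaffold_chains length-2 chain ids of the scaffold Gbs; `NULL` to
#'   use the scaffold's first two annotatable chains.
#' @param complex_ann,scaffold_ann optional precomputed `chain_annotation`s
#'   (`scaffold_ann` a list of two); when omitted they are computed by
#'   [annotate_chain()].
#' @param cutoff clash distance (default 4.0 Angstroms).
#' @param threshold classification threshold (default 0.05).
#' @return a [clash_report()], with the two placement RMSDs recorded.
#' @export
screen_on_scaffold <- function(complex, scaffold, nb_chain = NULL,
                               scaffold_chains = NULL, complex_ann = NULL,
                               scaffold_ann = NULL, cutoff = 4.0,
                               threshold = 0.05) {
  stopifnot(inherits(complex, "atom_set"), inherits(scaffold, "atom_set"))
  if (is.null(complex_ann)) {
    det <- detect_nanobody_chain(complex, nb_chain)
    complex_ann <- det$ann
    nb_chain <- det$chain
  } else nb_chain <- complex_ann$chain
  target_chains <- setdiff(unique(complex$chain), nb_chain)
  if (!length(target_chains))
    stop("complex has no target chain besides the nanobody", call. = FALSE)
  if (is.null(scaffold_ann)) {
    if (is.null(scaffold_chains)) scaffold_chains <- unique(scaffold$chain)[1:2]
    if (length(scaffold_chains) != 2 || anyNA(scaffold_chains))
      stop("scaffold must provide two Gb chains", call. = FALSE)
    scaffold_ann <- lapply(scaffold_chains, function(ch) annotate_chain(scaffold, ch))
  }
  placements <- lapply(scaffold_ann, function(ann)
    superpose_chains(complex, complex_ann, scaffold, ann))
  copy_a <- apply_transform(complex, placements[[1]])
  copy_b <- apply_transform(complex, placements[[2]])
  target_a <- select_atoms(copy_a, chain = target_chains, heavy_only = TRUE,
                           polymer_only = TRUE)
  target_b <- select_atoms(copy_b, chain = target_chains, heavy_only = TRUE,
                           polymer_only = TRUE)
  heavy_a <- select_atoms(copy_a, heavy_only = TRUE, polymer_only = TRUE)
  heavy_b <- select_atoms(copy_b, heavy_only = TRUE, polymer_only = TRUE)
  n_clash <- count_clash_atoms(target_a, heavy_b, cutoff) +
    count_clash_atoms(target_b, heavy_a, cutoff)
  clash_report(n_clash, nrow(target_a) + nrow(target_b), cutoff, threshold,
               placement_rmsd = vapply(placements, `[[`, 0, "rmsd"))
}

# The nanobody chain is the chain whose sequence annotates with the highest
# framework identity; an explicit chain id overrides.
detect_nanobody_chain <- function(atoms, nb_chain = NULL) {
  chains <- if (is.null(nb_chain)) unique(atoms$chain) else nb_chain
  best <- NULL
  for (ch in chains) {
    ann <- tryCatch(annotate_chain(atoms, ch), error = function(e) NULL)
    if (is.null(ann)) next
    if (is.null(best) || ann$map$framework_identity > best$ann$map$framework_identity)
      best <- list(chain = ch, ann = ann)
  }
  if (is.null(best))
    stop("no chain of the complex annotates as a nanobody", call. = FALSE)
  best
}

#' Screen a library of complexes against one scaffold
#'
#' Runs [screen_on_scaffold()] over a list of complexes; entries that fail
#' annotation or superposition are recorded as skipped (with the reason),
#' not fatal. Fractions are computed over the successfully screened entries;
#' `fraction_under_threshold` is cumulative (it includes the no-clash
#' entries).
#'
#' @param entries named list; each element either an `atom_set` or a list
#'   with fields `atoms` and optionally `ann` (a `chain_annotation` for the
#'   nanobody chain).
#' @param scaffold `atom_set` with two Gb chains.
#' @param scaffold_ann optional list of two `chain_annotation`s.
#' @param cutoff,threshold as in [screen_on_scaffold()].
#' @return a `survey_summary`: list with `reports` (per-entry
#'   `clash_report`s), `skipped` (named reasons), `fraction_no_clash`,
#'   `fraction_under_threshold`, `n_screened`.
#' @export
survey_library <- function(entries, scaffold, scaffold_ann = NULL,
                           cutoff = 4.0, threshold = 0.05) {
  if (!length(entries)) stop("empty library", call. = FALSE)
  if (is.null(names(entries)) || any(names(entries) == ""))
    names(entries) <- paste0("entry", seq_along(entries))
  if (is.null(scaffold_ann)) {
    chains <- unique(scaffold$chain)[1:2]
    scaffold_ann <- lapply(chains, function(ch) annotate_chain(scaffold, ch))
  }
  reports <- list(); skipped <- character()
  for (nm in names(entries)) {
    e <- entries[[nm]]
    atoms <- if (inherits(e, "atom_set")) e else e$atoms
    ann <- if (inherits(e, "atom_set")) NULL else e$ann
    rep <- tryCatch(
      screen_on_scaffold(atoms, scaffold, complex_ann = ann,
                         scaffold_ann = scaffold_ann,
                         cutoff = cutoff, threshold = threshold),
      error = function(err) conditionMessage(err))
    if (inherits(rep, "clash_report")) reports[[nm]] <- rep
    else skipped[nm] <- rep
  }
  if (!length(reports))
    stop("no entry could be screened (", length(skipped), " skipped)", call. = FALSE)
  cls <- vapply(reports, `[[`, "", "classification")
  out <- list(reports = reports, skipped = skipped,
              fraction_no_clash = mean(cls == "no_clash"),
              fraction_under_threshold = mean(cls != "over_5pct"),
              n_screened = length(reports),
              cutoff = cutoff, threshold = threshold)
  class(out) <- "survey_summary"
  out
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("<survey_summary> %d screened (%d skipped), cutoff %.1f A, threshold %d%%\n",
              x$n_screened, length(x$skipped), x$cutoff, round(100 * x$threshold)))
  cat(sprintf("  no clash: %.1f%%   under threshold (cumulative): %.1f%%\n",
              100 * x$fraction_no_clash, 100 * x$fraction_under_threshold))
  invisible(x)
}
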