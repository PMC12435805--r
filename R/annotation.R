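#' Map a nanobody sequence to IMGT positions
#'
#' Globally aligns the query (affine gap penalties, BLOSUM62) against the
#' embedded IMGT-numbered VHH reference ([gb_reference()]) and transfers IMGT
#' positions through the aligned columns. Framework positions transfer
#' one-to-one; residues falling between the framework anchors of a CDR are
#' renumbered over the CDR span with the IMGT middle-gap convention,
#' receiving 111/112-style insertion codes when the loop is longer than the
#' span. Length differences between nanobodies are thereby absorbed inside
#' the CDRs, which is what makes positions such as 7, 12, 14 and 125
#' comparable across nanobodies.
#'
#' @param query amino-acid string (standard one-letter codes, optionally X),
#'   length 90-160.
#' @param gap_open,gap_extend affine gap penalties for the alignment
#'   (defaults 10 and 1; the framework is conserved enough that the mapping
#'   is insensitive to the exact scoring).
#' @param min_identity minimum framework identity below which the query is
#'   rejected as not a nanobody (default 0.5).
#' @return a `framework_map`: list with `query` (the sequence), `table`
#'   (data frame `query_index` (1-based), `residue`, `imgt` (character label,
#'   insertion-coded inside CDRs), `region`), `cdr_spans`, and
#'   `framework_identity` (fraction of reference framework positions matched
#'   identically).
#' @export
align_to_reference <- function(query, gap_open = 10, gap_extend = 1,
                               min_identity = 0.5) {
  if (!is.character(query) || length(query) != 1)
    stop("query must be a single amino-acid string", call. = FALSE)
  query <- toupper(gsub("\\s", "", query))
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", query))
    stop("query contains non-amino-acid characters", call. = FALSE)
  if (nchar(query) < 90 || nchar(query) > 160)
    stop("query length ", nchar(query), " outside the expected 90-160 for a VHH",
         call. = FALSE)
  ref <- gb_reference()
  refseq <- paste(ref$res, collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(refseq),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend)
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  qi <- 0L; ri <- 0L
  ncol_aln <- length(qa)
  col_q <- integer(ncol_aln); col_r <- integer(ncol_aln)
  for (k in seq_len(ncol_aln)) {
    if (qa[k] != "-") qi <- qi + 1L
    if (ra[k] != "-") ri <- ri + 1L
    col_q[k] <- if (qa[k] != "-") qi else NA_integer_
    col_r[k] <- if (ra[k] != "-") ri else NA_integer_
  }
  ref_imgt_of_col <- ifelse(is.na(col_r), NA_integer_, ref$imgt[col_r])
  ref_region_of_col <- ifelse(is.na(col_r), NA_character_, ref$region[col_r])

  # framework transfer: both residues present, reference column is framework
  fr_cols <- which(!is.na(col_q) & !is.na(col_r) & ref_region_of_col == "FR")
  map <- data.frame(query_index = col_q[fr_cols],
                    residue = qa[fr_cols],
                    imgt = as.character(ref_imgt_of_col[fr_cols]),
                    region = "FR", stringsAsFactors = FALSE)

  # framework identity over reference framework positions
  n_fr_ref <- sum(ref$region == "FR")
  ident <- sum(qa[fr_cols] == ra[fr_cols])
  framework_identity <- ident / n_fr_ref
  if (framework_identity < min_identity)
    stop(sprintf("framework identity %.2f < %.2f: query does not look like a nanobody",
                 framework_identity, min_identity), call. = FALSE)

  # CDRs: all query residues between the flanking framework anchors
  for (nm in names(.imgt_cdr_spans)) {
    sp <- .imgt_cdr_spans[[nm]]
    fr <- map[map$region == "FR", , drop = FALSE]
    before <- fr$query_index[as.integer(fr$imgt) < sp[1]]
    after <- fr$query_index[as.integer(fr$imgt) > sp[2]]
    lo <- if (length(before)) max(before) else 0L
    hi <- if (length(after)) min(after) else nchar(query) + 1L
    idx <- seq.int(lo + 1L, hi - 1L)
    idx <- idx[idx >= 1L & idx <= nchar(query)]
    if (!length(idx)) next
    labels <- imgt_fill_with_insertions(sp, length(idx))
    map <- rbind(map, data.frame(query_index = idx,
                                 residue = strsplit(substr(query, min(idx), max(idx)), "")[[1]],
                                 imgt = labels, region = nm,
                                 stringsAsFactors = FALSE))
  }
  map <- map[order(map$query_index), , drop = FALSE]
  if (anyDuplicated(map$query_index))
    stop("internal error: query residue mapped twice", call. = FALSE)
  rownames(map) <- NULL
  out <- list(query = query, table = map, cdr_spans = .imgt_cdr_spans,
              framework_identity = framework_identity,
              alignment_score = Biostrings::score(aln))
  class(out) <- "framework_map"
  out
}

#' @export
print.framework_map <- function(x, ...) {
  cat(sprintf("<framework_map> query %d aa, %d residues numbered, framework identity %.2f\n",
              nchar(x$query), nrow(x$table), x$framework_identity))
  key <- c(7, 12, 14, 44, 46, 47, 84, 120, 123, 125)
  res <- vapply(key, function(p) {
    r <- imgt_residue(x, p); if (is.na(r)) "-" else r
  }, "")
  cat("  key positions: ", paste0(res, key, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Residue at an IMGT position
#' @param map a `framework_map`.
#' @param pos IMGT position (integer or character label).
#' @return one-letter residue, or `NA` if the position is not mapped.
#' @export
imgt_residue <- function(map, pos) {
  stopifnot(inherits(map, "framework_map"))
  i <- match(as.character(pos), map$table$imgt)
  if (is.na(i)) NA_character_ else map$table$residue[i]
}

imgt_query_index <- function(map, pos) {
  i <- match(as.character(pos), map$table$imgt)
  if (is.na(i)) NA_integer_ else map$table$query_index[i]
}

#' Interface-conservation advisories for a nanobody framework
#'
#' Checks the residues that form the Gb/DiGb interface against their
#' conserved identities on the nanobody scaffold: Q120, Q123, T125, Q14 and
#' S7 (all conserved at >80-95% frequency across nanobodies), and position
#' 12, which is usually leucine but serine in roughly 30% of sequences.
#' Deviations produce advisories, never errors: a shifted identity (as seen
#' when lysines at position 120 move the dimer interface to a new state) may
#' still dimerize, but the interface geometry can change.
#'
#' @param map a `framework_map`.
#' @return data frame with columns `imgt`, `expected`, `observed`, `level`
#'   (`"ok"`, `"note"` or `"advisory"`) and `message`. Zero advisory rows on
#'   a canonical framework.
#' @export
check_interface_conservation <- function(map) {
  stopifnot(inherits(map, "framework_map"))
  spec <- data.frame(imgt = c(120, 123, 125, 14, 7, 12),
                     expected = c("Q", "Q", "T", "Q", "S", "L/S"),
                     stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    p <- spec$imgt[i]
    obs <- imgt_residue(map, p)
    exp <- spec$expected[i]
    if (is.na(obs)) {
      lev <- "advisory"; msg <- sprintf("position %d is not mapped in this query", p)
    } else if (p == 12) {
      if (obs == "L") { lev <- "ok"; msg <- "canonical leucine" }
      else if (obs == "S") { lev <- "note"; msg <- "serine at 12 is a common variant (~30% of nanobodies)" }
      else if (obs == "C") { lev <- "note"; msg <- "cysteine at 12: Gb substitution already present" }
      else { lev <- "advisory"; msg <- sprintf("unusual residue %s at position 12 (usually L, often S)", obs) }
    } else if (obs == exp) {
      lev <- "ok"; msg <- "conserved"
    } else {
      lev <- "advisory"
      msg <- sprintf("%s at position %d instead of conserved %s; the dimer interface may shift to a different state",
                     obs, p, exp)
    }
    data.frame(imgt = p, expected = exp, observed = ifelse(is.na(obs), "-", obs),
               level = lev, message = msg, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annotate one chain of a structure
#'
#' Extracts the chain's sequence, maps it to IMGT positions with
#' [align_to_reference()] and records the author residue number behind each
#' IMGT label, so structure atoms can be addressed by IMGT position.
#'
#' @param atoms an `atom_set`.
#' @param chain chain id.
#' @param ... passed to [align_to_reference()].
#' @return a `chain_annotation`: list with `chain`, `map` (the
#'   `framework_map`) and `imgt_resno` (named character vector, IMGT label ->
#'   `"resno|insert"`).
#' @export
annotate_chain <- function(atoms, chain, ...) {
  cs <- chain_sequence(atoms, chain)
  map <- align_to_reference(cs$sequence, ...)
  resno_key <- paste(cs$resno, cs$insert, sep = "|")
  imgt_resno <- stats::setNames(resno_key[map$table$query_index], map$table$imgt)
  structure(list(chain = chain, map = map, imgt_resno = imgt_resno),
            class = "chain_annotation")
}

# Build a chain_annotation directly from known residue-number <-> IMGT pairs
# (used by the synthetic generators, which know their labels by construction).
chain_annotation_direct <- function(chain, map, resno, insert = NULL) {
  if (is.null(insert)) insert <- rep("", length(resno))
  imgt_resno <- stats::setNames(paste(resno, insert, sep = "|"),
                                map$table$imgt[seq_along(resno)])
  structure(list(chain = chain, map = map, imgt_resno = imgt_resno),
            class = "chain_annotation")
}

#' @export
print.chain_annotation <- function(x, ...) {
  cat(sprintf("<chain_annotation> chain %s, %d IMGT-labelled residues\n",
              x$chain, length(x$imgt_resno)))
  invisible(x)
}

# Atoms of a chain at one IMGT position.
atoms_at_imgt <- function(atoms, ann, pos, elety = NULL) {
  key <- ann$imgt_resno[as.character(pos)]
  if (is.na(key)) return(atoms[integer(), , drop = FALSE])
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  ins <- if (length(parts) > 1) parts[2] else ""
  sel <- atoms$chain == ann$chain & atoms$resno == as.integer(parts[1]) &
    atoms$insert == ins
  if (!is.null(elety)) sel <- sel & atoms$elety %in% elety
  out <- atoms[sel, , drop = FALSE]
  class(out) <- c("atom_set", "data.frame")
  out
}
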