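#' Read a protein coordinate file
#'
#' Parses PDB (fixed-column, via bio3d) or mmCIF (`atom_site` loop) files into
#' an [atom_set()]. All ATOM/HETATM records are returned. Alternate locations
#' are resolved per (chain, residue, atom name): the highest-occupancy record
#' is kept, the first listed on a tie. Only the first model of a multi-model
#' file is used (a notice is emitted). Author chain ids and residue numbers
#' are used.
#'
#' @param path path to a coordinate file.
#' @param format `"auto"` (by extension: `.cif`/`.mmcif` is mmCIF, anything
#'   else PDB), `"pdb"` or `"mmcif"`.
#' @param resolve_altloc keep a single conformer per atom (default `TRUE`).
#' @return an `atom_set`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           resolve_altloc = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  atoms <- if (format == "pdb") read_pdb_atoms(path) else read_mmcif_atoms(path)
  if (nrow(atoms) == 0) stop("no atoms parsed from '", path, "'", call. = FALSE)
  if (resolve_altloc) atoms <- resolve_altlocs(atoms)
  out <- atom_set(atoms, source = path)
  rownames(out) <- NULL
  out
}

read_pdb_atoms <- function(path) {
  n_model <- length(grep("^MODEL ", readLines(path, warn = FALSE)))
  if (n_model > 1)
    message("'", basename(path), "' has ", n_model, " models; using model 1 only")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) return(data.frame())
  el <- a$elesy
  el[is.na(el) | el == ""] <- NA
  el <- ifelse(is.na(el), guess_element(a$elety), el)
  data.frame(chain = ifelse(is.na(a$chain), "", a$chain),
             resno = a$resno,
             insert = ifelse(is.na(a$insert), "", a$insert),
             resid = a$resid, elety = a$elety, element = el,
             x = a$x, y = a$y, z = a$z,
             o = ifelse(is.na(a$o), 1, a$o),
             alt = ifelse(is.na(a$alt), "", a$alt),
             stringsAsFactors = FALSE)
}

# Minimal mmCIF atom_site reader. Handles the whitespace-delimited loop_
# table with quoted tokens; uses author ids (auth_*) when present, falling
# back to label ids. Keeps model 1 only.
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L; n <- length(lines)
  fields <- character(); rows <- list()
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L; hdr <- character()
      while (j <= n && grepl("^\\s*_", lines[j])) {
        hdr <- c(hdr, sub("^\\s*", "", sub("\\s*$", "", lines[j]))); j <- j + 1L
      }
      if (length(hdr) && all(grepl("^_atom_site\\.", hdr))) {
        fields <- sub("^_atom_site\\.", "", hdr)
        while (j <= n && !grepl("^\\s*(loop_|_|#|data_)", lines[j]) &&
               nzchar(trimws(lines[j]))) {
          rows[[length(rows) + 1L]] <- cif_tokens(lines[j]); j <- j + 1L
        }
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(rows)) return(data.frame())
  bad <- vapply(rows, length, 1L) != length(fields)
  if (any(bad)) stop("malformed mmCIF atom_site loop: token/field count mismatch",
                     call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  get <- function(a, b = NULL) {
    if (a %in% fields) m[, a] else if (!is.null(b) && b %in% fields) m[, b]
    else rep(NA_character_, nrow(m))
  }
  model <- get("pdbx_PDB_model_num")
  if (!all(is.na(model))) {
    first <- model[which(!is.na(model))[1]]
    if (length(unique(stats::na.omit(model))) > 1)
      message("'", basename(path), "' has multiple models; using model ", first,
              " only")
    keep <- is.na(model) | model == first
    m <- m[keep, , drop = FALSE]
  }
  blank <- function(v) { v[is.na(v) | v %in% c(".", "?")] <- ""; v }
  occ <- suppressWarnings(as.numeric(m[, "occupancy"]))
  data.frame(chain = blank(get2(m, fields, "auth_asym_id", "label_asym_id")),
             resno = as.integer(get2(m, fields, "auth_seq_id", "label_seq_id")),
             insert = blank(get("pdbx_PDB_ins_code")),
             resid = get2(m, fields, "auth_comp_id", "label_comp_id"),
             elety = get2(m, fields, "auth_atom_id", "label_atom_id"),
             element = blank(get("type_symbol")),
             x = as.numeric(m[, "Cartn_x"]),
             y = as.numeric(m[, "Cartn_y"]),
             z = as.numeric(m[, "Cartn_z"]),
             o = ifelse(is.na(occ), 1, occ),
             alt = blank(get("label_alt_id")),
             stringsAsFactors = FALSE)
}

get2 <- function(m, fields, a, b) {
  if (a %in% fields) m[, a] else if (b %in% fields) m[, b]
  else stop("mmCIF atom_site loop lacks both ", a, " and ", b, call. = FALSE)
}

cif_tokens <- function(line) {
  out <- character(); s <- trimws(line)
  while (nzchar(s)) {
    q <- substr(s, 1, 1)
    if (q %in% c("'", '"')) {
      rest <- substr(s, 2, nchar(s))
      end <- regexpr(paste0(q, "(\\s|$)"), rest)
      if (end < 0) end <- nchar(rest)
      out <- c(out, substr(rest, 1, end - 1))
      s <- trimws(substr(rest, end + 1, nchar(rest)))
    } else {
      sp <- regexpr("\\s", s)
      if (sp < 0) { out <- c(out, s); s <- "" }
      else { out <- c(out, substr(s, 1, sp - 1)); s <- trimws(substr(s, sp, nchar(s))) }
    }
  }
  out
}

# Keep the highest-occupancy conformer per (chain, resno, insert, elety);
# the first listed wins a tie. Deterministic by construction.
resolve_altlocs <- function(a) {
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  if (!anyDuplicated(key)) { a$alt <- ""; return(a) }
  ord <- order(key, -a$o, seq_len(nrow(a)))
  a2 <- a[ord, , drop = FALSE]
  a2 <- a2[!duplicated(key[ord]), , drop = FALSE]
  a2 <- a2[order(match(paste(a2$chain, a2$resno, a2$insert, a2$elety, sep = "\r"),
                       unique(key))), , drop = FALSE]
  a2$alt <- ""
  rownames(a2) <- NULL
  a2
}

#' Write an atom set to a coordinate file
#'
#' PDB output goes through bio3d (coordinates at 3 decimals, chain ids limited
#' to one character); mmCIF output writes a full `atom_site` loop and
#' round-trips coordinates exactly at the printed precision (6 decimals).
#'
#' @param atoms a nonempty `atom_set`.
#' @param path output path.
#' @param format `"pdb"` or `"mmcif"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path, format = c("auto", "pdb", "mmcif")) {
  stopifnot(inherits(atoms, "atom_set"))
  if (nrow(atoms) == 0) stop("refusing to write an empty atom_set", call. = FALSE)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (format == "pdb") {
    if (any(nchar(atoms$chain) > 1))
      stop("PDB chain id field is one character; use format = 'mmcif'", call. = FALSE)
    ok <- tryCatch({
      bio3d::write.pdb(file = path, xyz = as.numeric(t(coords(atoms))),
                       type = rep("ATOM", nrow(atoms)),
                       resno = atoms$resno, resid = atoms$resid,
                       eleno = seq_len(nrow(atoms)), elety = atoms$elety,
                       chain = ifelse(atoms$chain == "", " ", atoms$chain),
                       insert = ifelse(atoms$insert == "", "", atoms$insert),
                       o = atoms$o, b = rep(0, nrow(atoms)),
                       elesy = atoms$element)
      TRUE
    }, error = function(e) stop("cannot write PDB to '", path, "': ",
                                conditionMessage(e), call. = FALSE))
  } else {
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("cannot write to '", path, "'",
                                             call. = FALSE))
    on.exit(close(con))
    writeLines(c("data_digb", "#", "loop_",
                 paste0("_atom_site.",
                        c("group_PDB", "id", "type_symbol", "label_atom_id",
                          "label_alt_id", "label_comp_id", "label_asym_id",
                          "label_seq_id", "pdbx_PDB_ins_code",
                          "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                          "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                          "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"))),
               con)
    dotify <- function(v) ifelse(is.na(v) | v == "", ".", v)
    lines <- sprintf("ATOM %d %s %s . %s %s %d %s %.6f %.6f %.6f %.4f 0.00 %d %s %s %s 1",
                     seq_len(nrow(atoms)), dotify(atoms$element),
                     dotify(atoms$elety), atoms$resid, dotify(atoms$chain),
                     atoms$resno, dotify(atoms$insert),
                     atoms$x, atoms$y, atoms$z, atoms$o,
                     atoms$resno, atoms$resid, dotify(atoms$chain),
                     dotify(atoms$elety))
    writeLines(lines, con)
    writeLines("#", con)
  }
  invisible(path)
}

#' One-letter sequence of a chain
#'
#' Reads the residues of a chain in (resno, insertion-code) order, one per
#' residue with a CA atom, and translates 3-letter codes via bio3d.
#'
#' @param atoms an `atom_set`.
#' @param chain chain id.
#' @return list with `sequence` (string), `resno` (integer vector) and
#'   `insert` (character vector), aligned per residue.
#' @export
chain_sequence <- function(atoms, chain) {
  ca <- select_atoms(atoms, chain = chain, elety = "CA", polymer_only = TRUE)
  ca <- ca[!duplicated(paste(ca$resno, ca$insert)), , drop = FALSE]
  ord <- order(ca$resno, ca$insert)
  ca <- ca[ord, , drop = FALSE]
  if (nrow(ca) == 0) stop("chain '", chain, "' has no polymer CA atoms", call. = FALSE)
  one <- suppressWarnings(bio3d::aa321(ca$resid))
  one[is.na(one)] <- "X"
  list(sequence = paste(one, collapse = ""), resno = ca$resno, insert = ca$insert)
}
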