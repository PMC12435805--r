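# Independent oracles and tiny in-code fixtures.

# All-pairs clash count: number of probe points with at least one environment
# point within cutoff (inclusive). Deliberately naive; the package's
# cell-list search is checked against this.
brute_clash_count <- function(P, E, cutoff) {
  sum(vapply(seq_len(nrow(P)), function(i) {
    any(sqrt(colSums((t(E) - P[i, ])^2)) <= cutoff)
  }, logical(1)))
}

brute_min_distance <- function(A, B) {
  min(vapply(seq_len(nrow(A)), function(i) {
    min(sqrt(colSums((t(B) - A[i, ])^2)))
  }, numeric(1)))
}

# Uniform random rotation matrix via QR of a Gaussian matrix.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Three-atom glycine fixture (N, CA, C) used for parser round trips.
gly_fixture_coords <- matrix(c(11.104, 6.134, -6.504,
                               11.639, 6.071, -5.147,
                               10.729, 6.768, -4.123), 3, 3, byrow = TRUE)

write_gly_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   GLY A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   GLY A   1      10.729   6.768  -4.123  1.00  0.00           C",
    "END"), path)
  path
}

write_gly_cif <- function(path) {
  hdr <- paste0("_atom_site.",
                c("group_PDB", "id", "type_symbol", "label_atom_id",
                  "label_alt_id", "label_comp_id", "label_asym_id",
                  "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                  "Cartn_z", "occupancy", "B_iso_or_equiv", "auth_seq_id",
                  "auth_comp_id", "auth_asym_id", "auth_atom_id",
                  "pdbx_PDB_model_num"))
  rows <- sprintf("ATOM %d %s %s . GLY A 1 ? %.3f %.3f %.3f 1.00 0.00 1 GLY A %s 1",
                  1:3, c("N", "C", "C"), c("N", "CA", "C"),
                  gly_fixture_coords[, 1], gly_fixture_coords[, 2],
                  gly_fixture_coords[, 3], c("N", "CA", "C"))
  writeLines(c("data_gly", "loop_", hdr, rows), path)
  path
}

# Minimal atom_set builder for geometric tests.
points_atom_set <- function(xyz, chain = "A", element = "C", elety = "CA",
                            resno = NULL, resid = "GLY") {
  xyz <- matrix(xyz, ncol = 3)
  atom_set(data.frame(chain = chain,
                      resno = if (is.null(resno)) seq_len(nrow(xyz)) else resno,
                      resid = resid, elety = elety, element = element,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE))
}

# A GFP-binding nanobody framework: the embedded reference with distinct
# CDR loops spliced in (wild-type interface residues retained), used as a
# realistic query that is not the reference itself.
gfp_nanobody_sequence <- function() {
  ref <- gb_reference()
  res <- ref$res
  res[ref$region == "CDR1"] <- strsplit("GFPVNRYS", "")[[1]]
  res[ref$region == "CDR2"] <- strsplit("MSSAGDRS", "")[[1]]
  res[ref$region == "CDR3"] <- strsplit("NVGFEYAVY", "")[[1]]
  paste(res, collapse = "")
}

# Shared test helpers referencing package internals via exported surface.
imgt_query_index_for_test <- function(m, pos) {
  m$table$query_index[match(as.character(pos), m$table$imgt)]
}

vec_norm_for_test <- function(v) sqrt(sum(v^2))
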