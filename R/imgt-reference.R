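# Embedded IMGT-numbered VHH reference framework.
#
# This is a constructed consensus single-domain (VHH) sequence with exactly
# one residue per occupied IMGT slot. Framework residues follow the canonical
# identities of the nanobody scaffold (conserved anchors C23, W41, C104 and
# the interface-relevant wild types S7, L12, Q14, G40, Q44, P46, G47, E49,
# K84, V101, Q120, Q123, T125). It is a synthetic consensus, not a database
# germline entry; all numbering transfer in this package is by alignment to
# it, so only the relative framework geometry of the numbering matters.

.imgt_cdr_spans <- list(CDR1 = c(27L, 38L), CDR2 = c(56L, 65L), CDR3 = c(105L, 117L))

# IMGT symmetric fill: k residues occupy an m-slot span by taking the first
# ceiling(k/2) slots from the front and the rest from the back, leaving the
# gap in the middle of the loop (111/112-style convention).
imgt_fill_positions <- function(span, k) {
  slots <- seq.int(span[1], span[2])
  m <- length(slots)
  if (k > m) stop("span overflow: use imgt_fill_with_insertions()", call. = FALSE)
  if (k == 0) return(integer())
  front <- ceiling(k / 2)
  c(slots[seq_len(front)], if (k > front) rev(rev(slots)[seq_len(k - front)]))
}

# As above, but when k exceeds the span the extra residues get insertion
# codes on the two middle slots: left-middle ascending (e.g. 111A, 111B),
# right-middle descending (112B, 112A), following the IMGT CDR3 convention.
# Returns a character vector of IMGT labels in sequence order.
imgt_fill_with_insertions <- function(span, k) {
  slots <- seq.int(span[1], span[2])
  m <- length(slots)
  if (k <= m) return(as.character(imgt_fill_positions(span, k)))
  extra <- k - m
  mid_l <- slots[ceiling(m / 2)]; mid_r <- slots[ceiling(m / 2) + 1L]
  n_l <- ceiling(extra / 2); n_r <- extra - n_l
  left <- paste0(mid_l, LETTERS[seq_len(n_l)])
  right <- if (n_r > 0) paste0(mid_r, rev(LETTERS[seq_len(n_r)])) else character()
  c(as.character(slots[slots <= mid_l]), left, right,
    as.character(slots[slots > mid_l]))
}

# Build the reference table once at load time.
.build_reference <- function() {
  fr1 <- list(pos = c(1:9, 11:26),
              res = strsplit("QVQLVESGGGLVQPGGSLRLSCAAS", "")[[1]])
  cdr1_res <- strsplit("GFTFSSYA", "")[[1]]
  cdr1 <- list(pos = imgt_fill_positions(.imgt_cdr_spans$CDR1, length(cdr1_res)),
               res = cdr1_res)
  fr2 <- list(pos = 39:55, res = strsplit("MGWFRQAPGKEREFVAA", "")[[1]])
  cdr2_res <- strsplit("AISSGGST", "")[[1]]
  cdr2 <- list(pos = imgt_fill_positions(.imgt_cdr_spans$CDR2, length(cdr2_res)),
               res = cdr2_res)
  fr3 <- list(pos = c(66:72, 74:104),
              res = strsplit("NYADSVKGRFTISRDNAKNTLYLQMNSLRAEDTAVYYC", "")[[1]])
  cdr3_res <- strsplit("AADSTAYEY", "")[[1]]
  cdr3 <- list(pos = imgt_fill_positions(.imgt_cdr_spans$CDR3, length(cdr3_res)),
               res = cdr3_res)
  fr4 <- list(pos = 118:128, res = strsplit("WGQGTQVTVSS", "")[[1]])
  parts <- list(fr1, cdr1, fr2, cdr2, fr3, cdr3, fr4)
  pos <- unlist(lapply(parts, `[[`, "pos"))
  res <- unlist(lapply(parts, `[[`, "res"))
  stopifnot(length(pos) == length(res), !is.unsorted(pos), !anyDuplicated(pos))
  region <- rep("FR", length(pos))
  for (nm in names(.imgt_cdr_spans)) {
    sp <- .imgt_cdr_spans[[nm]]
    region[pos >= sp[1] & pos <= sp[2]] <- nm
  }
  data.frame(imgt = pos, res = res, region = region, stringsAsFactors = FALSE)
}

.reference_table <- .build_reference()

#' The embedded IMGT-numbered VHH reference
#'
#' Returns the consensus single-domain antibody framework used as the
#' numbering reference, as a data frame with columns `imgt` (position),
#' `res` (one-letter residue) and `region` (`FR`, `CDR1`, `CDR2`, `CDR3`).
#' The CDR spans follow the IMGT definitions 27-38, 56-65 and 105-117.
#'
#' @return data frame, one row per occupied IMGT position.
#' @export
gb_reference <- function() .reference_table

gb_reference_sequence <- function() paste(.reference_table$res, collapse = "")
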