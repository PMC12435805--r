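# Named Gembody substitution sets. Every set shares the core
# S7N;L12C;Q14K;T125M quartet that predisposes the nanobody-to-nanobody
# interface and installs the reactive cysteine at IMGT 12; named sets add
# variant-specific framework substitutions (solubility or interface tuning).
.gb_variant_sets <- list(
  core         = c("S7N", "L12C", "Q14K", "T125M"),
  `Gb5-006`    = c("S7N", "L12C", "Q14K", "G40T", "Q49E", "L52W", "K84E",
                   "I101V", "T125M"),
  GbD12        = c("S7N", "L12C", "Q14K", "K84E", "P123Q", "T125M"),
  GbS2A4       = c("Q5V", "S7N", "L12C", "Q14K", "Q44R", "T125M"),
  GbH12        = c("L2V", "S7N", "L12C", "Q14K", "K84E", "P123Q", "T125M"),
  GbRBD3       = c("S7N", "L12C", "Q14K", "T125M", "K84E"),
  GbRBD1       = c("S7N", "L12C", "Q14K", "T125M", "K84E"),
  GbRBD6       = c("S7N", "L12C", "Q14K", "T125M", "K84E"),
  GbC4         = c("L2G", "S7N", "L12C", "Q14K", "T125M"),
  Gb113        = c("S7N", "L12C", "Q14K", "T125M"),
  GbEnhancer   = c("S7N", "L12C", "Q14K", "T125M"),
  GbLysozyme   = c("S7N", "L12C", "Q14K", "T125M"),
  GbMBP        = c("S7N", "L12C", "Q14K", "T125M"),
  GbHIV        = c("S7N", "L12C", "Q14K", "T125M")
)

#' Named Gembody substitution sets
#'
#' @return named list of character vectors in `"S7N"` notation (wild type,
#'   IMGT position, replacement). `"core"` is the minimal quartet shared by
#'   every variant.
#' @export
gb_variants <- function() .gb_variant_sets

parse_mutation <- function(m) {
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", m)
  if (!all(ok)) stop("malformed mutation spec: ", paste(m[!ok], collapse = ", "),
                     call. = FALSE)
  data.frame(wt = substr(m, 1, 1),
             imgt = as.integer(gsub("[A-Z]", "", m)),
             new = substr(m, nchar(m), nchar(m)),
             stringsAsFactors = FALSE)
}

#' Design Gembody substitutions for a nanobody
#'
#' Instantiates a substitution set against an IMGT-annotated query.
#' Positions already carrying the replacement residue are omitted from the
#' emitted list and reported (`status = "already_present"`), so applying a
#' set to its own product yields an empty substitution list. A listed wild
#' type that does not match the residue actually found at that position is
#' flagged (`status = "wt_mismatch"`) and still applied, since the
#' replacement, not the wild type, defines the designed interface.
#'
#' @param map a `framework_map` from [align_to_reference()] (or a
#'   `chain_annotation`, whose map is used).
#' @param variant name of a set in [gb_variants()] (default `"core"`), or a
#'   character vector of `"S7N"`-style mutations for a custom list.
#' @return a `mutation_spec`: list with `label`, `table` (data frame `imgt`,
#'   `wt`, `new`, `observed`, `status`), `applied` (the emitted `"S7N"`
#'   strings) and `mutant_sequence`.
#' @export
design_gb_substitutions <- function(map, variant = "core") {
  if (inherits(map, "chain_annotation")) map <- map$map
  stopifnot(inherits(map, "framework_map"))
  if (length(variant) == 1 && variant %in% names(.gb_variant_sets)) {
    label <- variant
    muts <- parse_mutation(.gb_variant_sets[[variant]])
  } else {
    label <- "custom"
    muts <- parse_mutation(variant)
  }
  if (anyDuplicated(muts$imgt))
    stop("duplicate IMGT positions in substitution set", call. = FALSE)
  qseq <- strsplit(map$query, "")[[1]]
  rows <- lapply(seq_len(nrow(muts)), function(i) {
    p <- muts$imgt[i]
    obs <- imgt_residue(map, p)
    if (is.na(obs))
      stop("substitution set needs IMGT position ", p,
           ", which is not mapped in this query", call. = FALSE)
    status <- if (obs == muts$new[i]) "already_present"
    else if (obs == muts$wt[i]) "applied"
    else "wt_mismatch"
    data.frame(imgt = p, wt = muts$wt[i], new = muts$new[i], observed = obs,
               status = status, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  for (i in seq_len(nrow(tab))) {
    if (tab$status[i] == "already_present") next
    qi <- imgt_query_index(map, tab$imgt[i])
    qseq[qi] <- tab$new[i]
  }
  if (any(tab$status == "wt_mismatch"))
    warning("wild-type mismatch at IMGT ",
            paste(tab$imgt[tab$status == "wt_mismatch"], collapse = ", "),
            " (observed ", paste(tab$observed[tab$status == "wt_mismatch"],
                                 collapse = ", "), ")", call. = FALSE)
  emit <- tab[tab$status != "already_present", , drop = FALSE]
  out <- list(label = label, table = tab,
              applied = sprintf("%s%d%s", emit$observed, emit$imgt, emit$new),
              mutant_sequence = paste(qseq, collapse = ""))
  class(out) <- "mutation_spec"
  out
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat(sprintf("<mutation_spec> %s: %s\n", x$label,
              if (length(x$applied)) paste(x$applied, collapse = ";")
              else "(nothing to do)"))
  skip <- x$table[x$table$status == "already_present", , drop = FALSE]
  if (nrow(skip))
    cat("  already present: ",
        paste0(skip$new, skip$imgt, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Write a mutation list as tab-separated text
#' @param spec a `mutation_spec`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(spec, path) {
  stopifnot(inherits(spec, "mutation_spec"))
  utils::write.table(spec$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
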