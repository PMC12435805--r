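# Command-line pipeline: a thin, scriptable layer over the package
# functions. Subcommands: annotate, design, superpose, screen, survey,
# geometry, contacts, simulate. All tabular outputs are tab-separated with
# a '#'-comment header recording the package version and resolved
# parameters; exit statuses are 0 (success), 1 (usage error), 2 (data
# error).

parse_cli_args <- function(args) {
  if (!length(args)) stop_usage("no subcommand given")
  cmd <- args[[1]]
  opts <- list(); i <- 2L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop_usage("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i + 1L > length(args)) stop_usage("missing value for --", key)
    opts[[gsub("-", "_", key)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  list(cmd = cmd, opts = opts)
}

stop_usage <- function(...) {
  stop(structure(class = c("digb_usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

opt_get <- function(opts, key, default = NULL, required = FALSE) {
  v <- opts[[key]]
  if (is.null(v)) {
    if (required) stop_usage("missing required option --", gsub("_", "-", key))
    return(default)
  }
  v
}

opt_num <- function(opts, key, default) {
  v <- opt_get(opts, key)
  if (is.null(v)) return(default)
  n <- suppressWarnings(as.numeric(v))
  if (is.na(n)) stop_usage("--", gsub("_", "-", key), " must be numeric, got '", v, "'")
  n
}

check_infile <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop_usage(what, " file not found: ", if (is.null(path)) "(not given)" else path)
  path
}

tsv_header <- function(params) {
  c(sprintf("# digb %s", as.character(utils::packageVersion("digb"))),
    sprintf("# %s = %s", names(params), vapply(params, paste, "", collapse = ",")))
}

write_tsv_report <- function(df, path, params = list()) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(tsv_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_fasta_sequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*", "", names(x)))
}

# Chain-map sidecar: tab-separated (chain, resno, insert, imgt) linking
# structure residues to IMGT labels, as written by `simulate`.
read_chain_annotation <- function(path, chain) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "#")
  tab <- tab[tab$chain == chain, , drop = FALSE]
  if (!nrow(tab)) stop("chain '", chain, "' not present in ", path, call. = FALSE)
  if (is.null(tab$insert)) tab$insert <- ""
  map_tab <- data.frame(query_index = seq_len(nrow(tab)), residue = "X",
                        imgt = tab$imgt,
                        region = "FR", stringsAsFactors = FALSE)
  map <- structure(list(query = paste(rep("X", nrow(tab)), collapse = ""),
                        table = map_tab, cdr_spans = .imgt_cdr_spans,
                        framework_identity = 1, alignment_score = NA_real_),
                   class = "framework_map")
  chain_annotation_direct(chain, map, resno = as.integer(tab$resno),
                          insert = ifelse(is.na(tab$insert), "", tab$insert))
}

write_chain_map <- function(anns, path) {
  rows <- lapply(anns, function(ann) {
    parts <- strsplit(ann$imgt_resno, "|", fixed = TRUE)
    data.frame(chain = ann$chain,
               resno = vapply(parts, `[[`, "", 1),
               insert = vapply(parts, function(p) if (length(p) > 1) p[2] else "", ""),
               imgt = names(ann$imgt_resno), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the DiGb pipeline
#'
#' Entry point behind the `digb` command-line script. See the package
#' vignette for the subcommands and their options; each stage simply wraps
#' the corresponding exported function and writes tab-separated reports.
#'
#' @param args character vector of command-line arguments (subcommand first,
#'   then `--option value` pairs).
#' @return exit status, invisibly: 0 success, 1 usage error, 2 data error.
#' @export
run_pipeline <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    parsed <- parse_cli_args(args)
    dispatch_pipeline(parsed$cmd, parsed$opts)
    0L
  },
  digb_usage_error = function(e) {
    message("usage error: ", conditionMessage(e))
    1L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}

dispatch_pipeline <- function(cmd, opts) {
  out_dir <- opt_get(opts, "out", default = ".")
  handler <- switch(cmd,
                    annotate = pipeline_annotate,
                    design = pipeline_design,
                    superpose = pipeline_superpose,
                    screen = pipeline_screen,
                    survey = pipeline_survey,
                    geometry = pipeline_geometry,
                    contacts = pipeline_contacts,
                    simulate = pipeline_simulate,
                    stop_usage("unknown subcommand '", cmd, "'"))
  # resolve and validate inputs before creating any output
  handler(opts, out_dir)
}

pipeline_annotate <- function(opts, out_dir) {
  fasta <- check_infile(opt_get(opts, "fasta", required = TRUE), "FASTA")
  seqs <- read_fasta_sequences(fasta)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(seqs)) {
    map <- align_to_reference(seqs[[nm]])
    write_tsv_report(map$table, file.path(out_dir, paste0(nm, "_imgt.tsv")),
                     list(sequence = nm,
                          framework_identity = sprintf("%.4f", map$framework_identity)))
    adv <- check_interface_conservation(map)
    write_tsv_report(adv, file.path(out_dir, paste0(nm, "_conservation.tsv")),
                     list(sequence = nm))
  }
}

pipeline_design <- function(opts, out_dir) {
  fasta <- check_infile(opt_get(opts, "fasta", required = TRUE), "FASTA")
  variant <- opt_get(opts, "variant", default = "core")
  seqs <- read_fasta_sequences(fasta)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mut_lines <- character()
  for (nm in names(seqs)) {
    spec <- design_gb_substitutions(align_to_reference(seqs[[nm]]), variant)
    write_tsv_report(spec$table, file.path(out_dir, paste0(nm, "_mutations.tsv")),
                     list(sequence = nm, variant = variant))
    mut_lines <- c(mut_lines, paste0(">", nm, "_", variant), spec$mutant_sequence)
  }
  writeLines(mut_lines, file.path(out_dir, "mutants.fasta"))
}

pipeline_superpose <- function(opts, out_dir) {
  mob_f <- check_infile(opt_get(opts, "mobile", required = TRUE), "mobile structure")
  fix_f <- check_infile(opt_get(opts, "fixed", required = TRUE), "fixed structure")
  mob <- read_structure(mob_f); fix <- read_structure(fix_f)
  mob_ch <- opt_get(opts, "mobile_chain", default = unique(mob$chain)[1])
  fix_ch <- opt_get(opts, "fixed_chain", default = unique(fix$chain)[1])
  tf <- superpose_chains(mob, annotate_chain(mob, mob_ch),
                         fix, annotate_chain(fix, fix_ch))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_transform(tf, file.path(out_dir, "transform.txt"))
  write_structure(apply_transform(mob, tf), file.path(out_dir, "superposed.pdb"))
}

load_screen_entry <- function(path, chainmap, nb_chain) {
  atoms <- read_structure(path)
  ann <- if (!is.null(chainmap) && !is.null(nb_chain))
    read_chain_annotation(chainmap, nb_chain) else NULL
  list(atoms = atoms, ann = ann)
}

load_scaffold <- function(opts) {
  sc_f <- check_infile(opt_get(opts, "scaffold", required = TRUE), "scaffold")
  scaffold <- read_structure(sc_f)
  chains <- strsplit(opt_get(opts, "scaffold_chains",
                             default = paste(unique(scaffold$chain)[1:2], collapse = ",")),
                     ",")[[1]]
  chainmap <- opt_get(opts, "chainmap")
  ann <- if (!is.null(chainmap))
    lapply(chains, function(ch) read_chain_annotation(chainmap, ch))
  else lapply(chains, function(ch) annotate_chain(scaffold, ch))
  list(atoms = scaffold, ann = ann)
}

pipeline_screen <- function(opts, out_dir) {
  cx_f <- check_infile(opt_get(opts, "complex", required = TRUE), "complex")
  sc <- load_scaffold(opts)
  entry <- load_screen_entry(cx_f, opt_get(opts, "chainmap"),
                             opt_get(opts, "nb_chain"))
  cutoff <- opt_num(opts, "cutoff", 4.0)
  threshold <- opt_num(opts, "threshold", 0.05)
  rep <- screen_on_scaffold(entry$atoms, sc$atoms, complex_ann = entry$ann,
                            scaffold_ann = sc$ann, cutoff = cutoff,
                            threshold = threshold)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_report(data.frame(entry = basename(cx_f), n_clash = rep$n_clash,
                              n_total = rep$n_total, score = rep$score,
                              classification = rep$classification,
                              rmsd_copy_a = rep$placement_rmsd[1],
                              rmsd_copy_b = rep$placement_rmsd[2]),
                   file.path(out_dir, "screen.tsv"),
                   list(cutoff = cutoff, threshold = threshold))
}

pipeline_survey <- function(opts, out_dir) {
  listing <- opt_get(opts, "complexes", required = TRUE)
  files <- strsplit(listing, ",")[[1]]
  if (length(files) == 1 && dir.exists(files))
    files <- list.files(files, pattern = "\\.(pdb|cif|mmcif)$", full.names = TRUE)
  for (f in files) check_infile(f, "complex")
  if (!length(files)) stop_usage("no complex files found")
  sc <- load_scaffold(opts)
  chainmap <- opt_get(opts, "chainmap"); nb_chain <- opt_get(opts, "nb_chain")
  cutoff <- opt_num(opts, "cutoff", 4.0)
  threshold <- opt_num(opts, "threshold", 0.05)
  entries <- lapply(files, load_screen_entry, chainmap = chainmap,
                    nb_chain = nb_chain)
  names(entries) <- basename(files)
  sv <- survey_library(entries, sc$atoms, scaffold_ann = sc$ann,
                       cutoff = cutoff, threshold = threshold)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per <- do.call(rbind, lapply(names(sv$reports), function(nm) {
    r <- sv$reports[[nm]]
    data.frame(entry = nm, n_clash = r$n_clash, n_total = r$n_total,
               score = r$score, classification = r$classification,
               stringsAsFactors = FALSE)
  }))
  write_tsv_report(per, file.path(out_dir, "survey_entries.tsv"),
                   list(cutoff = cutoff, threshold = threshold))
  smry <- data.frame(n_screened = sv$n_screened, n_skipped = length(sv$skipped),
                     fraction_no_clash = sv$fraction_no_clash,
                     fraction_under_threshold = sv$fraction_under_threshold)
  write_tsv_report(smry, file.path(out_dir, "survey_summary.tsv"),
                   list(cutoff = cutoff, threshold = threshold))
  if (length(sv$skipped))
    writeLines(paste(names(sv$skipped), sv$skipped, sep = "\t"),
               file.path(out_dir, "survey_skipped.tsv"))
}

pipeline_geometry <- function(opts, out_dir) {
  listing <- opt_get(opts, "frames", required = TRUE)
  files <- strsplit(listing, ",")[[1]]
  if (length(files) == 1 && dir.exists(files))
    files <- sort(list.files(files, pattern = "\\.(pdb|cif|mmcif)$", full.names = TRUE))
  for (f in files) check_infile(f, "frame")
  static_ch <- opt_get(opts, "static_chain", default = "A")
  mobile_ch <- opt_get(opts, "mobile_chain", default = "B")
  chainmap <- opt_get(opts, "chainmap")
  weighting <- opt_get(opts, "weighting", default = "atomic_mass")
  frames <- lapply(files, read_structure)
  get_ann <- function(ch, atoms) {
    if (!is.null(chainmap)) read_chain_annotation(chainmap, ch)
    else annotate_chain(atoms, ch)
  }
  ann_s <- get_ann(static_ch, frames[[1]])
  ann_m <- get_ann(mobile_ch, frames[[1]])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(frames) == 1) {
    g <- digb_geometry(frames[[1]], ann_s, ann_m, weighting = weighting)
    write_tsv_report(data.frame(intra_digb_angle = round(g$intra_digb_angle, 1),
                                c12_separation = round(g$c12_separation, 2)),
                     file.path(out_dir, "geometry_summary.tsv"),
                     list(weighting = weighting, model = basename(files)))
  } else {
    gs <- wobble_series(frames, ann_s, ann_m, weighting = weighting)
    write_tsv_report(data.frame(frame = seq_len(gs$n_frames),
                                file = basename(files),
                                beta = round(gs$beta, 3)),
                     file.path(out_dir, "wobble_series.tsv"),
                     list(weighting = weighting))
    write_tsv_report(data.frame(intra_digb_angle = round(gs$intra_digb_angle, 1),
                                max_beta = round(gs$max_beta, 1),
                                wobble_range = round(gs$wobble_range, 1)),
                     file.path(out_dir, "geometry_summary.tsv"),
                     list(weighting = weighting, n_frames = gs$n_frames))
  }
}

pipeline_contacts <- function(opts, out_dir) {
  st_f <- check_infile(opt_get(opts, "structure", required = TRUE), "structure")
  atoms <- read_structure(st_f)
  chains <- strsplit(opt_get(opts, "chains",
                             default = paste(unique(atoms$chain)[1:2], collapse = ",")),
                     ",")[[1]]
  chainmap <- opt_get(opts, "chainmap")
  get_ann <- function(ch) {
    if (!is.null(chainmap)) read_chain_annotation(chainmap, ch)
    else annotate_chain(atoms, ch)
  }
  cutoff <- opt_num(opts, "cutoff", 4.0)
  hb <- opt_num(opts, "hbond_cutoff", 3.5)
  tab <- interface_contacts(atoms, get_ann(chains[1]), get_ann(chains[2]),
                            contact_cutoff = cutoff, hbond_cutoff = hb)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_report(as.data.frame(tab), file.path(out_dir, "contacts.tsv"),
                   list(cutoff = cutoff, hbond_cutoff = hb))
}

pipeline_simulate <- function(opts, out_dir) {
  what <- opt_get(opts, "what", required = TRUE)
  seed <- as.integer(opt_num(opts, "seed", 1))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (what == "digb") {
    gb <- make_toy_gb(seed)
    scene <- assemble_digb(gb, intra_angle = opt_num(opts, "intra_angle", 85),
                           c12_separation = opt_num(opts, "c12_separation", 6))
    write_structure(scene$atoms, file.path(out_dir, "digb.pdb"))
    write_chain_map(list(scene$ann_a, scene$ann_b),
                    file.path(out_dir, "chainmap.tsv"))
    write_tsv_report(data.frame(intra_angle = scene$truth$intra_angle,
                                c12_separation = scene$truth$c12_separation),
                     file.path(out_dir, "truth.tsv"), list(seed = seed))
  } else if (what == "wobble") {
    gb <- make_toy_gb(seed)
    scene <- assemble_digb(gb, intra_angle = opt_num(opts, "intra_angle", 85))
    series <- make_wobble_series(scene,
                                 amplitude = opt_num(opts, "amplitude", 8),
                                 n_frames = as.integer(opt_num(opts, "n_frames", 60)),
                                 seed = seed)
    for (i in seq_along(series$frames))
      write_structure(series$frames[[i]],
                      file.path(out_dir, sprintf("frame_%03d.pdb", i)))
    write_chain_map(list(series$ann_a, series$ann_b),
                    file.path(out_dir, "chainmap.tsv"))
    write_tsv_report(data.frame(frame = seq_along(series$truth$tilts),
                                tilt = series$truth$tilts),
                     file.path(out_dir, "truth.tsv"),
                     list(seed = seed, amplitude = series$truth$amplitude))
  } else if (what == "clash") {
    scene <- make_clash_scene(as.integer(opt_num(opts, "n_atoms", 100)),
                              as.integer(opt_num(opts, "k_clash", 5)),
                              cutoff = opt_num(opts, "cutoff", 4.0), seed = seed)
    write_structure(scene$probe, file.path(out_dir, "probe.pdb"))
    write_structure(scene$environment, file.path(out_dir, "environment.pdb"))
    write_tsv_report(data.frame(n_clash = scene$truth$n_clash,
                                cutoff = scene$truth$cutoff),
                     file.path(out_dir, "truth.tsv"), list(seed = seed))
  } else if (what == "library") {
    gb <- make_toy_gb(seed)
    scaffold <- assemble_digb(gb, intra_angle = opt_num(opts, "intra_angle", 85))
    write_structure(scaffold$atoms, file.path(out_dir, "scaffold.pdb"))
    write_chain_map(list(scaffold$ann_a, scaffold$ann_b,
                         reannotate(scaffold$ann_a, "N")),
                    file.path(out_dir, "chainmap.tsv"))
    fracs <- as.numeric(strsplit(opt_get(opts, "fractions",
                                         default = "0,0,0,0,0.03,0.03,0.03,0.1,0.1,0.1"),
                                 ",")[[1]])
    entry_dir <- file.path(out_dir, "entries")
    dir.create(entry_dir, showWarnings = FALSE)
    truth <- data.frame(entry = sprintf("entry_%02d.pdb", seq_along(fracs)),
                        planted_fraction = fracs)
    for (i in seq_along(fracs)) {
      e <- make_survey_entry(scaffold, fracs[i], seed = seed + i)
      write_structure(e$atoms, file.path(entry_dir, truth$entry[i]))
    }
    write_tsv_report(truth, file.path(out_dir, "truth.tsv"), list(seed = seed))
  } else stop_usage("unknown --what '", what,
                    "' (use digb, wobble, clash or library)")
}
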