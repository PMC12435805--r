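test_that("the reference aligns to itself as the identity mapping", {
  m <- align_to_reference(paste(gb_reference()$res, collapse = ""))
  expect_equal(m$framework_identity, 1.0)
  expect_equal(m$table$query_index, seq_len(nchar(m$query)))
  expect_identical(m$table$imgt, as.character(gb_reference()$imgt))
  expect_identical(m$table$residue, gb_reference()$res)
})

test_that("CDR insertions leave framework positions untouched", {
  ref <- gb_reference()
  res <- ref$res
  # splice 3 extra residues into CDR1
  cdr1_end <- max(which(ref$region == "CDR1"))
  spliced <- paste(c(res[1:cdr1_end], "W", "W", "W", res[(cdr1_end + 1):length(res)]),
                   collapse = "")
  m <- align_to_reference(spliced)
  for (p in c(7, 12, 14, 44, 46, 47, 84, 120, 123, 125)) {
    expect_identical(imgt_residue(m, p),
                     ref$res[ref$imgt == p],
                     label = paste("IMGT", p))
  }
  # the lengthened loop stays inside CDR1 labels
  cdr1_rows <- m$table[m$table$region == "CDR1", ]
  expect_equal(nrow(cdr1_rows), sum(ref$region == "CDR1") + 3)
})

test_that("numbering transfer is gap-consistent on the framework", {
  q <- gfp_nanobody_sequence()
  m <- align_to_reference(q)
  fr <- m$table[m$table$region == "FR", ]
  fr <- fr[order(as.integer(fr$imgt)), ]
  # concatenating mapped framework residues in IMGT order reproduces the
  # query framework subsequence (framework indices are increasing)
  expect_false(is.unsorted(fr$query_index))
  expect_identical(paste(fr$residue, collapse = ""),
                   paste(strsplit(q, "")[[1]][fr$query_index], collapse = ""))
})

test_that("a GFP-binder framework carries the expected wild types", {
  m <- align_to_reference(gfp_nanobody_sequence())
  expect_identical(imgt_residue(m, 7), "S")
  expect_identical(imgt_residue(m, 12), "L")
  expect_identical(imgt_residue(m, 14), "Q")
  expect_identical(imgt_residue(m, 125), "T")
})

test_that("malformed queries are rejected", {
  expect_error(align_to_reference("QVQLVESGGG123"), "non-amino-acid|length")
  expect_error(align_to_reference(paste(rep("A", 50), collapse = "")), "length")
  # an unrelated low-complexity sequence is not a nanobody
  expect_error(align_to_reference(paste(rep("PG", 55), collapse = "")),
               "framework identity")
})

test_that("core and GbD12 designs emit exactly the published sets", {
  refseq <- paste(gb_reference()$res, collapse = "")
  m <- align_to_reference(refseq)
  core <- design_gb_substitutions(m, "core")
  expect_identical(core$applied, c("S7N", "L12C", "Q14K", "T125M"))
  # GbD12 needs the P123 wild type of its parent nanobody
  chars <- strsplit(refseq, "")[[1]]
  chars[imgt_query_index_for_test(m, 123)] <- "P"
  m123 <- align_to_reference(paste(chars, collapse = ""))
  d12 <- design_gb_substitutions(m123, "GbD12")
  expect_identical(d12$applied,
                   c("S7N", "L12C", "Q14K", "K84E", "P123Q", "T125M"))
  expect_equal(length(d12$applied), 6)
})


test_that("substitution design is idempotent", {
  m <- align_to_reference(paste(gb_reference()$res, collapse = ""))
  core <- design_gb_substitutions(m, "core")
  m2 <- align_to_reference(core$mutant_sequence)
  again <- design_gb_substitutions(m2, "core")
  expect_length(again$applied, 0)
  expect_true(all(again$table$status == "already_present"))
  # a query already carrying C12 has position 12 omitted and flagged
  chars <- strsplit(m$query, "")[[1]]
  chars[imgt_query_index_for_test(m, 12)] <- "C"
  mc <- align_to_reference(paste(chars, collapse = ""))
  spec <- design_gb_substitutions(mc, "core")
  expect_false("L12C" %in% spec$applied)
  expect_identical(spec$table$status[spec$table$imgt == 12], "already_present")
})

test_that("designs referencing unmapped positions fail, naming the position", {
  m <- align_to_reference(paste(gb_reference()$res, collapse = ""))
  expect_error(design_gb_substitutions(m, c("A999Z")), "999")
})

test_that("every shipped variant set contains the core quartet", {
  v <- gb_variants()
  core <- v$core
  expect_identical(core, c("S7N", "L12C", "Q14K", "T125M"))
  for (nm in names(v)) expect_true(all(core %in% v[[nm]]), label = nm)
  expect_identical(v$`Gb5-006`,
                   c("S7N", "L12C", "Q14K", "G40T", "Q49E", "L52W", "K84E",
                     "I101V", "T125M"))
})

test_that("conservation checks advise on shifted interface identities", {
  m <- align_to_reference(paste(gb_reference()$res, collapse = ""))
  adv <- check_interface_conservation(m)
  expect_true(all(adv$level == "ok"))
  # lysine at 120, as on the SPNS2-binding homodimer, shifts the interface
  chars <- strsplit(m$query, "")[[1]]
  chars[imgt_query_index_for_test(m, 120)] <- "K"
  mk <- align_to_reference(paste(chars, collapse = ""))
  advk <- check_interface_conservation(mk)
  expect_identical(advk$level[advk$imgt == 120], "advisory")
  expect_match(advk$message[advk$imgt == 120], "shift")
  # serine at 12 is only an informational note
  chars <- strsplit(m$query, "")[[1]]
  chars[imgt_query_index_for_test(m, 12)] <- "S"
  ms <- align_to_reference(paste(chars, collapse = ""))
  advs <- check_interface_conservation(ms)
  expect_identical(advs$level[advs$imgt == 12], "note")
})
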