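# motif scanner: exhaustive overlapping matching, FASTA scanning, variant
# comparison

test_that("find_matches enumerates spans including gap alternatives", {
  ac <- motif_preset("ac_core")
  one <- find_matches(ac, "RYDVAAAAAAAAAKAD")
  expect_identical(nrow(one), 1L)
  expect_identical(one$start, 1L)
  expect_identical(one$end, 16L)
  # trailing extra D admits two gap resolutions -> two distinct spans
  two <- find_matches(ac, "RYDVAAAAAAAAAKADD")
  expect_identical(spans_of(two), cbind(start = c(1L, 1L), end = c(16L, 17L)))
  # witness assignment tiles the span in element order
  sp <- two$element_spans[[2]]
  expect_identical(sp[1, "start"], 1L)
  expect_identical(sp[nrow(sp), "end"], 17L)
  gaps <- sp[!is.na(sp[, "start"]), , drop = FALSE]
  expect_true(all(gaps[-1, "start"] == gaps[-nrow(gaps), "end"] + 1L))
  # empty and too-short sequences
  expect_identical(nrow(find_matches(ac, "")), 0L)
  expect_identical(nrow(find_matches(ac, "RYDV")), 0L)
})

test_that("named classes reject ambiguity codes; wildcards accept them", {
  m <- parse_motif("[DE]X{2}[KR]")
  # B in a wildcard position is fine
  expect_identical(nrow(find_matches(m, "DBAK")), 1L)
  # B never satisfies [DE]; '*' never matches anything, even a wildcard
  expect_identical(nrow(find_matches(m, "BBAK")), 0L)
  expect_identical(nrow(find_matches(m, "DA*K")), 0L)
  # lower case sequences are matched after upper-casing
  expect_identical(nrow(find_matches(m, "daak")), 1L)
})

test_that("scanner agrees exactly with the backtracking oracle", {
  set.seed(101)
  motifs <- c(lapply(names(acscan:::PRESET_PATTERNS), motif_preset),
              replicate(10, random_motif(), simplify = FALSE))
  for (m in motifs) {
    for (i in 1:25) {
      s <- random_protein(sample(30:200, 1),
                          alphabet = c(STANDARD_AA, "B", "X", "*"))
      expect_identical(spans_of(find_matches(m, s)), oracle_find_spans(m, s),
                       info = paste(motif_to_string(m), s))
    }
  }
})

test_that("scan_fasta aggregates records and handles edge cases", {
  ac <- motif_preset("ac_core")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">p1 has one centre", "RYDVAAAAAAAAAKAD",
    ">p2 no centre", "AAAAAAAAAAAAAAAAAAAA",
    ">p3 centre with trailing stop", "GGRYDVAAAAAAAAAKADG*"
  ), fa)
  s <- scan_fasta(ac, fa)
  expect_identical(s$n_records_scanned, 3L)
  expect_identical(s$n_records_hit, 2L)
  expect_identical(sort(unique(s$hits$record_id)), c("p1", "p3"))
  # empty FASTA
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_identical(scan_fasta(ac, empty)$n_records_hit, 0L)
  # duplicate ids warn and deduplicate; zero-length records are skipped
  messy <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">d1", "RYDVAAAAAAAAAKAD", ">d1", "RYDVAAAAAAAAAKAD",
               ">z0", ""), messy)
  expect_warning(expect_warning(s2 <- scan_fasta(ac, messy), "zero-length"),
                 "duplicate")
  expect_identical(s2$n_records_scanned, 2L)
  expect_identical(s2$n_records_hit, 2L)
  expect_error(scan_fasta(ac, "no/such/file.fa"), "cannot read")
})

test_that("locus counting collapses isoform suffixes", {
  ac <- motif_preset("ac_core")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">AT1G00001.1", "RYDVAAAAAAAAAKAD",
               ">AT1G00001.2", "RYDVAAAAAAAAAKAD",
               ">AT1G00002.1", "RYDVAAAAAAAAAKAD"), fa)
  expect_identical(scan_fasta(ac, fa)$n_records_hit, 3L)
  expect_identical(scan_fasta(ac, fa, collapse_isoforms = TRUE)$n_records_hit,
                   2L)
})

test_that("hit sets shrink monotonically under constraining and anchoring", {
  set.seed(7)
  ac <- motif_preset("ac_core")
  variants <- list(
    anchored = motif_preset("ac_anchored"),
    fv5 = motif_preset("ac_fv5"),
    narrowed = substitute_position(ac, 1, "[R]")
  )
  relaxed <- motif_preset("functional_core")
  # proteome enriched for near-motif content so hits actually occur
  records <- generate_proteome(60, 150, seed = 11)
  planted <- plant_motifs(records, ac, 25, seed = 12)$records
  hit_keys <- function(m) {
    s <- scan_records(m, planted)
    unique(paste(s$hits$record_id, s$hits$start))
  }
  parent_records <- unique(scan_records(ac, planted)$hits$record_id)
  for (v in variants) {
    vrec <- unique(scan_records(v, planted)$hits$record_id)
    expect_true(all(vrec %in% parent_records),
                info = motif_to_string(v))
  }
  # relaxation: every ac_core hit record is a functional_core hit record
  expect_true(all(parent_records %in%
                    unique(scan_records(relaxed, planted)$hits$record_id)))
})

test_that("compare_variants tabulates counts in input order", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  records <- generate_proteome(40, 120, seed = 5)
  planted <- plant_motifs(records, motif_preset("ac_core"), 15, seed = 6)
  write_protein_fasta(planted$records, fa)
  tab <- compare_variants(list(motif_preset("ac_core"),
                               motif_preset("ac_anchored"),
                               motif_preset("functional_core")), fa)
  expect_identical(tab$motif_name,
                   c("ac_core", "ac_anchored", "functional_core"))
  expect_true(tab$n_records_hit[2] <= tab$n_records_hit[1])
  expect_true(tab$n_records_hit[1] <= tab$n_records_hit[3])
  # single motif on empty FASTA -> one row of zeros
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  tab0 <- compare_variants(motif_preset("ac_core"), empty)
  expect_identical(nrow(tab0), 1L)
  expect_identical(tab0$n_records_hit, 0L)
  expect_identical(tab0$n_matches, 0L)
})

test_that("scan counts are independent of record order", {
  records <- generate_proteome(30, 120, seed = 21)
  planted <- plant_motifs(records, motif_preset("ac_core"), 10, seed = 22)
  s1 <- scan_records(motif_preset("ac_core"), planted$records)
  shuffled <- planted$records[rev(seq_len(nrow(planted$records))), ]
  s2 <- scan_records(motif_preset("ac_core"), shuffled)
  expect_identical(s1$n_records_hit, s2$n_records_hit)
  expect_identical(s1$n_matches, s2$n_matches)
})

test_that("hits TSV and GFF3 writers emit 1-based inclusive coordinates", {
  ac <- motif_preset("ac_core")
  hits <- find_matches(ac, "GGRYDVAAAAAAAAAKADG", record_id = "prot1")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, "ac_core", tsv)
  back <- read.delim(tsv)
  expect_identical(back$start, 3L)
  expect_identical(back$end, 18L)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_hits_gff3(hits, "ac_core", gff)
  lines <- readLines(gff)
  expect_identical(lines[1], "##gff-version 3")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_identical(fields[3], "polypeptide_motif")
  expect_identical(as.integer(fields[4:5]), c(3L, 18L))
})
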