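# motif model: parsing, serialization, derivation operators, presets

test_that("parse_motif handles the published patterns and computes spans", {
  cases <- list(
    list(pat = "[RKS][YFW][DE][VIL]X{9}[KR]X{1,3}[DE]",
         n = 8L, lo = 16L, hi = 18L),
    list(pat = "[RKS]X[DE]X{10}[KR]X{1,3}[DE]", n = 7L, lo = 16L, hi = 18L),
    list(pat = "X", n = 1L, lo = 1L, hi = 1L),
    list(pat = "[R]X{5,20}[RKS][YFW][DE][VIL]X{8}[KR][KR]X{0,2}[DE]",
         n = 11L, lo = 21L, hi = 38L)
  )
  for (cs in cases) {
    m <- parse_motif(cs$pat)
    expect_length(m$elements, cs$n)
    expect_identical(m$min_span, cs$lo)
    expect_identical(m$max_span, cs$hi)
    expect_identical(m$min_span,
                     sum(vapply(m$elements, function(e) e$min_repeat,
                                integer(1))))
    expect_identical(m$max_span,
                     sum(vapply(m$elements, function(e) e$max_repeat,
                                integer(1))))
  }
})

test_that("parse_motif rejects malformed patterns with located errors", {
  expect_error(parse_motif("[RKS"), "unterminated")
  expect_error(parse_motif("[]X"), "empty residue class")
  expect_error(parse_motif("X{3,1}"), "minimum exceeds maximum")
  expect_error(parse_motif("[rks]"), "invalid residue")
  expect_error(parse_motif("[RKB]"), "invalid residue")
  expect_error(parse_motif("[DE]z"), "offset 5")
  expect_error(parse_motif("X{a}"), "malformed repeat")
  expect_error(parse_motif(""), "empty motif")
})

test_that("serialization is canonical and round-trips", {
  m <- parse_motif("[SKR][WYF][ED][LIV]X{9}[RK]X{1,3}[ED]")
  expect_identical(motif_to_string(m),
                   "[KRS][FWY][DE][ILV]X{9}[KR]X{1,3}[DE]")
  expect_true(motif_equal(parse_motif(motif_to_string(m)), m))
  # variable gap emitted verbatim; adjacent fixed gaps merge
  expect_match(motif_to_string(m), "X\\{1,3\\}")
  expect_identical(motif_to_string(parse_motif("[DE]XX{3}X[KR]")),
                   "[DE]X{5}[KR]")
})

test_that("round-trip identity holds for random motifs", {
  set.seed(42)
  for (i in 1:50) {
    m <- random_motif()
    m2 <- parse_motif(motif_to_string(m))
    expect_identical(motif_to_string(m2), motif_to_string(m))
    expect_identical(m2$min_span, m$min_span)
    expect_identical(m2$max_span, m$max_span)
  }
})

test_that("substitute_position swaps one class and is an involution", {
  gc <- motif_preset("gc_core")
  ac <- substitute_position(gc, 3, "[DE]")
  expect_true(motif_equal(ac, motif_preset("ac_core")))
  expect_identical(ac$elements[[3]]$role, "substrate_specificity")
  # identity and involution
  expect_true(motif_equal(substitute_position(gc, 3, "[CTGH]"), gc))
  expect_true(motif_equal(substitute_position(ac, 3, "[CTGH]"), gc))
  # errors
  expect_error(substitute_position(gc, 5, "[DE]"), "wildcard gap")
  expect_error(substitute_position(gc, 99, "[DE]"), "out of range")
})

test_that("constrain_wildcard splits fixed gaps and preserves spans", {
  ac <- motif_preset("ac_core")
  fv5 <- constrain_wildcard(ac, 5, "[FV]")
  expect_identical(motif_to_string(fv5),
                   "[KRS][FWY][DE][ILV][FV]X{8}[KR]X{1,3}[DE]")
  expect_identical(fv5$min_span, ac$min_span)
  expect_identical(fv5$max_span, ac$max_span)
  # interior split leaves gap on both sides
  mid <- constrain_wildcard(ac, 8, "[AG]")
  expect_identical(motif_to_string(mid),
                   "[KRS][FWY][DE][ILV]X{3}[AG]X{5}[KR]X{1,3}[DE]")
  # constraining to wildcard is the identity after gap merging
  expect_true(motif_equal(constrain_wildcard(ac, 5, "X"), ac))
  # errors: class position, variable gap, out of range
  expect_error(constrain_wildcard(ac, 3, "[FV]"), "residue-class element")
  expect_error(constrain_wildcard(ac, 15, "[FV]"), "variable-length gap")
  expect_error(constrain_wildcard(ac, 99, "[FV]"), "minimal span")
})

test_that("add_upstream_anchor prepends anchor plus bounded gap", {
  ac <- motif_preset("ac_core")
  anch <- add_upstream_anchor(ac, "R", 5, 20)
  expect_identical(motif_to_string(anch),
                   "RX{5,20}[KRS][FWY][DE][ILV]X{9}[KR]X{1,3}[DE]")
  expect_identical(anch$elements[[1]]$role, "anchor")
  expect_identical(anch$min_span, ac$min_span + 6L)
  expect_identical(anch$max_span, ac$max_span + 21L)
  # zero gap puts the anchor adjacent to position 1
  adj <- add_upstream_anchor(ac, "R", 0, 0)
  expect_identical(adj$min_span, ac$min_span + 1L)
  expect_identical(expanded_position(adj, 2), 2L)
  expect_error(add_upstream_anchor(ac, "R", -1, 5), "non-negative")
  expect_error(add_upstream_anchor(ac, "R", 6, 5), "exceeds")
})

test_that("preset catalogue matches the published pattern family", {
  expect_identical(
    motif_to_string(motif_preset("ac_kr15")),
    "RX{5,20}[KRS][FWY][DE][ILV]X{8}[KR][KR]X{0,2}[DE]")
  expect_true(motif_equal(motif_preset("ac_core"),
                          substitute_position(motif_preset("gc_core"), 3,
                                              "[DE]")))
  expect_true(motif_equal(motif_preset("ac_fv5"),
                          constrain_wildcard(motif_preset("ac_core"), 5,
                                             "[FV]")))
  expect_true(motif_equal(motif_preset("ac_anchored"),
                          add_upstream_anchor(motif_preset("ac_core"),
                                              "R", 5, 20)))
  expect_error(motif_preset("nonsense"), "valid presets")
  cat_df <- preset_catalogue()
  expect_identical(cat_df$name,
                   c("gc_core", "ac_core", "ac_anchored", "ac_fv5",
                     "ac_kr15", "functional_core"))
})

test_that("functional roles sit at the documented expanded positions", {
  ac <- motif_preset("ac_core")
  expect_identical(role_position(ac, "purine_binding"), 1L)
  expect_identical(role_position(ac, "substrate_specificity"), 3L)
  expect_identical(role_position(ac, "transition_state"), 14L)
  # metal-binding [DE] trails the transition-state residue by 2-4 positions
  # (1-3 gap residues), and the anchored preset keeps the anchor role
  expect_identical(role_position(ac, "metal_binding"), 16L)
  expect_identical(role_position(motif_preset("ac_anchored"), "anchor"), 1L)
  expect_identical(role_position(motif_preset("functional_core"),
                                 "transition_state"), 14L)
})

test_that("preset JSON catalogue round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  export_presets_json(path)
  back <- import_presets_json(path)
  expect_identical(names(back), names(acscan:::PRESET_PATTERNS))
  for (nm in names(back))
    expect_true(motif_equal(back[[nm]], motif_preset(nm)))
})
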