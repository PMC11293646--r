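featurize_fixture <- function(hp, window = NULL) {
  st <- hp$structure
  ctx <- locate_hit(st, hp$truth$mir_span)
  stats <- duplex_stats(st, hp$truth$mir_span, hp$truth$star_span)
  extract_features(st, ctx, stats,
                   query_meta = list(query_length = hp$truth$mir_len,
                                     ld = 0, evalue = 1e-8,
                                     alignment_length = hp$truth$mir_len),
                   genomic_meta = list(window = window,
                                       hit_start_in_window =
                                         hp$truth$mir_span[1]))
}

test_that("schema has the fixed family sizes and 170 features", {
  sc <- feature_schema()
  expect_equal(nrow(sc), 170L)
  sizes <- table(factor(sc$family, levels = unique(sc$family)))
  expect_equal(unname(c(sizes)),
               c(7L, 4L, 5L, 4L, 8L, 23L, 36L, 83L))
  expect_equal(names(sizes),
               c("primary", "reference_query", "genomic_positions",
                 "nucleotide_composition", "energy", "linear_sequence",
                 "pair_composition", "major_structural"))
  expect_equal(anyDuplicated(sc$name), 0L)
})

test_that("extracted vectors are complete, schema-ordered and stable", {
  hp <- make_hairpin(21L, seed = 81)
  ft <- featurize_fixture(hp, interval("chr1", 100, 500, "+"))
  expect_equal(ncol(ft), 170L)
  expect_equal(names(ft), feature_schema()$name)
  expect_true(all(vapply(ft, is.numeric, TRUE)))
  expect_false(anyNA(unlist(ft)))
  # stability across runs
  ft2 <- featurize_fixture(hp, interval("chr1", 100, 500, "+"))
  expect_identical(ft, ft2)
  # invariance under record renaming is inherent: no id enters the vector
})

test_that("perfect-duplex fixture has clean mismatch and seed-state features", {
  hp <- make_hairpin(21L, seed = 82)
  ft <- featurize_fixture(hp)
  expect_equal(ft$n_mismatch, 0)
  expect_equal(ft$n_asym, 0)
  expect_equal(ft$has_secondary_stem, 0)
  expect_equal(c(ft$overhang_5p_side, ft$overhang_3p_side), c(2, 2))
  # seed positions 2-8 are Watson-Crick or wobble paired
  for (k in 2:8) {
    expect_true(ft[[paste0("m", k, "_state")]] %in% c(0, 1))
  }
  expect_true(all(unlist(ft[paste0("mismatch_pos_", 1:8)]) == -1))
})

test_that("a planted asymmetric bulge surfaces at the planted position", {
  hp <- make_hairpin(21L, hairpin_params(bulges = list(list(8, 2, "star"))),
                     seed = 83)
  ft <- featurize_fixture(hp)
  expect_equal(ft$n_asym, 2)
  expect_equal(ft$bulge1_offset, 8)
  expect_equal(ft$bulge1_left, 0)
  expect_equal(ft$bulge1_right, 2)
  expect_equal(ft$bulge2_offset, -1) # only one planted
})

test_that("features mirror duplex statistics exactly", {
  for (sd in c(91, 92)) {
    hp <- make_hairpin(22L, hairpin_params(
      mismatch_positions = c(6L, 12L)), seed = sd)
    stats <- duplex_stats(hp$structure, hp$truth$mir_span,
                          hp$truth$star_span)
    ft <- featurize_fixture(hp)
    expect_equal(ft$n_mismatch, stats$n_mismatch)
    expect_equal(ft$n_asym, stats$n_asym)
    expect_equal(ft$mir_len, stats$mir_len)
    expect_equal(ft$star_len, stats$star_len)
    expect_equal(ft$precursor_len, stats$precursor_len)
    expect_equal(ft$largest_loop, stats$largest_loop)
  }
})

test_that("energy features follow the defining formulas", {
  # AMFE = (MFE / L) * 100; MFEI = AMFE / GC%
  expect_equal(plantmir::compute_composition(list(whole = "GCGC"))[[1]], 100)
  expect_equal(plantmir::compute_composition(list(whole = "AUAU"))[[1]], 0)
  expect_equal(plantmir::compute_composition(list(whole = "GCAU"))[[1]], 50)
  expect_equal(plantmir::compute_composition(list(whole = NULL))[[1]], -1)

  hp <- make_hairpin(21L, seed = 93)
  st <- hp$structure
  ctx <- locate_hit(st, hp$truth$mir_span)
  pre <- c(min(hp$truth$mir_span[1], hp$truth$star_span[1]),
           max(hp$truth$mir_span[2], hp$truth$star_span[2]))
  en <- compute_energy_features(st, ctx, pre)
  expect_length(en, 8L)
  expect_equal(en[["amfe_premirna"]],
               en[["fe_premirna"]] / (pre[2] - pre[1] + 1) * 100)
  gc_pre <- plantmir::compute_composition(
    list(whole = substr(st$seq, pre[1], pre[2])))[[1]]
  expect_equal(en[["mfei_premirna"]], en[["amfe_premirna"]] / gc_pre)

  # all-unpaired precursor: zero energies
  open <- secondary_structure(strrep("A", 40), rep(0L, 40))
  ctx_open <- list(main_branch = c(NA_integer_, NA_integer_))
  en0 <- compute_energy_features(open, ctx_open, c(5, 30))
  expect_equal(unname(en0[c("fe_whole", "fe_premirna", "mfei_premirna")]),
               c(0, 0, 0))
})

test_that("unqualified candidates are refused", {
  hp <- make_hairpin(21L, seed = 94)
  st <- hp$structure
  loop_span <- c(hp$truth$mir_span[2] + 2, hp$truth$star_span[1] - 2)
  ctx <- locate_hit(st, loop_span)
  stats <- duplex_stats(st, hp$truth$mir_span, hp$truth$star_span)
  expect_error(extract_features(st, ctx, stats),
               class = "plantmir_contract_error")
  v <- disqualify(st, ctx)
  ctx_ok <- locate_hit(st, hp$truth$mir_span)
  expect_error(extract_features(st, ctx_ok, stats, verdict = v),
               class = "plantmir_contract_error")
})
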