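test_that("decomposition matches hand-worked examples", {
  st <- from_dot_bracket("GGGGAAAACCCC", "((((....))))")
  els <- decompose(st)
  kinds <- vapply(els, function(e) e$kind, "")
  stems <- els[kinds == "stem"]
  expect_length(stems, 1)
  expect_equal(stems[[1]]$n_pairs, 4L)
  hl <- els[kinds == "hairpin_loop"]
  expect_length(hl, 1)
  expect_equal(hl[[1]]$unpaired, 5:8)

  st2 <- from_dot_bracket("GGAAGGGAAACCCCC", "((..((...))))..")
  els2 <- decompose(st2)
  kinds2 <- vapply(els2, function(e) e$kind, "")
  expect_equal(sum(kinds2 == "stem"), 2)
  expect_equal(sum(kinds2 == "bulge"), 1)
  expect_equal(sum(kinds2 == "hairpin_loop"), 1)
  bu <- els2[kinds2 == "bulge"][[1]]
  expect_equal(length(bu$unpaired), 2L)
})

test_that("decomposition partitions positions and matches a brute-force scan", {
  structs <- random_structures(60, L = 40, seed = 202)
  for (st in structs) {
    els <- decompose(st)
    pos <- sort(unlist(lapply(els, function(e) e$positions)))
    expect_equal(pos, seq_len(nchar(st$seq))) # exact partition
    expect_equal(impl_position_kinds(st), oracle_position_kinds(st$pairs))
  }
})

test_that("hit location assigns arms, loop and crossing correctly", {
  hp <- make_hairpin(21L, seed = 31)
  tr <- hp$truth
  ctx5 <- locate_hit(hp$structure, tr$mir_span)
  expect_equal(ctx5$arm, "5p")
  expect_equal(ctx5$terminal_structure_count, 1L)
  ctx3 <- locate_hit(hp$structure, tr$star_span)
  expect_equal(ctx3$arm, "3p")

  # fully unpaired hit inside the terminal loop
  loop_pos <- (tr$mir_span[2] + 1):(tr$star_span[1] - 1)
  ctxl <- locate_hit(hp$structure, range(loop_pos) + c(2, -2))
  expect_equal(ctxl$arm, "loop")

  # straddling the loop apex
  ctxc <- locate_hit(hp$structure, c(tr$mir_span[2] - 4, tr$star_span[1] + 4))
  expect_equal(ctxc$arm, "crossing")
  expect_error(locate_hit(hp$structure, c(0, 10)),
               class = "plantmir_argument_error")
})

test_that("disqualification flags the six structural defects", {
  hp <- make_hairpin(21L, seed = 32)
  tr <- hp$truth
  clean <- disqualify(hp$structure, locate_hit(hp$structure, tr$mir_span))
  expect_true(clean$accepted)

  loop_span <- c(tr$mir_span[2] + 2, tr$star_span[1] - 2)
  vl <- disqualify(hp$structure, locate_hit(hp$structure, loop_span))
  expect_false(vl$accepted)
  expect_true("i_no_stem" %in% vl$violated)
  expect_equal(vl$stage, "disqualification")

  cross_span <- c(tr$mir_span[2] - 4, tr$star_span[1] + 4)
  vc <- disqualify(hp$structure, locate_hit(hp$structure, cross_span))
  expect_true("vi_crossing_loop" %in% vc$violated)

  # a two-hairpin (branched) structure: hit spanning the multiloop
  db <- "..((..((((....))))..((((....))))..)).."
  sq <- "AAGGAAGGGGAAAACCCCAAGGGGAAAACCCCAACCAA"
  st2 <- from_dot_bracket(sq, db)
  vb <- disqualify(st2, locate_hit(st2, c(5, 34)))
  expect_false(vb$accepted)
  expect_true("iv_inner_branches" %in% vb$violated)
  # hit whose partners straddle two helices: complementary side is branched
  vob <- disqualify(st2, locate_hit(st2, c(3, 10)))
  expect_false(vob$accepted)
  expect_true("v_branched_complement" %in% vob$violated)
})

test_that("primary filter tolerates at most three terminal structures", {
  # chain of hairpins hanging off one branch: hit on the outer stem
  mk <- function(n_hairpins) {
    inner <- paste(rep("((((....))))", n_hairpins), collapse = "..")
    db <- paste0("((((((((..", inner, "..))))))))")
    # build a sequence consistent with the brackets
    b <- strsplit(db, "")[[1]]
    out <- character(length(b))
    stack <- integer(0)
    for (i in seq_along(b)) {
      if (b[i] == "(") { stack <- c(stack, i); out[i] <- "G" }
      else if (b[i] == ")") { out[i] <- "C"; stack <- stack[-length(stack)] }
      else out[i] <- "A"
    }
    st <- from_dot_bracket(paste(out, collapse = ""), db)
    ctx <- locate_hit(st, c(1, 8))
    disqualify(st, ctx)
  }
  expect_true(mk(1)$accepted)
  expect_true(mk(3)$accepted)
  v4 <- mk(4)
  expect_false(v4$accepted)
  expect_true("pf_terminal_structures" %in% v4$violated)
  expect_equal(v4$stage, "primary_filter")
})

test_that("star inference applies the two-nucleotide overhang geometry", {
  for (sd in 1:10) {
    arm <- if (sd %% 2 == 0) "5p" else "3p"
    hp <- make_hairpin(21L, hairpin_params(arm = arm), seed = 400 + sd)
    star <- infer_star(hp$structure, hp$truth$mir_span)
    expect_equal(star, hp$truth$star_span)
  }
  # involution on a perfect duplex
  hp <- make_hairpin(21L, seed = 41)
  star <- infer_star(hp$structure, hp$truth$mir_span)
  back <- infer_star(hp$structure, star)
  expect_equal(back, hp$truth$mir_span)
  # all-unpaired mature
  open <- secondary_structure(strrep("A", 30), rep(0L, 30))
  expect_error(infer_star(open, c(5, 25)),
               class = "plantmir_argument_error")
})

test_that("duplex statistics recover planted generator truth", {
  set.seed(77)
  n_cases <- 0
  for (i in 1:500) {
    arm <- sample(c("5p", "3p"), 1)
    m <- sample(20:24, 1)
    n_mm <- sample(0:3, 1)
    dup_len <- m - 2
    mm <- if (n_mm > 0) sort(sample(3:(dup_len - 2), n_mm)) else integer(0)
    free <- setdiff(3:(dup_len - 2), c(mm - 1, mm, mm + 1))
    bulges <- list()
    if (length(free) > 3 && runif(1) < 0.5) {
      off <- sample(free, 1)
      bulges <- list(list(off, sample(1:2, 1), sample(c("mir", "star"), 1)))
    }
    par <- hairpin_params(loop_size = sample(4:9, 1),
                          lower_stem = sample(6:14, 1),
                          mismatch_positions = mm, bulges = bulges, arm = arm)
    hp <- tryCatch(make_hairpin(m, par, seed = 7000 + i),
                   error = function(e) NULL)
    if (is.null(hp)) next
    st <- duplex_stats(hp$structure, hp$truth$mir_span, hp$truth$star_span)
    expect_equal(st$n_mismatch, hp$truth$n_mismatch)
    expect_equal(st$n_asym, hp$truth$n_asym)
    expect_equal(st$overhang_5p_side, 2L)
    expect_equal(st$overhang_3p_side, 2L)
    expect_equal(st$mir_len, m)
    expect_false(st$secondary_stem)
    expect_lte(st$n_asym, st$n_mismatch)
    n_cases <- n_cases + 1
  }
  expect_gte(n_cases, 450)
})

test_that("duplex statistics: worked examples", {
  hp0 <- make_hairpin(21L, seed = 51)
  s0 <- duplex_stats(hp0$structure, hp0$truth$mir_span, hp0$truth$star_span)
  expect_equal(s0$n_mismatch, 0L)
  expect_equal(s0$n_asym, 0L)
  expect_false(s0$secondary_stem)
  expect_equal(c(s0$overhang_5p_side, s0$overhang_3p_side), c(2L, 2L))

  hp3 <- make_hairpin(21L, hairpin_params(mismatch_positions = c(5, 9, 13)),
                      seed = 52)
  s3 <- duplex_stats(hp3$structure, hp3$truth$mir_span, hp3$truth$star_span)
  expect_equal(s3$n_mismatch, 3L)
  expect_equal(s3$n_asym, 0L)
  expect_equal(s3$mismatch_positions, c(5L, 9L, 13L))

  hpb <- make_hairpin(21L, hairpin_params(bulges = list(list(8, 2, "star"))),
                      seed = 53)
  sb <- duplex_stats(hpb$structure, hpb$truth$mir_span, hpb$truth$star_span)
  expect_equal(sb$n_asym, 2L)
  expect_equal(sb$n_mismatch, 2L)
})

test_that("rule engine enforces each of the five structural criteria", {
  base <- make_hairpin(21L, seed = 61)
  stats <- duplex_stats(base$structure, base$truth$mir_span,
                        base$truth$star_span)
  expect_true(apply_rules(stats)$accepted)

  tweak <- function(st, ...) {
    mod <- utils::modifyList(unclass(st), list(...))
    class(mod) <- "duplex_stats"
    mod
  }
  v <- apply_rules(tweak(stats, n_mismatch = 7L))
  expect_equal(v$violated, "mismatch_limit")
  v <- apply_rules(tweak(stats, n_mismatch = 4L, n_asym = 4L))
  expect_equal(v$violated, "asym_limit")
  v <- apply_rules(tweak(stats, precursor_len = 301L))
  expect_equal(v$violated, "precursor_length")
  v <- apply_rules(tweak(stats, overhang_5p_side = 0L, overhang_3p_side = 0L))
  expect_equal(v$violated, "overhang")
  v <- apply_rules(tweak(stats, secondary_stem = TRUE))
  expect_equal(v$violated, "secondary_stem")
  v <- apply_rules(tweak(stats, mir_len = 19L))
  expect_equal(v$violated, "mature_length")
  v <- apply_rules(tweak(stats, mir_len = 25L))
  expect_equal(v$violated, "mature_length")

  # positional mismatch restriction
  cfgp <- rule_config(banned_positions = 9:11)
  hp <- make_hairpin(21L, hairpin_params(mismatch_positions = 10L), seed = 62)
  sp <- duplex_stats(hp$structure, hp$truth$mir_span, hp$truth$star_span)
  vb <- apply_rules(sp, cfgp)
  expect_true("banned_positions" %in% vb$violated)
  expect_true(apply_rules(sp)$accepted) # no ban by default

  # violations accumulate rather than short-circuit
  v2 <- apply_rules(tweak(stats, n_mismatch = 9L, n_asym = 5L,
                          precursor_len = 400L))
  expect_setequal(v2$violated,
                  c("mismatch_limit", "asym_limit", "precursor_length"))
})

test_that("generator boundary hairpins flag exactly the planted violation", {
  # blunt duplex (no overhangs)
  hp0 <- make_hairpin(21L, hairpin_params(overhang_mir = 0L,
                                          overhang_star = 0L), seed = 71)
  s <- duplex_stats(hp0$structure, hp0$truth$mir_span, hp0$truth$star_span)
  v <- apply_rules(s)
  expect_false(v$accepted)
  expect_true("overhang" %in% v$violated)

  # seven mismatches
  hp7 <- make_hairpin(24L, hairpin_params(
    mismatch_positions = c(3, 5, 7, 9, 11, 13, 15)), seed = 72)
  s7 <- duplex_stats(hp7$structure, hp7$truth$mir_span, hp7$truth$star_span)
  v7 <- apply_rules(s7)
  expect_equal(v7$violated, "mismatch_limit")
})
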