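test_that("level of dissimilarity follows the defining equation", {
  expect_equal(compute_ld(list(Q = 21, Qa = 21, G = 0, M = 0)), 0L)
  expect_equal(compute_ld(list(Q = 21, Qa = 19, G = 0, M = 1)), 3L)
  expect_equal(compute_ld(list(Q = 24, Qa = 20, G = 1, M = 1)), 6L)
})

test_that("internal aligner finds planted hits on both strands", {
  set.seed(42)
  subj <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                collapse = "")
  q <- "ACGTGCATGCGTAGCTAGCTA"
  substr(subj, 1001, 1021) <- q
  hits <- find_hits(list(seq_record("q", q)),
                    list(seq_record("s", subj)), engine = "internal")
  top <- hits[hits$ld == 0, ]
  expect_gte(nrow(top), 1)
  expect_equal(top$start[1], 1000L)
  expect_equal(top$end[1], 1021L)
  expect_equal(top$strand[1], "+")

  subj2 <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                 collapse = "")
  rc <- chartr("ACGT", "TGCA", q)
  rc <- paste(rev(strsplit(rc, "")[[1]]), collapse = "")
  substr(subj2, 5001, 5021) <- rc
  hits2 <- find_hits(list(seq_record("q", q)),
                     list(seq_record("s", subj2)), engine = "internal")
  top2 <- hits2[hits2$ld == 0, ]
  expect_gte(nrow(top2), 1)
  expect_equal(top2$strand[1], "-")
  expect_equal(top2$start[1], 5000L)
  expect_equal(top2$end[1], 5021L)

  expect_error(find_hits(list(), list(seq_record("s", subj))),
               class = "plantmir_argument_error")
  expect_error(find_hits(list(seq_record("q", q)), list()),
               class = "plantmir_argument_error")
})

test_that("internal aligner agrees with an independent local aligner on score", {
  set.seed(7)
  for (i in 1:25) {
    q <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
               collapse = "")
    s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
    # plant a corrupted copy so a real alignment exists
    mut <- strsplit(q, "")[[1]]
    mut[sample(21, 2)] <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
    substr(s, 50, 70) <- paste(mut, collapse = "")
    hits <- find_hits(list(seq_record("q", q)), list(seq_record("s", s)),
                      align_params(evalue_report = 1e6),
                      engine = "internal")
    hits <- hits[hits$strand == "+", ]
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(s), type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 2)
    expect_equal(max(hits$score), Biostrings::score(ref))
  }
})

test_that("dissimilarity equals the brute-force recount on random alignments", {
  set.seed(99)
  n_checked <- 0
  for (i in 1:200) {
    q <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
               collapse = "")
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
    mut <- strsplit(q, "")[[1]]
    k <- sample(0:4, 1)
    if (k > 0) mut[sample(21, k)] <- sample(c("A", "C", "G", "T"), k,
                                            replace = TRUE)
    at <- sample(1:(200 - 21), 1)
    substr(s, at, at + 20) <- paste(mut, collapse = "")
    hits <- find_hits(list(seq_record("q", q)), list(seq_record("s", s)),
                      align_params(evalue_report = 1e6),
                      engine = "internal")
    for (j in seq_len(nrow(hits))) {
      expect_equal(hits$ld[j],
                   oracle_ld(hits$qaln[j], hits$saln[j], hits$Q[j]))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 200)
})

test_that("hit selection modes implement their bands", {
  hits <- tibble::tibble(
    query_id = "q", Q = 21L, Qa = c(21L, 19L, 16L, 15L, 14L),
    G = 0L, M = c(0L, 1L, 0L, 0L, 0L), score = 20L,
    evalue = 1e-5, seq_id = "s", start = 0L, end = 21L, strand = "+",
    qstart = 1L, qend = 21L, qaln = "x", saln = "x",
    ld = c(0L, 3L, 5L, 6L, 7L))
  expect_equal(select_hits(hits, "decoy")$ld, c(5L, 6L))
  expect_equal(select_hits(hits, "prediction")$ld, c(0L, 3L))
  expect_equal(select_hits(hits, "positive")$ld, 0L)
  # evalue gate in decoy mode
  hits$evalue <- c(1e-5, 1e-5, 0.1, 1e-5, 1e-5)
  expect_equal(select_hits(hits, "decoy")$ld, 6L)
  expect_equal(nrow(select_hits(hits[0, ], "decoy")), 0)
  expect_error(select_hits(hits, "bogus"),
               class = "plantmir_argument_error")
  # selection is a subset and idempotent
  sel <- select_hits(hits, "prediction")
  expect_true(all(sel$ld %in% hits$ld))
  expect_equal(select_hits(sel, "prediction"), sel)
})

test_that("window extraction respects flanks, clipping and strand", {
  set.seed(1)
  subj <- list(seq_record("s", paste(sample(c("A", "C", "G", "T"), 10000,
                                            replace = TRUE), collapse = "")))
  hit <- tibble::tibble(query_id = "q", seq_id = "s", start = 1000L,
                        end = 1021L, strand = "+")
  w <- extract_window(hit, subj, 200L)
  expect_equal(c(w$interval$start, w$interval$end), c(800L, 1221L))
  expect_equal(nchar(w$seq), 421L)
  expect_equal(substr(w$seq, w$hit_start, w$hit_end),
               substr(subj[[1]]$seq, 1001, 1021))

  hit2 <- tibble::tibble(query_id = "q", seq_id = "s", start = 5L,
                         end = 26L, strand = "+")
  w2 <- extract_window(hit2, subj, 200L)
  expect_equal(c(w2$interval$start, w2$interval$end), c(0L, 226L))

  w3 <- extract_window(hit, subj, 20L)
  expect_equal(nchar(w3$seq), 61L)

  # minus-strand window reads the hit 5'->3'
  hm <- tibble::tibble(query_id = "q", seq_id = "s", start = 1000L,
                       end = 1021L, strand = "-")
  wm <- extract_window(hm, subj, 20L)
  seg <- substr(subj[[1]]$seq, 1001, 1021)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seg), "")[[1]]),
              collapse = "")
  expect_equal(substr(wm$seq, wm$hit_start, wm$hit_end), rc)
})

test_that("greedy clustering removes redundancy at the identity threshold", {
  a <- seq_record("a", "ACGTACGTACGTACGTACGTA")
  b <- seq_record("b", "ACGTACGTACGTACGTACGTA")
  expect_length(cluster_representatives(list(a, b), 0.9), 1)

  c1 <- seq_record("c", "ACGTACGTACGTACGTACGTA")
  d1 <- seq_record("d", "GGGGGGGGGGCCCCCCCCCCC")
  expect_length(cluster_representatives(list(c1, d1), 0.9), 2)

  # 1-mismatch 21-nt variant: identity 20/21 ~ 0.952 >= 0.90
  e1 <- seq_record("e", "ACGTACGTACGTACGTACGTA")
  f1 <- seq_record("f", "ACGTACGTACCTACGTACGTA")
  expect_length(cluster_representatives(list(e1, f1), 0.90), 1)
  expect_error(cluster_representatives(list(a), 0.5),
               class = "plantmir_argument_error")
})

test_that("blast adapter agrees with the internal engine on planted truth", {
  skip_if(!nzchar(Sys.which("blastn")), "blastn not on PATH")
  set.seed(5)
  subj <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                collapse = "")
  q <- "TACGGATTCAGCTACGGAACT"
  substr(subj, 7001, 7021) <- q
  qs <- list(seq_record("q", q)); ss <- list(seq_record("s", subj))
  hi <- find_hits(qs, ss, engine = "internal")
  hb <- find_hits(qs, ss, engine = "blast")
  ti <- hi[hi$ld == 0, ]; tb <- hb[hb$ld == 0, ]
  expect_gte(nrow(tb), 1)
  expect_equal(tb$start[1], ti$start[1])
  expect_equal(tb$end[1], ti$end[1])
  expect_equal(tb$strand[1], ti$strand[1])
})
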