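# Compilation of positive (genuine pre-miRNA) and negative (decoy) feature
# datasets from a genome, a miRNA reference set, a protein set and an
# rRNA/tRNA set.

#' Dataset-builder configuration
#'
#' @param flank Flank per side for positive windows (20 nt).
#' @param identity Redundancy-removal identity threshold.
#' @param coding_evalue_max Translated-search flagging threshold.
#' @param rfam_identity,rfam_coverage rRNA/tRNA filter thresholds.
#' @param fold_engine Engine passed to [fold_all()].
#' @param align_engine Engine passed to [find_hits()].
#' @param align [align_params()].
#' @param rules [rule_config()].
#' @param matures Optional list of mature `seq_record`s used to anchor the
#'   mature span inside positive windows (exact substring match).
#' @param decoy_evalue_max,ld_min,ld_max Decoy selection band.
#' @param max_structures Structures retained per window.
#' @param seed Seed for decoy window lengths and subsampling.
#' @return A configuration list.
#' @export
build_config <- function(flank = 20L, identity = 0.9,
                         coding_evalue_max = 0.001, rfam_identity = 0.85,
                         rfam_coverage = 0.8, fold_engine = "auto",
                         align_engine = "internal", align = align_params(),
                         rules = rule_config(), matures = NULL,
                         decoy_evalue_max = 0.001, ld_min = 5L, ld_max = 6L,
                         max_structures = 5L, seed = 1L) {
  list(flank = as.integer(flank), identity = identity,
       coding_evalue_max = coding_evalue_max, rfam_identity = rfam_identity,
       rfam_coverage = rfam_coverage, fold_engine = fold_engine,
       align_engine = align_engine, align = align, rules = rules,
       matures = matures, decoy_evalue_max = decoy_evalue_max,
       ld_min = as.integer(ld_min), ld_max = as.integer(ld_max),
       max_structures = as.integer(max_structures), seed = as.integer(seed))
}

# exact-substring mature anchoring, falling back to the best-paired 21-mer
# within the hit region
locate_mature_span <- function(window, struct, matures) {
  wdna <- to_dna(window$seq)
  if (!is.null(matures)) {
    for (m in matures) {
      at <- regexpr(to_dna(m$seq), wdna, fixed = TRUE)[1]
      if (at > 0) return(c(at, at + nchar(m$seq) - 1L))
    }
  }
  p <- struct$pairs
  hs <- window$hit_start; he <- window$hit_end
  k <- 21L
  if (he - hs + 1L <= k) return(c(hs, he))
  best <- hs; best_n <- -1L
  for (s in hs:(he - k + 1L)) {
    n <- sum(p[s:(s + k - 1L)] != 0L)
    if (n > best_n) { best_n <- n; best <- s }
  }
  c(best, best + k - 1L)
}

window_id <- function(w) sprintf("%s:%d-%d(%s)", w$interval$seq_id,
                                 w$interval$start, w$interval$end,
                                 w$interval$strand)

# fold + qualify + featurize one window; returns a list of feature rows
qualify_and_featurize <- function(w, config, label, hit_meta = NULL) {
  structs <- tryCatch(fold_all(w$seq, config$fold_engine),
                      error = function(e) list())
  if (length(structs) > config$max_structures)
    structs <- structs[seq_len(config$max_structures)]
  rows <- list()
  for (si in seq_along(structs)) {
    st <- structs[[si]]
    mir_span <- locate_mature_span(w, st, config$matures)
    ctx <- locate_hit(st, mir_span)
    v <- disqualify(st, ctx, config$rules)
    if (!v$accepted) next
    star <- tryCatch(infer_star(st, mir_span), error = function(e) NULL)
    if (is.null(star)) next
    stats <- tryCatch(duplex_stats(st, mir_span, star, config$rules),
                      error = function(e) NULL)
    if (is.null(stats)) next
    feats <- extract_features(
      st, ctx, stats,
      query_meta = hit_meta %||% list(),
      genomic_meta = list(window = w$interval,
                          hit_start_in_window = w$hit_start,
                          n_structures = length(structs)),
      verdict = v)
    meta <- tibble(window_id = window_id(w), seq_id = w$interval$seq_id,
                   genome_start = w$interval$start,
                   genome_end = w$interval$end,
                   strand = w$interval$strand, structure_index = si,
                   label = label)
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(meta, feats)
  }
  rows
}

#' Compile a positive (genuine pre-miRNA) feature dataset
#'
#' Perfect full-length stem-loop matches are windowed with 20-nt flanks,
#' deduplicated, screened against the protein and rRNA/tRNA sets, folded,
#' qualified by the structural disqualification rules and featurized. A
#' pre-miRNA may contribute several rows (one per surviving structure).
#'
#' @param stemloops Reference stem-loop `seq_record`s (queries).
#' @param genome Subject `seq_record`s.
#' @param protein_db Protein `seq_record`s.
#' @param rfam rRNA/tRNA `seq_record`s.
#' @param config A [build_config()].
#' @return A tibble: metadata columns, `label = 1`, and the 170 features.
#' @export
build_positive <- function(stemloops, genome, protein_db, rfam,
                           config = build_config()) {
  if (length(stemloops) == 0L) abort_argument("empty stem-loop set")
  hits <- find_hits(stemloops, genome, config$align, config$align_engine)
  sel <- select_hits(hits, "positive")
  wins <- lapply(seq_len(nrow(sel)), function(i)
    extract_window(sel[i, ], genome, config$flank))
  if (length(wins)) {
    recs <- lapply(seq_along(wins), function(i)
      seq_record(paste0("w", i), wins[[i]]$seq))
    reps <- cluster_representatives(recs, config$identity)
    keep <- as.integer(sub("^w", "", vapply(reps, function(r) r$id, "")))
    wins <- wins[sort(keep)]
    sel <- sel[sort(keep), , drop = FALSE]
  }
  keep_ids <- vapply(wins, window_id, "")
  wins2 <- coding_overlap_filter(wins, protein_db, "drop_coding",
                                 config$coding_evalue_max)
  wins2 <- rna_family_filter(wins2, rfam, config$rfam_identity,
                             config$rfam_coverage)
  rows <- list()
  for (w in wins2) {
    i <- match(window_id(w), keep_ids)
    hm <- list(query_length = sel$Q[i], ld = sel$ld[i],
               evalue = sel$evalue[i], alignment_length = sel$Qa[i])
    rows <- c(rows, qualify_and_featurize(w, config, 1L, hm))
  }
  if (!length(rows)) {
    warn("no qualified positive structures survived")
    return(tibble())
  }
  dplyr::bind_rows(rows)
}

extract_window_asym <- function(hit, subjects, left, right) {
  subj <- NULL
  for (s in subjects) if (s$id == hit$seq_id) { subj <- s; break }
  L <- nchar(subj$seq)
  if (hit$strand == "+") {
    w0 <- max(0L, hit$start - left); w1 <- min(L, hit$end + right)
  } else {
    w0 <- max(0L, hit$start - right); w1 <- min(L, hit$end + left)
  }
  seq <- substr(subj$seq, w0 + 1L, w1)
  if (hit$strand == "+") {
    hs <- hit$start - w0 + 1L; he <- hit$end - w0
  } else {
    seq <- revcomp_chr(seq); hs <- w1 - hit$end + 1L; he <- w1 - hit$start
  }
  structure(list(interval = interval(hit$seq_id, w0, w1, hit$strand),
                 seq = seq, hit_start = as.integer(hs),
                 hit_end = as.integer(he), flank = NA_integer_,
                 query_id = hit$query_id), class = "pm_window")
}

#' Compile a negative (decoy) feature dataset
#'
#' Hits in the dissimilarity band (`evalue <= 0.001`, `5 <= LD <= 6`) are
#' extended to window lengths drawn from the empirical positive length
#' distribution, restricted to windows overlapping protein-coding sequence,
#' folded, qualified by the same disqualification rules, featurized, and
#' finally subsampled (seeded, without replacement) to the positive count.
#'
#' @param mature_mirnas Mature miRNA `seq_record`s (queries).
#' @param genome Subject `seq_record`s.
#' @param protein_db Protein `seq_record`s.
#' @param positive_lengths Window lengths of the positive dataset (the
#'   target count and length distribution).
#' @param config A [build_config()].
#' @return A tibble like [build_positive()]'s, with `label = 0`.
#' @export
build_negative <- function(mature_mirnas, genome, protein_db,
                           positive_lengths, config = build_config()) {
  if (length(positive_lengths) == 0L)
    abort_argument("positive_lengths must be non-empty")
  set.seed(config$seed)
  hits <- find_hits(mature_mirnas, genome, config$align, config$align_engine)
  sel <- select_hits(hits, "decoy", list(
    decoy_evalue_max = config$decoy_evalue_max,
    ld_min = config$ld_min, ld_max = config$ld_max))
  rows <- list()
  for (i in seq_len(nrow(sel))) {
    hit <- sel[i, ]
    hl <- hit$end - hit$start
    target <- sample(positive_lengths, 1L)
    extra <- max(0L, as.integer(target) - hl)
    left <- sample.int(extra + 1L, 1L) - 1L
    w <- extract_window_asym(hit, genome, left, extra - left)
    wf <- coding_overlap_filter(list(w), protein_db, "keep_coding",
                                config$coding_evalue_max)
    if (!length(wf)) next
    hm <- list(query_length = hit$Q, ld = hit$ld, evalue = hit$evalue,
               alignment_length = hit$Qa)
    rows <- c(rows, qualify_and_featurize(wf[[1]], config, 0L, hm))
  }
  if (!length(rows)) {
    warn("no qualified decoy structures survived")
    return(tibble())
  }
  out <- dplyr::bind_rows(rows)
  n_target <- length(positive_lengths)
  if (nrow(out) > n_target) {
    out <- out[sort(sample.int(nrow(out), n_target)), , drop = FALSE]
  } else if (nrow(out) < n_target) {
    warn(sprintf("only %d qualified decoys for %d requested", nrow(out),
                 n_target))
  }
  out
}

#' Names of the 170 feature columns
#' @return Character vector in schema order.
#' @export
feature_cols <- function() feature_schema()$name
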