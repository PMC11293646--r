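#' Level of dissimilarity of an alignment hit
#'
#' `LD = Q - Qa + G + M`: query length minus the aligned query span, plus
#' total gaps and mismatches — equivalently, unaligned query nucleotides
#' plus gap and mismatch columns of the alignment. Zero for a perfect
#' full-length match; it grows with unaligned query ends, indels and
#' substitutions alike.
#'
#' @param hit A one-row hit tibble or list with fields `Q`, `Qa`, `G`, `M`.
#' @return Integer LD.
#' @export
compute_ld <- function(hit) {
  as.integer(hit$Q - hit$Qa + hit$G + hit$M)
}

#' Default scoring for the built-in exhaustive aligner
#'
#' BLASTn-like defaults: match +1, mismatch -2, gap open -5, gap extend -2,
#' with an ungapped Karlin-Altschul expectation `E = K * m * n * exp(-lambda*S)`
#' (lambda = 1.28, K = 0.46 for the +1/-2 system). All overridable.
#'
#' @param match,mismatch,gap_open,gap_ext Alignment scores (penalties as
#'   positive costs).
#' @param lambda,K Karlin-Altschul parameters for the expectation value.
#' @param evalue_report Hits with `E` above this are not reported.
#' @param max_hits_per_strand Greedy masking iterations per query/strand.
#' @return A named list of aligner parameters.
#' @export
align_params <- function(match = 1L, mismatch = 2L, gap_open = 5L,
                         gap_ext = 2L, lambda = 1.28, K = 0.46,
                         evalue_report = 10, max_hits_per_strand = 16L) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext, lambda = lambda, K = K,
       evalue_report = evalue_report,
       max_hits_per_strand = max_hits_per_strand)
}

ka_evalue <- function(score, m, n, params) {
  params$K * m * n * exp(-params$lambda * score)
}

min_score_for_evalue <- function(evalue, m, n, params) {
  s <- ceiling(log(params$K * m * n / evalue) / params$lambda)
  max(as.integer(s), params$match * 8L) # never chase sub-8-nt seeds
}

#' Find homologs of reference miRNAs in subject sequences
#'
#' Aligns each (short) query against both strands of every subject. Two
#' backends: the built-in exhaustive local aligner (`engine = "internal"`,
#' the default; deterministic, affine-gap Smith-Waterman recovering multiple
#' hits by greedy masking) and an external BLASTn adapter
#' (`engine = "blast"`). `engine = "auto"` uses BLASTn when `blastn` is on
#' the PATH and otherwise falls back to the internal aligner with a notice.
#'
#' @param queries List of `seq_record` (mature ~18-30 nt, or stem-loops).
#' @param subjects List of `seq_record` (genome/transcriptome).
#' @param params [align_params()].
#' @param engine `"internal"`, `"blast"` or `"auto"`.
#' @return A tibble of hits: `query_id`, `Q`, `Qa`, `G`, `M`, `ld`, `score`,
#'   `evalue`, `seq_id`, `start`, `end` (0-based half-open on the plus
#'   strand), `strand`, `qstart`, `qend` (1-based inclusive on the query),
#'   `qaln`, `saln` (the alignment trace, internal engine only).
#' @export
find_hits <- function(queries, subjects, params = align_params(),
                      engine = c("internal", "blast", "auto")) {
  engine <- match.arg(engine)
  if (length(queries) == 0L) abort_argument("empty query set")
  if (length(subjects) == 0L) abort_argument("empty subject set")
  if (engine == "auto") {
    engine <- if (nzchar(Sys.which("blastn"))) "blast" else {
      inform("blastn not found on PATH; using the built-in exhaustive aligner")
      "internal"
    }
  }
  hits <- if (engine == "blast") find_hits_blast(queries, subjects, params)
          else find_hits_internal(queries, subjects, params)
  hits[order(hits$query_id, hits$seq_id, hits$start), , drop = FALSE]
}

find_hits_internal <- function(queries, subjects, params) {
  total_n <- sum(vapply(subjects, function(s) nchar(s$seq), 1L)) * 2
  rows <- list()
  for (q in queries) {
    qs <- to_dna(q$seq)
    min_s <- min_score_for_evalue(params$evalue_report, nchar(qs), total_n,
                                  params)
    for (s in subjects) {
      ss <- to_dna(s$seq)
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") ss else revcomp_chr(ss)
        df <- .sw_align_all(qs, subj, params$match, params$mismatch,
                            params$gap_open, params$gap_ext,
                            min_s, params$max_hits_per_strand)
        if (nrow(df) == 0L) next
        L <- nchar(ss)
        # map minus-strand coordinates back to the plus strand
        start0 <- if (strand == "+") df$sstart - 1L else L - df$send
        end0 <- if (strand == "+") df$send else L - df$sstart + 1L
        Qa <- df$qend - df$qstart + 1L # aligned query span
        rows[[length(rows) + 1L]] <- tibble(
          query_id = q$id, Q = nchar(qs), Qa = as.integer(Qa),
          G = as.integer(df$gaps), M = as.integer(df$mismatches),
          score = as.integer(df$score),
          evalue = ka_evalue(df$score, nchar(qs), total_n, params),
          seq_id = s$id, start = as.integer(start0), end = as.integer(end0),
          strand = strand, qstart = as.integer(df$qstart),
          qend = as.integer(df$qend), qaln = df$qaln, saln = df$saln)
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_hits()
  out$ld <- compute_ld(out)
  out[out$evalue <= params$evalue_report, , drop = FALSE]
}

empty_hits <- function() {
  tibble(query_id = character(), Q = integer(), Qa = integer(),
         G = integer(), M = integer(), score = integer(), evalue = double(),
         seq_id = character(), start = integer(), end = integer(),
         strand = character(), qstart = integer(), qend = integer(),
         qaln = character(), saln = character())
}

find_hits_blast <- function(queries, subjects, params) {
  if (!nzchar(Sys.which("blastn")) || !nzchar(Sys.which("makeblastdb"))) {
    inform("blastn/makeblastdb not available; falling back to internal aligner")
    return(find_hits_internal(queries, subjects, params))
  }
  td <- tempfile("blastdb")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  dbf <- file.path(td, "subjects.fa")
  qf <- file.path(td, "queries.fa")
  write_fasta(lapply(subjects, function(s)
    seq_record(s$id, to_dna(s$seq))), dbf)
  write_fasta(lapply(queries, function(q)
    seq_record(q$id, to_dna(q$seq))), qf)
  system2("makeblastdb", c("-in", dbf, "-dbtype", "nucl"),
          stdout = FALSE, stderr = FALSE)
  outf <- file.path(td, "hits.tsv")
  system2("blastn", c("-task", "blastn-short", "-query", qf, "-db", dbf,
                      "-word_size", "7", "-evalue",
                      format(params$evalue_report, scientific = FALSE),
                      "-outfmt",
                      shQuote(paste("6 qseqid sseqid length mismatch gapopen",
                                    "gaps qstart qend sstart send evalue",
                                    "bitscore")),
                      "-out", outf), stdout = FALSE, stderr = FALSE)
  if (!file.exists(outf) || file.info(outf)$size == 0) return(empty_hits())
  tb <- read.table(outf, sep = "\t", stringsAsFactors = FALSE)
  names(tb) <- c("query_id", "seq_id", "len", "mismatch", "gapopen", "gaps",
                 "qstart", "qend", "sstart", "send", "evalue", "bits")
  qlen <- setNames(vapply(queries, function(q) nchar(q$seq), 1L),
                   vapply(queries, function(q) q$id, ""))
  strand <- ifelse(tb$send >= tb$sstart, "+", "-")
  s1 <- pmin(tb$sstart, tb$send); s2 <- pmax(tb$sstart, tb$send)
  out <- tibble(
    query_id = tb$query_id, Q = as.integer(qlen[tb$query_id]),
    Qa = as.integer(tb$qend - tb$qstart + 1L), G = as.integer(tb$gaps),
    M = as.integer(tb$mismatch), score = as.integer(round(tb$bits)),
    evalue = tb$evalue, seq_id = tb$seq_id,
    start = as.integer(s1 - 1L), end = as.integer(s2),
    strand = strand, qstart = as.integer(tb$qstart),
    qend = as.integer(tb$qend), qaln = NA_character_, saln = NA_character_)
  out$ld <- compute_ld(out)
  out
}

#' Select hits by pipeline mode
#'
#' * `positive`: perfect full-length matches only (`LD = 0`, no gaps or
#'   mismatches), the criterion for compiling positive datasets.
#' * `decoy`: `evalue <= 0.001` and `5 <= LD <= 6` — close enough to fold
#'   like a precursor, dissimilar enough to not be a functional miRNA.
#' * `prediction`: `evalue <= evalue_max` and `LD <= ld_max` (default 3).
#'
#' @param hits Hit tibble from [find_hits()].
#' @param mode `"positive"`, `"decoy"` or `"prediction"`.
#' @param config List with `evalue_max` and `ld_max` overrides.
#' @return The selected subset of `hits` (a tibble).
#' @export
select_hits <- function(hits, mode = c("prediction", "positive", "decoy"),
                        config = list()) {
  if (is.character(mode) && length(mode) == 1L &&
      !mode %in% c("prediction", "positive", "decoy"))
    abort_argument(paste0("unknown hit-selection mode: ", mode))
  mode <- match.arg(mode)
  if (nrow(hits) == 0L) return(hits)
  keep <- switch(mode,
    positive = hits$ld == 0L & hits$Qa == hits$Q & hits$G == 0L & hits$M == 0L,
    decoy = hits$evalue <= (config$decoy_evalue_max %||% 0.001) &
      hits$ld >= (config$ld_min %||% 5L) & hits$ld <= (config$ld_max %||% 6L),
    prediction = hits$evalue <= (config$evalue_max %||% 0.001) &
      hits$ld <= (config$ld_max %||% 3L))
  hits[keep, , drop = FALSE]
}

#' Extract a flanked genomic window around a hit
#'
#' The window is the hit extended by `flank` nt on each side, clipped at the
#' sequence boundaries. Minus-strand windows are reverse-complemented so the
#' hit reads 5' to 3'.
#'
#' @param hit One row of a hit tibble (or an equivalent list).
#' @param subjects The subject records the hit refers to.
#' @param flank Flank size per side in nt (200 for prediction, 20 for
#'   positive-dataset compilation).
#' @return A `pm_window` object: fields `interval`, `seq`, `hit_start`,
#'   `hit_end` (1-based inclusive within the window), `flank`, `query_id`.
#' @export
extract_window <- function(hit, subjects, flank = 200L) {
  subj <- NULL
  for (s in subjects) if (s$id == hit$seq_id) { subj <- s; break }
  if (is.null(subj)) abort_argument(paste0("hit subject not found: ", hit$seq_id))
  L <- nchar(subj$seq)
  w0 <- max(0L, hit$start - flank)
  w1 <- min(L, hit$end + flank)
  seq <- substr(subj$seq, w0 + 1L, w1)
  if (hit$strand == "+") {
    hs <- hit$start - w0 + 1L
    he <- hit$end - w0
  } else {
    seq <- revcomp_chr(seq)
    hs <- w1 - hit$end + 1L
    he <- w1 - hit$start
  }
  structure(list(interval = interval(hit$seq_id, w0, w1, hit$strand),
                 seq = seq, hit_start = as.integer(hs), hit_end = as.integer(he),
                 flank = as.integer(flank),
                 query_id = hit$query_id %||% NA_character_),
            class = "pm_window")
}

#' @export
print.pm_window <- function(x, ...) {
  cat(sprintf("<pm_window> %s:%d-%d(%s), %d nt, hit at %d-%d\n",
              x$interval$seq_id, x$interval$start, x$interval$end,
              x$interval$strand, nchar(x$seq), x$hit_start, x$hit_end))
  invisible(x)
}

#' Greedy longest-first redundancy removal
#'
#' CD-HIT-style clustering: records sorted by decreasing length (ties broken
#' by lexicographic id), each record joins the first existing representative
#' it matches at `>= identity_threshold`, otherwise founds a new cluster.
#' Identity is matches / alignment length of the global alignment of the
#' shorter sequence onto the longer.
#'
#' @param records List of `seq_record`s.
#' @param identity_threshold In (0.8, 1].
#' @return The cluster representatives, a list of `seq_record`s.
#' @export
cluster_representatives <- function(records, identity_threshold = 0.9) {
  if (identity_threshold <= 0.8 || identity_threshold > 1)
    abort_argument("identity_threshold must lie in (0.8, 1]")
  if (length(records) <= 1L) return(records)
  lens <- vapply(records, function(r) nchar(r$seq), 1L)
  ids <- vapply(records, function(r) r$id, "")
  ord <- order(-lens, ids)
  reps <- list()
  for (i in ord) {
    r <- records[[i]]
    joined <- FALSE
    for (rep in reps) {
      if (pair_identity(r$seq, rep$seq) >= identity_threshold) {
        joined <- TRUE
        break
      }
    }
    if (!joined) reps[[length(reps) + 1L]] <- r
  }
  reps
}

# identity of the global alignment of the shorter onto the longer
pair_identity <- function(a, b) {
  a <- to_dna(a); b <- to_dna(b)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
  Biostrings::nmatch(al) / Biostrings::nchar(al)
}
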