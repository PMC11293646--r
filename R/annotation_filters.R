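#' Flag or drop windows that overlap protein-coding sequence
#'
#' Each window is translated in all six reading frames; peptides between
#' stop codons (>= `min_orf_aa`, default 20 aa — shorter internal ORFs are
#' noise) are locally aligned against the protein set, and the best
#' expectation value decides the flag. Positive-dataset compilation drops
#' flagged windows (`mode = "drop_coding"`); decoy compilation keeps only
#' flagged windows (`mode = "keep_coding"`).
#'
#' Expectation values use the gapped BLOSUM62 Karlin-Altschul constants
#' (lambda = 0.267, K = 0.041) over the total database residue count.
#'
#' @param windows List of `pm_window`s.
#' @param protein_db List of `seq_record`s (amino-acid alphabet).
#' @param mode `"drop_coding"` or `"keep_coding"`.
#' @param evalue_max Flagging threshold (default 0.001).
#' @param min_orf_aa Minimum internal ORF length scored.
#' @return The filtered list of windows; the per-window decisions are
#'   attached as `attr(, "decisions")` (a tibble).
#' @export
coding_overlap_filter <- function(windows, protein_db,
                                  mode = c("drop_coding", "keep_coding"),
                                  evalue_max = 0.001, min_orf_aa = 20L) {
  mode <- match.arg(mode)
  if (length(protein_db) == 0L) {
    if (mode == "keep_coding") {
      warn("empty protein database: keep_coding retains no windows")
      out <- list()
      attr(out, "decisions") <- coding_decisions(windows, rep(FALSE, length(windows)),
                                                 rep(NA_real_, length(windows)),
                                                 rep(NA_character_, length(windows)))
      return(out)
    }
    out <- windows
    attr(out, "decisions") <- coding_decisions(windows, rep(FALSE, length(windows)),
                                               rep(NA_real_, length(windows)),
                                               rep(NA_character_, length(windows)))
    return(out)
  }
  db_n <- sum(vapply(protein_db, function(p) nchar(p$seq), 1L))
  best_e <- rep(NA_real_, length(windows))
  best_id <- rep(NA_character_, length(windows))
  # pool peptides across windows: one vectorised alignment per db protein
  pep_of <- lapply(windows, function(w) six_frame_peptides(w$seq, min_orf_aa))
  owner <- rep(seq_along(windows), lengths(pep_of))
  peps <- unlist(pep_of, use.names = FALSE)
  if (length(peps)) {
    pat <- Biostrings::AAStringSet(peps)
    plen <- nchar(peps)
    for (k in seq_along(protein_db)) {
      sc <- Biostrings::pairwiseAlignment(
        pat, Biostrings::AAString(protein_db[[k]]$seq), type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
        scoreOnly = TRUE)
      e <- protein_evalue(sc, plen, db_n)
      for (i in unique(owner)) {
        emin <- suppressWarnings(min(e[owner == i]))
        if (is.finite(emin) && (is.na(best_e[i]) || emin < best_e[i])) {
          best_e[i] <- emin
          best_id[i] <- protein_db[[k]]$id
        }
      }
    }
  }
  flagged <- !is.na(best_e) & best_e <= evalue_max
  keep <- if (mode == "drop_coding") !flagged else flagged
  out <- windows[keep]
  attr(out, "decisions") <- coding_decisions(windows, flagged, best_e, best_id)
  out
}

coding_decisions <- function(windows, flagged, best_e, best_id) {
  tibble(window = vapply(windows, function(w)
    sprintf("%s:%d-%d(%s)", w$interval$seq_id, w$interval$start,
            w$interval$end, w$interval$strand), ""),
    flagged = flagged, best_evalue = best_e, db_hit_id = best_id)
}

protein_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

# peptides (>= min_aa) between stops, all six frames
six_frame_peptides <- function(seq, min_aa = 20L) {
  dna <- to_dna(seq)
  strands <- c(dna, revcomp_chr(dna))
  peps <- character(0)
  for (s in strands) {
    for (off in 0:2) {
      sub <- substr(s, off + 1L, nchar(s))
      sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
      if (nchar(sub) < 3L * min_aa) next
      aa <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X")))
      for (p in strsplit(aa, "*", fixed = TRUE)[[1]]) {
        p <- gsub("X", "", p, fixed = TRUE)
        if (nchar(p) >= min_aa) peps <- c(peps, p)
      }
    }
  }
  peps
}

#' Remove windows resembling rRNA or tRNA family sequences
#'
#' A window is removed when it aligns locally to any family record at
#' identity >= `identity_min` over at least `coverage_min` of that record's
#' length.
#'
#' @param windows List of `pm_window`s.
#' @param rfam_records List of nucleotide `seq_record`s (rRNA/tRNA set).
#' @param identity_min Minimum alignment identity (default 0.85).
#' @param coverage_min Minimum fraction of the family record covered
#'   (default 0.8).
#' @return The retained windows.
#' @export
rna_family_filter <- function(windows, rfam_records, identity_min = 0.85,
                              coverage_min = 0.8) {
  if (length(rfam_records) == 0L || length(windows) == 0L) return(windows)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = FALSE)
  keep <- vapply(windows, function(w) {
    wseq <- Biostrings::DNAString(to_dna(w$seq))
    for (r in rfam_records) {
      rl <- nchar(r$seq)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(to_dna(r$seq)), wseq, type = "local",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
      idn <- Biostrings::nmatch(al) / max(1L, Biostrings::nchar(al))
      cov <- Biostrings::nchar(al) / rl
      if (idn >= identity_min && cov >= coverage_min) return(FALSE)
    }
    TRUE
  }, TRUE)
  windows[keep]
}
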