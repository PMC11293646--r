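#' Read a (multi-)FASTA file or string into sequence records
#'
#' Sequence records are the package's plain currency for genomic input,
#' reference miRNA sets, protein databases and rRNA/tRNA sets. Sequences are
#' upper-cased on read; the DNA/RNA alphabet of the input is preserved
#' (operations that need RNA convert on the fly). Ambiguity codes other than
#' `N` are rejected unless the record is a protein (`alphabet = "AA"`).
#'
#' @param input Path to a FASTA file, or a character scalar holding FASTA
#'   text (detected by a leading `>` before any newline content).
#' @param alphabet `"nt"` (default) validates against `A,C,G,T,U,N`;
#'   `"AA"` skips nucleotide validation (protein databases).
#' @param mask_lowercase How lowercase (soft-masked) residues are treated:
#'   `"keep"` (default) upper-cases them like any other base, `"n"` replaces
#'   them with `N` so downstream alignment ignores masked regions.
#' @return A list of `seq_record` objects (fields `id`, `description`, `seq`).
#' @export
read_fasta <- function(input, alphabet = c("nt", "AA"),
                       mask_lowercase = c("keep", "n")) {
  alphabet <- match.arg(alphabet)
  mask_lowercase <- match.arg(mask_lowercase)
  txt <- if (length(input) == 1L && grepl("^\\s*>", input)) {
    strsplit(input, "\n", fixed = TRUE)[[1]]
  } else if (length(input) == 1L && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else if (length(input) > 1L) {
    input
  } else {
    abort_format(paste0("not FASTA text and not an existing file: ", input))
  }
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) == 0L) abort_format("empty FASTA input")
  if (!startsWith(trimws(txt[[1]]), ">"))
    abort_format("malformed FASTA: first non-blank character is not '>'")
  is_hdr <- startsWith(trimws(txt), ">")
  grp <- cumsum(is_hdr)
  recs <- lapply(split(seq_along(txt), grp), function(idx) {
    hdr <- trimws(txt[[idx[1]]])
    body <- txt[idx[-1]]
    seq <- paste(gsub("\\s", "", body), collapse = "")
    if (mask_lowercase == "n") seq <- gsub("[acgtun]", "N", seq)
    seq <- toupper(seq)
    if (!nzchar(seq))
      abort_format(paste0("empty sequence under header ", hdr))
    if (alphabet == "nt" && grepl("[^ACGTUN]", seq))
      abort_format(paste0("unsupported residue code in record ", hdr,
                          " (only A,C,G,T,U,N accepted)"))
    hdr <- sub("^>", "", hdr)
    id <- sub("\\s.*$", "", hdr)
    desc <- sub("^\\S+\\s*", "", hdr)
    if (!nzchar(id)) abort_format("FASTA header with empty id")
    seq_record(id, seq, desc)
  })
  unname(recs)
}

#' Construct a sequence record
#' @param id Record identifier (non-empty).
#' @param seq Sequence string (non-empty, upper-cased).
#' @param description Free-text description (may be empty).
#' @return A `seq_record` object.
#' @export
seq_record <- function(id, seq, description = "") {
  if (!nzchar(id)) abort_argument("seq_record id must be non-empty")
  if (!nzchar(seq)) abort_argument("seq_record seq must be non-empty")
  structure(list(id = id, description = description, seq = toupper(seq)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  s <- x$seq
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("<seq_record> %s (%d nt) %s\n", x$id, nchar(x$seq), s))
  invisible(x)
}

#' Write sequence records as FASTA
#' @param records List of `seq_record`s.
#' @param path Output path; if `NULL`, the FASTA text is returned invisibly.
#' @param width Line-fold width.
#' @return The FASTA text, invisibly.
#' @export
write_fasta <- function(records, path = NULL, width = 70L) {
  lines <- as.character(unlist(lapply(records, function(r) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    body <- substring(r$seq, seq(1, nchar(r$seq), width),
                      pmin(seq(1, nchar(r$seq), width) + width - 1, nchar(r$seq)))
    c(paste0(">", hdr), body)
  })))
  if (!is.null(path)) writeLines(lines, path)
  invisible(paste0(paste(lines, collapse = "\n"), "\n"))
}

#' Genomic interval (0-based half-open, BED dialect)
#'
#' External coordinates are BED-style 0-based half-open; positions on a folded
#' sequence are 1-based inclusive (CT convention). [interval()] stores the
#' former.
#'
#' @param seq_id Name of the sequence the interval lies on.
#' @param start,end 0-based half-open bounds, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return An `interval` object.
#' @export
interval <- function(seq_id, start, end, strand = "+") {
  if (!(strand %in% c("+", "-"))) abort_argument("strand must be '+' or '-'")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    abort_argument("interval requires 0 <= start < end")
  structure(list(seq_id = seq_id, start = start, end = end, strand = strand),
            class = "interval")
}

#' Construct a secondary structure
#'
#' The pipeline's central object: an RNA sequence plus a 1-based pair table
#' (`pairs[i]` is the partner of position `i`, 0 if unpaired) and an optional
#' free energy in kcal/mol. Construction validates symmetry, irreflexivity,
#' the minimum hairpin loop of 3 nt and nestedness (no pseudoknots).
#'
#' @param seq Sequence (stored as RNA: T is converted to U).
#' @param pairs Integer vector of partners, length `nchar(seq)`.
#' @param energy Free energy in kcal/mol, or `NA`.
#' @return A `secondary_structure` object.
#' @export
secondary_structure <- function(seq, pairs, energy = NA_real_) {
  seq <- to_rna(seq)
  pairs <- as.integer(pairs)
  L <- nchar(seq)
  if (length(pairs) != L)
    abort_structure("pair table length does not match sequence length")
  idx <- which(pairs != 0L)
  if (any(pairs < 0L | pairs > L))
    abort_structure("pair partner out of range")
  if (any(pairs[idx] == idx))
    abort_structure("position paired with itself")
  if (any(pairs[pairs[idx]] != idx))
    abort_structure("pair table is not symmetric")
  if (any(abs(pairs[idx] - idx) < 4L))
    abort_structure("hairpin loop shorter than 3 nt")
  # nestedness: scan with a stack over opening positions
  opened <- integer(0)
  for (i in seq_len(L)) {
    j <- pairs[i]
    if (j > i) opened <- c(opened, j)
    else if (j != 0L && j < i) {
      if (length(opened) == 0L || opened[length(opened)] != i)
        abort_structure("pair table contains crossing (pseudoknotted) pairs")
      opened <- opened[-length(opened)]
    }
  }
  structure(list(seq = seq, pairs = pairs, energy = energy),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d pairs, energy %s\n",
              nchar(x$seq), sum(x$pairs != 0) / 2,
              if (is.na(x$energy)) "NA" else sprintf("%.2f", x$energy)))
  if (nchar(x$seq) <= 120) {
    cat(x$seq, "\n", dot_bracket(x), "\n", sep = "")
  }
  invisible(x)
}

#' Parse a CT (connectivity table) file
#'
#' Accepts the standard 6-column body with a header line carrying the length
#' and optionally the energy as `dG = x` or `ENERGY = x`.
#'
#' @param input Path to a CT file or CT text.
#' @return A [secondary_structure()].
#' @export
parse_ct <- function(input) {
  txt <- if (length(input) == 1L && !grepl("\n", input) && file.exists(input))
    readLines(input, warn = FALSE) else strsplit(paste(input, collapse = "\n"),
                                                 "\n", fixed = TRUE)[[1]]
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) < 2L) abort_format("CT input too short")
  hdr <- trimws(txt[[1]])
  L <- suppressWarnings(as.integer(sub("^(\\d+).*$", "\\1", hdr)))
  if (is.na(L)) abort_format("CT header does not start with a length")
  energy <- NA_real_
  em <- regmatches(hdr, regexpr("(dG|ENERGY)\\s*=\\s*-?[0-9.]+", hdr, ignore.case = TRUE))
  if (length(em) == 1L)
    energy <- as.numeric(sub(".*=\\s*", "", em))
  body <- txt[-1]
  if (length(body) != L)
    abort_format(sprintf("CT header claims %d rows, found %d", L, length(body)))
  f <- strsplit(trimws(body), "\\s+")
  bases <- vapply(f, function(x) x[2], "")
  partner <- vapply(f, function(x) as.integer(x[5]), 1L)
  pos <- vapply(f, function(x) as.integer(x[1]), 1L)
  if (!identical(pos, seq_len(L))) abort_format("CT rows out of order")
  idx <- which(partner != 0L)
  bad <- idx[partner[idx] > L | partner[idx] < 0L | partner[partner[idx]] != idx]
  if (length(bad))
    abort_structure(sprintf("CT partner asymmetry at position %d", bad[1]))
  secondary_structure(paste(bases, collapse = ""), partner, energy)
}

#' Write a secondary structure as CT text
#' @param structure A [secondary_structure()].
#' @param path Output path, or `NULL` to return text only.
#' @param title Title placed on the header line.
#' @return CT text, invisibly.
#' @export
write_ct <- function(structure, path = NULL, title = "structure") {
  L <- nchar(structure$seq)
  b <- strsplit(structure$seq, "")[[1]]
  hdr <- if (is.na(structure$energy)) sprintf("%d  %s", L, title) else
    sprintf("%d  dG = %.2f  %s", L, structure$energy, title)
  rows <- sprintf("%d %s %d %d %d %d", seq_len(L), b, seq_len(L) - 1L,
                  c(seq_len(L - 1) + 1L, 0L)[seq_len(L)], structure$pairs,
                  seq_len(L))
  out <- paste0(paste(c(hdr, rows), collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(c(hdr, rows), path)
  invisible(out)
}

#' Dot-bracket notation for a secondary structure
#' @param structure A [secondary_structure()].
#' @return A dot-bracket string: `(` at 5' partners, `)` at 3' partners,
#'   `.` unpaired.
#' @export
dot_bracket <- function(structure) {
  p <- structure$pairs
  out <- rep(".", length(p))
  out[p != 0 & p > seq_along(p)] <- "("
  out[p != 0 & p < seq_along(p)] <- ")"
  paste(out, collapse = "")
}

#' Build a secondary structure from dot-bracket notation
#' @param seq The sequence.
#' @param db Dot-bracket string of the same length.
#' @param energy Optional energy, kcal/mol.
#' @return A [secondary_structure()].
#' @export
from_dot_bracket <- function(seq, db, energy = NA_real_) {
  if (nchar(seq) != nchar(db))
    abort_format("sequence and dot-bracket lengths differ")
  ch <- strsplit(db, "")[[1]]
  if (any(!ch %in% c("(", ")", ".")))
    abort_format("dot-bracket may contain only '(', ')' and '.'")
  pairs <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0L) abort_format("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j; pairs[j] <- i
    }
  }
  if (length(stack)) abort_format("unbalanced dot-bracket string")
  secondary_structure(seq, pairs, energy)
}

#' Write predicted loci as BED6
#' @param intervals List of [interval()]s.
#' @param names Feature names (recycled).
#' @param scores Numeric scores (recycled).
#' @param path Output path or `NULL`.
#' @return BED text, invisibly.
#' @export
write_bed <- function(intervals, names = ".", scores = 0, path = NULL) {
  n <- length(intervals)
  names <- rep_len(names, n); scores <- rep_len(scores, n)
  lines <- vapply(seq_len(n), function(i) {
    iv <- intervals[[i]]
    sprintf("%s\t%d\t%d\t%s\t%g\t%s", iv$seq_id, iv$start, iv$end,
            names[i], scores[i], iv$strand)
  }, "")
  if (!is.null(path)) writeLines(lines, path)
  invisible(paste0(paste(lines, collapse = "\n"), if (n) "\n" else ""))
}
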