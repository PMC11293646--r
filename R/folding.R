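#' Folding engine parameters
#'
#' The built-in reference folder is a deterministic maximum-weight nested
#' pairing (dynamic programming with traceback enumeration of co-optimal
#' structures): pair weights GC = 3, AU = 2, GU = 1, minimum hairpin loop 3.
#' Energies are then assigned by [eval_energy()]. The external RNAfold
#' adapter runs the thermodynamic folder when the binary is on the PATH.
#'
#' @param wGC,wAU,wGU Pair weights of the reference folder.
#' @param min_loop Minimum hairpin loop size in nt.
#' @param max_structures Cap on enumerated co-optimal structures.
#' @return A named list of folding parameters.
#' @export
fold_params <- function(wGC = 3L, wAU = 2L, wGU = 1L, min_loop = 3L,
                        max_structures = 20L) {
  list(wGC = wGC, wAU = wAU, wGU = wGU, min_loop = min_loop,
       max_structures = max_structures)
}

#' Predict secondary structures for an RNA sequence
#'
#' Returns one or more valid [secondary_structure()]s sorted by energy
#' (ascending), duplicates (identical pair tables) removed. Input is folded
#' as RNA regardless of alphabet.
#'
#' @param seq Sequence (character) or a `seq_record`.
#' @param engine `"auto"` (RNAfold when available, else the reference
#'   folder), `"rnafold"`, or `"reference"`.
#' @param params [fold_params()] for the reference folder.
#' @return List of [secondary_structure()]s.
#' @export
fold_all <- function(seq, engine = c("auto", "rnafold", "reference"),
                     params = fold_params()) {
  engine <- match.arg(engine)
  if (inherits(seq, "seq_record")) seq <- seq$seq
  seq <- to_rna(seq)
  if (nchar(seq) < 12L)
    abort_argument("fold_all requires a sequence of at least 12 nt")
  if (engine == "auto")
    engine <- if (nzchar(Sys.which("RNAfold"))) "rnafold" else "reference"
  if (engine == "rnafold" && !nzchar(Sys.which("RNAfold"))) {
    inform("RNAfold not found on PATH; using the built-in reference folder")
    engine <- "reference"
  }
  structs <- switch(engine,
    rnafold = fold_rnafold(seq),
    reference = fold_reference(seq, params))
  # validate, dedup, order by energy
  keys <- vapply(structs, function(s) paste(s$pairs, collapse = ","), "")
  structs <- structs[!duplicated(keys)]
  en <- vapply(structs, function(s) s$energy, 1.0)
  structs[order(en)]
}

fold_reference <- function(seq, params) {
  res <- .nussinov_fold(seq, params$wGC, params$wAU, params$wGU,
                        params$min_loop, params$max_structures)
  lapply(res$structures, function(p) {
    st <- secondary_structure(seq, p)
    st$energy <- eval_energy(st)
    st
  })
}

fold_rnafold <- function(seq) {
  out <- system2("RNAfold", c("--noPS"), input = seq, stdout = TRUE,
                 stderr = FALSE)
  ln <- out[length(out)]
  db <- sub("\\s.*$", "", ln)
  en <- suppressWarnings(as.numeric(gsub("[()\\s]", "",
    regmatches(ln, regexpr("\\(\\s*-?[0-9.]+\\s*\\)$", ln)))))
  if (!nzchar(db) || nchar(db) != nchar(seq))
    abort_structure("could not parse RNAfold output")
  list(from_dot_bracket(seq, db, if (length(en)) en else NA_real_))
}

# --- simplified nearest-neighbour energy model -------------------------------

# pair strength used by the stacking term
.pair_strength <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)

#' Free energy of a secondary structure (simplified nearest-neighbour model)
#'
#' A documented, self-contained parameter set: every stack of two adjacent
#' base pairs contributes `-(s1 + s2)/2 - 0.5` kcal/mol where `s` is 3 for
#' GC, 2 for AU and 1 for GU; hairpin loops cost `4.5 + 1.1 log(n/3)`,
#' bulges `3.5 + 1.1 log(n)`, internal loops `2.0 + 1.1 log(n/2)` and
#' multiloops `3.4 + 0.4 b + 0.1 u` (b branches, u unpaired) kcal/mol.
#' An all-unpaired structure has energy 0.
#'
#' @param structure A [secondary_structure()].
#' @return Energy in kcal/mol.
#' @export
eval_energy <- function(structure) {
  p <- structure$pairs
  if (all(p == 0L)) return(0)
  b <- strsplit(structure$seq, "")[[1]]
  e <- 0
  # stacking: adjacent pairs (i,j), (i+1,j-1)
  for (i in seq_along(p)) {
    j <- p[i]
    if (j > i && i + 1 <= length(p) && p[i + 1] == j - 1 && j - 1 > i + 1) {
      s1 <- .pair_strength[paste0(b[i], b[j])]
      s2 <- .pair_strength[paste0(b[i + 1], b[j - 1])]
      e <- e - ((s1 + s2) / 2 + 0.5)
    }
  }
  els <- structure_elements(p)
  for (el in els) {
    n <- length(el$unpaired)
    e <- e + switch(el$kind,
      hairpin_loop = 4.5 + 1.1 * log(max(n, 3) / 3),
      bulge = 3.5 + 1.1 * log(max(n, 1)),
      internal_loop = 2.0 + 1.1 * log(max(n, 2) / 2),
      multiloop = 3.4 + 0.4 * el$branches + 0.1 * n,
      0)
  }
  unname(e)
}
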