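# The 170-feature record in 8 named families. The family sizes
# (7, 4, 5, 4, 8, 23, 36, 83) are the binding contract; the exact member
# list is this package's documented schema (see inst/extdata/feature_schema.tsv
# and feature_schema()). Sentinel -1 marks features undefined for a
# candidate (e.g. absent stems or mismatches).

.pm_base_code <- c(A = 1, C = 2, G = 3, U = 4, T = 4, N = 0)

feature_members <- function() {
  list(
    primary = c("arm_is_5p", "hit_paired_pct", "hit_longest_unpaired_run",
                "terminal_structure_count", "main_branch_len",
                "n_hairpin_loops_whole", "n_structures_reported"),
    reference_query = c("query_length", "hit_ld", "hit_neg_log10_evalue",
                        "hit_alignment_length"),
    genomic_positions = c("window_start", "window_end", "strand_plus",
                          "hit_start_in_window", "mature_start_on_precursor"),
    nucleotide_composition = c("gc_whole_pct", "gc_main_branch_pct",
                               "gc_premirna_pct", "gc_mature_pct"),
    energy = c("fe_whole", "mfei_whole", "fe_main_branch", "amfe_main_branch",
               "mfei_main_branch", "fe_premirna", "amfe_premirna",
               "mfei_premirna"),
    linear_sequence = c("hit_start", "hit_end", "mir_start", "mir_end",
                        "star_start", "star_end", "loop_start", "loop_end",
                        "precursor_start", "precursor_end",
                        "main_branch_start", "main_branch_end",
                        paste0("stem", rep(1:5, each = 2), "_",
                               rep(c("start", "end"), 5)),
                        "window_length"),
    pair_composition = {
      pos <- c(paste0("m", 1:11), "m_last")
      as.vector(t(outer(pos, c("state", "base", "partner_base"),
                        function(a, b) paste0(a, "_", b))))
    },
    major_structural = c(
      "n_mismatch", "n_asym", "largest_loop", "has_secondary_stem",
      "overhang_5p_side", "overhang_3p_side", "mir_len", "star_len",
      "precursor_len", "loop_len",
      "n_stems_main_branch", "n_bulges_main_branch",
      "n_internal_loops_main_branch", "n_sym_gaps_duplex",
      "n_asym_gaps_duplex", "n_multiloops_whole",
      "n_hairpin_loops_main_branch", "longest_stem_len", "mean_stem_len",
      paste0("mismatch_pos_", 1:8),
      paste0("bulge", rep(1:4, each = 3), "_",
             rep(c("offset", "left", "right"), 4)),
      paste0("iloop", rep(1:4, each = 3), "_",
             rep(c("offset", "left", "right"), 4)),
      paste0("stem", rep(1:8, each = 2), "_", rep(c("pos", "len"), 8)),
      "apical_loop_start", "apical_loop_size",
      "sec_stem_positions", "sec_stem_max_run",
      "duplex_n_pairs", "duplex_n_gu", "duplex_n_wc",
      "precursor_paired_pct", "mir_unpaired", "star_unpaired",
      "mir_longest_paired_run", "star_paired_pct",
      "dist_mir_to_loop", "dist_star_to_loop",
      "dist_precursor_to_window_5p", "dist_precursor_to_window_3p"))
}

#' The published feature schema
#'
#' @return A tibble with columns `family`, `name` and `index` describing
#'   all 170 features in their stable order. Family sizes are fixed at
#'   primary = 7, reference_query = 4, genomic_positions = 5,
#'   nucleotide_composition = 4, energy = 8, linear_sequence = 23,
#'   pair_composition = 36, major_structural = 83.
#' @export
feature_schema <- function() {
  mem <- feature_members()
  tb <- tibble(family = rep(names(mem), lengths(mem)),
               name = unlist(mem, use.names = FALSE))
  tb$index <- seq_len(nrow(tb))
  tb
}

gc_pct <- function(seq) {
  if (is.null(seq) || !nzchar(seq)) return(-1)
  b <- strsplit(to_rna(seq), "")[[1]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

# restrict a structure to a span; pairs escaping the span are opened
substructure <- function(structure, span) {
  s <- max(1L, as.integer(span[1])); e <- min(nchar(structure$seq), as.integer(span[2]))
  p <- structure$pairs[s:e]
  out <- ifelse(p >= s & p <= e, p - s + 1L, 0L)
  secondary_structure(substr(structure$seq, s, e), out)
}

#' GC content of the candidate's sequence segments
#'
#' @param seq_segments Named list with elements `whole`, `main_branch`,
#'   `premirna`, `mature` (character; `NULL`/empty gives sentinel -1).
#' @return Named numeric vector of four GC percentages on 0-100.
#' @export
compute_composition <- function(seq_segments) {
  c(gc_whole_pct = gc_pct(seq_segments$whole),
    gc_main_branch_pct = gc_pct(seq_segments$main_branch),
    gc_premirna_pct = gc_pct(seq_segments$premirna),
    gc_mature_pct = gc_pct(seq_segments$mature))
}

amfe <- function(mfe, L) if (L > 0) (mfe / L) * 100 else 0
mfei <- function(amfe_val, gc) if (is.finite(gc) && gc > 0) amfe_val / gc else 0

#' Energy features of a candidate
#'
#' `AMFE = (MFE / L) * 100` (energy per 100 nt) and `MFEI = AMFE / GC%`
#' (GC on the 0-100 scale; defined as 0 when GC is 0). Reports free
#' energy, AMFE and MFEI for the main branch and the presumed pre-miRNA,
#' and free energy and MFEI for the whole structure (8 values).
#'
#' @param structure A [secondary_structure()] (whole window).
#' @param ctx A [locate_hit()] context.
#' @param precursor_span Span of the presumed pre-miRNA on the window.
#' @return Named numeric vector of the 8 energy features.
#' @export
compute_energy_features <- function(structure, ctx, precursor_span) {
  L <- nchar(structure$seq)
  fe_whole <- if (!is.na(structure$energy)) structure$energy else
    eval_energy(structure)
  gc_whole <- gc_pct(structure$seq)
  br <- ctx$main_branch
  if (any(is.na(br))) br <- c(1L, L)
  sub_br <- substructure(structure, br)
  fe_br <- eval_energy(sub_br)
  sub_pre <- substructure(structure, precursor_span)
  fe_pre <- eval_energy(sub_pre)
  a_br <- amfe(fe_br, nchar(sub_br$seq))
  a_pre <- amfe(fe_pre, nchar(sub_pre$seq))
  a_whole <- amfe(fe_whole, L)
  c(fe_whole = fe_whole, mfei_whole = mfei(a_whole, gc_whole),
    fe_main_branch = fe_br, amfe_main_branch = a_br,
    mfei_main_branch = mfei(a_br, gc_pct(sub_br$seq)),
    fe_premirna = fe_pre, amfe_premirna = a_pre,
    mfei_premirna = mfei(a_pre, gc_pct(sub_pre$seq)))
}

#' Extract the 170-feature record for a qualified candidate
#'
#' The candidate must have passed [disqualify()]; pass its verdict (or at
#' least a context whose arm is `5p` or `3p`), otherwise a contract error
#' is raised. Feature names and order are fixed by [feature_schema()].
#'
#' @param structure The folded window ([secondary_structure()]).
#' @param ctx [locate_hit()] context.
#' @param stats [duplex_stats()] for the mature/star spans.
#' @param query_meta List: `query_length`, `ld`, `evalue`, `alignment_length`.
#' @param genomic_meta List: `window` ([interval()]), `hit_start_in_window`,
#'   optional `n_structures`.
#' @param verdict Optional verdict from [disqualify()]; a rejected verdict
#'   raises a contract error.
#' @return A one-row tibble with 170 numeric columns in schema order.
#' @export
extract_features <- function(structure, ctx, stats, query_meta = list(),
                             genomic_meta = list(), verdict = NULL) {
  if (!is.null(verdict) && !isTRUE(verdict$accepted))
    abort_contract("candidate is unqualified: call disqualify() first")
  if (!ctx$arm %in% c("5p", "3p"))
    abort_contract("candidate is unqualified (hit not on a hairpin arm)")
  p <- structure$pairs
  L <- length(p)
  b <- strsplit(structure$seq, "")[[1]]
  els <- structure_elements(p)
  br <- ctx$main_branch; if (any(is.na(br))) br <- c(1L, L)
  in_br <- function(x) x >= br[1] & x <= br[2]
  br_stems <- Filter(function(e) e$kind == "stem" && in_br(e$outer[1]), els)
  br_stems <- br_stems[order(vapply(br_stems, function(e) e$outer[1], 1L))]
  hloops <- hairpin_loops_of(els)
  mir <- stats$mir_span; star <- stats$star_span
  pre <- c(min(mir[1], star[1]), max(mir[2], star[2]))

  fam <- list()
  # --- primary
  fam$primary <- c(
    arm_is_5p = as.numeric(ctx$arm == "5p"),
    hit_paired_pct = 100 * ctx$paired_fraction,
    hit_longest_unpaired_run = ctx$longest_unpaired_run,
    terminal_structure_count = ctx$terminal_structure_count,
    main_branch_len = br[2] - br[1] + 1,
    n_hairpin_loops_whole = length(hloops),
    n_structures_reported = genomic_meta$n_structures %||% 1)
  # --- reference query
  ev <- query_meta$evalue %||% NA_real_
  fam$reference_query <- c(
    query_length = query_meta$query_length %||% -1,
    hit_ld = query_meta$ld %||% -1,
    hit_neg_log10_evalue = if (is.na(ev) || ev <= 0) -1 else -log10(ev),
    hit_alignment_length = query_meta$alignment_length %||% -1)
  # --- genomic positions
  w <- genomic_meta$window
  fam$genomic_positions <- c(
    window_start = if (is.null(w)) -1 else w$start,
    window_end = if (is.null(w)) -1 else w$end,
    strand_plus = if (is.null(w)) -1 else as.numeric(w$strand == "+"),
    hit_start_in_window = genomic_meta$hit_start_in_window %||% ctx$hit_span[1],
    mature_start_on_precursor = mir[1] - pre[1] + 1)
  # --- nucleotide composition
  fam$nucleotide_composition <- compute_composition(list(
    whole = structure$seq,
    main_branch = substr(structure$seq, br[1], br[2]),
    premirna = substr(structure$seq, pre[1], pre[2]),
    mature = substr(structure$seq, mir[1], mir[2])))
  # --- energy
  fam$energy <- compute_energy_features(structure, ctx, pre)
  # --- linear sequence
  tl <- ctx$terminal_loop
  lin <- c(hit_start = ctx$hit_span[1], hit_end = ctx$hit_span[2],
           mir_start = mir[1], mir_end = mir[2],
           star_start = star[1], star_end = star[2],
           loop_start = if (any(is.na(tl))) -1 else tl[1] + 1,
           loop_end = if (any(is.na(tl))) -1 else tl[2] - 1,
           precursor_start = pre[1], precursor_end = pre[2],
           main_branch_start = br[1], main_branch_end = br[2])
  for (k in 1:5) {
    if (k <= length(br_stems)) {
      st <- br_stems[[k]]
      lin[paste0("stem", k, "_start")] <- st$outer[1]
      lin[paste0("stem", k, "_end")] <- st$inner[1]
    } else {
      lin[paste0("stem", k, "_start")] <- -1
      lin[paste0("stem", k, "_end")] <- -1
    }
  }
  lin["window_length"] <- L
  fam$linear_sequence <- lin
  # --- pair composition at crucial positions
  # mature 1-11 (5'-cut-adjacent, seed 2-8, central 9-11) and the 3' end
  crucial <- c(mir[1] + 0:10, mir[2])
  pc <- numeric(0)
  labs <- c(paste0("m", 1:11), "m_last")
  for (k in seq_along(crucial)) {
    pos <- crucial[k]
    if (pos < 1 || pos > L || pos > mir[2]) {
      pc[paste0(labs[k], "_state")] <- -1
      pc[paste0(labs[k], "_base")] <- -1
      pc[paste0(labs[k], "_partner_base")] <- -1
      next
    }
    j <- p[pos]
    key <- if (j != 0) paste0(b[pos], b[j]) else ""
    state <- if (j == 0) 3 else if (key %in% c("GU", "UG")) 1 else 0
    pc[paste0(labs[k], "_state")] <- state
    pc[paste0(labs[k], "_base")] <- unname(.pm_base_code[b[pos]])
    pc[paste0(labs[k], "_partner_base")] <-
      if (j == 0) 0 else unname(.pm_base_code[b[j]])
  }
  fam$pair_composition <- pc
  # --- major structural
  g <- stats$gaps
  sym <- g[g$left == g$right, , drop = FALSE]
  asym <- g[g$left != g$right, , drop = FALSE]
  bulges <- g[g$left == 0 | g$right == 0, , drop = FALSE]
  iloops <- g[g$left > 0 & g$right > 0, , drop = FALSE]
  br_bulge <- sum(vapply(els, function(e)
    e$kind == "bulge" && in_br(e$closing[1]), TRUE))
  br_iloop <- sum(vapply(els, function(e)
    e$kind == "internal_loop" && in_br(e$closing[1]), TRUE))
  stem_lens <- vapply(br_stems, function(e) e$n_pairs, 1L)
  dup_pos <- c(mir[1]:mir[2], star[1]:star[2])
  escape <- p[dup_pos] != 0 &
    !((p[dup_pos] >= mir[1] & p[dup_pos] <= mir[2]) |
        (p[dup_pos] >= star[1] & p[dup_pos] <= star[2]))
  esc_runs <- rle(escape)
  prepos <- pre[1]:pre[2]
  mirpos <- mir[1]:mir[2]
  starpos <- star[1]:star[2]
  mruns <- rle(p[mirpos] != 0)
  ms <- c(
    n_mismatch = stats$n_mismatch, n_asym = stats$n_asym,
    largest_loop = stats$largest_loop,
    has_secondary_stem = as.numeric(stats$secondary_stem),
    overhang_5p_side = stats$overhang_5p_side,
    overhang_3p_side = stats$overhang_3p_side,
    mir_len = stats$mir_len, star_len = stats$star_len,
    precursor_len = stats$precursor_len, loop_len = stats$loop_len,
    n_stems_main_branch = length(br_stems),
    n_bulges_main_branch = br_bulge,
    n_internal_loops_main_branch = br_iloop,
    n_sym_gaps_duplex = nrow(sym), n_asym_gaps_duplex = nrow(asym),
    n_multiloops_whole = sum(vapply(els, function(e)
      e$kind == "multiloop", TRUE)),
    n_hairpin_loops_main_branch = sum(vapply(hloops, function(h)
      in_br(h$closing[1]), TRUE)),
    longest_stem_len = if (length(stem_lens)) max(stem_lens) else -1,
    mean_stem_len = if (length(stem_lens)) mean(stem_lens) else -1)
  mp <- stats$mismatch_positions
  for (k in 1:8)
    ms[paste0("mismatch_pos_", k)] <- if (k <= length(mp)) mp[k] else -1
  for (k in 1:4) {
    v <- if (k <= nrow(bulges)) unlist(bulges[k, ]) else c(-1, -1, -1)
    ms[paste0("bulge", k, "_offset")] <- v[1]
    ms[paste0("bulge", k, "_left")] <- v[2]
    ms[paste0("bulge", k, "_right")] <- v[3]
  }
  for (k in 1:4) {
    v <- if (k <= nrow(iloops)) unlist(iloops[k, ]) else c(-1, -1, -1)
    ms[paste0("iloop", k, "_offset")] <- v[1]
    ms[paste0("iloop", k, "_left")] <- v[2]
    ms[paste0("iloop", k, "_right")] <- v[3]
  }
  for (k in 1:8) {
    if (k <= length(br_stems)) {
      ms[paste0("stem", k, "_pos")] <- br_stems[[k]]$outer[1]
      ms[paste0("stem", k, "_len")] <- br_stems[[k]]$n_pairs
    } else {
      ms[paste0("stem", k, "_pos")] <- -1
      ms[paste0("stem", k, "_len")] <- -1
    }
  }
  ap <- if (any(is.na(tl))) c(-1, -1) else
    c(tl[1] + 1, max(0, tl[2] - tl[1] - 1))
  ms["apical_loop_start"] <- ap[1]
  ms["apical_loop_size"] <- ap[2]
  ms["sec_stem_positions"] <- sum(escape)
  ms["sec_stem_max_run"] <- if (any(esc_runs$values))
    max(esc_runs$lengths[esc_runs$values]) else 0
  wc <- stats$n_pairs - stats$n_gu
  ms["duplex_n_pairs"] <- stats$n_pairs
  ms["duplex_n_gu"] <- stats$n_gu
  ms["duplex_n_wc"] <- wc
  ms["precursor_paired_pct"] <- 100 * sum(p[prepos] != 0) / length(prepos)
  ms["mir_unpaired"] <- sum(p[mirpos] == 0)
  ms["star_unpaired"] <- sum(p[starpos] == 0)
  ms["mir_longest_paired_run"] <- if (any(mruns$values))
    max(mruns$lengths[mruns$values]) else 0
  ms["star_paired_pct"] <- 100 * sum(p[starpos] != 0) / length(starpos)
  ms["dist_mir_to_loop"] <- if (any(is.na(tl))) -1 else
    min(abs(c(mir[1], mir[2]) - tl[1]), abs(c(mir[1], mir[2]) - tl[2]))
  ms["dist_star_to_loop"] <- if (any(is.na(tl))) -1 else
    min(abs(c(star[1], star[2]) - tl[1]), abs(c(star[1], star[2]) - tl[2]))
  ms["dist_precursor_to_window_5p"] <- pre[1] - 1
  ms["dist_precursor_to_window_3p"] <- L - pre[2]
  fam$major_structural <- ms

  mem <- feature_members()
  for (f in names(mem)) {
    stopifnot(identical(names(fam[[f]]), mem[[f]]))
  }
  vec <- unlist(fam, use.names = FALSE)
  names(vec) <- unlist(mem, use.names = FALSE)
  vec[!is.finite(vec)] <- -1
  as_tibble(as.list(vec))
}
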