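# Structure decomposition and the miRNA/miRNA* rule machinery.
# Positions are 1-based inclusive throughout (CT convention).

# Enumerate the loop/stem elements of a pair table. Returns a list of
# elements; kinds: stem, hairpin_loop, bulge, internal_loop, multiloop,
# exterior. Elements partition 1..L: stems own their paired positions,
# loops own their unpaired positions.
structure_elements <- function(p) {
  L <- length(p)
  els <- list()
  # --- stems: maximal runs of stacked pairs
  open_pairs <- which(p > seq_along(p))
  is_start <- vapply(open_pairs, function(i) {
    !(i - 1 >= 1 && p[i - 1] == p[i] + 1)
  }, TRUE)
  for (i in open_pairs[is_start]) {
    run <- i
    while (run + 1 <= L && p[run + 1] == p[run] - 1 && p[run] - 1 > run + 1)
      run <- run + 1L
    fives <- i:run
    els[[length(els) + 1L]] <- list(
      kind = "stem", positions = sort(c(fives, p[fives])),
      outer = c(i, p[i]), inner = c(run, p[run]), n_pairs = length(fives))
  }
  # --- loops: for each innermost pair of a stem, classify the enclosed region
  for (el in els) {
    if (el$kind != "stem") next
    ci <- el$inner[1]; cj <- el$inner[2]
    k <- ci + 1L
    unp <- integer(0)
    children <- list()
    while (k < cj) {
      if (p[k] > k) {
        children[[length(children) + 1L]] <- c(k, p[k])
        k <- p[k] + 1L
      } else {
        unp <- c(unp, k)
        k <- k + 1L
      }
    }
    nk <- length(children)
    if (nk == 0L) {
      els[[length(els) + 1L]] <- list(kind = "hairpin_loop", positions = unp,
                                      unpaired = unp, closing = c(ci, cj))
    } else if (nk == 1L) {
      ch <- children[[1]]
      left <- sum(unp < ch[1]); right <- sum(unp > ch[2])
      kind <- if (left > 0 && right > 0) "internal_loop" else "bulge"
      els[[length(els) + 1L]] <- list(kind = kind, positions = unp,
                                      unpaired = unp, left = left,
                                      right = right, closing = c(ci, cj),
                                      child = ch)
    } else {
      els[[length(els) + 1L]] <- list(kind = "multiloop", positions = unp,
                                      unpaired = unp, branches = nk,
                                      closing = c(ci, cj))
    }
  }
  # --- exterior: everything not enclosed by any pair
  ext <- integer(0)
  k <- 1L
  while (k <= L) {
    if (p[k] > k) k <- p[k] + 1L
    else { ext <- c(ext, k); k <- k + 1L }
  }
  if (length(ext))
    els[[length(els) + 1L]] <- list(kind = "exterior", positions = ext,
                                    unpaired = ext)
  els
}

#' Decompose a secondary structure into stems and loops
#'
#' Standard loop taxonomy: stems are maximal runs of stacked base pairs;
#' the region enclosed by a stem's innermost pair is a hairpin loop (no
#' inner helix), a bulge (one inner helix, unpaired on one side), an
#' internal loop (one inner helix, unpaired on both sides) or a multiloop
#' (two or more inner helices). Unenclosed positions form the exterior.
#' The elements partition positions 1..L.
#'
#' @param structure A [secondary_structure()].
#' @return A list of elements; each has `kind` and a sorted `positions`
#'   vector (stems additionally `outer`, `inner`, `n_pairs`; loops
#'   `unpaired` and, for bulges/internal loops, `left`/`right` counts).
#' @export
decompose <- function(structure) {
  structure_elements(structure$pairs)
}

hairpin_loops_of <- function(els) Filter(function(e) e$kind == "hairpin_loop", els)

#' Locate a homology hit on a folded structure
#'
#' Assigns the hit to an arm of its hairpin by comparing its positions with
#' the terminal loop of the branch holding the majority of the hit's base
#' pairs: entirely 5' of the loop is `5p`, entirely 3' is `3p`, fully
#' unpaired inside a loop is `loop`, and spanning the loop apex is
#' `crossing`. Also identifies the main branch (the top-level helix subtree
#' containing the hit) and counts the hairpin loops distal to the hit on
#' that branch.
#'
#' @param structure A [secondary_structure()].
#' @param hit_span Integer length-2 vector, 1-based inclusive.
#' @return A `hit_context`: `hit_span`, `arm`, `terminal_loop` (closing
#'   pair), `main_branch` (span), `terminal_structure_count`,
#'   `paired_fraction`, `longest_unpaired_run`.
#' @export
locate_hit <- function(structure, hit_span) {
  p <- structure$pairs
  L <- length(p)
  hs <- as.integer(hit_span[1]); he <- as.integer(hit_span[2])
  if (hs < 1 || he > L || hs > he)
    abort_argument("hit span outside the structure")
  hpos <- hs:he
  paired <- hpos[p[hpos] != 0L]
  els <- structure_elements(p)
  hloops <- hairpin_loops_of(els)
  paired_fraction <- length(paired) / length(hpos)
  runs <- rle(p[hpos] == 0L)
  longest_unp <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L

  # terminal loop by majority vote of hit pairs
  tl <- NULL
  if (length(hloops)) {
    votes <- integer(length(hloops))
    sizes <- vapply(hloops, function(h) h$closing[2] - h$closing[1], 1L)
    for (i in paired) {
      lo <- min(i, p[i]); hi <- max(i, p[i])
      inside <- which(vapply(hloops, function(h)
        h$closing[1] > lo & h$closing[2] < hi, TRUE))
      if (length(inside)) {
        # vote for the nearest reachable loop
        inside <- inside[order(sizes[inside])]
        votes[inside[1]] <- votes[inside[1]] + 1L
      }
    }
    if (all(votes == 0L)) {
      # unpaired hit: the loop whose region overlaps the hit, if any
      ov <- which(vapply(hloops, function(h)
        length(intersect(h$positions, hpos)) > 0, TRUE))
      if (length(ov)) tl <- hloops[[ov[1]]]
    } else {
      tl <- hloops[[which.max(votes)]]
    }
  }
  if (is.null(tl)) {
    arm <- "loop" # no terminal loop reachable: treat as unstructured
    tloop <- c(NA_integer_, NA_integer_)
    tcount <- 0L
    branch <- c(NA_integer_, NA_integer_)
  } else {
    ci <- tl$closing[1]; cj <- tl$closing[2]
    tloop <- c(ci, cj)
    on5 <- any(hpos <= ci); on3 <- any(hpos >= cj)
    inloop <- all(hpos > ci & hpos < cj)
    arm <- if (inloop) "loop" else if (on5 && on3) "crossing"
           else if (on5) "5p" else "3p"
    # main branch: outermost enclosing pair of the terminal loop
    bi <- ci; bj <- cj
    repeat {
      enc <- which(seq_len(L) < bi & p > 0 & p[seq_len(L)] > bj)
      if (!length(enc)) break
      bi <- max(enc); bj <- p[bi]
    }
    branch <- c(bi, bj)
    # hairpin loops distal to the hit on its branch
    region <- if (arm == "5p") {
      inner <- if (length(paired)) max(paired) else he
      c(inner, if (length(paired)) p[max(paired)] else bj)
    } else if (arm == "3p") {
      inner <- if (length(paired)) min(paired) else hs
      c(if (length(paired)) p[min(paired)] else bi, inner)
    } else c(hs, he)
    tcount <- sum(vapply(hloops, function(h)
      h$closing[1] >= region[1] & h$closing[2] <= region[2], TRUE))
    if (arm %in% c("loop", "crossing")) tcount <- max(tcount, 1L)
  }
  structure(list(hit_span = c(hs, he), arm = arm, terminal_loop = tloop,
                 main_branch = branch, terminal_structure_count = tcount,
                 paired_fraction = paired_fraction,
                 longest_unpaired_run = as.integer(longest_unp)),
            class = "hit_context")
}

#' Rule-engine and qualification thresholds
#'
#' Defaults follow the generally accepted criteria for plant miRNA
#' identification: two-nucleotide 3' overhangs on both duplex ends, no
#' secondary stems, at most six mismatched duplex positions of which at
#' most three in asymmetric bulges, precursor at most 300 nt, mature
#' length 20-24 nt. `banned_positions` optionally forbids mismatches at
#' given mature positions (e.g. 9-11). Qualification thresholds govern the
#' primary filter: minimum paired fraction of the hit, longest tolerated
#' unpaired run, largest tolerated internal-loop side in the duplex, and
#' at most three terminal structures.
#'
#' @param overhang_len Required 3' overhang, nt.
#' @param max_mismatch Maximum mismatched duplex positions.
#' @param max_asym Maximum mismatched positions in asymmetric bulges.
#' @param max_precursor Maximum precursor length, nt.
#' @param mature_min,mature_max Mature length bounds, nt.
#' @param banned_positions Mature positions where mismatches are forbidden.
#' @param wobble_as_pair Treat G:U as a pair (default) or as a mismatch.
#' @param min_paired_fraction,max_unpaired_run,max_loop_side,max_terminal_structures
#'   Primary-filter thresholds.
#' @return A `rule_config` list.
#' @export
rule_config <- function(overhang_len = 2L, max_mismatch = 6L, max_asym = 3L,
                        max_precursor = 300L, mature_min = 20L,
                        mature_max = 24L, banned_positions = integer(0),
                        wobble_as_pair = TRUE, min_paired_fraction = 0.6,
                        max_unpaired_run = 5L, max_loop_side = 5L,
                        max_terminal_structures = 3L) {
  if (mature_min > mature_max)
    abort_argument("mature_min must not exceed mature_max")
  structure(list(overhang_len = overhang_len, max_mismatch = max_mismatch,
                 max_asym = max_asym, max_precursor = max_precursor,
                 mature_min = mature_min, mature_max = mature_max,
                 banned_positions = as.integer(banned_positions),
                 wobble_as_pair = wobble_as_pair,
                 min_paired_fraction = min_paired_fraction,
                 max_unpaired_run = max_unpaired_run,
                 max_loop_side = max_loop_side,
                 max_terminal_structures = max_terminal_structures),
            class = "rule_config")
}

verdict <- function(violated, stage) {
  structure(list(accepted = length(violated) == 0L,
                 violated = as.character(violated), stage = stage),
            class = "pm_verdict")
}

#' @export
print.pm_verdict <- function(x, ...) {
  if (x$accepted) cat(sprintf("<verdict> accepted (stage %s)\n", x$stage))
  else cat(sprintf("<verdict> rejected at %s: %s\n", x$stage,
                   paste(x$violated, collapse = ", ")))
  invisible(x)
}

#' Structure disqualification and primary qualification filter
#'
#' Evaluates the six structural disqualification rules — the hit region
#' (i) is not involved in a double-stranded stem, (ii) has only a few
#' residues in complementarity, (iii) lacks a continuous complementary
#' region, (iv) contains inner branches, (v) is complementary to a branched
#' region, or (vi) is not located entirely on the same side of the duplex —
#' followed by the primary filter (an uninterrupted stem of near-perfect
#' complementarity, no large internal loops in the presumed duplex, and a
#' simple terminal loop with at most three terminal structures).
#' Violations accumulate; nothing short-circuits.
#'
#' @param structure A [secondary_structure()].
#' @param ctx A [locate_hit()] context built from the same structure.
#' @param config A [rule_config()].
#' @return A verdict: `accepted`, `violated` (rule identifiers), `stage`.
#' @export
disqualify <- function(structure, ctx, config = rule_config()) {
  p <- structure$pairs
  hs <- ctx$hit_span[1]; he <- ctx$hit_span[2]
  hpos <- hs:he
  viol <- character(0)
  if (ctx$paired_fraction == 0 || ctx$arm == "loop")
    viol <- c(viol, "i_no_stem")
  if (ctx$paired_fraction < config$min_paired_fraction)
    viol <- c(viol, "ii_low_complementarity")
  if (ctx$longest_unpaired_run > config$max_unpaired_run)
    viol <- c(viol, "iii_no_continuous_stem")
  els <- structure_elements(p)
  multis <- Filter(function(e) e$kind == "multiloop", els)
  if (length(multis)) {
    in_hit <- any(vapply(multis, function(m)
      length(intersect(m$positions, hpos)) > 0 ||
        (m$closing[1] >= hs && m$closing[2] <= he), TRUE))
    if (in_hit) viol <- c(viol, "iv_inner_branches")
    partners <- p[hpos][p[hpos] != 0L]
    if (length(partners)) {
      comp <- setdiff(min(partners):max(partners), hpos)
      if (length(comp)) {
        in_comp <- any(vapply(multis, function(m)
          length(intersect(m$positions, comp)) > 0 ||
            (m$closing[1] >= min(comp) && m$closing[2] <= max(comp)), TRUE))
        if (in_comp) viol <- c(viol, "v_branched_complement")
      }
    }
  }
  if (ctx$arm == "crossing") viol <- c(viol, "vi_crossing_loop")
  if (length(viol)) return(verdict(viol, "disqualification"))

  # primary qualification filter
  pviol <- character(0)
  if (ctx$terminal_structure_count > config$max_terminal_structures)
    pviol <- c(pviol, "pf_terminal_structures")
  # large internal loops / bulges touching the hit region
  loops <- Filter(function(e) e$kind %in% c("internal_loop", "bulge"), els)
  big <- any(vapply(loops, function(l) {
    touches <- length(intersect(l$positions, hpos)) > 0
    touches && max(l$left, l$right) > config$max_loop_side
  }, TRUE))
  if (big) pviol <- c(pviol, "pf_large_internal_loop")
  verdict(pviol, "primary_filter")
}

#' Infer the miRNA* span from the mature span
#'
#' Applies the two-nucleotide 3' overhang geometry of DCL cleavage: the
#' star 3' end is the partner of the mature 5' end offset by +2, and the
#' star 5' end is the partner of mature position `end - 2`. Unpaired
#' mature end positions are resolved by scanning inward to the nearest
#' paired position and re-applying the offset; the result is clipped to
#' the structure.
#'
#' @param structure A [secondary_structure()].
#' @param mir_span Mature span, 1-based inclusive.
#' @return Integer length-2 star span.
#' @export
infer_star <- function(structure, mir_span) {
  p <- structure$pairs
  L <- length(p)
  s <- as.integer(mir_span[1]); e <- as.integer(mir_span[2])
  paired <- (s:e)[p[s:e] != 0L]
  if (length(paired) == 0L)
    abort_argument("cannot infer the star strand: mature has no paired position")
  q0 <- min(paired)
  star_end <- p[q0] + 2L + (q0 - s)
  anchor <- e - 2L
  cand <- paired[paired <= anchor]
  q1 <- if (length(cand)) max(cand) else min(paired)
  star_start <- p[q1] - (anchor - q1)
  out <- sort(c(star_start, star_end))
  c(max(1L, out[1]), min(L, out[2]))
}

#' Mismatch, bulge and overhang statistics of a miRNA/miRNA* duplex
#'
#' Walks the duplex between the mature and star spans. A gap between
#' consecutive duplex pairs with `left` unpaired guide nucleotides and
#' `right` unpaired star nucleotides contributes `max(left, right)`
#' mismatched positions (guide-side unpaired plus asymmetric excess) and
#' `|left - right|` asymmetric-bulge nucleotides. Secondary stems are
#' duplex positions paired outside the opposite span. Overhangs are the
#' 3' extensions past the last duplex pair at both ends.
#'
#' @param structure A [secondary_structure()].
#' @param mir_span,star_span 1-based inclusive spans (disjoint).
#' @param config A [rule_config()] (`wobble_as_pair = FALSE` counts G:U
#'   pairs as mismatches).
#' @return A `duplex_stats` list: `mir_span`, `star_span`, `n_mismatch`,
#'   `n_asym`, `largest_loop`, `secondary_stem`, `overhang_5p_side`,
#'   `overhang_3p_side`, `mir_len`, `star_len`, `precursor_len`,
#'   `loop_len`, `n_pairs`, `n_gu`, `mismatch_positions` (mature-relative),
#'   `gaps` (tibble of left/right sizes by mature offset).
#' @export
duplex_stats <- function(structure, mir_span, star_span,
                         config = rule_config()) {
  p <- structure$pairs
  b <- strsplit(structure$seq, "")[[1]]
  s <- as.integer(mir_span[1]); e <- as.integer(mir_span[2])
  ss <- as.integer(star_span[1]); se <- as.integer(star_span[2])
  if (max(s, ss) <= min(e, se))
    abort_argument("mature and star spans must be disjoint")
  in_star <- function(j) j >= ss & j <= se
  in_mir <- function(j) j >= s & j <= e
  dpos <- (s:e)[p[s:e] != 0L & in_star(p[s:e])]
  if (length(dpos) == 0L)
    abort_argument("no duplex pairs between the given spans")
  q0 <- min(dpos); q1 <- max(dpos)
  n_mis <- 0L; n_asym <- 0L; largest <- 0L
  mis_pos <- integer(0)
  gaps <- list()
  if (length(dpos) > 1L) {
    for (k in seq_len(length(dpos) - 1L)) {
      i <- dpos[k]; i2 <- dpos[k + 1L]
      left <- i2 - i - 1L
      right <- abs(p[i] - p[i2]) - 1L
      if (left > 0L || right > 0L) {
        n_mis <- n_mis + max(left, right)
        n_asym <- n_asym + abs(left - right)
        largest <- max(largest, left + right)
        if (left > 0L) mis_pos <- c(mis_pos, (i + 1L):(i2 - 1L) - s + 1L)
        else mis_pos <- c(mis_pos, i - s + 1L) # star-side bulge, flanking pos
        gaps[[length(gaps) + 1L]] <- c(mir_offset = i - s + 1L,
                                       left = left, right = right)
      }
    }
  }
  # G:U wobbles, optionally demoted to mismatches
  pairkey <- paste0(b[dpos], b[p[dpos]])
  n_gu <- sum(pairkey %in% c("GU", "UG"))
  if (!isTRUE(config$wobble_as_pair)) {
    n_mis <- n_mis + n_gu
    mis_pos <- sort(c(mis_pos, dpos[pairkey %in% c("GU", "UG")] - s + 1L))
  }
  # secondary stems: pairing that escapes the duplex
  allpos <- c(s:e, ss:se)
  partners <- p[allpos]
  sec <- any(partners != 0L & !(in_star(partners) | in_mir(partners)))
  # overhangs (3' extensions at both duplex ends)
  o_star_end <- (se - p[q0]) - (q0 - s)
  r0 <- min((ss:se)[p[ss:se] != 0L & in_mir(p[ss:se])])
  o_mir_end <- (e - p[r0]) - (r0 - ss)
  mir_is_5p <- s < ss
  structure(list(
    mir_span = c(s, e), star_span = c(ss, se),
    n_mismatch = as.integer(n_mis), n_asym = as.integer(n_asym),
    largest_loop = as.integer(largest), secondary_stem = sec,
    overhang_5p_side = as.integer(if (mir_is_5p) o_mir_end else o_star_end),
    overhang_3p_side = as.integer(if (mir_is_5p) o_star_end else o_mir_end),
    mir_len = e - s + 1L, star_len = se - ss + 1L,
    precursor_len = max(e, se) - min(s, ss) + 1L,
    loop_len = max(0L, max(s, ss) - min(e, se) - 1L),
    n_pairs = length(dpos), n_gu = as.integer(n_gu),
    mismatch_positions = sort(unique(mis_pos)),
    gaps = if (length(gaps)) as_tibble(do.call(rbind, gaps)) else
      tibble(mir_offset = integer(), left = integer(), right = integer())),
    class = "duplex_stats")
}

#' Final rule-based validation of a miRNA/miRNA* duplex
#'
#' Checks the duplex statistics against the configured thresholds:
#' two-nucleotide 3' overhangs at both ends, no secondary stems, at most
#' `max_mismatch` mismatched positions with at most `max_asym` of them in
#' asymmetric bulges, precursor length at most `max_precursor`, mature
#' length within `[mature_min, mature_max]`, and (optionally) no mismatch
#' at the banned mature positions. All violations are reported.
#'
#' @param stats A [duplex_stats()] result.
#' @param config A [rule_config()].
#' @return A verdict with stage `"rule_engine"`.
#' @export
apply_rules <- function(stats, config = rule_config()) {
  viol <- character(0)
  if (stats$overhang_5p_side != config$overhang_len ||
      stats$overhang_3p_side != config$overhang_len)
    viol <- c(viol, "overhang")
  if (isTRUE(stats$secondary_stem)) viol <- c(viol, "secondary_stem")
  if (stats$n_mismatch > config$max_mismatch) viol <- c(viol, "mismatch_limit")
  if (stats$n_asym > config$max_asym) viol <- c(viol, "asym_limit")
  if (stats$precursor_len > config$max_precursor)
    viol <- c(viol, "precursor_length")
  if (stats$mir_len < config$mature_min || stats$mir_len > config$mature_max)
    viol <- c(viol, "mature_length")
  if (length(config$banned_positions) &&
      length(intersect(stats$mismatch_positions, config$banned_positions)))
    viol <- c(viol, "banned_positions")
  verdict(viol, "rule_engine")
}
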