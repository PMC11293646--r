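# Generators producing every input the pipeline needs, with planted ground
# truth, so the whole test suite runs without downloads. The generators emit
# intended structures directly (no folding), which makes them independent
# oracles for the duplex statistics, the rule engine and the end-to-end run.

rand_bases <- function(n, gc = 0.5) {
  sample(c("G", "C", "A", "U"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

complement_base <- c(A = "U", U = "A", G = "C", C = "G", T = "A", N = "N")

# a base guaranteed not to pair (WC or wobble) with `b`
nonpairing_base <- function(b) switch(b, A = "C", C = "A", G = "A", U = "C",
                                      T = "C", "C")

#' Hairpin generator parameters
#'
#' @param loop_size Terminal loop length, nt.
#' @param lower_stem Base pairs below the miRNA/miRNA* duplex.
#' @param overhang_mir,overhang_star 3' overhang lengths (nt) of the mature
#'   and star strands (2 and 2 for canonical DCL cleavage).
#' @param mismatch_positions Mature positions carrying a symmetric 1x1
#'   mismatch.
#' @param bulges List of `c(offset, size, side)`-like lists: a bulge of
#'   `size` unpaired nt after mature duplex position `offset`, on the
#'   `"mir"` or `"star"` side.
#' @param arm `"5p"` or `"3p"`: which arm carries the mature.
#' @param gc GC fraction used for generated paired regions.
#' @return A parameter list for [make_hairpin()].
#' @export
hairpin_params <- function(loop_size = 6L, lower_stem = 12L,
                           overhang_mir = 2L, overhang_star = 2L,
                           mismatch_positions = integer(0), bulges = list(),
                           arm = "5p", gc = 0.55) {
  list(loop_size = as.integer(loop_size), lower_stem = as.integer(lower_stem),
       overhang_mir = as.integer(overhang_mir),
       overhang_star = as.integer(overhang_star),
       mismatch_positions = as.integer(mismatch_positions),
       bulges = bulges, arm = arm, gc = gc)
}

#' Generate a pre-miRNA hairpin with planted structural truth
#'
#' Emits the precursor sequence and its intended secondary structure
#' directly (no folding is involved), together with a truth record of all
#' planted quantities — the oracle for the duplex statistics, the rule
#' engine and feature extraction.
#'
#' @param mir_seq Mature sequence (character, RNA or DNA alphabet), or an
#'   integer length to draw a random mature.
#' @param params A [hairpin_params()].
#' @param seed Integer seed.
#' @return A list: `precursor` (`seq_record`), `structure`
#'   ([secondary_structure()]), `truth` (planted spans and counts).
#' @export
make_hairpin <- function(mir_seq = 21L, params = hairpin_params(), seed = 1L) {
  set.seed(seed)
  if (is.numeric(mir_seq)) mir_seq <- paste(rand_bases(mir_seq, params$gc),
                                            collapse = "")
  mir <- strsplit(to_rna(mir_seq), "")[[1]]
  m <- length(mir)
  o_mir <- params$overhang_mir; o_star <- params$overhang_star
  mm <- sort(unique(params$mismatch_positions))
  dup_len <- m - o_mir
  if (any(mm < 1 | mm > dup_len))
    abort_argument("mismatch position outside the mature duplex region")
  bulge_after <- lapply(params$bulges, function(b)
    list(offset = as.integer(b[[1]]), size = as.integer(b[[2]]),
         side = as.character(b[[3]])))
  for (b in bulge_after) {
    if (b$offset < 1 || b$offset >= dup_len)
      abort_argument("bulge offset outside the mature duplex region")
    if (b$offset %in% mm || (b$side == "mir" &&
        any((b$offset + 1):(b$offset + b$size) %in% mm)))
      abort_argument("inconsistent parameters: mismatch at a bulge position")
    if (!b$side %in% c("mir", "star")) abort_argument("bulge side must be mir/star")
  }
  mir_bulge_pos <- unlist(lapply(bulge_after, function(b)
    if (b$side == "mir") (b$offset + 1):(b$offset + b$size) else integer(0)))
  mir_bulge_pos <- as.integer(mir_bulge_pos %||% integer(0))
  # a bulge reaching the duplex end is indistinguishable from a longer
  # overhang; bulges must stay strictly interior
  if (any(mir_bulge_pos >= dup_len))
    abort_argument("mir-side bulge touches the duplex end")
  if (any(vapply(bulge_after, function(b)
    b$side == "star" && b$offset >= dup_len - 1L, TRUE)))
    abort_argument("star-side bulge touches the duplex end")
  star_bulge_after <- lapply(Filter(function(b) b$side == "star", bulge_after),
                             function(b) b)

  # walk the duplex base->loop in mature coordinates, building the star
  # strand in base->loop order (its 3' -> 5')
  star_rev <- character(0)       # bases, base-side first
  star_rev_pairs <- integer(0)   # mature index paired to, 0 if unpaired
  if (o_star > 0) {
    # overhang base k could pair the mature's base-side position k' under a
    # small register shift when the window is re-folded; exclude exactly the
    # complementary choice ({A,C} always leaves an option)
    ov <- vapply(seq_len(o_star), function(k) {
      # zipping the base-side overhang into the duplex would pair overhang
      # base k (3'-terminal first) with mature base k; on the 3p arm the
      # overhang faces the loop (A/C there cannot pair A/C)
      facing <- if (params$arm == "5p") mir[min(m, k)] else "A"
      allowed <- setdiff(c("A", "C"),
                         switch(facing, U = "A", G = "C", character(0)))
      sample(rep(allowed, 2L), 1)
    }, "")
    star_rev <- c(star_rev, ov)
    star_rev_pairs <- c(star_rev_pairs, rep(0L, o_star))
  }
  i <- 1L
  while (i <= dup_len) {
    sb <- Filter(function(b) b$offset + 1L == i, star_bulge_after)
    if (length(sb)) {
      for (b in sb) {
        star_rev <- c(star_rev, rep("", b$size))
        idx <- (length(star_rev) - b$size + 1L):length(star_rev)
        star_rev[idx] <- vapply(idx, function(z) sample(c("A", "C"), 1), "")
        star_rev_pairs <- c(star_rev_pairs, rep(0L, b$size))
      }
    }
    if (i %in% mm) {
      star_rev <- c(star_rev, nonpairing_base(mir[i]))
      star_rev_pairs <- c(star_rev_pairs, 0L)
    } else if (i %in% mir_bulge_pos) {
      # mature base unpaired, no star counterpart
    } else {
      star_rev <- c(star_rev, unname(complement_base[mir[i]]))
      star_rev_pairs <- c(star_rev_pairs, i)
    }
    i <- i + 1L
  }
  st <- length(star_rev)
  loop <- vapply(seq_len(params$loop_size), function(z) sample(c("A", "C"), 1), "")
  # the mature 3' overhang bases come from the mature itself; keep the loop
  # bases they could stack-pair with (helix extension) non-complementary
  if (params$arm == "5p" && o_mir > 0) {
    for (k in seq_len(min(o_mir, params$loop_size))) {
      b_m <- mir[dup_len + k]
      pos <- params$loop_size - k + 1L
      allowed <- setdiff(c("A", "C"), switch(b_m, U = "A", G = "C", character(0)))
      if (!loop[pos] %in% allowed) loop[pos] <- allowed[1]
    }
  }
  ls5 <- rand_bases(params$lower_stem, params$gc)
  Ls <- params$lower_stem
  # keep the lower-stem top from pairing with the base-side overhang bases
  # (prevents a shifted helix register when the window is re-folded)
  pairs_with <- function(b) switch(b, A = "U", U = c("A", "G"),
                                   G = c("C", "U"), C = "G", character(0))
  base_side <- if (params$arm == "5p") {
    star_rev[seq_len(o_star)]
  } else {
    rev(mir[seq_len(m) > dup_len])
  }
  # a straight helix continuation across the flush junction would pair
  # overhang base k (3'-terminal first) with lower-stem position
  # Ls - n_overhang + k; forbid exactly those pairings
  for (k in seq_along(base_side)) {
    at <- Ls - length(base_side) + k
    if (at < 1L) next
    bad <- pairs_with(base_side[k])
    if (ls5[at] %in% bad)
      ls5[at] <- sample(setdiff(c("A", "C", "G", "U"), bad), 1)
  }
  ls3 <- rev(vapply(ls5, function(b) unname(complement_base[b]), ""))

  if (params$arm == "5p") {
    # [ls5][mir][loop][star (loop->base)][ls3]
    star_fwd <- rev(star_rev)
    seqv <- c(ls5, mir, loop, star_fwd, ls3)
    L <- length(seqv)
    pos_mir <- function(i) Ls + i
    pos_star_rev <- function(j) Ls + m + params$loop_size + (st - j + 1L)
    pairs <- integer(L)
    for (j in seq_len(st)) {
      mi <- star_rev_pairs[j]
      if (mi > 0) {
        pairs[pos_mir(mi)] <- pos_star_rev(j)
        pairs[pos_star_rev(j)] <- pos_mir(mi)
      }
    }
    mir_span <- c(Ls + 1L, Ls + m)
    star_span <- c(Ls + m + params$loop_size + 1L,
                   Ls + m + params$loop_size + st)
  } else if (params$arm == "3p") {
    # [ls5][star reversed (base->loop)][loop][mir][ls3]; the star 3'
    # overhang sits loop-adjacent and the mature 3' overhang base-adjacent
    seqv <- c(ls5, rev(star_rev), loop, mir, ls3)
    L <- length(seqv)
    pos_mir <- function(i) Ls + st + params$loop_size + i
    pos_star_rev <- function(j) Ls + (st - j + 1L)
    pairs <- integer(L)
    for (j in seq_len(st)) {
      mi <- star_rev_pairs[j]
      if (mi > 0) {
        pairs[pos_mir(mi)] <- pos_star_rev(j)
        pairs[pos_star_rev(j)] <- pos_mir(mi)
      }
    }
    mir_span <- c(Ls + st + params$loop_size + 1L,
                  Ls + st + params$loop_size + m)
    star_span <- c(Ls + 1L, Ls + st)
  } else abort_argument("arm must be '5p' or '3p'")
  for (k in seq_len(Ls)) {
    pairs[k] <- L - k + 1L
    pairs[L - k + 1L] <- k
  }
  struct <- secondary_structure(paste(seqv, collapse = ""), pairs)
  struct$energy <- eval_energy(struct)
  n_mm_expected <- length(mm) +
    sum(vapply(bulge_after, function(b) b$size, 1L))
  n_asym_expected <- sum(vapply(bulge_after, function(b) b$size, 1L))
  truth <- list(mir_span = mir_span, star_span = star_span,
                arm = params$arm, mir_len = m,
                star_len = st, precursor_len = L,
                loop_size = params$loop_size,
                overhang_mir = o_mir, overhang_star = o_star,
                n_mismatch = as.integer(n_mm_expected),
                n_asym = as.integer(n_asym_expected),
                mismatch_positions = mm,
                mature = paste(mir, collapse = ""))
  list(precursor = seq_record(paste0("hairpin_", params$arm), struct$seq),
       structure = struct, truth = truth)
}

#' Generate a synthetic genome with planted miRNA loci, coding regions and
#' decoys
#'
#' Builds a random background sequence carrying: clean hairpin loci whose
#' matures populate the reference miRNA set; coding regions (ORF-structured,
#' with their six-frame peptides in the protein set), each optionally
#' embedding a hairpin homolog; decoy loci — hairpins whose guide is an
#' 18-19 nt exact substring of a 24-nt reference mature (dissimilarity band
#' 5-6) — planted inside coding regions; and tRNA-like records for the
#' rRNA/tRNA set. Every planted element is recorded in the truth table.
#'
#' @param n_loci Clean (non-coding) hairpin loci.
#' @param n_cds Coding regions embedding a hairpin homolog.
#' @param n_decoys Decoy loci inside additional coding regions.
#' @param seed Integer seed.
#' @param genome_length Background length, nt.
#' @param n_rfam tRNA-like records emitted in the rfam set.
#' @param minus_strand_fraction Fraction of planted hairpins inserted as
#'   reverse complements.
#' @return A list: `genome`, `mirnas` (matures), `stemloops`, `proteins`,
#'   `rfam` (all lists of `seq_record`s) and `truth` (a tibble).
#' @export
make_genome <- function(n_loci = 5L, n_cds = 5L, n_decoys = 5L, seed = 1L,
                        genome_length = 100000L, n_rfam = 3L,
                        minus_strand_fraction = 0.4) {
  set.seed(seed)
  genome <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
  truth <- list()
  mirnas <- list(); stemloops <- list(); proteins <- list(); rfam <- list()

  n_elements <- n_loci + n_cds + n_decoys
  slot_len <- 900L
  margin <- 600L
  usable <- genome_length - 2L * margin
  if (n_elements > 0 && usable < n_elements * slot_len)
    abort_argument("genome too short for the requested elements")
  starts <- if (n_elements > 0)
    margin + sort(sample.int(usable - slot_len, n_elements)) else integer(0)
  # enforce pairwise distance
  if (n_elements > 1) {
    for (i in 2:n_elements)
      starts[i] <- max(starts[i], starts[i - 1] + slot_len)
  }
  el <- 0L

  plant <- function(segment, at, minus) {
    seg <- to_dna(segment)
    if (minus) seg <- revcomp_chr(seg)
    seg <- strsplit(seg, "")[[1]]
    genome[at:(at + length(seg) - 1L)] <<- seg
    c(at - 1L, at - 1L + length(seg)) # 0-based half-open
  }

  make_codons <- function(n) {
    codons <- expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                          c("T", "C", "A", "G"))
    codons <- apply(codons, 1, paste, collapse = "")
    stops <- c("TAA", "TAG", "TGA")
    ok <- setdiff(codons, stops)
    paste(sample(ok, n, replace = TRUE), collapse = "")
  }

  add_cds <- function(core, at, name) {
    # ATG + 35 codons + core (padded to frame) + 35 codons + stop
    pad <- (3L - nchar(core) %% 3L) %% 3L
    core_p <- paste0(core, paste(rep("A", pad), collapse = ""))
    cds <- paste0("ATG", make_codons(35L), core_p, make_codons(35L), "TAA")
    iv <- plant(cds, at, minus = FALSE)
    # six-frame peptides of the planted region feed the protein set
    peps <- six_frame_peptides(cds, 20L)
    for (k in seq_along(peps))
      proteins[[length(proteins) + 1L]] <<-
        seq_record(sprintf("%s_pep%d", name, k), peps[[k]])
    iv
  }

  # clean hairpin loci
  for (i in seq_len(n_loci)) {
    el <- el + 1L
    mat <- paste(rand_bases(21L, 0.55), collapse = "")
    hp <- make_hairpin(mat, hairpin_params(loop_size = 6L, lower_stem = 12L),
                       seed = seed * 1000L + el)
    minus <- runif(1) < minus_strand_fraction
    iv <- plant(hp$precursor$seq, starts[el], minus)
    nm <- sprintf("mir%03d", i)
    mirnas[[length(mirnas) + 1L]] <- seq_record(nm, to_dna(mat))
    stemloops[[length(stemloops) + 1L]] <-
      seq_record(paste0(nm, "_stemloop"), to_dna(hp$precursor$seq))
    truth[[length(truth) + 1L]] <- tibble(
      type = "mirna_locus", name = nm, start = iv[1], end = iv[2],
      strand = if (minus) "-" else "+", mature = mat)
  }
  # coding regions embedding a hairpin homolog
  for (i in seq_len(n_cds)) {
    el <- el + 1L
    mat <- paste(rand_bases(21L, 0.55), collapse = "")
    hp <- make_hairpin(mat, hairpin_params(loop_size = 6L, lower_stem = 12L),
                       seed = seed * 2000L + el)
    nm <- sprintf("cdsmir%03d", i)
    iv <- add_cds(to_dna(hp$precursor$seq), starts[el], nm)
    mirnas[[length(mirnas) + 1L]] <- seq_record(nm, to_dna(mat))
    truth[[length(truth) + 1L]] <- tibble(
      type = "cds_hairpin", name = nm, start = iv[1], end = iv[2],
      strand = "+", mature = mat)
  }
  # decoys: guide is an exact 18-19 nt substring of a 24-nt mature
  for (i in seq_len(n_decoys)) {
    el <- el + 1L
    mat24 <- paste(rand_bases(24L, 0.55), collapse = "")
    core_len <- if (i %% 2L == 0L) 18L else 19L # dissimilarity 6 or 5
    guide <- substr(mat24, 1L, core_len)
    hp <- make_hairpin(guide, hairpin_params(loop_size = 4L, lower_stem = 6L),
                       seed = seed * 3000L + el)
    # ensure the alignment cannot extend past the planted core: the two
    # bases 3' of the core inside the hairpin must mismatch the query tail
    pre <- hp$precursor$seq
    gpos <- regexpr(guide, pre, fixed = TRUE)[1]
    tail2 <- strsplit(substr(mat24, core_len + 1L, core_len + 2L), "")[[1]]
    for (k in 1:2) {
      at <- gpos + core_len - 1L + k
      if (at <= nchar(pre)) {
        cur <- substr(pre, at, at)
        if (cur == tail2[k])
          substr(pre, at, at) <- nonpairing_base(tail2[k])
      }
    }
    nm <- sprintf("decoysrc%03d", i)
    iv <- add_cds(to_dna(pre), starts[el], nm)
    mirnas[[length(mirnas) + 1L]] <- seq_record(nm, to_dna(mat24))
    truth[[length(truth) + 1L]] <- tibble(
      type = "decoy", name = nm, start = iv[1], end = iv[2],
      strand = "+", mature = mat24)
  }
  for (i in seq_len(n_rfam)) {
    rfam[[length(rfam) + 1L]] <-
      seq_record(sprintf("trna%02d", i),
                 paste(sample(c("A", "C", "G", "T"), 76L, replace = TRUE),
                       collapse = ""))
  }
  list(genome = list(seq_record("chr1", paste(genome, collapse = ""))),
       mirnas = mirnas, stemloops = stemloops, proteins = proteins,
       rfam = rfam,
       truth = if (length(truth)) dplyr::bind_rows(truth) else
         tibble(type = character(), name = character(), start = integer(),
                end = integer(), strand = character(), mature = character()))
}

#' Generate a labelled synthetic feature table
#'
#' Two multivariate Gaussian clusters over the 170-feature schema,
#' separated by `class_sep` along a random unit direction, with label-noise
#' rate `noise`.
#'
#' @param n_per_class Rows per class (at least 10).
#' @param class_sep Separation between class means (in sd units).
#' @param noise Label-flip probability.
#' @param seed Integer seed.
#' @return A tibble: `label` (0/1) plus the 170 schema-named features.
#' @export
make_feature_table <- function(n_per_class = 1000L, class_sep = 6,
                               noise = 0, seed = 1L) {
  if (n_per_class < 10L) abort_argument("n_per_class must be at least 10")
  set.seed(seed)
  sc <- feature_schema()
  d <- nrow(sc)
  u <- rnorm(d); u <- u / sqrt(sum(u^2))
  X0 <- matrix(rnorm(n_per_class * d), n_per_class, d)
  X1 <- matrix(rnorm(n_per_class * d), n_per_class, d) +
    matrix(class_sep * u, n_per_class, d, byrow = TRUE)
  X <- rbind(X0, X1)
  colnames(X) <- sc$name
  y <- rep(c(0L, 1L), each = n_per_class)
  if (noise > 0) {
    flip <- runif(length(y)) < noise
    y[flip] <- 1L - y[flip]
  }
  dplyr::bind_cols(tibble(label = y), as_tibble(X))
}
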