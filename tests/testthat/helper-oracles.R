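# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# dissimilarity recount straight from an alignment trace:
# unaligned query nt + gap columns + mismatch columns
oracle_ld <- function(qaln, saln, Q) {
  qa <- strsplit(qaln, "")[[1]]
  sa <- strsplit(saln, "")[[1]]
  qbases <- sum(qa != "-")
  gaps <- sum(qa == "-") + sum(sa == "-")
  eq <- function(a, b) chartr("T", "U", a) == chartr("T", "U", b)
  mism <- sum(qa != "-" & sa != "-" & !eq(qa, sa))
  (Q - qbases) + gaps + mism
}

# per-position structural classification by direct scanning of the pair
# table (independent of structure_elements)
oracle_position_kinds <- function(p) {
  L <- length(p)
  kinds <- character(L)
  enclosing <- function(i) {
    best <- NULL; bw <- Inf
    for (a in seq_len(L)) {
      b <- p[a]
      if (b > a && a < i && i < b && (b - a) < bw) { best <- c(a, b); bw <- b - a }
    }
    best
  }
  children_of <- function(a, b) {
    ch <- list(); k <- a + 1
    while (k < b) {
      if (p[k] > k) { ch[[length(ch) + 1]] <- c(k, p[k]); k <- p[k] + 1 }
      else k <- k + 1
    }
    ch
  }
  for (i in seq_len(L)) {
    if (p[i] != 0) { kinds[i] <- "stem"; next }
    enc <- enclosing(i)
    if (is.null(enc)) { kinds[i] <- "exterior"; next }
    # the loop owning i is closed by the innermost enclosing pair whose
    # direct interior contains i (not hidden inside a child helix)
    ch <- children_of(enc[1], enc[2])
    nk <- length(ch)
    if (nk == 0) kinds[i] <- "hairpin_loop"
    else if (nk >= 2) kinds[i] <- "multiloop"
    else {
      unp <- setdiff((enc[1] + 1):(enc[2] - 1), ch[[1]][1]:ch[[1]][2])
      left <- sum(unp < ch[[1]][1]); right <- sum(unp > ch[[1]][2])
      kinds[i] <- if (left > 0 && right > 0) "internal_loop" else "bulge"
    }
  }
  kinds
}

# implementation's position -> kind mapping
impl_position_kinds <- function(structure) {
  els <- decompose(structure)
  kinds <- character(nchar(structure$seq))
  for (e in els) kinds[e$positions] <- e$kind
  kinds
}

# exhaustive enumeration of all nested pairings of a short sequence,
# returning the maximum attainable pair weight (oracle for the reference
# folder's DP); min hairpin loop 3
oracle_max_weight <- function(seq, wGC = 3, wAU = 2, wGU = 1) {
  b <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  w <- function(x, y) {
    k <- paste0(b[x], b[y])
    if (k %in% c("GC", "CG")) wGC
    else if (k %in% c("AU", "UA")) wAU
    else if (k %in% c("GU", "UG")) wGU
    else -Inf
  }
  memo <- new.env()
  best <- function(i, j) {
    if (j - i < 4) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- best(i, j - 1)
    for (k in i:(j - 4)) {
      wk <- w(k, j)
      if (is.finite(wk)) {
        left <- if (k - 1 >= i) best(i, k - 1) else 0
        inner <- if (k + 1 <= j - 1) best(k + 1, j - 1) else 0
        res <- max(res, left + inner + wk)
      }
    }
    memo[[key]] <- res
    res
  }
  best(1, length(b))
}

# confusion-matrix recount and O(n^2) pairwise AUC
oracle_metrics <- function(labels, scores, threshold = 0.5) {
  y <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  fp <- sum(pred & !y); fn <- sum(!pred & y)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(accuracy = (tp + tn) / length(y),
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       precision = tp / (tp + fp),
       f1 = 2 * tp / (2 * tp + fp + fn),
       mcc = (tp * tn - fp * fn) /
         (sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)),
       auc = mean(cmp))
}

# valid random structures for property tests: fold random sequences with
# the deterministic reference folder
random_structures <- function(n, L = 40, seed = 1) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    s <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
    st <- fold_all(s, engine = "reference")[[1]]
    out[[length(out) + 1]] <- st
  }
  out
}

ct_text_hairpin <- paste(
  "9  dG = -1.2  fixture",
  "1 G 0 2 9 1",
  "2 G 1 3 8 2",
  "3 G 2 4 7 3",
  "4 A 3 5 0 4",
  "5 A 4 6 0 5",
  "6 A 5 7 0 6",
  "7 C 6 8 3 7",
  "8 C 7 9 2 8",
  "9 C 8 0 1 9", sep = "\n")
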