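# End-to-end orchestration: homology search, window selection, annotation
# screening, folding, qualification, feature extraction, classification and
# the final rule-based validation, with stage-by-stage attrition accounting.

#' Pipeline configuration
#'
#' Every threshold of the pipeline with its default: maximum level of
#' dissimilarity 3, expectation value 0.001, 200-nt flanks, redundancy
#' identity 0.9, the rule-engine thresholds of [rule_config()], decision
#' threshold 0.5.
#'
#' @param genome,mirnas,proteins,rfam Inputs: lists of `seq_record`s or
#'   FASTA paths. `proteins`/`rfam` may be empty lists (filters pass).
#' @param model `NULL` (rule-based only) or a trained `pm_mlp`.
#' @param ld_max,evalue_max Prediction-mode hit selection.
#' @param flank Window flank per side, nt.
#' @param identity Redundancy-removal threshold.
#' @param coding_evalue_max,rfam_identity,rfam_coverage Annotation filters.
#' @param fold_engine,align_engine Backends.
#' @param align [align_params()].
#' @param rules [rule_config()].
#' @param prob_threshold Classifier decision threshold.
#' @param max_structures Structures retained per window.
#' @param seed Seed echoed into the run log.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genome = NULL, mirnas = NULL, proteins = list(),
                            rfam = list(), model = NULL, ld_max = 3L,
                            evalue_max = 0.001, flank = 200L, identity = 0.9,
                            coding_evalue_max = 0.001, rfam_identity = 0.85,
                            rfam_coverage = 0.8, fold_engine = "auto",
                            align_engine = "internal",
                            align = align_params(), rules = rule_config(),
                            prob_threshold = 0.5, max_structures = 5L,
                            seed = 1L) {
  structure(list(genome = genome, mirnas = mirnas, proteins = proteins,
                 rfam = rfam, model = model, ld_max = as.integer(ld_max),
                 evalue_max = evalue_max, flank = as.integer(flank),
                 identity = identity, coding_evalue_max = coding_evalue_max,
                 rfam_identity = rfam_identity,
                 rfam_coverage = rfam_coverage, fold_engine = fold_engine,
                 align_engine = align_engine, align = align, rules = rules,
                 prob_threshold = prob_threshold,
                 max_structures = as.integer(max_structures),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

as_records <- function(x, what, alphabet = "nt") {
  if (is.null(x)) abort(paste0("missing pipeline input: ", what),
                        class = "plantmir_config_error")
  if (is.character(x) && length(x) == 1L) return(read_fasta(x, alphabet))
  x
}

#' Run the prediction pipeline
#'
#' Stages: homology search against both strands; hit selection
#' (`LD <= ld_max`, `E <= evalue_max`); flanked window extraction;
#' redundancy removal; protein-coding and rRNA/tRNA screening; secondary
#' structure prediction; structural qualification; feature extraction;
#' classification (skipped when no model is configured); star inference,
#' duplex statistics and the final rule engine. Zero candidates at any
#' stage produce an empty report with the attrition table, never an error.
#'
#' @param config A [pipeline_config()] with at least `genome` and `mirnas`.
#' @return A `pm_report`: `candidates` (tibble), `features` (tibble),
#'   `attrition` (tibble of per-stage window counts), `config`.
#' @export
run_pipeline <- function(config) {
  genome <- as_records(config$genome, "genome")
  mirnas <- as_records(config$mirnas, "mirnas")
  proteins <- if (is.character(config$proteins))
    read_fasta(config$proteins, "AA") else config$proteins
  rfam <- if (is.character(config$rfam)) read_fasta(config$rfam) else
    config$rfam
  att <- list()
  note <- function(stage, n) att[[length(att) + 1L]] <<-
    tibble(stage = stage, windows = as.integer(n))

  hits <- find_hits(mirnas, genome, config$align, config$align_engine)
  note("hits", nrow(hits))
  sel <- select_hits(hits, "prediction",
                     list(ld_max = config$ld_max,
                          evalue_max = config$evalue_max))
  note("selected_hits", nrow(sel))
  wins <- lapply(seq_len(nrow(sel)), function(i)
    extract_window(sel[i, ], genome, config$flank))
  note("windows", length(wins))
  if (length(wins)) {
    recs <- lapply(seq_along(wins), function(i)
      seq_record(paste0("w", i), wins[[i]]$seq))
    reps <- cluster_representatives(recs, config$identity)
    keep <- sort(as.integer(sub("^w", "", vapply(reps, function(r) r$id, ""))))
    wins <- wins[keep]
    sel <- sel[keep, , drop = FALSE]
  }
  note("nonredundant", length(wins))
  ids_all <- vapply(wins, window_id, "")
  wins2 <- coding_overlap_filter(wins, proteins, "drop_coding",
                                 config$coding_evalue_max)
  note("noncoding", length(wins2))
  wins2 <- rna_family_filter(wins2, rfam, config$rfam_identity,
                             config$rfam_coverage)
  note("non_rrna_trna", length(wins2))

  bcfg <- build_config(fold_engine = config$fold_engine,
                       rules = config$rules,
                       max_structures = config$max_structures)
  cand <- list(); featrows <- list()
  n_folded <- 0L; n_qual <- 0L; n_class <- 0L; n_final <- 0L
  for (w in wins2) {
    i <- match(window_id(w), ids_all)
    hit <- sel[i, ]
    structs <- tryCatch(fold_all(w$seq, config$fold_engine),
                        error = function(e) list())
    if (length(structs) > config$max_structures)
      structs <- structs[seq_len(config$max_structures)]
    if (!length(structs)) next
    n_folded <- n_folded + 1L
    any_q <- FALSE; any_c <- FALSE; any_f <- FALSE
    mir_span <- c(w$hit_start, w$hit_end)
    for (si in seq_along(structs)) {
      st <- structs[[si]]
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
        query_meta = list(query_length = hit$Q, ld = hit$ld,
                          evalue = hit$evalue, alignment_length = hit$Qa),
        genomic_meta = list(window = w$interval,
                            hit_start_in_window = w$hit_start,
                            n_structures = length(structs)),
        verdict = v)
      any_q <- TRUE
      prob <- if (is.null(config$model)) NA_real_ else
        predict_proba(config$model, feats)
      if (!is.na(prob) && prob < config$prob_threshold) next
      any_c <- TRUE
      rv <- apply_rules(stats, config$rules)
      if (!rv$accepted) next
      any_f <- TRUE
      pre <- c(min(stats$mir_span[1], stats$star_span[1]),
               max(stats$mir_span[2], stats$star_span[2]))
      iv <- w$interval
      if (iv$strand == "+") {
        g0 <- iv$start + pre[1] - 1L; g1 <- iv$start + pre[2]
      } else {
        g0 <- iv$end - pre[2]; g1 <- iv$end - pre[1] + 1L
      }
      cid <- sprintf("%s.s%d", window_id(w), si)
      cand[[length(cand) + 1L]] <- tibble(
        candidate_id = cid, window_id = window_id(w),
        query_id = hit$query_id, seq_id = iv$seq_id,
        precursor_start = g0, precursor_end = g1, strand = iv$strand,
        precursor_seq = substr(w$seq, pre[1], pre[2]),
        mature_seq = substr(w$seq, stats$mir_span[1], stats$mir_span[2]),
        structure_db = substr(dot_bracket(st), pre[1], pre[2]),
        window_seq = w$seq, window_db = dot_bracket(st),
        energy = st$energy, probability = prob, ld = hit$ld,
        evalue = hit$evalue, mature_len = stats$mir_len,
        precursor_len = stats$precursor_len, structure_index = si)
      featrows[[length(featrows) + 1L]] <-
        dplyr::bind_cols(tibble(candidate_id = cid), feats)
    }
    n_qual <- n_qual + any_q
    n_class <- n_class + any_c
    n_final <- n_final + any_f
  }
  note("folded", n_folded)
  note("qualified", n_qual)
  note("classified", n_class)
  note("final", n_final)
  candidates <- if (length(cand)) dplyr::bind_rows(cand) else tibble()
  if (nrow(candidates) > 0) {
    candidates <- candidates |>
      dplyr::group_by(window_id) |>
      dplyr::mutate(overlapping_in_window = dplyr::n() > 1L) |>
      dplyr::ungroup()
  }
  structure(list(candidates = candidates,
                 features = if (length(featrows))
                   dplyr::bind_rows(featrows) else tibble(),
                 attrition = dplyr::bind_rows(att), config = config),
            class = "pm_report")
}

#' @export
print.pm_report <- function(x, ...) {
  cat("<pm_report>\n")
  a <- x$attrition
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-14s %d\n", a$stage[i], a$windows[i]))
  cat(sprintf("  candidates: %d\n", nrow(x$candidates)))
  invisible(x)
}

#' @export
tidy.pm_report <- function(x, ...) x$candidates

#' @export
glance.pm_report <- function(x, ...) {
  a <- setNames(as.list(x$attrition$windows), x$attrition$stage)
  as_tibble(c(a, list(candidates = nrow(x$candidates))))
}

#' Write the pipeline report to disk
#'
#' Emits `precursors.fasta`, `matures.fasta`, `structures.ct`,
#' `structures.dbn`, `features.tsv`, `predictions.bed`, `attrition.tsv` and
#' `run_config.yaml` (config echo including all seeds). Outputs are
#' byte-stable for identical configs and seeds.
#'
#' @param report A `pm_report`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
emit_report <- function(report, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outdir, 2) != 0)
    abort(paste0("cannot write to output directory ", outdir),
          class = "plantmir_io_error")
  cd <- report$candidates
  n <- nrow(cd)
  pre_recs <- if (n) lapply(seq_len(n), function(i)
    seq_record(cd$candidate_id[i], cd$precursor_seq[i])) else list()
  mat_recs <- if (n) lapply(seq_len(n), function(i)
    seq_record(cd$candidate_id[i], cd$mature_seq[i])) else list()
  write_fasta(pre_recs, file.path(outdir, "precursors.fasta"))
  write_fasta(mat_recs, file.path(outdir, "matures.fasta"))
  ct_lines <- character(0)
  dbn_lines <- character(0)
  if (n) for (i in seq_len(n)) {
    st <- from_dot_bracket(to_rna(cd$precursor_seq[i]), cd$structure_db[i],
                           cd$energy[i])
    ct_lines <- c(ct_lines, sub("\n$", "", write_ct(st, title = cd$candidate_id[i])))
    dbn_lines <- c(dbn_lines, paste0(">", cd$candidate_id[i]),
                   to_rna(cd$precursor_seq[i]), cd$structure_db[i])
  }
  writeLines(ct_lines, file.path(outdir, "structures.ct"))
  writeLines(dbn_lines, file.path(outdir, "structures.dbn"))
  ivs <- if (n) lapply(seq_len(n), function(i)
    interval(cd$seq_id[i], cd$precursor_start[i], cd$precursor_end[i],
             cd$strand[i])) else list()
  write_bed(ivs, names = if (n) cd$candidate_id else character(0),
            scores = if (n) ifelse(is.na(cd$probability), 1, cd$probability)
            else numeric(0),
            path = file.path(outdir, "predictions.bed"))
  write.table(report$features, file.path(outdir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$attrition, file.path(outdir, "attrition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- report$config
  echo <- list(seed = cfg$seed, ld_max = cfg$ld_max,
               evalue_max = cfg$evalue_max, flank = cfg$flank,
               identity = cfg$identity,
               coding_evalue_max = cfg$coding_evalue_max,
               rfam_identity = cfg$rfam_identity,
               rfam_coverage = cfg$rfam_coverage,
               fold_engine = cfg$fold_engine,
               align_engine = cfg$align_engine,
               prob_threshold = cfg$prob_threshold,
               max_structures = cfg$max_structures,
               rules = unclass(cfg$rules))
  yaml::write_yaml(echo, file.path(outdir, "run_config.yaml"))
  invisible(outdir)
}

#' Plot per-fold evaluation metrics
#'
#' Registered as an `autoplot()` method when ggplot2 is installed; also
#' callable directly as `plot_metrics()`.
#'
#' @param object A `pm_metrics_report` from [kfold_cv()].
#' @param ... Unused.
#' @return A ggplot object (requires the ggplot2 package).
#' @exportS3Method ggplot2::autoplot
autoplot.pm_metrics_report <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort_argument("ggplot2 is required for autoplot")
  long <- tidyr_pivot(object$folds)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "per-fold value") +
    ggplot2::theme_minimal()
}

tidyr_pivot <- function(folds) {
  mcols <- c("accuracy", "sensitivity", "specificity", "precision", "f1",
             "mcc", "auc")
  out <- lapply(mcols, function(m)
    tibble(metric = m, value = folds[[m]]))
  dplyr::bind_rows(out)
}

#' @rdname autoplot.pm_metrics_report
#' @export
plot_metrics <- function(object, ...) autoplot.pm_metrics_report(object, ...)
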