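#' Deterministic per-stage sub-seed
#'
#' Fans the pipeline's master seed out to independent, reproducible
#' sub-seeds: a small string hash of the stage name is combined with the
#' master seed modulo 2^31 - 1, so each stage can be re-run in isolation.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return A positive integer seed below 2^31.
#' @export
stage_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(master) * 2654435 + h) %% 2147483647L + 1)
}

#' Balanced subsampling of grade groups
#'
#' Draws exactly `n` samples per requested grade, without replacement,
#' deterministically for a given seed (equal group sizes avoid class
#' imbalance in the classifier).
#'
#' @param samples a sample table.
#' @param grades grades to balance (default all three).
#' @param n samples per grade.
#' @param seed integer seed.
#' @return Character vector of selected sample ids.
#' @export
balance_groups <- function(samples, grades = c("G1", "G2", "G3"), n,
                           seed = 1L) {
  set.seed(as.integer(seed))
  out <- character()
  for (g in grades) {
    ids <- samples$sample_id[samples$grade == g]
    if (length(ids) < n) {
      stop(sprintf("grade %s has only %d samples (need %d)", g,
                   length(ids), n))
    }
    out <- c(out, sort(sample(ids, n)))
  }
  out
}

#' Run one combination approach end-to-end
#'
#' Executes the full pipeline on a cohort for one of the five feature-
#' selection approaches, then cross-validates the G1-vs-G3 SVM on the
#' selected features, re-classifies the G2 samples as G1*/G3*, retrains on
#' the reclassified labels, and compares relapse-free survival between the
#' original and reclassified groups.
#'
#' Approaches: `I` all SAM-called mRNAs; `II` the union of the stage-II
#' (expression x CNA) gene sets; `III` the stage-III gene signature
#' (expression x CNA x opposite-direction miRNA targets); `IV` the
#' stage-III miRNA signature, classified on the miRNA matrix; `V` the
#' stage-III signature downsized against reference signatures.
#'
#' @param cohort a `grade_cohort` (or an equivalently named list of
#'   artifacts loaded from disk).
#' @param approach `"I"` to `"V"`.
#' @param q q-value threshold for differential calls.
#' @param B permutations for the q-value null.
#' @param topk CNA top-frequency cutoff.
#' @param cna_mode copy-number encoding, `"absolute"` or `"log2ratio"`.
#' @param classifier a [classifier_config()].
#' @param references named list of reference signatures (approach V only).
#' @param balanced_n if non-NULL, subsample this many samples per grade
#'   first.
#' @param batch_mode batch harmonization mode (`"meanvar"`, `"eb"`, or
#'   `"none"`).
#' @param seed master seed; stage seeds derive from it via [stage_seed()].
#' @return object of class `approach_report`: `approach`, `features`,
#'   `de` (mRNA sam_de), `classes` (approach >= II), `cv`
#'   (performance_report), `reclass` (reclassification), `survival`
#'   (reclass_survival), `seed`.
#' @export
run_approach <- function(cohort, approach = c("I", "II", "III", "IV", "V"),
                         q = 0.01, B = 300L, topk = 6000L,
                         cna_mode = "absolute",
                         classifier = classifier_config(),
                         references = NULL, balanced_n = NULL,
                         batch_mode = c("meanvar", "eb", "none"),
                         seed = 1L) {
  approach <- match.arg(approach)
  batch_mode <- match.arg(batch_mode)
  if (approach == "V" && (is.null(references) || !length(references))) {
    stop("approach V requires at least one reference signature")
  }
  samples <- cohort$samples
  if (!is.null(balanced_n)) {
    ids <- balance_groups(samples, n = balanced_n,
                          seed = stage_seed(seed, "balance"))
    samples <- samples[samples$sample_id %in% ids, , drop = FALSE]
  }
  mrna <- cohort$mrna[, samples$sample_id, drop = FALSE]
  mrna <- expression_matrix(mrna, "mRNA")
  mirna <- cohort$mirna[, samples$sample_id, drop = FALSE]
  mirna <- expression_matrix(mirna, "miRNA")
  if (batch_mode != "none") {
    mrna <- batch_adjust(mrna, samples$batch, batch_mode)
    mirna <- batch_adjust(mirna, samples$batch, batch_mode)
  }

  de <- sam_de(mrna, samples, "G1", "G3", threshold = q, B = B,
               seed = stage_seed(seed, "sam_mrna"))
  classes <- NULL
  features <- NULL
  feature_matrix <- mrna
  if (approach == "I") {
    features <- sort(c(called_features(de, "up"), called_features(de, "down")))
  } else {
    cna_g1 <- cna_gene_sets(cohort$genes, cohort$segments, samples, "G1",
                            K = topk, mode = cna_mode)
    cna_g3 <- cna_gene_sets(cohort$genes, cohort$segments, samples, "G3",
                            K = topk, mode = cna_mode)
    s2 <- stage2_sets(de, cna_g1, cna_g3)
    if (approach == "II") {
      features <- sort(unique(unlist(s2)))
    } else {
      mirna_de <- sam_de(mirna, samples, "G1", "G3", threshold = q, B = B,
                         seed = stage_seed(seed, "sam_mirna"))
      classes <- stage3_classes(s2, mirna_de, cohort$targets)
      features <- switch(approach,
        III = classes$gene_signature,
        IV = classes$mirna_signature,
        V = downsize_signature(list(name = "stage3", genes =
                                      classes$gene_signature),
                               references)$genes)
      if (approach == "IV") feature_matrix <- mirna
    }
  }
  if (!length(features)) {
    stop("approach ", approach, " selected an empty feature set")
  }

  X <- t(unclass(feature_matrix)[features, , drop = FALSE])
  grade <- samples$grade
  g1g3 <- grade %in% c("G1", "G3")
  classifier$seed <- stage_seed(seed, "cv")
  cv <- cross_validate(X[g1g3, , drop = FALSE], grade[g1g3], classifier)
  reclass <- reclassify_g2(X[g1g3, , drop = FALSE], grade[g1g3],
                           X[grade == "G2", , drop = FALSE], classifier)
  surv <- compare_reclassified_groups(samples, reclass)
  structure(list(approach = approach, features = features, de = de,
                 classes = classes, cv = cv, reclass = reclass,
                 survival = surv, seed = seed),
            class = "approach_report")
}

#' @export
print.approach_report <- function(x, ...) {
  cat(sprintf("<approach_report> approach %s: %d features\n", x$approach,
              length(x$features)))
  print(x$cv)
  print(x$reclass)
  print(x$survival)
  invisible(x)
}

#' Run approaches I-V on one cohort
#'
#' @inheritParams run_approach
#' @param approaches which approaches to run (default all five; `V` is
#'   skipped with a message when no `references` are given).
#' @return named list of `approach_report`s, class `approach_set`.
#' @export
run_all_approaches <- function(cohort, approaches = c("I", "II", "III",
                                                      "IV", "V"), ...,
                               references = NULL) {
  if (is.null(references)) approaches <- setdiff(approaches, "V")
  reports <- lapply(approaches, function(a) {
    run_approach(cohort, a, references = references, ...)
  })
  names(reports) <- approaches
  structure(reports, class = "approach_set")
}

#' @export
print.approach_set <- function(x, ...) {
  cat(sprintf("<approach_set> %d approaches\n", length(x)))
  tab <- summary(x)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.approach_set <- function(object, ...) {
  do.call(rbind, lapply(object, function(r) {
    cm <- r$survival$comparisons[["G1*_vs_G3*"]]
    data.frame(approach = r$approach, n_features = length(r$features),
               cv_accuracy = r$cv$metrics$accuracy[["estimate"]],
               cv_auc = r$cv$metrics$auc[["estimate"]],
               n_g1_star = sum(r$reclass$assigned == "G1*"),
               n_g3_star = sum(r$reclass$assigned == "G3*"),
               logrank_p_g1s_g3s = if (cm$degenerate) NA_real_
                                   else cm$logrank_p,
               stringsAsFactors = FALSE)
  }))
}

#' Serialize an approach report (or set) to JSON
#'
#' Produces a deterministic JSON document (no timestamps) so re-running a
#' configuration byte-reproduces the report.
#'
#' @param x an `approach_report` or `approach_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(report_payload(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

report_payload <- function(x) {
  if (inherits(x, "approach_set")) {
    return(lapply(unclass(x), report_payload))
  }
  perf <- function(p) {
    if (is.null(p)) return(NULL)
    c(lapply(p$metrics, as.list),
      list(kernel = p$best_kernel, gamma = p$best_gamma, C = p$best_C,
           k_folds = p$k_folds))
  }
  list(
    approach = x$approach,
    seed = x$seed,
    n_features = length(x$features),
    features = as.list(x$features),
    s0 = x$de$s0,
    cv = perf(x$cv),
    reclassification = list(
      assigned = as.list(x$reclass$assigned),
      degenerate = x$reclass$degenerate,
      retrain = perf(x$reclass$retrain_report)),
    survival = lapply(x$survival$comparisons, function(cm) {
      cm[setdiff(names(cm), c("group_a", "group_b"))]
    }))
}
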