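#' Construct an expression matrix
#'
#' The central container for log2-scale expression data: a numeric matrix
#' with unique feature ids as rownames, unique sample ids as colnames, and a
#' declared feature kind (`"mRNA"` or `"miRNA"`). Values are assumed to be
#' already normalized (e.g. RMA) and on the log2 scale; no background
#' correction is performed here.
#'
#' @param values numeric matrix, rows = features, columns = samples, with
#'   dimnames set (or supplied via `feature_ids` / `sample_ids`).
#' @param feature_kind `"mRNA"` or `"miRNA"`.
#' @param feature_ids,sample_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @return An object of class `expr_matrix`: the numeric matrix with
#'   attribute `feature_kind`.
#' @export
expression_matrix <- function(values, feature_kind = c("mRNA", "miRNA"),
                              feature_ids = NULL, sample_ids = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (!is.null(feature_ids)) rownames(values) <- feature_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix requires feature and sample ids")
  }
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup)) {
    stop("duplicate feature id(s): ", paste(dup, collapse = ", "))
  }
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup)) {
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite")
  }
  structure(values, feature_kind = feature_kind,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d %s features x %d samples\n",
              nrow(x), attr(x, "feature_kind"), ncol(x)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `expr_matrix`.
#' @export
feature_kind <- function(x) attr(x, "feature_kind")

valid_grades <- c("G1", "G2", "G3")

#' Construct a sample annotation table
#'
#' Per-sample covariates used throughout the pipeline: histological grade,
#' batch (sub-cohort) label, relapse-free survival time in months, event
#' indicator, and - for synthetic cohorts only - the latent G1/G3 truth
#' label of each sample.
#'
#' @param sample_id character, unique.
#' @param grade character, each in `G1`/`G2`/`G3`.
#' @param batch character batch labels.
#' @param time non-negative relapse-free survival times (months).
#' @param event 0 (censored) or 1 (relapse).
#' @param latent_label optional character (`G1`/`G3` or `NA`), synthetic
#'   ground truth only.
#' @return A `data.frame` with one row per sample.
#' @export
sample_table <- function(sample_id, grade, batch, time, event,
                         latent_label = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  grade <- as.character(grade)
  bad <- setdiff(unique(grade), valid_grades)
  if (length(bad)) stop("unknown grade token(s): ", paste(bad, collapse = ", "))
  time <- as.numeric(time)
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("survival times must be finite and non-negative")
  }
  event <- as.numeric(event)
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  if (is.null(latent_label)) latent_label <- rep(NA_character_, length(sample_id))
  latent_label <- as.character(latent_label)
  bad <- setdiff(unique(latent_label[!is.na(latent_label)]), c("G1", "G3"))
  if (length(bad)) stop("latent_label must be G1/G3/NA, got: ",
                        paste(bad, collapse = ", "))
  data.frame(sample_id = sample_id, grade = grade,
             batch = as.character(batch), time = time, event = event,
             latent_label = latent_label, stringsAsFactors = FALSE)
}

#' Construct a gene model table
#'
#' Gene coordinates in the BED convention: 0-based, half-open intervals.
#' Strand is stored but ignored by all overlap logic (copy-number
#' alteration is strand-agnostic).
#'
#' @param gene character gene symbols, unique.
#' @param chrom chromosome names.
#' @param start,end integer coordinates, `0 <= start < end`, half-open.
#' @param strand `"+"`, `"-"` or `"."`.
#' @return A `data.frame` with columns gene, chrom, start, end, strand.
#' @export
gene_models <- function(gene, chrom, start, end, strand = ".") {
  gene <- as.character(gene)
  if (any(!nzchar(gene))) stop("blank gene symbol")
  if (anyDuplicated(gene)) {
    stop("duplicate gene id(s): ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0) || any(start >= end)) {
    stop("gene intervals require 0 <= start < end (0-based half-open)")
  }
  strand <- rep_len(as.character(strand), length(gene))
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  data.frame(gene = gene, chrom = as.character(chrom), start = start,
             end = end, strand = strand, stringsAsFactors = FALSE)
}

#' Construct a copy-number segment table
#'
#' SEG-style per-sample segmented copy number. Coordinates are 0-based
#' half-open (SEG files using 1-based inclusive coordinates must be
#' pre-converted). `copy_number` is on the scale declared downstream:
#' absolute copies (diploid = 2, the default interpretation) or log2 ratio.
#' Segments of one sample on one chromosome must not overlap.
#'
#' @param sample_id,chrom character vectors.
#' @param start,end integer, `0 <= start < end`, half-open.
#' @param copy_number non-negative numeric.
#' @return A `data.frame` sorted by (sample_id, chrom, start).
#' @export
segment_records <- function(sample_id, chrom, start, end, copy_number) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) && (any(start < 0) || any(start >= end))) {
    stop("segments require 0 <= start < end (0-based half-open)")
  }
  copy_number <- as.numeric(copy_number)
  if (any(!is.finite(copy_number))) stop("copy_number must be finite")
  df <- data.frame(sample_id = as.character(sample_id),
                   chrom = as.character(chrom),
                   start = start, end = end, copy_number = copy_number,
                   stringsAsFactors = FALSE)
  df <- df[order(df$sample_id, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  check_segment_overlaps(df)
  df
}

check_segment_overlaps <- function(df) {
  if (!nrow(df)) return(invisible(df))
  key <- paste(df$sample_id, df$chrom, sep = "\r")
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    if (nrow(sub) < 2L) next
    sub <- sub[order(sub$start), , drop = FALSE]
    bad <- which(sub$start[-1L] < sub$end[-nrow(sub)])
    if (length(bad)) {
      i <- bad[1L]
      stop(sprintf(
        "overlapping segments for sample %s on %s: [%d,%d) and [%d,%d)",
        sub$sample_id[1L], sub$chrom[1L],
        sub$start[i], sub$end[i], sub$start[i + 1L], sub$end[i + 1L]))
    }
  }
  invisible(df)
}

#' Construct a miRNA-to-target map
#'
#' @param pairs two-column data.frame (mirna, gene) or a named list of
#'   character vectors.
#' @return A named list: miRNA id -> sorted unique character vector of
#'   target gene symbols (possibly empty).
#' @export
target_map <- function(pairs) {
  if (is.data.frame(pairs)) {
    mirna <- as.character(pairs[[1L]])
    gene <- as.character(pairs[[2L]])
    if (any(!nzchar(mirna))) stop("empty miRNA id in target map")
    if (any(!nzchar(gene))) stop("blank gene symbol in target map")
    tm <- lapply(split(gene, mirna), function(g) sort(unique(g)))
  } else if (is.list(pairs)) {
    if (length(pairs) &&
        (is.null(names(pairs)) || any(!nzchar(names(pairs))))) {
      stop("empty miRNA id in target map")
    }
    tm <- lapply(pairs, function(g) sort(unique(as.character(g))))
  } else {
    stop("'pairs' must be a data.frame or named list")
  }
  if (!length(tm)) return(structure(list(), names = character()))
  tm[order(names(tm))]
}
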