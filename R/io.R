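#' Read and write the pipeline's on-disk formats
#'
#' All formats are UTF-8, tab-separated; lines starting with `#` are
#' ignored. Coordinates on disk follow the same convention as in memory:
#' 0-based half-open (BED-style). Readers validate invariants and never
#' silently drop rows.
#'
#' @param path file path.
#' @param feature_kind `"mRNA"` or `"miRNA"`.
#' @return `read_expression_matrix`: an [expression_matrix()].
#' @name gradeweaver-io
NULL

read_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines[!grepl("^#", lines) & nzchar(lines)]
}

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' @rdname gradeweaver-io
#' @export
read_expression_matrix <- function(path, feature_kind = c("mRNA", "miRNA")) {
  feature_kind <- match.arg(feature_kind)
  lines <- read_tsv_lines(path)
  if (!length(lines)) stop("missing header row in ", path)
  fields <- split_fields(lines)
  header <- fields[[1L]]
  if (length(header) < 2L) stop("missing header row (no sample columns) in ", path)
  sample_ids <- header[-1L]
  body <- fields[-1L]
  nfeat <- length(body)
  vals <- matrix(NA_real_, nrow = nfeat, ncol = length(sample_ids))
  ids <- character(nfeat)
  for (i in seq_len(nfeat)) {
    row <- body[[i]]
    if (length(row) != length(header)) {
      stop(sprintf("row %d of %s has %d fields, expected %d",
                   i, path, length(row), length(header)))
    }
    ids[i] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric value '%s' at row %d (feature %s), column %d of %s",
                   row[-1L][j], i, ids[i], j, path))
    }
    vals[i, ] <- v
  }
  expression_matrix(vals, feature_kind, feature_ids = ids,
                    sample_ids = sample_ids)
}

#' @rdname gradeweaver-io
#' @param x object to write (matching the reader's return type).
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(feature = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("feature", colnames(x)))
  invisible(path)
}

#' @rdname gradeweaver-io
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "grade", "batch", "time", "event")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("sample table missing column(s): ", paste(missing, collapse = ", "))
  }
  lat <- if ("latent_label" %in% names(df)) {
    ifelse(df$latent_label %in% c("", "NA"), NA_character_, df$latent_label)
  } else NULL
  sample_table(df$sample_id, df$grade, df$batch,
               as.numeric(df$time), as.numeric(df$event), lat)
}

#' @rdname gradeweaver-io
#' @export
write_sample_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gradeweaver-io
#' @export
read_segments <- function(path) {
  lines <- read_tsv_lines(path)
  if (!length(lines)) {
    return(segment_records(character(), character(), integer(), integer(),
                           numeric()))
  }
  fields <- split_fields(lines)
  # tolerate a SEG header line
  if (identical(tolower(fields[[1L]][1L]), "sample") ||
      identical(tolower(fields[[1L]][1L]), "sample_id")) {
    fields <- fields[-1L]
  }
  if (!length(fields)) {
    return(segment_records(character(), character(), integer(), integer(),
                           numeric()))
  }
  n <- length(fields)
  if (any(lengths(fields) < 5L)) {
    stop("SEG rows must have 5 fields: sample, chrom, start, end, copy_number")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:5))
  start <- suppressWarnings(as.integer(m[, 3L]))
  end <- suppressWarnings(as.integer(m[, 4L]))
  cn <- suppressWarnings(as.numeric(m[, 5L]))
  if (anyNA(start) || anyNA(end) || anyNA(cn)) {
    stop("non-numeric coordinate or copy_number in ", path)
  }
  segment_records(m[, 1L], m[, 2L], start, end, cn)
}

#' @rdname gradeweaver-io
#' @export
write_segments <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname gradeweaver-io
#' @export
read_gene_models <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[!grepl("^(track|browser)\\b", lines)]
  if (!length(lines)) {
    return(gene_models(character(), character(), integer(), integer()))
  }
  fields <- split_fields(lines)
  if (any(lengths(fields) < 4L)) stop("BED rows must have at least 4 fields")
  m <- lapply(fields, function(f) {
    c(f[1:4], if (length(f) >= 6L) f[6L] else ".")
  })
  m <- do.call(rbind, m)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start) || anyNA(end)) stop("non-integer BED coordinate in ", path)
  gene_models(m[, 4L], m[, 1L], start, end, m[, 5L])
}

#' @rdname gradeweaver-io
#' @export
write_gene_models <- function(x, path) {
  bed <- data.frame(x$chrom, x$start, x$end, x$gene, 0L, x$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname gradeweaver-io
#' @export
read_target_map <- function(path) {
  lines <- read_tsv_lines(path)
  if (!length(lines)) return(target_map(list()))
  fields <- split_fields(lines)
  if (any(lengths(fields) < 2L)) {
    stop("target map rows must be miRNA<TAB>gene")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:2))
  target_map(data.frame(mirna = m[, 1L], gene = m[, 2L],
                        stringsAsFactors = FALSE))
}

#' @rdname gradeweaver-io
#' @export
write_target_map <- function(x, path) {
  mirna <- rep(names(x), lengths(x))
  gene <- unlist(x, use.names = FALSE)
  if (!length(mirna)) {
    file.create(path)
    return(invisible(path))
  }
  utils::write.table(data.frame(mirna, gene), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
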