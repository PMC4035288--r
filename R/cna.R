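#' Classify a copy-number value as gain, loss or neutral
#'
#' Two encodings of segmented copy number are supported: `absolute`
#' (diploid = 2; default thresholds gain at CN >= 2.5, loss at CN <= 1.5)
#' and `log2ratio` (diploid = 0; gain at >= +0.3, loss at <= -0.3).
#'
#' @param copy_number numeric vector of segment values.
#' @param mode `"absolute"` or `"log2ratio"`.
#' @param gain_thr,loss_thr override the mode's default thresholds.
#' @return character vector: `"gain"`, `"loss"` or `"neutral"`.
#' @export
classify_segment <- function(copy_number, mode = c("absolute", "log2ratio"),
                             gain_thr = NULL, loss_thr = NULL) {
  mode <- match.arg(mode)
  if (is.null(gain_thr)) gain_thr <- if (mode == "absolute") 2.5 else 0.3
  if (is.null(loss_thr)) loss_thr <- if (mode == "absolute") 1.5 else -0.3
  if (gain_thr <= loss_thr) stop("gain_thr must exceed loss_thr")
  ifelse(copy_number >= gain_thr, "gain",
         ifelse(copy_number <= loss_thr, "loss", "neutral"))
}

#' Per-sample, per-gene alteration status
#'
#' A gene is gained (lost) in a sample iff its interval overlaps, by at
#' least one base in half-open coordinates, any segment of that sample
#' classified as gain (loss). A gene overlapping both a gain and a loss
#' segment in the same sample is marked `"conflict"` and excluded from
#' downstream frequency counts. Genes covered by no segment are neutral.
#' Overlap is computed with IRanges; strand is ignored.
#'
#' @param genes a gene model table ([gene_models()]).
#' @param segments a segment table ([segment_records()]).
#' @param mode,gain_thr,loss_thr passed to [classify_segment()].
#' @return character matrix genes x samples with entries in
#'   gain/loss/neutral/conflict. Samples are the distinct sample ids in
#'   `segments`.
#' @export
gene_alteration_status <- function(genes, segments,
                                   mode = c("absolute", "log2ratio"),
                                   gain_thr = NULL, loss_thr = NULL) {
  mode <- match.arg(mode)
  seg_class <- classify_segment(segments$copy_number, mode, gain_thr, loss_thr)
  samples <- unique(segments$sample_id)
  status <- matrix("neutral", nrow(genes), length(samples),
                   dimnames = list(genes$gene, samples))
  if (!nrow(segments) || !nrow(genes)) return(status)
  keep <- seg_class != "neutral"
  segs <- segments[keep, , drop = FALSE]
  seg_class <- seg_class[keep]
  if (!nrow(segs)) return(status)
  for (chr in unique(genes$chrom)) {
    gi <- which(genes$chrom == chr)
    si <- which(segs$chrom == chr)
    if (!length(gi) || !length(si)) next
    gr <- IRanges::IRanges(start = genes$start[gi] + 1L, end = genes$end[gi])
    sr <- IRanges::IRanges(start = segs$start[si] + 1L, end = segs$end[si])
    hits <- IRanges::findOverlaps(gr, sr)
    if (!length(hits)) next
    g <- gi[S4Vectors::queryHits(hits)]
    s <- si[S4Vectors::subjectHits(hits)]
    for (k in seq_along(g)) {
      row <- g[k]
      col <- match(segs$sample_id[s[k]], samples)
      cur <- status[row, col]
      new <- seg_class[s[k]]
      status[row, col] <-
        if (cur == "neutral") new
        else if (cur == new || cur == "conflict") cur
        else "conflict"
    }
  }
  status
}

#' Per-grade alteration frequencies
#'
#' Counts, over the samples of one histological grade, how often each gene
#' is gained or lost. Conflicted statuses are excluded from both counts.
#'
#' @param status genes x samples status matrix from
#'   [gene_alteration_status()].
#' @param samples a sample table.
#' @param grade the grade whose samples to count over. Samples of that
#'   grade absent from `status` (no segments at all) count as neutral.
#' @return data.frame(gene, gain_count, loss_count, n_samples, gain_freq,
#'   loss_freq).
#' @export
alteration_frequencies <- function(status, samples, grade) {
  ids <- samples$sample_id[samples$grade == grade]
  if (!length(ids)) stop("no samples of grade ", grade)
  present <- intersect(ids, colnames(status))
  sub <- status[, present, drop = FALSE]
  gain <- rowSums(sub == "gain")
  loss <- rowSums(sub == "loss")
  n <- length(ids)
  data.frame(gene = rownames(status), gain_count = unname(gain),
             loss_count = unname(loss), n_samples = n,
             gain_freq = unname(gain) / n, loss_freq = unname(loss) / n,
             stringsAsFactors = FALSE)
}

#' Select the most frequently altered genes
#'
#' Ranks genes by their dominant alteration frequency
#' `max(gain_freq, loss_freq)` (descending; ties broken by lexical gene
#' id), keeps the top `K` genes with any alteration, and assigns each to
#' the amplified set if `gain_freq >= loss_freq`, else to the deleted set.
#' If fewer than `K` genes carry any alteration, all of them are returned.
#'
#' @param freq an [alteration_frequencies()] table.
#' @param K number of genes to keep (default 6000).
#' @return list(amplified, deleted): disjoint character vectors.
#' @export
select_top_altered <- function(freq, K = 6000L) {
  if (K < 1L) stop("K must be at least 1")
  dom <- pmax(freq$gain_freq, freq$loss_freq)
  altered <- freq[dom > 0, , drop = FALSE]
  dom <- dom[dom > 0]
  ord <- order(-dom, altered$gene)
  keep <- altered[ord[seq_len(min(K, nrow(altered)))], , drop = FALSE]
  if (nrow(altered) < K) {
    message("only ", nrow(altered), " genes carry any alteration (K = ", K, ")")
  }
  amp <- keep$gain_freq >= keep$loss_freq
  list(amplified = sort(keep$gene[amp]), deleted = sort(keep$gene[!amp]))
}

#' Grade-specific amplified/deleted gene sets from segments
#'
#' Convenience wrapper chaining [gene_alteration_status()],
#' [alteration_frequencies()] and [select_top_altered()] for one grade.
#'
#' @inheritParams gene_alteration_status
#' @inheritParams alteration_frequencies
#' @inheritParams select_top_altered
#' @return list(amplified, deleted, frequencies).
#' @export
cna_gene_sets <- function(genes, segments, samples, grade, K = 6000L,
                          mode = c("absolute", "log2ratio"),
                          gain_thr = NULL, loss_thr = NULL) {
  ids <- samples$sample_id[samples$grade == grade]
  segs <- segments[segments$sample_id %in% ids, , drop = FALSE]
  status <- gene_alteration_status(genes, segs, mode, gain_thr, loss_thr)
  freq <- alteration_frequencies(status, samples, grade)
  sets <- select_top_altered(freq, K)
  c(sets, list(frequencies = freq))
}
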