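#' Configuration for the synthetic multi-omic cohort generator
#'
#' The generator emulates the statistical structure of a merged breast
#' cancer microarray study: three histological grade groups with balanced
#' sizes, G2 a latent mixture of G1-like and G3-like tumors, batch
#' (sub-cohort) location/scale effects, grade-associated copy-number
#' alterations at the informative genes, miRNAs anticorrelated with their
#' mRNA targets, and grade-dependent relapse hazards.
#'
#' Defaults mirror the balanced design the pipeline targets (78 samples per
#' grade group) with moderate effect and noise (`delta = 1.5`,
#' `noise_sd = 1` log2 units) and an exponential relapse model with a
#' four-fold hazard ratio between G3-like and G1-like tumors.
#'
#' @param n_g1,n_g2,n_g3 samples per histological grade.
#' @param n_genes,n_mirnas feature counts for the two expression matrices.
#' @param n_informative_up,n_informative_down genes planted up/down in
#'   latent-G3 samples.
#' @param delta planted expression effect size (log2 units).
#' @param noise_sd residual sd (log2 units).
#' @param batches data.frame with columns `label`, `shift_sd` (sd of the
#'   per-gene additive batch offset) and `scale` (multiplier on the
#'   residual sd). One row per sub-cohort.
#' @param cna_gain_freq,cna_loss_freq probability that an informative gene
#'   is gained/lost in a sample of the concordant latent grade.
#' @param targets_per_mirna informative genes targeted by each planted miRNA.
#' @param mirna_effect planted miRNA effect size (log2 units); planted
#'   miRNAs move opposite to their targets.
#' @param hazard_g1,hazard_g3 exponential relapse rates (per month) for
#'   latent G1 / G3 tumors.
#' @param censor_rate probability a subject is censored before the event.
#' @param g2_mixture_prop probability a G2 sample's latent label is G3.
#' @param seed integer RNG seed; the same seed reproduces the cohort
#'   byte-for-byte.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_g1 = 78, n_g2 = 78, n_g3 = 78,
                          n_genes = 2000, n_mirnas = 200,
                          n_informative_up = 50, n_informative_down = 50,
                          delta = 1.5, noise_sd = 1,
                          batches = data.frame(
                            label = c("b1", "b2", "b3"),
                            shift_sd = c(0.4, 0.4, 0.4),
                            scale = c(1, 1.15, 0.9)),
                          cna_gain_freq = 0.6, cna_loss_freq = 0.6,
                          targets_per_mirna = 5, mirna_effect = 1.5,
                          hazard_g1 = 0.01, hazard_g3 = 0.04,
                          censor_rate = 0.3, g2_mixture_prop = 0.5,
                          seed = 1L) {
  cfg <- list(n_g1 = as.integer(n_g1), n_g2 = as.integer(n_g2),
              n_g3 = as.integer(n_g3), n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas),
              n_informative_up = as.integer(n_informative_up),
              n_informative_down = as.integer(n_informative_down),
              delta = delta, noise_sd = noise_sd, batches = batches,
              cna_gain_freq = cna_gain_freq, cna_loss_freq = cna_loss_freq,
              targets_per_mirna = as.integer(targets_per_mirna),
              mirna_effect = mirna_effect, hazard_g1 = hazard_g1,
              hazard_g3 = hazard_g3, censor_rate = censor_rate,
              g2_mixture_prop = g2_mixture_prop, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_g1 >= 0, n_g2 >= 0, n_g3 >= 0, n_genes >= 1, n_mirnas >= 0,
              n_informative_up >= 0, n_informative_down >= 0,
              noise_sd >= 0, targets_per_mirna >= 1,
              hazard_g1 > 0, hazard_g3 > 0)
    if (n_informative_up + n_informative_down > n_genes) {
      stop("n_informative_up + n_informative_down exceeds n_genes")
    }
    for (p in c(cna_gain_freq, cna_loss_freq, censor_rate, g2_mixture_prop)) {
      if (p < 0 || p > 1) stop("rates/probabilities must lie in [0, 1]")
    }
  })
  if (!is.data.frame(cfg$batches) ||
      !all(c("label", "shift_sd", "scale") %in% names(cfg$batches)) ||
      nrow(cfg$batches) < 1L) {
    stop("'batches' must be a data.frame with label, shift_sd, scale")
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic multi-omic cohort
#'
#' Draws mRNA and miRNA expression, per-sample copy-number segments, sample
#' annotation with relapse-free survival, a toy genome (one chromosome,
#' gene `i` occupying `[i*1000, i*1000 + 500)`), a miRNA target map, and a
#' ground-truth record for recovery tests.
#'
#' The expression model for gene i in sample s is
#' `baseline_i + grade_effect(i, latent(s)) + batch_shift(batch(s), i) +
#' scale(batch(s)) * N(0, noise_sd^2)`. G2 samples draw their grade effect
#' from a latent label that is G3 with probability `g2_mixture_prop`.
#' Informative-up genes gain `+delta` in latent-G3 samples (and are
#' amplified there at rate `cna_gain_freq`, and deleted in latent-G1
#' samples at rate `cna_loss_freq`); informative-down genes mirror this.
#' Planted miRNAs partition the informative genes into target blocks and
#' move by `mirna_effect` in the direction opposite to their targets.
#' Relapse times are exponential with the latent grade's hazard; a subject
#' is censored with probability `censor_rate` at a Uniform(0, t) instant.
#'
#' @param config a [cohort_config()].
#' @return A list of class `grade_cohort` with elements `mrna`, `mirna`
#'   (expr_matrix), `segments`, `samples`, `genes` (data.frames),
#'   `targets` (target map), and `truth` (see Details).
#' @details `truth` holds `informative`: data.frame(gene, direction) of the
#'   planted genes ("up" = higher in G3); `mirna_direction`: data.frame
#'   (mirna, direction) of planted miRNAs (direction of change in G3);
#'   `latent`: per-sample latent labels; `cna_plan`: data.frame(gene,
#'   grade, type) of planted alterations.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  n <- config$n_g1 + config$n_g2 + config$n_g3
  grade <- rep(c("G1", "G2", "G3"), c(config$n_g1, config$n_g2, config$n_g3))
  sample_id <- sprintf("s%03d", seq_len(n))

  latent <- grade
  g2 <- which(grade == "G2")
  latent[g2] <- ifelse(stats::runif(length(g2)) < config$g2_mixture_prop,
                       "G3", "G1")

  nb <- nrow(config$batches)
  batch_idx <- rep_len(seq_len(nb), n)[sample.int(n)]
  batch <- config$batches$label[batch_idx]

  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  n_up <- config$n_informative_up
  n_dn <- config$n_informative_down
  up_genes <- genes[seq_len(n_up)]
  dn_genes <- genes[n_up + seq_len(n_dn)]

  baseline <- stats::runif(config$n_genes, 6, 10)
  effect <- matrix(0, config$n_genes, n)
  is_g3 <- latent == "G3"
  effect[seq_len(n_up), is_g3] <- config$delta
  effect[n_up + seq_len(n_dn), is_g3] <- -config$delta

  shift <- matrix(0, config$n_genes, nb)
  for (b in seq_len(nb)) {
    shift[, b] <- stats::rnorm(config$n_genes, 0,
                               config$batches$shift_sd[b])
  }
  noise <- matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
                  config$n_genes, n)
  noise <- sweep(noise, 2L, config$batches$scale[batch_idx], `*`)
  mrna_vals <- baseline + effect + shift[, batch_idx, drop = FALSE] + noise
  mrna <- expression_matrix(mrna_vals, "mRNA", feature_ids = genes,
                            sample_ids = sample_id)

  # planted miRNAs: consecutive blocks of informative genes as targets;
  # the miRNA moves opposite to its targets
  mirnas <- sprintf("mir%03d", seq_len(config$n_mirnas))
  plant_blocks <- function(gs) {
    if (!length(gs)) return(list())
    split(gs, ceiling(seq_along(gs) / config$targets_per_mirna))
  }
  blocks_up <- plant_blocks(up_genes)   # targets up-in-G3 -> miRNA down in G3
  blocks_dn <- plant_blocks(dn_genes)   # targets down-in-G3 -> miRNA up in G3
  n_planted <- length(blocks_up) + length(blocks_dn)
  if (n_planted > config$n_mirnas) {
    stop("n_mirnas too small for the planted target blocks")
  }
  planted_dir <- rep(c("down", "up"), c(length(blocks_up), length(blocks_dn)))
  targets <- c(blocks_up, blocks_dn)
  names(targets) <- mirnas[seq_len(n_planted)]
  # background miRNAs target random non-informative genes
  null_pool <- setdiff(genes, c(up_genes, dn_genes))
  for (m in mirnas[setdiff(seq_len(config$n_mirnas), seq_len(n_planted))]) {
    targets[[m]] <- sort(sample(null_pool,
                                min(config$targets_per_mirna,
                                    length(null_pool))))
  }
  targets <- target_map(targets)

  mirna_effect <- matrix(0, config$n_mirnas, n)
  rownames(mirna_effect) <- mirnas
  if (n_planted) {
    sgn <- ifelse(planted_dir == "up", 1, -1)
    mirna_effect[seq_len(n_planted), is_g3] <-
      matrix(sgn * config$mirna_effect, n_planted, sum(is_g3))
  }
  mirna_base <- stats::runif(config$n_mirnas, 4, 8)
  mirna_shift <- matrix(0, config$n_mirnas, nb)
  for (b in seq_len(nb)) {
    mirna_shift[, b] <- stats::rnorm(config$n_mirnas, 0,
                                     config$batches$shift_sd[b])
  }
  mirna_noise <- matrix(stats::rnorm(config$n_mirnas * n, 0, config$noise_sd),
                        config$n_mirnas, n)
  mirna_noise <- sweep(mirna_noise, 2L, config$batches$scale[batch_idx], `*`)
  mirna_vals <- mirna_base + mirna_effect +
    mirna_shift[, batch_idx, drop = FALSE] + mirna_noise
  mirna <- expression_matrix(mirna_vals, "miRNA", feature_ids = mirnas,
                             sample_ids = sample_id)

  # toy genome: one chromosome, gene i at [(i-1)*1000, (i-1)*1000 + 500)
  gene_start <- (seq_len(config$n_genes) - 1L) * 1000L
  genes_df <- gene_models(genes, "chr1", gene_start, gene_start + 500L)

  # planted CNA: up-in-G3 genes gained in latent-G3 / lost in latent-G1
  # samples; down-in-G3 genes the mirror image
  plan_rows <- function(gs, grade, type) {
    data.frame(gene = gs, grade = rep(grade, length(gs)),
               type = rep(type, length(gs)), stringsAsFactors = FALSE)
  }
  cna_plan <- rbind(
    plan_rows(up_genes, "G3", "gain"), plan_rows(up_genes, "G1", "loss"),
    plan_rows(dn_genes, "G3", "loss"), plan_rows(dn_genes, "G1", "gain"))
  seg <- list()
  gene_row <- match(cna_plan$gene, genes)
  for (s in seq_len(n)) {
    plan <- cna_plan[cna_plan$grade == latent[s], , drop = FALSE]
    rows <- gene_row[cna_plan$grade == latent[s]]
    freq <- ifelse(plan$type == "gain", config$cna_gain_freq,
                   config$cna_loss_freq)
    hit <- stats::runif(nrow(plan)) < freq
    if (!any(hit)) next
    seg[[length(seg) + 1L]] <- data.frame(
      sample_id = sample_id[s], chrom = "chr1",
      start = gene_start[rows[hit]], end = gene_start[rows[hit]] + 500L,
      copy_number = ifelse(plan$type[hit] == "gain", 3, 1))
  }
  seg <- if (length(seg)) do.call(rbind, seg) else
    data.frame(sample_id = character(), chrom = character(),
               start = integer(), end = integer(), copy_number = numeric())
  segments <- segment_records(seg$sample_id, seg$chrom, seg$start, seg$end,
                              seg$copy_number)

  rate <- ifelse(latent == "G3", config$hazard_g3, config$hazard_g1)
  t_event <- stats::rexp(n, rate)
  censored <- stats::runif(n) < config$censor_rate
  time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  event <- as.numeric(!censored)

  samples <- sample_table(sample_id, grade, batch, time, event,
                          ifelse(grade == "G2", latent, NA_character_))

  truth <- list(
    informative = data.frame(gene = c(up_genes, dn_genes),
                             direction = rep(c("up", "down"), c(n_up, n_dn)),
                             stringsAsFactors = FALSE),
    mirna_direction = data.frame(mirna = mirnas[seq_len(n_planted)],
                                 direction = planted_dir,
                                 stringsAsFactors = FALSE),
    latent = stats::setNames(latent, sample_id),
    cna_plan = cna_plan)

  structure(list(mrna = mrna, mirna = mirna, segments = segments,
                 samples = samples, genes = genes_df, targets = targets,
                 truth = truth, config = config),
            class = "grade_cohort")
}

#' @export
print.grade_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "<grade_cohort> %d samples (G1 %d / G2 %d / G3 %d), %d genes, %d miRNAs\n",
    "  %d planted informative genes, %d planted miRNAs, %d CNA segments\n"),
    nrow(x$samples), sum(x$samples$grade == "G1"),
    sum(x$samples$grade == "G2"), sum(x$samples$grade == "G3"),
    nrow(x$mrna), nrow(x$mirna), nrow(x$truth$informative),
    nrow(x$truth$mirna_direction), nrow(x$segments)))
  invisible(x)
}

#' Observed G3 - G1 mean differences at the planted informative genes
#'
#' Recovery-test helper: recomputes, per informative gene, the difference
#' between latent-G3 and latent-G1 group means so tests can check the
#' planted effect size was realized.
#'
#' @param matrix an `expr_matrix` produced by [generate_cohort()].
#' @param samples the cohort's sample table.
#' @param truth the cohort's truth record.
#' @return data.frame(gene, direction, observed_diff).
#' @export
empirical_effect_check <- function(matrix, samples, truth) {
  if (!all(samples$sample_id %in% colnames(matrix))) {
    stop("sample ids in 'samples' missing from the matrix")
  }
  if (!all(truth$informative$gene %in% rownames(matrix))) {
    stop("informative gene ids missing from the matrix")
  }
  latent <- truth$latent[samples$sample_id]
  m <- matrix[truth$informative$gene,
              samples$sample_id[latent == "G3"], drop = FALSE]
  g3 <- rowMeans(m)
  m <- matrix[truth$informative$gene,
              samples$sample_id[latent == "G1"], drop = FALSE]
  g1 <- rowMeans(m)
  data.frame(gene = truth$informative$gene,
             direction = truth$informative$direction,
             observed_diff = unname(g3 - g1), stringsAsFactors = FALSE)
}

#' Write all cohort artifacts to a directory
#'
#' @param cohort a `grade_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Writes mrna.tsv, mirna.tsv, segments.seg,
#'   samples.tsv, genes.bed, targets.tsv and truth.json.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$mrna, file.path(dir, "mrna.tsv"))
  write_expression_matrix(cohort$mirna, file.path(dir, "mirna.tsv"))
  write_segments(cohort$segments, file.path(dir, "segments.seg"))
  write_sample_table(cohort$samples, file.path(dir, "samples.tsv"))
  write_gene_models(cohort$genes, file.path(dir, "genes.bed"))
  write_target_map(cohort$targets, file.path(dir, "targets.tsv"))
  truth <- cohort$truth
  truth$latent <- as.list(truth$latent)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
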