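#' Moderated two-class statistic
#'
#' Per-feature relative difference `d_i = (mean_B - mean_A) / (s_i + s0)`
#' with the pooled standard error
#' `s_i = sqrt((1/n_A + 1/n_B) * (SS_A + SS_B) / (n_A + n_B - 2))`
#' (SS = within-class sum of squared deviations) and a "fudge factor" `s0`
#' that stabilizes `d` for low-variance features. "Up" means higher mean in
#' class B.
#'
#' @param x expression matrix (features x samples).
#' @param labels two-class vector aligned with the columns; the second
#'   level in sorted order (or of the factor) is class B.
#' @param s0 non-negative fudge factor.
#' @return list(d, s, constant) where `constant` flags features with
#'   `s_i + s0 == 0` (their d is set to 0).
#' @export
sam_statistic <- function(x, labels, s0 = 0) {
  parts <- sam_parts(x, labels)
  if (s0 < 0) stop("s0 must be non-negative")
  denom <- parts$s + s0
  constant <- denom == 0
  if (any(constant)) {
    warning(sum(constant), " feature(s) with s_i + s0 = 0: d set to 0")
  }
  d <- ifelse(constant, 0, parts$num / denom)
  list(d = unname(d), s = unname(parts$s), constant = unname(constant))
}

sam_parts <- function(x, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly 2 classes")
  if (length(labels) != ncol(x)) stop("one label per sample required")
  a <- labels == levels(labels)[1L]
  b <- labels == levels(labels)[2L]
  na <- sum(a); nb <- sum(b)
  if (na < 2L || nb < 2L) stop("each class needs at least 2 samples")
  xa <- x[, a, drop = FALSE]; xb <- x[, b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ss <- rowSums((xa - ma)^2) + rowSums((xb - mb)^2)
  s <- sqrt((1 / na + 1 / nb) * ss / (na + nb - 2L))
  list(num = mb - ma, s = s)
}

#' Choose the fudge factor s0
#'
#' Scans candidate values of `s0` over the alpha-percentiles
#' (alpha = 0, 5, ..., 100) of the per-feature pooled sd `s_i`. For each
#' candidate the features are binned into deciles of `s_i`, the median
#' absolute deviation of `d` is computed within each bin, and the candidate
#' minimizing the coefficient of variation of those MADs is returned (ties
#' go to the smallest alpha). This makes the spread of `d` roughly
#' independent of `s_i`.
#'
#' @inheritParams sam_statistic
#' @return The chosen `s0` (a value within `[min s_i, max s_i]`).
#' @export
choose_s0 <- function(x, labels) {
  parts <- sam_parts(x, labels)
  s <- parts$s
  if (all(s == 0)) stop("all features have zero pooled sd; cannot choose s0")
  alphas <- seq(0, 100, by = 5)
  cands <- stats::quantile(s, alphas / 100, names = FALSE, type = 7)
  br <- unique(stats::quantile(s, seq(0, 1, 0.1), names = FALSE))
  bins <- if (length(br) < 2L) factor(rep(1L, length(s)))
          else cut(s, breaks = br, include.lowest = TRUE)
  cvs <- vapply(cands, function(s0) {
    d <- ifelse(s + s0 == 0, 0, parts$num / (s + s0))
    mads <- tapply(d, bins, stats::mad)
    mads <- mads[!is.na(mads)]
    m <- mean(mads)
    if (m == 0) Inf else stats::sd(mads) / m
  }, numeric(1))
  cands[which.min(cvs)]
}

#' Permutation q-values for SAM statistics
#'
#' Estimates per-feature false discovery rates from the permutation null of
#' `d`. For feature i,
#' `q_i = min(1, mean_b #\{j : |d*_jb| >= |d_i|\} / #\{j : |d_j| >= |d_i|\})`
#' with the null fraction pi0 fixed at 1 (conservative), followed by
#' monotone enforcement: q is non-decreasing as |d| decreases. The null
#' statistics `d*` are computed with the same `s0` on label permutations.
#'
#' @inheritParams sam_statistic
#' @param B number of label permutations, or `"all"` to enumerate every
#'   distinct assignment of class labels to samples (exact null for small
#'   cohorts).
#' @param seed integer seed for the permutation stream.
#' @return Numeric vector of q-values in `[0, 1]`.
#' @export
permutation_qvalues <- function(x, labels, s0, B = 300L, seed = 1L) {
  labels <- as.factor(labels)
  obs <- sam_statistic(x, labels, s0)
  n <- length(labels)
  na <- sum(labels == levels(labels)[1L])
  perms <- if (identical(B, "all")) {
    combos <- utils::combn(n, na)
    lapply(seq_len(ncol(combos)), function(k) combos[, k])
  } else {
    B <- as.integer(B)
    if (B < 1L) stop("B must be at least 1")
    rng <- local({
      set.seed(as.integer(seed))
      lapply(seq_len(B), function(b) sample.int(n)[seq_len(na)])
    })
    rng
  }
  abs_d <- abs(obs$d)
  ord <- order(abs_d, decreasing = TRUE)
  sorted <- abs_d[ord]
  # obs_count[i]: #{j : |d_j| >= |d_i|}
  obs_count <- findInterval(-sorted, -sorted)
  null_count <- numeric(length(sorted))
  lab_b <- levels(labels)[2L]
  for (p in perms) {
    perm_labels <- rep(lab_b, n)
    perm_labels[p] <- levels(labels)[1L]
    d_star <- sam_statistic(x, perm_labels, s0)$d
    # for each threshold |d_i| (descending), count permuted |d*| >= it
    ds <- sort(abs(d_star), decreasing = TRUE)
    null_count <- null_count + findInterval(-sorted, -ds)
  }
  q_sorted <- pmin(1, (null_count / length(perms)) / obs_count)
  q_sorted <- cummax(q_sorted)  # non-decreasing as |d| decreases
  q <- numeric(length(sorted))
  q[ord] <- q_sorted
  q
}

#' Directional significance calls
#'
#' A feature is called `up` if `q < threshold` and `d > 0`, `down` if
#' `q < threshold` and `d < 0`, else `ns`.
#'
#' @param d,q aligned numeric vectors.
#' @param threshold q-value cutoff (default 0.01).
#' @return character vector of calls.
#' @export
call_differential <- function(d, q, threshold = 0.01) {
  if (length(d) != length(q)) stop("d and q must have the same length")
  ifelse(q < threshold & d > 0, "up",
         ifelse(q < threshold & d < 0, "down", "ns"))
}

#' Two-class differential expression with permutation FDR
#'
#' The module's fitting entry point: given an expression matrix and sample
#' annotation, contrasts two grade classes with the moderated statistic,
#' automatic fudge-factor selection, permutation q-values, and directional
#' calls at a q-value threshold. `"up"` means higher mean expression in
#' `class_b`.
#'
#' @param x an `expr_matrix`.
#' @param samples a sample table ([sample_table()]); only samples of the
#'   two contrasted grades are used.
#' @param class_a,class_b the two grade labels to contrast (direction
#'   convention: "up" = higher in `class_b`).
#' @param threshold q-value cutoff for calls.
#' @param B permutations (or `"all"`).
#' @param s0 fudge factor; `NULL` (default) selects it with [choose_s0()].
#' @param seed permutation seed.
#' @return An object of class `sam_de`: a list with `table`
#'   (data.frame feature, d, s, q, call), `s0`, `B`, `seed`, `contrast`.
#' @export
sam_de <- function(x, samples, class_a, class_b, threshold = 0.01,
                   B = 300L, s0 = NULL, seed = 1L) {
  if (class_a == class_b) stop("contrast classes must differ")
  keep <- samples$grade %in% c(class_a, class_b)
  ids <- samples$sample_id[keep]
  ids <- ids[ids %in% colnames(x)]
  if (!length(ids)) stop("no samples of the contrasted grades in the matrix")
  xx <- unclass(x)[, ids, drop = FALSE]
  grade <- samples$grade[match(ids, samples$sample_id)]
  labels <- factor(grade, levels = c(class_a, class_b))
  if (is.null(s0)) s0 <- choose_s0(xx, labels)
  st <- sam_statistic(xx, labels, s0)
  q <- permutation_qvalues(xx, labels, s0, B = B, seed = seed)
  q[st$constant] <- 1
  call <- call_differential(st$d, q, threshold)
  structure(list(
    table = data.frame(feature = rownames(x), d = st$d, s = st$s, q = q,
                       call = call, stringsAsFactors = FALSE),
    s0 = s0, B = B, seed = seed, threshold = threshold,
    contrast = c(class_a = class_a, class_b = class_b)),
    class = "sam_de")
}

#' @export
print.sam_de <- function(x, ...) {
  tab <- table(factor(x$table$call, levels = c("up", "down", "ns")))
  cat(sprintf(
    "<sam_de> %s vs %s: %d features, s0 = %.4g, B = %s, q < %g\n  up %d / down %d / ns %d\n",
    x$contrast[["class_a"]], x$contrast[["class_b"]], nrow(x$table), x$s0,
    format(x$B), x$threshold, tab[["up"]], tab[["down"]], tab[["ns"]]))
  invisible(x)
}

#' @export
summary.sam_de <- function(object, ...) {
  tab <- object$table
  tab <- tab[tab$call != "ns", , drop = FALSE]
  tab[order(tab$q, -abs(tab$d)), , drop = FALSE]
}

#' Features called in a given direction
#'
#' @param de a `sam_de` object.
#' @param direction `"up"` or `"down"` (relative to `class_b`).
#' @return Character vector of feature ids.
#' @export
called_features <- function(de, direction) {
  stopifnot(inherits(de, "sam_de"), direction %in% c("up", "down"))
  de$table$feature[de$table$call == direction]
}

#' Overlap between the calls of two contrasts
#'
#' For each direction of contrast `x`, the fraction of its called features
#' contained in each direction of contrast `y` (both same-direction and
#' cross-direction containment), mirroring the comparison of the G1-vs-G2 /
#' G2-vs-G3 call sets against the G1-vs-G3 calls.
#'
#' @param x,y `sam_de` objects over the same feature universe.
#' @return data.frame(x_direction, y_direction, n_x, n_overlap, fraction);
#'   `fraction` is `NA` when `x` has no calls in that direction.
#' @export
compare_contrast_overlap <- function(x, y) {
  fx <- sort(x$table$feature); fy <- sort(y$table$feature)
  if (!length(intersect(fx, fy))) stop("disjoint feature universes")
  if (!identical(fx, fy)) stop("contrasts must share the same feature universe")
  out <- expand.grid(x_direction = c("up", "down"),
                     y_direction = c("up", "down"),
                     stringsAsFactors = FALSE)
  out$n_x <- NA_integer_; out$n_overlap <- NA_integer_
  for (i in seq_len(nrow(out))) {
    sx <- called_features(x, out$x_direction[i])
    sy <- called_features(y, out$y_direction[i])
    out$n_x[i] <- length(sx)
    out$n_overlap[i] <- length(intersect(sx, sy))
  }
  out$fraction <- ifelse(out$n_x > 0, out$n_overlap / out$n_x, NA_real_)
  out
}
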