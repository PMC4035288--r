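# Independent brute-force oracles used to check the package's vectorized
# implementations. Deliberately written as plain per-element loops.

# Moderated statistic, one feature at a time, straight from the formula.
oracle_sam_d <- function(x, labels, s0) {
  labels <- as.factor(labels)
  a <- which(labels == levels(labels)[1]); b <- which(labels == levels(labels)[2])
  d <- s <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    xa <- x[i, a]; xb <- x[i, b]
    ssq <- sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)
    s[i] <- sqrt((1 / length(xa) + 1 / length(xb)) * ssq /
                   (length(xa) + length(xb) - 2))
    d[i] <- if (s[i] + s0 == 0) 0 else (mean(xb) - mean(xa)) / (s[i] + s0)
  }
  list(d = d, s = s)
}

# Exhaustive-permutation q-values: every distinct assignment of class-A
# labels, counted pair by pair, then the running-max monotone pass.
oracle_perm_q <- function(x, labels, s0) {
  labels <- as.factor(labels)
  n <- length(labels); na <- sum(labels == levels(labels)[1])
  obs <- abs(oracle_sam_d(x, labels, s0)$d)
  combos <- utils::combn(n, na)
  nulls <- matrix(NA_real_, nrow(x), ncol(combos))
  for (k in seq_len(ncol(combos))) {
    lab <- rep(levels(labels)[2], n)
    lab[combos[, k]] <- levels(labels)[1]
    nulls[, k] <- abs(oracle_sam_d(x, lab, s0)$d)
  }
  q <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    null_ge <- 0
    for (k in seq_len(ncol(combos))) null_ge <- null_ge + sum(nulls[, k] >= obs[i])
    obs_ge <- sum(obs >= obs[i])
    q[i] <- min(1, (null_ge / ncol(combos)) / obs_ge)
  }
  ord <- order(obs, decreasing = TRUE)
  qs <- q[ord]
  for (i in seq_along(qs)[-1]) qs[i] <- max(qs[i], qs[i - 1])
  q[ord] <- qs
  q
}

# Quadratic all-pairs gene/segment overlap scan (half-open intervals).
oracle_alteration_status <- function(genes, segments, gain_thr = 2.5,
                                     loss_thr = 1.5) {
  samples <- unique(segments$sample_id)
  status <- matrix("neutral", nrow(genes), length(samples),
                   dimnames = list(genes$gene, samples))
  for (gi in seq_len(nrow(genes))) {
    for (si in seq_len(nrow(segments))) {
      if (genes$chrom[gi] != segments$chrom[si]) next
      if (genes$start[gi] >= segments$end[si]) next
      if (segments$start[si] >= genes$end[gi]) next
      cls <- if (segments$copy_number[si] >= gain_thr) "gain"
             else if (segments$copy_number[si] <= loss_thr) "loss"
             else next
      col <- match(segments$sample_id[si], samples)
      cur <- status[gi, col]
      status[gi, col] <- if (cur == "neutral") cls
                         else if (cur == cls || cur == "conflict") cur
                         else "conflict"
    }
  }
  status
}

# Per-gene predicate scan for the stage-II sets.
oracle_stage2 <- function(universe, up_g3, dn_g3, amp_g1, del_g1, amp_g3,
                          del_g3) {
  res <- list(up_amplified_g3 = character(), down_deleted_g3 = character(),
              up_amplified_g1 = character(), down_deleted_g1 = character())
  for (g in universe) {
    if (g %in% up_g3 && g %in% amp_g3)
      res$up_amplified_g3 <- c(res$up_amplified_g3, g)
    if (g %in% dn_g3 && g %in% del_g3)
      res$down_deleted_g3 <- c(res$down_deleted_g3, g)
    if (g %in% dn_g3 && g %in% amp_g1)
      res$up_amplified_g1 <- c(res$up_amplified_g1, g)
    if (g %in% up_g3 && g %in% del_g1)
      res$down_deleted_g1 <- c(res$down_deleted_g1, g)
  }
  lapply(res, sort)
}

# Exhaustive (gene, miRNA, class) triple enumeration for stage III.
oracle_stage3 <- function(stage2, up_mir, dn_mir, targets) {
  spec <- list(class1 = list(genes = stage2$down_deleted_g3, mirs = up_mir),
               class2 = list(genes = stage2$up_amplified_g1, mirs = up_mir),
               class3 = list(genes = stage2$up_amplified_g3, mirs = dn_mir),
               class4 = list(genes = stage2$down_deleted_g1, mirs = dn_mir))
  lapply(spec, function(cl) {
    genes <- character(); mirs <- character()
    for (g in cl$genes) for (m in cl$mirs) {
      if (m %in% names(targets) && g %in% targets[[m]]) {
        genes <- c(genes, g); mirs <- c(mirs, m)
      }
    }
    list(genes = sort(unique(genes)), mirnas = sort(unique(mirs)))
  })
}

# Log-rank O/E/V tabulation over the pooled distinct event times.
oracle_logrank <- function(times_a, events_a, times_b, events_b) {
  times <- c(times_a, times_b); events <- c(events_a, events_b)
  grp <- rep(c(1, 2), c(length(times_a), length(times_b)))
  event_times <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (t in event_times) {
    n1 <- sum(times[grp == 1] >= t); n2 <- sum(times[grp == 2] >= t)
    d1 <- sum(times_a == t & events_a == 1)
    d2 <- sum(times_b == t & events_b == 1)
    n <- n1 + n2; d <- d1 + d2
    if (n < 1) next
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# Breslow partial log-likelihood, maximized over a beta grid.
oracle_cox_grid <- function(times, events, x, betas = seq(-5, 5, by = 1e-4)) {
  loglik <- function(beta) {
    ll <- 0
    for (t in sort(unique(times[events == 1]))) {
      dead <- which(times == t & events == 1)
      risk <- which(times >= t)
      ll <- ll + beta * sum(x[dead]) -
        length(dead) * log(sum(exp(beta * x[risk])))
    }
    ll
  }
  vals <- vapply(betas, loglik, numeric(1))
  betas[which.max(vals)]
}

# One-step EB location/scale estimates, per gene and batch, plain loops.
oracle_eb_effects <- function(vals, batches) {
  levels <- unique(batches)
  G <- nrow(vals); n <- ncol(vals)
  alpha <- numeric(G); sigma2 <- numeric(G)
  for (g in seq_len(G)) {
    mns <- sapply(levels, function(b) mean(vals[g, batches == b]))
    nbs <- sapply(levels, function(b) sum(batches == b))
    alpha[g] <- sum(mns * nbs) / n
    ssq <- 0
    for (b in seq_along(levels)) {
      xb <- vals[g, batches == levels[b]]
      ssq <- ssq + sum((xb - mns[b])^2)
    }
    sigma2[g] <- ssq / n
  }
  z <- (vals - alpha) / sqrt(sigma2)
  out <- list()
  for (b in levels) {
    cols <- batches == b
    nb <- sum(cols)
    g_hat <- apply(z[, cols, drop = FALSE], 1, mean)
    d_hat <- apply(z[, cols, drop = FALSE], 1, var)
    g_bar <- mean(g_hat); t2 <- var(g_hat)
    v_bar <- mean(d_hat); s2 <- var(d_hat)
    lambda <- (2 * s2 + v_bar^2) / s2
    theta <- (v_bar * s2 + v_bar^3) / s2
    g_star <- numeric(nrow(vals)); d_star <- numeric(nrow(vals))
    for (g in seq_len(nrow(vals))) {
      g_star[g] <- (nb * t2 * g_hat[g] + d_hat[g] * g_bar) /
        (nb * t2 + d_hat[g])
      ss <- sum((z[g, cols] - g_star[g])^2)
      d_star[g] <- (theta + 0.5 * ss) / (nb / 2 + lambda - 1)
    }
    out[[b]] <- list(gamma_star = g_star, delta2_star = d_star)
  }
  out
}
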