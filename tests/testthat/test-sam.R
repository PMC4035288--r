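named_mat <- function(v, nr) {
  matrix(v, nrow = nr, dimnames = list(paste0("g", seq_len(nr)),
                                       paste0("s", seq_len(length(v) / nr))))
}

test_that("the moderated statistic follows its closed form", {
  x <- named_mat(c(1, 2, 3, 4, 5, 6), 1)
  st <- sam_statistic(x, rep(c("A", "B"), each = 3), s0 = 0)
  expect_equal(st$s, sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(st$d, 3 / sqrt(2 / 3), tolerance = 1e-10)

  # identical class means: d = 0 regardless of spread
  x2 <- named_mat(c(1, 3, 2, 1, 3, 2), 1)
  expect_equal(sam_statistic(x2, rep(c("A", "B"), each = 3))$d, 0)

  # swapping class labels negates d, leaves s unchanged
  st_sw <- sam_statistic(x, rep(c("B", "A"), each = 3), s0 = 0)
  expect_equal(st_sw$d, -st$d)
  expect_equal(st_sw$s, st$s)

  expect_error(sam_statistic(x, c("A", "B", "B", "B", "B", "B")),
               "at least 2")
  expect_error(sam_statistic(x, rep(c("A", "B"), each = 3), s0 = -1),
               "non-negative")
})

test_that("vectorized d and s match the per-gene oracle on random data", {
  set.seed(10)
  x <- named_mat(rnorm(200 * 8), 200)
  labels <- rep(c("A", "B"), each = 4)
  for (s0 in c(0, 0.2, 1)) {
    st <- sam_statistic(x, labels, s0)
    or <- oracle_sam_d(x, labels, s0)
    expect_equal(st$d, or$d, tolerance = 1e-10)
    expect_equal(st$s, or$s, tolerance = 1e-10)
  }
})

test_that("zero-variance features get d = 0 with a flag when s0 = 0", {
  # g1 flat everywhere; g2 flat within classes but at different levels
  x <- named_mat(rep(c(1, 1), each = 1, times = 6), 2)
  x[2, 4:6] <- 2
  labels <- rep(c("A", "B"), each = 3)
  expect_warning(st <- sam_statistic(x, labels, s0 = 0), "d set to 0")
  expect_equal(st$d, c(0, 0))
  expect_true(all(st$constant))
  # a positive fudge factor restores the shifted gene's signal
  st2 <- sam_statistic(x, labels, s0 = 0.5)
  expect_equal(st2$d, c(0, 2))
  expect_false(any(st2$constant))
})

test_that("the fudge factor scan behaves on degenerate and random input", {
  # every gene shares the same class pattern: all s_i equal
  x <- named_mat(rep(c(0, 1, 0, 1, 2, 1), each = 50), 50)
  labels <- rep(c("A", "B"), each = 3)
  st <- sam_statistic(x, labels)
  expect_equal(diff(range(st$s)), 0)
  expect_equal(choose_s0(x, labels), st$s[1])

  set.seed(11)
  xr <- named_mat(rnorm(500 * 10, sd = rep(runif(500, 0.2, 3), 10)), 500)
  s0 <- choose_s0(xr, rep(c("A", "B"), each = 5))
  sr <- sam_statistic(xr, rep(c("A", "B"), each = 5))$s
  expect_gte(s0, min(sr))
  expect_lte(s0, max(sr))

  # brute-force rescan over the same alpha grid agrees
  cands <- stats::quantile(sr, seq(0, 100, 5) / 100, names = FALSE)
  br <- unique(stats::quantile(sr, seq(0, 1, 0.1), names = FALSE))
  bins <- cut(sr, br, include.lowest = TRUE)
  num <- oracle_sam_d(xr, rep(c("A", "B"), each = 5), 0)
  cv <- sapply(cands, function(cand) {
    d <- (num$d * num$s) / (num$s + cand)
    m <- tapply(d, bins, stats::mad)
    sd(m, na.rm = TRUE) / mean(m, na.rm = TRUE)
  })
  expect_equal(s0, cands[which.min(cv)])
})

test_that("exhaustive permutation q-values match the enumeration oracle", {
  set.seed(12)
  x <- named_mat(rnorm(200 * 8), 200)
  x[1:20, 5:8] <- x[1:20, 5:8] + 2
  labels <- rep(c("A", "B"), each = 4)
  s0 <- choose_s0(x, labels)
  q <- permutation_qvalues(x, labels, s0, B = "all")
  expect_equal(q, oracle_perm_q(x, labels, s0), tolerance = 1e-12)
  expect_true(all(q >= 0 & q <= 1))
})

test_that("a dominant feature unreached by the permuted null gets q = 0", {
  set.seed(99)
  x <- rbind(c(0, 0, 0, 0, 100, 100, 100, 100), rnorm(8, sd = 0.1))
  dimnames(x) <- list(c("g1", "g2"), paste0("s", 1:8))
  labels <- rep(c("A", "B"), each = 4)
  q <- permutation_qvalues(x, labels, s0 = 0.05, B = 3, seed = 123)
  expect_equal(q[1], 0)
})

test_that("q-values are monotone in |d| and respond to B and seed", {
  set.seed(13)
  x <- named_mat(rnorm(100 * 12), 100)
  labels <- rep(c("A", "B"), each = 6)
  q <- permutation_qvalues(x, labels, s0 = 0.1, B = 40, seed = 2)
  d <- abs(sam_statistic(x, labels, 0.1)$d)
  ord <- order(d, decreasing = TRUE)
  expect_true(all(diff(q[ord]) >= 0))
  expect_identical(q, permutation_qvalues(x, labels, 0.1, B = 40, seed = 2))
  expect_error(permutation_qvalues(x, labels, 0.1, B = 0), "at least 1")
})

test_that("directional calls apply the q threshold and sign convention", {
  expect_equal(call_differential(2, 0.001), "up")
  expect_equal(call_differential(-2, 0.001), "down")
  expect_equal(call_differential(5, 0.2), "ns")
  expect_equal(call_differential(c(1, -1, 1), c(0.005, 0.005, 0.5)),
               c("up", "down", "ns"))
  expect_error(call_differential(c(1, 2), 0.1), "length")
})

test_that("reversing the contrast flips every call", {
  co <- generate_cohort(cohort_config(
    n_g1 = 15, n_g2 = 0, n_g3 = 15, n_genes = 150, n_mirnas = 10,
    n_informative_up = 10, n_informative_down = 10,
    batches = data.frame(label = "b1", shift_sd = 0, scale = 1), seed = 31))
  fwd <- sam_de(co$mrna, co$samples, "G1", "G3", B = 40, seed = 9)
  rev <- sam_de(co$mrna, co$samples, "G3", "G1", B = 40, seed = 9,
                s0 = fwd$s0)
  expect_equal(rev$table$d, -fwd$table$d, tolerance = 1e-10)
  map <- c(up = "down", down = "up", ns = "ns")
  expect_equal(unname(map[fwd$table$call]), rev$table$call)
})

test_that("contrast overlap reports containment in both directions", {
  co <- generate_cohort(cohort_config(
    n_g1 = 12, n_g2 = 12, n_g3 = 12, n_genes = 120, n_mirnas = 10,
    n_informative_up = 8, n_informative_down = 8,
    batches = data.frame(label = "b1", shift_sd = 0, scale = 1), seed = 37))
  de13 <- sam_de(co$mrna, co$samples, "G1", "G3", B = 40)
  ov <- compare_contrast_overlap(de13, de13)
  same <- ov[ov$x_direction == ov$y_direction, ]
  expect_true(all(same$fraction[same$n_x > 0] == 1))
  cross <- ov[ov$x_direction != ov$y_direction & ov$n_x > 0, ]
  expect_true(all(cross$fraction == 0))

  # toy containment 2/3
  fake <- function(calls) {
    structure(list(table = data.frame(
      feature = names(calls), d = ifelse(calls == "up", 1, -1),
      s = 1, q = ifelse(calls == "ns", 1, 0), call = unname(calls)),
      contrast = c(class_a = "G1", class_b = "G3")), class = "sam_de")
  }
  x <- fake(c(A = "up", B = "up", C = "up", D = "ns"))
  y <- fake(c(A = "ns", B = "up", C = "up", D = "up"))
  ov <- compare_contrast_overlap(x, y)
  expect_equal(ov$fraction[ov$x_direction == "up" & ov$y_direction == "up"],
               2 / 3)
  none <- fake(c(A = "ns", B = "ns", C = "ns", D = "ns"))
  ov0 <- compare_contrast_overlap(none, y)
  expect_true(all(ov0$n_x == 0))
  expect_true(all(is.na(ov0$fraction)))
})
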