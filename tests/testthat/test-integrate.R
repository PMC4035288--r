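fake_de <- function(calls, contrast = c("G1", "G3")) {
  structure(list(table = data.frame(
    feature = names(calls), d = ifelse(calls == "up", 2,
                                       ifelse(calls == "down", -2, 0)),
    s = 1, q = ifelse(calls == "ns", 1, 0), call = unname(calls),
    stringsAsFactors = FALSE),
    s0 = 0.1, B = 10, seed = 1, threshold = 0.01,
    contrast = c(class_a = contrast[1], class_b = contrast[2])),
    class = "sam_de")
}

test_that("stage-II sets are the four directional intersections", {
  de <- fake_de(c(A = "up", B = "up", C = "down", D = "ns", E = "down"))
  s2 <- stage2_sets(de,
                    cna_g1 = list(amplified = c("C", "D"), deleted = c("A")),
                    cna_g3 = list(amplified = c("B", "C"), deleted = c("E")))
  expect_equal(s2$up_amplified_g3, "B")
  expect_equal(s2$down_deleted_g3, "E")
  expect_equal(s2$up_amplified_g1, "C")   # down in G3 = up in G1
  expect_equal(s2$down_deleted_g1, "A")   # up in G3 = down in G1
  # empty CNA sets give empty stage-II sets
  s2e <- stage2_sets(de, list(amplified = character(), deleted = character()),
                     list(amplified = character(), deleted = character()))
  expect_true(all(lengths(unclass(s2e)) == 0))
  expect_error(stage2_sets(fake_de(c(A = "up"), c("G1", "G2")),
                           list(), list()), "G1-vs-G3")
})

test_that("stage-II matches a brute-force predicate scan on random instances", {
  set.seed(51)
  for (rep in 1:10) {
    genes <- paste0("g", 1:50)
    calls <- sample(c("up", "down", "ns"), 50, TRUE)
    names(calls) <- genes
    de <- fake_de(calls)
    rand_set <- function() sample(genes, sample(0:20, 1))
    cna_g1 <- list(amplified = rand_set(), deleted = rand_set())
    cna_g3 <- list(amplified = rand_set(), deleted = rand_set())
    got <- stage2_sets(de, cna_g1, cna_g3)
    want <- oracle_stage2(genes, names(calls)[calls == "up"],
                          names(calls)[calls == "down"],
                          cna_g1$amplified, cna_g1$deleted,
                          cna_g3$amplified, cna_g3$deleted)
    expect_equal(unclass(got)[names(want)], want)
  }
})

test_that("stage-III classes gate on miRNA direction and targeting", {
  s2 <- structure(list(up_amplified_g3 = "B", down_deleted_g3 = character(),
                       up_amplified_g1 = character(),
                       down_deleted_g1 = character()),
                  class = "stage2_sets")
  m_down <- fake_de(c(m1 = "down"))
  cls <- stage3_classes(s2, m_down, target_map(list(m1 = c("B", "D"))))
  expect_equal(cls$classes$class3, list(genes = "B", mirnas = "m1"))
  expect_equal(cls$gene_signature, "B")
  expect_equal(cls$mirna_signature, "m1")
  # direction mismatch empties the class
  m_up <- fake_de(c(m1 = "up"))
  cls2 <- stage3_classes(s2, m_up, target_map(list(m1 = c("B", "D"))))
  expect_length(cls2$classes$class3$genes, 0)
  expect_warning(stage3_classes(s2, m_down, target_map(list())), "empty")
})

test_that("stage-III equals exhaustive triple enumeration on random instances", {
  for (seed in 13:17) {
    set.seed(seed)
    genes <- paste0("g", 1:50)
    mirs <- paste0("m", 1:10)
    s2 <- structure(lapply(
      stats::setNames(nm = c("up_amplified_g3", "down_deleted_g3",
                             "up_amplified_g1", "down_deleted_g1")),
      function(...) sample(genes, sample(3:15, 1))), class = "stage2_sets")
    mir_calls <- sample(c("up", "down", "ns"), 10, TRUE)
    names(mir_calls) <- mirs
    de <- fake_de(mir_calls)
    tm <- target_map(stats::setNames(
      lapply(mirs, function(m) sample(genes, sample(0:12, 1))), mirs))
    tm <- tm[lengths(tm) > 0]
    got <- stage3_classes(s2, de, tm)
    want <- oracle_stage3(s2, names(mir_calls)[mir_calls == "up"],
                          names(mir_calls)[mir_calls == "down"], tm)
    expect_equal(got$classes, want)
    expect_equal(got$gene_signature,
                 sort(unique(unlist(lapply(want, `[[`, "genes")))))
  }
})

test_that("enlarging the target map never shrinks a class", {
  set.seed(61)
  genes <- paste0("g", 1:30)
  s2 <- structure(list(up_amplified_g3 = genes[1:10],
                       down_deleted_g3 = genes[11:20],
                       up_amplified_g1 = genes[21:25],
                       down_deleted_g1 = genes[26:30]),
                  class = "stage2_sets")
  de <- fake_de(c(m1 = "down", m2 = "up", m3 = "down", m4 = "up"))
  small <- target_map(list(m1 = genes[1:3], m2 = genes[11:12]))
  big <- target_map(list(m1 = genes[1:6], m2 = genes[11:14],
                         m3 = genes[21:23], m4 = genes[26:28]))
  cs <- stage3_classes(s2, de, small)
  cb <- stage3_classes(s2, de, big)
  for (cl in names(cs$classes)) {
    expect_true(all(cs$classes[[cl]]$genes %in% cb$classes[[cl]]$genes))
    expect_true(all(cs$classes[[cl]]$mirnas %in% cb$classes[[cl]]$mirnas))
  }
  # within-grade disjointness: a gene is up or down, never both
  expect_length(intersect(cb$classes$class1$genes, cb$classes$class3$genes), 0)
  expect_lte(length(cb$gene_signature),
             sum(lengths(lapply(cb$classes, `[[`, "genes"))))
})

test_that("planted consistent triples land in their intended classes", {
  for (seed in 1:5) {
    co <- generate_cohort(cohort_config(
      n_g1 = 40, n_g2 = 0, n_g3 = 40, n_genes = 300, n_mirnas = 30,
      n_informative_up = 10, n_informative_down = 10, delta = 2,
      mirna_effect = 2, cna_gain_freq = 0.8, cna_loss_freq = 0.8,
      targets_per_mirna = 5,
      batches = data.frame(label = "b1", shift_sd = 0, scale = 1),
      seed = seed))
    de <- sam_de(co$mrna, co$samples, "G1", "G3", B = 100, seed = seed)
    mde <- sam_de(co$mirna, co$samples, "G1", "G3", B = 100, seed = seed)
    cna_g1 <- cna_gene_sets(co$genes, co$segments, co$samples, "G1")
    cna_g3 <- cna_gene_sets(co$genes, co$segments, co$samples, "G3")
    s2 <- stage2_sets(de, cna_g1, cna_g3)
    cls <- stage3_classes(s2, mde, co$targets)
    up <- co$truth$informative$gene[co$truth$informative$direction == "up"]
    dn <- co$truth$informative$gene[co$truth$informative$direction == "down"]
    # up-in-G3 genes: amplified in G3 under down-miRNAs (class 3) and
    # deleted in G1 under up-in-G1 miRNAs (class 4); down genes mirror
    expect_true(all(up %in% cls$classes$class3$genes))
    expect_true(all(up %in% cls$classes$class4$genes))
    expect_true(all(dn %in% cls$classes$class1$genes))
    expect_true(all(dn %in% cls$classes$class2$genes))
    expect_setequal(cls$gene_signature, c(up, dn))
  }
})

test_that("downsizing keeps candidate genes found in any reference", {
  cand <- c("FOXM1", "KPNA4", "H2AFV", "DDX19A", "XTRA")
  refs <- list(refA = c("FOXM1", "KPNA4", "H2AFV", "DDX19A"),
               refB = "FOXM1", refC = character())
  sig <- downsize_signature(cand, refs)
  expect_setequal(sig$genes, c("FOXM1", "KPNA4", "H2AFV", "DDX19A"))
  mem <- sig$membership
  expect_true(mem$refB[mem$gene == "FOXM1"])
  expect_true(all(!mem$refB[mem$gene != "FOXM1"]))
  expect_true(all(mem$refA))
  # disjoint reference -> empty signature; candidate subset -> unchanged
  expect_length(downsize_signature(cand, list(r = "OTHER"))$genes, 0)
  expect_setequal(downsize_signature(c("FOXM1"), refs)$genes, "FOXM1")
  expect_error(downsize_signature(cand, list()), "at least one")
})
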