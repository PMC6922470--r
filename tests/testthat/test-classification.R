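make_matrix <- function(values, genes, fams) {
  m <- matrix(values, nrow = length(genes), ncol = length(fams),
              dimnames = list(genes, fams))
  m
}

test_that("uniform matrices classify to a single label", {
  genes <- paste0("g", 1:5); fams <- paste0("f", 1:10)
  all_high <- make_matrix(100, genes, fams)
  expect_true(all(classify_genes(all_high)$label == "stable"))
  all_low <- make_matrix(40, genes, fams)
  expect_true(all(classify_genes(all_low)$label == "sensitive"))
})

test_that("coverage counts columns against the 90% rule", {
  fams <- sprintf("f%03d", 1:248)
  m <- make_matrix(90, "g1", fams)
  m[1, 1:8] <- 40  # 240 of 248 columns high: 96.8% >= 90% -> stable
  expect_equal(as.character(classify_genes(m)$label), "stable")
  m[1, 1:30] <- 40  # 218 of 248: 87.9% < 90% -> not stable
  expect_equal(as.character(classify_genes(m)$label), "other")
})

test_that("threshold comparisons are strict", {
  fams <- paste0("f", 1:10)
  at_threshold <- make_matrix(85, "g1", fams)
  expect_equal(as.character(classify_genes(at_threshold)$label), "other")
  at_50 <- make_matrix(50, "g1", fams)
  expect_equal(as.character(classify_genes(at_50)$label), "other")
})

test_that("raising the stable threshold never grows the stable set", {
  set.seed(7)
  m <- make_matrix(runif(600, 0, 100), sprintf("g%02d", 1:30),
                   paste0("f", 1:20))
  prev <- NULL
  for (thr in c(60, 75, 85, 95)) {
    cur <- classify_genes(m, stable_threshold = thr)$gene[
      classify_genes(m, stable_threshold = thr)$label == "stable"]
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  # coverage 1 is the intersection over columns; coverage -> 0 approaches
  # the union (any single qualifying column suffices)
  strict <- classify_genes(m, coverage = 1)
  loose <- classify_genes(m, coverage = 1e-9)
  n_stable <- rowSums(m > 85)
  expect_setequal(strict$gene[strict$label == "stable"],
                  rownames(m)[n_stable == 20])
  expect_setequal(loose$gene[loose$label == "stable"],
                  rownames(m)[n_stable > 0])
})

test_that("gene features count families, sites and expression", {
  mirna <- profile_from_counts(c(fA = 1000L, fB = 3000L, fC = 46000L),
                               "miRNA")
  mrna <- profile_from_counts(c(g1 = 100L, g2 = 100L, lonely = 100L))
  ints <- interactions_from(gene = c("g1", "g1", "g2"),
                            family = c("fA", "fB", "fC"),
                            score = c(-1, -1, -2),
                            sites = c("0,60,120", "0,80", "0"))
  feats <- gene_features(ints, mirna, mrna)
  g1 <- feats[feats$gene == "g1", ]
  expect_equal(g1$n_targeting_families, 2)
  expect_equal(g1$n_mbs, 5)
  expect_equal(g1$mean_targeting_mirna_expression, 2000)
  lonely <- feats[feats$gene == "lonely", ]
  expect_false(lonely$targeted)
  expect_equal(lonely$n_mbs, 0)
  expect_true(all(feats$n_mbs >= feats$n_targeting_families))
})

test_that("feature comparisons behave like a Welch t test", {
  cl <- tibble::tibble(
    gene = sprintf("g%02d", 1:12),
    label = factor(rep(c("stable", "sensitive", "other"), each = 4),
                   levels = c("stable", "sensitive", "other")))
  set.seed(1)
  feats <- tibble::tibble(gene = cl$gene,
                          n_mbs = c(rep(0, 4), rep(10, 4), rep(5, 4)) +
                            rnorm(12, sd = 1e-3))
  res <- compare_feature(cl, feats, "n_mbs", c("stable", "sensitive"))
  expect_lt(res$p_value, 1e-3)
  same <- tibble::tibble(gene = cl$gene, n_mbs = rnorm(12, 5, 1e-6))
  res2 <- compare_feature(cl, same, "n_mbs", c("stable", "sensitive"))
  expect_gt(res2$p_value, 0.05)
  tiny <- cl[cl$label != "sensitive", ]
  expect_error(compare_feature(tiny, feats, "n_mbs",
                               c("stable", "sensitive")), "2 genes")
})

test_that("hypergeometric overlap matches direct tail summation", {
  bg <- sprintf("g%03d", 1:100)
  A <- bg[1:10]; B <- bg[1:10]
  res <- set_overlap(A, B, bg)
  # oracle: direct summation over all achievable overlaps >= 10
  direct <- sum(vapply(10:10, function(k) {
    choose(10, k) * choose(90, 10 - k) / choose(100, 10)
  }, numeric(1)))
  expect_equal(res$p_value, direct)
  expect_equal(res$overlap, 10)

  # two-element universe: observing the single shared placement has p 0.5
  res2 <- set_overlap("x", "x", c("x", "y"))
  expect_equal(res2$p_value, 0.5)
  # disjoint sets can never beat the tail that includes everything
  res3 <- set_overlap("x", "y", c("x", "y"))
  expect_equal(res3$p_value, 1)

  expect_error(set_overlap("z", "x", c("x", "y")), "background")
  # chi-square route agrees in direction on a strong overlap
  res4 <- set_overlap(bg[1:20], bg[1:20], bg, method = "chisq")
  expect_lt(res4$p_value, 1e-6)
})
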