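test_that("undetected families are floored at 0.01% of the pool", {
  mirna <- profile_from_counts(c(mirA = 30000L, mirB = 20000L), "miRNA")
  floored <- apply_floor(mirna, "mirNew")
  # 0.01% of 50,000 = 5 molecules, surviving renormalization
  expect_identical(floored$molecules[floored$id == "mirNew"], 5L)
  expect_identical(sum(floored$molecules), 50000L)
  # families already above the floor are untouched
  expect_identical(as.data.frame(apply_floor(mirna, "mirA")),
                   as.data.frame(mirna))
})

test_that("overexpression renormalizes to the closed-form fraction", {
  pool <- 50000L
  f0 <- 0.001
  n0 <- as.integer(f0 * pool)
  mirna <- profile_from_counts(c(mirX = n0, mirRest = pool - n0), "miRNA")
  for (F in c(0.5, 3, 9, 18, 90, 300, 1000)) {
    out <- overexpress(mirna, "mirX", F)
    expect_identical(sum(out$molecules), pool)
    expected <- F * f0 / (1 + (F - 1) * f0)
    got <- out$molecules[out$id == "mirX"] / pool
    expect_lt(abs(got - expected), 1 / pool + 1e-12)
  }
  # factor 1 is the identity on an integer profile
  expect_identical(overexpress(mirna, "mirX", 1)$molecules, mirna$molecules)
  expect_error(overexpress(mirna, "mirX", 0), "positive")
  expect_error(overexpress(mirna, "absent", 2), "apply_floor")
})

test_that("a lowly expressed family reaches ~20%/~50% at x300/x1000", {
  # the regime of a barely expressed miRNA driven to dominance
  pool <- 50000L
  mirna <- profile_from_counts(c(lo = 42L, rest = pool - 42L), "miRNA")
  f0 <- 42 / pool
  at <- function(F) {
    out <- overexpress(mirna, "lo", F)
    out$molecules[out$id == "lo"] / pool
  }
  expect_equal(at(300), 300 * f0 / (1 + 299 * f0), tolerance = 1e-3)
  expect_gt(at(300), 0.15); expect_lt(at(300), 0.25)
  expect_gt(at(1000), 0.40); expect_lt(at(1000), 0.50)
})

test_that("screens have the right shape and reproduce baseline at factor 1", {
  fx <- make_fixture(synthetic_spec(seed = 6))
  cfg <- simulation_config(n_iterations = 2000L, checkpoint_interval = 2000L)
  fams <- c("fam-03", "fam-07", "fam-12")
  scr <- run_screen(fx$mirna, fx$mrna, fx$interactions, families = fams,
                    factor = 1, config = cfg, master_seed = 99L)
  expect_identical(dim(scr$values), c(length(scr$genes), 3L))
  expect_true(all(scr$values >= 0 & scr$values <= 100))

  # factor 1 on a family above the floor leaves the profile unchanged, so
  # the column equals a plain run at that column's derived seed
  cfg1 <- cfg
  cfg1$seed <- scr$seeds[["fam-03"]]
  base <- run_comics(fx$mirna, fx$mrna, fx$interactions, cfg1)
  expect_identical(unname(scr$values[, "fam-03"]),
                   unname(final_retention(base)[scr$genes]))
})

test_that("screen columns are independent of family order", {
  fx <- make_fixture(synthetic_spec(seed = 6))
  cfg <- simulation_config(n_iterations = 1000L, checkpoint_interval = 1000L)
  fams <- c("fam-01", "fam-05", "fam-09")
  a <- run_screen(fx$mirna, fx$mrna, fx$interactions, families = fams,
                  factor = 9, config = cfg, master_seed = 5L)
  b <- run_screen(fx$mirna, fx$mrna, fx$interactions, families = rev(fams),
                  factor = 9, config = cfg, master_seed = 5L)
  expect_identical(a$values, b$values[, fams])
})

test_that("the overexpressed family's private target drops the most", {
  # g_target is bound only by mirX; overexpressing mirX must make it the
  # lowest-retention gene of that column
  mirna <- profile_from_counts(c(mirX = 50L, mirY = 49950L), "miRNA")
  mrna <- profile_from_counts(c(g_target = 8000L, g_other = 9000L,
                                g_third = 8000L))
  ints <- interactions_from(
    gene = c("g_target", "g_other", "g_third"),
    family = c("mirX", "mirY", "mirY"),
    score = c(-6, -0.5, -0.5))
  cfg <- simulation_config(n_iterations = 10000L,
                           checkpoint_interval = 10000L,
                           mirna_pool = 50000L, mrna_pool = 25000L)
  scr <- run_screen(mirna, mrna, ints, families = "mirX", factor = 300,
                    config = cfg, master_seed = 3L)
  expect_equal(names(which.min(scr$values[, "mirX"])), "g_target")
})

test_that("target retention decreases with the overexpression factor", {
  mirna <- profile_from_counts(c(mirX = 50L, mirY = 49950L), "miRNA")
  mrna <- profile_from_counts(c(g_target = 12000L, g_other = 13000L))
  ints <- interactions_from(gene = c("g_target", "g_other"),
                            family = c("mirX", "mirY"),
                            score = c(-6, -0.3))
  cfg <- simulation_config(n_iterations = 8000L, checkpoint_interval = 8000L,
                           mirna_pool = 50000L, mrna_pool = 25000L)
  ret <- vapply(c(1, 9, 90, 1000), function(F) {
    scr <- run_screen(mirna, mrna, ints, families = "mirX", factor = F,
                      config = cfg, master_seed = 11L)
    scr$values["g_target", "mirX"]
  }, numeric(1))
  expect_true(all(diff(ret) < 0))
})
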