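test_that("a probability-zero matrix leaves every transcript untouched", {
  sys <- toy_system()
  null_ints <- interactions_from(gene = c("g1", "g2"),
                                 family = c("mirA", "mirB"),
                                 score = c(0, 0))
  cfg <- tiny_config(sys$mirna, sys$mrna, n_iterations = 500L)
  run <- run_comics(sys$mirna, sys$mrna, null_ints, cfg)
  expect_true(all(run$trajectory == 100))
  expect_identical(unname(run$live), unname(run$initial))
  expect_equal(nrow(run$engaged), 0)
})

test_that("miRNA molecules are conserved and retention never increases", {
  fx <- make_fixture(synthetic_spec(seed = 2))
  cfg <- simulation_config(n_iterations = 10000L, seed = 4L)
  run <- run_comics(fx$mirna, fx$mrna, fx$interactions, cfg)
  expect_true(all(run$conservation$mirna_total == run$conservation$pool))
  expect_true(all(apply(run$trajectory, 1, function(r) all(diff(r) <= 0))))
  expect_true(all(run$trajectory >= 0 & run$trajectory <= 100))
})

test_that("identical seeds reproduce the trajectory and engagement log", {
  fx <- make_fixture(synthetic_spec(seed = 8))
  cfg <- simulation_config(n_iterations = 5000L, seed = 123L)
  a <- run_comics(fx$mirna, fx$mrna, fx$interactions, cfg)
  b <- run_comics(fx$mirna, fx$mrna, fx$interactions, cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$engaged, b$engaged)
  expect_identical(a$live, b$live)
  cfg$seed <- 124L
  c <- run_comics(fx$mirna, fx$mrna, fx$interactions, cfg)
  expect_false(identical(a$trajectory, c$trajectory))
})

test_that("genes without an interaction record are excluded and logged", {
  sys <- toy_system()
  mrna <- profile_from_counts(c(g1 = 100L, g2 = 50L, orphan = 50L))
  cfg <- tiny_config(sys$mirna, mrna, n_iterations = 100L)
  run <- run_comics(sys$mirna, mrna, sys$interactions, cfg)
  expect_identical(run$excluded_genes, "orphan")
  expect_false("orphan" %in% run$genes)
})

test_that("family and target draws follow abundance weights", {
  # two families, each exclusively targeting its own gene with p = 1:
  # binding counts then expose the miRNA draw frequencies
  mirna <- profile_from_counts(c(mirA = 7500L, mirB = 2500L), "miRNA")
  mrna <- profile_from_counts(c(g1 = 5000L, g2 = 5000L))
  ints <- interactions_from(gene = c("g1", "g2"), family = c("mirA", "mirB"),
                            score = c(-50, -50))
  cfg <- tiny_config(mirna, mrna, n_iterations = 2000L,
                     removal_delay = 100000L, checkpoint_interval = 1000L,
                     seed = 17L)
  run <- run_comics(mirna, mrna, ints, cfg)
  draws_A <- 7500 - run$free_mirna[["mirA"]]
  n <- draws_A + (2500 - run$free_mirna[["mirB"]])
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(draws_A / n - 0.75), 4 * se)

  # one family over two genes at 75:25 molecule counts: removal counts at
  # delay 1 expose the target draw frequencies (slight drift from depletion
  # is well under a percentage point at 800 draws on 10,000 molecules)
  mirna2 <- profile_from_counts(c(mirA = 10000L), "miRNA")
  mrna2 <- profile_from_counts(c(g1 = 7500L, g2 = 2500L))
  ints2 <- interactions_from(gene = c("g1", "g2"), family = c("mirA", "mirA"),
                             score = c(-50, -50))
  cfg3 <- tiny_config(mirna2, mrna2, n_iterations = 800L,
                      removal_delay = 1L, checkpoint_interval = 800L,
                      seed = 23L)
  run3 <- run_comics(mirna2, mrna2, ints2, cfg3)
  removed <- run3$initial - run3$live
  frac_g1 <- removed[["g1"]] / sum(removed)
  se2 <- sqrt(0.75 * 0.25 / sum(removed))
  expect_lt(abs(frac_g1 - 0.75), 4 * se2 + 0.01)
})

test_that("occupied sites block conflicting sites but not distant ones", {
  mirna <- profile_from_counts(c(mirA = 100L), "miRNA")
  mrna <- profile_from_counts(c(g1 = 1L))
  cfg <- tiny_config(mirna, mrna, n_iterations = 400L,
                     removal_delay = 100000L, checkpoint_interval = 400L)
  # two sites 30 nt apart: after the first binding the second conflicts,
  # so exactly one miRNA is ever consumed
  close_sites <- interactions_from(gene = "g1", family = "mirA",
                                   score = -50, sites = "0,30")
  run_close <- run_comics(mirna, mrna, close_sites, cfg)
  expect_identical(run_close$free_mirna[["mirA"]], 99L)
  # 60 nt apart: both sites fill
  far_sites <- interactions_from(gene = "g1", family = "mirA",
                                 score = -50, sites = "0,60")
  run_far <- run_comics(mirna, mrna, far_sites, cfg)
  expect_identical(run_far$free_mirna[["mirA"]], 98L)
})

test_that("removal happens exactly removal_delay iterations after binding", {
  mirna <- profile_from_counts(c(mirA = 1L), "miRNA")
  mrna <- profile_from_counts(c(g1 = 1L))
  ints <- interactions_from(gene = "g1", family = "mirA", score = -50)
  cfg <- tiny_config(mirna, mrna, n_iterations = 20L, removal_delay = 10L,
                     checkpoint_interval = 5L)
  run <- run_comics(mirna, mrna, ints, cfg)
  # p ~ 1 so binding happens at iteration 1; the deadline is iteration 11
  expect_equal(unname(run$trajectory["g1", ]), c(100, 100, 0, 0))
  # the bound miRNA was recycled into the free pool on removal
  expect_identical(run$free_mirna[["mirA"]], 1L)
  expect_equal(run$conservation$mirna_total, rep(1, 4))
})

test_that("profile/pool mismatches and empty inputs are rejected", {
  sys <- toy_system()
  cfg <- simulation_config(mirna_pool = 999L, mrna_pool = 200L,
                           n_iterations = 100L, removal_delay = 10L,
                           checkpoint_interval = 100L)
  expect_error(run_comics(sys$mirna, sys$mrna, sys$interactions, cfg),
               "pool")
  cfg2 <- tiny_config(sys$mirna, sys$mrna)
  expect_error(run_comics(sys$mirna, sys$mrna,
                          sys$interactions[0, ], cfg2))
})

test_that("tidy and glance summarise a run faithfully", {
  sys <- toy_system()
  cfg <- tiny_config(sys$mirna, sys$mrna, n_iterations = 200L)
  run <- run_comics(sys$mirna, sys$mrna, sys$interactions, cfg)
  long <- tidy(run)
  expect_equal(nrow(long), 2 * length(run$checkpoints))
  expect_equal(sort(unique(long$gene)), c("g1", "g2"))
  g <- glance(run)
  expect_equal(g$n_bindings + g$n_failed_attempts, 200L)
  expect_true(g$mirna_pool_conserved)
  expect_equal(g$mean_final_retention, mean(final_retention(run)))
})
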