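test_that("pinned-rate posterior root matches the GLS closed form", {
  cherry <- read_time_tree(text = "(A:1,B:1);")
  cfg <- mvbm_config(iterations = 50000, seed = 42, rate_prior_sd = 0)
  p <- mvbm_mcmc(cherry, c(A = 0, B = 2), cfg)
  root <- p$node_summary[3, ]
  mcse <- root$state_sd / sqrt(p$diagnostics$ess_root_state)
  expect_lt(abs(root$state_mean - 1), 3 * mcse)
})

test_that("pinned-rate node means match the joint-normal conditional means", {
  phy <- random_time_tree(8, seed = 77)
  x <- simulate_mvbm(phy, 0.5, 1, seed = 78)$tip_values
  p <- mvbm_mcmc(phy, x, mvbm_config(iterations = 80000, seed = 79,
                                     rate_prior_sd = 0))
  oracle <- bm_conditional_means(phy, x)
  ints <- which(!p$node_summary$is_tip)
  for (k in seq_along(ints)) {
    i <- ints[k]
    mcse <- p$node_summary$state_sd[i] /
      sqrt(bitephylo:::.ess(p$chains$states[, i]))
    expect_lt(abs(p$node_summary$state_mean[i] - oracle[k]), 3 * mcse)
  }
})

test_that("tip states are never altered by the sampler", {
  phy <- random_time_tree(10, seed = 8)
  x <- simulate_mvbm(phy, 0.3, 0, seed = 9)$tip_values
  p <- mvbm_mcmc(phy, x, mvbm_config(iterations = 5000, seed = 10))
  n <- length(phy$tip.label)
  expect_equal(p$node_summary$state_mean[1:n], unname(x[phy$tip.label]))
  expect_equal(p$node_summary$state_sd[1:n], rep(0, n))
  # the raw chain columns for tips are constant
  expect_true(all(apply(p$chains$states[, 1:n, drop = FALSE], 2,
                        function(col) all(col == col[1]))))
})

test_that("identical seed and config give identical output", {
  phy <- random_time_tree(12, seed = 20)
  x <- simulate_mvbm(phy, 0.3, 0, seed = 21)$tip_values
  cfg <- mvbm_config(iterations = 8000, seed = 22)
  p1 <- mvbm_mcmc(phy, x, cfg)
  p2 <- mvbm_mcmc(phy, x, cfg)
  expect_identical(p1$node_summary, p2$node_summary)
  expect_identical(p1$branch_summary, p2$branch_summary)
})

test_that("log joint density is finite at every retained sample", {
  phy <- random_time_tree(10, seed = 30)
  x <- simulate_mvbm(phy, 0.3, 0, seed = 31)$tip_values
  p <- mvbm_mcmc(phy, x, mvbm_config(iterations = 5000, seed = 32))
  expect_true(all(is.finite(p$chains$log_joint)))
  expect_true(all(p$chains$sigma2 > 0))
  expect_true(all(exp(p$chains$ln_mult) > 0))
})

test_that("credible intervals are ordered and multipliers positive", {
  phy <- random_time_tree(10, seed = 33)
  x <- simulate_mvbm(phy, 0.3, 0, seed = 34)$tip_values
  p <- mvbm_mcmc(phy, x, mvbm_config(iterations = 8000, seed = 35))
  b <- p$branch_summary
  expect_true(all(b$mult_lo <= b$mult_hi))
  expect_true(all(b$mult_lo > 0))
  expect_true(all(b$eff_rate_lo <= b$eff_rate_hi))
  s <- p$node_summary
  expect_true(all(s$state_lo <= s$state_hi))
})

test_that("single-rate data gives wide multiplier intervals covering 1", {
  phy <- simulate_tree(64, 0.2, seed = 11)
  x <- simulate_mvbm(phy, 1, 0, seed = 12)$tip_values
  p <- mvbm_mcmc(phy, x, mvbm_config(iterations = 30000, seed = 13))
  coverage <- mean(p$branch_summary$mult_lo <= 1 & p$branch_summary$mult_hi >= 1)
  expect_gte(coverage, 0.9)
})

test_that("an elevated branch is detected near the information ceiling", {
  # a multiplier is informed by a single increment, so top-rank detection
  # of one 25x branch is capped well below certainty; the working claim
  # is that the target ranks at the very top of the distribution
  ranks <- vapply(1:10, function(s) {
    phy <- simulate_tree(64, 0.2, seed = 100 + s)
    internal <- which(phy$edge[, 2] > 65)
    b <- internal[which.max(phy$edge.length[internal])]
    target <- phy$edge[b, 2]
    sim <- simulate_mvbm(phy, 0.1, 0,
                         multipliers = stats::setNames(25, target),
                         seed = 200 + s)
    p <- mvbm_mcmc(phy, sim$tip_values,
                   mvbm_config(iterations = 20000, seed = 300 + s))
    rank(-p$branch_summary$mult_mean)[p$branch_summary$node_id == target]
  }, 0)
  expect_lte(stats::median(ranks), 5)
  expect_gte(sum(ranks == 1), 5) # top-ranked in at least half the replicates
})

test_that("multiplier recovery is significantly positive on mixed-rate data", {
  for (i in 1:3) {
    phy <- simulate_tree(64, 0.2, seed = 130 + i)
    branches <- as.character(phy$edge[, 2])
    set.seed(140 + i)
    targets <- sample(branches, round(0.3 * length(branches)))
    sim <- simulate_mvbm(phy, 0.1, 0,
                         multipliers = stats::setNames(rep(25, length(targets)),
                                                       targets),
                         seed = 150 + i)
    p <- suppressWarnings(
      mvbm_mcmc(phy, sim$tip_values,
                mvbm_config(iterations = 50000, seed = 160 + i)))
    truth <- sim$truth$multipliers[as.character(p$branch_summary$node_id)]
    ct <- suppressWarnings(
      stats::cor.test(truth, p$branch_summary$mult_mean,
                      method = "spearman", alternative = "greater"))
    expect_lt(ct$p.value, 0.01)
  }
})

test_that("posterior node table is keyed, complete and reproducible", {
  cherry <- read_time_tree(text = "(A:1,B:1);")
  cfg <- mvbm_config(iterations = 5000, seed = 50)
  p <- mvbm_mcmc(cherry, c(A = 0, B = 2), cfg)
  tab <- posterior_node_table(p, cherry)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$state_mean[tab$node_id %in% 1:2],
               c(0, 2)) # tips echo observations

  phy <- random_time_tree(9, seed = 51)
  x <- simulate_mvbm(phy, 0.3, 0, seed = 52)$tip_values
  p2 <- mvbm_mcmc(phy, x, cfg)
  tab2 <- posterior_node_table(p2, phy)
  expect_equal(nrow(tab2), 2 * 9 - 1)

  # byte-identical re-run
  p3 <- mvbm_mcmc(phy, x, cfg)
  expect_identical(posterior_node_table(p3, phy), tab2)

  other <- random_time_tree(9, seed = 53)
  expect_error(posterior_node_table(p2, other), "does not match")
})

test_that("acceptance-fraction diagnostics flag a mistuned proposal", {
  phy <- random_time_tree(8, seed = 60)
  x <- simulate_mvbm(phy, 0.3, 0, seed = 61)$tip_values
  cfg <- mvbm_config(iterations = 5000, seed = 62, proposal_sd = 50)
  expect_warning(p <- mvbm_mcmc(phy, x, cfg), "acceptance fraction")
  expect_true(length(p$diagnostics$warnings) > 0)
})
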