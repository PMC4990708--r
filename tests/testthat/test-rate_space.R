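test_that("branch rates are child-minus-parent change over duration", {
  phy <- read_time_tree(text = "(A:0.5,B:1);")
  # node ids: A=1, B=2, root=3
  post_rap <- fake_posterior(phy, c(2.0, 1.5, 1.0))
  post_hw <- fake_posterior(phy, c(1.2, 0.8, 1.0))
  rec <- branch_rates(post_rap, post_hw, phy)
  expect_equal(nrow(rec), 2L) # node count - 1
  a <- rec[rec$node_id == 1, ]
  expect_equal(a$delta_rap, 1.0)
  expect_equal(a$rate_rap, 2.0) # 1.0 / 0.5 Myr
  expect_equal(a$delta_hw, 0.2)
  expect_equal(a$rate_hw, 0.4)
  b <- rec[rec$node_id == 2, ]
  expect_equal(b$rate_rap, 0.5)

  # parent == child -> zero delta, zero rate
  flat <- fake_posterior(phy, c(1, 1, 1))
  rec0 <- branch_rates(flat, post_hw, phy)
  expect_equal(rec0$delta_rap, c(0, 0))
  expect_equal(rec0$rate_rap, c(0, 0))

  other <- read_time_tree(text = "(A:1,C:1);")
  expect_error(branch_rates(post_rap, post_hw, other), "not computed")
})

test_that("RMA slope and intercept follow the sd-ratio closed form", {
  f <- rma_fit(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)

  f2 <- rma_fit(c(0, 1, 2, 3), c(1, 3, 4, 8))
  expect_equal(f2$slope, sqrt(26 / 5), tolerance = 1e-10)
  expect_equal(f2$intercept, 4 - sqrt(26 / 5) * 1.5, tolerance = 1e-10)
  expect_equal(f2$slope, 2.280, tolerance = 1e-3)
  expect_equal(f2$intercept, 0.580, tolerance = 1e-2)

  expect_error(rma_fit(c(1, 1, 1), c(0, 1, 2)), "zero variance")
  expect_error(rma_fit(c(0, 1), c(0, 1)), "at least 3")
})

test_that("RMA is symmetric: slope(x,y) * slope(y,x) = 1", {
  set.seed(99)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- 0.5 * x + rnorm(15, sd = runif(1, 0.1, 2))
    expect_equal(rma_fit(x, y)$slope * rma_fit(y, x)$slope, 1,
                 tolerance = 1e-10)
  }
})

test_that("the seven-scenario fixture is labeled exactly", {
  fx <- scenario_fixture()
  out <- classify_branches(fx, identity_rma())
  expect_equal(as.character(out$scenario), fx$expected)
  # exhaustive and exclusive
  expect_false(anyNA(out$scenario))
})

test_that("classification is exhaustive and antisymmetric under negation", {
  set.seed(7)
  u <- rnorm(1000); v <- rnorm(1000)
  fit <- rma_fit(u, v)
  lab <- classify_branches(data.frame(rate_hw = u, rate_rap = v), fit)$scenario
  expect_false(anyNA(lab))
  fit_neg <- rma_fit(-u, -v)
  lab_neg <- classify_branches(data.frame(rate_hw = -u, rate_rap = -v),
                               fit_neg)$scenario
  map <- c(AI = "AD", DI = "DD", SEP_POS = "SEP_NEG",
           DD = "DI", AD = "AI", SEP_NEG = "SEP_POS", ISO = "ISO")
  expect_equal(as.character(lab_neg), unname(map[as.character(lab)]))
})

test_that("points on the line and the origin are ISO", {
  fit <- identity_rma()
  rec <- data.frame(rate_hw = c(0.5, -0.5, 0), rate_rap = c(0.5, -0.5, 0))
  expect_equal(as.character(classify_branches(rec, fit)$scenario),
               c("ISO", "ISO", "ISO"))
})

test_that("painting yields a census, annotated Newick and AI runs", {
  # caterpillar: the focal tip A has 4 branches on its root path
  phy <- read_time_tree(text = "((((A:1,B:1):1,C:2):1,D:3):1,E:4);")
  rec <- data.frame(node_id = phy$edge[, 2])
  chainA <- setdiff(ancestor_chain(phy, "A"), 6L) # all but the root
  rec$scenario <- factor(ifelse(rec$node_id %in% chainA, "AI", "ISO"),
                         levels = SCENARIOS)
  painted <- paint_tree(phy, rec)
  expect_equal(sum(painted$census), nrow(phy$edge))
  expect_equal(painted$census[["AI"]], 4L)
  expect_equal(painted$longest_ai_run, 4L)
  expect_equal(painted$longest_ai_tip, "A")
  expect_match(painted$newick, "\\[&scenario=AI\\]")
  expect_match(painted$newick, "\\[&scenario=ISO\\]")

  # all ISO: zero AI run
  rec$scenario <- factor(rep("ISO", nrow(rec)), levels = SCENARIOS)
  p2 <- paint_tree(phy, rec)
  expect_equal(p2$census[["ISO"]], nrow(phy$edge))
  expect_equal(p2$longest_ai_run, 0L)
  expect_true(is.na(p2$longest_ai_tip))

  rec$scenario[1] <- NA
  expect_error(paint_tree(phy, rec), "classified")
})

test_that("a lineage with elevated RAP multipliers is AI-enriched", {
  ai_lin <- 0L; n_lin <- 0L; ai_bg <- 0L; n_bg <- 0L
  for (s in 1:6) {
    phy <- simulate_tree(36, 0.15, seed = 400 + s)
    tip <- names(which.max(tip_depths(phy)))
    lineage <- as.character(ancestor_chain(phy, tip)[-1])
    sim_rap <- simulate_mvbm(phy, 0.05, 3,
                             multipliers = stats::setNames(rep(25, length(lineage)),
                                                           lineage),
                             seed = 500 + s)
    sim_hw <- simulate_mvbm(phy, 0.05, 4, seed = 600 + s)
    p_rap <- mvbm_mcmc(phy, sim_rap$tip_values,
                       mvbm_config(iterations = 20000, seed = 700 + s))
    p_hw <- mvbm_mcmc(phy, sim_hw$tip_values,
                      mvbm_config(iterations = 20000, seed = 800 + s))
    rec <- branch_rates(p_rap, p_hw, phy)
    rec <- classify_branches(rec, rma_fit(rec$rate_hw, rec$rate_rap))
    lin <- rec$node_id %in% as.integer(lineage)
    ai_lin <- ai_lin + sum(rec$scenario[lin] == "AI"); n_lin <- n_lin + sum(lin)
    ai_bg <- ai_bg + sum(rec$scenario[!lin] == "AI"); n_bg <- n_bg + sum(!lin)
  }
  expect_gt(ai_lin / n_lin, ai_bg / n_bg)
})

test_that("scenario probabilities propagate posterior draws", {
  phy <- random_time_tree(10, seed = 90)
  x1 <- simulate_mvbm(phy, 0.3, 0, seed = 91)$tip_values
  x2 <- simulate_mvbm(phy, 0.3, 0, seed = 92)$tip_values
  p1 <- mvbm_mcmc(phy, x1, mvbm_config(iterations = 5000, seed = 93))
  p2 <- mvbm_mcmc(phy, x2, mvbm_config(iterations = 5000, seed = 94))
  probs <- scenario_probabilities(p1, p2, phy, max_draws = 100)
  expect_equal(nrow(probs), nrow(phy$edge))
  expect_equal(unname(rowSums(probs[, -1])), rep(1, nrow(probs)))
})
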