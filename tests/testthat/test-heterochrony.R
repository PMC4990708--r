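test_that("equal ln-spacing puts one specimen per stage", {
  hw <- exp(seq(log(20), log(200), length.out = 10))
  series <- data.frame(rap_mm = 0.2 * hw, hw_mm = hw)
  tr <- ontogeny_trajectory(series)
  expect_equal(tr$n_in_bin, rep(1L, 10))
  expect_equal(sum(tr$n_in_bin), nrow(series))
})

test_that("rap = hw gives unit log-quotient at every stage", {
  hw <- exp(seq(log(5), log(100), length.out = 12))
  series <- data.frame(rap_mm = hw, hw_mm = hw)
  tr <- ontogeny_trajectory(series)
  nz <- tr$n_in_bin > 0
  expect_equal(tr$mean_ratio[nz], rep(1, sum(nz)))
})

test_that("binning conserves specimens and ignores specimen order", {
  series <- simulate_ontogeny(seed = 3)
  tr <- ontogeny_trajectory(series)
  expect_equal(sum(tr$n_in_bin), nrow(series))
  set.seed(1)
  shuffled <- series[sample.int(nrow(series)), ]
  expect_equal(ontogeny_trajectory(shuffled)$mean_ratio, tr$mean_ratio)
})

test_that("noise-free biphasic ontogeny rises then flattens", {
  series <- simulate_ontogeny(noise_sd = 0)
  tr <- ontogeny_trajectory(series)
  inc <- diff(tr$mean_ratio)
  expect_true(all(inc > 0)) # monotone rise throughout
  # deceleration after the breakpoint stage: later increments are an
  # order of magnitude below the first
  expect_true(all(inc[5:9] < inc[1] / 4))
})

test_that("single-power-law stage means follow the closed form", {
  a <- 0.3; b <- 1.2
  hw <- exp(seq(log(10), log(250), length.out = 30))
  series <- data.frame(rap_mm = a * hw^b, hw_mm = hw)
  tr <- ontogeny_trajectory(series)
  edges <- seq(log(10), log(250), length.out = 11)
  stage <- findInterval(log(hw), edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
  for (s in which(tr$n_in_bin > 0)) {
    # per-bin mean of b + ln(a)/ln(hw)
    expected <- b + log(a) * mean(1 / log(hw[stage == s]))
    expect_equal(tr$mean_ratio[s], expected, tolerance = 1e-12)
  }
})

test_that("unit convention matters: mm and cm give different ratios", {
  series_mm <- simulate_ontogeny(noise_sd = 0)
  series_cm <- series_mm
  series_cm$rap_mm <- series_mm$rap_mm / 10
  series_cm$hw_mm <- series_mm$hw_mm / 10
  tr_mm <- ontogeny_trajectory(series_mm)
  tr_cm <- ontogeny_trajectory(series_cm)
  expect_false(isTRUE(all.equal(tr_mm$mean_ratio, tr_cm$mean_ratio)))
  # pin the mm convention on a hand value: ln(4)/ln(50)
  single <- data.frame(rap_mm = c(4, 4), hw_mm = c(50, 60))
  expect_equal(ontogeny_trajectory(single, n_stages = 2)$mean_ratio[1],
               log(4) / log(50), tolerance = 1e-12)
})

test_that("degenerate ontogeny inputs error clearly", {
  expect_error(ontogeny_trajectory(data.frame(rap_mm = numeric(),
                                              hw_mm = numeric())), "empty")
  expect_error(
    ontogeny_trajectory(data.frame(rap_mm = c(2, 3), hw_mm = c(1, 50))),
    "1 mm")
})

test_that("chain entries map to stages by the ceiling rule", {
  # m = 15: first entry stage 1, entry 8 -> stage 6, last entry stage 10
  lnhw <- seq(3, 5, length.out = 15)
  lnrap <- 0.8 * lnhw
  tr <- evolution_trajectory(lnrap, lnhw)
  stage_of <- ceiling(10 * seq_len(15) / 15)
  expect_equal(stage_of[1], 1)
  expect_equal(stage_of[8], 6)
  expect_equal(stage_of[15], 10)
  expect_equal(tr$n_in_bin, as.integer(table(factor(stage_of, levels = 1:10))))
  expect_equal(sum(tr$n_in_bin), 15L)

  # m = 10: identity mapping
  tr10 <- evolution_trajectory(lnrap[1:10], lnhw[1:10])
  expect_equal(tr10$n_in_bin, rep(1L, 10))

  # m < n_stages still reaches stage 1 and stage 10
  tr5 <- evolution_trajectory(lnrap[1:5], lnhw[1:5])
  expect_gt(tr5$n_in_bin[2], 0)
  expect_gt(tr5$n_in_bin[10], 0)

  expect_error(evolution_trajectory(lnrap, lnhw[1:10]), "mismatch")
  expect_error(evolution_trajectory(1, 1), "at least 2")
})

test_that("log-ratio convention is the difference of logs", {
  lnhw <- seq(3, 5, length.out = 10)
  lnrap <- lnhw - 1.5
  tr <- evolution_trajectory(lnrap, lnhw, ratio = "log-ratio")
  expect_equal(tr$mean_ratio, rep(-1.5, 10))
})

test_that("inverted heterochrony is flagged from inflection stages", {
  # ontogeny rising sharply to stage 3 then flat; evolution flat with a
  # late rise at stage 8
  onto_means <- c(0.5, 0.65, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8)
  evo_means <- c(0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.86, 0.92)
  mk <- function(means, kind) {
    df <- data.frame(stage = 1:10, mean_ratio = means,
                     n_in_bin = rep(1L, 10), bin_lo = NA_real_,
                     bin_hi = NA_real_)
    class(df) <- c("stage_trajectory", "data.frame")
    attr(df, "kind") <- kind
    df
  }
  cmp <- compare_trajectories(mk(evo_means, "evolution"),
                              mk(onto_means, "ontogeny"))
  expect_equal(cmp$inflection_onto, 3L)
  expect_equal(cmp$inflection_evo, 8L)
  expect_true(cmp$inversion_flag)
  expect_equal(cmp$stage_diff$diff, evo_means - onto_means)

  # identical linear trajectories: no inflection, no inversion
  lin <- mk(seq(0.5, 0.9, length.out = 10), "ontogeny")
  cmp2 <- compare_trajectories(mk(seq(0.5, 0.9, length.out = 10), "evolution"),
                               lin)
  expect_true(is.na(cmp2$inflection_evo))
  expect_false(cmp2$inversion_flag)

  # equal step functions: equal inflections, no inversion
  step <- c(rep(0.5, 5), rep(0.9, 5))
  cmp3 <- compare_trajectories(mk(step, "evolution"), mk(step, "ontogeny"))
  expect_equal(cmp3$inflection_evo, cmp3$inflection_onto)
  expect_false(cmp3$inversion_flag)

  sparse <- mk(c(0.5, 0.6, rep(NA, 8)), "ontogeny")
  sparse$n_in_bin <- c(1L, 1L, rep(0L, 8))
  expect_error(compare_trajectories(mk(evo_means, "evolution"), sparse),
               "nonempty")
})

test_that("ties in the second difference resolve to the earliest stage", {
  means <- c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4) # equal |d2| at many stages
  df <- data.frame(stage = 1:10, mean_ratio = means, n_in_bin = 1L,
                   bin_lo = NA_real_, bin_hi = NA_real_)
  class(df) <- c("stage_trajectory", "data.frame")
  cmp <- compare_trajectories(df, df)
  expect_equal(cmp$inflection_evo, 2L)
})
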