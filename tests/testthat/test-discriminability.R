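# The gap statistic, border line and normal-model separation probability.

test_that("the gap statistic is min(large) - max(small)", {
  expect_equal(compute_delta(volume_sample(10, 70, c(80, 90)),
                             volume_sample(30, 70, c(150, 200))), 60)
  # overlapping ranges give a negative gap
  expect_equal(compute_delta(volume_sample(10, 70, c(80, 160)),
                             volume_sample(30, 70, c(150, 200))), -10)
  expect_error(compute_delta(volume_sample(10, 70, numeric(0)),
                             volume_sample(30, 70, 150)), "empty")
  expect_error(compute_delta(volume_sample(30, 70, 80),
                             volume_sample(10, 70, 150)), "smaller")
})

test_that("the border is the lower norm limit minus half the gap", {
  s30 <- volume_summary(214.80, 36.87, 25, injected_volume = 30, kv = 70)
  expect_equal(compute_border(s30, 0), unname(s30$norm_interval[1]))
  s <- volume_summary(120, 10.2040816326530613, 25, injected_volume = 30)
  expect_equal(s$norm_interval[["lower"]], 100)
  expect_equal(compute_border(s, 20), 90)
  expect_equal(compute_border(s, -10), 105)  # overlap raises the border
})

test_that("separation probability follows the normal model", {
  s <- volume_summary(90, 10, 25, injected_volume = 10)
  expect_equal(separation_probability(s, 90), 0.5)      # border at the mean
  expect_equal(separation_probability(s, 110), stats::pnorm(2))
  # published-summary-scale inputs: z ~ 5.2 -> essentially certain
  s1070 <- volume_summary(89.46, 10.14, 25, injected_volume = 10, kv = 70)
  p <- separation_probability(s1070, 142.52)
  expect_gt(p, 0.9999)
  # degenerate SD
  s0 <- volume_summary(90, 0, 25, injected_volume = 10)
  expect_equal(separation_probability(s0, 100), 1)
  expect_equal(separation_probability(s0, 80), 0)
})

test_that("separation probability is monotone in border and mean", {
  s <- volume_summary(90, 10, 25, injected_volume = 10)
  borders <- seq(60, 140, by = 5)
  p <- sapply(borders, separation_probability, summary_small = s)
  expect_true(all(diff(p) >= 0))
  means <- seq(60, 140, by = 5)
  p2 <- sapply(means, function(m)
    separation_probability(volume_summary(m, 10, 25, 10), 100))
  expect_true(all(diff(p2) <= 0))
})

test_that("closed form matches a Monte-Carlo sampling oracle", {
  set.seed(99)
  for (r in 1:20) {
    mu <- stats::runif(1, 50, 150)
    sd <- stats::runif(1, 5, 40)
    border <- stats::runif(1, 40, 180)
    n <- 1e5
    draws <- stats::rnorm(n, mu, sd)
    p_mc <- mean(draws < border)
    p_cf <- separation_probability(volume_summary(mu, sd, 25, 10), border)
    se <- sqrt(max(p_cf * (1 - p_cf), 1 / n) / n)
    expect_lte(abs(p_mc - p_cf), 3 * se + 1e-12)
  }
})

test_that("assessment chains gap, border and probability with the 95% cutoff", {
  set.seed(12)
  small <- volume_sample(10, 70, stats::rnorm(25, 90, 10))
  large <- volume_sample(30, 70, stats::rnorm(25, 215, 37))
  res <- assess_discriminability(small, large)
  expect_equal(res$border,
               compute_border(summarize_volumes(large),
                              compute_delta(small, large)))
  expect_equal(res$prob_above_border, 1 - res$separation_probability)
  expect_identical(res$reliable, res$separation_probability > 0.95)
  # identical groups cannot be differentiated
  same <- stats::rnorm(25, 100, 10)
  res2 <- assess_discriminability(volume_sample(10, 70, same),
                                  volume_sample(30, 70, same))
  expect_false(res2$reliable)
})

test_that("well-separated groups are reliably differentiated across replicates", {
  # a 20k-replicate brute-force simulation of this design puts the
  # reliability rate at 0.950 (SE 0.0015); 89/100 is its 3-sigma lower bound
  set.seed(314)
  reliable <- 0L
  for (r in 1:100) {
    small <- volume_sample(10, 70, stats::rnorm(25, 90, 10))
    large <- volume_sample(30, 70, stats::rnorm(25, 200, 35))
    if (assess_discriminability(small, large)$reliable)
      reliable <- reliable + 1L
  }
  expect_gte(reliable, 89L)
})

test_that("the assessment is invariant under reordering of sample values", {
  set.seed(21)
  sv <- stats::rnorm(25, 90, 10); lv <- stats::rnorm(25, 200, 35)
  r1 <- assess_discriminability(volume_sample(10, 70, sv),
                                volume_sample(30, 70, lv))
  r2 <- assess_discriminability(volume_sample(10, 70, sample(sv)),
                                volume_sample(30, 70, sample(lv)))
  expect_equal(r1$delta, r2$delta)
  expect_equal(r1$border, r2$border)
  expect_equal(r1$separation_probability, r2$separation_probability)
})
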