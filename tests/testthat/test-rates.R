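test_that("the plating-rate arithmetic reproduces the worked example and edge cases", {
  r <- rate_from_plating(15, 1e-2, 10, 1e-7)
  expect_equal(r$rate, 1.5e-5, tolerance = 1e-12)
  expect_false(r$censored)

  expect_equal(rate_from_plating(20, 1e-3, 20, 1e-3)$rate, 1)
  expect_error(rate_from_plating(15, 1e-2, 0, 1e-7), "culture size")
  expect_error(rate_from_plating(15, 2, 10, 1e-7), "dilutions")
  z <- rate_from_plating(0, 1e-2, 10, 1e-7)
  expect_equal(z$rate, 0)
  expect_true(z$censored)
})

test_that("rate is invariant to how the dilution is split from the count expectation", {
  a <- rate_from_plating(30, 2e-2, 10, 1e-7)$rate
  b <- rate_from_plating(15, 1e-2, 10, 1e-7)$rate
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("fold change divides by the wild-type mean and logs naturally", {
  rates <- data.frame(
    genotype = c("WT", "WT", "mut"),
    rate = c(1e-5, 2.06e-5, 5.06e-5),
    sample_id = c("w1", "w2", "m1"))
  out <- fold_change_ln(rates, "WT")
  expect_equal(attr(out, "wt_mean_rate"), 1.53e-5)
  expect_equal(out$fold_change[3], 5.06e-5 / 1.53e-5, tolerance = 1e-12)
  expect_equal(out$fold_change[3], 3.307, tolerance = 1e-3)
  expect_equal(out$ln_fold[3], 1.196, tolerance = 1e-3)

  at_mean <- data.frame(genotype = "WT", rate = 1.53e-5, sample_id = "w")
  om <- fold_change_ln(at_mean, "WT")
  expect_equal(om$fold_change, 1)
  expect_equal(om$ln_fold, 0)

  expect_error(fold_change_ln(rates, "nope"), "wild-type label")
  rates0 <- rbind(rates, data.frame(genotype = "mut", rate = 0, sample_id = "m0"))
  expect_warning(o0 <- fold_change_ln(rates0, "WT"), "zero-rate")
  expect_true(is.na(o0$ln_fold[4]) && !o0$ln_defined[4])
})

test_that("mean WT ln fold equals log of geometric over arithmetic mean", {
  cf <- make_colony_fixture(1.5e-5, n_cultures = 40, seed = 9)
  rt <- rate_table(cf)
  out <- fold_change_ln(rt, "WT")
  lhs <- mean(out$ln_fold[out$genotype == "WT"])
  gm <- exp(mean(log(out$rate[out$genotype == "WT"])))
  expect_equal(lhs, log(gm / mean(out$rate[out$genotype == "WT"])),
               tolerance = 1e-12)
})

test_that("simulated two-genotype fixtures recover the planted fold change and rate", {
  wt <- make_colony_fixture(1.5e-5, n_cultures = 50, genotype = "WT", seed = 11)
  mut <- make_colony_fixture(6.0e-5, n_cultures = 50, genotype = "mut", seed = 12)
  out <- fold_change_ln(rate_table(rbind(wt, mut)), "WT")
  expect_equal(mean(out$fold_change[out$genotype == "mut"]), 4, tolerance = 0.10)

  # the per-culture ratio estimator carries a small Jensen bias of order
  # 1/E[colonies_permissive] from the reciprocal of the permissive count
  big <- make_colony_fixture(1.5e-5, n_cultures = 200, seed = 13)
  est <- rate_table(big)$rate
  se <- sd(est) / sqrt(length(est))
  jensen <- 1.5e-5 / mean(big$colonies_permissive)
  expect_lt(abs(mean(est) - 1.5e-5), 3 * se + jensen)
})
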