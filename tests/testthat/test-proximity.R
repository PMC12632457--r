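iv <- function(chrom, start, end) {
  list(chrom = chrom, start = start, end = end)
}

test_that("interval gap handles overlap, separation and chromosome partition", {
  expect_equal(interval_gap(iv("chrI", 100, 200), iv("chrI", 150, 300)), 0)
  expect_equal(interval_gap(iv("chrI", 100, 200), iv("chrI", 250, 300)), 50)
  expect_equal(interval_gap(iv("chrI", 100, 200), iv("chrI", 200, 300)), 0) # book-ended
  expect_equal(interval_gap(iv("chrI", 100, 200), iv("chrII", 100, 200)), Inf)
  expect_equal(interval_gap(iv("chrI", 250, 300), iv("chrI", 100, 200)), 50) # symmetric
})

test_that("sorted sweep equals the brute-force scan on planted and random interval sets", {
  fx <- make_interval_fixture(30, 25, c(chrI = 3e5, chrII = 3e5),
                              planted_fraction = 0.4, seed = 5)
  expect_identical(nearest_peak(fx$features, fx$peaks),
                   oracle_nearest_gap(fx$features, fx$peaks))
  for (seed in 1:30) {
    feats <- random_interval_set(25, seed = seed)
    pks <- random_interval_set(18, seed = seed + 1000)
    expect_identical(nearest_peak(feats, pks), oracle_nearest_gap(feats, pks))
  }
})

test_that("features overlapping a peak score zero; chromosomes without peaks score Inf", {
  feats <- intervals(data.frame(chrom = c("chrI", "chrIII"),
                                start = c(100L, 100L), end = c(200L, 200L),
                                name = c("f1", "f2")))
  pks <- intervals(data.frame(chrom = "chrI", start = 150L, end = 160L,
                              name = "p1"))
  d <- nearest_peak(feats, pks)
  expect_equal(d, c(0, Inf))
  expect_true(all(nearest_peak(feats, pks[0, ]) == Inf))
})

test_that("proximity fraction returns planted fractions exactly and respects edge cases", {
  fx <- make_interval_fixture(40, 30, c(chrI = 4e5, chrII = 4e5),
                              planted_fraction = 0.5, threshold_bp = 600,
                              seed = 7)
  pr <- proximity_fraction(fx$features, fx$peaks, threshold = 600)
  expect_equal(pr$fraction, 0.5)
  expect_equal(pr$n_within, 20L)

  pr_inf <- proximity_fraction(fx$features, fx$peaks, threshold = Inf)
  expect_equal(pr_inf$fraction, 1)
  pr_none <- proximity_fraction(fx$features, fx$peaks[0, ], threshold = 600)
  expect_equal(pr_none$fraction, 0)
  expect_error(proximity_fraction(fx$features[0, ], fx$peaks), "empty feature")
})

test_that("the within-threshold fraction is monotone in the threshold", {
  feats <- random_interval_set(40, seed = 11)
  pks <- random_interval_set(15, seed = 12)
  fr <- vapply(c(0, 100, 300, 600, 1200, 5000, 2e4),
               function(th) proximity_fraction(feats, pks, th)$fraction, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("record order never changes proximity output", {
  feats <- random_interval_set(30, seed = 21)
  pks <- random_interval_set(20, seed = 22)
  pr1 <- proximity_fraction(feats, pks)
  withr::with_seed(5, {
    feats2 <- feats[sample(nrow(feats)), ]
    pks2 <- pks[sample(nrow(pks)), ]
  })
  pr2 <- proximity_fraction(feats2, pks2)
  expect_equal(pr2$fraction, pr1$fraction)
  m1 <- pr1$per_feature[order(pr1$per_feature$name), ]
  m2 <- pr2$per_feature[order(pr2$per_feature$name), ]
  expect_equal(m2$nearest_distance, m1$nearest_distance, ignore_attr = TRUE)
})
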