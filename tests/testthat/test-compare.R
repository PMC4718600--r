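test_that("identical groups are never significant", {
  r <- compare_feature_pair(c(3, 3, 3), c(3, 3, 3))
  expect_equal(r$statistic, 0)
  expect_false(r$significant)
  expect_equal(r$direction, 0)
})

test_that("small-sample rank-test p-values match exact enumeration", {
  r <- compare_feature_pair(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$p, 2 / 20)  # only the two extreme assignments
  expect_equal(r$p, oracle_kw_exact(c(1, 2, 3), c(4, 5, 6)))
  set.seed(31)
  for (i in 1:12) {
    a <- round(runif(sample(3:6, 1), 0, 10), 1)
    b <- round(runif(sample(3:6, 1), 0, 10) + runif(1, 0, 3), 1)
    r <- compare_feature_pair(a, b)
    expect_equal(r$p, oracle_kw_exact(a, b), tolerance = 1e-12,
                 info = paste("case", i))
  }
  # quantized values with heavy ties
  a <- c(0, 30, 30, 60); b <- c(30, 60, 60, 90)
  expect_equal(compare_feature_pair(a, b)$p, oracle_kw_exact(a, b))
})

test_that("direction falls back to means when medians tie", {
  a <- c(1, 5, 9)        # median 5, mean 5
  b <- c(0, 5, 100)      # median 5, mean 35
  r <- compare_feature_pair(a, b)
  expect_equal(r$direction, 1)
  r2 <- compare_feature_pair(b, a)
  expect_equal(r2$direction, -1)
})

test_that("missing values are dropped and tiny groups rejected", {
  r <- compare_feature_pair(c(1, 2, NA, 3), c(4, NA, 5, 6))
  expect_equal(r$n_a, 3)
  expect_equal(r$n_b, 3)
  expect_error(compare_feature_pair(c(1, NA, NA), c(2, 3)), "at least two")
})

test_that("agreement counts stratify by the direct verdict", {
  m <- rbind(rep(TRUE, 9), rep(FALSE, 9), c(rep(TRUE, 4), rep(FALSE, 5)))
  res <- agreement_counts(m, direct_significant = c(TRUE, FALSE, TRUE))
  expect_equal(unname(res$counts), c(9, 0, 4))
  expect_equal(as.integer(res$histogram[c("0", "4", "9")]), c(1, 1, 1))
  expect_equal(as.integer(res$histogram_direct_sig["9"]), 1)
  expect_equal(as.integer(res$histogram_direct_nonsig["0"]), 1)
  m2 <- m; m2[2, 3] <- NA
  expect_warning(res2 <- agreement_counts(m2), "excluded")
  expect_length(res2$counts, 2)
})

test_that("two-sample KS p-values match exact path enumeration", {
  # fully separated samples: D = 1
  a <- 1:10 / 100; b <- 1:10 / 100 + 5
  r <- specific_effects(list(`0` = a), list(`0` = b))
  expect_equal(r$D, 1)
  expect_equal(r$p, oracle_ks_exact(10, 10, 1), tolerance = 1e-10)
  set.seed(17)
  for (i in 1:10) {
    n <- sample(4:10, 1); m <- sample(4:10, 1)
    x <- rnorm(n); y <- rnorm(m, 0.5)
    r <- specific_effects(list(`0` = x), list(`0` = y))
    expect_equal(r$p, oracle_ks_exact(n, m, r$D), tolerance = 1e-9,
                 info = paste("case", i))
  }
})

test_that("specific effects flag per-stimulus modulations with direction", {
  set.seed(23)
  dirs <- as.character(seq(0, 330, 30))
  a <- lapply(seq(0, 330, 30), function(d) rnorm(10, 20, 2))
  names(a) <- dirs
  b <- a
  b[["240"]] <- b[["240"]] + 15   # strong enhancement at 240 only
  r <- specific_effects(a, b)
  expect_equal(nrow(r), 12)
  expect_true(r$significant[r$direction == 240])
  expect_equal(r$direction_of_change[r$direction == 240], 1)
  expect_lt(sum(r$significant), 4)  # other directions mostly null
  # suppression flips the sign
  b2 <- a; b2[["60"]] <- b2[["60"]] - 15
  r2 <- specific_effects(a, b2)
  expect_equal(r2$direction_of_change[r2$direction == 60], -1)
  # identical ensembles: D = 0, never significant
  r3 <- specific_effects(a, a)
  expect_true(all(r3$D == 0))
  expect_false(any(r3$significant))
})

test_that("stimuli with fewer than two trials are marked untestable", {
  a <- list(`0` = c(1, 2, 3), `30` = c(5))
  b <- list(`0` = c(1, 2, 9), `30` = c(4, 5))
  r <- specific_effects(a, b)
  expect_false(r$testable[r$direction == 30])
  expect_true(r$testable[r$direction == 0])
  expect_true(is.na(r$p[r$direction == 30]))
})

test_that("population summaries aggregate specific effects", {
  blank <- data.frame(direction = seq(0, 330, 30), n_a = 5, n_b = 5,
                      D = 0.2, p = 0.8, significant = FALSE,
                      direction_of_change = 1, testable = TRUE)
  s <- specific_effect_summary(list(blank, blank))
  expect_equal(as.integer(s$count_histogram["0"]), 2)
  expect_true(all(s$per_stimulus$fraction_none == 1))
  one <- blank
  one$significant[one$direction %in% c(0, 120, 240)] <- TRUE
  one$direction_of_change[one$direction == 240] <- -1
  s2 <- specific_effect_summary(list(one))
  expect_equal(as.integer(s2$count_histogram["3"]), 1)
  expect_equal(s2$per_stimulus$fraction_enhanced[s2$per_stimulus$direction == 0], 1)
  expect_equal(s2$per_stimulus$fraction_suppressed[s2$per_stimulus$direction == 240], 1)
  expect_equal(rowSums(s2$per_stimulus[, -1]), rep(1, 12))
})
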