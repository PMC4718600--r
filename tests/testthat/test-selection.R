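fake_fit <- function(sse, M, K = 12, family = "F2", converged = TRUE) {
  structure(list(family = family, modality = "unimodal", sse = sse,
                 chi2 = sse, K = K, M = M, converged = converged),
            class = "tunefit")
}

test_that("AIC follows K log(SSE/K) + 2M", {
  expect_equal(AIC(fake_fit(120, 5)), 12 * log(10) + 10)
  # hand value ~ 37.631
  expect_equal(AIC(fake_fit(120, 5)), 37.63102, tolerance = 1e-5)
  # equal SSE, M = 5 vs 7: difference exactly 4
  expect_equal(AIC(fake_fit(80, 7)) - AIC(fake_fit(80, 5)), 4)
  # scaling SSE by e raises AIC by exactly K
  expect_equal(AIC(fake_fit(80 * exp(1), 5)) - AIC(fake_fit(80, 5)), 12)
  expect_warning(a <- AIC(fake_fit(0, 5)), "SSE = 0")
  expect_lt(a, -1e9)
})

test_that("AICc adds the small-sample correction", {
  expect_equal(aicc(fake_fit(120, 5)) - AIC(fake_fit(120, 5)), 10)
  expect_equal(aicc(fake_fit(120, 9)) - AIC(fake_fit(120, 9)), 90)
  expect_error(aicc(fake_fit(120, 11)), "undefined")
  # correction vanishes as K grows
  expect_lt(aicc(fake_fit(1200, 5, K = 1200)) - AIC(fake_fit(1200, 5, K = 1200)), 0.06)
})

test_that("select_model ranks by delta and breaks ties deterministically", {
  s <- select_model(list(fake_fit(100, 5, family = "F2")))
  expect_equal(s$best, "F2")
  expect_equal(s$table$delta, 0)

  fits <- list(fake_fit(100, 5, family = "F2"),
               fake_fit(100, 5, family = "F3"),
               fake_fit(90, 9, family = "F4"))
  names(fits) <- c("F2", "F3", "F4")
  s <- select_model(fits)
  expect_equal(min(s$table$delta), 0)
  expect_true(s$best %in% s$contenders)
  # exact AIC tie between F2 and F3 (same SSE, same M): order breaks it
  fits2 <- list(F3 = fake_fit(100, 5, family = "F3"),
                F2 = fake_fit(100, 5, family = "F2"))
  expect_equal(select_model(fits2)$best, "F2")
  # tie across different M: parsimony wins
  sse7 <- 100 * exp(-4 / 12)  # compensates the 2*(7-5) penalty exactly
  fits3 <- list(wG = fake_fit(sse7, 7, family = "wG"),
                F2 = fake_fit(100, 5, family = "F2"))
  s3 <- select_model(fits3)
  expect_equal(s3$best, "F2")
  expect_setequal(s3$contenders, c("wG", "F2"))
})

test_that("non-converged fits are excluded with a warning", {
  fits <- list(F2 = fake_fit(100, 5, family = "F2"),
               wG = fake_fit(1, 7, family = "wG", converged = FALSE))
  expect_warning(s <- select_model(fits), "wG")
  expect_equal(s$best, "F2")
  expect_error(suppressWarnings(select_model(list(
    wG = fake_fit(1, 7, family = "wG", converged = FALSE)))), "no converged")
})

test_that("population fractions count best and contender models", {
  sel1 <- select_model(list(wG = fake_fit(50, 7, family = "wG"),
                            F2 = fake_fit(500, 5, family = "F2")))
  fr <- model_fractions(list(sel1, sel1))
  expect_equal(fr$fraction_best[fr$family == "wG"], 1)
  expect_equal(fr$fraction_contender[fr$family == "wG"], 1)
  expect_equal(fr$fraction_best[fr$family == "F2"], 0)

  sel2 <- select_model(list(wG = fake_fit(500, 7, family = "wG"),
                            F4 = fake_fit(50, 9, family = "F4")))
  fr2 <- model_fractions(list(sel1, sel2))
  expect_equal(fr2$fraction_best[fr2$family == "wG"], 0.5)
  expect_equal(fr2$fraction_best[fr2$family == "F4"], 0.5)
  expect_equal(sum(fr2$fraction_best), 1)
  expect_error(model_fractions(list()), "no selections")
})

test_that("the generating family wins model selection on its own surrogates", {
  # Surrogate ensemble built from F3 fits to noisy bimodal curves: among the
  # five 7-parameter families F3 should be selected most often.  Trial noise
  # is homoscedastic across directions here so that the weighted fits are
  # also the least-squares fits that AIC (unweighted SSE) ranks.
  set.seed(21)
  th <- seq(0, 330, 30)
  n_cells <- 80
  wins <- character(n_cells)
  fams7 <- c("F3", "sbeta", "vM", "wC", "wG")
  for (i in seq_len(n_cells)) {
    p <- c(runif(1, 12, 30), runif(1, 30, 55), 120,
           runif(1, 12, 30), runif(1, 30, 55), 240, runif(1, 2, 8))
    mu <- eval_tuning("wG", p, th, modality = "bimodal")
    sig <- rep(0.38 * mean(mu), 12)
    base <- tuning_curve(pmax(mu + rnorm(12, 0, sig), 0), sigma = sig,
                         condition = "afix")
    f3 <- tunefit(base, "F3")
    sur <- simulate(f3, nsim = 1)[[1]]
    fits <- lapply(fams7, function(f) tunefit(sur, f, modality = "bimodal"))
    names(fits) <- fams7
    wins[i] <- suppressWarnings(select_model(fits)$best)
  }
  tab <- table(factor(wins, levels = fams7))
  expect_equal(names(which.max(tab)), "F3")
})
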