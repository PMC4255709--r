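test_that("G-skew R-loop potential follows the sense strand strictly", {
  expect_equal(gskew_rloop_potential("GGGCC", "+"), 1L)
  expect_equal(gskew_rloop_potential("GGCC", "+"), 0L)   # tie -> 0
  expect_equal(gskew_rloop_potential("GGGCC", "-"), 0L)  # sense = revcomp
  expect_equal(gskew_rloop_potential("CCCGG", "-"), 1L)
  expect_equal(gskew_rloop_potential("GNGCC", "+"), 0L)  # N counts as neither
  expect_warning(g <- gskew_rloop_potential("GGGCC", "*"), "unknown")
  expect_true(is.na(g))
})

test_that("logistic fits match closed forms on saturated 2x2 designs", {
  # intercept-only, balanced outcome
  d <- data.frame(M = rep(c(0, 1), 25))
  f <- fit_logistic(d, M ~ 1)
  expect_equal(unname(f$coefficients[1, 1]), 0, tolerance = 1e-8)
  expect_equal(f$deviance, f$null_deviance)

  # cells (x=0: 25/75, x=1: 75/25): intercept log(1/3), slope log(9)
  d <- data.frame(x = rep(c(0, 1), each = 100),
                  M = c(rep(c(1, 0), c(25, 75)), rep(c(1, 0), c(75, 25))))
  f <- fit_logistic(d, M ~ x)
  expect_equal(unname(f$coefficients["(Intercept)", 1]), log(1 / 3),
               tolerance = 1e-6)
  expect_equal(unname(f$coefficients["x", 1]), log(9), tolerance = 1e-6)
})

test_that("logistic fit agrees with a grid-search likelihood maximiser", {
  withr::local_seed(61)
  for (i in 1:3) {
    x <- rbinom(80, 1, 0.5)
    y <- rbinom(80, 1, plogis(-0.5 + 1.2 * x))
    if (length(unique(y)) < 2 || length(unique(x)) < 2) next
    f <- fit_logistic(data.frame(x = x, M = y), M ~ x)
    oracle <- grid_logistic_oracle(x, y)
    expect_equal(unname(f$coefficients[, 1]), oracle, tolerance = 1e-3)
  }
})

test_that("rank-deficient designs error with the collinear term named", {
  d <- data.frame(M = rbinom(50, 1, 0.5), a = rep(c(0, 1), 25))
  d$b <- d$a
  expect_error(fit_logistic(d, M ~ a + b), "collinear.*b")
})

test_that("deviance reduction has its closed form for a perfect predictor", {
  d <- data.frame(M = rep(c(0, 1), each = 50), x = rep(c(0, 1), each = 50))
  dr <- deviance_reduction(d, "x")
  expect_equal(dr$reduction, 2 * 100 * log(2), tolerance = 1e-4)
  expect_lt(dr$p, 1e-10)
  # duplicated factor column gives the identical reduction
  d$y <- d$x
  expect_equal(deviance_reduction(d, "y")$reduction, dr$reduction)
})

test_that("added-value test of a duplicate factor is null", {
  d <- data.frame(M = rbinom(200, 1, 0.5), a = rbinom(200, 1, 0.5))
  d$b <- d$a
  av <- added_value_test(d, "a", "b")
  expect_equal(av$reduction, 0, tolerance = 1e-8)
  expect_equal(av$p, 1)
})

test_that("added-value test detects an independent true effect", {
  sim <- sim_factor_table(5000, c(`(Intercept)` = -0.5, a = 0.8, b = 1.0),
                          prevalence = c(a = 0.5, b = 0.5), seed = 67)
  av <- added_value_test(sim$table, "a", "b")
  expect_lt(av$p, 1e-6)
})

test_that("interaction network tests every pair with Bonferroni m = pairs", {
  sim <- sim_factor_table(
    2000, c(`(Intercept)` = -0.5, a = 0.6, b = -0.6, c = 0.4, d = -0.4,
            e = 0.5),
    prevalence = c(a = 0.5, b = 0.4, c = 0.6, d = 0.5, e = 0.3), seed = 73)
  net <- interaction_network(sim$table, c("a", "b", "c", "d", "e"))
  expect_equal(nrow(net), choose(5, 2))
  expect_equal(attr(net, "m"), 10)
  expect_equal(net$p_bonferroni, pmin(net$p * 10, 1))
})

test_that("a strong planted interaction is detected after Bonferroni", {
  sim <- sim_factor_table(
    5000, c(`(Intercept)` = -0.5, a = 0.5, b = 0.5, c = 0.3, `a:b` = 1.5),
    prevalence = c(a = 0.5, b = 0.5, c = 0.5), seed = 79)
  net <- interaction_network(sim$table, c("a", "b", "c"))
  ab <- net[net$factor1 == "a" & net$factor2 == "b", ]
  expect_true(ab$significant)
  expect_gt(ab$effect_size, 10)
})

test_that("printed-coefficient models evaluate correctly", {
  coefs <- c(`(Intercept)` = -1.31, P = -1.63, E2F1 = -3.49, `P:E2F1` = 0.60)
  p <- predict_logistic(coefs, data.frame(P = c(0, 1, 0), E2F1 = c(0, 0, 1)))
  expect_equal(p, plogis(c(-1.31, -2.94, -4.80)), tolerance = 1e-12)
  expect_gt(p[1], 0.2)
  expect_lt(p[2], 0.2)
  expect_lt(p[3], 0.01)
})

test_that("stratified odds ratios are protective-oriented", {
  # one stratum: 2x2 with unexposed 10 methylated / 20 not,
  # exposed 5 methylated / 40 not
  d <- data.frame(M = c(rep(1, 10), rep(0, 20), rep(1, 5), rep(0, 40)),
                  E = c(rep(0, 30), rep(1, 45)), S = "s1")
  res <- stratified_or(d, "E", "S")
  expect_equal(res$or_protective, 4.0)
  expect_equal(res$or_risk, 0.25)
  expect_equal(res$meth_reduction_pp,
               100 * (10 / 30 - 5 / 45), tolerance = 1e-12)
  expect_false(res$degenerate)
  # independence -> OR near 1 (simulated)
  sim <- sim_factor_table(4000, c(`(Intercept)` = -0.3, E = 0),
                          prevalence = c(E = 0.5), seed = 83)
  sim$table$S <- "all"
  res <- stratified_or(sim$table, "E", "S")
  expect_gt(res$or_protective, 0.8)
  expect_lt(res$or_protective, 1.25)
})

test_that("stratified OR recovers generator odds ratios within 2 SE", {
  # two strata calibrated to protective ORs 1.5 and 2.8
  mk <- function(n, p0, or, seed) {
    # P(M|E=0)=p0; odds(M|E=1) = odds(M|E=0)/or
    odds1 <- (p0 / (1 - p0)) / or
    p1 <- odds1 / (1 + odds1)
    withr::with_seed(seed, data.frame(
      M = c(rbinom(n, 1, p0), rbinom(n, 1, p1)),
      E = rep(c(0, 1), each = n)))
  }
  d <- rbind(cbind(mk(2000, 0.3, 1.5, 87), S = "pa"),
             cbind(mk(2000, 0.6, 2.8, 89), S = "intra"))
  res <- stratified_or(d, "E", "S")
  for (i in seq_len(nrow(res))) {
    truth <- if (res$stratum[i] == "pa") 1.5 else 2.8
    tab <- d[d$S == res$stratum[i], ]
    a <- sum(tab$M == 1 & tab$E == 0); b <- sum(tab$M == 0 & tab$E == 0)
    cc <- sum(tab$M == 1 & tab$E == 1); dd <- sum(tab$M == 0 & tab$E == 1)
    se_log <- sqrt(1 / a + 1 / b + 1 / cc + 1 / dd)
    expect_lt(abs(log(res$or_protective[i]) - log(truth)), 2 * se_log)
  }
})

test_that("factor correlations are phi coefficients with flagged constants", {
  d <- data.frame(a = c(0, 0, 1, 1), b = c(1, 1, 0, 0), M = c(0, 1, 0, 1))
  cm <- factor_correlations(d)
  expect_equal(cm["a", "a"], 1)
  expect_equal(cm["a", "b"], -1)
  d$const <- 1
  expect_warning(cm <- factor_correlations(d), "constant")
  expect_true(all(is.na(cm["const", c("a", "b", "M")])))
})
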