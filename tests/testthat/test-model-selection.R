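test_that("2-SD standardization matches hand arithmetic and affine invariance", {
  expect_equal(as.numeric(standardize_2sd(c(0, 2))),
               c(-1, 1) / (2 * sqrt(2)))
  z <- rnorm(50)
  zs <- standardize_2sd(z)
  expect_equal(sd(zs), 0.5)
  expect_equal(as.numeric(standardize_2sd(3 - 2 * z)), -as.numeric(zs))
  expect_error(standardize_2sd(rep(1, 10)), "constant")
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(aicc(0, 1, 100), 2 + 4 / 98)
  expect_equal(aicc(-10, 3, 1e9), 26, tolerance = 1e-6)  # AIC limit
  expect_error(aicc(0, 5, 6), "n > K")
})

test_that("linear fits expose exact least-squares likelihood quantities", {
  set.seed(31)
  d <- data.frame(x = rnorm(40))
  d$y <- 1 + 2 * d$x  # exact linear relation: flagged as a perfect fit
  expect_warning(f <- fit_linear(y ~ x, d), "perfect fit")
  expect_equal(f$r2_marginal, 1)
  expect_equal(unname(coef(f)), c(1, 2), tolerance = 1e-10)
  # intercept-only logLik equals the closed-form Gaussian value
  d$y2 <- rnorm(40, 5, 2)
  f0 <- fit_linear(y2 ~ 1, d)
  s2_ml <- mean((d$y2 - mean(d$y2))^2)
  expect_equal(f0$logLik, -20 * (log(2 * pi * s2_ml) + 1))
  expect_equal(f0$K, 2)  # mean + residual variance
  # slope recovery within 3 SE under noise
  d$y3 <- 2 * d$x + rnorm(40)
  f3 <- fit_linear(y3 ~ x, d)
  expect_lt(abs(f3$coefficients["x", 1] - 2),
            3 * f3$coefficients["x", 2])
  # aliased columns are named
  d$x2 <- d$x
  expect_error(fit_linear(y3 ~ x + x2, d), "aliased.*x2")
})

test_that("selection tables reproduce weight arithmetic", {
  # hand-set delta pattern: logLik chosen so AICc deltas are exact
  tab <- selection_table(data.frame(
    name = c("m1", "m2", "m3", "m4", "m5"),
    logLik = c(0, -2.19, -5.19, -9.28, -12.15) / 2,
    K = 3, n = 87))
  w <- exp(-c(0, 2.19, 5.19, 9.28, 12.15) / 2)
  expect_equal(tab$weight, w / sum(w))
  expect_equal(round(tab$weight[1], 2), 0.70)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(tab$weight) <= 0))
  # two identical models split evenly; a single model gets weight 1
  two <- selection_table(data.frame(name = c("a", "b"), logLik = -5,
                                    K = 2, n = 30))
  expect_equal(two$weight, c(0.5, 0.5))
  one <- selection_table(data.frame(name = "a", logLik = -5, K = 2, n = 30))
  expect_equal(one$weight, 1)
  expect_error(selection_table(data.frame(name = c("a", "b"), logLik = -5,
                                          K = 2, n = c(30, 31))),
               "not comparable")
})

test_that("weights depend on likelihoods only through differences", {
  base <- data.frame(name = c("a", "b", "c"), logLik = c(-10, -12, -15),
                     K = c(4, 3, 2), n = 50)
  shifted <- base
  shifted$logLik <- base$logLik + 7.3
  t1 <- selection_table(base)
  t2 <- selection_table(shifted)
  expect_equal(t1$delta, t2$delta)
  expect_equal(t1$weight, t2$weight)
  # an implausible model barely perturbs existing weights
  far <- rbind(base, data.frame(name = "junk", logLik = -10 - 25, K = 4,
                                n = 50))
  t3 <- selection_table(far)
  expect_lt(max(abs(t3$weight[match(base$name, t3$name)] - t1$weight)),
            1e-10)
})

test_that("model averaging follows the natural-average and RVI sum rules", {
  m1 <- stub_model("m1", -10, 3, 50, c(`(Intercept)` = 1, x = 1.0),
                   se = c(0.2, 0.3))
  m2 <- stub_model("m2", -10, 3, 50, c(`(Intercept)` = 1, x = 2.0),
                   se = c(0.2, 0.3))
  tab <- data.frame(name = c("m1", "m2"), weight = c(0.75, 0.25),
                    averaging_set = TRUE)
  avg <- model_average(list(m1, m2), tab)
  x <- avg[avg$term == "x", ]
  expect_equal(x$estimate, 1.25)
  expect_equal(x$rvi, 1)
  # Buckland unconditional SE
  expect_equal(x$se_unconditional,
               0.75 * sqrt(0.09 + 0.0625) + 0.25 * sqrt(0.09 + 0.5625))
  # identical coefficients average to themselves with no deviation term
  m2b <- stub_model("m2", -10, 3, 50, c(`(Intercept)` = 1, x = 1.0),
                    se = c(0.2, 0.3))
  avg2 <- model_average(list(m1, m2b), tab)
  expect_equal(avg2[avg2$term == "x", "estimate"], 1)
  expect_equal(avg2[avg2$term == "x", "se_unconditional"], 0.3)
  # RVI sums full-set weights of models containing the predictor
  m3 <- stub_model("m3", -10, 2, 50, c(`(Intercept)` = 1))
  tab3 <- data.frame(name = c("m1", "m2", "m3"),
                     weight = c(0.6, 0.3, 0.1), averaging_set = TRUE)
  avg3 <- model_average(list(m1, m2, m3), tab3)
  expect_equal(avg3[avg3$term == "x", "rvi"], 0.9)
})

test_that("random-intercept ML collapses to ordinary least squares when flat", {
  set.seed(32)
  d <- data.frame(x = rnorm(120), g = rep(letters[1:6], each = 20))
  d$y <- 1 + 0.5 * d$x + rnorm(120)  # no group effect
  fr <- fit_random_intercept(y ~ x, d, "g")
  fl <- fit_linear(y ~ x, d)
  expect_lte(fl$logLik, fr$logLik + 1e-9)
  if (fr$boundary) expect_equal(fr$logLik, fl$logLik, tolerance = 1e-6)
  expect_equal(fr$K, 4)  # 2 fixed effects + 2 variance components
})

test_that("variance-ratio recovery is unbiased enough at scale", {
  set.seed(33)
  est <- replicate(40, {
    g <- rep(seq_len(50), each = 20)
    u <- rnorm(50)          # between-group variance 1
    y <- u[g] + rnorm(1000) # residual variance 1
    f <- fit_random_intercept(y ~ 1, data.frame(y = y, g = g), "g")
    f$lambda
  })
  expect_lt(abs(median(est) - 1), 0.3)
})

test_that("the profiled optimum dominates a brute-force lambda grid", {
  set.seed(34)
  for (i in 1:5) {
    g <- rep(1:9, each = 10)
    y <- rnorm(9)[g] * 0.7 + rnorm(90) + 0.3 * (g / 3)
    d <- data.frame(y = y, x = rnorm(90), g = g)
    f <- fit_random_intercept(y ~ x, d, "g")
    X <- cbind(1, d$x)
    grid <- grid_ri_loglik(d$y, X, factor(d$g),
                           c(0, exp(seq(-10, 6, length.out = 120))))
    expect_gte(f$logLik, max(grid) - 1e-8)
  }
})

test_that("ML and REML likelihoods agree with an independent mixed-model engine", {
  skip_if_not_installed("lme4")
  set.seed(35)
  sim <- generate_isotope_dataset(niche_scenario("H2"), seed = 36)
  d <- sim$data
  d$length_s <- as.numeric(standardize_2sd(d$length))
  own_ml <- fit_random_intercept(d15N ~ length_s * status, d, "site", "ML")
  ref_ml <- lme4::lmer(d15N ~ length_s * status + (1 | site), d,
                       REML = FALSE)
  expect_equal(own_ml$logLik, as.numeric(stats::logLik(ref_ml)),
               tolerance = 1e-6)
  expect_equal(unname(coef(own_ml)), unname(lme4::fixef(ref_ml)),
               tolerance = 1e-5)
  own_reml <- fit_random_intercept(d15N ~ length_s * status, d, "site",
                                   "REML")
  ref_reml <- lme4::lmer(d15N ~ length_s * status + (1 | site), d,
                         REML = TRUE)
  expect_equal(own_reml$logLik, as.numeric(stats::logLik(ref_reml)),
               tolerance = 1e-6)
})

test_that("the d15N candidate set is the five nested models on shared data", {
  sim <- generate_isotope_dataset(niche_scenario("H2"), seed = 37)
  ms <- d15n_model_set(sim$data)
  expect_length(ms, 5)
  expect_true(all(vapply(ms, `[[`, numeric(1), "n") == nrow(sim$data)))
  expect_true(all(vapply(ms, `[[`, logical(1), "has_random_intercept")))
  # marginality: the interaction model carries both main effects
  inter <- ms[["Length + Status + Length*Status"]]
  expect_setequal(rownames(inter$coefficients),
                  c("(Intercept)", "length_s", "statusprotected",
                    "length_s:statusprotected"))
  tab <- selection_table(ms)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  avg <- model_average(ms, tab)
  expect_true(all(avg$rvi >= 0 & avg$rvi <= 1))
})
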