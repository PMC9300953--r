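test_that("km_estimate reproduces hand product-limit results", {
  # all events at 1, 2, 3
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # middle observation censored: S(1) = 2/3, S(3) = (2/3) * (1 - 1/1) = 0
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$time, c(1, 3))
  expect_equal(km2$survival, c(2 / 3, 0))
  # no events: S identically 1
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km3), 0)
  expect_equal(km_survival_at(km3, c(0, 5)), c(1, 1))
})

test_that("km_estimate is invariant to input ordering and validates input", {
  set.seed(21)
  tm <- rexp(40); ev <- rbinom(40, 1, 0.6)
  o <- sample(40)
  expect_equal(km_estimate(tm, ev)$survival, km_estimate(tm[o], ev[o])$survival)
  expect_error(km_estimate(numeric(0), numeric(0)), class = "sighub_parameter_error")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), class = "sighub_parameter_error")
})

test_that("km_estimate agrees with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(22)
  tm <- round(rexp(60, 0.1), 1); ev <- rbinom(60, 1, 0.7)
  km <- km_estimate(tm, ev)
  sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
  s_or <- summary(sf, times = km$time)$surv
  expect_equal(km$survival, s_or, tolerance = 1e-12)
})

test_that("logrank_test matches the hand-computed 6-subject tied example", {
  # A: (1,e) (3,e) (5,c); B: (1,e) (4,c) (6,e); tie at t=1.
  # t=1: n=6, nA=3, d=2, dA=1 -> E=1,   V=2*.5*.5*4/5=0.4
  # t=3: n=4, nA=2, d=1, dA=1 -> E=0.5, V=0.25
  # t=6: n=1, nA=0, d=1       -> E=0,   V=0
  # O=2, E=1.5, V=0.65, chi2=0.25/0.65
  lr <- logrank_test(c(1, 3, 5), c(1, 1, 0), c(1, 4, 6), c(1, 0, 1))
  expect_equal(lr$observed_a, 2)
  expect_equal(lr$expected_a, 1.5)
  expect_equal(lr$variance, 0.65)
  expect_equal(lr$statistic, 0.25 / 0.65, tolerance = 1e-12)
})

test_that("logrank_test is zero on identical groups and symmetric in labels", {
  tm <- c(2, 4, 6, 8); ev <- c(1, 0, 1, 1)
  same <- logrank_test(tm, ev, tm, ev)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(23)
  t1 <- rexp(30); e1 <- rbinom(30, 1, 0.7)
  t2 <- rexp(25, 0.5); e2 <- rbinom(25, 1, 0.7)
  expect_equal(logrank_test(t1, e1, t2, e2)$statistic,
               logrank_test(t2, e2, t1, e1)$statistic, tolerance = 1e-12)
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
               class = "sighub_degenerate_error")
})

test_that("logrank_test agrees with survival::survdiff", {
  skip_if_not_installed("survival")
  set.seed(24)
  for (i in 1:10) {
    t1 <- round(rexp(40, 0.2), 1); e1 <- rbinom(40, 1, 0.7)
    t2 <- round(rexp(40, 0.3), 1); e2 <- rbinom(40, 1, 0.7)
    lr <- logrank_test(t1, e1, t2, e2)
    sd_ <- survival::survdiff(
      survival::Surv(c(t1, t2), c(e1, e2)) ~ rep(1:2, c(40, 40)))
    expect_equal(lr$statistic, sd_$chisq, tolerance = 1e-10)
  }
})

test_that("median_split follows the documented tie rule", {
  s1 <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(s1), c("low", "low", "high", "high"))
  s2 <- median_split(c(1, 2, 3))
  expect_equal(abs(sum(s2 == "low") - sum(s2 == "high")), 1)
  s3 <- median_split(c(1, 1, 2, 2))
  expect_equal(sum(s3 == "low"), 2)
  expect_equal(sum(s3 == "high"), 2)
  # ties at the cut value are assigned to low first, in sample order
  s4 <- median_split(c(2, 1, 2, 3))
  expect_equal(as.character(s4), c("low", "low", "high", "high"))
  expect_error(median_split(rep(5, 4)), class = "sighub_degenerate_error")
})

test_that("cox_univariate recovers a known coefficient and matches coxph", {
  set.seed(25)
  n <- 400
  x <- rnorm(n)
  tm <- round(rexp(n, exp(0.7 * x) / 20), 1)   # rounding induces ties
  cen <- runif(n, 0, 40)
  ev <- as.numeric(tm <= cen); t2 <- pmin(tm, cen)
  fit <- cox_univariate(t2, ev, x)
  expect_true(fit$converged)
  skip_if_not_installed("survival")
  or <- survival::coxph(survival::Surv(t2, ev) ~ x, ties = "efron")
  expect_equal(fit$beta, unname(coef(or)), tolerance = 1e-6)
  expect_equal(fit$se, unname(sqrt(vcov(or)[1, 1])), tolerance = 1e-6)
})

test_that("cox score test at beta = 0 equals the log-rank statistic", {
  set.seed(26)
  for (i in 1:10) {
    n <- 80
    tm <- rexp(n) + seq_len(n) * 1e-7     # break ties
    ev <- rbinom(n, 1, 0.75)
    x <- rbinom(n, 1, 0.5)
    if (var(x) == 0 || sum(ev) < 5) next
    fit <- cox_univariate(tm, ev, x)
    lr <- logrank_test(tm[x == 1], ev[x == 1], tm[x == 0], ev[x == 0])
    expect_equal(fit$score_chisq_0, lr$statistic, tolerance = 1e-8)
  }
})

test_that("cox null Wald p-values are approximately uniform", {
  set.seed(27)
  p <- replicate(500, {
    n <- 120
    tm <- rexp(n); ev <- rbinom(n, 1, 0.7); x <- rnorm(n)
    cox_univariate(tm, ev, x)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("cox log partial likelihood is maximized (degenerate inputs error)", {
  set.seed(28)
  tm <- rexp(50); ev <- rbinom(50, 1, 0.8); x <- rnorm(50)
  fit <- cox_univariate(tm, ev, x)
  # perturbing beta in either direction must not increase the likelihood
  eval_ll <- function(b) {
    o <- order(tm)
    sighub:::cox_eval(b * sd(x[o] - mean(x)), scale(x[o])[, 1], tm[o], ev[o])$loglik
  }
  expect_lte(eval_ll(fit$beta + 0.01), fit$loglik + 1e-8)
  expect_lte(eval_ll(fit$beta - 0.01), fit$loglik + 1e-8)
  expect_error(cox_univariate(tm, ev, rep(1, 50)), class = "sighub_degenerate_error")
  expect_error(cox_univariate(tm, rep(0, 50), x), class = "sighub_degenerate_error")
})

test_that("binary-covariate beta sign agrees with the lower KM curve", {
  set.seed(29)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, exp(0.9 * x) / 10)
  ev <- rep(1, n)
  fit <- cox_univariate(tm, ev, x)
  km1 <- km_estimate(tm[x == 1], ev[x == 1])
  km0 <- km_estimate(tm[x == 0], ev[x == 0])
  t_star <- min(max(tm[x == 1]), max(tm[x == 0]))
  below <- km_survival_at(km1, t_star) < km_survival_at(km0, t_star)
  expect_equal(fit$beta > 0, below)
})
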