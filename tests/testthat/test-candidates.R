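test_that("unadjusted logistic OR on a 2x2 table equals ad/bc", {
  # counts: exposed/event 20, exposed/no 10, unexposed/event 5, unexposed/no 25
  y <- rep(c(1, 0, 1, 0), c(20, 10, 5, 25))
  x <- rep(c(1, 1, 0, 0), c(20, 10, 5, 25))
  n <- length(y)
  samp <- make_samples(n, 1)
  samp$pcr <- as.integer(y)
  score <- setNames(x, samp$sample_id)
  got <- univariable_adjusted(score, samp, adjust = character(0), feature = "f")
  expect_equal(got$odds_ratio, (20 * 25) / (10 * 5), tolerance = 1e-6)
  expect_equal(got$n_used, n)
})

test_that("adjusted fit matches a direct glm oracle", {
  set.seed(41)
  n <- 150
  samp <- make_samples(n, 1)
  samp$t_stage <- sample(1:4, n, TRUE)
  samp$n_stage <- sample(0:2, n, TRUE)
  s <- rnorm(n)
  samp$pcr <- rbinom(n, 1, plogis(0.8 * s - 0.2 * samp$t_stage))
  score <- setNames(s, samp$sample_id)
  got <- univariable_adjusted(score, samp, adjust = c("t_stage", "n_stage"),
                              feature = "f")
  oracle <- glm(samp$pcr ~ s + samp$t_stage + samp$n_stage, family = binomial)
  b <- coef(summary(oracle))["s", ]
  expect_equal(got$odds_ratio, exp(b["Estimate"]), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(got$p_value, b["Pr(>|z|)"], ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(got$ci_low, exp(b["Estimate"] - qnorm(0.975) * b["Std. Error"]),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("perfect separation yields the infinite-OR sentinel", {
  n <- 40
  samp <- make_samples(n, 20)
  score <- setNames(as.numeric(samp$pcr) * 2 - 1, samp$sample_id)
  got <- suppressWarnings(  # glm also warns about fitted 0/1
    univariable_adjusted(score, samp, adjust = character(0), feature = "sep"))
  expect_true(got$separated)
  expect_identical(got$odds_ratio, Inf)
  expect_true(is.na(got$ci_low))
})

test_that("constant feature aborts and few events warn", {
  samp <- make_samples(30, 4)
  score <- setNames(rep(1, 30), samp$sample_id)
  expect_error(univariable_adjusted(score, samp, adjust = character(0)),
               class = "radresp_scoring_error")
  score2 <- setNames(rnorm(30), samp$sample_id)
  expect_warning(univariable_adjusted(score2, samp, adjust = character(0)),
                 "fewer than 10 events")
})

test_that("backward stepwise retains true features and drops noise", {
  set.seed(42)
  n <- 200
  samp <- make_samples(n, 1)
  f1 <- rnorm(n); f2 <- rnorm(n); noise <- rnorm(n)
  samp$pcr <- rbinom(n, 1, plogis(1.2 * f1 - 1.0 * f2))
  feats <- cbind(f1 = f1, f2 = f2, noise = noise)
  rownames(feats) <- samp$sample_id
  m <- backward_stepwise(feats, samp, adjust = character(0))
  expect_setequal(m$retained, c("f1", "f2"))
  expect_identical(m$trace$feature, "noise")
  expect_s3_class(m, "stepwise_model")
  # retained features all have drop-one LR p <= alpha (self-consistency)
  expect_true(all(vapply(m$retained, function(v) {
    red <- glm(samp$pcr ~ ., data = as.data.frame(feats[, setdiff(m$retained, v),
                                                        drop = FALSE]),
               family = binomial)
    stat <- 2 * (m$log_likelihood - as.numeric(logLik(red)))
    pchisq(stat, 1, lower.tail = FALSE) <= 0.05
  }, logical(1))))
})

test_that("stepwise on pure noise can eliminate everything, with warning", {
  set.seed(43)
  n <- 80
  samp <- make_samples(n, 1)
  samp$pcr <- rbinom(n, 1, 0.5)
  feats <- matrix(rnorm(n * 2), n, 2, dimnames = list(samp$sample_id, c("a", "b")))
  # not guaranteed empty for one draw; use a draw where both p-values are
  # large, asserted via the model itself
  m <- suppressWarnings(backward_stepwise(feats, samp, adjust = character(0)))
  expect_true(length(m$retained) %in% 0:2)
  if (!length(m$retained)) expect_equal(nrow(m$trace), 2L)
})

test_that("compound_score is the retained linear predictor", {
  set.seed(44)
  n <- 120
  samp <- make_samples(n, 1)
  f1 <- rnorm(n); f2 <- rnorm(n)
  samp$pcr <- rbinom(n, 1, plogis(1.5 * f1 + 1.2 * f2))
  feats <- cbind(f1 = f1, f2 = f2)
  rownames(feats) <- samp$sample_id
  m <- backward_stepwise(feats, samp, adjust = character(0))
  cs <- compound_score(m, feats)
  manual <- m$intercept + feats[, m$retained, drop = FALSE] %*%
    m$coefficients[m$retained]
  expect_equal(unname(cs), unname(as.numeric(manual)), tolerance = 1e-12)
  cs0 <- compound_score(m, feats, include_intercept = FALSE)
  expect_equal(cs - cs0, setNames(rep(m$intercept, n), samp$sample_id))
  expect_error(compound_score(m, feats[, 1, drop = FALSE][, 0, drop = FALSE]),
               class = "radresp_validation_error")
})

test_that("AUC equals brute-force all-pairs concordance, ties at 1/2", {
  set.seed(45)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    score <- sample(round(rnorm(n), 1))  # rounding forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    pairs <- outer(score[labels == 1], score[labels == 0],
                   function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(score, labels)$auc, mean(pairs), tolerance = 1e-12)
  }
  # constant score: all ties -> 0.5
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), class = "radresp_validation_error")
})

test_that("ROC polyline starts at (0,0), ends at (1,1), is monotone", {
  set.seed(46)
  r <- roc_auc(rnorm(40), rbinom(40, 1, 0.4))$roc
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

test_that("LRT matches the chi-square oracle", {
  set.seed(47)
  n <- 100
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(x1))
  f0 <- glm(y ~ x1, family = binomial)
  f1 <- glm(y ~ x1 + x2, family = binomial)
  got <- likelihood_ratio_test(f0, f1)
  stat <- 2 * (as.numeric(logLik(f1)) - as.numeric(logLik(f0)))
  expect_equal(got$statistic, stat, tolerance = 1e-10)
  expect_equal(got$df, 1L)
  expect_equal(got$p_value, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # identical models -> df 0, p 1
  same <- likelihood_ratio_test(f1, f1)
  expect_equal(same$df, 0L)
  expect_equal(same$p_value, 1)
  # non-nested rejected
  f2 <- glm(y ~ x2, family = binomial)
  expect_error(likelihood_ratio_test(f2, f0), class = "radresp_validation_error")
})

test_that("meta-analysis reproduces the closed-form fixture", {
  m <- meta_analyse(c(1, 3), c(0.5, 0.5))
  expect_equal(m$beta, 2.0, tolerance = 1e-12)
  expect_equal(m$se, 1 / (2 * sqrt(2)), tolerance = 1e-9)  # = 0.353553
  expect_equal(m$Q, 8.0, tolerance = 1e-12)
  expect_equal(m$I2, 87.5, tolerance = 1e-12)
})

test_that("meta-analysis agrees with metafor in FE and DL modes", {
  beta <- c(0.4, 1.1, -0.2, 0.8); se <- c(0.3, 0.5, 0.4, 0.25)
  got <- meta_analyse(beta, se)
  fe <- metafor::rma(yi = beta, sei = se, method = "FE")
  dl <- metafor::rma(yi = beta, sei = se, method = "DL")
  expect_equal(got$beta, as.numeric(coef(fe)), tolerance = 1e-10)
  expect_equal(got$se, fe$se, tolerance = 1e-10)
  expect_equal(got$Q, fe$QE, tolerance = 1e-10)
  expect_equal(got$tau2, dl$tau2, tolerance = 1e-10)
  expect_equal(got$beta_re, as.numeric(coef(dl)), tolerance = 1e-10)
  expect_equal(got$se_re, dl$se, tolerance = 1e-10)
  expect_equal(got$I2, max(0, (fe$QE - 3) / fe$QE) * 100, tolerance = 1e-10)
})

test_that("meta-analysis singleton and input validation", {
  m <- meta_analyse(1.5, 0.4)
  expect_equal(m$beta, 1.5); expect_equal(m$Q, 0); expect_equal(m$I2, 0)
  expect_equal(m$beta_re, 1.5)
  expect_error(meta_analyse(numeric(0), numeric(0)),
               class = "radresp_validation_error")
  expect_error(meta_analyse(c(1, 2), c(0.5, 0)),
               class = "radresp_validation_error")
  expect_error(meta_analyse(c(1, 2), 0.5), class = "radresp_validation_error")
})
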