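test_that("normality screen flags outliers and degenerate vectors, not normal data", {
  set.seed(10)
  hits <- vapply(1:200, function(i) {
    screen_normality(data.frame(x = rnorm(15)))$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.005)   # the test has nonzero type-I rate
  expect_lt(mean(hits), 0.12)    # ... close to its nominal 5%
  out <- screen_normality(data.frame(x = c(rnorm(14), 10)))
  expect_lt(out$p, 0.05)
  expect_gte(out$n_outliers, 1L)
  cst <- screen_normality(data.frame(x = rep(1, 15)))
  expect_true(cst$degenerate)
})

test_that("Pearson correlation with Fisher interval and magnitude labels", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0, 6.3, 7.7)
  r1 <- pearson_with_ci(x, 2 * x + 1)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  r2 <- pearson_with_ci(x, -x)
  expect_equal(r2$r, -1, tolerance = 1e-12)
  expect_true(r1$ci_low <= r1$r && r1$r <= r1$ci_high)
  expect_equal(as.character(correlation_magnitude(c(0.05, 0.2, 0.4, 0.6, 0.9))),
               c("trivial", "small", "moderate", "strong", "very strong"))
  expect_error(pearson_with_ci(rep(1, 10), 1:10), "degenerate")
  expect_error(pearson_with_ci(1:3, 2:4), "at least 4")
})

test_that("Fisher 95% interval covers the true correlation at nominal rate", {
  set.seed(77)
  rho <- 0.5
  n <- 15
  cover <- vapply(1:1000, function(i) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- pearson_with_ci(x, y)
    ci$ci_low <= rho && rho <= ci$ci_high
  }, logical(1))
  expect_gt(mean(cover), 0.93)
  expect_lt(mean(cover), 0.97)
})

test_that("stepwise regression selects an exact predictor with beta 1", {
  set.seed(5)
  x1 <- rnorm(15); x2 <- rnorm(15)
  res <- suppressWarnings(   # lm warns about the perfect fit
    stepwise_regression(x1, data.frame(a = x1, b = x2)))
  expect_equal(res$selected, "a")
  expect_equal(res$coefficients$beta, 1, tolerance = 1e-10)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
})

test_that("with one predictor the standardized beta equals Pearson r", {
  set.seed(6)
  x <- rnorm(20)
  y <- x + 0.4 * rnorm(20)
  res <- stepwise_regression(y, data.frame(x = x))
  expect_equal(res$coefficients$beta, cor(x, y), tolerance = 1e-12)
})

test_that("no candidate entering yields an explicit empty model", {
  set.seed(9)
  y <- rnorm(20)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  res <- stepwise_regression(y, X, enter_p = 1e-6)
  expect_true(res$empty)
  expect_equal(res$r_squared, 0)
})

test_that("stepwise selection lands on a stable subset of the exhaustive search", {
  set.seed(123)
  n_agree <- 0
  for (i in 1:100) {
    n <- 15
    k <- sample(2:3, 1)
    X <- as.data.frame(matrix(rnorm(n * k), ncol = k))
    names(X) <- paste0("v", seq_len(k))
    beta <- sample(c(0, 0, 1, 2), k, replace = TRUE)
    y <- as.numeric(as.matrix(X) %*% beta + rnorm(n))
    res <- suppressWarnings(stepwise_regression(y, X))
    stable <- stable_subsets(y, X)
    found <- any(vapply(stable, function(s) identical(s, sort(res$selected)),
                        logical(1)))
    n_agree <- n_agree + found
    # coefficients must match a plain least-squares refit on z-scores
    if (!res$empty) {
      zs <- function(v) (v - mean(v)) / sd(v)
      fit <- lm(zs(y) ~ .,
                data = as.data.frame(lapply(X[, res$selected, drop = FALSE], zs)))
      expect_equal(sort(res$coefficients$beta),
                   sort(unname(coef(fit)[-1])), tolerance = 1e-10)
    }
  }
  expect_equal(n_agree, 100)
})

test_that("R-squared changes telescope to the model R-squared", {
  set.seed(31)
  n <- 30
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- X$a + 0.5 * X$b + rnorm(n, sd = 0.3)
  res <- stepwise_regression(y, X)
  expect_equal(sum(res$coefficients$R2_change), res$r_squared,
               tolerance = 1e-10)
})

test_that("repeated-measures ANOVA edge and oracle cases", {
  m <- matrix(rnorm(30), ncol = 2)
  m <- cbind(m[, 1], m[, 1], m[, 1])
  colnames(m) <- c("a", "b", "c")
  res_id <- rm_anova_holm(m)
  expect_equal(res_id$F, 0, tolerance = 1e-10)
  expect_true(all(res_id$pairs$d == 0))

  # two-condition case equals the paired t-test: F = t^2
  set.seed(12)
  m2 <- cbind(a = rnorm(15, 1), b = rnorm(15, 1.4))
  res2 <- rm_anova_holm(m2)
  tt <- t.test(m2[, 1], m2[, 2], paired = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-8)

  expect_equal(as.character(effect_magnitude(0.6)), "moderate")
  expect_equal(as.character(effect_magnitude(c(0.1, 0.3, 1.0))),
               c("trivial", "small", "strong"))
})

test_that("Holm adjustment dominates raw p-values monotonically", {
  set.seed(13)
  m <- matrix(rnorm(45), ncol = 3,
              dimnames = list(NULL, c("speed", "overspeed", "flat")))
  m[, 2] <- m[, 2] + 0.8
  res <- rm_anova_holm(m)
  p <- res$pairs[order(res$pairs$raw_p), ]
  expect_true(all(p$holm_p >= p$raw_p))
  expect_true(all(diff(p$holm_p) >= -1e-15))
})

test_that("Cohen's d is antisymmetric under pair swap", {
  set.seed(14)
  a <- rnorm(12); b <- rnorm(12, 0.5)
  d_ab <- rm_anova_holm(cbind(a = a, b = b))$pairs$d
  d_ba <- rm_anova_holm(cbind(b = b, a = a))$pairs$d
  expect_equal(d_ab, -d_ba, tolerance = 1e-12)
})

test_that("stepped model resolves an exact course-time dependency", {
  # synthetic cohort summaries where T is a linear function of the course
  # energy index
  fake_summary <- function(de, L, Fr, Ftot, RF, Fout, Fdiff, T) {
    course <- c(T_turn = 1.7, v_in = 15, v_avg = 15, L = L, dalt = 10,
                r = 20, F_tot = Ftot, F_out = Fout,
                F_ins = Ftot - Fout, F_diff = Fdiff, F_max = 3,
                F_maxout = 2.4, F_maxins = 1.4, F_r = Fr, RF = RF,
                de_per_vin = de)
    secs <- as.data.frame(rbind(speed = course, overspeed = course,
                                flat = course))
    structure(list(turns = NULL, course = course, sections = secs, T = T),
              class = "run_summary")
  }
  set.seed(15)
  de <- rnorm(12, -5.6, 0.5)
  L <- rnorm(12, 26.5, 0.3)
  RF <- runif(12, 0.6, 0.75)
  Ftot <- runif(12, 1.4, 1.8)
  Fr <- RF * Ftot
  split <- runif(12, 1.8, 2.2)
  summaries <- lapply(1:12, function(i)
    fake_summary(de[i], L[i], Fr[i], Ftot[i], RF[i],
                 Ftot[i] * split[i] / (1 + split[i]),
                 (split[i] - 1) / (split[i] + 1),
                 T = 40 - 2 * de[i]))
  rep <- run_stepped_model(summaries)
  l1 <- rep$datasets$course$level1
  expect_equal(l1$selected, "de_per_vin")
  expect_equal(l1$r_squared, 1, tolerance = 1e-9)
  l3 <- rep$datasets$course$level3
  expect_gt(l3$r_squared, 0.99)
  l4 <- rep$datasets$course$level4
  expect_gt(l4$r_squared, 0.99)
  suppressWarnings(
    expect_warning(run_stepped_model(summaries[1:3]), "below the recommended"))
})
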