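test_that("univariate screen matches the closed-form t test", {
  set.seed(3)
  x <- 1:10
  tab <- data.frame(x = x, y = 3 * x)
  sc <- suppressWarnings(univariateScreen(tab, "y"))   # exact fit warns
  expect_equal(sc$slope[sc$predictor == "x"], 3, tolerance = 1e-9)
  expect_true(sc$kept[sc$predictor == "x"])

  # independent predictor: p from the closed-form t distribution
  set.seed(17)
  n <- 200
  tab2 <- data.frame(z = rnorm(n), y = rnorm(n))
  sc2 <- univariateScreen(tab2, "y")
  fit <- lm(y ~ z, tab2)
  b <- coef(fit)[2]
  se <- sqrt(sum(residuals(fit)^2) / (n - 2) /
             sum((tab2$z - mean(tab2$z))^2))
  pHand <- 2 * pt(-abs(b / se), n - 2)
  expect_equal(sc2$p_value[sc2$predictor == "z"], unname(pHand),
               tolerance = 1e-9)
  expect_equal(sc2$kept[sc2$predictor == "z"], unname(pHand) < 0.2)

  expect_error(univariateScreen(data.frame(x = 1:2, y = c(1, 2)), "y"),
               "n < 3")
  expect_error(univariateScreen(data.frame(x = 1:5, y = rep(1, 5)), "y"),
               "constant outcome")
})

test_that("stepwise regression retains signal and drops noise", {
  set.seed(3)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 2 * x1 + rnorm(n)
  tab <- data.frame(y = y, x1 = x1, x2 = x2)
  res <- stepwiseRegression(tab, "y", c("x1", "x2"))
  expect_identical(res@retained, "x1")
  ci <- res@ci95["x1", ]
  expect_true(ci[1] <= 2 && 2 <= ci[2])
  expect_true(all(res@vifs >= 1))

  # duplicated column is reported by name
  tab$x3 <- tab$x1
  expect_error(stepwiseRegression(tab, "y", c("x1", "x2", "x3")),
               "x1 and x3")

  # nothing to enter: intercept-only with r2 = 0
  set.seed(8)
  tabN <- data.frame(y = rnorm(50), a = rnorm(50), b = rnorm(50))
  resN <- stepwiseRegression(tabN, "y", c("a", "b"), pEnter = 1e-6)
  expect_length(resN@retained, 0L)
  expect_equal(resN@r2, 0)
})

test_that("stepwise recovers the true support on seeded replicates", {
  # known linear model, strong signal: support recovered in >= 95/100 runs
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    n <- 120
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
    y <- 1.5 * x1 - 1 * x2 + rnorm(n, sd = sqrt((1.5^2 + 1) / 5))
    tab <- data.frame(y = y, x1 = x1, x2 = x2, x3 = x3)
    res <- stepwiseRegression(tab, "y", c("x1", "x2", "x3"))
    if (setequal(res@retained, c("x1", "x2"))) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("VIFs agree with the standard implementation", {
  set.seed(4)
  n <- 80
  x1 <- rnorm(n); x2 <- 0.7 * x1 + rnorm(n, sd = 0.5); x3 <- rnorm(n)
  y <- x1 + x2 + x3 + rnorm(n)
  tab <- data.frame(y = y, x1 = x1, x2 = x2, x3 = x3)
  res <- stepwiseRegression(tab, "y", c("x1", "x2", "x3"))
  fit <- lm(y ~ x1 + x2 + x3, tab)
  ref <- car::vif(fit)
  expect_equal(unname(res@vifs[c("x1", "x2", "x3")]),
               unname(ref[c("x1", "x2", "x3")]), tolerance = 1e-9)
})

test_that("ROC analysis uses the abnormality rule and rank AUC", {
  # strictly-below-cutoff labelling
  truth <- c(53.9, 54.0, 54.1, 60, 50)
  roc <- rocAnalysis(scores = truth, truth = truth, cutoff = 54)
  expect_equal(roc$n_abnormal, 2L)        # 53.9 and 50 only
  # perfectly separating scores
  expect_equal(rocAnalysis(c(40, 45, 65, 70), c(40, 45, 65, 70))$auc, 1)
  # uninformative scores
  expect_equal(rocAnalysis(rep(5, 6), c(40, 40, 40, 70, 70, 70))$auc, 0.5)
  expect_error(rocAnalysis(1:5, rep(80, 5)), "both")
})

test_that("rank AUC equals brute-force pair ordering on random inputs", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(6:50, 1)
    truth <- runif(n, 30, 80)
    scores <- truth + rnorm(n, sd = 8)
    if (sample(2, 1) == 1) scores <- round(scores)   # force ties sometimes
    if (min(truth) >= 54 || max(truth) < 54) next
    roc <- rocAnalysis(scores, truth)
    pos <- which(truth < 54); neg <- which(truth >= 54)
    risk <- -scores
    tot <- 0
    for (i in pos) for (j in neg)
      tot <- tot + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    expect_equal(roc$auc, tot / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with pROC", {
  set.seed(9)
  truth <- runif(40, 35, 75)
  scores <- truth + rnorm(40, sd = 6)
  roc <- rocAnalysis(scores, truth)
  ref <- suppressMessages(pROC::roc(response = truth < 54,
                                    predictor = -scores,
                                    direction = "<"))
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("agreement statistics hit identity and constant-shift forms", {
  x <- c(50, 55, 60, 65, 70)
  agIdent <- agreementStats(x, x)
  expect_equal(agIdent@meanDiff, 0)
  expect_equal(agIdent@linCCC, 1)
  expect_equal(agIdent@icc, 1)

  agShift <- agreementStats(x, x + 2)
  expect_equal(agShift@pearsonR, 1)
  expect_equal(agShift@meanDiff, -2)
  expect_lt(agShift@linCCC, 1)
})

test_that("agreement statistics match a 5-point hand oracle to 1e-9", {
  x <- c(52.1, 58.4, 61.0, 66.7, 71.2)
  y <- c(50.3, 59.1, 59.8, 68.2, 69.5)
  ag <- agreementStats(x, y)
  n <- 5
  d <- x - y
  md <- sum(d) / n
  sdd <- sqrt(sum((d - md)^2) / (n - 1))
  expect_equal(ag@meanDiff, md, tolerance = 1e-9)
  expect_equal(ag@loaLow, md - 1.96 * sdd, tolerance = 1e-9)
  expect_equal(ag@loaHigh, md + 1.96 * sdd, tolerance = 1e-9)
  tq <- qt(0.975, n - 1)
  expect_equal(ag@ciMean, c(md - tq * sdd / sqrt(n), md + tq * sdd / sqrt(n)),
               tolerance = 1e-9)
  expect_equal(ag@ciLoaLow,
               c(md - 1.96 * sdd - tq * sdd * sqrt(3 / n),
                 md - 1.96 * sdd + tq * sdd * sqrt(3 / n)), tolerance = 1e-9)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ag@pearsonR, r, tolerance = 1e-9)
  ccc <- 2 * sum((x - mean(x)) * (y - mean(y))) / n /
    (sum((x - mean(x))^2) / n + sum((y - mean(y))^2) / n +
       (mean(x) - mean(y))^2)
  expect_equal(ag@linCCC, ccc, tolerance = 1e-9)
  expect_equal(ag@biasCorrectionFactor, ccc / r, tolerance = 1e-9)
  # ICC(A,1) from the two-way ANOVA mean squares, assembled by hand
  k <- 2; grand <- mean(c(x, y))
  msr <- k * sum(((x + y) / 2 - grand)^2) / (n - 1)
  msc <- n * sum((c(mean(x), mean(y)) - grand)^2) / (k - 1)
  sse <- sum((c(x, y) - grand)^2) - k * sum(((x + y) / 2 - grand)^2) -
    n * sum((c(mean(x), mean(y)) - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  iccHand <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(ag@icc, iccHand, tolerance = 1e-9)
  # structural identities
  expect_lte(abs(ag@linCCC), abs(ag@pearsonR) + 1e-12)
  expect_equal(ag@linCCC, ag@pearsonR * ag@biasCorrectionFactor,
               tolerance = 1e-12)
  expect_error(agreementStats(x, y[1:4]), "length")
  expect_error(agreementStats(rep(1, 5), y), "zero variance")
})

test_that("Bonferroni adjustment is min(1, m p) and monotone", {
  p <- c(0.001, 0.02, 0.3, 0.9)
  adj <- bonferroniAdjust(p)
  expect_equal(adj, pmin(1, 4 * p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_equal(bonferroniAdjust(0.04, m = 10), 0.4)
})
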