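test_that("segment indicator applies the strict-inequality tie rule", {
    g <- seq(0, 2, length.out = 10)
    D <- PersistenceDiagram(cbind(0, 2), reduced = TRUE)
    cv <- lifespanCurve(D, g)
    zero <- lifespanCurve(PersistenceDiagram(reduced = TRUE), g)
    expect_identical(segmentIndicator(cv, cv, cv), 0L)    # tie -> 0
    expect_identical(segmentIndicator(cv, cv, zero), 1L)
    expect_identical(segmentIndicator(cv, zero, cv), 0L)
    # repeated calls agree
    expect_identical(segmentIndicator(cv, cv, zero),
                     segmentIndicator(cv, cv, zero))
})

test_that("cohort indicators use leave-one-out group means", {
    set.seed(21)
    # test patients cluster at 1, controls at 0
    curves <- rbind(matrix(1 + rnorm(40, 0, 0.01), 4),
                    matrix(rnorm(40, 0, 0.01), 4))
    isTest <- rep(c(TRUE, FALSE), each = 4)
    ind <- segmentIndicators(curves, isTest)
    expect_identical(unname(ind), c(rep(1L, 4), rep(0L, 4)))
    # invariance to patient ordering
    perm <- sample(8)
    expect_identical(unname(segmentIndicators(curves[perm, ],
                                              isTest[perm])),
                     unname(ind[perm]))
})

test_that("center-of-mass indicator thresholds on the one-sided t bound", {
    expect_identical(centerOfMassIndicator(0.5, 0.5, 0.1, 10, "gain"), 0L)
    expect_identical(centerOfMassIndicator(0.5, 0.5, 0.1, 10, "loss"), 0L)
    expect_identical(centerOfMassIndicator(1.5, 0.5, 0.1, 10, "gain"), 1L)
    # losses mirror the gain bound below the mean
    expect_identical(centerOfMassIndicator(-0.5, 0, 0.1, 10, "loss"), 1L)
    # loss bound at these parameters is 0.5 - 1.833 * 0.1 / sqrt(10) = 0.442
    expect_identical(centerOfMassIndicator(0.46, 0.5, 0.1, 10, "loss"), 0L)
    expect_identical(centerOfMassIndicator(0.43, 0.5, 0.1, 10, "loss"), 1L)
    # sigma = 0 collapses the interval to the mean
    expect_identical(centerOfMassIndicator(0.01, 0, 0, 10, "gain"), 1L)
    # explicit bound check at alpha = 0.05
    mu <- 0; sg <- 0.2; n <- 16
    thr <- mu + qt(0.95, n - 1) * sg / sqrt(n)
    expect_identical(centerOfMassIndicator(thr + 1e-9, mu, sg, n, "gain"), 1L)
    expect_identical(centerOfMassIndicator(thr - 1e-9, mu, sg, n, "gain"), 0L)
    expect_error(centerOfMassIndicator(0, 0, 1, 1, "gain"), "n >= 2")
})

test_that("null logistic model reproduces the closed-form Bernoulli AIC", {
    y <- c(rep(1, 7), rep(0, 3))
    X <- data.frame(noise = rep(0L, 10))   # constant covariate: never added
    m <- fitForwardAIC(X, y)
    expect_identical(m@covariates, character(0))
    expect_equal(m@logLik, 7 * log(0.7) + 3 * log(0.3))
    expect_equal(m@aic, 2 * 1 - 2 * (7 * log(0.7) + 3 * log(0.3)))
})

test_that("forward addition selects informative covariates and stops on AIC", {
    set.seed(13)
    n <- 60
    y <- rep(c(1, 0), each = n / 2)
    X <- data.frame(good = y, junk1 = rbinom(n, 1, 0.5),
                    junk2 = rbinom(n, 1, 0.5))
    m <- fitForwardAIC(X, y)
    expect_true("good" %in% m@covariates)
    expect_true(m@separated)   # perfect predictor separates
    # AIC identity: 2k - 2 lnL with k counting the intercept
    k <- length(coef(m@fit))
    expect_equal(m@aic, 2 * k - 2 * m@logLik)
    # independent covariates only: null model wins
    X0 <- data.frame(j1 = rbinom(n, 1, 0.5), j2 = rbinom(n, 1, 0.5))
    y0 <- rbinom(n, 1, 0.5)
    m0 <- fitForwardAIC(X0, y0)
    expect_equal(m0@aic, 2 * length(coef(m0@fit)) - 2 * m0@logLik)
    expect_error(fitForwardAIC(X, rep(1, n)), "both classes")
})

test_that("confusion matrices use the closed >= 0.5 threshold", {
    y <- c(1, 1, 0, 0)
    X <- data.frame(x = c(1, 1, 0, 0))
    m <- fitForwardAIC(X, y)
    cs <- predictConfusion(m, X, y)
    expect_equal(accuracy(cs), 1)
    expect_equal(cs@fp + cs@fn, 0)
    expect_equal(cs@tp + cs@fp + cs@tn + cs@fn, 4)
    # all probabilities exactly 0.5 -> everything classified positive
    ynull <- c(1, 0, 1, 0)
    mnull <- fitForwardAIC(data.frame(z = rep(0L, 4)), ynull)
    csnull <- predictConfusion(mnull, data.frame(z = rep(0L, 4)), ynull)
    expect_equal(csnull@tn + csnull@fn, 0)
    expect_equal(csnull@tp + csnull@fp, 4)
    expect_error(predictConfusion(m, data.frame(w = 1), y), "missing")
})

test_that("LOOCV MSE matches the Bernoulli variance on null data and 0 on perfect data", {
    set.seed(17)
    n <- 40
    y <- rep(c(1, 0), each = n / 2)
    Xgood <- data.frame(x = y)
    expect_lt(loocvMSE(Xgood, y), 0.05)
    Xnull <- data.frame(x = rbinom(n, 1, 0.5))
    mse <- loocvMSE(Xnull, y)
    phat <- mean(y)
    expect_equal(as.numeric(mse), phat * (1 - phat), tolerance = 0.1)
    expect_gte(as.numeric(mse), 0)
    expect_lte(as.numeric(mse), 1)
})

test_that("end-to-end subtype classifier recovers a planted segment", {
    ps <- makeToyProfileSet(nCase = 10, nCtrl = 10, gain = 1, seed = 8)
    rep <- classifySubtype(ps, "Case", nPerm = 199, seed = 2)
    expect_true("1qs1" %in% rep$segments)
    expect_true(rep$accuracy > 0.8)
    expect_true(rep$loocvMSE >= 0 && rep$loocvMSE <= 1)
})
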