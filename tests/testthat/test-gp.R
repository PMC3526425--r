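test_that("NN covariance matches its closed form and basic identities", {
    h <- list(l = c(1, 1), sigma = 1, noise = 0.1)
    expect_equal(nnCovariance(c(1, 0), c(1, 0), h), pi / 6,
                 tolerance = 1e-14)
    set.seed(42)
    for (i in 1:25) {
        xp <- c(1, runif(1, -3, 3)); xq <- c(1, runif(1, -3, 3))
        hh <- list(l = exp(runif(2, -2, 2)), sigma = exp(runif(1, -2, 2)),
                   noise = 0.1)
        k1 <- nnCovariance(xp, xq, hh)
        expect_equal(k1, nnCovariance(xq, xp, hh))      # symmetry
        hh2 <- hh; hh2$sigma <- 2 * hh$sigma
        expect_equal(nnCovariance(xp, xq, hh2), 2 * k1) # sigma is a factor
        # the asin argument is strictly inside (-1, 1)
        w <- 1 / hh$l^2
        r <- sum(xp * w * xq) /
            sqrt((1 + sum(xp * w * xp)) * (1 + sum(xq * w * xq)))
        expect_true(abs(r) < 1)
        expect_true(is.finite(k1))
    }
    expect_error(nnCovariance(c(1, 0), c(1, 0),
                              list(l = c(-1, 1), sigma = 1, noise = 0.1)),
                 "positive")
})

test_that("covariance matrices are symmetric and factorizable", {
    h <- list(l = c(0.7, 1.2), sigma = 1.4, noise = 0.2)
    X1 <- augmentTimes(24, 72)
    K1 <- covarianceMatrix(X1, h, jitter = 1e-8)
    expect_equal(dim(K1), c(1L, 1L))
    expect_equal(K1[1, 1],
                 nnCovariance(X1[1, ], X1[1, ], h) + 1e-8)
    times <- c(0, 12, 24, 48, 72)
    X <- augmentTimes(times, 72)
    K <- covarianceMatrix(X, h, jitter = 1e-8)
    expect_identical(K, t(K))
    expect_silent(chol(K))
    # duplicated rows (replicates at the same time) stay factorizable once
    # jitter and the noise term are in place
    Xr <- augmentTimes(rep(times, each = 3), 72)
    Kr <- covarianceMatrix(Xr, h) + diag(h$noise, 15)
    expect_silent(chol(Kr))
    expect_equal(diag(covarianceMatrix(X, h)),
                 vapply(seq_len(5), function(i)
                     nnCovariance(X[i, ], X[i, ], h), numeric(1)))
})

test_that("log marginal likelihood equals the multivariate-normal density", {
    # n = 1 closed forms: choose sigma so K(x,x) + noise = 1 at t = 0
    h <- list(l = c(1, 1), sigma = 0.5 / asin(0.5), noise = 0.5)
    X <- augmentTimes(0, 72)
    expect_equal(logMarginalLikelihood(X, 0, h), -0.5 * log(2 * pi),
                 tolerance = 1e-12)
    expect_equal(logMarginalLikelihood(X, 1, h), -0.5 - 0.5 * log(2 * pi),
                 tolerance = 1e-12)
    # brute-force oracle with explicit inverse and determinant
    set.seed(7)
    for (i in 1:30) {
        n <- sample(2:10, 1)
        t <- sort(runif(n, 0, 72))
        y <- rnorm(n)
        hh <- list(l = exp(runif(2, -1.5, 1.5)),
                   sigma = exp(runif(1, -1, 1)),
                   noise = exp(runif(1, -3, 0)))
        X <- augmentTimes(t, 72)
        Ky <- covarianceMatrix(X, hh) + diag(hh$noise, n)
        oracle <- -0.5 * drop(t(y) %*% solve(Ky) %*% y) -
            0.5 * determinant(Ky)$modulus[1] - 0.5 * n * log(2 * pi)
        expect_equal(logMarginalLikelihood(X, y, hh), oracle,
                     tolerance = 1e-8)
        # invariance under permutation of (input, target) pairs
        o <- sample(n)
        expect_equal(logMarginalLikelihood(X[o, , drop = FALSE], y[o], hh),
                     logMarginalLikelihood(X, y, hh), tolerance = 1e-8)
    }
})

test_that("fitGP is deterministic and monotone in restarts", {
    set.seed(11)
    t <- rep(c(0, 12, 24, 48, 72), each = 2)
    y <- sin(t / 20) + rnorm(10, 0, 0.2)
    f1 <- fitGP(t, y, nRestarts = 4, seed = 99)
    f2 <- fitGP(t, y, nRestarts = 4, seed = 99)
    expect_identical(f1@hyper, f2@hyper)
    expect_identical(f1@logMarginal, f2@logMarginal)
    # restart sub-seeds are nested, so more restarts never lose ground
    lml <- vapply(c(1, 2, 4, 8), function(r)
        fitGP(t, y, nRestarts = r, seed = 99)@logMarginal, numeric(1))
    expect_true(all(diff(lml) >= -1e-9))
    expect_equal(f1@logMarginal, max(f1@restartLogMarginals))
})

test_that("constant data reduces to the zero-signal noise-only model", {
    y <- rep(3.25, 8)
    t <- c(0, 0, 12, 24, 48, 48, 72, 72)
    f <- fitGP(t, y, nRestarts = 3, seed = 5)
    # oracle: zero-signal model log N(0 | 0, v I) maximized over the
    # feasible noise range [1e-12, Inf) -- the optimum pins at the floor
    oracle <- stats::optimize(function(lv)
        sum(stats::dnorm(y - mean(y), 0, sqrt(exp(lv)), log = TRUE)),
        lower = log(1e-12), upper = 5, maximum = TRUE,
        tol = .Machine$double.eps^0.5)
    bound <- sum(stats::dnorm(rep(0, 8), 0, sqrt(1e-12), log = TRUE))
    expect_gte(f@logMarginal + 1e-6, max(oracle$objective, bound))
    pp <- posteriorPredict(f, seq(0, 72, length.out = 20))
    expect_equal(pp$mean, rep(3.25, 20), tolerance = 1e-4)
    expect_true(all(pp$variance > 0))
})

test_that("fits never crash across dataset sizes and missing values", {
    set.seed(3)
    for (n in 2:20) {
        t <- sort(runif(n, 0, 72))
        y <- cos(t / 15) + rnorm(n, 0, 0.3)
        f <- fitGP(t, y, nRestarts = 2, seed = n)
        expect_true(is.finite(f@logMarginal))
    }
    # NA targets are dropped
    f <- fitGP(c(0, 12, 24, 48), c(1, NA, 2, 3), nRestarts = 2, seed = 1)
    expect_length(f@y, 3)
    expect_error(fitGP(c(0, 12), c(NA, 1), nRestarts = 1, seed = 1),
                 "fewer than 2")
})

test_that("noise variance is recovered from matched-model simulations", {
    # data drawn from the NN-covariance GP itself at the reference design
    # shape (42 observations), known noise variance 0.09
    trueNoise <- 0.3^2
    times <- rep(rep(c(0, 12, 24, 48, 72), times = c(3, 3, 3, 3, 2)), 3)
    h <- list(l = c(1, 0.6), sigma = 1.5, noise = 0)
    K <- covarianceMatrix(augmentTimes(times, 72), h, jitter = 1e-8)
    L <- chol(K)
    hit <- 0
    for (s in 1:50) {
        set.seed(1000 + s)
        f_latent <- drop(crossprod(L, rnorm(length(times))))
        y <- f_latent + rnorm(length(times), 0, sqrt(trueNoise))
        fit <- fitGP(times, y, nRestarts = 5, seed = s)
        est <- fit@hyper[["noise"]]
        if (est > trueNoise / 2 && est < trueNoise * 2) hit <- hit + 1
    }
    expect_gte(hit / 50, 0.8)
})

test_that("posterior prediction interpolates and widens off the data", {
    set.seed(21)
    t <- c(0, 12, 24, 48, 72)
    y <- c(5, 6.5, 7.2, 7.0, 6.0)
    # small-noise fit constructed directly: near-interpolation at the data
    f <- new("GPFit", times = t, y = y - mean(y), center = mean(y),
             tmax = 72, hyper = c(l_bias = 1, l_time = 0.3, sigma = 4,
                                  noise = 1e-8),
             logMarginal = 0, restartLogMarginals = 0)
    pp <- posteriorPredict(f, t)
    expect_equal(pp$mean, y, tolerance = 1e-3)
    far <- posteriorPredict(f, 720)
    expect_lt(max(pp$variance), far$variance)
    expect_true(all(pp$variance > 0))
})
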