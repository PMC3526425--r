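## Gaussian-process regression with the non-stationary neural-network (NN)
## covariance
##   k(x, x') = sigma * asin( x' diag(l^-2) x' /
##                sqrt[(1 + x' diag(l^-2) x)(1 + x'' diag(l^-2) x'')] )
## on bias-augmented inputs x = (1, t / tmax). The +1 terms bound the asin
## argument strictly inside (-1, 1) (Cauchy-Schwarz), so the kernel is always
## defined. Hyperparameters are optimized on the log scale by type-II maximum
## likelihood with analytic gradients.

#' Bias-augment and scale observation times
#'
#' Times are divided by \code{tmax} and prefixed with a constant bias entry
#' of 1, giving the two-dimensional inputs the NN covariance operates on.
#'
#' @param times numeric vector of times in hours.
#' @param tmax positive scaling constant (typically the maximum time in the
#'   dataset), so scaled times live in \code{[0, 1]}.
#' @return a numeric matrix with columns \code{bias} (all 1) and \code{time}.
#' @export
augmentTimes <- function(times, tmax) {
    stopifnot(is.numeric(times), tmax > 0)
    cbind(bias = 1, time = times / tmax)
}

checkHyper <- function(hyper) {
    if (!is.list(hyper) || !all(c("l", "sigma", "noise") %in% names(hyper)))
        stop("hyper must be a list with elements l, sigma, noise")
    if (any(hyper$l <= 0) || hyper$sigma <= 0 || hyper$noise < 0)
        stop("hyperparameters must be strictly positive (noise >= 0)")
    invisible(hyper)
}

#' Non-stationary neural-network covariance between two augmented inputs
#'
#' @param x_p,x_q numeric vectors of equal length (bias-augmented inputs, see
#'   [augmentTimes()]).
#' @param hyper list with \code{l} (positive lengthscale per input dimension),
#'   \code{sigma} (signal variance) and \code{noise} (noise variance; unused
#'   here but part of the hyperparameter set).
#' @return the scalar covariance \code{sigma * asin(...)}.
#' @examples
#' nnCovariance(c(1, 0), c(1, 0),
#'              hyper = list(l = c(1, 1), sigma = 1, noise = 0.1))  # pi/6
#' @export
nnCovariance <- function(x_p, x_q, hyper) {
    checkHyper(hyper)
    stopifnot(length(x_p) == length(x_q), length(x_p) == length(hyper$l))
    w <- 1 / hyper$l^2
    u <- sum(x_p * w * x_q)
    spp <- sum(x_p * w * x_p)
    sqq <- sum(x_q * w * x_q)
    hyper$sigma * asin(u / sqrt((1 + spp) * (1 + sqq)))
}

#' NN covariance matrix over a set of augmented inputs
#'
#' @param X numeric matrix, one augmented input per row.
#' @param hyper see [nnCovariance()].
#' @param jitter non-negative value added to the diagonal for numerical
#'   stability.
#' @return a symmetric matrix \code{K + jitter * I}.
#' @export
covarianceMatrix <- function(X, hyper, jitter = 0) {
    checkHyper(hyper)
    X <- as.matrix(X)
    stopifnot(nrow(X) >= 1, ncol(X) == length(hyper$l), jitter >= 0)
    w <- 1 / hyper$l^2
    Xw <- sweep(X, 2, sqrt(w), `*`)
    U <- tcrossprod(Xw)                  # x_p' diag(l^-2) x_q
    p <- 1 + diag(U)
    R <- U / sqrt(outer(p, p))
    R[R > 1] <- 1; R[R < -1] <- -1       # guard rounding at |r| ~ 1
    K <- hyper$sigma * asin(R)
    K <- (K + t(K)) / 2
    K + diag(jitter, nrow(K))
}

## Cholesky with escalating jitter: start at `jitter`, double up to 6 times.
cholSafe <- function(M, jitter = 0) {
    n <- nrow(M)
    j <- jitter
    base <- 1e-6 * mean(diag(M))
    for (attempt in 0:7) {
        L <- tryCatch(chol(M + diag(j, n)), error = function(e) NULL)
        if (!is.null(L)) return(list(L = L, jitter = j))
        j <- if (j == 0) base else 2 * j
        if (attempt == 7)
            stop("covariance matrix not factorizable after jitter escalation")
    }
}

#' Analytic log marginal likelihood of a zero-mean GP
#'
#' Evaluates \code{log N(y | 0, K + noise * I)}, the marginal likelihood of
#' the observations after integrating out the latent function, where \code{K}
#' is the NN covariance over \code{X}.
#'
#' @param X augmented-input matrix (one row per observation).
#' @param y numeric targets (already centered).
#' @param hyper list with \code{l}, \code{sigma}, \code{noise}.
#' @return the scalar log marginal likelihood.
#' @export
logMarginalLikelihood <- function(X, y, hyper) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == length(y), length(y) >= 1)
    K <- covarianceMatrix(X, hyper)
    Ky <- K + diag(hyper$noise, nrow(K))
    cf <- cholSafe(Ky)
    L <- cf$L
    a <- backsolve(L, forwardsolve(t(L), y))
    -0.5 * sum(y * a) - sum(log(diag(L))) - 0.5 * length(y) * log(2 * pi)
}

## Fast internal kernel + gradient for inputs (1, s): returns K (no noise) and
## the list of dK/dtheta for theta = (log l_bias, log l_time, log sigma).
nnKernelGrad <- function(s, l0, l1, sigma) {
    v0 <- 1 / l0^2
    v1 <- 1 / l1^2
    U <- v0 + v1 * tcrossprod(s)
    p <- 1 + diag(U)
    sp <- sqrt(outer(p, p))
    R <- U / sp
    R[R > 1] <- 1; R[R < -1] <- -1
    K <- sigma * asin(R)
    dasin <- 1 / sqrt(pmax(1 - R^2, 1e-12))
    ip <- 1 / (2 * p)
    ## d r / d v0: (1 - u (1/(2Pi) + 1/(2Pj))) / sqrt(Pi Pj)
    dR0 <- (1 - U * outer(ip, ip, `+`)) / sp
    ## d r / d v1: (s_i s_j - u (s_i^2/(2Pi) + s_j^2/(2Pj))) / sqrt(Pi Pj)
    s2p <- s^2 * ip
    dR1 <- (tcrossprod(s) - U * outer(s2p, s2p, `+`)) / sp
    list(K = K,
         dK = list(l0 = sigma * dasin * dR0 * (-2 * v0),
                   l1 = sigma * dasin * dR1 * (-2 * v1),
                   sigma = K))
}

## Negative log marginal likelihood and gradient in
## theta = (log l0, log l1, log sigma, log(noise - floor)). The kernel and
## Cholesky state is memoized on theta, so the optimizer's separate value and
## gradient calls at the same point share one factorization.
negLogMLFactory <- function(s, y, noiseFloor) {
    n <- length(y)
    lastTheta <- NULL
    state <- NULL
    function(theta, grad = FALSE) {
        if (is.null(lastTheta) || !identical(theta, lastTheta)) {
            l0 <- exp(theta[1]); l1 <- exp(theta[2]); sigma <- exp(theta[3])
            noise <- noiseFloor + exp(theta[4])
            kg <- nnKernelGrad(s, l0, l1, sigma)
            Ky <- kg$K + diag(noise, n)
            cf <- tryCatch(cholSafe(Ky), error = function(e) NULL)
            if (is.null(cf)) {
                state <<- list(value = Inf, gradient = rep(0, 4))
            } else {
                L <- cf$L
                a <- backsolve(L, forwardsolve(t(L), y))
                nll <- 0.5 * sum(y * a) + sum(log(diag(L))) +
                    0.5 * n * log(2 * pi)
                state <<- list(value = nll, L = L, a = a, kg = kg,
                               gradient = NULL)
            }
            lastTheta <<- theta
        }
        if (grad && is.null(state$gradient) && is.finite(state$value)) {
            Kinv <- chol2inv(state$L)
            W <- tcrossprod(state$a) - Kinv   # d logML / dK = W / 2
            g <- vapply(state$kg$dK, function(D) -0.5 * sum(W * D),
                        numeric(1))
            gn <- -0.5 * sum(diag(W)) * exp(theta[4])
            state$gradient <<- c(unname(g), gn)
        }
        state
    }
}

#' Fit a GP to one data block by type-II maximum likelihood
#'
#' Targets are mean-centered, times scaled by \code{tmax} and bias-augmented,
#' and the three kernel hyperparameters plus the noise variance are optimized
#' on the log scale with analytic gradients, restarted from \code{nRestarts}
#' initial values (the first restart starts at a fixed midpoint, the rest at
#' log-uniform random draws). The restart with the largest optimized log
#' marginal likelihood wins. Fully deterministic given \code{seed}.
#'
#' @param times numeric observation times in hours (length >= 2; replicates
#'   are repeated times).
#' @param y numeric observations, same length as \code{times}.
#' @param nRestarts positive integer, number of optimizer restarts
#'   (default 10).
#' @param seed integer seed from which per-restart sub-seeds are derived.
#' @param tmax time-scaling constant; defaults to \code{max(times)} (pass the
#'   dataset-wide maximum when fitting blocks of a larger dataset).
#' @param centerValue value subtracted from the targets before fitting;
#'   defaults to \code{mean(y)}. When several blocks of one gene are compared
#'   as alternative hypotheses, all blocks must share one center (the gene
#'   mean), otherwise each extra block gains a free location parameter and
#'   the evidences are not comparable.
#' @return a [GPFit-class] object.
#' @export
fitGP <- function(times, y, nRestarts = 10, seed = 1, tmax = max(times),
                  centerValue = NULL) {
    stopifnot(length(times) == length(y), length(y) >= 2, nRestarts >= 1)
    keep <- !is.na(y)
    times <- times[keep]; y <- y[keep]
    if (length(y) < 2) stop("fewer than 2 non-missing observations")
    jf <- fitJointGP(list(times), list(y), nRestarts = nRestarts,
                     seed = seed, tmax = tmax, centerValue = centerValue)
    jf$fits[[1]]
}

## Joint type-II ML fit of one hypothesis: several independent data blocks
## (block-diagonal covariance) sharing ONE hyperparameter set. The evidence
## of the hypothesis is the summed block log marginal likelihoods at the
## shared optimum. With a single block this is an ordinary GP fit. Sharing
## one theta across blocks keeps the number of free hyperparameters equal
## across hypotheses, so evidence comparisons are not biased toward finer
## partitions by per-block hyperparameter re-estimation.
fitJointGP <- function(blockTimes, blockY, nRestarts = 10, seed = 1,
                       tmax = NULL, centerValue = NULL) {
    stopifnot(length(blockTimes) == length(blockY), length(blockY) >= 1,
              nRestarts >= 1)
    if (is.null(tmax)) tmax <- max(unlist(blockTimes))
    if (tmax <= 0) tmax <- 1
    yall <- unlist(blockY, use.names = FALSE)
    center <- if (is.null(centerValue) || stats::sd(yall) == 0) mean(yall)
              else centerValue
    ycs <- lapply(blockY, function(y) y - center)
    oneBlock <- length(blockY) == 1
    makeFits <- function(hyper, blockLml, restartVals) {
        fits <- mapply(function(tt, yc, lml)
            new("GPFit", times = tt, y = yc, center = center, tmax = tmax,
                hyper = hyper, logMarginal = lml,
                ## a single-block fit records the full restart trace; blocks
                ## of a joint fit have no restart trace of their own
                restartLogMarginals = if (oneBlock) restartVals else lml),
            blockTimes, ycs, blockLml, SIMPLIFY = FALSE)
        list(logMarginal = sum(blockLml), hyper = hyper, fits = fits,
             restartLogMarginals = restartVals)
    }
    vy <- stats::var(unlist(ycs, use.names = FALSE))
    if (!is.finite(vy) || vy < .Machine$double.eps) {
        ## constant data: zero-signal model, noise pinned at a tiny floor
        hyper <- c(l_bias = 0.5, l_time = 0.5, sigma = 1e-300, noise = 1e-12)
        lmlB <- vapply(ycs, function(y)
            -0.5 * length(y) * log(2 * pi * 1e-12), numeric(1))
        return(makeFits(hyper, lmlB, sum(lmlB)))
    }
    noiseFloor <- 1e-6 * vy
    objs <- mapply(function(tt, yc) negLogMLFactory(tt / tmax, yc,
                                                    noiseFloor),
                   blockTimes, ycs, SIMPLIFY = FALSE)
    fn <- function(th) sum(vapply(objs, function(o) o(th)$value,
                                  numeric(1)))
    gr <- function(th) Reduce(`+`, lapply(objs, function(o)
        o(th, grad = TRUE)$gradient))
    best <- NULL
    restartVals <- rep(NA_real_, nRestarts)
    for (r in seq_len(nRestarts)) {
        if (r == 1) {
            init <- c(log(0.5), log(0.5), log(vy), log(0.1 * vy))
        } else {
            set.seed(deriveSeed(seed, 7L, r))
            init <- c(stats::runif(2, log(0.05), log(5)),
                      log(vy) + stats::runif(1, log(0.1), log(10)),
                      log(vy) + stats::runif(1, log(0.01), log(1)))
        }
        opt <- tryCatch(
            stats::optim(init, fn, gr, method = "BFGS",
                         control = list(maxit = 200, reltol = 1e-6)),
            error = function(e) NULL)
        if (is.null(opt) || !is.finite(opt$value)) next
        restartVals[r] <- -opt$value
        if (is.null(best) || -opt$value > best$value) {
            best <- list(value = -opt$value, par = opt$par)
        }
    }
    if (is.null(best))
        stop("all optimizer restarts failed for this data block")
    th <- best$par
    hyper <- c(l_bias = exp(th[1]), l_time = exp(th[2]),
               sigma = exp(th[3]), noise = noiseFloor + exp(th[4]))
    lmlB <- vapply(objs, function(o) -o(th)$value, numeric(1))
    makeFits(hyper, lmlB, restartVals[is.finite(restartVals)])
}

gpHyperList <- function(fit) {
    list(l = unname(fit@hyper[c("l_bias", "l_time")]),
         sigma = unname(fit@hyper[["sigma"]]),
         noise = unname(fit@hyper[["noise"]]))
}

#' Posterior predictive mean and variance of a fitted GP
#'
#' Standard GP predictive equations on a time grid; the returned variance is
#' that of the latent function (observation noise excluded), matching the
#' 95 percent bands drawn by [plotProfiles()].
#'
#' @param fit a [GPFit-class] from [fitGP()].
#' @param t_grid numeric vector of prediction times in hours.
#' @return a list with \code{time}, \code{mean} (re-shifted by the training
#'   mean) and \code{variance} (strictly positive).
#' @export
posteriorPredict <- function(fit, t_grid) {
    stopifnot(is(fit, "GPFit"), length(t_grid) >= 1)
    hyper <- gpHyperList(fit)
    Xtr <- augmentTimes(fit@times, fit@tmax)
    Xte <- augmentTimes(t_grid, fit@tmax)
    K <- covarianceMatrix(Xtr, hyper)
    Ky <- K + diag(hyper$noise, nrow(K))
    cf <- cholSafe(Ky)
    L <- cf$L
    w <- 1 / hyper$l^2
    XwTr <- sweep(Xtr, 2, sqrt(w), `*`)
    XwTe <- sweep(Xte, 2, sqrt(w), `*`)
    ptr <- 1 + rowSums(XwTr^2)
    pte <- 1 + rowSums(XwTe^2)
    Rst <- tcrossprod(XwTr, XwTe) / sqrt(outer(ptr, pte))
    Rst[Rst > 1] <- 1; Rst[Rst < -1] <- -1
    Kst <- hyper$sigma * asin(Rst)               # train x test
    kss <- hyper$sigma * asin(rowSums(XwTe^2) / pte)
    a <- backsolve(L, forwardsolve(t(L), fit@y))
    mu <- drop(crossprod(Kst, a)) + fit@center
    V <- forwardsolve(t(L), Kst)
    varf <- pmax(kss - colSums(V^2), 1e-12)
    list(time = as.numeric(t_grid), mean = mu, variance = varf)
}
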