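# Exact Gaussian-process regression with a kernel tailored to normative
# growth modeling:
#
#   k(x, x') = sf^2 * exp(-(a - a')^2 / (2 l^2))  +  sl^2 * (x . x')  +  sn^2 I
#
# where a is standardized age (first input column) and the linear term runs
# over all input columns (age + binary sex), giving smooth nonlinear age
# effects plus an additive sex offset. Hyperparameters are optimized by
# maximizing the log marginal likelihood (type-II ML) with analytic
# gradients and random restarts. The learned white-noise sd sn supplies the
# normative variance; the posterior latent sd (excluding the noise term)
# supplies the predictive uncertainty. These are kept separate because the
# deviation z-score combines them as independent variance components.

gpr_nll_factory <- function(X, y, jitter) {
  n <- length(y)
  D2 <- outer(X[, 1], X[, 1], `-`)^2
  XX <- tcrossprod(X)
  I <- diag(n)
  cache <- new.env(parent = emptyenv())
  compute <- function(theta) {
    key <- paste(format(theta, digits = 17), collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    sf2 <- exp(2 * theta[1]); ell2 <- exp(2 * theta[2])
    sl2 <- exp(2 * theta[3]); sn2 <- exp(2 * theta[4])
    Krbf <- sf2 * exp(-D2 / (2 * ell2))
    K <- Krbf + sl2 * XX + (sn2 + jitter) * I
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) {
      val <- list(nll = 1e10, grad = rep(0, 4))
    } else {
      alpha <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
      nll <- 0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
      Kinv <- chol2inv(ch)
      A <- tcrossprod(alpha) - Kinv     # d(logL)/dtheta = 0.5 tr(A dK)
      g <- c(-sum(A * Krbf),                       # 2 * 0.5 * sf2-scaled
             -0.5 * sum(A * (Krbf * (D2 / ell2))),
             -sum(A * XX) * sl2,
             -sum(diag(A)) * sn2)
      val <- list(nll = nll, grad = g)
    }
    cache$key <- key; cache$val <- val
    val
  }
  compute
}

# Fit hyperparameters for one region. X: n x d inputs (standardized age
# first); y: standardized response. Returns theta (log sf, log l, log sl,
# log sn) plus the achieved negative log marginal likelihood.
gpr_fit <- function(X, y, n_restarts = 5, seed = 1, jitter = 1e-8,
                    maxit = 100) {
  compute <- gpr_nll_factory(X, y, jitter)
  fn <- function(th) compute(th)$nll
  gr <- function(th) compute(th)$grad
  sy <- max(sd(y), 1e-3)
  starts <- list(log(c(sy, 1, 0.3, 0.5 * sy)))
  if (n_restarts > 1) {
    extra <- with_seed(seed, replicate(n_restarts - 1, c(
      runif(1, log(0.2), log(2)), runif(1, log(0.3), log(3)),
      runif(1, log(0.05), log(1.5)), runif(1, log(0.1), log(1))),
      simplify = FALSE))
    starts <- c(starts, extra)
  }
  lower <- c(log(1e-3), log(0.05), log(1e-4), log(1e-3))
  upper <- rep(log(1e3), 4)
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      optim(st, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("GP hyperparameter optimization failed")
  list(theta = best$par, nll = best$value, jitter = jitter)
}

# Posterior predictive mean and latent (noise-free) sd at new inputs.
gpr_predict <- function(fit, X, y, Xnew) {
  theta <- fit$theta
  sf2 <- exp(2 * theta[1]); ell2 <- exp(2 * theta[2])
  sl2 <- exp(2 * theta[3]); sn2 <- exp(2 * theta[4])
  n <- length(y)
  D2 <- outer(X[, 1], X[, 1], `-`)^2
  K <- sf2 * exp(-D2 / (2 * ell2)) + sl2 * tcrossprod(X) +
    (sn2 + fit$jitter) * diag(n)
  ch <- chol(K)
  alpha <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  d2s <- outer(Xnew[, 1], X[, 1], `-`)^2
  Ks <- sf2 * exp(-d2s / (2 * ell2)) + sl2 * tcrossprod(Xnew, X)
  mean <- drop(Ks %*% alpha)
  v <- backsolve(ch, t(Ks), transpose = TRUE)
  kss <- sf2 + sl2 * rowSums(Xnew^2)
  var_latent <- pmax(kss - colSums(v^2), 0)
  list(mean = mean, sd_latent = sqrt(var_latent), sd_noise = sqrt(sn2))
}
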