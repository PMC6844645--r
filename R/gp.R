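#' Variance-stabilizing transform for midpoint counts
#'
#' `y = log(alpha * m + beta)` with defaults `alpha = 1000`, `beta = 1`,
#' chosen so that zero signal maps to zero and metaplot-scale rates (counts
#' per bp per site, typically well below 1) are lifted into a numerically
#' comfortable range before assuming a Gaussian likelihood.
#'
#' @param m non-negative signal (counts per bp).
#' @param alpha,beta transform parameters.
#' @return transformed values `y`.
#' @export
transform_signal <- function(m, alpha = 1000, beta = 1) {
  if (any(m < 0)) stop("negative input to transform")
  log(alpha * m + beta)
}

#' @rdname transform_signal
#' @param y transformed values.
#' @export
inverse_transform <- function(y, alpha = 1000, beta = 1) {
  (exp(y) - beta) / alpha
}

se_kernel <- function(x1, x2, sigma_f2, lengthscale) {
  d <- outer(x1, x2, "-")
  sigma_f2 * exp(-0.5 * d * d / lengthscale^2)
}

#' Exact log marginal likelihood of a dense squared-exponential GP
#'
#' Used as the reference against which the sparse variational bound is
#' checked (the bound can never exceed it).
#'
#' @param x,y training inputs / (centered) outputs.
#' @param sigma_f2 signal variance.
#' @param lengthscale kernel lengthscale, bp.
#' @param sigma_n2 noise variance.
#' @return log marginal likelihood (scalar).
#' @export
gp_log_marginal <- function(x, y, sigma_f2, lengthscale, sigma_n2) {
  n <- length(x)
  K <- se_kernel(x, x, sigma_f2, lengthscale)
  diag(K) <- diag(K) + sigma_n2
  U <- chol(K)
  a <- backsolve(U, forwardsolve(t(U), y))
  -0.5 * sum(y * a) - sum(log(diag(U))) - 0.5 * n * log(2 * pi)
}

#' Dense GP posterior prediction
#'
#' @inheritParams gp_log_marginal
#' @param xstar prediction inputs.
#' @return list with `mean` and `var` (latent, noise-free) at `xstar`.
#' @export
gp_dense_predict <- function(x, y, sigma_f2, lengthscale, sigma_n2, xstar) {
  K <- se_kernel(x, x, sigma_f2, lengthscale)
  diag(K) <- diag(K) + sigma_n2
  U <- chol(K)
  Ks <- se_kernel(xstar, x, sigma_f2, lengthscale)
  a <- backsolve(U, forwardsolve(t(U), y))
  V <- backsolve(U, forwardsolve(t(U), t(Ks)))
  list(mean = as.numeric(Ks %*% a),
       var = pmax(sigma_f2 - colSums(t(Ks) * V), 0))
}

# Titsias collapsed variational lower bound and its analytic gradient,
# parameterized by u = log(c(sigma_f2, lengthscale, sigma_n2)).
# All quantities are O(n m^2); no n x n matrix is formed.
sparse_gp_objective <- function(u, x, y, z) {
  sf2 <- exp(u[1L]); l <- exp(u[2L]); sn2 <- exp(u[3L])
  n <- length(x); m <- length(z)
  Dnm <- outer(x, z, "-"); Dnm2 <- Dnm * Dnm
  Dmm <- outer(z, z, "-"); Dmm2 <- Dmm * Dmm
  Knm <- sf2 * exp(-0.5 * Dnm2 / l^2)
  Kmm <- sf2 * exp(-0.5 * Dmm2 / l^2)
  diag(Kmm) <- diag(Kmm) + 1e-8 * sf2 + 1e-12
  U <- chol(Kmm)                       # Kmm = t(U) %*% U
  A <- forwardsolve(t(U), t(Knm))      # m x n
  B <- tcrossprod(A)                   # A A'
  diag(B) <- diag(B) + sn2
  UB <- chol(B)
  c_vec <- A %*% y
  Binv_c <- backsolve(UB, forwardsolve(t(UB), c_vec))
  yGy <- (sum(y * y) - sum(c_vec * Binv_c)) / sn2
  logdetG <- (n - m) * log(sn2) + 2 * sum(log(diag(UB)))
  trKnn <- n * sf2
  trQnn <- sum(A * A)
  F1 <- -0.5 * (n * log(2 * pi) + logdetG + yGy)
  F2 <- -(trKnn - trQnn) / (2 * sn2)
  value <- F1 + F2

  # shared gradient quantities
  P <- backsolve(U, A)                 # Kmm^{-1} Kmn,  m x n
  v <- (y - crossprod(A, Binv_c)) / sn2            # G^{-1} y,  n
  Pt <- t(P)                                       # n x m
  APt <- A %*% Pt                                  # m x m
  W <- (Pt - crossprod(A, backsolve(UB, forwardsolve(t(UB), APt)))) / sn2
  Tm <- P %*% W                                    # m x m
  a_vec <- P %*% v                                 # m
  PPt <- tcrossprod(P)                             # m x m

  grad_kernel <- function(dKnm, dKmm, dknn_sum) {
    quad <- 2 * sum(v * (dKnm %*% a_vec)) -
      as.numeric(crossprod(a_vec, dKmm %*% a_vec))
    trace <- 2 * sum(W * dKnm) - sum(Tm * dKmm)
    dF1 <- 0.5 * quad - 0.5 * trace
    dtrQ <- 2 * sum(Pt * dKnm) - sum(PPt * dKmm)
    dF2 <- -(dknn_sum - dtrQ) / (2 * sn2)
    dF1 + dF2
  }
  # d/d sigma_f2: dK = K / sf2 (jitter term negligible)
  g_sf2 <- grad_kernel(Knm / sf2, (Kmm - diag(1e-8 * sf2 + 1e-12, m)) / sf2,
                       n)
  # d/d lengthscale: dK = K * D^2 / l^3
  g_l <- grad_kernel(Knm * Dnm2 / l^3,
                     sf2 * exp(-0.5 * Dmm2 / l^2) * Dmm2 / l^3, 0)
  # d/d sigma_n2
  trGinv <- (n - m + sn2 * sum(diag(chol2inv(UB)))) / sn2
  g_sn2 <- 0.5 * sum(v * v) - 0.5 * trGinv +
    (trKnn - trQnn) / (2 * sn2^2)
  grad <- c(g_sf2 * sf2, g_l * l, g_sn2 * sn2)   # chain rule to log scale
  list(value = value, grad = grad)
}

#' Fit a sparse variational squared-exponential GP
#'
#' Maximizes the collapsed variational lower bound on the marginal
#' likelihood (inducing-point sparse GP regression) with analytic
#' gradients and L-BFGS-B, multi-start. Inducing inputs are fixed on a
#' regular grid (`inducing_spacing` bp) over the training interval(s).
#' Hyperparameters are optimized only on data inside `intervals` (a single
#' interval or a union, e.g. to mask a region of non-stationary covariance
#' around the anchor), but predictions may be made anywhere.
#'
#' The observed signal is centered before fitting (zero-mean GP prior);
#' predictions revert to the data mean far from support.
#'
#' @param x input positions (bp).
#' @param y transformed signal at `x` (see [transform_signal()]).
#' @param intervals list of closed intervals `c(lo, hi)` defining the
#'   training support (default the full range of `x`).
#' @param inducing_spacing spacing of the inducing-input grid, bp.
#' @param restarts number of optimizer starts (first from the default
#'   initialization `sigma_f2 = var(y)`, `lengthscale = 50`,
#'   `sigma_n2 = 0.1 var(y)`; the rest perturbed, seeded).
#' @param seed RNG seed for restart perturbations.
#' @param maxit L-BFGS-B iteration cap per start.
#' @param alpha,beta transform parameters recorded for back-transformation.
#' @return object of class `gp_fit`: hyperparameters (`sigma_f2`,
#'   `lengthscale`, `sigma_n2`), `elbo`, `inducing`, training data,
#'   `y_mean`, `converged` flag.
#' @export
fit_gp <- function(x, y, intervals = NULL, inducing_spacing = 10,
                   restarts = 3L, seed = 1L, maxit = 200L,
                   alpha = 1000, beta = 1) {
  stopifnot(length(x) == length(y))
  if (is.null(intervals)) intervals <- list(range(x))
  if (!is.list(intervals)) intervals <- list(intervals)
  mask <- Reduce(`|`, lapply(intervals, function(iv) x >= iv[1L] &
                               x <= iv[2L]))
  xt <- x[mask]
  yt <- y[mask]
  if (length(xt) < 20L) stop("fewer than 20 training points in interval")
  y_mean <- mean(yt)
  yc <- yt - y_mean
  z <- unlist(lapply(intervals, function(iv)
    seq(iv[1L], iv[2L], by = inducing_spacing)))
  z <- sort(unique(z))
  vy <- var(yc)
  if (vy <= .Machine$double.eps) {
    # constant signal: degenerate fit, posterior mean = the constant
    fit <- list(sigma_f2 = 1e-12, lengthscale = 50, sigma_n2 = 1e-12,
                elbo = NA_real_, inducing = z, x = xt, y = yt,
                y_mean = y_mean, converged = TRUE, degenerate = TRUE,
                alpha = alpha, beta = beta)
    class(fit) <- "gp_fit"
    return(fit)
  }
  init0 <- log(c(vy, 50, 0.1 * vy))
  lower <- c(log(vy) - 20, log(2), log(vy) - 20)
  upper <- c(log(vy) + 10, log(2000), log(vy) + 10)
  best <- NULL
  set.seed(seed)
  for (r in seq_len(restarts)) {
    init <- if (r == 1L) init0 else init0 + rnorm(3L, 0, 0.7)
    init <- pmin(pmax(init, lower), upper)
    opt <- tryCatch(
      optim(init,
            fn = function(u) -sparse_gp_objective(u, xt, yc, z)$value,
            gr = function(u) -sparse_gp_objective(u, xt, yc, z)$grad,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) stop("sparse GP optimization failed in all restarts")
  th <- exp(best$par)
  fit <- list(sigma_f2 = th[1L], lengthscale = th[2L], sigma_n2 = th[3L],
              elbo = -best$value, inducing = z, x = xt, y = yt,
              y_mean = y_mean, converged = best$convergence == 0,
              degenerate = FALSE, alpha = alpha, beta = beta)
  if (!fit$converged) {
    warning("sparse GP optimizer did not report convergence; best bound kept")
  }
  class(fit) <- "gp_fit"
  fit
}

#' Sparse GP variational bound at the fitted hyperparameters
#'
#' @param fit a [fit_gp()] object.
#' @return the collapsed variational lower bound (on centered data).
#' @export
gp_elbo <- function(fit) fit$elbo

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf(
    "sparse GP fit: sigma_f2 = %.4g, lengthscale = %.4g bp, sigma_n2 = %.4g\n",
    x$sigma_f2, x$lengthscale, x$sigma_n2))
  cat(sprintf("  %d training points, %d inducing inputs, ELBO = %.3f\n",
              length(x$x), length(x$inducing), x$elbo))
  invisible(x)
}

#' Posterior prediction from a sparse GP fit
#'
#' @param object a [fit_gp()] object.
#' @param xstar prediction positions.
#' @param ... unused.
#' @return list with `mean` and `var` of the latent function on the
#'   transformed scale (data mean added back).
#' @export
predict.gp_fit <- function(object, xstar, ...) {
  if (isTRUE(object$degenerate)) {
    return(list(mean = rep(object$y_mean, length(xstar)),
                var = rep(0, length(xstar))))
  }
  sf2 <- object$sigma_f2; l <- object$lengthscale; sn2 <- object$sigma_n2
  x <- object$x; yc <- object$y - object$y_mean; z <- object$inducing
  m <- length(z)
  Kmm <- se_kernel(z, z, sf2, l)
  diag(Kmm) <- diag(Kmm) + 1e-8 * sf2 + 1e-12
  U <- chol(Kmm)
  A <- forwardsolve(t(U), se_kernel(z, x, sf2, l))
  B <- tcrossprod(A)
  diag(B) <- diag(B) + sn2
  UB <- chol(B)
  c_vec <- A %*% yc
  Ksz <- se_kernel(xstar, z, sf2, l)
  Ls <- forwardsolve(t(U), t(Ksz))          # m x n*
  mean_star <- crossprod(Ls, backsolve(UB, forwardsolve(t(UB), c_vec)))
  # var = k** - K*z Kmm^{-1} Kz* + sn2 * || UB^{-T} L* ||^2 terms
  Qss <- colSums(Ls * Ls)
  Hs <- forwardsolve(t(UB), Ls)
  var_star <- pmax(sf2 - Qss + sn2 * colSums(Hs * Hs), 0)
  list(mean = as.numeric(mean_star) + object$y_mean, var = var_star)
}

#' Back-transformed posterior median profile
#'
#' Inverts the variance-stabilizing transform at the posterior mean; since
#' the transform is monotone, this is the posterior median of the signal.
#'
#' @param fit a [fit_gp()] object.
#' @param xstar prediction positions.
#' @return numeric vector of median signal estimates (small negative values
#'   are possible and reported as-is).
#' @export
predict_median <- function(fit, xstar) {
  pr <- predict(fit, xstar)
  inverse_transform(pr$mean, fit$alpha, fit$beta)
}

#' Spectral density of the fitted squared-exponential kernel
#'
#' `S(s) = sigma_f2 * sqrt(2 pi l^2) * exp(-2 pi^2 s^2 l^2)` evaluated at
#' `s = 1/period`; the default period of 180 bp corresponds to one
#' nucleosome plus linker, so a large value indicates strong phasing at
#' nucleosomal periodicity.
#'
#' @param fit a [fit_gp()] object (or any list with `sigma_f2` and
#'   `lengthscale`).
#' @param period period in bp at which to evaluate (s = 1/period).
#' @param log10 return log10(S) (default) or S.
#' @return scalar spectral density.
#' @export
spectral_density <- function(fit, period = 180, log10 = TRUE) {
  s <- 1 / period
  # evaluated in log space so long lengthscales cannot underflow to zero
  logS <- log(fit$sigma_f2) + 0.5 * log(2 * pi * fit$lengthscale^2) -
    2 * pi^2 * s^2 * fit$lengthscale^2
  if (log10) logS / log(10) else exp(logS)
}

#' Profile similarity R-squared
#'
#' Squared Pearson correlation between two equal-length metaplot vectors
#' (`method = "pearson"`), or the regression-style
#' `1 - SS_res / SS_tot` of `profile` against `control`
#' (`method = "ss"`).
#'
#' @param profile,control numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"ss"`.
#' @return scalar R-squared.
#' @export
profile_r2 <- function(profile, control, method = c("pearson", "ss")) {
  method <- match.arg(method)
  stopifnot(length(profile) == length(control))
  if (sd(profile) == 0 || sd(control) == 0) {
    stop("zero-variance input to profile_r2")
  }
  if (method == "pearson") {
    cor(profile, control)^2
  } else {
    1 - sum((profile - control)^2) / sum((profile - mean(profile))^2)
  }
}

#' Smooth a metaplot with the GP model
#'
#' Convenience wrapper: applies the variance-stabilizing transform to a
#' metaplot, fits the sparse GP over `intervals`, and returns the
#' back-transformed posterior median over the full offset range.
#'
#' @param mp metaplot data.frame (`offset`, `value`) from [metaplot()].
#' @param intervals training interval(s); default `c(-500, 500)`.
#' @param ... passed to [fit_gp()].
#' @return list with `fit` (the `gp_fit`) and `median` data.frame
#'   (`offset`, `value`).
#' @export
smooth_metaplot <- function(mp, intervals = list(c(-500, 500)), ...) {
  y <- transform_signal(mp$value)
  fit <- fit_gp(mp$offset, y, intervals = intervals, ...)
  med <- predict_median(fit, mp$offset)
  list(fit = fit, median = data.frame(offset = mp$offset, value = med))
}
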